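#' Read a pipeline configuration file
#'
#' YAML key-value configuration. Recognized keys: `focal_expression`
#' (path), `units` (`rpkm`/`counts`), `gene_lengths`, `library_sizes`
#' (paths, required for counts), `tissue_scheme` (map group -> sample
#' list), `criteria` (`high`, `low`), `evalue_max`, `high_fraction`,
#' `species` (list of maps with `name`, `blast`, `expression`, optional
#' `tissue_of`), `clustering` (`method`, `metric`), `min_edge`, `qpcr`
#' (path, optional), `annotation` (path, optional), `sep`.
#' Every threshold defaults to its standard value (high 1, low 0.5,
#' e-value 1e-5, high fraction 0.8, alpha 0.05).
#'
#' @param path path to a YAML file.
#' @return A named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

default_config <- function(cfg) {
  cfg$units <- cfg$units %||% "rpkm"
  cfg$criteria <- cfg$criteria %||% list()
  cfg$criteria$high <- cfg$criteria$high %||% 1
  cfg$criteria$low <- cfg$criteria$low %||% 0.5
  cfg$evalue_max <- cfg$evalue_max %||% 1e-5
  cfg$high_fraction <- cfg$high_fraction %||% 0.8
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$min_edge <- cfg$min_edge %||% 0
  cfg$clustering <- cfg$clustering %||% list()
  cfg$clustering$method <- cfg$clustering$method %||% "complete"
  cfg$clustering$metric <- cfg$clustering$metric %||% "euclidean"
  cfg$sep <- cfg$sep %||% "\t"
  cfg
}

#' Left-join an annotation mapping onto a gene table
#'
#' Terms for each gene are concatenated with `"; "`, de-duplicated in first
#' appearance order; genes without terms keep an empty annotation field and
#' are never dropped.
#'
#' @param genes data.frame with a `gene_id` column.
#' @param mapping two-column data.frame (gene_id, term) or path to a
#'   two-column delimited file with a header.
#' @param sep delimiter when `mapping` is a path.
#' @return `genes` with an added `annotation` column.
#' @export
annotate_genes <- function(genes, mapping, sep = "\t") {
  if (is.character(mapping)) {
    lines <- readLines(mapping)
    body <- lines[-1L][nzchar(lines[-1L])]
    fields <- strsplit(body, sep, fixed = TRUE)
    bad <- which(lengths(fields) != 2L)
    if (length(bad))
      fail(sprintf("malformed annotation line %d: '%s'", bad[1L] + 1L,
                   body[bad[1L]]))
    mapping <- data.frame(gene_id = vapply(fields, `[[`, "", 1L),
                          term = vapply(fields, `[[`, "", 2L),
                          stringsAsFactors = FALSE)
  }
  terms <- lapply(split(mapping$term, mapping$gene_id),
                  function(t) paste(unique(t), collapse = "; "))
  genes$annotation <- vapply(genes$gene_id, function(g)
    terms[[g]] %||% "", character(1L))
  genes
}

#' Run the full cross-species comparison pipeline
#'
#' Reads the focal expression matrix (converting counts to RPKM if
#' needed), calls TSGs, consolidates BLAST hits per target species,
#' computes the homology breakdown and per-species similarity matrices,
#' clusters homolog profiles, exports the similarity network, and — when
#' Ct data are supplied — runs the qRT-PCR testing workflow. Outputs are
#' written with stable file names; any stage failure aborts with the stage
#' named and removes partial outputs. Re-running with unchanged inputs
#' reproduces the bundle byte for byte.
#'
#' @param config a `pipeline_config` (or list, or path to a YAML file).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list of class `tissuesim_run` with the in-memory
#'   results (`tsgs`, `map`, `breakdown`, `similarity`, `clusters`,
#'   `network`, `qpcr`) and `files` (paths written).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- default_config(config)
  for (f in c(cfg$focal_expression, cfg$qpcr, cfg$annotation,
              vapply(cfg$species, `[[`, "", "blast"),
              vapply(cfg$species, `[[`, "", "expression"))) {
    if (!is.null(f) && !file.exists(f))
      fail("input file does not exist: ", f)
  }
  stage <- "setup"
  log <- c(sprintf("tissuesim %s", as.character(utils::packageVersion("tissuesim"))),
           sprintf("thresholds: high=%g low=%g evalue_max=%g high_fraction=%g alpha=%g",
                   cfg$criteria$high, cfg$criteria$low, cfg$evalue_max,
                   cfg$high_fraction, cfg$alpha))
  staging <- tempfile("tissuesim_run_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  files <- character()
  emit <- function(name) file.path(staging, name)

  result <- tryCatch({
    stage <- "expression"
    expr <- read_expression_table(cfg$focal_expression, units = cfg$units,
                                  sep = cfg$sep)
    if (expr_units(expr) == "counts") {
      expr <- counts_to_rpkm(expr,
                             read_id_value_table(cfg$gene_lengths, cfg$sep),
                             read_id_value_table(cfg$library_sizes, cfg$sep))
    }
    log <- c(log, sprintf("genes read: %d over %d samples", nrow(expr), ncol(expr)))

    stage <- "tsg_calling"
    scheme <- tissue_scheme(cfg$tissue_scheme)
    crit <- tsg_criteria(cfg$criteria$high, cfg$criteria$low)
    tsgs <- call_tsgs(expr, scheme, crit)
    write_tsg_table(tsgs, emit("tsg_calls.tsv"))
    files <- c(files, "tsg_calls.tsv")
    log <- c(log, sprintf("TSGs called: %d", nrow(tsgs)))

    stage <- "homology"
    hits <- lapply(cfg$species, function(sp)
      read_blast_tabular(sp$blast, sp$name))
    map <- best_hits(hits, evalue_max = cfg$evalue_max)
    log <- c(log, sprintf("hits read: %d; best hits kept: %d",
                          sum(vapply(hits, nrow, 0L)), nrow(map)))
    sp_names <- vapply(cfg$species, `[[`, "", "name")
    breakdown <- homology_breakdown(tsgs, map, sp_names[1L],
                                    if (length(sp_names) > 1L) sp_names[2L]
                                    else "(none)")
    write_breakdown_table(breakdown, emit("homology_breakdown.tsv"))
    files <- c(files, "homology_breakdown.tsv")

    stage <- "similarity"
    sims <- list()
    clusters <- list()
    for (sp in cfg$species) {
      target <- read_expression_table(sp$expression, sep = cfg$sep)
      tissue_of <- if (!is.null(sp$tissue_of)) unlist(sp$tissue_of) else NULL
      sim <- similarity_matrix(tsgs, map, target, sp$name,
                               tissue_of = tissue_of,
                               high_fraction = cfg$high_fraction)
      sims[[sp$name]] <- sim
      fn <- sprintf("similarity_%s.tsv", sp$name)
      write_similarity_table(sim, emit(fn))
      files <- c(files, fn)
      log <- c(log, sprintf(
        "%s: %d homolog profiles, %d unresolvable dropped, %d degenerate excluded",
        sp$name, sum(sim$n), sum(sim$dropped), sum(sim$degenerate)))
      sp_map <- map[map$species == sp$name, , drop = FALSE]
      subj <- intersect(sp_map$subject_id[sp_map$query_id %in% tsgs$gene_id],
                        rownames(target))
      if (length(subj) >= 2L) {
        norm <- minmax_normalize(unclass(target)[subj, , drop = FALSE])
        cl <- cluster_profiles(norm$values[!norm$degenerate, , drop = FALSE],
                               method = cfg$clustering$method,
                               metric = cfg$clustering$metric)
        clusters[[sp$name]] <- cl
        fn <- sprintf("cluster_order_%s.tsv", sp$name)
        utils::write.table(cl$leaf_ranks, emit(fn), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        files <- c(files, fn)
      }
    }

    stage <- "network"
    net <- export_network(sims, min_edge = cfg$min_edge)
    write_network(net, emit("network_edges.tsv"))
    files <- c(files, "network_edges.tsv", "network_edges.tsv.nodes")

    stage <- "qpcr"
    qpcr <- NULL
    if (!is.null(cfg$qpcr)) {
      qpcr <- qpcr_workflow(read_qpcr_table(cfg$qpcr, sep = cfg$sep),
                            alpha = cfg$alpha)
      utils::write.table(qpcr_report_table(qpcr), emit("qpcr_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, "qpcr_report.tsv")
      log <- c(log, sprintf("qPCR genes tested: %d", length(qpcr)))
    }

    stage <- "annotation"
    if (!is.null(cfg$annotation)) {
      ann <- annotate_genes(as.data.frame(tsgs), cfg$annotation, sep = cfg$sep)
      utils::write.table(ann, emit("tsg_calls_annotated.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, "tsg_calls_annotated.tsv")
    }

    list(tsgs = tsgs, map = map, breakdown = breakdown, similarity = sims,
         clusters = clusters, network = net, qpcr = qpcr)
  }, error = function(e) {
    fail(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })

  writeLines(log, emit("run_log.txt"))
  files <- c(files, "run_log.txt")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ok <- file.copy(file.path(staging, files), file.path(out_dir, files),
                  overwrite = TRUE)
  if (!all(ok)) fail("could not write outputs to ", out_dir)
  result$files <- file.path(out_dir, files)
  invisible(structure(result, class = "tissuesim_run"))
}

#' @export
print.tissuesim_run <- function(x, ...) {
  cat("tissuesim pipeline run\n")
  cat(sprintf("  TSGs called: %d\n", nrow(x$tsgs)))
  cat(sprintf("  species: %s\n", paste(names(x$similarity), collapse = ", ")))
  cat(sprintf("  outputs: %d files\n", length(x$files)))
  invisible(x)
}
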