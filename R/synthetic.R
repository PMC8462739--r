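# Synthetic data with planted ground truth. The generators emulate the
# statistical shape the analysis assumes -- a focal species assayed over ~9
# tissue groups with strictly tissue-specific genes, target species with
# tissue-biased homolog expression, and qPCR replicates against a
# constitutive reference -- not read-level sequencing data.

# deterministic per-component seeding below 2^31
derive_seed <- function(seed, offset) (as.integer(seed) + 104729L * offset) %% 2147483647L

#' Generate a focal-species RPKM matrix with planted TSGs
#'
#' Planted TSGs draw in-group RPKM from Uniform(2, 50) and out-of-group
#' RPKM from Uniform(0, 0.4), clearing the default calling thresholds
#' (high 1, low 0.5) with a factor-of-two margin on both sides so calling
#' recovers them exactly. Background genes are log-normal across all
#' samples, with 10% forced into a broadly expressed regime (> 1
#' everywhere); any background draw that would itself satisfy the strict
#' TSG rule is redrawn, so the planted labels are the complete truth.
#'
#' @param n_genes total number of genes.
#' @param scheme a [tissue_scheme()].
#' @param n_tsg_per_group integer, or named integer vector per group.
#' @param seed integer seed; output is deterministic given the seed.
#' @return List with `matrix` (an [expr_matrix()], RPKM) and `truth`
#'   (list: `tsg` data.frame of `gene_id`, `group_label`; `seed`).
#' @export
generate_focal_expression <- function(n_genes, scheme, n_tsg_per_group,
                                      seed = 1L) {
  if (length(n_tsg_per_group) == 1L && is.null(names(n_tsg_per_group)))
    n_tsg_per_group <- stats::setNames(rep(n_tsg_per_group, length(scheme)),
                                       names(scheme))
  n_tsg_per_group <- n_tsg_per_group[names(scheme)]
  if (anyNA(n_tsg_per_group)) fail("n_tsg_per_group must cover every group")
  n_tsg <- sum(n_tsg_per_group)
  if (n_tsg > n_genes) fail("more TSGs requested than genes")
  set.seed(derive_seed(seed, 1L))
  samples <- unlist(scheme, use.names = FALSE)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  vals <- matrix(0, n_genes, length(samples),
                 dimnames = list(gene_ids, samples))
  tsg_rows <- sample.int(n_genes, n_tsg)
  labels <- rep(names(scheme), n_tsg_per_group)
  for (k in seq_along(tsg_rows)) {
    i <- tsg_rows[k]
    members <- scheme[[labels[k]]]
    vals[i, ] <- stats::runif(length(samples), 0, 0.4)
    vals[i, members] <- stats::runif(length(members), 2, 50)
  }
  bg_rows <- setdiff(seq_len(n_genes), tsg_rows)
  n_broad <- floor(0.1 * length(bg_rows))
  broad <- bg_rows[seq_len(n_broad)]
  for (i in broad) vals[i, ] <- stats::runif(length(samples), 1.5, 30)
  rest <- setdiff(bg_rows, broad)
  crit <- tsg_criteria()
  is_tsg_row <- function(v) {
    gm <- vapply(scheme, function(m) max(v[m]), 0)
    any(vapply(seq_along(scheme), function(gi) {
      gm[gi] > crit$high &&
        max(v[setdiff(samples, scheme[[gi]])]) < crit$low
    }, logical(1L)))
  }
  for (i in rest) {
    for (tries in 1:100) {
      v <- stats::setNames(stats::rlnorm(length(samples), meanlog = 0,
                                         sdlog = 1.2), samples)
      if (!is_tsg_row(v)) break
    }
    vals[i, ] <- v
  }
  truth <- list(
    tsg = data.frame(gene_id = gene_ids[tsg_rows], group_label = labels,
                     stringsAsFactors = FALSE),
    seed = seed)
  truth$tsg <- truth$tsg[order(truth$tsg$group_label, truth$tsg$gene_id), ]
  rownames(truth$tsg) <- NULL
  list(matrix = expr_matrix(vals, "rpkm"), truth = truth)
}

#' Generate a target species with tissue-biased homolog expression
#'
#' Each planted TSG independently gains a target-species homolog with
#' probability `homolog_fraction`. A linked homolog is highly expressed in
#' the tissue its focal group maps to with probability `q` (its min-max
#' normalized value there exceeds 0.9) and otherwise in a uniformly chosen
#' other tissue, so the expected similarity cell for the mapped tissue is
#' exactly `q`. A 12-column BLAST tabular hit set is produced with true
#' links at e-values 10^-Uniform(6, 50) plus decoy hits above the 1e-5
#' threshold that carry high bit scores (only the e-value filter can remove
#' them).
#'
#' @param truth the `truth` element of [generate_focal_expression()].
#' @param species species tag (e.g. `"mouse"`).
#' @param tissues character vector of target tissue labels (>= 2).
#' @param bias_map named list: focal group label -> list(tissue =, q =).
#'   Groups absent from the map bias uniformly (q = 1/length(tissues) at
#'   the mapped-tissue position is not defined; their homologs pick a
#'   uniformly random high tissue).
#' @param homolog_fraction probability a TSG has a homolog, in \[0, 1\].
#' @param decoy_fraction fraction of focal TSGs that additionally get a
#'   decoy hit with e-value >= 1e-5, default 0.3.
#' @param n_background extra unlinked target genes, default 50.
#' @param seed integer seed.
#' @return List with `expr` (target [expr_matrix()]), `blast` (12-column
#'   data.frame, see [write_blast_tabular()]), `links` (data.frame
#'   `gene_id`, `group_label`, `subject_id`, `high_tissue`), and
#'   `expected` (focal group x target tissue matrix of expected similarity,
#'   `NA` for unmapped groups).
#' @export
generate_target_species <- function(truth, species, tissues, bias_map,
                                    homolog_fraction = 0.8,
                                    decoy_fraction = 0.3,
                                    n_background = 50L, seed = 1L) {
  if (length(tissues) < 2L) fail("need >= 2 target tissues")
  set.seed(derive_seed(seed, 2L))
  tsg <- truth$tsg
  linked <- stats::runif(nrow(tsg)) < homolog_fraction
  links <- tsg[linked, , drop = FALSE]
  if (nrow(links)) {
    links$subject_id <- sprintf("%s_SBJ%05d", toupper(species),
                                seq_len(nrow(links)))
    links$high_tissue <- vapply(links$group_label, function(g) {
      bm <- bias_map[[g]]
      if (!is.null(bm) && stats::runif(1L) < bm$q) bm$tissue
      else sample(if (is.null(bm)) tissues else setdiff(tissues, bm$tissue), 1L)
    }, character(1L))
  } else {
    links$subject_id <- character(0)
    links$high_tissue <- character(0)
  }
  subj_ids <- c(links$subject_id,
                sprintf("%s_BG%04d", toupper(species), seq_len(n_background)))
  vals <- matrix(stats::runif(length(subj_ids) * length(tissues), 0, 1),
                 length(subj_ids), length(tissues),
                 dimnames = list(subj_ids, tissues))
  for (k in seq_len(nrow(links)))
    vals[links$subject_id[k], links$high_tissue[k]] <- stats::runif(1L, 9, 11)
  blast_rows <- list()
  blast_line <- function(q, s, ev, bits) {
    data.frame(qseqid = q, sseqid = s,
               pident = round(stats::runif(1L, 30, 90), 1), length = 100L,
               mismatch = 50L, gapopen = 2L, qstart = 1L, qend = 100L,
               sstart = 1L, send = 100L, evalue = ev, bitscore = bits,
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(links))) {
    blast_rows[[length(blast_rows) + 1L]] <- blast_line(
      links$gene_id[k], links$subject_id[k],
      10^-stats::runif(1L, 6, 50), round(stats::runif(1L, 100, 300), 1))
  }
  decoys <- tsg$gene_id[stats::runif(nrow(tsg)) < decoy_fraction]
  for (g in decoys) {
    blast_rows[[length(blast_rows) + 1L]] <- blast_line(
      g, sprintf("%s_DECOY_%s", toupper(species), g),
      10^-stats::runif(1L, 0, 4.5), 400)
  }
  blast <- if (length(blast_rows)) do.call(rbind, blast_rows) else
    blast_line(character(0), character(0), numeric(0), numeric(0))
  expected <- matrix(NA_real_, length(unique(tsg$group_label)),
                     length(tissues),
                     dimnames = list(unique(tsg$group_label), tissues))
  for (g in names(bias_map)) {
    if (!g %in% rownames(expected)) next
    q <- bias_map[[g]]$q
    expected[g, ] <- (1 - q) / (length(tissues) - 1)
    expected[g, bias_map[[g]]$tissue] <- q
  }
  list(expr = expr_matrix(vals, "rpkm"), blast = blast,
       links = links, expected = expected, species = species)
}

#' Write hits in 12-column BLAST tabular format
#' @param blast data.frame with the 12 outfmt-6 columns (as produced by
#'   [generate_target_species()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(blast, path) {
  fmt <- blast
  fmt$evalue <- sprintf("%.3g", fmt$evalue)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate qRT-PCR Ct replicates with a planted tissue effect
#'
#' Reference-gene Ct values are Normal(20, noise_sd) (a constitutive
#' reference). Each target gene's Ct equals its reference Ct plus
#' `baseline_dct`, lowered by `effect_dct` in the gene's planted tissue,
#' plus Normal(0, noise_sd) measurement noise, so replicate dCt values are
#' Normal(baseline_dct - effect, noise_sd). Undetected replicate sets can
#' be injected per (gene, tissue).
#'
#' @param genes data.frame with columns `gene_id` and `tissue` (the planted
#'   high-expression tissue; `NA` for a null gene with no effect).
#' @param tissues character vector of assayed tissues.
#' @param effect_dct dCt drop in the planted tissue, default 10.
#' @param n_replicates replicate sets per tissue (>= 3), default 4.
#' @param noise_sd Ct measurement SD in cycles, default 0.3.
#' @param baseline_dct dCt away from the planted tissue, default 10.
#' @param undetected optional data.frame (`gene_id`, `tissue`, `n_sets`)
#'   marking that many replicate sets undetected.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `tissue`, `replicate_set`,
#'   `ct_target`, `ct_reference`, `detected`.
#' @export
generate_qpcr_dataset <- function(genes, tissues, effect_dct = 10,
                                  n_replicates = 4L, noise_sd = 0.3,
                                  baseline_dct = 10, undetected = NULL,
                                  seed = 1L) {
  if (n_replicates < 3L) fail("need >= 3 replicate sets")
  set.seed(derive_seed(seed, 3L))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    for (t in tissues) {
      ref <- stats::rnorm(n_replicates, 20, noise_sd)
      eff <- if (!is.na(genes$tissue[i]) && t == genes$tissue[i])
        effect_dct else 0
      tgt <- ref + baseline_dct - eff + stats::rnorm(n_replicates, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes$gene_id[i], tissue = t,
        replicate_set = seq_len(n_replicates),
        ct_target = tgt, ct_reference = ref, detected = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(undetected)) {
    for (i in seq_len(nrow(undetected))) {
      idx <- which(out$gene == undetected$gene_id[i] &
                     out$tissue == undetected$tissue[i])
      idx <- idx[seq_len(min(undetected$n_sets[i], length(idx)))]
      out$detected[idx] <- FALSE
      out$ct_target[idx] <- NA_real_
    }
  }
  rownames(out) <- NULL
  out
}
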