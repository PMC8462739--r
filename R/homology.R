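#' Parse BLAST tabular (outfmt 6) hits
#'
#' Reads the standard 12-column tabular output (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Columns beyond the twelfth are ignored; lines starting with `#` and blank
#' lines are skipped.
#'
#' @param path path to the tabular hit file.
#' @param species species tag to attach to every hit (e.g. `"mouse"`).
#' @return data.frame of class `blast_hits` with columns `query_id`,
#'   `subject_id`, `percent_identity`, `evalue`, `bitscore`, `species`.
#' @export
read_blast_tabular <- function(path, species) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(structure(
      data.frame(query_id = character(), subject_id = character(),
                 percent_identity = numeric(), evalue = numeric(),
                 bitscore = numeric(), species = character(),
                 stringsAsFactors = FALSE),
      class = c("blast_hits", "data.frame")))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12L)
  if (length(short))
    fail(sprintf("line %d of '%s' has %d column(s); BLAST tabular needs 12",
                 idx[short[1L]], path, lengths(fields)[short[1L]]))
  col <- function(k) vapply(fields, `[[`, character(1L), k)
  num <- function(k, what) {
    v <- suppressWarnings(as.numeric(col(k)))
    bad <- which(is.na(v))
    if (length(bad))
      fail(sprintf("line %d of '%s': cannot parse %s '%s'",
                   idx[bad[1L]], path, what, col(k)[bad[1L]]))
    v
  }
  out <- data.frame(
    query_id = col(1L), subject_id = col(2L),
    percent_identity = num(3L, "percent identity"),
    evalue = num(11L, "e-value"), bitscore = num(12L, "bit score"),
    species = species, stringsAsFactors = FALSE)
  if (any(out$evalue < 0)) fail("negative e-value in ", path)
  structure(out, class = c("blast_hits", "data.frame"))
}

#' Consolidate hits to one best hit per (query, species)
#'
#' Hits with e-value >= `evalue_max` are discarded (the filter is strict,
#' mirroring an e-value < 1e-5 cutoff). Among survivors, for each
#' (query, species) pair the hit with the highest bit score is kept; ties
#' fall back to the smallest e-value, then the lexicographically smallest
#' subject id, so the result is independent of input order.
#'
#' @param hits a `blast_hits` data.frame (rbind several species' files to
#'   consolidate them together), or a list of them.
#' @param evalue_max strict e-value cutoff, default `1e-5`.
#' @param keep_all if `TRUE`, return every surviving hit rather than the
#'   single best per (query, species). Default `FALSE`.
#' @return data.frame of class `homology_map` with columns `query_id`,
#'   `species`, `subject_id`, `evalue`, `bitscore`, sorted by
#'   (query_id, species). Queries with no surviving hit are absent.
#' @export
best_hits <- function(hits, evalue_max = 1e-5, keep_all = FALSE) {
  if (is.list(hits) && !is.data.frame(hits)) hits <- do.call(rbind, hits)
  surv <- hits[hits$evalue < evalue_max, , drop = FALSE]
  surv <- surv[, c("query_id", "species", "subject_id", "evalue", "bitscore")]
  if (!keep_all && nrow(surv)) {
    o <- order(surv$query_id, surv$species,
               -surv$bitscore, surv$evalue, surv$subject_id)
    surv <- surv[o, , drop = FALSE]
    surv <- surv[!duplicated(surv[, c("query_id", "species")]), , drop = FALSE]
  }
  surv <- surv[order(surv$query_id, surv$species, surv$subject_id), ,
               drop = FALSE]
  rownames(surv) <- NULL
  structure(surv, evalue_max = evalue_max,
            class = c("homology_map", "data.frame"))
}

#' Classify TSGs by homology presence in two target species
#'
#' For each tissue group, counts its TSGs with a surviving best hit in both
#' species, in species A only, in species B only, or in neither, and
#' reports the percentage with any homolog, rounded half-up to one decimal.
#' Groups with zero TSGs get zero counts and an `NA` percentage (undefined,
#' not 0).
#'
#' @param tsg_calls a `tsg_calls` data.frame (or any data.frame with
#'   `gene_id` and `group_label` columns).
#' @param map a [best_hits()] homology map.
#' @param species_a,species_b the two species tags, in report order.
#' @param groups group labels to report (default: those present in
#'   `tsg_calls`); labels with no TSGs get zero counts and `NA` percentage.
#' @return data.frame of class `homology_breakdown` with columns `group`,
#'   `n_tsg`, `both`, `a_only`, `b_only`, `none`, `pct_homologous`.
#' @export
homology_breakdown <- function(tsg_calls, map, species_a, species_b,
                               groups = unique(tsg_calls$group_label)) {
  in_a <- unique(map$query_id[map$species == species_a])
  in_b <- unique(map$query_id[map$species == species_b])
  rows <- lapply(groups, function(g) {
    genes <- tsg_calls$gene_id[tsg_calls$group_label == g]
    a <- genes %in% in_a
    b <- genes %in% in_b
    n <- length(genes)
    none <- sum(!a & !b)
    pct <- if (n == 0L) NA_real_ else round_half_up(100 * (n - none) / n, 1)
    data.frame(group = g, n_tsg = n, both = sum(a & b),
               a_only = sum(a & !b), b_only = sum(!a & b), none = none,
               pct_homologous = pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "species") <- c(species_a, species_b)
  structure(out, class = c("homology_breakdown", "data.frame"))
}

#' Write a homology breakdown table
#' @param breakdown a `homology_breakdown`.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_breakdown_table <- function(breakdown, path, sep = "\t") {
  utils::write.table(as.data.frame(breakdown), path, sep = sep,
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
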