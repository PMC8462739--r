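#' Define a tissue grouping scheme
#'
#' Maps tissue-group labels to member sample columns. Composite groups (e.g.
#' oral + atrial siphon, or the three intestine segments) carry "any member
#' high" semantics: a gene qualifies for the group when any member sample
#' clears the high threshold, and fellow members are exempt from the low
#' test.
#'
#' @param groups named list; names are group labels, elements are character
#'   vectors of sample ids. Members must be non-empty and disjoint.
#' @return A `tissue_scheme` (validated named list).
#' @examples
#' tissue_scheme(list(siphons = c("oral_siphon", "atrial_siphon"),
#'                    heart = "heart"))
#' @export
tissue_scheme <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    fail("`groups` must be a fully named list of sample-id vectors")
  if (anyDuplicated(names(groups)))
    fail("duplicate group label(s): ",
         paste(unique(names(groups)[duplicated(names(groups))]), collapse = ", "))
  groups <- lapply(groups, as.character)
  if (any(lengths(groups) == 0L)) fail("every group needs >= 1 member sample")
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members))
    fail("sample(s) assigned to more than one group: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  structure(groups, class = "tissue_scheme")
}

#' @export
print.tissue_scheme <- function(x, ...) {
  cat(sprintf("Tissue scheme: %d groups, %d samples\n",
              length(x), length(unlist(x))))
  for (g in names(x)) cat(sprintf("  %s: %s\n", g, paste(x[[g]], collapse = ", ")))
  invisible(x)
}

#' Thresholds for tissue-specific gene calling
#'
#' A gene is tissue-specific when its RPKM exceeds `high` in (a member of)
#' one tissue group and stays below `low` in every sample outside that
#' group. Both inequalities are strict, so at the defaults (high 1, low 0.5)
#' every call is guaranteed a more than 2-fold margin over any other tissue.
#'
#' @param high high RPKM threshold (default 1).
#' @param low low RPKM threshold (default 0.5); must satisfy 0 < low < high.
#' @return A `tsg_criteria` list.
#' @export
tsg_criteria <- function(high = 1, low = 0.5) {
  if (!(is.numeric(high) && is.numeric(low) && low > 0 && low < high))
    fail("criteria must satisfy 0 < low < high")
  structure(list(high = high, low = low), class = "tsg_criteria")
}

# gene x group matrix of within-group maxima; checks scheme coverage
group_maxima <- function(matrix, scheme) {
  samples <- colnames(matrix)
  covered <- unlist(scheme, use.names = FALSE)
  uncovered <- setdiff(samples, covered)
  if (length(uncovered))
    fail("samples not covered by the tissue scheme: ",
         paste(uncovered, collapse = ", "))
  absent <- setdiff(covered, samples)
  if (length(absent))
    fail("scheme refers to samples absent from the matrix: ",
         paste(absent, collapse = ", "))
  gm <- do.call(cbind, lapply(scheme, function(members) {
    apply(matrix[, members, drop = FALSE], 1L, max)
  }))
  dimnames(gm) <- list(rownames(matrix), names(scheme))
  gm
}

#' Call tissue-specific genes
#'
#' Gene g is called for group G iff the maximum RPKM over G's member samples
#' exceeds `criteria$high` and every sample outside G is below
#' `criteria$low` (strict inequalities; fellow members of a composite group
#' are exempt from the low test). Each gene can be called for at most one
#' group.
#'
#' @param matrix an [expr_matrix()] in RPKM units.
#' @param scheme a [tissue_scheme()] covering the matrix's samples.
#' @param criteria a [tsg_criteria()].
#' @return An object of class `tsg_calls`: a data.frame with columns
#'   `gene_id`, `group_label`, `max_in_group`, `max_outside_group`, sorted
#'   by (group_label, gene_id), with the criteria attached as an attribute.
#' @export
call_tsgs <- function(matrix, scheme, criteria = tsg_criteria()) {
  if (expr_units(matrix) != "rpkm") fail("TSG calling requires RPKM units")
  gm <- group_maxima(matrix, scheme)
  calls <- vector("list", length(scheme))
  for (gi in seq_along(scheme)) {
    members <- scheme[[gi]]
    outside <- setdiff(colnames(matrix), members)
    out_max <- if (length(outside)) {
      apply(matrix[, outside, drop = FALSE], 1L, max)
    } else rep(0, nrow(matrix))
    hit <- gm[, gi] > criteria$high & out_max < criteria$low
    calls[[gi]] <- data.frame(
      gene_id = rownames(matrix)[hit],
      group_label = rep(names(scheme)[gi], sum(hit)),
      max_in_group = unname(gm[hit, gi]),
      max_outside_group = unname(out_max[hit]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$group_label, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, criteria = criteria,
            class = c("tsg_calls", "data.frame"))
}

#' @export
as.data.frame.tsg_calls <- function(x, ...) {
  attr(x, "criteria") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.tsg_calls <- function(x, ...) {
  crit <- attr(x, "criteria")
  cat(sprintf("TSG calls: %d genes (RPKM > %g in one group, < %g elsewhere)\n",
              nrow(x), crit$high, crit$low))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more calls\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.tsg_calls <- function(object, ...) {
  tab <- table(factor(object$group_label))
  cat("TSG calls per tissue group:\n")
  print(tab)
  invisible(tab)
}

#' Relaxed two-tissue specificity calls
#'
#' Returns genes whose within-group maximum exceeds the high threshold in
#' exactly two groups — one of which is `focal_group` — and that stay below
#' the low threshold in every sample of every other group. Strict
#' single-group TSGs are not returned; union them with [call_tsgs()] output
#' to form the combined relaxed set.
#'
#' @inheritParams call_tsgs
#' @param focal_group label of the group that must be one of the two.
#' @return data.frame with columns `gene_id`, `group_a` (the focal group),
#'   `group_b` (the partner group).
#' @export
call_two_tissue_genes <- function(matrix, scheme, focal_group,
                                  criteria = tsg_criteria()) {
  if (!focal_group %in% names(scheme))
    fail("unknown focal group: ", focal_group)
  if (expr_units(matrix) != "rpkm") fail("TSG calling requires RPKM units")
  gm <- group_maxima(matrix, scheme)
  focal_i <- match(focal_group, names(scheme))
  res <- list()
  for (gene in seq_len(nrow(matrix))) {
    high_groups <- which(gm[gene, ] > criteria$high)
    if (length(high_groups) != 2L || !(focal_i %in% high_groups)) next
    other_samples <- unlist(scheme[-high_groups], use.names = FALSE)
    if (length(other_samples) &&
        any(matrix[gene, other_samples] >= criteria$low)) next
    partner <- names(scheme)[setdiff(high_groups, focal_i)]
    res[[length(res) + 1L]] <- data.frame(
      gene_id = rownames(matrix)[gene],
      group_a = focal_group, group_b = partner,
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_id = character(), group_a = character(),
               group_b = character(), stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Write TSG calls as a delimited table
#' @param calls a `tsg_calls` object.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_tsg_table <- function(calls, path, sep = "\t") {
  utils::write.table(as.data.frame(calls), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
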