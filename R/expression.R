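#' Construct and validate an expression matrix
#'
#' An expression matrix is a numeric gene x sample matrix with unique row
#' (gene) and column (sample) names, all values finite and non-negative, and
#' a units tag saying whether the values are raw read counts or RPKM
#' (reads per kilobase of transcript per million mapped reads). Every stage
#' of the pipeline consumes this container.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param units `"counts"` or `"rpkm"`.
#' @return A validated matrix of class `expr_matrix` with a `units` attribute.
#' @examples
#' m <- matrix(c(1, 0.5, 0, 0.5, 2, 0.5), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expr_matrix(m, "rpkm")
#' @export
expr_matrix <- function(values, units = c("rpkm", "counts")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    fail("`values` must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    fail("expression matrix needs gene rownames and sample colnames")
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    fail("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    fail("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    fail(sprintf(
      "non-finite or negative expression value at gene '%s', sample '%s'",
      genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  structure(values, units = units, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (units: %s)\n",
              nrow(x), ncol(x), expr_units(x)))
  n <- min(nrow(x), 6L)
  m <- min(ncol(x), 8L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n) cat(sprintf("... %d more genes\n", nrow(x) - n))
  invisible(x)
}

#' Units tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"counts"` or `"rpkm"`.
#' @export
expr_units <- function(x) attr(x, "units") %||% "rpkm"

#' Read a delimited gene x sample expression table
#'
#' Expects a header row of sample labels and gene identifiers in the first
#' column; cells must parse as non-negative finite numbers (scientific
#' notation accepted, period decimal mark).
#'
#' @param path path to the delimited text file.
#' @param units units tag to attach, `"rpkm"` (default) or `"counts"`.
#' @param sep field delimiter; tab by default, use `","` for CSV.
#' @return An [expr_matrix()].
#' @export
read_expression_table <- function(path, units = c("rpkm", "counts"),
                                  sep = "\t") {
  units <- match.arg(units)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) fail("expression table needs gene ids plus >= 1 sample")
  genes <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                 dimnames = list(genes, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      fail(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                   body[bad[1L], j], bad[1L], genes[bad[1L]],
                   colnames(body)[j]))
    neg <- which(v < 0)
    if (length(neg))
      fail(sprintf("negative value %s at row %d (gene '%s'), column '%s'",
                   format(v[neg[1L]]), neg[1L], genes[neg[1L]],
                   colnames(body)[j]))
    vals[, j] <- v
  }
  expr_matrix(vals, units)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_table()]: header of sample labels, first
#' column `gene_id`. Round-trips cell-for-cell at full double precision.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(x), unclass(x),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column id/value table (gene lengths or library sizes)
#'
#' @param path delimited text with a header and two columns: identifier,
#'   positive numeric value.
#' @param sep field delimiter.
#' @return Named numeric vector.
#' @export
read_id_value_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, quote = "",
                          comment.char = "", colClasses = c("character", "numeric"))
  if (ncol(df) != 2L) fail("expected exactly two columns (id, value)")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Convert raw counts to RPKM
#'
#' RPKM(g, s) = count(g, s) * 1e9 / (length_bp(g) * total_mapped_reads(s)).
#' Library sizes are supplied, not recomputed as column sums, because the
#' per-million denominator is the total mapped reads of the library, which
#' may include genes absent from the matrix.
#'
#' @param counts an `expr_matrix` with units `"counts"`.
#' @param gene_lengths named numeric vector of transcript lengths in bp
#'   (>= 1), one entry per gene in `counts`.
#' @param library_sizes named numeric vector of total mapped reads (>= 1),
#'   one entry per sample in `counts`.
#' @return An `expr_matrix` with units `"rpkm"`.
#' @examples
#' m <- expr_matrix(matrix(1000, 1, 1, dimnames = list("g1", "s1")), "counts")
#' counts_to_rpkm(m, c(g1 = 1000), c(s1 = 1e7))  # 100 RPKM
#' @export
counts_to_rpkm <- function(counts, gene_lengths, library_sizes) {
  if (expr_units(counts) != "counts")
    fail("`counts` must carry units 'counts'")
  missing_g <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing_g))
    fail("missing gene length for: ", paste(missing_g, collapse = ", "))
  missing_s <- setdiff(colnames(counts), names(library_sizes))
  if (length(missing_s))
    fail("missing library size for: ", paste(missing_s, collapse = ", "))
  len <- gene_lengths[rownames(counts)]
  lib <- library_sizes[colnames(counts)]
  if (any(len < 1)) fail("gene lengths must be >= 1 bp")
  if (any(lib < 1)) fail("library sizes must be >= 1 read")
  rpkm <- unclass(counts) * 1e9 / outer(len, lib)
  dimnames(rpkm) <- dimnames(counts)
  expr_matrix(rpkm, "rpkm")
}
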