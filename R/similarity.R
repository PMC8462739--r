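#' Min-max normalize an expression profile
#'
#' Rescales a per-tissue profile so the lowest tissue is 0 and the highest
#' is 1: v' = (v - min) / (max - min). A constant (flat) profile has no
#' defined scaling; it is flagged degenerate and set to all zeros, and
#' downstream similarity counting excludes it entirely.
#'
#' @param profile numeric vector of non-negative expression over >= 2
#'   tissues (names preserved), or a gene x tissue matrix normalized
#'   row-wise.
#' @return For a vector: the normalized vector with attribute `degenerate`.
#'   For a matrix: a list with `values` (normalized matrix) and
#'   `degenerate` (logical per row).
#' @examples
#' minmax_normalize(c(a = 2, b = 4, c = 10))  # 0, 0.25, 1
#' @export
minmax_normalize <- function(profile) {
  if (is.matrix(profile)) {
    if (ncol(profile) < 2L) fail("need >= 2 tissues to normalize")
    lo <- apply(profile, 1L, min)
    hi <- apply(profile, 1L, max)
    deg <- hi == lo
    span <- ifelse(deg, 1, hi - lo)
    vals <- (profile - lo) / span
    vals[deg, ] <- 0
    return(list(values = vals, degenerate = stats::setNames(deg, rownames(profile))))
  }
  if (length(profile) < 2L) fail("need >= 2 tissues to normalize")
  lo <- min(profile)
  hi <- max(profile)
  if (hi == lo)
    return(structure(stats::setNames(rep(0, length(profile)), names(profile)),
                     degenerate = TRUE))
  structure((profile - lo) / (hi - lo), degenerate = FALSE)
}

#' Fraction of homolog profiles highly expressed per tissue
#'
#' Given min-max normalized homolog profiles over a common tissue set,
#' counts per tissue the profiles whose normalized value exceeds
#' `high_fraction` (strict), and divides by the number of non-degenerate
#' profiles. This fraction is the "tissue similarity" between a focal
#' tissue (whose TSG homologs these are) and each target-species tissue.
#'
#' @param profiles gene x tissue matrix of normalized values in \[0, 1\].
#' @param degenerate logical per row; degenerate profiles are excluded from
#'   numerator and denominator. Default: none.
#' @param high_fraction threshold in (0, 1), default 0.8.
#' @return Named numeric vector of per-tissue fractions, with attribute
#'   `n` = number of non-degenerate profiles (the denominator).
#' @export
tissue_similarity <- function(profiles, degenerate = NULL,
                              high_fraction = 0.8) {
  if (!(high_fraction > 0 && high_fraction < 1))
    fail("high_fraction must lie strictly between 0 and 1")
  if (is.null(degenerate)) degenerate <- rep(FALSE, nrow(profiles))
  keep <- profiles[!degenerate, , drop = FALSE]
  n <- nrow(keep)
  if (n == 0L) fail("no non-degenerate profiles: similarity undefined")
  frac <- colSums(keep > high_fraction) / n
  structure(frac, n = n)
}

#' Per-species similarity matrices for all focal tissue groups
#'
#' For each focal tissue group, gathers the best-hit subject of every TSG in
#' the group (per species), pulls the subject's profile from the target
#' expression matrix, averages replicate columns per tissue when
#' `tissue_of` is given, min-max normalizes, and applies
#' [tissue_similarity()]. Two TSGs sharing one target subject contribute two
#' profiles (the denominator counts TSG-homolog pairs). Subjects absent
#' from the target matrix and degenerate profiles are dropped and counted
#' in the result.
#'
#' @param tsg_calls a `tsg_calls` data.frame.
#' @param map a [best_hits()] homology map.
#' @param target_expr [expr_matrix()] of the target species
#'   (gene x tissue/sample).
#' @param species species tag to select from `map`.
#' @param tissue_of optional named character vector mapping target sample
#'   columns to tissue labels; replicate columns of one tissue are averaged
#'   before normalization. Default: each column is its own tissue.
#' @param high_fraction threshold passed to [tissue_similarity()].
#' @return Object of class `tissue_similarity_matrix`: list with `values`
#'   (focal group x target tissue matrix; `NA` rows where no homolog
#'   resolved), `n` (per-group denominators), `dropped` (per-group count of
#'   unresolvable subjects), `degenerate` (per-group count of flat
#'   profiles), and `species`.
#' @export
similarity_matrix <- function(tsg_calls, map, target_expr, species,
                              tissue_of = NULL, high_fraction = 0.8) {
  sp_map <- map[map$species == species, , drop = FALSE]
  expr <- unclass(target_expr)
  if (!is.null(tissue_of)) {
    miss <- setdiff(colnames(expr), names(tissue_of))
    if (length(miss))
      fail("tissue_of does not cover sample(s): ", paste(miss, collapse = ", "))
    tiss <- unique(unname(tissue_of[colnames(expr)]))
    avg <- do.call(cbind, lapply(tiss, function(t) {
      rowMeans(expr[, intersect(colnames(expr),
                                names(tissue_of)[tissue_of == t]),
                    drop = FALSE])
    }))
    dimnames(avg) <- list(rownames(expr), tiss)
    expr <- avg
  }
  tissues <- colnames(expr)
  groups <- unique(tsg_calls$group_label)
  vals <- matrix(NA_real_, length(groups), length(tissues),
                 dimnames = list(groups, tissues))
  n <- dropped <- degen <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    genes <- tsg_calls$gene_id[tsg_calls$group_label == g]
    subjects <- sp_map$subject_id[match(genes, sp_map$query_id)]
    subjects <- subjects[!is.na(subjects)]
    resolvable <- subjects %in% rownames(expr)
    dropped[g] <- sum(!resolvable)
    subjects <- subjects[resolvable]
    if (!length(subjects)) next
    prof <- expr[subjects, , drop = FALSE]
    norm <- minmax_normalize(prof)
    degen[g] <- sum(norm$degenerate)
    if (all(norm$degenerate)) next
    sim <- tissue_similarity(norm$values, norm$degenerate, high_fraction)
    vals[g, ] <- sim
    n[g] <- attr(sim, "n")
  }
  structure(list(values = vals, n = n, dropped = dropped,
                 degenerate = degen, species = species,
                 high_fraction = high_fraction),
            class = "tissue_similarity_matrix")
}

#' @export
print.tissue_similarity_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Tissue similarity vs %s (fraction of homologs > %g):\n",
              x$species, x$high_fraction))
  print(round(x$values, digits))
  cat("Homologs per focal group (denominators):\n")
  print(x$n)
  if (any(x$dropped > 0))
    cat(sprintf("Unresolvable subjects dropped: %d\n", sum(x$dropped)))
  if (any(x$degenerate > 0))
    cat(sprintf("Degenerate (flat) profiles excluded: %d\n", sum(x$degenerate)))
  invisible(x)
}

#' @export
plot.tissue_similarity_matrix <- function(x, ...) {
  v <- x$values
  op <- graphics::par(mar = c(7, 7, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(v)), seq_len(nrow(v)), t(v),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("Tissue similarity vs %s", x$species), ...)
  graphics::axis(1, seq_len(ncol(v)), colnames(v), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(v)), rownames(v), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Write a similarity matrix as delimited text
#' @param x a `tissue_similarity_matrix`.
#' @param path output path.
#' @param percent multiply by 100 (half-up, 1 decimal) before writing.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(x, path, percent = FALSE, sep = "\t") {
  v <- x$values
  if (percent) v <- round_half_up(100 * v, 1)
  df <- data.frame(group = rownames(v), n_homologs = unname(x$n[rownames(v)]),
                   v, check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Hierarchically cluster normalized expression profiles
#'
#' Deterministic agglomerative clustering for heatmap row ordering:
#' Euclidean distance on the normalized values and complete linkage by
#' default (both configurable through the usual [stats::dist()] /
#' [stats::hclust()] method names).
#'
#' @param profiles gene x tissue numeric matrix (>= 2 rows).
#' @param method linkage method, default `"complete"`.
#' @param metric distance metric, default `"euclidean"`.
#' @return List with `hclust` (the merge tree), `order` (leaf order,
#'   row indices) and `leaf_ranks` (data.frame gene_id, leaf_rank).
#' @export
cluster_profiles <- function(profiles, method = "complete",
                             metric = "euclidean") {
  if (nrow(profiles) < 2L) fail("need >= 2 profiles to cluster")
  hc <- stats::hclust(stats::dist(profiles, method = metric), method = method)
  structure(list(
    hclust = hc, order = hc$order,
    leaf_ranks = data.frame(gene_id = rownames(profiles)[hc$order],
                            leaf_rank = seq_along(hc$order),
                            stringsAsFactors = FALSE)),
    class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("Profile clustering: %d genes, %s linkage on %s distance\n",
              length(x$order), x$hclust$method, x$hclust$dist.method))
  invisible(x)
}

#' @export
plot.profile_clustering <- function(x, ...) {
  graphics::plot(x$hclust, ...)
  invisible(x)
}

#' Export similarity matrices as a network edge/node table
#'
#' One edge per (focal tissue, target tissue, species) whose similarity
#' exceeds `min_edge`; edge weight is the similarity, the quantity a viewer
#' renders as line width. Nodes are tissues tagged by species; focal and
#' target node sets are disjoint, so there are no self-edges.
#'
#' @param matrices a `tissue_similarity_matrix` or list of them (one per
#'   species).
#' @param min_edge minimum weight (strict), default 0.
#' @param focal_species tag used for focal-tissue node ids, default
#'   `"focal"`.
#' @return List of class `similarity_network` with `edges` (source, weight,
#'   target) and `nodes` (id, tissue, species).
#' @export
export_network <- function(matrices, min_edge = 0, focal_species = "focal") {
  if (inherits(matrices, "tissue_similarity_matrix")) matrices <- list(matrices)
  edges <- list()
  nodes <- list()
  for (m in matrices) {
    v <- m$values
    src <- sprintf("%s:%s", focal_species, rownames(v) %||% character(0))
    tgt <- sprintf("%s:%s", m$species, colnames(v) %||% character(0))
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = c(src, tgt),
      tissue = c(rownames(v) %||% character(0),
                 colnames(v) %||% character(0)),
      species = c(rep(focal_species, length(src)),
                  rep(m$species, length(tgt))),
      stringsAsFactors = FALSE)
    keep <- which(!is.na(v) & v > min_edge, arr.ind = TRUE)
    if (nrow(keep))
      edges[[length(edges) + 1L]] <- data.frame(
        source = src[keep[, 1L]],
        weight = v[keep],
        target = tgt[keep[, 2L]], stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), weight = numeric(),
               target = character(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- unique(do.call(rbind, nodes))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes), class = "similarity_network")
}

#' Write / read a similarity network as SIF-style text
#'
#' `write_network()` emits a three-column tab-delimited edge file (source,
#' weight, target) with a header, plus a node-attribute table next to it;
#' `read_network_edges()` reads the edge file back, reconstructing every
#' exported cell exactly (weights are written at full precision).
#'
#' @param network a `similarity_network`.
#' @param edge_path path for the edge table; the node table goes to
#'   `<edge_path>.nodes`.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(network, edge_path) {
  edges <- network$edges
  edges$weight <- sprintf("%.17g", edges$weight)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, paste0(edge_path, ".nodes"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(edge_path)
}

#' @rdname write_network
#' @param edge_path path to an edge table written by `write_network()`.
#' @export
read_network_edges <- function(edge_path) {
  utils::read.table(edge_path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric", "character"),
                    stringsAsFactors = FALSE)
}
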