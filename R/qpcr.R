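#' Read a qRT-PCR replicate table
#'
#' Expects a delimited table with columns `gene`, `tissue`,
#' `replicate_set`, `ct_target`, `ct_reference`, `detected` (logical or
#' 0/1). Undetected wells may leave `ct_target` empty.
#'
#' @param path path to the delimited file.
#' @param sep field delimiter.
#' @return data.frame with those columns, `detected` as logical.
#' @export
read_qpcr_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("gene", "tissue", "replicate_set", "ct_target", "ct_reference",
            "detected")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("qPCR table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$detected <- as.logical(df$detected)
  df
}

#' Compute delta-Ct and relative expression
#'
#' dCt = ct_target - ct_reference against a constitutive reference gene;
#' relative expression = 2^(-dCt). Undetected wells get relative
#' expression 0 and `NA` dCt (detection filtering decides how they enter
#' testing).
#'
#' @param measurements data.frame with columns `ct_target`, `ct_reference`,
#'   `detected`.
#' @return The input with added `dct` and `rel_expr` columns.
#' @examples
#' compute_dct(data.frame(ct_target = 25, ct_reference = 20,
#'                        detected = TRUE))  # dCt 5, rel 2^-5
#' @export
compute_dct <- function(measurements) {
  m <- measurements
  det <- m$detected
  bad <- det & (is.na(m$ct_target) | is.na(m$ct_reference))
  if (any(bad))
    fail("detected well with missing Ct at row ", which(bad)[1L])
  if (any(det & (m$ct_target <= 0 | m$ct_reference <= 0)))
    fail("Ct values must be positive when detected")
  m$dct <- ifelse(det, m$ct_target - m$ct_reference, NA_real_)
  m$rel_expr <- ifelse(det, 2^(-m$dct), 0)
  m
}

#' Apply the detection filter to one gene's measurements
#'
#' A tissue with two or more undetected replicate sets for the gene is
#' excluded from that gene's statistical comparison; a tissue with exactly
#' one undetected set is retained, the undetected replicate contributing an
#' expression of zero.
#'
#' @param measurements one gene's rows (see [compute_dct()]), with columns
#'   `tissue` and `detected`.
#' @return List with `included` (retained rows), `excluded` (data.frame
#'   `tissue`, `n_undetected`, `reason`).
#' @export
filter_detection <- function(measurements) {
  und <- tapply(!measurements$detected, measurements$tissue, sum)
  out_tissues <- names(und)[und >= 2L]
  excluded <- data.frame(
    tissue = out_tissues,
    n_undetected = as.integer(und[out_tissues]),
    reason = rep(">= 2 replicate sets below detection", length(out_tissues)),
    stringsAsFactors = FALSE)
  list(included = measurements[!measurements$tissue %in% out_tissues, ,
                               drop = FALSE],
       excluded = excluded)
}

# Dunn's rank-based pairwise comparisons after a Kruskal-Wallis omnibus
# test: z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)),
# with tie correction T = sum(t^3 - t) / (12 (N - 1)).
dunn_pairwise <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             statistic = z, p_raw = p,
             p_adj = pmin(1, p * ncol(pairs)),
             stringsAsFactors = FALSE)
}

#' Levene-gated tissue comparison test on dCt values
#'
#' Runs Levene's test (mean-centered) for homoscedasticity across tissue
#' groups. If the Levene p-value is at or above `alpha`, variances are
#' treated as equal and a parametric one-way ANOVA with Tukey HSD pairwise
#' comparisons follows; otherwise a Kruskal-Wallis omnibus test with Dunn's
#' rank-based pairwise comparisons and Bonferroni adjustment. Groups with
#' fewer than two replicates are dropped (and logged); fewer than two
#' surviving groups yields a no-test report.
#'
#' @param dct_groups named list of numeric dCt replicate vectors, one per
#'   tissue, or a data.frame with columns `tissue` and `dct`.
#' @param alpha significance level, default 0.05.
#' @param gene_id optional label carried into the report.
#' @return Object of class `qpcr_test`: list with `gene_id`, `levene_p`,
#'   `branch` (`"parametric"`, `"nonparametric"`, or `"none"`),
#'   `omnibus_p`, `posthoc` (pairwise table with adjusted p-values),
#'   `alpha`, `dropped` (groups removed, with reasons), `significant`.
#' @export
tissue_comparison_test <- function(dct_groups, alpha = 0.05, gene_id = NA) {
  if (is.data.frame(dct_groups))
    dct_groups <- split(dct_groups$dct, dct_groups$tissue)
  dct_groups <- lapply(dct_groups, function(v) v[!is.na(v)])
  small <- names(dct_groups)[lengths(dct_groups) < 2L]
  dropped <- if (length(small)) {
    data.frame(tissue = small, reason = "< 2 replicates after filtering",
               stringsAsFactors = FALSE)
  } else {
    data.frame(tissue = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  dct_groups <- dct_groups[lengths(dct_groups) >= 2L]
  if (length(dct_groups) < 2L) {
    return(structure(list(gene_id = gene_id, levene_p = NA_real_,
                          branch = "none", omnibus_p = NA_real_,
                          posthoc = NULL, alpha = alpha, dropped = dropped,
                          significant = NA),
                     class = "qpcr_test"))
  }
  y <- unlist(dct_groups, use.names = FALSE)
  g <- factor(rep(names(dct_groups), lengths(dct_groups)),
              levels = names(dct_groups))
  lev <- car::leveneTest(y, g, center = mean)
  levene_p <- lev[["Pr(>F)"]][1L]
  if (levene_p >= alpha) {
    branch <- "parametric"
    fit <- stats::aov(y ~ g)
    omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$g
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    posthoc <- data.frame(group1 = vapply(cmp, `[[`, "", 2L),
                          group2 = vapply(cmp, `[[`, "", 1L),
                          estimate = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          stringsAsFactors = FALSE, row.names = NULL)
  } else {
    branch <- "nonparametric"
    omnibus_p <- stats::kruskal.test(y, g)$p.value
    posthoc <- dunn_pairwise(y, g)
  }
  posthoc$significant <- posthoc$p_adj < alpha
  structure(list(gene_id = gene_id, levene_p = levene_p, branch = branch,
                 omnibus_p = omnibus_p, posthoc = posthoc, alpha = alpha,
                 dropped = dropped, significant = omnibus_p < alpha),
            class = "qpcr_test")
}

#' @export
print.qpcr_test <- function(x, ...) {
  if (!is.na(x$gene_id)) cat("Gene:", x$gene_id, "\n")
  if (x$branch == "none") {
    cat("No test performed (< 2 tissue groups with >= 2 replicates)\n")
    return(invisible(x))
  }
  lab <- if (x$branch == "parametric") "one-way ANOVA (P_p)" else
    "Kruskal-Wallis (P_np)"
  cat(sprintf("Levene P_L = %.4g -> %s branch\n%s omnibus P = %.4g%s\n",
              x$levene_p, x$branch, lab, x$omnibus_p,
              if (isTRUE(x$significant)) " *" else ""))
  if (nrow(x$dropped))
    cat("Dropped groups:", paste(x$dropped$tissue, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.qpcr_test <- function(object, ...) {
  print(object)
  if (!is.null(object$posthoc)) {
    cat("Pairwise comparisons (adjusted p-values):\n")
    print(object$posthoc, digits = 4)
  }
  invisible(object)
}

#' Run the full qRT-PCR testing workflow over a replicate table
#'
#' Per gene: compute dCt and relative expression, apply the detection
#' filter, then run the Levene-gated comparison on the dCt values. An
#' undetected replicate in a retained tissue contributes 0 on the
#' relative-expression scale; on the dCt scale it is dropped by default
#' (`undetected = "drop"`) or entered as dCt 0 (`undetected = "zero"`).
#'
#' @param measurements data.frame as from [read_qpcr_table()].
#' @param alpha significance level, default 0.05.
#' @param undetected how undetected replicates in retained tissues enter
#'   dCt-scale testing: `"drop"` (default) or `"zero"`.
#' @return Named list of [tissue_comparison_test()] reports, one per gene,
#'   each with the detection exclusions attached as `excluded_tissues`.
#' @export
qpcr_workflow <- function(measurements, alpha = 0.05,
                          undetected = c("drop", "zero")) {
  undetected <- match.arg(undetected)
  m <- compute_dct(measurements)
  reports <- lapply(split(m, m$gene), function(mg) {
    flt <- filter_detection(mg)
    inc <- flt$included
    if (undetected == "zero") inc$dct[!inc$detected] <- 0
    rep <- tissue_comparison_test(
      data.frame(tissue = inc$tissue, dct = inc$dct), alpha = alpha,
      gene_id = mg$gene[1L])
    rep$excluded_tissues <- flt$excluded
    rep
  })
  reports
}

#' Flatten qPCR reports into the per-gene summary table
#'
#' One row per gene: Levene p (P_L), branch, omnibus p, smallest adjusted
#' pairwise p, significance stars at 0.05 / 0.01.
#'
#' @param reports output of [qpcr_workflow()].
#' @return data.frame.
#' @export
qpcr_report_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    min_p <- if (is.null(r$posthoc) || !nrow(r$posthoc)) NA_real_ else
      min(r$posthoc$p_adj)
    stars <- if (is.na(r$omnibus_p)) "" else
      if (r$omnibus_p < 0.01) "**" else if (r$omnibus_p < 0.05) "*" else ""
    data.frame(gene = r$gene_id, levene_p = r$levene_p, branch = r$branch,
               omnibus_p = r$omnibus_p, min_pairwise_p_adj = min_p,
               stars = stars,
               excluded_tissues = paste(r$excluded_tissues$tissue,
                                        collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
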