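test_that("dCt and relative expression follow the 2^-dCt convention", {
  m <- compute_dct(data.frame(ct_target = c(25, 20, NA),
                              ct_reference = c(20, 20, 20),
                              detected = c(TRUE, TRUE, FALSE)))
  expect_equal(m$dct, c(5, 0, NA))
  expect_equal(m$rel_expr, c(2^-5, 1, 0))

  expect_error(compute_dct(data.frame(ct_target = NA, ct_reference = 20,
                                      detected = TRUE)),
               "missing Ct")
})

test_that("relative expression decreases strictly with dCt", {
  dct <- sort(runif(20, -5, 15))
  rel <- compute_dct(data.frame(ct_target = 20 + dct, ct_reference = 20,
                                detected = TRUE))$rel_expr
  expect_true(all(diff(rel) < 0))
})

test_that("detection filter excludes tissues with >= 2 undetected sets", {
  m <- data.frame(
    gene = "g1",
    tissue = rep(c("heart", "ovary", "stomach"), each = 4),
    replicate_set = rep(1:4, 3),
    detected = c(TRUE, TRUE, FALSE, FALSE,   # 2 undetected -> excluded
                 TRUE, TRUE, TRUE, FALSE,    # 1 undetected -> retained
                 TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  flt <- filter_detection(m)
  expect_equal(flt$excluded$tissue, "heart")
  expect_setequal(unique(flt$included$tissue), c("ovary", "stomach"))
  expect_equal(sum(!flt$included$detected), 1L)
})

test_that("equal-variance groups take the parametric ANOVA branch", {
  set.seed(101)
  groups <- lapply(setNames(1:5, paste0("t", 1:5)),
                   function(i) rnorm(4, mean = 10, sd = 0.5))
  groups$t1 <- groups$t1 - 6   # strong shift in one tissue
  rep <- tissue_comparison_test(groups)
  expect_equal(rep$branch, "parametric")
  expect_gte(rep$levene_p, 0.05)
  expect_lt(rep$omnibus_p, 0.05)
  expect_true(rep$significant)
  # independent oracle: classical equal-variance one-way ANOVA
  y <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)))
  expect_equal(rep$omnibus_p,
               stats::oneway.test(y ~ g, var.equal = TRUE)$p.value)
  # Tukey rows cover every tissue pair, with significance at the shift
  expect_equal(nrow(rep$posthoc), choose(5, 2))
  t1_rows <- rep$posthoc[rep$posthoc$group1 == "t1" |
                           rep$posthoc$group2 == "t1", ]
  expect_true(all(t1_rows$p_adj < 0.05))
})

test_that("unequal variances route to Kruskal-Wallis with Dunn post hoc", {
  set.seed(202)
  groups <- list(a = rnorm(6, 0, 0.05), b = rnorm(6, 0, 5),
                 c = rnorm(6, 8, 0.05))
  rep <- tissue_comparison_test(groups)
  expect_equal(rep$branch, "nonparametric")
  expect_lt(rep$levene_p, 0.05)
  y <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)))
  expect_equal(rep$omnibus_p, stats::kruskal.test(y, g)$p.value)
  expect_true(all(rep$posthoc$p_adj >= rep$posthoc$p_raw))
  expect_equal(rep$posthoc$p_adj,
               pmin(1, rep$posthoc$p_raw * nrow(rep$posthoc)))
})

test_that("Dunn z-statistics match a hand computation without ties", {
  # two groups reduce to the normal approximation on rank sums
  vals <- c(1, 2, 3, 10, 11, 12)
  grp <- rep(c("lo", "hi"), each = 3)
  d <- tissuesim:::dunn_pairwise(vals, grp)
  # mean ranks 2 and 5, N = 6: z = (5 - 2) / sqrt((6*7/12)*(2/3))
  expect_equal(abs(d$statistic), 3 / sqrt((6 * 7 / 12) * (2 / 3)))
})

test_that("small groups are dropped and <2 groups means no test", {
  groups <- list(a = c(1, 2, 3), b = 5, c = c(2, 3, 4))
  rep <- tissue_comparison_test(groups)
  expect_equal(rep$dropped$tissue, "b")
  expect_true(rep$branch %in% c("parametric", "nonparametric"))

  rep2 <- tissue_comparison_test(list(a = c(1, 2), b = 7))
  expect_equal(rep2$branch, "none")
  expect_true(is.na(rep2$omnibus_p))
})

test_that("branch choice is a pure function of the data", {
  set.seed(77)
  groups <- lapply(setNames(1:4, paste0("t", 1:4)), function(i) rnorm(4))
  r1 <- tissue_comparison_test(groups)
  r2 <- tissue_comparison_test(groups)
  expect_identical(r1[c("levene_p", "branch", "omnibus_p")],
                   r2[c("levene_p", "branch", "omnibus_p")])
})

test_that("the workflow wires detection filtering into per-gene reports", {
  genes <- data.frame(gene_id = c("gA", "gB"),
                      tissue = c("neural_complex", NA),
                      stringsAsFactors = FALSE)
  tissues <- c("neural_complex", "heart", "ovary", "stomach")
  und <- data.frame(gene_id = "gB", tissue = "heart", n_sets = 2,
                    stringsAsFactors = FALSE)
  m <- generate_qpcr_dataset(genes, tissues, effect_dct = 8,
                             n_replicates = 4, noise_sd = 0.3,
                             undetected = und, seed = 5)
  reports <- qpcr_workflow(m)
  expect_named(reports, c("gA", "gB"))
  expect_equal(reports$gB$excluded_tissues$tissue, "heart")
  expect_true(reports$gA$significant)
  tab <- qpcr_report_table(reports)
  expect_equal(tab$gene, c("gA", "gB"))
  expect_equal(tab$excluded_tissues, c("", "heart"))
  expect_equal(tab$stars[1], "**")
})
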