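# shared fixtures and independent reference (oracle) implementations

# 9-group adult-ascidian-style scheme: siphons and intestine are composite
ciona_scheme <- function() {
  tissue_scheme(list(
    siphons = c("oral_siphon", "atrial_siphon"),
    neural_complex = "neural_complex",
    endostyle = "endostyle",
    heart = "heart",
    ovary = "ovary",
    pharynx = "pharynx",
    stomach = "stomach",
    intestine = c("intestine_prox", "intestine_mid", "intestine_dist")))
}

make_expr <- function(values, genes, samples, units = "rpkm") {
  expr_matrix(matrix(values, nrow = length(genes), byrow = TRUE,
                     dimnames = list(genes, samples)), units)
}

# naive double-loop TSG caller, the reference call_tsgs must agree with
naive_call_tsgs <- function(matrix, scheme, criteria = tsg_criteria()) {
  out <- list()
  for (g in rownames(matrix)) {
    for (lab in names(scheme)) {
      members <- scheme[[lab]]
      inside <- max(matrix[g, members])
      outside_samples <- setdiff(colnames(matrix), members)
      outside <- if (length(outside_samples))
        max(matrix[g, outside_samples]) else 0
      if (inside > criteria$high && outside < criteria$low)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, group_label = lab, max_in_group = inside,
          max_outside_group = outside, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), group_label = character(),
               max_in_group = numeric(), max_outside_group = numeric())
  res <- res[order(res$group_label, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# brute-force similarity recount
naive_tissue_similarity <- function(profiles, degenerate, threshold = 0.8) {
  n <- 0L
  counts <- stats::setNames(numeric(ncol(profiles)), colnames(profiles))
  for (i in seq_len(nrow(profiles))) {
    if (degenerate[i]) next
    n <- n + 1L
    for (t in colnames(profiles))
      if (profiles[i, t] > threshold) counts[t] <- counts[t] + 1
  }
  counts / n
}

# build a small synthetic study on disk and return the pipeline config list
write_fixture <- function(dir, seed = 17, with_qpcr = TRUE) {
  scheme <- ciona_scheme()
  sim <- generate_focal_expression(150, scheme, 3, seed = seed)
  write_expression_table(sim$matrix, file.path(dir, "focal.tsv"))
  bias <- list(neural_complex = list(tissue = "brain", q = 0.8))
  tg_m <- generate_target_species(sim$truth, "mouse",
                                  c("brain", "liver", "kidney", "heart"),
                                  bias_map = bias, seed = seed)
  tg_z <- generate_target_species(sim$truth, "zebrafish",
                                  c("brain", "gill", "muscle"),
                                  bias_map = bias, seed = seed + 1)
  write_expression_table(tg_m$expr, file.path(dir, "mouse_expr.tsv"))
  write_expression_table(tg_z$expr, file.path(dir, "zebrafish_expr.tsv"))
  write_blast_tabular(tg_m$blast, file.path(dir, "mouse.blast"))
  write_blast_tabular(tg_z$blast, file.path(dir, "zebrafish.blast"))
  cfg <- list(
    focal_expression = file.path(dir, "focal.tsv"),
    tissue_scheme = lapply(unclass(scheme), as.list),
    species = list(
      list(name = "mouse", blast = file.path(dir, "mouse.blast"),
           expression = file.path(dir, "mouse_expr.tsv")),
      list(name = "zebrafish", blast = file.path(dir, "zebrafish.blast"),
           expression = file.path(dir, "zebrafish_expr.tsv"))))
  if (with_qpcr) {
    genes <- data.frame(gene_id = c("gA", "gB"),
                        tissue = c("neural_complex", NA),
                        stringsAsFactors = FALSE)
    qp <- generate_qpcr_dataset(genes,
                                c("neural_complex", "heart", "ovary"),
                                seed = seed)
    utils::write.table(qp, file.path(dir, "qpcr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg$qpcr <- file.path(dir, "qpcr.tsv")
  }
  cfg
}

random_scheme <- function(samples, n_groups) {
  cut <- sort(sample(seq_len(length(samples) - 1L), n_groups - 1L))
  idx <- findInterval(seq_along(samples), c(0, cut) + 1L)
  tissue_scheme(split(samples, paste0("grp", idx)))
}
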