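test_that("min-max normalization pins min to 0 and max to 1", {
  expect_equal(as.numeric(minmax_normalize(c(a = 2, b = 4, c = 10))),
               c(0, 0.25, 1))
  flat <- minmax_normalize(c(a = 5, b = 5, c = 5))
  expect_true(attr(flat, "degenerate"))
  expect_equal(as.numeric(flat), c(0, 0, 0))
  two <- minmax_normalize(c(a = 0, b = 1))
  expect_equal(as.numeric(two), c(0, 1))
  expect_false(attr(two, "degenerate"))
  expect_error(minmax_normalize(c(a = 1)), ">= 2 tissues")
})

test_that("similarity counts profiles above the threshold per tissue", {
  prof <- rbind(p1 = c(a = 1, b = 0.85, c = 0),
                p2 = c(a = 1, b = 0, c = 0.3))
  sim <- tissue_similarity(prof)
  expect_equal(unname(sim[c("a", "b", "c")]), c(1, 0.5, 0))
  expect_equal(attr(sim, "n"), 2L)
  expect_gt(sum(sim), 1)  # a gene may be high in several tissues

  exact <- rbind(p1 = c(a = 0.8, b = 1))
  expect_equal(unname(tissue_similarity(exact)["a"]), 0)  # strict >

  expect_error(tissue_similarity(prof, degenerate = c(TRUE, TRUE)),
               "no non-degenerate")
})

test_that("similarity matches a brute-force recount on random instances", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(2:500, 1)
    t <- sample(2:30, 1)
    prof <- matrix(runif(n * t), n, t,
                   dimnames = list(paste0("p", 1:n), paste0("t", 1:t)))
    deg <- runif(n) < 0.1
    if (all(deg)) deg[1] <- FALSE
    prof[deg, ] <- 0
    got <- tissue_similarity(prof, deg)
    want <- naive_tissue_similarity(prof, deg)
    expect_equal(unclass(got), want, ignore_attr = TRUE)
  }
})

test_that("each non-degenerate profile with a unique max is always counted", {
  set.seed(3)
  prof <- matrix(runif(50 * 8), 50, 8,
                 dimnames = list(paste0("p", 1:50), paste0("t", 1:8)))
  norm <- minmax_normalize(prof)
  sim <- tissue_similarity(norm$values, norm$degenerate)
  counts <- sim * attr(sim, "n")
  expect_gte(sum(counts), sum(!norm$degenerate))
})

test_that("similarity_matrix resolves best-hit profiles per focal group", {
  tsgs <- data.frame(gene_id = c("g1", "g2"),
                     group_label = "neural_complex",
                     stringsAsFactors = FALSE)
  map <- data.frame(query_id = c("g1", "g2"), species = "mouse",
                    subject_id = c("NP_1", "NP_1"),  # shared subject
                    evalue = 1e-10, bitscore = 100, stringsAsFactors = FALSE)
  target <- make_expr(c(0.1, 0.2, 9), "NP_1",
                      c("liver", "kidney", "brain"))
  sim <- similarity_matrix(tsgs, map, target, "mouse")
  # both TSGs map to the same subject: denominator counts TSG-homolog pairs
  expect_equal(unname(sim$n["neural_complex"]), 2L)
  expect_equal(unname(sim$values["neural_complex", "brain"]), 1)
  expect_equal(unname(sim$values["neural_complex", "liver"]), 0)
})

test_that("unresolvable subjects and degenerate profiles are logged", {
  tsgs <- data.frame(gene_id = c("g1", "g2", "g3"), group_label = "heart",
                     stringsAsFactors = FALSE)
  map <- data.frame(query_id = c("g1", "g2", "g3"), species = "mouse",
                    subject_id = c("NP_1", "NP_flat", "NP_missing"),
                    evalue = 1e-10, bitscore = 100, stringsAsFactors = FALSE)
  target <- make_expr(c(0, 1, 5, 2, 2, 2), c("NP_1", "NP_flat"),
                      c("t1", "t2", "t3"))
  sim <- similarity_matrix(tsgs, map, target, "mouse")
  expect_equal(unname(sim$dropped["heart"]), 1L)
  expect_equal(unname(sim$degenerate["heart"]), 1L)
  expect_equal(unname(sim$n["heart"]), 1L)
})

test_that("replicate target columns are averaged before normalization", {
  tsgs <- data.frame(gene_id = "g1", group_label = "heart",
                     stringsAsFactors = FALSE)
  map <- data.frame(query_id = "g1", species = "mouse", subject_id = "NP_1",
                    evalue = 1e-10, bitscore = 100, stringsAsFactors = FALSE)
  target <- make_expr(c(8, 10, 0, 1), "NP_1",
                      c("brain_r1", "brain_r2", "liver_r1", "liver_r2"))
  sim <- similarity_matrix(tsgs, map, target, "mouse",
                           tissue_of = c(brain_r1 = "brain",
                                         brain_r2 = "brain",
                                         liver_r1 = "liver",
                                         liver_r2 = "liver"))
  expect_equal(colnames(sim$values), c("brain", "liver"))
  expect_equal(unname(sim$values["heart", "brain"]), 1)
})

test_that("clustering is deterministic and merges by linkage distance", {
  prof <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  cl <- cluster_profiles(prof)
  # a-b at distance 1 merge first; c joins at complete-linkage height 10
  expect_equal(cl$hclust$height, c(1, 10))
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))

  dup <- rbind(a = c(0, 5), b = c(0, 5), c = c(3, 1), d = c(9, 9))
  expect_equal(min(cluster_profiles(dup)$hclust$height), 0)

  set.seed(8)
  m <- matrix(runif(40), 10, 4, dimnames = list(letters[1:10], NULL))
  perm <- sample(10)
  h1 <- cluster_profiles(m)$hclust
  h2 <- cluster_profiles(m[perm, ])$hclust
  expect_equal(h1$height, h2$height)
  expect_identical(cluster_profiles(m)$leaf_ranks$gene_id,
                   cluster_profiles(m)$leaf_ranks$gene_id)
  expect_error(cluster_profiles(m[1, , drop = FALSE]), ">= 2 profiles")
})

test_that("network export filters, tags species, and round-trips", {
  vals <- matrix(c(0.625, 0.1, 0.3, NA), 2, 2,
                 dimnames = list(c("nc", "heart"), c("brain", "liver")))
  sim <- structure(list(values = vals, n = c(nc = 4L, heart = 3L),
                        dropped = c(nc = 0L, heart = 0L),
                        degenerate = c(nc = 0L, heart = 0L),
                        species = "mouse", high_fraction = 0.8),
                   class = "tissue_similarity_matrix")
  net <- export_network(sim)
  expect_equal(nrow(net$edges), 3L)
  single <- net$edges[net$edges$source == "focal:nc" &
                        net$edges$target == "mouse:brain", ]
  expect_equal(single$weight, 0.625)
  expect_false(any(net$edges$source == net$edges$target))

  filtered <- export_network(sim, min_edge = 0.2)
  expect_equal(sort(filtered$edges$weight), c(0.3, 0.625))

  empty <- export_network(structure(
    list(values = vals[0, , drop = FALSE], n = integer(), dropped = integer(),
         degenerate = integer(), species = "mouse", high_fraction = 0.8),
    class = "tissue_similarity_matrix"))
  expect_equal(nrow(empty$edges), 0L)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network_edges(path)
  expect_equal(back$weight, net$edges$weight)
  expect_equal(back$source, net$edges$source)
  expect_equal(back$target, net$edges$target)
})
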