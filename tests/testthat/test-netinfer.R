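test_that("cluster aggregation is additive and warns on unmapped ids", {
  m <- rbind(a = c(0.1, 0.2), b = c(0.2, 0.1), c = c(0.7, 0.7))
  colnames(m) <- c("s1", "s2")
  tab <- otu_table(m, mode = "relative")
  map <- data.frame(otu_id = c("a", "b", "c"),
                    cluster = c("C1", "C1", "C2"))
  agg <- aggregate_clusters(tab, map)
  expect_equal(unname(unclass(agg)["C1", ]), c(0.3, 0.3))
  expect_equal(unname(unclass(agg)["C2", ]), c(0.7, 0.7))  # singleton

  map2 <- rbind(map, data.frame(otu_id = "ghost", cluster = "C3"))
  expect_warning(agg2 <- aggregate_clusters(tab, map2), "absent")
  expect_setequal(rownames(agg2), c("C1", "C2"))

  map3 <- data.frame(otu_id = "ghost", cluster = "C3")
  expect_warning(expect_warning(agg3 <- aggregate_clusters(tab, map3),
                                "absent"), "no mapped OTUs")
  expect_equal(nrow(agg3), 0)
})

test_that("pairwise scores capture linear and monotone association", {
  n <- 12
  x <- seq(0.01, 0.2, length.out = n)
  tab <- rbind(f1 = x, f2 = 2 * x, f3 = exp(5 * x), f4 = rep(0.1, n))
  colnames(tab) <- sprintf("s%02d", 1:n)
  expect_message(sc <- pairwise_scores(tab), "zero-variance")
  lin <- sc[sc$source == "f1" & sc$target == "f2", ]
  expect_equal(lin$pearson, 1)
  expect_equal(lin$spearman, 1)
  mono <- sc[sc$source == "f1" & sc$target == "f3", ]
  expect_equal(mono$spearman, 1)
  expect_lt(mono$pearson, 1)
  expect_false("f4" %in% c(sc$source, sc$target))
})

test_that("reboot null is calibrated, extreme for planted pairs, deterministic", {
  X <- planted_block_table(n_block = 2, n_noise = 20, strength = 2,
                           noise_sd = 0.1, seed = 3)
  strong <- reboot_null(X, c("B01", "B02"), "spearman", n_iter = 499,
                        seed = 1)
  expect_equal(strong$p_value, 1 / 500)

  # an observation at the null center is unremarkable
  weak <- reboot_null(X, c("N01", "N02"), "pearson", n_iter = 499, seed = 1)
  expect_gt(weak$p_value, 0.05)

  again <- reboot_null(X, c("B01", "B02"), "spearman", n_iter = 499,
                       seed = 1)
  expect_identical(strong$null, again$null)
  expect_identical(strong$p_value, again$p_value)

  # null mean of correlation measures sits near zero
  expect_lt(abs(mean(weak$null)), 0.1)
})

test_that("build_network recovers a planted block with correct signs", {
  X <- planted_block_table(n_block = 4, n_noise = 25, seed = 11)
  net <- build_network(X, n_iter = 1999, seed = 11)
  e <- net$edges
  block_edges <- e[grepl("^B", e$source) & grepl("^B", e$target), ]
  expect_gte(nrow(block_edges), 5)       # of 6 block pairs
  expect_true(all(block_edges$sign == "+"))
  expect_true(all(e$q <= net$fdr))
  expect_true(all(e$support >= net$min_support))
  expect_false(any(e$source == e$target))

  # anti-correlated features carry the negative sign convention
  Xn <- planted_block_table(n_block = 2, n_noise = 25, negative = TRUE,
                            strength = 1.5, seed = 13)
  net2 <- build_network(Xn, n_iter = 1999, seed = 13)
  neg <- net2$scored_pairs[net2$scored_pairs$source == "B01" &
                             net2$scored_pairs$target == "B02", ]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$sign, "-")
  expect_lt(neg$p_merged, 0.05)
})

test_that("edge sets are invariant to sample and feature order", {
  X <- planted_block_table(n_block = 3, n_noise = 10, seed = 21)
  net1 <- build_network(X, n_iter = 299, seed = 5)
  Xp <- X[sample(nrow(X)), sample(ncol(X))]
  net2 <- build_network(Xp, n_iter = 299, seed = 5)
  key <- function(net) paste(net$edges$source, net$edges$target)
  expect_identical(sort(key(net1)), sort(key(net2)))
})

test_that("cluster-cluster pairs are excluded and node kinds recorded", {
  X <- planted_block_table(n_block = 2, n_noise = 6, seed = 31)
  cl <- rbind(Cl1 = colMeans(X[3:5, ]), Cl2 = colMeans(X[6:8, ]))
  colnames(cl) <- colnames(X)
  net <- build_network(X, cl, n_iter = 99, seed = 2)
  expect_setequal(unique(net$nodes$kind), c("otu", "cfix_cluster"))
  sp <- net$scored_pairs
  kinds <- stats::setNames(net$nodes$kind, net$nodes$id)
  expect_false(any(kinds[sp$source] == "cfix_cluster" &
                     kinds[sp$target] == "cfix_cluster"))
})

test_that("networks export to edge list TSV and igraph", {
  X <- planted_block_table(n_block = 3, n_noise = 8, seed = 41)
  net <- build_network(X, n_iter = 299, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  lines <- readLines(path)
  expect_match(lines[1], "^source\ttarget\tsign")
  expect_length(lines, nrow(net$edges) + 1)
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
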