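test_that("simulate_tree yields valid, reproducible Yule trees", {
  expect_error(simulate_tree(1), "n_tips")

  t2 <- simulate_tree(2, seed = 1)
  expect_length(t2$tip.label, 2)
  expect_gt(patristic_matrix(t2)[1, 2], 0)

  a <- ape::write.tree(simulate_tree(50, seed = 1))
  b <- ape::write.tree(simulate_tree(50, seed = 1))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_tree(50, seed = 2))))

  t100 <- simulate_tree(100, seed = 5)
  expect_length(t100$tip.label, 100)
  expect_false(anyDuplicated(t100$tip.label) > 0)
  expect_true(all(t100$edge.length > 0))
  # rooted binary: n - 1 internal nodes, 2(n - 1) edges
  expect_equal(t100$Nnode, 99)
  expect_equal(nrow(t100$edge), 198)
})

test_that("evolve_trait is Brownian with the requested rate", {
  tr <- toy_tree()
  expect_equal(unname(evolve_trait(tr, 0, seed = 1)), c(0, 0, 0))

  sisters <- ape::read.tree(text = "((A:0.001,B:0.001):2,C:2.001);")
  tv <- evolve_trait(sisters, 1, seed = 3)
  expect_lt(abs(tv["A"] - tv["B"]), 0.2)

  # Monte-Carlo check of the variance on a fixed 2-tip tree of depth 1.5
  two <- ape::read.tree(text = "(A:1.5,B:1.5);")
  sigma2 <- 2
  tips <- vapply(1:500, function(s) evolve_trait(two, sigma2, seed = s)["A"],
                 numeric(1))
  expect_lt(abs(var(tips) - sigma2 * 1.5) / (sigma2 * 1.5), 0.15)
})

test_that("sample_community implements Gaussian niche filtering", {
  traits <- stats::setNames(c(-2, -1, 0, 1, 2), paste0("t", 1:5))
  meta <- rep(0.2, 5)

  x <- sample_community(traits, meta, env_value = 0, filtering_strength = 0,
                        depth = 1000, seed = 1)
  expect_equal(sum(x), 1000)
  expect_true(all(x >= 0))

  # neutral limit: the environment has no effect at all (identical draws
  # for any env_value with the same seed) and frequencies track the
  # metacommunity
  meta2 <- c(0.5, 0.2, 0.1, 0.1, 0.1)
  n1 <- sample_community(traits, meta2, env_value = -5,
                         filtering_strength = 0, depth = 1e5, seed = 99)
  n2 <- sample_community(traits, meta2, env_value = +5,
                         filtering_strength = 0, depth = 1e5, seed = 99)
  expect_identical(n1, n2)
  expect_lt(max(abs(n1 / 1e5 - meta2)), 0.01)

  # strong filtering concentrates on the optimum nearest env_value
  y <- sample_community(traits, meta, env_value = 1.9,
                        filtering_strength = 50, niche_breadth = 1,
                        depth = 5000, seed = 2)
  expect_equal(names(which.max(y)), "t5")
  expect_gt(y["t5"] / 5000, 0.95)

  expect_error(
    sample_community(traits, meta, env_value = 100,
                     filtering_strength = 1e6, depth = 10),
    "degenerate niche")
})

test_that("generate_dataset matches the sampling design and is reproducible", {
  cfg <- sim_config(n_tips = 40, replicates_per_cell = 6,
                    sequencing_depth = 300, seed = 11)
  ds <- generate_dataset(cfg)
  expect_equal(ncol(ds$otu), 3 * 2 * 6)
  expect_equal(unname(colSums(ds$otu)), rep(300, 36))
  expect_true(all(grepl("^W[ABC][12]_r\\d+$", colnames(ds$otu))))
  expect_setequal(unique(ds$env$station), c("WA", "WB", "WC"))
  expect_setequal(unique(ds$env$layer), c("surface", "bottom"))
  expect_gte(length(unique(ds$cluster_map$cluster)), 2)
  expect_true(all(ds$cluster_map$otu_id %in% ds$tree$tip.label))
  expect_setequal(rownames(ds$cbbl), ds$cluster_map$otu_id)

  # byte-identical files from the same seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_dataset(generate_dataset(cfg), d1)
  p2 <- write_dataset(generate_dataset(cfg), d2)
  for (k in seq_along(p1))
    expect_identical(readLines(p1[k]), readLines(p2[k]))
})

test_that("filtering strength monotonically increases between-station turnover", {
  mono <- vapply(1:8, function(s) {
    ms <- vapply(c(0, 2, 6), function(fs) {
      cfg <- sim_config(n_tips = 60, n_layers = 1, replicates_per_cell = 3,
                        sequencing_depth = 800, filtering_strength = fs,
                        seed = s)
      ds <- generate_dataset(cfg)
      st <- stats::setNames(ds$env$station, ds$env$sample_id)
      bc <- as.matrix(bray_curtis(ds$otu))
      idx <- which(outer(st[rownames(bc)], st[colnames(bc)], "!=") &
                     upper.tri(bc))
      mean(bc[idx])
    }, numeric(1))
    all(diff(ms) > 0)
  }, logical(1))
  expect_gte(mean(mono), 0.8)
})
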