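test_that("patristic distances equal an independent path-sum oracle", {
  d <- patristic_matrix(toy_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))

  # brute-force shortest paths on the tree seen as a weighted graph
  for (s in 1:20) {
    tr <- simulate_tree(sample(4:12, 1), seed = s)
    g <- igraph::graph_from_edgelist(apply(tr$edge, 2, as.character),
                                     directed = FALSE)
    igraph::E(g)$weight <- tr$edge.length
    sp <- igraph::distances(g, v = as.character(seq_along(tr$tip.label)),
                            to = as.character(seq_along(tr$tip.label)))
    dimnames(sp) <- list(tr$tip.label, tr$tip.label)
    mine <- patristic_matrix(tr)
    expect_equal(mine, sp[rownames(mine), colnames(mine)],
                 tolerance = 1e-12)
  }
})

test_that("bmntd matches hand computation and is symmetric", {
  d <- patristic_matrix(toy_tree())
  expect_equal(bmntd(c(A = 1, B = 2), c(A = 1, B = 2), d), 0)
  expect_equal(bmntd(c(A = 1), c(B = 1), d), 2)
  # 0.5 * ((0.75*2 + 0.25*4) + 1*2) = 2.25
  expect_equal(bmntd(c(A = 3, C = 1), c(B = 1), d), 2.25)
  expect_identical(bmntd(c(A = 3, C = 1), c(B = 1), d),
                   bmntd(c(B = 1), c(A = 3, C = 1), d))

  # unweighted: equal taxon weights
  expect_equal(bmntd(c(A = 3, C = 1), c(B = 1), d, weighted = FALSE),
               0.5 * ((0.5 * 2 + 0.5 * 4) + 2))

  expect_error(bmntd(c(A = 0), c(B = 1), d), "empty community")
  expect_error(bmntd(c(Z = 1), c(B = 1), d), "absent from the tree")
})

test_that("bmntd agrees with picante on random data", {
  skip_if_not_installed("picante")
  set.seed(8)
  tr <- simulate_tree(15, seed = 9)
  cm <- matrix(rpois(4 * 15, 3), nrow = 4,
               dimnames = list(paste0("s", 1:4), tr$tip.label))
  D <- patristic_matrix(tr)
  mine <- outer(1:4, 1:4, Vectorize(function(i, j)
    if (i == j) 0 else bmntd(cm[i, ], cm[j, ], D)))
  ref <- as.matrix(picante::comdistnt(cm, stats::cophenetic(tr),
                                      abundance.weighted = TRUE))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("tip-shuffle null is reproducible and matches exhaustive moments", {
  pair <- disjoint_pair_on_tree(3)
  n1 <- null_bmntd(pair$a, pair$b, pair$tree, n_null = 99, seed = 5)
  n2 <- null_bmntd(pair$a, pair$b, pair$tree, n_null = 99, seed = 5)
  expect_identical(n1, n2)

  # 5-tip exhaustive (120 permutations) vs sampled moments within 5%
  for (s in c(2, 4, 6)) {
    p <- disjoint_pair_on_tree(s)
    ex <- null_bmntd(p$a, p$b, p$tree, exhaustive = TRUE)
    expect_equal(length(ex), factorial(length(p$tree$tip.label)))
    sm <- null_bmntd(p$a, p$b, p$tree, n_null = 999, seed = s)
    expect_lt(abs(mean(sm) - mean(ex)) / mean(ex), 0.05)
    expect_lt(abs(sd(sm) - sd(ex)) / sd(ex), 0.25)
  }
})

test_that("a distance-degenerate topology is flagged, not mis-scored", {
  # star tree: all tip-to-tip distances equal, the null cannot vary
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  m <- cbind(s1 = c(5, 1, 0, 0), s2 = c(0, 0, 2, 4))
  rownames(m) <- c("A", "B", "C", "D")
  ot <- otu_table(m, mode = "counts")
  expect_warning(res <- bnti_matrix(ot, star, n_null = 49, seed = 1),
                 "degenerate null")
  expect_true(is.na(res$pairs$bnti[1]))
})

test_that("betaNTI is scale-covariant in branch lengths", {
  pair <- disjoint_pair_on_tree(11)
  tr2 <- pair$tree
  tr2$edge.length <- tr2$edge.length * 1000
  obs1 <- bmntd(pair$a, pair$b, patristic_matrix(pair$tree))
  obs2 <- bmntd(pair$a, pair$b, patristic_matrix(tr2))
  expect_equal(obs2, obs1 * 1000, tolerance = 1e-9)
  n1 <- null_bmntd(pair$a, pair$b, pair$tree, n_null = 199, seed = 2)
  n2 <- null_bmntd(pair$a, pair$b, tr2, n_null = 199, seed = 2)
  z1 <- (obs1 - mean(n1)) / sd(n1)
  z2 <- (obs2 - mean(n2)) / sd(n2)
  expect_lt(abs(z1 - z2), 1e-9)
})

test_that("bnti_matrix stores consistent fields and classifications", {
  cfg <- sim_config(n_tips = 30, n_layers = 1, replicates_per_cell = 3,
                    sequencing_depth = 300, filtering_strength = 2,
                    seed = 6)
  ds <- generate_dataset(cfg)
  res <- suppressWarnings(bnti_matrix(ds$otu, ds$tree, n_null = 99,
                                      seed = 4))
  p <- res$pairs
  expect_equal(nrow(p), choose(9, 2))
  ok <- !is.na(p$bnti)
  expect_equal(p$bnti[ok], (p$bmntd_obs[ok] - p$null_mean[ok]) /
                 p$null_sd[ok], tolerance = 1e-12)
  expect_identical(p$deterministic[ok], abs(p$bnti[ok]) > 2)

  res2 <- suppressWarnings(bnti_matrix(ds$otu, ds$tree, n_null = 99,
                                       seed = 4))
  expect_identical(res$pairs, res2$pairs)
})

test_that("group fractions count within-group pairs exactly", {
  fake <- structure(list(
    pairs = data.frame(
      sample_i = c("a1", "a1", "a2", "a1", "b1"),
      sample_j = c("a2", "a3", "a3", "b1", "b2"),
      bmntd_obs = 1, null_mean = 1, null_sd = 1,
      bnti = c(3, 0, -2.5, 5, 1),
      deterministic = c(TRUE, FALSE, TRUE, TRUE, FALSE)),
    n_null = 99, seed = 1, weighted = TRUE), class = "assembly_result")
  grouping <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  gf <- group_fractions(fake, grouping)
  expect_equal(gf$n_pairs, c(3L, 1L))
  expect_equal(gf$n_deterministic, c(2L, 0L))
  expect_equal(gf$fraction_deterministic, c(2 / 3, 0))
  expect_equal(gf$percent, c(66.7, 0))
  # |bnti| exactly 2 would be stochastic: strict inequality
  fake$pairs$bnti[1] <- 2
  gf2 <- group_fractions(fake, grouping)
  expect_equal(gf2$n_deterministic[1], 1L)

  expect_error(group_fractions(fake, grouping[-1]), "without a group")
})

test_that("group of six samples yields fifteen pairs", {
  cfg <- sim_config(n_tips = 60, n_stations = 1, n_layers = 1,
                    replicates_per_cell = 6, sequencing_depth = 200,
                    seed = 2)
  ds <- generate_dataset(cfg)
  res <- bnti_matrix(ds$otu, ds$tree, n_null = 49, seed = 1)
  gf <- group_fractions(res, stats::setNames(ds$env$station,
                                             ds$env$sample_id))
  expect_equal(gf$n_pairs, 15L)
})
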