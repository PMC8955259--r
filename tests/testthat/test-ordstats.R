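test_that("nmds embeds exactly embeddable configurations", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE,
               dimnames = list(paste0("p", 1:4), NULL))
  fit <- nmds(dist(sq), k = 2, n_restarts = 5, seed = 1)
  expect_lt(fit$stress, 1e-3)

  tri <- matrix(c(0, 0, 3, 0, 1, 2), 3, 2,
                dimnames = list(paste0("p", 1:3), NULL))
  expect_lt(nmds(dist(tri), k = 2, n_restarts = 5, seed = 1)$stress, 1e-6)
})

test_that("nmds is deterministic and internally consistent", {
  set.seed(4)
  y <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("s", 1:12), NULL))
  d <- dist(y)
  f1 <- nmds(d, seed = 7, n_restarts = 5)
  f2 <- nmds(d, seed = 7, n_restarts = 5)
  expect_identical(f1$points, f2$points)
  expect_identical(f1$stress, f2$stress)
  # stress recomputed independently from the returned coordinates
  expect_lt(abs(f1$stress - recompute_stress(f1$points, d)), 1e-10)
})

test_that("anosim matches the exhaustive oracle and detects separation", {
  set.seed(1)
  x <- rbind(matrix(rnorm(6, 0, 0.5), 3, 2), matrix(rnorm(6, 10, 0.5), 3, 2))
  rownames(x) <- paste0("s", 1:6)
  d <- dist(x)
  g <- rep(c("a", "b"), each = 3)
  fit <- anosim_test(d, g, n_permutations = 1e4, seed = 2)
  expect_equal(fit$statistic, 1)  # all between > all within

  # exhaustive 20-split enumeration of the R statistic
  rank_m <- matrix(0, 6, 6)
  rank_m[lower.tri(rank_m)] <- rank(as.vector(d))
  rank_m <- rank_m + t(rank_m)
  r_stat <- function(gg) {
    same <- outer(gg, gg, "==")[lower.tri(rank_m)]
    rk <- rank_m[lower.tri(rank_m)]
    (mean(rk[!same]) - mean(rk[same])) / (15 / 2)
  }
  splits <- utils::combn(6, 3)
  null_r <- apply(splits, 2, function(ix) {
    gg <- rep("b", 6); gg[ix] <- "a"; r_stat(gg)
  })
  p_exact <- mean(null_r >= r_stat(g))
  expect_lt(abs(fit$p_value - p_exact), 0.02)

  expect_error(anosim_test(d, c("a", rep("b", 5))), "at least 2 samples")
})

test_that("anosim null labels give R near 0 and uniform p-values", {
  out <- t(vapply(1:60, function(s) {
    set.seed(s)
    y <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
    gg <- sample(rep(c("a", "b"), each = 6))
    fit <- anosim_test(dist(y), gg, n_permutations = 199, seed = s)
    c(fit$statistic, fit$p_value)
  }, numeric(2)))
  expect_lt(abs(mean(out[, 1])), 0.1)
  ks <- suppressWarnings(stats::ks.test(out[, 2], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mantel and partial mantel behave on constructed cases", {
  set.seed(2)
  y <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  da <- dist(y)
  expect_equal(mantel_test(da, da, n_permutations = 99, seed = 1)$statistic,
               1)
  db <- da * 3
  expect_equal(mantel_test(da, db, n_permutations = 99, seed = 1)$statistic,
               1)
  const <- da; const[] <- 1
  expect_error(mantel_test(da, const, n_permutations = 99), "zero variance")

  # constant control degenerates to the plain test
  dc <- da; dc[] <- 2
  expect_warning(
    pm <- partial_mantel_test(da, db, dc, n_permutations = 99, seed = 1),
    "constant")
  expect_equal(pm$statistic,
               mantel_test(da, db, n_permutations = 99, seed = 1)$statistic)

  # conditional independence: a = c + noise, b = c + independent noise
  pr <- vapply(1:40, function(s) {
    set.seed(s)
    z <- matrix(rnorm(20), 10, 2)
    dz <- dist(z)
    d1 <- as.dist(as.matrix(dz) + as.matrix(dist(matrix(rnorm(10), 10))))
    d2 <- as.dist(as.matrix(dz) + as.matrix(dist(matrix(rnorm(10), 10))))
    partial_mantel_test(d1, d2, dz, n_permutations = 49, seed = s)$statistic
  }, numeric(1))
  expect_lt(abs(mean(pr)), 0.15)

  # a = b: partial correlation stays positive whatever the control
  set.seed(9)
  dd <- dist(matrix(rnorm(30), 10, 3))
  ctrl <- dist(matrix(rnorm(30), 10, 3))
  expect_gt(partial_mantel_test(dd, dd, ctrl, n_permutations = 49,
                                seed = 1)$statistic, 0.9)
})

test_that("hellinger transform has unit sample norms", {
  m <- cbind(s1 = c(1, 1, 1, 1), s2 = c(4, 0, 0, 0))
  rownames(m) <- paste0("o", 1:4)
  h <- hellinger(otu_table(m, mode = "counts"))
  expect_equal(unname(h["s1", ]), rep(0.5, 4))
  expect_equal(unname(h["s2", ]), c(1, 0, 0, 0))
  ot <- random_counts_table(30, 10, seed = 5)
  expect_equal(unname(rowSums(hellinger(ot)^2)), rep(1, 10))
})

test_that("rda explains a linear response perfectly and flags collinearity", {
  set.seed(3)
  n <- 30
  env <- data.frame(v1 = rnorm(n), v2 = rnorm(n))
  y <- outer(env$v1, c(1, 2, -1))
  fit <- rda_constrained(y, env, c("v1", "v2"))
  expect_equal(fit$total_explained, 1, tolerance = 1e-9)
  expect_true(all(diff(fit$prop_explained) <= 1e-12))
  expect_lte(sum(fit$prop_explained), 1 + 1e-12)

  env$v3 <- env$v1
  expect_error(rda_constrained(y, env, c("v1", "v3")), "collinear")

  # pure noise explains little
  y2 <- matrix(rnorm(n * 8), n, 8)
  fit2 <- rda_constrained(y2, env, "v1")
  expect_lt(fit2$total_explained, 0.15)
})

test_that("forward selection finds planted predictors and nothing else", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 36
    env <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    names(env) <- paste0("v", 1:8)
    y <- outer(env$v1, rnorm(10)) + outer(env$v2, rnorm(10)) +
      matrix(rnorm(n * 10, 0, 0.3), n, 10)
    sel <- forward_select(y, env, paste0("v", 1:8), alpha = 0.05,
                          n_permutations = 199, seed = s)
    identical(sort(sel$variable), c("v1", "v2"))
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # single dominant variable: selected first, at the permutation floor
  set.seed(5)
  n <- 36
  env <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  names(env) <- paste0("v", 1:4)
  y <- outer(env$v2, c(1, -1, 2))
  sel <- forward_select(y, env, paste0("v", 1:4), n_permutations = 199,
                        seed = 2)
  expect_equal(sel$variable[1], "v2")
  expect_equal(sel$p_value[1], 1 / 200)
})
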