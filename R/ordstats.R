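as_square_dist <- function(d, what = "distance matrix") {
  if (inherits(d, "dist")) return(d)
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
      stop(what, " must be symmetric and square")
    if (any(diag(d) != 0)) stop(what, " must have a zero diagonal")
    return(as.dist(d))
  }
  stop(what, " must be a 'dist' object or a square matrix")
}

upper_vec <- function(d) as.vector(as_square_dist(d))

check_aligned <- function(a, b, what = "distance matrices") {
  la <- attr(as_square_dist(a), "Labels")
  lb <- attr(as_square_dist(b), "Labels")
  if (attr(as_square_dist(a), "Size") != attr(as_square_dist(b), "Size"))
    stop(what, " differ in size")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop(what, " are not aligned on the same ids/order")
  invisible(TRUE)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal NMDS (stress-1, monotone regression on dissimilarity ranks with
#' primary tie treatment) via [vegan::monoMDS()], run from the default
#' metric-scaling start plus `n_restarts - 1` random starts; the lowest
#' stress solution is returned.  Non-convergence is reported in the
#' `converged` flag, never as an error.
#'
#' @param d a `dist` or square symmetric matrix.
#' @param k number of ordination axes (default 2).
#' @param n_restarts number of starts (default 20).
#' @param max_iter iterations per start.
#' @param seed integer seed making the random starts reproducible.
#' @return an object of class `nmds_result`: `points` (n x k), `stress`,
#'   `converged`, `n_restarts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 500, seed = 1) {
  d <- as_square_dist(d)
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k + 1 samples")
  set.seed(derive_seed(seed, "nmds"))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- if (r == 1) {
      vegan::monoMDS(d, k = k, model = "global", itmax = max_iter)
    } else {
      y0 <- matrix(rnorm(n * k), n, k)
      vegan::monoMDS(d, y = y0, k = k, model = "global", itmax = max_iter)
    }
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  rownames(pts) <- attr(d, "Labels")
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress,
                 converged = best$icause != 1L, n_restarts = n_restarts,
                 seed = seed),
            class = "nmds_result")
}

#' Recompute Kruskal stress-1 from a configuration
#'
#' Independent check of an NMDS solution: fits a monotone (isotonic)
#' regression of configuration distances on the input dissimilarity order
#' and returns sqrt(sum (d - dhat)^2 / sum d^2).
#'
#' @param points ordination coordinates (n x k).
#' @param d the dissimilarities the configuration was fitted to.
#' @return the stress-1 value.
#' @export
recompute_stress <- function(points, d) {
  d <- as_square_dist(d)
  dd <- as.vector(d)
  cd <- as.vector(dist(points))
  ord <- order(dd, cd)
  fit <- isoreg(cd[ord])$yf
  sqrt(sum((cd[ord] - fit)^2) / sum(cd^2))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between- versus within-group distances,
#' R = (mean between-rank - mean within-rank) / (M / 2) with
#' M = n(n-1)/2, tested by permuting group labels; the permutation p-value
#' carries the +1 correction so it is never exactly 0.
#'
#' @param d a `dist` or square symmetric matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return a `perm_test` list: `statistic` (R), `p_value`,
#'   `n_permutations`, `seed`.
#' @export
anosim_test <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- as_square_dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size"))
    stop("length of `groups` does not match the distance matrix")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(droplevels(groups)) < 2))
    stop("every group must contain at least 2 samples")
  set.seed(derive_seed(seed, "anosim"))
  fit <- vegan::anosim(d, groups, permutations = n_permutations)
  structure(list(statistic = unname(fit$statistic),
                 p_value = fit$signif,
                 n_permutations = n_permutations, seed = seed,
                 method = "ANOSIM"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Mantel and partial Mantel tests
#'
#' Correlation between the upper triangles of two distance matrices
#' (`mantel_test`), or between their residuals after removing a third
#' (`partial_mantel_test`); significance by jointly permuting the rows and
#' columns of one matrix.  A constant comparison matrix is an error (the
#' correlation is undefined); a constant *control* matrix degenerates the
#' partial test to the plain Mantel test and is handled that way with a
#' warning.
#'
#' @param dm_a,dm_b,dm_c aligned `dist` objects or square matrices.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return a `perm_test` list with `statistic` (r), `p_value`,
#'   `n_permutations`, `seed`.
#' @export
mantel_test <- function(dm_a, dm_b, method = c("pearson", "spearman"),
                        n_permutations = 999, seed = 1) {
  method <- match.arg(method)
  check_aligned(dm_a, dm_b)
  if (sd(upper_vec(dm_b)) == 0 || sd(upper_vec(dm_a)) == 0)
    stop("Mantel correlation undefined: a matrix has zero variance")
  set.seed(derive_seed(seed, "mantel"))
  fit <- vegan::mantel(as_square_dist(dm_a), as_square_dist(dm_b),
                       method = method, permutations = n_permutations)
  structure(list(statistic = unname(fit$statistic), p_value = fit$signif,
                 n_permutations = n_permutations, seed = seed,
                 method = paste("Mantel", method)),
            class = "perm_test")
}

#' @rdname mantel_test
#' @export
partial_mantel_test <- function(dm_a, dm_b, dm_c,
                                method = c("pearson", "spearman"),
                                n_permutations = 999, seed = 1) {
  method <- match.arg(method)
  check_aligned(dm_a, dm_b)
  check_aligned(dm_a, dm_c)
  if (sd(upper_vec(dm_b)) == 0 || sd(upper_vec(dm_a)) == 0)
    stop("partial Mantel correlation undefined: a matrix has zero variance")
  if (sd(upper_vec(dm_c)) == 0) {
    warning("control matrix is constant; returning the plain Mantel test")
    out <- mantel_test(dm_a, dm_b, method = method,
                       n_permutations = n_permutations, seed = seed)
    out$method <- paste("partial Mantel (degenerate control),", method)
    return(out)
  }
  set.seed(derive_seed(seed, "pmantel"))
  fit <- vegan::mantel.partial(as_square_dist(dm_a), as_square_dist(dm_b),
                               as_square_dist(dm_c), method = method,
                               permutations = n_permutations)
  structure(list(statistic = unname(fit$statistic), p_value = fit$signif,
                 n_permutations = n_permutations, seed = seed,
                 method = paste("partial Mantel", method)),
            class = "perm_test")
}

#' Hellinger transformation
#'
#' y'_ij = sqrt(y_ij / sample total), applied per sample; every transformed
#' sample has unit sum of squares.  This is the transformation that turns
#' ordinary RDA into transformation-based RDA for community data.
#'
#' @param otu an [otu_table()] (counts or relative).
#' @return a samples x OTUs numeric matrix.
#' @export
hellinger <- function(otu) {
  stopifnot(inherits(otu, "otu_table"))
  x <- t(unclass(otu))
  if (any(rowSums(x) == 0))
    stop("Hellinger transform undefined for all-zero sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  vegan::decostand(x, method = "hellinger")
}

zscore_env <- function(env, variables) {
  miss <- setdiff(variables, names(env))
  if (length(miss) > 0)
    stop("variables not in metadata: ", paste(miss, collapse = ", "))
  z <- env[, variables, drop = FALSE]
  bad <- !vapply(z, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric variables: ", paste(variables[bad], collapse = ", "))
  as.data.frame(scale(z))
}

#' Constrained ordination (RDA) on transformed community data
#'
#' Redundancy analysis of a (typically Hellinger-transformed) community
#' matrix on z-scored environmental variables, via [vegan::rda()].
#' Reports raw and adjusted R-squared, per-axis eigenvalues and
#' proportions of total community variance, sample scores and variable
#' biplot arrows.
#'
#' @param response samples x features numeric matrix (e.g. [hellinger()]
#'   output).
#' @param env metadata `data.frame` with rows matching the response rows.
#' @param variables character vector of (numeric) constraint variables.
#' @return an object of class `rda_result`.
#' @export
rda_constrained <- function(response, env, variables) {
  response <- as.matrix(response)
  if (nrow(response) <= length(variables) + 1)
    stop("need more samples than constraint variables + 1")
  z <- zscore_env(env, variables)
  mm <- as.matrix(z)
  if (kappa(crossprod(mm), exact = TRUE) > 1e10) {
    cc <- abs(cor(mm))
    diag(cc) <- 0
    pair <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("collinear constraint variables (e.g. ",
         variables[pair[1]], " and ", variables[pair[2]], ")")
  }
  .Y <- response
  fml <- reformulate(variables, response = ".Y")
  environment(fml) <- environment()
  fit <- vegan::rda(fml, data = z)
  eig <- fit$CCA$eig
  tot <- fit$tot.chi
  structure(list(
    eigenvalues = eig,
    prop_explained = eig / tot,
    prop_constrained = eig / sum(eig),
    total_explained = sum(eig) / tot,
    adj_r_squared = vegan::RsquareAdj(fit)$adj.r.squared,
    site_scores = vegan::scores(fit, display = "sites",
                                choices = seq_along(eig)),
    biplot_scores = vegan::scores(fit, display = "bp",
                                  choices = seq_along(eig)),
    variables = variables, model = fit),
    class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "tb-RDA: %d constrained axes, %.1f%% of total variance explained (adj R2 = %.3f)\n",
    length(x$eigenvalues), 100 * x$total_explained, x$adj_r_squared))
  invisible(x)
}

#' Stepwise forward selection of constraint variables
#'
#' Greedy forward selection for RDA: at each step the candidate variable
#' giving the largest increase in adjusted R-squared is tested by a
#' marginal permutation test (conditioning on the variables already
#' selected) and added only if p <= alpha; selection also stops when the
#' adjusted R-squared of the candidate model would exceed that of the
#' full model (the double stopping criterion guarding against
#' overfitting).  An empty selection is a valid result.
#'
#' @param response samples x features numeric matrix.
#' @param env metadata `data.frame`.
#' @param variables candidate variable names (default: all numeric
#'   metadata columns except `sample_id`).
#' @param alpha significance threshold for entering (default 0.05).
#' @param n_permutations permutations per marginal test (default 199).
#' @param seed integer seed.
#' @return a `data.frame` of selected variables in selection order with
#'   per-step adjusted R-squared and permutation p-values (0 rows when
#'   nothing is selected).
#' @export
forward_select <- function(response, env, variables = NULL, alpha = 0.05,
                           n_permutations = 199, seed = 1) {
  if (is.null(variables)) {
    num <- vapply(env, is.numeric, logical(1))
    variables <- setdiff(names(env)[num], "sample_id")
  }
  response <- as.matrix(response)
  z <- zscore_env(env, variables)
  set.seed(derive_seed(seed, "forward"))
  .Y <- response
  mk <- function(terms) {
    fml <- reformulate(terms, response = ".Y")
    environment(fml) <- environment()
    fml
  }
  full <- vegan::rda(mk(variables), data = z)
  adj_full <- vegan::RsquareAdj(full)$adj.r.squared
  selected <- character(0)
  steps <- list()
  current_adj <- 0
  # marginal permutation p, with a perfect fit (no residual component)
  # scored at the permutation floor since no permutation can beat it
  perm_p <- function(m) {
    resid <- m$tot.chi - sum(m$CCA$eig)
    if (resid < 1e-10 * m$tot.chi) return(1 / (n_permutations + 1))
    vegan::anova.cca(m, permutations = n_permutations)[["Pr(>F)"]][1]
  }
  # overfitting guard: a permutation test of the full model gates the
  # whole selection; nothing is selected when the data carry no signal
  p_global <- perm_p(full)
  if (!is.na(p_global) && p_global <= alpha) {
    repeat {
      # adjusted-R2 ceiling: once the current model explains as much as
      # the full model, further additions only fit noise
      if (length(selected) > 0 && current_adj >= adj_full) break
      remaining <- setdiff(variables, selected)
      if (length(remaining) == 0) break
      adj <- vapply(remaining, function(v) {
        m <- vegan::rda(mk(c(selected, v)), data = z)
        a <- vegan::RsquareAdj(m)$adj.r.squared
        if (is.null(a) || is.na(a)) -Inf else a
      }, numeric(1))
      best_v <- remaining[which.max(adj)]
      best_adj <- max(adj)
      if (best_adj <= current_adj && length(selected) > 0) break
      terms <- if (length(selected) == 0) best_v else
        c(best_v, sprintf("Condition(%s)", paste(selected, collapse = " + ")))
      m <- vegan::rda(mk(terms), data = z)
      p <- perm_p(m)
      if (is.na(p) || p > alpha) break
      selected <- c(selected, best_v)
      steps[[best_v]] <- data.frame(variable = best_v,
                                    adj_r_squared = best_adj,
                                    p_value = p, stringsAsFactors = FALSE)
      current_adj <- best_adj
    }
  }
  out <- if (length(steps) == 0)
    data.frame(variable = character(0), adj_r_squared = numeric(0),
               p_value = numeric(0))
  else do.call(rbind, steps)
  rownames(out) <- NULL
  attr(out, "adj_r_squared_full") <- adj_full
  attr(out, "alpha") <- alpha
  out
}
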