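#' Patristic distance matrix over tree tips
#'
#' d(i, j) = sum of branch lengths along the path between tips i and j;
#' symmetric with zero diagonal.
#'
#' @param tree a `phylo` with branch lengths.
#' @return a labelled square numeric matrix.
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree)
  d <- cophenetic(tree)
  d[order(rownames(d)), order(colnames(d)), drop = FALSE]
}

# resolve abundances against the tip distance matrix; returns 0-based
# indices and within-community relative weights
community_on_tree <- function(abund, tipnames, weighted) {
  if (is.null(names(abund)))
    stop("abundance vectors must be named by OTU id")
  abund <- abund[abund > 0]
  if (length(abund) == 0) stop("betaMNTD undefined for an empty community")
  miss <- setdiff(names(abund), tipnames)
  if (length(miss) > 0)
    stop("OTUs absent from the tree: ", paste(miss, collapse = ", "))
  idx <- match(names(abund), tipnames) - 1L
  w <- if (weighted) as.numeric(abund) / sum(abund)
       else rep(1 / length(abund), length(abund))
  list(idx = idx, w = w)
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' betaMNTD between two communities on a shared phylogeny:
#' `0.5 * (sum_k f_ik min_l d(k, l) + sum_l f_jl min_k d(k, l))`,
#' where k runs over taxa present in community i, l over taxa present in
#' community j, and f are relative abundances within each community
#' (`weighted = TRUE`, the default) or 1/S (unweighted).  Symmetric in its
#' two arguments; identical communities give 0.
#'
#' @param abund_i,abund_j named non-negative abundance vectors.
#' @param tip_distances patristic distance matrix (see
#'   [patristic_matrix()]) whose row/column names cover all present OTUs.
#' @param weighted abundance-weight the taxon contributions.
#' @return a single non-negative number.
#' @export
bmntd <- function(abund_i, abund_j, tip_distances, weighted = TRUE) {
  tipnames <- rownames(tip_distances)
  ci <- community_on_tree(abund_i, tipnames, weighted)
  cj <- community_on_tree(abund_j, tipnames, weighted)
  cpp_bmntd(tip_distances, ci$idx, cj$idx, ci$w, cj$w)
}

# all permutations of 1..n as an n! x n matrix (small n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  row <- 1L
  for (v in seq_len(n)) {
    rest <- setdiff(seq_len(n), v)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(v, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Tip-shuffle null distribution of betaMNTD
#'
#' Generates the null distribution used for betaNTI: each draw relabels
#' the taxa by a uniform random permutation of *all* tree tips (abundances
#' untouched) and recomputes betaMNTD for the pair.  With
#' `exhaustive = TRUE` (small trees only) every permutation of the tips is
#' enumerated instead, which serves as an oracle for the sampled null.
#'
#' @param abund_i,abund_j named abundance vectors.
#' @param tree a `phylo`, or a precomputed patristic matrix.
#' @param n_null number of random draws (default 999).
#' @param seed integer seed.
#' @param exhaustive enumerate all tip permutations (requires <= 8 tips).
#' @param weighted abundance weighting as in [bmntd()].
#' @return numeric vector of null betaMNTD values.
#' @export
null_bmntd <- function(abund_i, abund_j, tree, n_null = 999, seed = 1,
                       exhaustive = FALSE, weighted = TRUE) {
  D <- if (inherits(tree, "phylo")) patristic_matrix(tree) else tree
  tipnames <- rownames(D)
  ci <- community_on_tree(abund_i, tipnames, weighted)
  cj <- community_on_tree(abund_j, tipnames, weighted)
  if (exhaustive) {
    n <- nrow(D)
    if (n > 8) stop("exhaustive null restricted to <= 8 tips")
    perms <- all_permutations(n) - 1L
    return(cpp_bmntd_perms(D, perms, ci$idx, cj$idx, ci$w, cj$w))
  }
  if (n_null < 1) stop("n_null must be >= 1")
  set.seed(derive_seed(seed, "bmntd_null"))
  cpp_bmntd_null(D, ci$idx, cj$idx, ci$w, cj$w, as.integer(n_null))
}

#' Pairwise betaNTI across all samples of an OTU table
#'
#' For every sample pair, computes the observed abundance-weighted
#' betaMNTD, a tip-shuffle null distribution (`n_null` independent draws
#' per pair), and the beta nearest taxon index
#' `betaNTI = (betaMNTD_obs - mean(null)) / sd(null)`.  Pairs whose null
#' standard deviation collapses (e.g. on a star phylogeny) get `NA` with a
#' warning and are excluded from downstream fractions.  |betaNTI| > 2 is
#' read as deterministic (selection-driven) assembly, |betaNTI| <= 2 as
#' stochastic.
#'
#' @param otu an [otu_table()].
#' @param tree a `phylo` whose tips cover the table's OTUs (extra tips or
#'   OTUs are dropped via [align_inputs()]).
#' @param n_null null draws per pair (default 999).
#' @param seed integer seed.
#' @param weighted abundance weighting as in [bmntd()].
#' @param sample_pairs optional 2-column matrix/data.frame of sample ids
#'   restricting which pairs are evaluated (default: all pairs).
#' @return an `assembly_result`: `pairs` data.frame (`sample_i`,
#'   `sample_j`, `bmntd_obs`, `null_mean`, `null_sd`, `bnti`,
#'   `deterministic`), plus `n_null`, `seed`, `weighted`.
#' @export
bnti_matrix <- function(otu, tree, n_null = 999, seed = 1, weighted = TRUE,
                        sample_pairs = NULL) {
  al <- align_inputs(otu, tree = tree)
  otu <- al$otu
  if (ncol(otu) < 2) stop("need at least 2 samples")
  D <- patristic_matrix(al$tree)
  samples <- colnames(otu)
  if (is.null(sample_pairs)) {
    idx <- which(upper.tri(matrix(0, length(samples), length(samples))),
                 arr.ind = TRUE)
    sample_pairs <- cbind(samples[idx[, 1]], samples[idx[, 2]])
  } else {
    sample_pairs <- as.matrix(sample_pairs)
    if (!all(sample_pairs %in% samples))
      stop("sample_pairs contains unknown sample ids")
  }
  set.seed(derive_seed(seed, "bnti"))
  tipnames <- rownames(D)
  res <- vector("list", nrow(sample_pairs))
  n_degenerate <- 0L
  for (p in seq_len(nrow(sample_pairs))) {
    si <- sample_pairs[p, 1]
    sj <- sample_pairs[p, 2]
    ci <- community_on_tree(unclass(otu)[, si], tipnames, weighted)
    cj <- community_on_tree(unclass(otu)[, sj], tipnames, weighted)
    obs <- cpp_bmntd(D, ci$idx, cj$idx, ci$w, cj$w)
    nulls <- cpp_bmntd_null(D, ci$idx, cj$idx, ci$w, cj$w,
                            as.integer(n_null))
    mu <- mean(nulls)
    sdev <- sd(nulls)
    bnti <- if (is.na(sdev) || sdev < 1e-12) {
      n_degenerate <- n_degenerate + 1L
      NA_real_
    } else (obs - mu) / sdev
    res[[p]] <- data.frame(sample_i = si, sample_j = sj, bmntd_obs = obs,
                           null_mean = mu, null_sd = sdev, bnti = bnti,
                           deterministic = !is.na(bnti) & abs(bnti) > 2,
                           stringsAsFactors = FALSE)
  }
  if (n_degenerate > 0)
    warning(n_degenerate,
            " pair(s) had a degenerate null (sd ~ 0); betaNTI set to NA")
  structure(list(pairs = do.call(rbind, res), n_null = n_null, seed = seed,
                 weighted = weighted),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  ok <- !is.na(x$pairs$bnti)
  cat(sprintf(
    "betaNTI over %d pairs (%d null draws): %.1f%% deterministic (|betaNTI| > 2)\n",
    nrow(x$pairs), x$n_null,
    100 * mean(x$pairs$deterministic[ok])))
  invisible(x)
}

#' Deterministic/stochastic fractions per sample group
#'
#' Summarizes an [bnti_matrix()] result over within-group sample pairs:
#' for each group, the number of pairs, the count with |betaNTI| > 2 and
#' the deterministic fraction (a group of n samples contributes
#' n(n-1)/2 pairs, so with n = 6 fractions are multiples of 1/15).
#'
#' @param result an `assembly_result`.
#' @param grouping named vector mapping every sample id to a group label.
#' @return a `data.frame` with columns `group`, `n_pairs`,
#'   `n_deterministic`, `fraction_deterministic`, `percent`.
#' @export
group_fractions <- function(result, grouping) {
  stopifnot(inherits(result, "assembly_result"))
  pairs <- result$pairs
  samples <- unique(c(pairs$sample_i, pairs$sample_j))
  miss <- setdiff(samples, names(grouping))
  if (length(miss) > 0)
    stop("sample(s) without a group: ", paste(miss, collapse = ", "))
  gi <- grouping[pairs$sample_i]
  gj <- grouping[pairs$sample_j]
  within <- pairs[gi == gj, ]
  within$group <- grouping[within$sample_i]
  dropped <- sum(is.na(within$bnti))
  if (dropped > 0)
    warning(dropped, " within-group pair(s) with undefined betaNTI excluded")
  within <- within[!is.na(within$bnti), ]
  groups <- sort(unique(unname(grouping)))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- within[within$group == g, ]
    n <- nrow(sub)
    k <- sum(abs(sub$bnti) > 2)
    data.frame(group = g, n_pairs = n, n_deterministic = k,
               fraction_deterministic = if (n > 0) k / n else NA_real_,
               percent = if (n > 0) round(100 * k / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write betaNTI results as long-format TSV
#' @param result an `assembly_result`.
#' @param path file path.
#' @export
write_assembly_result <- function(result, path) {
  stopifnot(inherits(result, "assembly_result"))
  p <- result$pairs
  lines <- c(paste(names(p), collapse = "\t"),
             paste(p$sample_i, p$sample_j, fmt_num(p$bmntd_obs),
                   fmt_num(p$null_mean), fmt_num(p$null_sd),
                   fmt_num(p$bnti), p$deterministic, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
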