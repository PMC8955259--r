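#' Aggregate carbon-fixer OTUs into cluster abundances
#'
#' Sums the relative abundances of the member OTUs of each cbbL cluster
#' per sample.  The cluster assignment is an upstream input (a
#' phylogenetic grouping of cbbL sequences); mapped OTUs missing from the
#' table are dropped with a warning, and clusters left empty after
#' dropping are omitted.
#'
#' @param cbbl_table an [otu_table()] of carbon-fixer OTUs (counts are
#'   converted to relative abundances).
#' @param cluster_map `data.frame` with columns `otu_id`, `cluster`.
#' @return an [otu_table()] in (partial) relative mode, one row per
#'   cluster.
#' @export
aggregate_clusters <- function(cbbl_table, cluster_map) {
  stopifnot(inherits(cbbl_table, "otu_table"),
            all(c("otu_id", "cluster") %in% names(cluster_map)))
  rel <- if (table_mode(cbbl_table) == "relative") cbbl_table else
    to_relative(cbbl_table)
  missing <- setdiff(cluster_map$otu_id, rownames(rel))
  if (length(missing) > 0) {
    warning(length(missing), " mapped OTU(s) absent from the table dropped")
    cluster_map <- cluster_map[!cluster_map$otu_id %in% missing, ]
  }
  if (nrow(cluster_map) == 0) {
    warning("no mapped OTUs remain; returning an empty table")
    return(otu_table(matrix(numeric(0), 0, ncol(rel),
                            dimnames = list(NULL, colnames(rel))),
                     otu_ids = character(0), mode = "relative",
                     partial = TRUE))
  }
  clusters <- sort(unique(cluster_map$cluster))
  m <- do.call(rbind, lapply(clusters, function(cl) {
    members <- cluster_map$otu_id[cluster_map$cluster == cl]
    colSums(unclass(rel)[members, , drop = FALSE])
  }))
  rownames(m) <- clusters
  otu_table(m, mode = "relative", partial = TRUE)
}

# observed ensemble scores for two renormalized feature vectors
obs_scores <- function(x, y) {
  c(pearson = suppressWarnings(cor(x, y)),
    spearman = suppressWarnings(cor(x, y, method = "spearman")),
    bray = if (sum(x + y) > 0) 1 - sum(abs(x - y)) / sum(x + y) else
      NA_real_)
}

#' Observed pairwise association scores
#'
#' For each feature pair, the three ensemble measures used for network
#' inference: Pearson r, Spearman rho, and Bray-Curtis similarity
#' (1 - BC dissimilarity).  Zero-variance features make a pair unscorable
#' and it is skipped with a message.
#'
#' @param feature_table features x samples matrix (or [otu_table()]) of
#'   relative abundances.
#' @param pairs optional 2-column matrix of feature ids (default: all
#'   pairs).
#' @return a `data.frame` with one row per scored pair.
#' @export
pairwise_scores <- function(feature_table, pairs = NULL) {
  X <- as.matrix(feature_table)
  if (ncol(X) < 5) stop("need at least 5 samples")
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(nrow(X))), arr.ind = TRUE)
    pairs <- cbind(rownames(X)[idx[, 1]], rownames(X)[idx[, 2]])
  }
  keep <- logical(nrow(pairs))
  out <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    x <- X[pairs[p, 1], ]
    y <- X[pairs[p, 2], ]
    if (sd(x) == 0 || sd(y) == 0) next
    s <- obs_scores(x, y)
    keep[p] <- TRUE
    out[[p]] <- data.frame(source = pairs[p, 1], target = pairs[p, 2],
                           pearson = s["pearson"], spearman = s["spearman"],
                           bray = s["bray"], stringsAsFactors = FALSE,
                           row.names = NULL)
  }
  if (any(!keep))
    message(sum(!keep), " pair(s) skipped (zero-variance feature)")
  do.call(rbind, out[keep])
}

#' Renormalized-permutation (ReBoot-style) null for one pair
#'
#' The compositionality correction of the ensemble network: each of
#' `n_iter` iterations permutes the two features' values across samples
#' independently, renormalizes every sample total over the feature set,
#' and recomputes the association measures.  The empirical two-sided
#' p-value is `(1 + #{|null - c| >= |obs - c|}) / (n_iter + 1)` with
#' center c = 0 for the correlation measures and c = the null mean for
#' Bray-Curtis similarity (whose null is not centered at zero).
#'
#' @param feature_table features x samples relative-abundance matrix (or
#'   [otu_table()]).
#' @param pair length-2 vector of feature ids.
#' @param measure `"pearson"`, `"spearman"` or `"bray"`.
#' @param n_iter permutations (default 1000).
#' @param seed integer seed.
#' @return a list: `observed`, `null` (length `n_iter`), `p_value`.
#' @export
reboot_null <- function(feature_table, pair,
                        measure = c("pearson", "spearman", "bray"),
                        n_iter = 1000, seed = 1) {
  measure <- match.arg(measure)
  X <- as.matrix(feature_table)
  stopifnot(length(pair) == 2, all(pair %in% rownames(X)))
  i <- match(pair[1], rownames(X))
  j <- match(pair[2], rownames(X))
  obs <- obs_scores(X[i, ], X[j, ])[measure]
  set.seed(derive_seed(seed, paste0("reboot_", pair[1], "_", pair[2])))
  nulls <- cpp_reboot_null(X, i - 1L, j - 1L, as.integer(n_iter))
  col <- match(measure, c("pearson", "spearman", "bray"))
  nv <- nulls[, col]
  ctr <- if (measure == "bray") mean(nv, na.rm = TRUE) else 0
  p <- (1 + sum(abs(nv - ctr) >= abs(obs - ctr), na.rm = TRUE)) /
    (n_iter + 1)
  list(observed = unname(obs), null = nv, p_value = p)
}

# Brown's method for combining correlated p-values, with the covariance
# of the -2 log p terms estimated from per-draw empirical p-values of the
# null scores; falls back to Fisher's method when the estimate degenerates.
brown_merge <- function(p_values, null_scores, centers) {
  k <- length(p_values)
  X <- -2 * sum(log(pmax(p_values, 1e-300)))
  L <- vapply(seq_len(k), function(m) {
    s <- null_scores[, m]
    a <- abs(s - centers[m])
    n <- length(a)
    pt <- (n + 1 - rank(a, ties.method = "min")) / n
    -2 * log(pmax(pt, 1 / n))
  }, numeric(nrow(null_scores)))
  C <- tryCatch(stats::cov(L), error = function(e) NULL)
  fisher <- function() pchisq(X, df = 2 * k, lower.tail = FALSE)
  if (is.null(C) || anyNA(C)) return(fisher())
  V <- 4 * k + 2 * sum(C[upper.tri(C)])
  if (!is.finite(V) || V <= 0) return(fisher())
  E <- 2 * k
  cc <- V / (2 * E)
  f <- 2 * E^2 / V
  pchisq(X / cc, df = f, lower.tail = FALSE)
}

#' Ensemble co-occurrence network inference
#'
#' CoNet-style network between key heterotroph OTUs and carbon-fixer
#' clusters (and among the key OTUs themselves; cluster-cluster pairs are
#' not tested).  For every candidate pair, three association measures
#' (Pearson, Spearman, Bray-Curtis similarity) are scored against a
#' renormalized-permutation null; per-measure two-sided p-values are
#' merged with Brown's method (Fisher fallback) and corrected across
#' pairs by Benjamini-Hochberg.  An edge is kept when at least
#' `min_support` measures agree on its sign (sign of observed minus null
#' mean) and the merged q-value is at or below `fdr`.
#'
#' Per-measure p-values use the exactly calibrated discrete exceedance
#' formula of [reboot_null()] by default (`p_method = "empirical"`); its
#' resolution is `1 / (n_iter + 1)`, so `n_iter` should grow with the
#' number of tested pairs when a genome-scale FDR cut is wanted.
#' `p_method = "gaussian"` fits a Gaussian to the permutation null (on
#' the Fisher z scale for the correlation measures), giving continuous
#' tail p-values at a moderate permutation count at the price of relying
#' on the null being near-Gaussian in its tails.
#'
#' @param key_table features x samples relative abundances of the key
#'   OTUs (an [otu_table()] or matrix).
#' @param cluster_table optional cluster abundance table from
#'   [aggregate_clusters()] (same samples).
#' @param min_support minimum number of sign-agreeing measures (default
#'   2).
#' @param fdr Benjamini-Hochberg threshold (default 0.05).
#' @param n_iter permutations per pair (default 1000).
#' @param p_method `"empirical"` (default) or `"gaussian"`.
#' @param seed integer seed.
#' @param layer optional label stored on the network (e.g. `"surface"`).
#' @return a `cooccurrence_network`: `nodes` (`id`, `kind`,
#'   `mean_abundance`), `edges` (source, target, sign, per-measure scores
#'   and p-values, merged p, q, support), and the inference settings.
#' @export
build_network <- function(key_table, cluster_table = NULL, min_support = 2,
                          fdr = 0.05, n_iter = 1000,
                          p_method = c("empirical", "gaussian"), seed = 1,
                          layer = NULL) {
  p_method <- match.arg(p_method)
  stopifnot(fdr > 0, fdr < 1, n_iter >= 1)
  K <- as.matrix(key_table)
  kinds <- rep("otu", nrow(K))
  if (!is.null(cluster_table)) {
    Cm <- as.matrix(cluster_table)
    if (!identical(colnames(K), colnames(Cm)))
      stop("key and cluster tables must share the same samples")
    X <- rbind(K, Cm)
    kinds <- c(kinds, rep("cfix_cluster", nrow(Cm)))
  } else {
    X <- K
  }
  if (anyDuplicated(rownames(X))) stop("duplicate feature ids")
  if (ncol(X) < 5) stop("need at least 5 samples")
  names(kinds) <- rownames(X)
  ord <- order(rownames(X))  # feature-order invariance
  X <- X[ord, , drop = FALSE]
  X <- X[, order(colnames(X)), drop = FALSE]
  kinds <- kinds[rownames(X)]

  idx <- which(upper.tri(diag(nrow(X))), arr.ind = TRUE)
  keep_pair <- !(kinds[idx[, 1]] == "cfix_cluster" &
                   kinds[idx[, 2]] == "cfix_cluster")
  idx <- idx[keep_pair, , drop = FALSE]
  sds <- apply(X, 1, sd)
  scorable <- sds[idx[, 1]] > 0 & sds[idx[, 2]] > 0
  if (any(!scorable))
    message(sum(!scorable), " pair(s) skipped (zero-variance feature)")
  idx <- idx[scorable, , drop = FALSE]

  set.seed(derive_seed(seed, "network"))
  rows <- vector("list", nrow(idx))
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    obs <- obs_scores(X[i, ], X[j, ])
    nulls <- cpp_reboot_null(X, i - 1L, j - 1L, as.integer(n_iter))
    mu <- colMeans(nulls, na.rm = TRUE)
    sdev <- apply(nulls, 2, sd, na.rm = TRUE)
    centers <- c(0, 0, mu[3])
    if (anyNA(obs) || anyNA(sdev) || any(sdev < 1e-12)) next
    pv <- if (p_method == "gaussian") {
      # Fisher z-scale for the correlation measures: the permutation null
      # of r has heavier-than-normal tails, atanh(r) is close to normal
      zclip <- function(r) atanh(pmax(pmin(r, 0.99999), -0.99999))
      vapply(1:3, function(m) {
        o <- if (m < 3) zclip(obs[m]) else obs[m]
        nv <- if (m < 3) zclip(nulls[, m]) else nulls[, m]
        m0 <- mean(nv, na.rm = TRUE)
        s0 <- sd(nv, na.rm = TRUE)
        if (is.na(s0) || s0 < 1e-12) return(NA_real_)
        2 * pnorm(-abs(o - m0) / s0)
      }, numeric(1))
    } else {
      vapply(1:3, function(m) {
        (1 + sum(abs(nulls[, m] - centers[m]) >= abs(obs[m] - centers[m]),
                 na.rm = TRUE)) / (n_iter + 1)
      }, numeric(1))
    }
    pv <- pmin(pmax(pv, 1e-300), 1)
    signs <- sign(obs - centers)
    sign_tab <- table(factor(signs[signs != 0], levels = c(-1, 1)))
    support <- max(sign_tab)
    maj_sign <- if (support == 0) 0 else
      c(-1, 1)[which.max(sign_tab)]
    merged <- brown_merge(pv, nulls, centers)
    rows[[p]] <- data.frame(
      source = rownames(X)[i], target = rownames(X)[j],
      sign = if (maj_sign >= 0) "+" else "-", support = as.integer(support),
      pearson = unname(obs[1]), spearman = unname(obs[2]),
      bray = unname(obs[3]),
      p_pearson = pv[1], p_spearman = pv[2], p_bray = pv[3],
      p_merged = merged, stringsAsFactors = FALSE)
  }
  scored <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(scored)) {
    scored <- data.frame(source = character(0), target = character(0),
                         sign = character(0), support = integer(0),
                         pearson = numeric(0), spearman = numeric(0),
                         bray = numeric(0), p_pearson = numeric(0),
                         p_spearman = numeric(0), p_bray = numeric(0),
                         p_merged = numeric(0))
  }
  scored$q <- p.adjust(scored$p_merged, method = "BH")
  edges <- scored[scored$support >= min_support & scored$q <= fdr, ,
                  drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(id = rownames(X), kind = unname(kinds),
                      mean_abundance = rowMeans(X),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, scored_pairs = scored,
                 n_pairs_tested = nrow(scored), min_support = min_support,
                 fdr = fdr, n_iter = n_iter, p_method = p_method,
                 seed = seed, layer = layer),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "co-occurrence network%s: %d nodes, %d edges (of %d tested pairs, FDR %.2g)\n",
    if (is.null(x$layer)) "" else paste0(" [", x$layer, "]"),
    nrow(x$nodes), nrow(x$edges), x$n_pairs_tested, x$fdr))
  invisible(x)
}

#' Export a network
#'
#' [write_edge_list()] writes the edge table as TSV
#' (source, target, sign, scores, q); [as_igraph()] converts to an
#' [igraph::graph] for GraphML export or topology work.
#'
#' @param network a `cooccurrence_network`.
#' @param path file path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "cooccurrence_network"))
  e <- network$edges
  lines <- c("source\ttarget\tsign\tsupport\tpearson\tspearman\tbray\tp_merged\tq_value",
             if (nrow(e) > 0)
               paste(e$source, e$target, e$sign, e$support,
                     fmt_num(e$pearson), fmt_num(e$spearman),
                     fmt_num(e$bray), fmt_num(e$p_merged), fmt_num(e$q),
                     sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cooccurrence_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
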