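#' Rank OTUs by Random-Forest importance
#'
#' Fits a Random-Forest classifier predicting a sample grouping (station)
#' from relative OTU abundances and ranks OTUs by variable importance:
#' mean decrease in Gini impurity by default, or permutation importance
#' (mean decrease in accuracy), which is less biased toward high-variance
#' features.  Ties are broken lexicographically by OTU id so the ranking
#' is fully deterministic given the seed.
#'
#' @param otu an [otu_table()]; converted to relative abundances
#'   internally.
#' @param labels class label per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param n_trees number of trees (default 1000).
#' @param importance `"gini"` or `"permutation"`.
#' @param seed integer seed.
#' @return an `importance_ranking`: `ranking` data.frame (`otu_id`,
#'   `importance`, `rank`), `oob_accuracy`, `n_trees`, `seed`.
#' @export
rank_otus <- function(otu, labels, n_trees = 1000,
                      importance = c("gini", "permutation"), seed = 1) {
  importance <- match.arg(importance)
  stopifnot(inherits(otu, "otu_table"))
  labels <- as.factor(labels)
  if (length(labels) != ncol(otu))
    stop("one label per sample is required")
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 classes")
  if (any(table(droplevels(labels)) < 2))
    stop("every class must contain at least 2 samples")
  rel <- if (table_mode(otu) == "relative") otu else to_relative(otu)
  x <- t(unclass(rel))
  set.seed(derive_seed(seed, "randomforest"))
  rf <- randomForest::randomForest(
    x = x, y = droplevels(labels), ntree = n_trees,
    importance = importance == "permutation")
  imp_col <- if (importance == "gini") "MeanDecreaseGini" else
    "MeanDecreaseAccuracy"
  imp <- randomForest::importance(rf)[, imp_col]
  ord <- order(-imp, names(imp))
  ranking <- data.frame(otu_id = names(imp)[ord],
                        importance = unname(imp[ord]),
                        rank = seq_along(imp), stringsAsFactors = FALSE)
  oob <- 1 - unname(rf$err.rate[n_trees, "OOB"])
  structure(list(ranking = ranking, oob_accuracy = oob, n_trees = n_trees,
                 importance_type = importance, seed = seed),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("Random-Forest ranking of %d OTUs (OOB accuracy %.3f)\n",
              nrow(x$ranking), x$oob_accuracy))
  print(head(x$ranking, 5))
  invisible(x)
}

#' Select the top-k key OTUs
#'
#' @param ranking an [rank_otus()] result.
#' @param k number of OTUs to keep (default 30; boundary ties are already
#'   resolved lexicographically in the ranking).
#' @return character vector of the first `k` OTU ids by rank.
#' @export
select_top <- function(ranking, k = 30) {
  stopifnot(inherits(ranking, "importance_ranking"))
  n <- nrow(ranking$ranking)
  if (k > n) stop("k = ", k, " exceeds the number of ranked OTUs (", n, ")")
  if (k < 1) stop("k must be >= 1")
  ranking$ranking$otu_id[seq_len(k)]
}
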