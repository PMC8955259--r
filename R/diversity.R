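#' Alpha diversity indices per sample
#'
#' Computes richness (number of OTUs with non-zero count), bias-corrected
#' Chao1, Shannon entropy (natural log) and the Gini-Simpson index
#' (1 - sum p^2) for every sample of a count-mode OTU table.  Chao1 uses the
#' bias-corrected form S_obs + F1(F1-1) / (2(F2+1)), which is defined even
#' when no doubletons are observed.  Counts are required because Chao1
#' depends on singleton and doubleton frequencies; an all-zero sample yields
#' an NA record (flagged in the `note` column) rather than a failure.
#'
#' @param otu a count-mode [otu_table()].
#' @return a `data.frame` with columns `sample_id`, `richness`, `chao1`,
#'   `shannon`, `simpson`, `note`.
#' @export
alpha_diversity <- function(otu) {
  stopifnot(inherits(otu, "otu_table"))
  if (table_mode(otu) != "counts")
    stop("alpha_diversity() needs count data (Chao1 uses singletons)")
  x <- t(unclass(otu))  # samples x OTUs for vegan
  empty <- rowSums(x) == 0
  rich <- vegan::specnumber(x)
  shan <- suppressWarnings(vegan::diversity(x, index = "shannon"))
  simp <- suppressWarnings(vegan::diversity(x, index = "simpson"))
  chao <- apply(x, 1, function(v) {
    s <- sum(v > 0)
    f1 <- sum(v == 1)
    f2 <- sum(v == 2)
    s + f1 * (f1 - 1) / (2 * (f2 + 1))
  })
  out <- data.frame(sample_id = rownames(x), richness = as.integer(rich),
                    chao1 = chao, shannon = shan, simpson = simp,
                    note = "", stringsAsFactors = FALSE)
  if (any(empty)) {
    out[empty, c("richness", "chao1", "shannon", "simpson")] <- NA
    out$note[empty] <- "empty sample"
  }
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed between every pair
#' of sample columns.  Accepts counts or relative abundances (the index is
#' invariant to joint rescaling of a pair, and equals the relative-abundance
#' value exactly when sequencing depths are equal).
#'
#' @param otu an [otu_table()].
#' @return a `dist` object labelled by sample id (zero diagonal implied,
#'   values in `[0, 1]`).
#' @export
bray_curtis <- function(otu) {
  stopifnot(inherits(otu, "otu_table"))
  if (ncol(otu) < 2) stop("need at least 2 samples")
  zero <- colSums(otu) == 0
  if (any(zero))
    stop("Bray-Curtis undefined for all-zero sample(s): ",
         paste(colnames(otu)[zero], collapse = ", "))
  vegan::vegdist(t(unclass(otu)), method = "bray")
}
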