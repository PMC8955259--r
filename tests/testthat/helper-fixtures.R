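# shared fixtures, all built in code

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

random_counts_table <- function(n_otus, n_samples, seed = 1, lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_otus * n_samples, lambda), n_otus, n_samples,
              dimnames = list(sprintf("OTU%03d", seq_len(n_otus)),
                              sprintf("s%02d", seq_len(n_samples))))
  otu_table(m, mode = "counts")
}

# features x samples relative table with a planted correlated block on a
# shared lognormal latent factor, the rest independent noise
planted_block_table <- function(n_block = 5, n_noise = 50, n = 18,
                                strength = 1.2, noise_sd = 0.35,
                                block_scale = 0.3, negative = FALSE,
                                seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  block <- if (n_block > 0) {
    sapply(seq_len(n_block), function(i) {
      s <- if (negative && i %% 2 == 0) -strength else strength
      block_scale * exp(s * z + noise_sd * rnorm(n))
    })
  } else NULL
  noise <- sapply(seq_len(n_noise), function(i) exp(rnorm(n)))
  X <- t(cbind(block, noise))
  rownames(X) <- c(if (n_block > 0) sprintf("B%02d", seq_len(n_block)),
                   sprintf("N%02d", seq_len(n_noise)))
  colnames(X) <- sprintf("s%02d", seq_len(n))
  sweep(X, 2, colSums(X), "/")
}

# two communities with disjoint support on a small random tree, for the
# exhaustive tip-shuffle oracle
disjoint_pair_on_tree <- function(seed) {
  set.seed(seed)
  n <- sample(5:6, 1)
  tr <- simulate_tree(n, seed = seed * 7)
  tips <- sample(tr$tip.label)
  na <- sample(2:(n - 2), 1)
  list(tree = tr,
       a = stats::setNames(rpois(na, 2) + 1, tips[seq_len(na)]),
       b = stats::setNames(rpois(n - na, 2) + 1, tips[(na + 1):n]))
}
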