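#' Configuration for the synthetic community generator
#'
#' Bundles every knob of the simulator that emulates the sampling design of
#' a small-scale coral-habitat seawater survey: a fixed number of stations
#' along an environmental gradient, two water layers, replicated samples
#' per station-layer cell, one shared phylogeny, and communities assembled
#' under a tunable mixture of environmental filtering and neutral
#' (metacommunity-proportional) sampling.
#'
#' @param n_tips number of OTUs / tree tips (>= 2).
#' @param birth_rate Yule (pure-birth) speciation rate; branch lengths are
#'   in arbitrary time units.
#' @param trait_sigma2 Brownian-motion rate of the environmental-optimum
#'   trait (0 gives no phylogenetic niche signal).
#' @param n_stations,n_layers,replicates_per_cell sampling design.
#' @param env_values one environmental value per station (the gradient,
#'   e.g. a nitrite proxy); defaults to an evenly spaced gradient matched
#'   to the trait scale.
#' @param filtering_strength exponent on the Gaussian niche kernel; 0 is
#'   strictly neutral sampling.
#' @param niche_breadth Gaussian niche kernel width (same units as
#'   `env_values`).
#' @param sequencing_depth reads per sample (multinomial total).
#' @param metacommunity_shape lognormal sigma of metacommunity relative
#'   abundances (right-skewed, as in 16S surveys).
#' @param cfix_fraction fraction of tips labelled as carbon fixers.
#' @param n_cfix_clusters number of clade-based carbon-fixer clusters.
#' @param layer_effect environmental offset added in the bottom layer.
#' @param seed integer; every random draw is reproducible from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_tips = 100, birth_rate = 1, trait_sigma2 = 1,
                       n_stations = 3, n_layers = 2,
                       replicates_per_cell = 6, env_values = NULL,
                       filtering_strength = 0, niche_breadth = 1,
                       sequencing_depth = 2000, metacommunity_shape = 1,
                       cfix_fraction = 0.1, n_cfix_clusters = 4,
                       layer_effect = 0.5, seed = 1) {
  if (is.null(env_values))
    env_values <- seq(-2, 2, length.out = n_stations)
  cfg <- list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
              trait_sigma2 = trait_sigma2,
              n_stations = as.integer(n_stations),
              n_layers = as.integer(n_layers),
              replicates_per_cell = as.integer(replicates_per_cell),
              env_values = as.numeric(env_values),
              filtering_strength = filtering_strength,
              niche_breadth = niche_breadth,
              sequencing_depth = as.integer(sequencing_depth),
              metacommunity_shape = metacommunity_shape,
              cfix_fraction = cfix_fraction,
              n_cfix_clusters = as.integer(n_cfix_clusters),
              layer_effect = layer_effect, seed = as.integer(seed))
  stopifnot(cfg$n_tips >= 2, cfg$birth_rate > 0, cfg$trait_sigma2 >= 0,
            cfg$n_stations >= 1, cfg$n_layers >= 1,
            cfg$replicates_per_cell >= 1,
            cfg$filtering_strength >= 0, cfg$niche_breadth > 0,
            cfg$sequencing_depth >= 1, cfg$metacommunity_shape > 0,
            cfg$cfix_fraction > 0, cfg$cfix_fraction < 1,
            cfg$n_cfix_clusters >= 2)
  if (length(cfg$env_values) != cfg$n_stations)
    stop("env_values must have one entry per station")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a Yule phylogeny
#'
#' Pure-birth tree with `n_tips` uniquely labelled tips and strictly
#' positive branch lengths.  The same seed always yields the same Newick
#' string.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return a rooted binary `phylo` with tips `OTU0001`, `OTU0002`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(derive_seed(seed, "tree"))
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  # guard against zero-length edges from coincident event times
  tr$edge.length[tr$edge.length <= 0] <- 1e-8
  tr$tip.label <- sprintf("OTU%04d", seq_len(n_tips))
  validate_tree(tr)
  tr
}

#' Evolve an environmental-optimum trait along a tree
#'
#' Brownian motion from a root value of 0, so that the variance of a tip's
#' optimum equals `trait_sigma2` times its root-to-tip path length and
#' closely related tips have correlated optima (the phylogenetic signal the
#' tip-shuffle null model destroys).
#'
#' @param tree a `phylo`.
#' @param trait_sigma2 Brownian rate (>= 0); 0 returns all-zero optima.
#' @param seed integer seed.
#' @return named numeric vector of optima, one per tip.
#' @export
evolve_trait <- function(tree, trait_sigma2, seed = 1) {
  validate_tree(tree)
  if (trait_sigma2 < 0) stop("trait_sigma2 must be >= 0")
  if (trait_sigma2 == 0)
    return(setNames(numeric(length(tree$tip.label)), tree$tip.label))
  set.seed(derive_seed(seed, "trait"))
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(trait_sigma2),
                  root.value = 0)
}

#' Lognormal metacommunity relative abundances
#' @param n_tips number of OTUs.
#' @param shape lognormal sigma.
#' @param seed integer seed.
#' @return numeric vector summing to 1.
#' @export
metacommunity_abundances <- function(n_tips, shape = 1, seed = 1) {
  set.seed(derive_seed(seed, "metacommunity"))
  x <- rlnorm(n_tips, meanlog = 0, sdlog = shape)
  x / sum(x)
}

#' Sample one community under niche filtering
#'
#' Draws `depth` reads from a multinomial whose per-OTU probability is
#' proportional to
#' `metacommunity_i * exp(-(optimum_i - env_value)^2 / (2 niche_breadth^2))^filtering_strength`.
#' With `filtering_strength = 0` the sampling probabilities equal the
#' metacommunity proportions exactly (neutral limit); as it grows, the
#' community is increasingly dominated by OTUs whose optima sit near
#' `env_value`.
#'
#' @param traits named vector of environmental optima.
#' @param metacommunity relative abundances (same order/names as `traits`),
#'   summing to 1.
#' @param env_value local environmental value.
#' @param filtering_strength,niche_breadth see [sim_config()].
#' @param depth number of reads to draw (>= 1).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return named integer vector of counts summing to `depth`.
#' @export
sample_community <- function(traits, metacommunity, env_value,
                             filtering_strength = 0, niche_breadth = 1,
                             depth = 2000, seed = NULL) {
  stopifnot(length(traits) == length(metacommunity), depth >= 1,
            abs(sum(metacommunity) - 1) < 1e-6)
  if (!is.null(seed)) set.seed(derive_seed(seed, "community"))
  kern <- exp(-(traits - env_value)^2 / (2 * niche_breadth^2))
  p <- metacommunity * kern^filtering_strength
  if (sum(p) <= 0)
    stop("degenerate niche: all sampling probabilities are zero")
  p <- p / sum(p)
  counts <- as.integer(rmultinom(1, size = depth, prob = p)[, 1])
  setNames(counts, names(traits))
}

#' Generate a full synthetic dataset
#'
#' Produces everything the downstream pipeline consumes: a count-mode OTU
#' table whose sample ids encode station and layer (e.g. `WA2_r01` for
#' station A, surface), the shared phylogeny, a metadata table holding the
#' driving environmental gradient (`nitrite`), a coral-coverage gradient
#' and uncorrelated nuisance variables, a carbon-fixer (cbbL) OTU table
#' drawn on a designated subset of tips, and a clade-based OTU-to-cluster
#' map for those tips.  Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with elements `otu`, `tree`, `env`, `cbbl`, `cluster_map`,
#'   `traits`, `metacommunity`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  tree <- simulate_tree(cf$n_tips, cf$birth_rate, seed = cf$seed)
  traits <- evolve_trait(tree, cf$trait_sigma2, seed = cf$seed)
  meta <- metacommunity_abundances(cf$n_tips, cf$metacommunity_shape,
                                   seed = cf$seed)
  names(meta) <- tree$tip.label
  traits <- traits[tree$tip.label]

  # carbon-fixer tips: random fixed fraction, clustered by clade
  set.seed(derive_seed(cf$seed, "cfix"))
  n_cfix <- max(cf$n_cfix_clusters, round(cf$cfix_fraction * cf$n_tips))
  cfix_tips <- sort(sample(tree$tip.label, n_cfix))
  dtips <- cophenetic(tree)[cfix_tips, cfix_tips]
  k <- min(cf$n_cfix_clusters, n_cfix)
  cl <- cutree(hclust(as.dist(dtips), method = "average"), k = k)
  cluster_map <- data.frame(otu_id = cfix_tips,
                            cluster = paste0("Cluster", cl[cfix_tips]),
                            stringsAsFactors = FALSE)

  layer_names <- if (cf$n_layers == 2) c("surface", "bottom") else
    paste0("L", seq_len(cf$n_layers))
  layer_codes <- if (cf$n_layers == 2) c("2", "1") else
    as.character(seq_len(cf$n_layers))

  samples <- list()
  cbbl_samples <- list()
  env_rows <- list()
  meta_cfix <- meta[cfix_tips] / sum(meta[cfix_tips])
  for (s in seq_len(cf$n_stations)) {
    for (l in seq_len(cf$n_layers)) {
      env_here <- cf$env_values[s] + (l - 1) * cf$layer_effect
      for (r in seq_len(cf$replicates_per_cell)) {
        id <- sprintf("W%s%s_r%02d", LETTERS[s], layer_codes[l], r)
        sseed <- derive_seed(cf$seed, paste0("sample_", id))
        samples[[id]] <- sample_community(traits, meta, env_here,
                                          cf$filtering_strength,
                                          cf$niche_breadth,
                                          cf$sequencing_depth, seed = sseed)
        cseed <- derive_seed(cf$seed, paste0("cbbl_", id))
        cbbl_samples[[id]] <- sample_community(traits[cfix_tips], meta_cfix,
                                               env_here,
                                               cf$filtering_strength,
                                               cf$niche_breadth,
                                               cf$sequencing_depth,
                                               seed = cseed)
        eseed <- derive_seed(cf$seed, paste0("env_", id))
        set.seed(eseed)
        coverage <- if (cf$n_stations == 3) c(20, 5, 0)[s] else
          rev(seq(0, 20, length.out = cf$n_stations))[s]
        env_rows[[id]] <- data.frame(
          sample_id = id, station = paste0("W", LETTERS[s]),
          layer = layer_names[l],
          depth = (if (layer_names[l] == "surface") 0.5 else 8) +
            abs(rnorm(1, 0, 0.2)),
          nitrite = env_here + rnorm(1, 0, 0.1),
          coverage = coverage + rnorm(1, 0, 0.5),
          ammonium = rnorm(1, 0.022, 0.005),
          nitrate = rnorm(1, 0.29, 0.05),
          phosphate = rnorm(1, 0.003, 0.001),
          silicate = rnorm(1, 0.5, 0.1),
          Chla = rnorm(1, 1, 0.2),
          DOC = rnorm(1, 90, 10), DIC = rnorm(1, 2000, 50),
          salinity = rnorm(1, 33.5, 0.3), pH = rnorm(1, 8.1, 0.05),
          stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(cbind, samples)
  rownames(counts) <- tree$tip.label
  cbbl <- do.call(cbind, cbbl_samples)
  rownames(cbbl) <- cfix_tips
  env <- do.call(rbind, env_rows)
  rownames(env) <- env$sample_id
  list(otu = otu_table(counts, mode = "counts"), tree = tree, env = env,
       cbbl = otu_table(cbbl, mode = "counts"), cluster_map = cluster_map,
       traits = traits, metacommunity = meta, config = cf)
}

#' Write a synthetic dataset to disk
#'
#' Emits the OTU table, Newick tree, metadata, cbbL table, cluster map and
#' a YAML copy of the generating configuration into `dir`.  Identical
#' configurations produce byte-identical files.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    otu = file.path(dir, "otu_table.tsv"),
    tree = file.path(dir, "tree.nwk"),
    env = file.path(dir, "metadata.tsv"),
    cbbl = file.path(dir, "cbbl_table.tsv"),
    cluster_map = file.path(dir, "cluster_map.tsv"),
    config = file.path(dir, "sim_config.yaml"))
  write_otu_table(dataset$otu, paths["otu"])
  write_newick(dataset$tree, paths["tree"])
  write_env_table(dataset$env, paths["env"])
  write_otu_table(dataset$cbbl, paths["cbbl"])
  write_cluster_map(dataset$cluster_map, paths["cluster_map"])
  yaml::write_yaml(unclass(dataset$config), paths["config"])
  invisible(paths)
}
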