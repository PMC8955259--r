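default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "reefwater_run",
    synthetic = unclass(sim_config()),
    input = NULL,
    ordination = list(k = 2L, n_restarts = 20L),
    tests = list(n_permutations = 999L),
    forward = list(alpha = 0.05, n_permutations = 199L),
    keytaxa = list(top_k = 30L, n_trees = 1000L),
    network = list(fdr = 0.05, n_iter = 1000L, min_support = 2L,
                   p_method = "empirical"),
    assembly = list(n_null = 999L, group_by = "station_layer"))
}

#' Validate a pipeline configuration
#'
#' Accepts a configuration list or the path of a YAML file, fills in
#' defaults, warns on unknown keys (forward compatibility) and checks all
#' cross-field constraints, reporting every violation at once with its
#' field path.
#'
#' @param config a list or a YAML file path.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  config <- config[setdiff(names(config), unknown)]
  merged <- modifyList(defaults, config)
  # keep an explicit `input` element even when NULL (modifyList and YAML
  # both drop nulls), so configs round-trip through serialization
  if (!"input" %in% names(merged)) merged["input"] <- list(NULL)
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(is.numeric(merged$seed) && merged$seed == round(merged$seed),
      "seed: must be an integer")
  chk(merged$network$fdr > 0 && merged$network$fdr < 1,
      sprintf("network.fdr: %s not in (0, 1)", merged$network$fdr))
  chk(merged$network$n_iter >= 1, "network.n_iter: must be >= 1")
  chk(merged$network$min_support >= 1, "network.min_support: must be >= 1")
  chk(merged$network$p_method %in% c("gaussian", "empirical"),
      "network.p_method: must be 'empirical' or 'gaussian'")
  chk(merged$assembly$n_null >= 1, "assembly.n_null: must be >= 1")
  chk(merged$forward$alpha > 0 && merged$forward$alpha < 1,
      "forward.alpha: must be in (0, 1)")
  chk(merged$keytaxa$top_k >= 1, "keytaxa.top_k: must be >= 1")
  chk(merged$tests$n_permutations >= 1,
      "tests.n_permutations: must be >= 1")
  if (is.null(merged$input)) {
    sc <- tryCatch(do.call(sim_config, merged$synthetic),
                   error = function(e) e)
    if (inherits(sc, "error"))
      errs <- c(errs, paste0("synthetic: ", conditionMessage(sc)))
    else {
      chk(merged$keytaxa$top_k <= sc$n_tips,
          sprintf("keytaxa.top_k: %d exceeds synthetic.n_tips = %d",
                  merged$keytaxa$top_k, sc$n_tips))
      merged$synthetic <- unclass(sc)
    }
  } else {
    for (f in c("otu_table", "tree", "metadata")) {
      chk(!is.null(merged$input[[f]]),
          sprintf("input.%s: required when synthetic data is not used", f))
      if (!is.null(merged$input[[f]]))
        chk(file.exists(merged$input[[f]]),
            sprintf("input.%s: file not found (%s)", f, merged$input[[f]]))
    }
  }
  if (length(errs) > 0)
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  class(merged) <- "pipeline_config"
  merged
}

pipeline_inputs <- function(config) {
  if (is.null(config$input)) {
    ds <- generate_dataset(do.call(sim_config, config$synthetic))
  } else {
    otu <- read_otu_table(config$input$otu_table)
    tree <- read_newick(config$input$tree)
    env <- read_env_table(config$input$metadata)
    cbbl <- if (!is.null(config$input$cbbl_table))
      read_otu_table(config$input$cbbl_table) else NULL
    cmap <- if (!is.null(config$input$cluster_map))
      read_cluster_map(config$input$cluster_map) else NULL
    ds <- list(otu = otu, tree = tree, env = env, cbbl = cbbl,
               cluster_map = cmap, config = NULL)
  }
  ds
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole workflow from one configuration: data
#' (synthetic generation or file inputs), alpha/beta diversity, NMDS,
#' ANOSIM, Mantel test against the environment, forward-selected tb-RDA,
#' per-layer Random-Forest key OTUs, per-layer co-occurrence networks
#' (when a carbon-fixer table is available), and betaNTI community
#' assembly with per-station-layer deterministic fractions.  Every stage
#' seed is derived deterministically from the global seed, all outputs
#' are TSV files under `run_dir`, and the returned manifest records
#' per-file MD5 checksums; rerunning an identical configuration
#' reproduces identical checksums.
#'
#' @param config a `pipeline_config`, list, or YAML path (validated via
#'   [validate_config()]).
#' @param run_dir output directory; defaults to a timestamped directory
#'   under `config$output_dir`.
#' @return the run manifest (list), invisibly written to
#'   `manifest.json` in `run_dir`.
#' @export
run_pipeline <- function(config, run_dir = NULL) {
  config <- validate_config(config)
  if (is.null(run_dir))
    run_dir <- file.path(config$output_dir,
                         format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(seed = seed, stages = list(), files = character(0),
                   status = "partial")
  outputs <- character(0)
  record <- function(stage, path) {
    outputs <<- c(outputs, path)
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]], basename(path))
  }

  # -- data ----------------------------------------------------------
  ds <- pipeline_inputs(config)
  al <- align_inputs(ds$otu, tree = ds$tree, env = ds$env)
  otu <- al$otu; tree <- al$tree; env <- al$env
  write_otu_table(otu, file.path(run_dir, "otu_table.tsv"))
  write_newick(tree, file.path(run_dir, "tree.nwk"))
  write_env_table(env, file.path(run_dir, "metadata.tsv"))
  record("data", file.path(run_dir, "otu_table.tsv"))
  record("data", file.path(run_dir, "tree.nwk"))
  record("data", file.path(run_dir, "metadata.tsv"))

  # -- diversity -----------------------------------------------------
  alpha <- alpha_diversity(otu)
  path <- file.path(run_dir, "alpha_diversity.tsv")
  utils::write.table(alpha, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("diversity", path)
  bc <- bray_curtis(otu)
  path <- file.path(run_dir, "bray_curtis.tsv")
  write_distance_matrix(bc, path)
  record("diversity", path)

  # -- ordination & tests --------------------------------------------
  ord <- nmds(bc, k = config$ordination$k,
              n_restarts = config$ordination$n_restarts,
              seed = derive_seed(seed, "stage_nmds"))
  path <- file.path(run_dir, "nmds_coordinates.tsv")
  coords <- data.frame(sample_id = rownames(ord$points), ord$points,
                       stringsAsFactors = FALSE)
  utils::write.table(coords, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("ordination", path)

  station <- setNames(env$station, env$sample_id)[colnames(otu)]
  an <- anosim_test(bc, station,
                    n_permutations = config$tests$n_permutations,
                    seed = derive_seed(seed, "stage_anosim"))
  env_num <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
  denv <- dist(scale(env_num))
  attr(denv, "Labels") <- env$sample_id
  mt <- mantel_test(bc, denv,
                    n_permutations = config$tests$n_permutations,
                    seed = derive_seed(seed, "stage_mantel"))
  path <- file.path(run_dir, "permutation_tests.tsv")
  writeLines(c("test\tstatistic\tp_value\tn_permutations",
               paste("anosim_station", fmt_num(an$statistic),
                     fmt_num(an$p_value), an$n_permutations, sep = "\t"),
               paste("mantel_env", fmt_num(mt$statistic),
                     fmt_num(mt$p_value), mt$n_permutations, sep = "\t")),
             path)
  record("tests", path)

  hel <- hellinger(otu)
  fs <- forward_select(hel, env, alpha = config$forward$alpha,
                       n_permutations = config$forward$n_permutations,
                       seed = derive_seed(seed, "stage_forward"))
  path <- file.path(run_dir, "forward_selection.tsv")
  utils::write.table(fs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("ordination", path)
  if (nrow(fs) > 0) {
    rd <- rda_constrained(hel, env, fs$variable)
    path <- file.path(run_dir, "rda_summary.tsv")
    writeLines(c("axis\teigenvalue\tprop_total\tprop_constrained",
                 paste(seq_along(rd$eigenvalues),
                       fmt_num(rd$eigenvalues),
                       fmt_num(rd$prop_explained),
                       fmt_num(rd$prop_constrained), sep = "\t")),
               path)
    record("ordination", path)
  }

  # -- key taxa & networks, per layer --------------------------------
  layers <- unique(env$layer)
  clusters <- if (!is.null(ds$cbbl) && !is.null(ds$cluster_map))
    aggregate_clusters(ds$cbbl, ds$cluster_map) else NULL
  rel <- to_relative(otu)
  for (ly in layers) {
    in_layer <- env$sample_id[env$layer == ly]
    sub <- otu_table(unclass(rel)[, in_layer, drop = FALSE],
                     mode = "relative")
    st <- setNames(env$station, env$sample_id)[in_layer]
    if (length(unique(st)) < 2 || any(table(st) < 2)) next
    rk <- rank_otus(sub, st, n_trees = config$keytaxa$n_trees,
                    seed = derive_seed(seed, paste0("stage_rf_", ly)))
    path <- file.path(run_dir, sprintf("key_otus_%s.tsv", ly))
    utils::write.table(rk$ranking, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("keytaxa", path)
    top <- select_top(rk, min(config$keytaxa$top_k, nrow(rk$ranking)))
    if (!is.null(clusters)) {
      key_tab <- unclass(rel)[top, in_layer, drop = FALSE]
      cl_tab <- unclass(clusters)[, in_layer, drop = FALSE]
      net <- build_network(key_tab, cl_tab,
                           min_support = config$network$min_support,
                           fdr = config$network$fdr,
                           n_iter = config$network$n_iter,
                           p_method = config$network$p_method,
                           seed = derive_seed(seed,
                                              paste0("stage_net_", ly)),
                           layer = ly)
      path <- file.path(run_dir, sprintf("network_%s_edges.tsv", ly))
      write_edge_list(net, path)
      record("network", path)
    }
  }

  # -- community assembly --------------------------------------------
  asm <- bnti_matrix(otu, tree, n_null = config$assembly$n_null,
                     seed = derive_seed(seed, "stage_assembly"))
  path <- file.path(run_dir, "bnti_pairs.tsv")
  write_assembly_result(asm, path)
  record("assembly", path)
  grouping <- switch(config$assembly$group_by,
                     station = setNames(env$station, env$sample_id),
                     layer = setNames(env$layer, env$sample_id),
                     setNames(paste(env$station, env$layer, sep = "_"),
                              env$sample_id))
  gf <- group_fractions(asm, grouping)
  path <- file.path(run_dir, "bnti_group_fractions.tsv")
  utils::write.table(gf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("assembly", path)

  # -- manifest ------------------------------------------------------
  manifest$status <- "complete"
  sums <- tools::md5sum(outputs)
  manifest$files <- setNames(unname(sums), basename(outputs))
  cfg_path <- file.path(run_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest$n_samples <- ncol(otu)
  manifest$n_otus <- nrow(otu)
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
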