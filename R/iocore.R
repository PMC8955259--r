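#' OTU abundance table
#'
#' Construct a validated OTU table: a non-negative numeric matrix with OTUs
#' as rows and samples as columns (the common amplicon convention), carrying
#' a mode flag that records whether the values are raw counts or relative
#' abundances.
#'
#' @param values numeric matrix, OTUs in rows, samples in columns.
#' @param otu_ids,sample_ids character vectors of unique identifiers;
#'   default to the matrix dimnames.
#' @param mode `"counts"` or `"relative"`.  In relative mode every sample
#'   column must sum to 1 (within 1e-9) unless `partial = TRUE`.
#' @param partial logical; allow relative columns to sum to less than 1
#'   (used for tables restricted to a subset of the community, e.g.
#'   carbon-fixer clusters).
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(values, otu_ids = rownames(values),
                      sample_ids = colnames(values),
                      mode = c("counts", "relative"), partial = FALSE) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(otu_ids) || is.null(sample_ids))
    stop("OTU and sample identifiers are required")
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values)) stop("OTU table contains missing values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at OTU '%s', sample '%s'",
                 otu_ids[bad[1]], sample_ids[bad[2]]))
  }
  if (mode == "relative") {
    cs <- colSums(values)
    ok <- if (partial) cs <= 1 + 1e-9 else abs(cs - 1) <= 1e-9
    if (!all(ok))
      stop("relative-mode sample(s) do not sum to 1: ",
           paste(sample_ids[!ok], collapse = ", "))
  }
  dimnames(values) <- list(otu_ids, sample_ids)
  structure(values, mode_flag = mode, partial = partial,
            class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%s mode)\n",
              nrow(x), ncol(x), table_mode(x)))
  invisible(x)
}

#' Abundance mode of an OTU table
#' @param x an [otu_table()].
#' @return `"counts"` or `"relative"`.
#' @export
table_mode <- function(x) attr(x, "mode_flag")

#' Convert an OTU table to relative abundances
#'
#' Explicit per-sample closure: each sample column is divided by its total.
#' Conversion is never done implicitly by other functions that accept both
#' modes.
#'
#' @param x an [otu_table()].
#' @return an `otu_table` in relative mode.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (table_mode(x) == "relative") return(x)
  cs <- colSums(x)
  if (any(cs == 0))
    stop("cannot convert all-zero sample(s) to relative abundance: ",
         paste(colnames(x)[cs == 0], collapse = ", "))
  otu_table(sweep(unclass(x), 2, cs, "/"), mode = "relative")
}

# strict TSV reader: rejects ragged rows, returns character matrix body
read_tsv_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("file '", path, "' has no data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1]])
  lens <- lengths(cells)
  if (any(lens != width))
    stop(sprintf("ragged row %d in '%s': %d fields, expected %d",
                 which(lens != width)[1], path, lens[lens != width][1], width))
  cells
}

#' Read / write OTU tables as TSV
#'
#' The canonical on-disk format is a tab-separated table with OTU ids in the
#' first column, sample ids in the header row, and a numeric body.  Reading
#' validates uniqueness, numeric values and rectangular shape; writing uses
#' 12 significant digits so that write-then-read is an identity on ids and
#' values to within float formatting.
#'
#' @param path file path.
#' @param mode abundance mode to stamp on the table.
#' @return [read_otu_table()] returns an [otu_table()];
#'   [write_otu_table()] returns `path` invisibly.
#' @export
read_otu_table <- function(path, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  cells <- read_tsv_matrix(path)
  header <- cells[[1]]
  sample_ids <- header[-1]
  body <- cells[-1]
  otu_ids <- vapply(body, `[`, character(1), 1L)
  vals <- lapply(body, function(row) {
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in row '%s' of '%s'", row[1], path))
    v
  })
  m <- do.call(rbind, vals)
  rownames(m) <- otu_ids
  colnames(m) <- sample_ids
  otu_table(m, mode = mode, partial = TRUE)
}

#' @rdname read_otu_table
#' @param table an [otu_table()].
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  header <- paste(c("otu_id", colnames(table)), collapse = "\t")
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], fmt_num(table[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read / write rooted phylogenies in Newick format
#'
#' Thin, validating wrappers around [ape::read.tree()] and
#' [ape::write.tree()].  Trees must contain a single topology with at least
#' two uniquely labelled tips; by default every edge must carry a
#' non-negative branch length, since all downstream phylogenetic distances
#' are patristic.
#'
#' @param path file path.
#' @param require_lengths reject trees with missing branch lengths
#'   (default `TRUE`).
#' @return a `phylo` object / `path` invisibly.
#' @export
read_newick <- function(path, require_lengths = TRUE) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo"))
    stop("'", path, "' contains more than one tree")
  if (is.null(tr)) stop("could not parse a tree from '", path, "'")
  validate_tree(tr, require_lengths = require_lengths)
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

validate_tree <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (require_lengths) {
    if (is.null(tree$edge.length) || anyNA(tree$edge.length))
      stop("tree has missing branch lengths")
    if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  }
  invisible(tree)
}

#' Read / write sample metadata tables
#'
#' One row per sample; the first column holds the sample id, `station` and
#' `layer` are kept as categorical labels, every other column is parsed as
#' numeric where possible.
#'
#' @param path file path.
#' @return a `data.frame` with rownames set to the sample ids.
#' @export
read_env_table <- function(path) {
  cells <- read_tsv_matrix(path)
  header <- cells[[1]]
  body <- cells[-1]
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sample ids in '", path, "'")
  df <- as.data.frame(lapply(seq_along(header)[-1], function(j) {
    col <- vapply(body, `[`, character(1), j)
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) col else num
  }), optional = TRUE)
  names(df) <- header[-1]
  df <- cbind(sample_id = ids, df, stringsAsFactors = FALSE)
  rownames(df) <- ids
  df
}

#' @rdname read_env_table
#' @param env a metadata `data.frame` with a `sample_id` column.
#' @export
write_env_table <- function(env, path) {
  stopifnot(is.data.frame(env), "sample_id" %in% names(env))
  cols <- lapply(env, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  lines <- c(paste(names(env), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write OTU-to-cluster assignments
#'
#' Two-column TSV mapping carbon-fixer (cbbL) OTU ids onto cluster labels;
#' the clustering itself (phylogenetic grouping of cbbL sequences) is an
#' upstream input, not computed here.
#'
#' @param path file path.
#' @return a `data.frame` with columns `otu_id` and `cluster`.
#' @export
read_cluster_map <- function(path) {
  cells <- read_tsv_matrix(path)
  body <- cells[-1]
  df <- data.frame(otu_id = vapply(body, `[`, character(1), 1L),
                   cluster = vapply(body, `[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$otu_id))
    stop("duplicate OTU ids in cluster map '", path, "'")
  df
}

#' @rdname read_cluster_map
#' @param map a `data.frame` with columns `otu_id` and `cluster`.
#' @export
write_cluster_map <- function(map, path) {
  stopifnot(all(c("otu_id", "cluster") %in% names(map)))
  lines <- c("otu_id\tcluster",
             paste(map$otu_id, map$cluster, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a distance matrix as a square TSV
#' @param d a `dist` object or labelled square matrix.
#' @param path file path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  header <- paste(c("sample_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Align an OTU table, phylogeny and metadata on shared identifiers
#'
#' Restricts the OTU set to the intersection of table rows and tree tips,
#' and the sample set to the intersection of table columns and metadata
#' rows, in deterministic sorted order.  Dropped identifiers are reported
#' via `message()`.
#'
#' @param otu an [otu_table()].
#' @param tree optional `phylo`; pruned to the shared OTU set.
#' @param env optional metadata `data.frame` (see [read_env_table()]).
#' @return a list with elements `otu`, `tree`, `env` and a `dropped` report.
#' @export
align_inputs <- function(otu, tree = NULL, env = NULL) {
  stopifnot(inherits(otu, "otu_table"))
  otus <- rownames(otu)
  samples <- colnames(otu)
  dropped <- list()
  if (!is.null(tree)) {
    validate_tree(tree)
    shared <- sort(intersect(otus, tree$tip.label))
    if (length(shared) == 0)
      stop("no shared OTUs between table and tree")
    dropped$otus_not_in_tree <- setdiff(otus, shared)
    dropped$tips_not_in_table <- setdiff(tree$tip.label, shared)
    if (length(dropped$tips_not_in_table) > 0)
      tree <- ape::drop.tip(tree, dropped$tips_not_in_table)
    otus <- shared
  } else {
    otus <- sort(otus)
  }
  if (!is.null(env)) {
    shared_s <- sort(intersect(samples, env$sample_id))
    if (length(shared_s) == 0)
      stop("no shared samples between table and metadata")
    dropped$samples_not_in_env <- setdiff(samples, shared_s)
    dropped$env_not_in_table <- setdiff(env$sample_id, shared_s)
    env <- env[match(shared_s, env$sample_id), , drop = FALSE]
    samples <- shared_s
  } else {
    samples <- sort(samples)
  }
  n_drop <- sum(lengths(dropped))
  if (n_drop > 0)
    message("align_inputs: dropped ", n_drop, " unmatched identifier(s)")
  out <- otu_table(unclass(otu)[otus, samples, drop = FALSE],
                   mode = table_mode(otu), partial = TRUE)
  list(otu = out, tree = tree, env = env, dropped = dropped)
}
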