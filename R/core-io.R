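#' Read an abundance table from TSV
#'
#' Reads a tab-delimited count table whose first column holds identifiers and
#' whose header row holds the other axis. Amplicon tables come in both
#' orientations; the canonical in-memory form is samples x features.
#'
#' @param path Path to a TSV file.
#' @param samples_as_rows Logical; `TRUE` (default) when rows are samples,
#'   `FALSE` when rows are features (the table is transposed on load).
#' @return Integer matrix, samples x features, with dimnames.
#' @export
read_abundance_table <- function(path, samples_as_rows = TRUE) {
  if (!file.exists(path)) stopf("abundance table not found: %s", path)
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr)) {
    stopf("duplicate ids in header of %s: %s", path,
          paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stopf("duplicate ids in first column of %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- hdr
  if (!samples_as_rows) m <- t(m)
  assert_count_matrix(m)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stopf("samples with zero total counts: %s",
          paste(rownames(m)[zero], collapse = ", "))
  }
  m
}

#' Write an abundance table to TSV
#'
#' @param table Samples x features count matrix.
#' @param path Output path.
#' @param samples_as_rows Orientation of the written file.
#' @return The path, invisibly.
#' @export
write_abundance_table <- function(table, path, samples_as_rows = TRUE) {
  assert_count_matrix(table)
  m <- if (samples_as_rows) table else t(table)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (samples_as_rows) "sample_id" else "feature_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Expects a `sample_id` column (or uses the first column). Numeric columns
#' may contain missing values; consumers drop affected samples pairwise.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata table not found: %s", path)
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) names(md)[1] <- "sample_id"
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) {
    stopf("duplicate sample ids in metadata: %s",
          paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  md
}

#' Write sample metadata to TSV
#' @param metadata Data frame with a `sample_id` column.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load and cross-validate a count table, phylogeny and metadata
#'
#' Reads the three standard inputs, checks that every table feature is a tree
#' tip (extra tips are pruned with a logged warning) and that every table
#' sample has metadata, and normalises ordering: metadata rows follow the
#' table's sample order and tree tips cover exactly the table's features.
#'
#' @param table_path TSV count table.
#' @param tree_path Newick file with a rooted tree and branch lengths.
#' @param metadata_path TSV metadata with a `sample_id` column.
#' @param samples_as_rows Orientation of the count table on disk.
#' @return A list with elements `table` (samples x features matrix), `tree`
#'   (an [ape::phylo]) and `metadata` (data.frame aligned to the table).
#' @export
load_dataset <- function(table_path, tree_path, metadata_path,
                         samples_as_rows = TRUE) {
  table <- read_abundance_table(table_path, samples_as_rows = samples_as_rows)
  if (!file.exists(tree_path)) stopf("tree file not found: %s", tree_path)
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stopf("could not parse newick tree: %s", tree_path)
  metadata <- read_sample_metadata(metadata_path)

  feats <- colnames(table)
  missing_tips <- setdiff(feats, tree$tip.label)
  if (length(missing_tips) > 0) {
    stopf("features absent from the tree: %s",
          paste(missing_tips, collapse = ", "))
  }
  extra <- setdiff(tree$tip.label, feats)
  if (length(extra) > 0) {
    pn_log("pruning %d tree tips not present in the table", length(extra))
    tree <- ape::keep.tip(tree, feats)
  }
  missing_md <- setdiff(rownames(table), metadata$sample_id)
  if (length(missing_md) > 0) {
    stopf("samples without metadata: %s", paste(missing_md, collapse = ", "))
  }
  metadata <- metadata[match(rownames(table), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  list(table = table, tree = tree, metadata = metadata)
}

#' Write a co-occurrence network to disk
#'
#' GraphML preserves all node and edge attributes in one file. The TSV edge
#' list writes `<path>` with one edge per row (columns `from`, `to`, `r`,
#' `sign`, `q`) and a companion `<path>.nodes.tsv` with per-node module
#' labels, so a round-trip reproduces the network exactly.
#'
#' @param network An [igraph::igraph] as built by [build_network()].
#' @param path Output path.
#' @param format `"graphml"` or `"edge_list_tsv"`.
#' @return The path, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edge_list_tsv")) {
  format <- match.arg(format)
  if (igraph::vcount(network) < 1) stopf("network has no nodes")
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network, what = "edges")
    num <- vapply(el, is.numeric, logical(1))
    el[num] <- lapply(el[num], function(x) sprintf("%.17g", x))
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
    nodes <- igraph::as_data_frame(network, what = "vertices")
    if (!"name" %in% names(nodes)) nodes$name <- as.character(seq_len(nrow(nodes)))
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path Path given to [write_network()].
#' @param format Format used when writing.
#' @return An [igraph::igraph].
#' @export
read_network <- function(path, format = c("graphml", "edge_list_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("network file not found: %s", path)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  el <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nodes <- utils::read.delim(paste0(path, ".nodes.tsv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
  nodes$name <- as.character(nodes$name)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
}

#' Default run configuration
#'
#' Central record of the tunable parameters of the pipeline; every randomised
#' stage takes its seed from here and records it in its output.
#'
#' @param rarefaction_depth Reads per sample after rarefaction (`NULL` skips
#'   rarefaction).
#' @param abundant_relab Per-sample relative-abundance cutoff for the
#'   occurrence route to "abundant" (default 0.01, i.e. 1%).
#' @param abundant_occupancy Fraction of samples that must exceed
#'   `abundant_relab` (default 0.10).
#' @param abundant_sum Cutoff on the summed relative abundance route to
#'   "abundant" (default 0.20).
#' @param rare_sum Summed relative abundance below which a feature is "rare"
#'   (default 0.005).
#' @param sum_convention `"total"` (sum of per-sample relative abundances)
#'   or `"mean"` (that sum divided by the number of samples).
#' @param n_null Null-model replicates for SES MNTD, beta-NTI and Raup-Crick.
#' @param cor_method Correlation for network edges, `"spearman"` or
#'   `"pearson"`.
#' @param r_min Minimum absolute correlation for an edge.
#' @param q_max Maximum BH-adjusted p-value for an edge.
#' @param prevalence_min Minimum occupancy fraction for a feature to enter
#'   the network.
#' @param remove_fraction Fraction of nodes removed in the random-robustness
#'   simulation.
#' @param robustness_reps Replicates for the removal simulations.
#' @param seed Base random seed recorded in every stochastic output.
#' @return A list of class `plankton_config`.
#' @export
plankton_config <- function(rarefaction_depth = NULL,
                            abundant_relab = 0.01,
                            abundant_occupancy = 0.10,
                            abundant_sum = 0.20,
                            rare_sum = 0.005,
                            sum_convention = c("total", "mean"),
                            n_null = 999,
                            cor_method = c("spearman", "pearson"),
                            r_min = 0.6,
                            q_max = 0.05,
                            prevalence_min = 0.5,
                            remove_fraction = 0.5,
                            robustness_reps = 100,
                            seed = 1L) {
  cfg <- list(rarefaction_depth = rarefaction_depth,
              abundant_relab = abundant_relab,
              abundant_occupancy = abundant_occupancy,
              abundant_sum = abundant_sum,
              rare_sum = rare_sum,
              sum_convention = match.arg(sum_convention),
              n_null = n_null,
              cor_method = match.arg(cor_method),
              r_min = r_min,
              q_max = q_max,
              prevalence_min = prevalence_min,
              remove_fraction = remove_fraction,
              robustness_reps = robustness_reps,
              seed = seed)
  if (cfg$n_null < 1 || cfg$robustness_reps < 1) {
    stopf("replicate counts must be >= 1")
  }
  class(cfg) <- "plankton_config"
  cfg
}
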