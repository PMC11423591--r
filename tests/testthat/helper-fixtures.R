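options(planktonet.quiet = TRUE)

# --- small analytic graphs ------------------------------------------------

graph_from_edges <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!is.null(nodes)) {
    g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)))
  }
  g
}

make_triangle <- function() {
  igraph::graph_from_literal(a - b, b - c, a - c)
}

make_two_triangles <- function() {
  igraph::graph_from_literal(a - b, b - c, a - c, d - e, e - f, d - f)
}

make_path3 <- function() {
  igraph::graph_from_literal(a - b, b - c)
}

make_star <- function(n_leaves) {
  el <- cbind("hub", paste0("leaf", seq_len(n_leaves)))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

make_complete <- function(n) {
  g <- igraph::make_full_graph(n)
  igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n)))
}

# --- small community fixtures --------------------------------------------

# deterministic 3-sample x 4-feature table
toy_table <- function() {
  m <- matrix(c(5, 3, 0, 2,
                1, 0, 4, 4,
                2, 2, 2, 2), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(c("s1", "s2", "s3"), paste0("ASV_", 1:4))
  m
}

toy_tree <- function(tips = paste0("ASV_", 1:4)) {
  tr <- ape::read.tree(text = "((ASV_1:1,ASV_2:1):0.5,(ASV_3:1,(ASV_4:0.5,ASV_5:0.5):0.5):0.5):0;")
  ape::keep.tip(tr, tips)
}

toy_metadata <- function(ids = c("s1", "s2", "s3")) {
  data.frame(sample_id = ids,
             latitude = c(32, 35, 39.5)[seq_along(ids)],
             longitude = c(120, 122, 124)[seq_along(ids)],
             temperature = c(26, 24, 21)[seq_along(ids)],
             salinity = c(30, 31, 31.5)[seq_along(ids)],
             stringsAsFactors = FALSE)
}

write_toy_files <- function(dir, table = toy_table(), tree = toy_tree(),
                            metadata = toy_metadata()) {
  paths <- list(table = file.path(dir, "table.tsv"),
                tree = file.path(dir, "tree.nwk"),
                metadata = file.path(dir, "metadata.tsv"))
  write_abundance_table(table, paths$table)
  ape::write.tree(tree, paths$tree)
  write_sample_metadata(metadata, paths$metadata)
  paths
}

# --- independent test-side oracles ---------------------------------------

# beta-MNTD by explicit double loops (independent of the C++ engine)
bmntd_brute <- function(table, D, weighted = TRUE) {
  n <- nrow(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (k in seq_len(n - 1)) {
    for (l in (k + 1):n) {
      a <- which(table[k, ] > 0)
      b <- which(table[l, ] > 0)
      wa <- if (weighted) table[k, a] / sum(table[k, a]) else
        rep(1 / length(a), length(a))
      wb <- if (weighted) table[l, b] / sum(table[l, b]) else
        rep(1 / length(b), length(b))
      s1 <- 0
      for (i in seq_along(a)) {
        mn <- Inf
        for (j in seq_along(b)) mn <- min(mn, D[a[i], b[j]])
        s1 <- s1 + wa[i] * mn
      }
      s2 <- 0
      for (j in seq_along(b)) {
        mn <- Inf
        for (i in seq_along(a)) mn <- min(mn, D[b[j], a[i]])
        s2 <- s2 + wb[j] * mn
      }
      out[k, l] <- out[l, k] <- 0.5 * (s1 + s2)
    }
  }
  out
}

# Zi / Pi by explicit per-node loops over the adjacency matrix
zipi_brute <- function(adj, membership) {
  n <- nrow(adj)
  mods <- sort(unique(membership))
  k_within <- numeric(n)
  for (i in seq_len(n)) {
    k_within[i] <- sum(adj[i, membership == membership[i]])
  }
  zi <- numeric(n)
  for (m in mods) {
    idx <- which(membership == m)
    mu <- mean(k_within[idx]); sdv <- stats::sd(k_within[idx])
    for (i in idx) zi[i] <- if (is.na(sdv) || sdv == 0) 0 else
      (k_within[i] - mu) / sdv
  }
  pi <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(adj[i, ])
    if (ki == 0) { pi[i] <- 0; next }
    acc <- 0
    for (m in mods) acc <- acc + (sum(adj[i, membership == m]) / ki)^2
    pi[i] <- 1 - acc
  }
  list(zi = zi, pi = pi)
}
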