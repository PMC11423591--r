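#' Build a correlation-based co-occurrence network
#'
#' Features present in at least `prevalence_min` of the samples are
#' log10-transformed relative abundances (percent scale; zeros replaced by
#' the pseudo-abundance `pseudo` before the log, following the molecular
#' ecological network convention). All pairwise correlations are computed,
#' p-values are Benjamini-Hochberg adjusted over the tested pairs, and an
#' undirected signed edge is kept where |r| >= `r_min` and q <= `q_max`.
#' Nodes are the features incident to at least one edge.
#'
#' @param table Samples x features count matrix (>= 10 samples advised).
#' @param prevalence_min Minimum occupancy fraction for a feature to be
#'   tested (default 0.5).
#' @param method Correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @param r_min Minimum absolute correlation for an edge (default 0.6).
#' @param q_max Maximum BH-adjusted p-value (default 0.05).
#' @param pseudo Pseudo-abundance replacing zeros on the percent scale
#'   (default 0.01).
#' @param seed Unused by the (deterministic) construction; recorded in the
#'   graph attributes for provenance.
#' @return An [igraph::igraph] with edge attributes `r`, `sign`
#'   (`"positive"`/`"negative"`), `q` and `weight` (= r), and graph
#'   attributes recording the construction parameters.
#' @export
build_network <- function(table, prevalence_min = 0.5,
                          method = c("spearman", "pearson"),
                          r_min = 0.6, q_max = 0.05, pseudo = 0.01,
                          seed = NULL) {
  method <- match.arg(method)
  assert_count_matrix(table)
  n <- nrow(table)
  keep <- colMeans(table > 0) >= prevalence_min
  if (sum(keep) < 2) {
    stopf("fewer than 2 features pass the prevalence filter (%.2f)",
          prevalence_min)
  }
  sub <- table[, keep, drop = FALSE]
  rel <- relative_abundance(sub) * 100
  rel[rel == 0] <- pseudo
  x <- log10(rel)

  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    pn_log("excluding %d constant feature(s) from correlation", sum(const))
    x <- x[, !const, drop = FALSE]
    if (ncol(x) < 2) stopf("fewer than 2 non-constant features")
  }
  cm <- stats::cor(x, method = method)
  # t approximation for the correlation p-value (standard for both methods
  # at these sample sizes; ties make the exact Spearman law unavailable)
  r_off <- cm[upper.tri(cm)]
  tstat <- r_off * sqrt((n - 2) / pmax(1 - r_off^2, 1e-12))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  qval <- stats::p.adjust(pval, method = "BH")

  ut <- which(upper.tri(cm), arr.ind = TRUE)
  sel <- abs(r_off) >= r_min & qval <= q_max & !is.na(r_off)
  edges <- data.frame(from = colnames(x)[ut[sel, 1]],
                      to = colnames(x)[ut[sel, 2]],
                      r = r_off[sel],
                      sign = ifelse(r_off[sel] >= 0, "positive", "negative"),
                      q = qval[sel], stringsAsFactors = FALSE)
  edges$weight <- edges$r
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- igraph::set_graph_attr(g, "method", method)
  g <- igraph::set_graph_attr(g, "r_min", r_min)
  g <- igraph::set_graph_attr(g, "q_max", q_max)
  g <- igraph::set_graph_attr(g, "prevalence_min", prevalence_min)
  g <- igraph::set_graph_attr(g, "pseudo", pseudo)
  g <- igraph::set_graph_attr(g, "n_tested_pairs", length(r_off))
  if (!is.null(seed)) g <- igraph::set_graph_attr(g, "seed", seed)
  g
}

#' Detect network modules by greedy modularity optimisation
#'
#' Deterministic fast-greedy agglomeration ([igraph::cluster_fast_greedy])
#' on the unweighted topology; modularity
#' Q = sum_m \[ l_m/L - (d_m/2L)^2 \]. Connected components that are
#' singletons form their own modules.
#'
#' @param network An [igraph::igraph].
#' @param seed Accepted for interface symmetry; the algorithm is
#'   deterministic.
#' @return List with `membership` (named integer vector), `modularity` (Q),
#'   `n_modules`, and `network` (the input with a `module` vertex
#'   attribute).
#' @export
detect_modules <- function(network, seed = NULL) {
  if (igraph::ecount(network) < 1) stopf("network has no edges")
  g0 <- network
  if ("weight" %in% igraph::edge_attr_names(g0)) {
    g0 <- igraph::delete_edge_attr(g0, "weight")
  }
  cl <- igraph::cluster_fast_greedy(g0)
  membership <- igraph::membership(cl)
  q <- igraph::modularity(g0, membership)
  # greedy agglomeration can overshoot on very dense graphs; the connected
  # components are always an admissible partition, so take the better one
  comp <- igraph::components(g0)$membership
  q_comp <- igraph::modularity(g0, comp)
  if (q_comp > q) {
    membership <- comp
    q <- q_comp
  }
  network <- igraph::set_vertex_attr(network, "module",
                                     value = as.integer(membership))
  list(membership = stats::setNames(as.integer(membership),
                                    igraph::V(network)$name),
       modularity = q,
       n_modules = length(unique(membership)),
       network = network)
}

#' Whole-network topology summary
#'
#' Node and edge counts, average degree, average local clustering
#' coefficient (nodes of degree < 2 contribute 0), average shortest-path
#' length over reachable pairs, modularity and module count (computed via
#' [detect_modules()] when not already present), and the degree power-law
#' fit of [powerlaw_fit()].
#'
#' @param network An [igraph::igraph].
#' @param modules Optional result of [detect_modules()].
#' @return List of class `topology_summary`.
#' @export
topology_summary <- function(network, modules = NULL) {
  if (igraph::vcount(network) < 1) stopf("network has no nodes")
  deg <- igraph::degree(network)
  avg_cc <- igraph::transitivity(network, type = "localaverage",
                                 isolates = "zero")
  if (is.nan(avg_cc)) avg_cc <- 0
  L <- if (igraph::ecount(network) > 0) {
    igraph::mean_distance(network, directed = FALSE, unconnected = TRUE,
                          weights = NA)
  } else {
    NA_real_
  }
  if (is.null(modules) && igraph::ecount(network) > 0) {
    modules <- detect_modules(network)
  }
  pl <- powerlaw_fit(deg)
  structure(list(
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    avg_degree = mean(deg),
    avg_clustering = avg_cc,
    avg_path_distance = L,
    modularity = if (is.null(modules)) NA_real_ else modules$modularity,
    n_modules = if (is.null(modules)) NA_integer_ else modules$n_modules,
    powerlaw = pl
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Network topology\n")
  cat(sprintf("  nodes %d  edges %d  avg degree %.2f\n",
              x$n_nodes, x$n_edges, x$avg_degree))
  cat(sprintf("  avgCC %.3f  L %.3f  Q %.3f  modules %s\n",
              x$avg_clustering, x$avg_path_distance, x$modularity,
              x$n_modules))
  if (isTRUE(x$powerlaw$assessable)) {
    cat(sprintf("  degree power law: gamma %.2f  R2 %.3f  p %.3g\n",
                x$powerlaw$gamma, x$powerlaw$R2, x$powerlaw$p_value))
  }
  invisible(x)
}

#' Per-node metrics and topological roles
#'
#' Degree, normalised betweenness centrality, within-module degree z-score
#' Zi, among-module participation coefficient Pi, and the Guimera-Amaral
#' role: module hub (Zi >= 2.5), connector (Pi >= 0.62), network hub
#' (both), peripheral (neither).
#'
#' @param network An [igraph::igraph].
#' @param membership Optional module membership (from [detect_modules()]);
#'   computed if absent.
#' @return Data frame: `feature_id`, `degree`, `betweenness`, `module`,
#'   `zi`, `pi`, `role`.
#' @export
node_metrics <- function(network, membership = NULL) {
  if (is.null(membership)) {
    membership <- if (!is.null(igraph::V(network)$module)) {
      stats::setNames(igraph::V(network)$module, igraph::V(network)$name)
    } else {
      detect_modules(network)$membership
    }
  }
  nodes <- igraph::V(network)$name
  membership <- membership[nodes]
  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, directed = FALSE, normalized = TRUE,
                             weights = NA)
  adj <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  mods <- sort(unique(membership))
  # within-module degree of every node towards every module
  kim <- vapply(mods, function(m) {
    rowSums(adj[, membership == m, drop = FALSE])
  }, numeric(length(nodes)))
  if (is.null(dim(kim))) kim <- matrix(kim, nrow = length(nodes))
  own <- match(membership, mods)
  k_within <- kim[cbind(seq_along(nodes), own)]
  zi <- numeric(length(nodes))
  for (m in seq_along(mods)) {
    members <- which(own == m)
    mu <- mean(k_within[members])
    sdv <- stats::sd(k_within[members])
    zi[members] <- if (is.na(sdv) || sdv == 0) 0 else
      (k_within[members] - mu) / sdv
  }
  pi <- ifelse(deg > 0, 1 - rowSums((kim / pmax(deg, 1))^2), 0)
  role <- ifelse(zi >= 2.5 & pi >= 0.62, "network hub",
          ifelse(zi >= 2.5, "module hub",
          ifelse(pi >= 0.62, "connector", "peripheral")))
  data.frame(feature_id = nodes, degree = as.numeric(deg),
             betweenness = as.numeric(btw), module = as.integer(membership),
             zi = zi, pi = as.numeric(pi), role = role,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Power-law fit of the degree distribution
#'
#' Least-squares regression of log frequency on log degree over the
#' positive degrees: P(k) ~ k^-gamma. Needs at least 5 distinct degrees to
#' be assessable.
#'
#' @param degrees Integer vector of node degrees.
#' @return List with `assessable` and, when assessable, `gamma`, `R2`,
#'   `p_value`.
#' @export
powerlaw_fit <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 5) {
    return(list(assessable = FALSE,
                reason = sprintf("only %d distinct positive degrees",
                                 length(tab))))
  }
  k <- as.numeric(names(tab))
  freq <- as.numeric(tab) / sum(tab)
  fit <- stats::lm(log(freq) ~ log(k))
  sm <- summary(fit)
  list(assessable = TRUE,
       gamma = -unname(stats::coef(fit)[2]),
       R2 = sm$r.squared,
       p_value = sm$coefficients[2, 4])
}
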