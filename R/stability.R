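# Survivors after removing `drop` nodes: remaining nodes that still hold at
# least one edge (newly isolated nodes go secondarily extinct). The
# no-cascade variant counts all remaining nodes.
pn_survivors <- function(network, drop, cascade = TRUE) {
  keep <- setdiff(igraph::V(network)$name, drop)
  if (length(keep) == 0) return(0L)
  sub <- igraph::induced_subgraph(network, keep)
  if (!cascade) return(length(keep))
  sum(igraph::degree(sub) > 0)
}

#' Network robustness under random node removal
#'
#' Per replicate, `floor(remove_fraction * n)` nodes are removed uniformly
#' at random; remaining nodes left without any surviving edge go
#' secondarily extinct; robustness is the proportion of the original nodes
#' that survive.
#'
#' @param network An [igraph::igraph] with >= 2 nodes.
#' @param remove_fraction Fraction of nodes removed, in (0, 1).
#' @param reps Number of replicates.
#' @param seed Random seed.
#' @param cascade Apply the secondary-extinction rule (default TRUE).
#' @return List with `mean`, `sd`, `values` (per-replicate robustness),
#'   `n_removed`, `seed`.
#' @export
robustness_random <- function(network, remove_fraction = 0.5, reps = 100,
                              seed = NULL, cascade = TRUE) {
  n <- igraph::vcount(network)
  if (n < 2) stopf("need >= 2 nodes")
  if (remove_fraction <= 0 || remove_fraction >= 1) {
    stopf("remove_fraction must be in (0, 1)")
  }
  n_rm <- floor(remove_fraction * n)
  nodes <- igraph::V(network)$name
  vals <- with_seed(seed, vapply(seq_len(reps), function(r) {
    pn_survivors(network, sample(nodes, n_rm), cascade) / n
  }, numeric(1)))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals,
       n_removed = n_rm, seed = seed)
}

#' Network robustness under module-hub removal
#'
#' Per replicate, half of the module hubs (`ceiling(H/2)` of the H nodes
#' with role `"module hub"` or `"network hub"`) are removed uniformly at
#' random, followed by the secondary-extinction cascade. With no module
#' hubs the network is vacuously robust (1.0, with a warning).
#'
#' @param network An [igraph::igraph].
#' @param metrics Node metrics from [node_metrics()].
#' @param reps Number of replicates.
#' @param seed Random seed.
#' @param cascade Apply the secondary-extinction rule.
#' @return As [robustness_random()], plus `n_hubs`.
#' @export
robustness_targeted <- function(network, metrics, reps = 100, seed = NULL,
                                cascade = TRUE) {
  hubs <- metrics$feature_id[metrics$role %in% c("module hub", "network hub")]
  n <- igraph::vcount(network)
  if (length(hubs) == 0) {
    warnf("no module hubs in network: targeted robustness is vacuously 1")
    return(list(mean = 1, sd = 0, values = rep(1, reps), n_removed = 0L,
                n_hubs = 0L, seed = seed))
  }
  n_rm <- ceiling(length(hubs) / 2)
  vals <- with_seed(seed, vapply(seq_len(reps), function(r) {
    pn_survivors(network, sample(hubs, n_rm), cascade) / n
  }, numeric(1)))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals,
       n_removed = n_rm, n_hubs = length(hubs), seed = seed)
}

# Global efficiency: mean over ordered node pairs of 1/d(i,j), with
# unreachable pairs contributing 0.
pn_efficiency <- function(network) {
  n <- igraph::vcount(network)
  if (n < 2) return(0)
  d <- igraph::distances(network, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Node and network vulnerability
#'
#' The vulnerability of node i is the relative drop in global efficiency
#' when i is removed: V_i = (E - E_-i) / E, where E is the mean over
#' ordered reachable pairs of the inverse shortest-path length. Network
#' vulnerability is the maximum V_i. Peripheral nodes can have negative
#' V_i (their removal raises the mean efficiency).
#'
#' @param network An [igraph::igraph] with >= 3 nodes.
#' @return List with `per_node` (named numeric), `max` (network
#'   vulnerability) and `which` (the most vulnerable node's id).
#' @export
vulnerability <- function(network) {
  n <- igraph::vcount(network)
  if (n < 3) stopf("need >= 3 nodes")
  E0 <- pn_efficiency(network)
  if (E0 == 0) stopf("no connected component with >= 2 nodes")
  nodes <- igraph::V(network)$name
  v <- vapply(nodes, function(nd) {
    (E0 - pn_efficiency(igraph::delete_vertices(network, nd))) / E0
  }, numeric(1))
  list(per_node = v, max = max(v), which = nodes[which.max(v)])
}

#' Fragmentation under targeted betweenness removal
#'
#' Consecutively removes the node with the highest betweenness centrality
#' (recomputed after every removal; ties broken by higher degree, then
#' lexicographic id) and records the fragmentation index
#' \deqn{F = 1 - \frac{\sum_k s_k (s_k - 1)}{N_r (N_r - 1)}}
#' over the component sizes s_k of the N_r remaining nodes -- the
#' probability that two surviving nodes are disconnected. The
#' largest-component share is recorded alongside.
#'
#' @param network An [igraph::igraph].
#' @param n_steps Number of removals (< number of nodes).
#' @param adaptive Recompute betweenness after every removal (default);
#'   `FALSE` uses the initial ranking.
#' @return Data frame: `step` (0 = intact network), `removed` (node id,
#'   `NA` at step 0), `fragmentation`, `lcc_fraction`.
#' @export
fragmentation_series <- function(network, n_steps = 10, adaptive = TRUE) {
  n <- igraph::vcount(network)
  if (n_steps >= n) stopf("n_steps must be smaller than the node count")
  frag <- function(g) {
    nr <- igraph::vcount(g)
    if (nr < 2) return(c(1, ifelse(nr == 1, 1, 0)))
    cs <- igraph::components(g)$csize
    c(1 - sum(cs * (cs - 1)) / (nr * (nr - 1)), max(cs) / nr)
  }
  pick <- function(g, btw) {
    deg <- igraph::degree(g)
    ord <- order(-btw, -deg, igraph::V(g)$name)
    igraph::V(g)$name[ord[1]]
  }
  g <- network
  f0 <- frag(g)
  out <- data.frame(step = 0L, removed = NA_character_,
                    fragmentation = f0[1], lcc_fraction = f0[2],
                    stringsAsFactors = FALSE)
  static_rank <- if (!adaptive) {
    b <- igraph::betweenness(g, directed = FALSE, weights = NA)
    d <- igraph::degree(g)
    igraph::V(g)$name[order(-b, -d, igraph::V(g)$name)]
  } else NULL
  for (s in seq_len(n_steps)) {
    if (igraph::vcount(g) < 2) {
      warnf("network exhausted after %d removals; series truncated", s - 1)
      break
    }
    target <- if (adaptive) {
      pick(g, igraph::betweenness(g, directed = FALSE, weights = NA))
    } else {
      static_rank[s]
    }
    g <- igraph::delete_vertices(g, target)
    fs <- frag(g)
    out <- rbind(out, data.frame(step = s, removed = target,
                                 fragmentation = fs[1], lcc_fraction = fs[2],
                                 stringsAsFactors = FALSE))
  }
  out
}
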