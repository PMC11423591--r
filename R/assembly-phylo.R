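# Cophenetic (tip-to-tip patristic) distances aligned to the table's
# feature order.
pn_cophenetic <- function(tree, features) {
  missing <- setdiff(features, tree$tip.label)
  if (length(missing) > 0) {
    stopf("tree is missing tips for features: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  if (length(setdiff(tree$tip.label, features)) > 0) {
    tree <- ape::keep.tip(tree, features)
  }
  D <- ape::cophenetic.phylo(tree)
  D[features, features]
}

# Present-taxon index (0-based, for the C++ engines) and weight lists.
# Weighted variants use within-sample relative abundances restricted to the
# present taxa; unweighted uses 1/S.
pn_comm_lists <- function(table, weighted) {
  idx <- vector("list", nrow(table))
  w <- vector("list", nrow(table))
  for (s in seq_len(nrow(table))) {
    pres <- which(table[s, ] > 0)
    idx[[s]] <- as.integer(pres - 1L)
    w[[s]] <- if (weighted) {
      as.numeric(table[s, pres] / sum(table[s, pres]))
    } else {
      rep(1 / length(pres), length(pres))
    }
  }
  list(idx = idx, w = w)
}

# Identity permutation in row 1 followed by n_null random tip-label
# permutations (each applied to the whole matrix, hence to every sample /
# pair of a replicate at once -- the "taxa.labels" null convention).
pn_null_perms <- function(K, n_null, seed = NULL) {
  with_seed(seed, {
    perms <- matrix(0L, n_null + 1L, K)
    perms[1, ] <- 0:(K - 1L)
    for (r in seq_len(n_null)) perms[r + 1L, ] <- sample.int(K) - 1L
    perms
  })
}

#' Standardised effect size of mean nearest-taxon distance (SES MNTD)
#'
#' MNTD is the mean, over taxa present in a sample, of the cophenetic
#' distance to the nearest co-occurring taxon (optionally abundance
#' weighted). The null shuffles taxon labels on the distance matrix; SES =
#' (observed - null mean) / null sd. Negative SES indicates phylogenetic
#' clustering towards the tips.
#'
#' @param table Samples x features count matrix.
#' @param tree Rooted [ape::phylo] covering the features.
#' @param n_null Number of label-shuffle null replicates.
#' @param weighted Abundance-weight the per-taxon contributions.
#' @param seed Random seed for the shuffles.
#' @return Data frame: `sample_id`, `ntaxa`, `mntd_obs`, `null_mean`,
#'   `null_sd`, `ses`. `ses` is `NA` (flagged degenerate) when the null sd
#'   collapses, e.g. when a sample contains every tip. Samples with < 2 taxa
#'   yield `NA` with a warning.
#' @export
ses_mntd <- function(table, tree, n_null = 999, weighted = FALSE,
                     seed = NULL) {
  assert_count_matrix(table)
  D <- pn_cophenetic(tree, colnames(table))
  cl <- pn_comm_lists(table, weighted)
  few <- vapply(cl$idx, length, integer(1)) < 2
  if (any(few)) {
    warnf("%d sample(s) with < 2 taxa: SES MNTD undefined", sum(few))
  }
  perms <- pn_null_perms(ncol(table), n_null, seed)
  vals <- mntd_perm_engine(D, cl$idx, cl$w, perms)
  obs <- vals[, 1]
  null_mean <- rowMeans(vals[, -1, drop = FALSE])
  null_sd <- apply(vals[, -1, drop = FALSE], 1, stats::sd)
  ses <- ifelse(null_sd > 1e-12, (obs - null_mean) / null_sd, NA_real_)
  if (any(null_sd <= 1e-12, na.rm = TRUE)) {
    pn_log("%d sample(s) with degenerate null (sd ~ 0); SES flagged NA",
           sum(null_sd <= 1e-12, na.rm = TRUE))
  }
  data.frame(sample_id = rownames(table),
             ntaxa = vapply(cl$idx, length, integer(1)),
             mntd_obs = obs, null_mean = null_mean, null_sd = null_sd,
             ses = ses, row.names = NULL, stringsAsFactors = FALSE)
}

#' Between-community mean nearest-taxon distance (beta-MNTD)
#'
#' Pairwise phylogenetic turnover: for samples k and l,
#' \deqn{\beta MNTD(k,l) = \tfrac12\Big[\sum_{i\in k} w_{ik}\min_{j\in l} d_{ij}
#'   + \sum_{j\in l} w_{jl}\min_{i\in k} d_{ij}\Big]}
#' with w the within-sample relative abundances (weighted) or 1/S
#' (unweighted). Shared taxa contribute zero distance.
#'
#' @inheritParams ses_mntd
#' @param weighted Abundance-weight the contributions (default TRUE, the
#'   convention under which the +/-2 beta-NTI thresholds were calibrated).
#' @return A [stats::dist] over samples.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  assert_count_matrix(table)
  if (nrow(table) < 2) stopf("need >= 2 samples")
  if (any(rowSums(table) == 0)) stopf("empty sample(s)")
  D <- pn_cophenetic(tree, colnames(table))
  cl <- pn_comm_lists(table, weighted)
  pairs <- t(utils::combn(nrow(table), 2))
  ident <- matrix(0:(ncol(table) - 1L), nrow = 1)
  vals <- bmntd_perm_engine(D, cl$idx, cl$w, pairs - 1L, ident)[, 1]
  m <- matrix(0, nrow(table), nrow(table),
              dimnames = list(rownames(table), rownames(table)))
  m[pairs] <- vals
  m[pairs[, 2:1, drop = FALSE]] <- vals
  stats::as.dist(m)
}

#' Beta nearest-taxon index (beta-NTI)
#'
#' Standardised effect size of [beta_mntd()] against a tip-label-shuffle
#' null: for each pair, beta-NTI = (observed - null mean) / null sd. Each
#' null replicate applies one permutation to the whole cophenetic matrix and
#' re-evaluates every pair, so the replicates are shared across pairs.
#' |beta-NTI| above 2 flags deterministic assembly (below -2 homogeneous
#' selection, above +2 variable selection).
#'
#' @inheritParams beta_mntd
#' @param n_null Number of null replicates (>= 99).
#' @param seed Random seed.
#' @param pairs Optional integer matrix (n x 2) of sample-index pairs to
#'   restrict the computation; default all pairs.
#' @return Object of class `beta_nti`: list with symmetric matrices `bnti`,
#'   `bmntd`, `null_mean`, `null_sd` (NA diagonal and NA for uncomputed
#'   pairs), plus `n_null`, `weighted`, `seed`, `n_degenerate`.
#' @export
beta_nti <- function(table, tree, n_null = 999, weighted = TRUE,
                     seed = NULL, pairs = NULL) {
  assert_count_matrix(table)
  if (n_null < 99) stopf("n_null must be >= 99")
  n <- nrow(table)
  if (n < 2) stopf("need >= 2 samples")
  D <- pn_cophenetic(tree, colnames(table))
  cl <- pn_comm_lists(table, weighted)
  if (is.null(pairs)) pairs <- t(utils::combn(n, 2))
  storage.mode(pairs) <- "integer"
  perms <- pn_null_perms(ncol(table), n_null, seed)
  vals <- bmntd_perm_engine(D, cl$idx, cl$w, pairs - 1L, perms)
  obs <- vals[, 1]
  null_mean <- rowMeans(vals[, -1, drop = FALSE])
  null_sd <- apply(vals[, -1, drop = FALSE], 1, stats::sd)
  bnti_vals <- ifelse(null_sd > 1e-12, (obs - null_mean) / null_sd, NA_real_)
  n_degen <- sum(null_sd <= 1e-12)
  if (n_degen > 0) {
    pn_log("%d pair(s) with degenerate null (sd ~ 0); beta-NTI flagged NA",
           n_degen)
  }
  empty <- matrix(NA_real_, n, n,
                  dimnames = list(rownames(table), rownames(table)))
  fill <- function(v) {
    m <- empty
    m[pairs] <- v
    m[pairs[, 2:1, drop = FALSE]] <- v
    m
  }
  structure(list(bnti = fill(bnti_vals), bmntd = fill(obs),
                 null_mean = fill(null_mean), null_sd = fill(null_sd),
                 n_null = n_null, weighted = weighted, seed = seed,
                 n_degenerate = n_degen),
            class = "beta_nti")
}
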