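#' Raup-Crick dissimilarity on Bray-Curtis
#'
#' For each sample pair, compares the observed Bray-Curtis dissimilarity
#' with a null distribution in which both communities are reassembled at
#' fixed richness and fixed total abundance: taxa colonise with probability
#' proportional to their occupancy across the whole table (one individual
#' each), and the remaining individuals are filled in proportionally to the
#' pool relative abundances of the colonisers. The score
#' \deqn{RC = 2\,\frac{\#\{BC_{null} < BC_{obs}\} + \tfrac12\#\{BC_{null} =
#'   BC_{obs}\}}{n_{null}} - 1}
#' lies in \[-1, 1\]; RC > 0.95 indicates more turnover than expected
#' (dispersal limitation), RC < -0.95 less (homogenising dispersal).
#'
#' @param table Samples x features count matrix.
#' @param n_null Null replicates per pair (>= 99).
#' @param seed Random seed.
#' @param pairs Optional integer matrix (n x 2) of sample-index pairs;
#'   default all pairs.
#' @param occupancy,pool_abundance Optional per-feature occupancy counts
#'   and pool abundances defining the regional pool of the null model;
#'   by default both are estimated from `table` itself. Supplying them is
#'   useful when the regional pool is known (or fixed by a simulation).
#' @return Symmetric matrix of RC values with `NA` diagonal (and `NA` for
#'   pairs not requested).
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = NULL, pairs = NULL,
                            occupancy = NULL, pool_abundance = NULL) {
  assert_count_matrix(table)
  if (n_null < 99) stopf("n_null must be >= 99")
  n <- nrow(table); K <- ncol(table)
  if (n < 2) stopf("need >= 2 samples")
  occ <- occupancy %||% colSums(table > 0)
  pool_ab <- pool_abundance %||% colSums(table)
  if (length(occ) != K || length(pool_ab) != K) {
    stopf("occupancy / pool_abundance must have one entry per feature")
  }
  n_occ <- sum(occ > 0)
  if (n_occ < 2) stopf("degenerate pool: fewer than 2 taxa ever observed")
  if (is.null(pairs)) pairs <- t(utils::combn(n, 2))
  storage.mode(pairs) <- "integer"

  richness <- rowSums(table > 0)
  totals <- rowSums(table)
  if (any(richness[unique(as.vector(pairs))] > n_occ)) {
    stopf("sample richness exceeds the number of taxa in the pool")
  }
  bray <- function(x, y) sum(abs(x - y)) / sum(x + y)
  draw_null <- function(S, Ntot) rc_null_community(occ, pool_ab, S, Ntot)

  rc_vals <- with_seed(seed, {
    apply(pairs, 1, function(pr) {
      i <- pr[1]; j <- pr[2]
      obs <- bray(table[i, ], table[j, ])
      null_bc <- vapply(seq_len(n_null), function(r) {
        bray(draw_null(richness[i], totals[i]),
             draw_null(richness[j], totals[j]))
      }, numeric(1))
      frac <- (sum(null_bc < obs) + 0.5 * sum(null_bc == obs)) / n_null
      2 * frac - 1
    })
  })

  m <- matrix(NA_real_, n, n, dimnames = list(rownames(table),
                                              rownames(table)))
  m[pairs] <- rc_vals
  m[pairs[, 2:1, drop = FALSE]] <- rc_vals
  m
}

# One null community at fixed richness S and total abundance Ntot: taxa
# colonise with probability proportional to occupancy (weighted sampling
# without replacement via exponential keys), one individual each, and the
# remaining Ntot - S individuals are multinomial on the colonisers' pool
# abundances. Also the data generator for the self-calibration tests.
rc_null_community <- function(occ, pool_ab, S, Ntot) {
  K <- length(occ)
  keys <- stats::rexp(K) / occ
  chosen <- order(keys)[seq_len(S)]
  cnt <- numeric(K)
  cnt[chosen] <- 1
  if (Ntot > S) {
    cnt[chosen] <- cnt[chosen] +
      stats::rmultinom(1, Ntot - S, prob = pool_ab[chosen])[, 1]
  }
  cnt
}

#' Classify pairwise assembly processes from beta-NTI and Raup-Crick
#'
#' Applies the standard two-stage decision: beta-NTI < -2 homogeneous
#' selection; beta-NTI > 2 variable selection; otherwise (|beta-NTI| <= 2,
#' stochastic) RC > 0.95 dispersal limitation, RC < -0.95 homogenising
#' dispersal, |RC| <= 0.95 undominated drift. Pairs with degenerate
#' (`NA`) beta-NTI are excluded from the fractions with a logged count.
#'
#' @param bnti A `beta_nti` object or symmetric matrix of beta-NTI values.
#' @param rc Symmetric matrix from [raup_crick_bray()]; may be omitted only
#'   if every pair is deterministic.
#' @param bnti_threshold Threshold on |beta-NTI| (default 2).
#' @param rc_threshold Threshold on |RC| (default 0.95).
#' @return Object of class `assembly_result`: list with `pairs` (data.frame
#'   `sample_1`, `sample_2`, `bnti`, `rc`, `process`) and `fractions`
#'   (named proportions over the five processes, summing to 1).
#' @export
classify_assembly <- function(bnti, rc = NULL, bnti_threshold = 2,
                              rc_threshold = 0.95) {
  if (inherits(bnti, "beta_nti")) bnti <- bnti$bnti
  bnti <- as.matrix(bnti)
  n <- nrow(bnti)
  idx <- which(upper.tri(bnti) & !is.na(bnti), arr.ind = TRUE)
  n_degen <- sum(upper.tri(bnti)) - nrow(idx)
  if (n_degen > 0) {
    pn_log("excluding %d pair(s) with undefined beta-NTI from process fractions",
           n_degen)
  }
  if (nrow(idx) == 0) stopf("no classifiable pairs")
  b <- bnti[idx]
  r <- if (is.null(rc)) rep(NA_real_, length(b)) else as.matrix(rc)[idx]
  stochastic <- abs(b) <= bnti_threshold
  if (any(stochastic & is.na(r))) {
    stopf("Raup-Crick values required for the %d pair(s) with |beta-NTI| <= %g",
          sum(stochastic & is.na(r)), bnti_threshold)
  }
  levels <- c("homogeneous selection", "variable selection",
              "dispersal limitation", "homogenizing dispersal", "drift")
  process <- ifelse(b < -bnti_threshold, levels[1],
             ifelse(b > bnti_threshold, levels[2],
             ifelse(r > rc_threshold, levels[3],
             ifelse(r < -rc_threshold, levels[4], levels[5]))))
  process <- factor(process, levels = levels)
  fractions <- as.numeric(table(process)) / length(process)
  names(fractions) <- levels
  ids <- rownames(bnti) %||% as.character(seq_len(n))
  structure(list(
    pairs = data.frame(sample_1 = ids[idx[, 1]], sample_2 = ids[idx[, 2]],
                       bnti = b, rc = r, process = process,
                       stringsAsFactors = FALSE),
    fractions = fractions,
    n_excluded = n_degen,
    thresholds = c(bnti = bnti_threshold, rc = rc_threshold)
  ), class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("Assembly process fractions over", nrow(x$pairs), "pairs\n")
  for (nm in names(x$fractions)) {
    cat(sprintf("  %-24s %.3f\n", nm, x$fractions[[nm]]))
  }
  if (x$n_excluded > 0) cat("  (", x$n_excluded, "degenerate pairs excluded )\n")
  invisible(x)
}
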