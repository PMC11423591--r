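#' Remove sparse, low-count features
#'
#' Retains features that occur in at least `min_samples` samples and have a
#' summed count of at least `min_total`; everything else is treated as
#' unqualified (likely sequencing noise) and dropped. The sample set is
#' unchanged.
#'
#' @param table Samples x features count matrix.
#' @param min_samples Minimum number of samples a feature must occur in.
#' @param min_total Minimum total count across samples.
#' @return The filtered count matrix.
#' @export
filter_features <- function(table, min_samples = 2, min_total = 5) {
  assert_count_matrix(table)
  occ <- colSums(table > 0)
  tot <- colSums(table)
  keep <- occ >= min_samples & tot >= min_total
  if (!any(keep)) stopf("all %d features removed by the filter", ncol(table))
  pn_log("feature filter removed %d of %d features", sum(!keep), ncol(table))
  table[, keep, drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample to exactly `depth` reads without replacement
#' (via [vegan::rrarefy]). Samples with fewer than `depth` reads are dropped
#' with a warning.
#'
#' @param table Samples x features count matrix.
#' @param depth Target reads per sample (>= 1).
#' @param seed Random seed; fixed seed gives an identical rarefied table.
#' @return Rarefied count matrix; every row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  assert_count_matrix(table)
  if (depth < 1) stopf("rarefaction depth must be >= 1")
  totals <- rowSums(table)
  low <- totals < depth
  if (all(low)) stopf("all samples have fewer than %d reads", depth)
  if (any(low)) {
    warnf("dropping %d sample(s) below rarefaction depth %d: %s",
          sum(low), depth, paste(rownames(table)[low], collapse = ", "))
    table <- table[!low, , drop = FALSE]
  }
  out <- with_seed(seed, vegan::rrarefy(table, sample = depth))
  storage.mode(out) <- "double"
  out
}

#' Per-sample relative abundances
#'
#' @param table Samples x features count matrix with positive row sums.
#' @return Matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  assert_count_matrix(table)
  totals <- rowSums(table)
  if (any(totals <= 0)) {
    stopf("zero-sum sample(s): %s",
          paste(rownames(table)[totals <= 0], collapse = ", "))
  }
  sweep(table, 1, totals, "/")
}

#' Partition features into abundant, rare and moderate classes
#'
#' A feature is *abundant* when its per-sample relative abundance exceeds
#' `abundant_relab` in at least `abundant_occupancy` of the samples, or when
#' its summed relative abundance exceeds `abundant_sum`; it is *rare* when
#' its summed relative abundance is below `rare_sum`; every remaining
#' feature is *moderate*. "Summed relative abundance" is, under the default
#' `"total"` convention, the literal sum across samples of the per-sample
#' proportions (so the thresholds are on the 0--n_samples scale, quoted as
#' percentages); the `"mean"` convention divides that sum by the number of
#' samples. Under `"total"` with at least 5 samples the abundant and rare
#' rules are provably disjoint; a feature matching both raises an error.
#'
#' @param table Samples x features count matrix.
#' @param abundant_relab Per-sample proportion cutoff (default 0.01 = 1%).
#' @param abundant_occupancy Fraction of samples required (default 0.10).
#' @param abundant_sum Summed-abundance cutoff for the second abundant route
#'   (default 0.20 = 20%).
#' @param rare_sum Summed-abundance cutoff below which a feature is rare
#'   (default 0.005 = 0.5%).
#' @param sum_convention `"total"` or `"mean"`; see Details.
#' @return A data.frame (`feature_id`, `class`, `mean_relabund`,
#'   `occupancy`) of class `abundance_classes`; `class` is a factor with
#'   levels abundant, moderate, rare.
#' @export
classify_abundance_groups <- function(table,
                                      abundant_relab = 0.01,
                                      abundant_occupancy = 0.10,
                                      abundant_sum = 0.20,
                                      rare_sum = 0.005,
                                      sum_convention = c("total", "mean")) {
  sum_convention <- match.arg(sum_convention)
  if (nrow(table) == 0 || ncol(table) == 0) stopf("empty abundance table")
  rel <- relative_abundance(table)
  occ_frac <- colMeans(rel > abundant_relab)
  summed <- colSums(rel)
  stat <- if (sum_convention == "total") summed else summed / nrow(rel)
  abundant <- occ_frac >= abundant_occupancy | stat > abundant_sum
  rare <- stat < rare_sum
  both <- abundant & rare
  if (any(both)) {
    stopf("feature(s) satisfy both the abundant and rare rule under the '%s' convention: %s",
          sum_convention, paste(colnames(table)[both], collapse = ", "))
  }
  cls <- rep("moderate", ncol(table))
  cls[abundant] <- "abundant"
  cls[rare] <- "rare"
  out <- data.frame(
    feature_id = colnames(table),
    class = factor(cls, levels = c("abundant", "moderate", "rare")),
    mean_relabund = colMeans(rel),
    occupancy = colMeans(table > 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("abundance_classes", "data.frame")
  out
}
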