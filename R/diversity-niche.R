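#' Per-sample alpha diversity
#'
#' Richness S, Shannon H (natural log), Pielou evenness J = H / ln S
#' (`NA` when S = 1, where evenness is undefined), and Faith's phylogenetic
#' diversity (total branch length of the subtree spanning the sample's taxa,
#' including the path to the root; via [picante::pd]).
#'
#' @param table Samples x features count matrix.
#' @param tree Optional rooted [ape::phylo] whose tips cover the features;
#'   PD is skipped when `NULL`.
#' @return Data frame with columns `sample_id`, `richness`, `shannon`,
#'   `pielou`, and `faith_pd` when a tree is supplied.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  assert_count_matrix(table)
  if (any(rowSums(table) == 0)) stopf("empty sample(s) in table")
  S <- rowSums(table > 0)
  H <- vegan::diversity(table, index = "shannon")
  J <- ifelse(S > 1, H / log(S), NA_real_)
  out <- data.frame(sample_id = rownames(table), richness = as.numeric(S),
                    shannon = as.numeric(H), pielou = as.numeric(J),
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    missing <- setdiff(colnames(table), tree$tip.label)
    if (length(missing) > 0) {
      stopf("tree is missing tips for features: %s",
            paste(utils::head(missing, 5), collapse = ", "))
    }
    pd <- picante::pd(table, tree, include.root = TRUE)
    out$faith_pd <- pd$PD
  }
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param table Samples x features count matrix.
#' @param proportions Compute on per-sample proportions instead of raw
#'   counts (identical for rarefied tables).
#' @return A [stats::dist] with values in \[0, 1\].
#' @export
bray_curtis_matrix <- function(table, proportions = FALSE) {
  assert_count_matrix(table)
  if (nrow(table) < 2) stopf("need >= 2 samples")
  if (any(rowSums(table) == 0)) stopf("zero-sum sample(s)")
  x <- if (proportions) relative_abundance(table) else table
  vegan::vegdist(x, method = "bray")
}

#' Pairwise geographic distances between samples
#'
#' @param metadata Data frame with `sample_id`, `latitude`, `longitude`.
#' @param method `"euclidean"` (degrees, default) or `"haversine"`
#'   (great-circle kilometres).
#' @return A [stats::dist] labelled by sample id.
#' @export
geographic_distance_matrix <- function(metadata,
                                       method = c("euclidean", "haversine")) {
  method <- match.arg(method)
  need <- c("latitude", "longitude")
  if (!all(need %in% names(metadata))) {
    stopf("metadata must contain columns: %s", paste(need, collapse = ", "))
  }
  if (anyNA(metadata$latitude) || anyNA(metadata$longitude)) {
    stopf("missing coordinates in metadata")
  }
  xy <- cbind(metadata$longitude, metadata$latitude)
  if (method == "euclidean") {
    d <- stats::dist(xy)
  } else {
    # haversine on a sphere of radius 6371 km
    rad <- pi / 180
    lat <- metadata$latitude * rad
    lon <- metadata$longitude * rad
    n <- nrow(xy)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      a <- sin((lat[j] - lat[i]) / 2)^2 +
        cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
      m[j, i] <- m[i, j] <- 2 * 6371 * asin(pmin(1, sqrt(a)))
    }
    d <- stats::as.dist(m)
  }
  attr(d, "Labels") <- as.character(metadata$sample_id)
  d
}

#' Mantel test between two distance matrices
#'
#' Correlates the lower triangles of two sample-by-sample distance matrices
#' and assesses significance by jointly permuting rows and columns of the
#' second matrix (via [vegan::mantel]):
#' p = (1 + #\{permuted r >= observed r\}) / (1 + n_perm).
#'
#' @param d1,d2 [stats::dist] objects (or symmetric matrices) over the same
#'   samples.
#' @param n_perm Number of permutations (>= 99).
#' @param method `"spearman"` (default, rank-robust) or `"pearson"`.
#' @param seed Random seed for the permutations.
#' @return List with `statistic` (Mantel r), `p_value`, `n_perm`, `method`,
#'   `seed`. A constant matrix yields `NA` statistics with a warning.
#' @export
mantel_test <- function(d1, d2, n_perm = 999,
                        method = c("spearman", "pearson"), seed = NULL) {
  method <- match.arg(method)
  if (n_perm < 99) stopf("n_perm must be >= 99")
  d1 <- stats::as.dist(d1)
  d2 <- stats::as.dist(d2)
  if (attr(d1, "Size") != attr(d2, "Size")) {
    stopf("distance matrices differ in size (%d vs %d)",
          attr(d1, "Size"), attr(d2, "Size"))
  }
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    stopf("distance matrices cover different samples")
  }
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0) {
    warnf("constant distance matrix: Mantel r undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, n_perm = n_perm,
                method = method, seed = seed))
  }
  fit <- with_seed(seed,
    vegan::mantel(d1, d2, method = method, permutations = n_perm))
  list(statistic = unname(fit$statistic), p_value = fit$signif,
       n_perm = n_perm, method = method, seed = seed)
}

#' Levins niche breadth per feature
#'
#' For feature j with across-sample usage proportions
#' P_ij = x_ij / sum_i x_ij, Levins breadth is B_j = 1 / sum_i P_ij^2
#' (inverse Simpson concentration of the feature's distribution over
#' samples). B ranges from 1 (found in one sample only; specialist) to the
#' number of samples (evenly spread; generalist).
#'
#' @param table Samples x features count matrix; every feature must occur in
#'   at least one sample.
#' @param labels Optional `abundance_classes` data.frame (or named character
#'   vector feature -> class) used to summarise B by class.
#' @return List with `B` (named numeric vector) and, when labels are given,
#'   `summary` (data.frame of class, n, mean_B, median_B).
#' @export
levins_niche_breadth <- function(table, labels = NULL) {
  assert_count_matrix(table)
  tot <- colSums(table)
  if (any(tot == 0)) {
    stopf("feature(s) with zero total count: %s",
          paste(utils::head(colnames(table)[tot == 0], 5), collapse = ", "))
  }
  P <- sweep(table, 2, tot, "/")
  B <- 1 / colSums(P^2)
  names(B) <- colnames(table)
  out <- list(B = B)
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      cls <- stats::setNames(as.character(labels$class), labels$feature_id)
    } else {
      cls <- labels
    }
    cls <- cls[names(B)]
    grp <- split(B, factor(cls, levels = unique(c("abundant", "moderate",
                                                  "rare", unique(cls)))))
    grp <- grp[lengths(grp) > 0]
    out$summary <- data.frame(
      class = names(grp),
      n = lengths(grp),
      mean_B = vapply(grp, mean, numeric(1)),
      median_B = vapply(grp, stats::median, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out
}
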