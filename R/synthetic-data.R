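#' Simulate a random rooted phylogeny
#'
#' Random binary topology (via [ape::rtree]) with independent exponential
#' branch lengths, tips labelled `ASV_1 ... ASV_n`. Deterministic given the
#' seed.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Random seed (`NULL` uses the ambient RNG stream).
#' @param rate Rate of the exponential branch-length law (mean branch
#'   length = 1/rate).
#' @param prefix Tip-label prefix.
#' @return A rooted [ape::phylo] with branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, rate = 1, prefix = "ASV_") {
  if (n_taxa < 2) stopf("n_taxa must be >= 2")
  with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = TRUE,
                     br = function(n) stats::rexp(n, rate = rate))
    tr$tip.label <- paste0(prefix, seq_len(n_taxa))
    tr
  })
}

# Log-series-like skewed source pool: normalised Gamma(shape) draws (a
# symmetric Dirichlet). Small shape gives the heavy dominance + long rare
# tail typical of amplicon surveys.
pn_source_pool <- function(n_taxa, shape = 0.1) {
  x <- stats::rgamma(n_taxa, shape = shape, rate = 1)
  x <- pmax(x, 1e-12)
  x / sum(x)
}

# Brownian motion of a trait along the tree: root value 0, each child node =
# parent + N(0, sigma^2 * branch length). Returns tip values, so close
# relatives get correlated trait values (phylogenetic signal).
pn_brownian_trait <- function(tree, sigma = 1) {
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  val <- numeric(max(tree$edge))
  steps <- stats::rnorm(nrow(tree$edge), 0,
                        sigma * sqrt(pmax(tree$edge.length, 0)))
  for (k in seq_len(nrow(tree$edge))) {
    val[tree$edge[k, 2]] <- val[tree$edge[k, 1]] + steps[k]
  }
  stats::setNames(val[seq_len(ntip)], tree$tip.label)
}

# Coastal-transect style metadata: a south-to-north latitude gradient with
# covarying temperature, salinity and nutrient fields plus sampling noise.
pn_make_metadata <- function(n_samples, seed = NULL) {
  with_seed(seed, {
    lat <- seq(32, 39.5, length.out = n_samples)
    lon <- seq(119.9, 124.57, length.out = n_samples) +
      stats::rnorm(n_samples, 0, 0.3)
    z <- as.numeric(scale(lat))
    noise <- function(s) stats::rnorm(n_samples, 0, s)
    data.frame(
      sample_id = sprintf("S%02d", seq_len(n_samples)),
      latitude = lat,
      longitude = lon,
      temperature = 27 - 2.2 * z + noise(0.6),
      salinity = 30.5 + 0.9 * z + noise(0.25),
      DO = 7.2 + 0.5 * z + noise(0.3),
      chl_a = exp(0.4 - 0.5 * z + noise(0.35)),
      total_N = exp(1.8 + 0.45 * z + noise(0.3)),
      inorganic_N = exp(1.2 + 0.5 * z + noise(0.3)),
      nitrite = exp(-1.2 + 0.3 * z + noise(0.3)),
      nitrate = exp(0.9 + 0.5 * z + noise(0.3)),
      ammonia = exp(-0.3 + 0.2 * z + noise(0.35)),
      DIP = exp(-1.0 + 0.4 * z + noise(0.3)),
      silicate = exp(1.5 + 0.55 * z + noise(0.3)),
      stringsAsFactors = FALSE
    )
  })
}

# Shared generator behind the neutral / selection / mixed modes. Per sample,
# a taxon's latent relative abundance is Beta(N*m*p, N*m*(1-p)) -- the Sloan
# local-community marginal around the source pool p -- optionally tilted by a
# Gaussian niche response on the environmental gradient; counts are one
# multinomial draw of size N. With selection_strength = 0 the code path is
# identical to the neutral mode, so the two agree bit-for-bit at equal seeds.
pn_simulate <- function(n_samples, n_taxa, N, m,
                        selection_strength = 0, niche_width_mean = 0.7,
                        mix_weights = 1, drift_noise = 0,
                        phylo_signal = TRUE, n_guilds = 0,
                        guild_noise = 0, seed = NULL,
                        pool = NULL, pool_shape = 0.1,
                        tree = NULL, metadata = NULL) {
  if (m <= 0 || m > 1) stopf("migration m must be in (0, 1]")
  if (N < 100) stopf("community size N must be >= 100")
  if (selection_strength < 0) stopf("selection_strength must be >= 0")
  mix_weights <- rep_len(mix_weights, n_samples)
  if (any(mix_weights < 0 | mix_weights > 1)) {
    stopf("mix_weights must lie in [0, 1]")
  }
  with_seed(seed, {
    if (is.null(tree)) tree <- simulate_tree(n_taxa, seed = NULL)
    if (length(tree$tip.label) != n_taxa) {
      stopf("tree has %d tips but n_taxa = %d", length(tree$tip.label), n_taxa)
    }
    if (is.null(pool)) pool <- pn_source_pool(n_taxa, shape = pool_shape)
    pool <- stats::setNames(pool, tree$tip.label)
    if (is.null(metadata)) metadata <- pn_make_metadata(n_samples, seed = NULL)

    grad <- as.numeric(scale(metadata$latitude))
    optima_raw <- pn_brownian_trait(tree)
    # rank-map the Brownian trait uniformly onto the realised gradient
    # range: clades keep similar ranks (phylogenetic signal) while the
    # niche landscape always covers the whole gradient
    rk <- rank(optima_raw, ties.method = "first")
    optima <- min(grad) + (rk - 0.5) / n_taxa * diff(range(grad))
    if (n_guilds > 0) {
      # discrete niche guilds: clades (via their Brownian ranks) snap to a
      # few shared optima along the gradient, the structure that yields
      # modular co-occurrence networks
      centres <- min(grad) +
        (seq_len(n_guilds) - 0.5) / n_guilds * diff(range(grad))
      optima <- centres[ceiling(rk / n_taxa * n_guilds)] +
        stats::rnorm(n_taxa, 0, 0.05)
    }
    names(optima) <- tree$tip.label
    guild <- if (n_guilds > 0) ceiling(rk / n_taxa * n_guilds) else
      rep(1L, n_taxa)
    if (!phylo_signal) {
      # same marginal law of optima (and guilds), but decoupled from the
      # tree: selection still structures co-occurrence yet leaves
      # phylogenetic turnover at its null expectation
      shuf <- sample(n_taxa)
      optima <- stats::setNames(optima[shuf], tree$tip.label)
      guild <- guild[shuf]
    }
    widths <- exp(stats::rnorm(n_taxa, log(niche_width_mean), 0.4))

    counts <- matrix(0L, n_samples, n_taxa,
                     dimnames = list(metadata$sample_id, tree$tip.label))
    a1 <- N * m * pool
    a2 <- N * m * (1 - pool)
    for (s in seq_len(n_samples)) {
      lambda <- stats::rbeta(n_taxa, a1, a2)
      lambda[!is.finite(lambda)] <- 0
      w <- selection_strength * mix_weights[s]
      if (w > 0) {
        lambda <- lambda * exp(-w * (grad[s] - optima)^2 / (2 * widths^2))
      }
      if (guild_noise > 0 && n_guilds > 0) {
        # synchronous within-guild fluctuations (e.g. blooms): positive
        # co-occurrence inside guilds, hence modular networks
        gshift <- stats::rnorm(n_guilds, 0, guild_noise)
        lambda <- lambda * exp(gshift[guild])
      }
      if (drift_noise > 0) {
        lambda <- lambda * exp(stats::rnorm(n_taxa, 0, drift_noise))
      }
      if (sum(lambda) <= 0) lambda <- pool
      counts[s, ] <- stats::rmultinom(1, size = N, prob = lambda)
    }
    mode <- if (selection_strength == 0) "neutral"
            else if (all(mix_weights == 1)) "selection" else "mixed"
    structure(list(
      table = counts, tree = tree, metadata = metadata,
      truth = list(assembly_mode = mode, m = m, N = N, pool = pool,
                   selection_strength = selection_strength,
                   optima = optima, niche_widths = widths,
                   gradient = grad, mix_weights = mix_weights,
                   drift_noise = drift_noise, phylo_signal = phylo_signal,
                   n_guilds = n_guilds, guild = guild,
                   guild_noise = guild_noise, seed = seed)
    ), class = "plankton_sim")
  })
}

#' Simulate a community assembled by the Sloan neutral process
#'
#' Each sample's composition is a Beta/multinomial draw around a shared
#' skewed source pool, with immigration parameter `m`: the per-taxon latent
#' relative abundance is Beta(N m p, N m (1 - p)). Sampling-based, hence an
#' independent cross-check for the CDF-based fitter [fit_ncm()].
#'
#' @param n_samples Number of samples.
#' @param n_taxa Source-pool richness.
#' @param N Individuals (reads) per sample; every row sums to `N`.
#' @param m Migration probability in (0, 1]; `m = 1` reproduces the pool in
#'   expectation.
#' @param seed Random seed.
#' @param pool Optional source-pool proportions (drawn from a skewed
#'   Gamma/Dirichlet law when `NULL`).
#' @param pool_shape Shape of the pool law; smaller = more skewed.
#' @param tree Optional [ape::phylo]; simulated when `NULL`.
#' @param metadata Optional metadata data.frame; simulated when `NULL`.
#' @return A `plankton_sim` list: `table`, `tree`, `metadata`, `truth`.
#' @export
simulate_neutral_dataset <- function(n_samples, n_taxa, N = 1000, m = 0.1,
                                     seed = NULL, pool = NULL,
                                     pool_shape = 0.1, tree = NULL,
                                     metadata = NULL) {
  pn_simulate(n_samples, n_taxa, N, m, selection_strength = 0,
              seed = seed, pool = pool, pool_shape = pool_shape,
              tree = tree, metadata = metadata)
}

#' Simulate a community assembled under environmental selection
#'
#' Adds to the neutral generator a Gaussian niche response per taxon along a
#' standardised latitude gradient. Niche optima evolve by Brownian motion on
#' the tree, so clades share optima and phylogenetic turnover tracks the
#' gradient -- the condition under which beta-NTI detects selection.
#' `selection_strength = 0` degenerates exactly (bit-for-bit at equal seed)
#' to [simulate_neutral_dataset()].
#'
#' @inheritParams simulate_neutral_dataset
#' @param selection_strength Non-negative tilt strength; 0 = neutral.
#' @param niche_width_mean Mean Gaussian niche width in gradient SD units.
#' @param mix_weights Per-sample weight in \[0, 1\] scaling the selection
#'   tilt; values strictly between 0 and 1 give the "mixed" mode.
#' @param drift_noise SD of multiplicative lognormal noise on the latent
#'   abundances (taxon-by-sample ecological drift / unmeasured
#'   micro-environment); 0 disables it.
#' @param phylo_signal If `TRUE` (default) niche optima follow a Brownian
#'   trait on the tree (clades share optima); `FALSE` shuffles the optima
#'   across taxa, preserving their marginal law but removing the
#'   phylogenetic signal that beta-NTI requires.
#' @param n_guilds Number of discrete niche guilds the optima snap to
#'   (0 = continuous optima).
#' @param guild_noise SD of synchronous lognormal fluctuations shared by
#'   all taxa of a guild (bloom dynamics; the source of modular
#'   co-occurrence structure).
#' @return A `plankton_sim` list; `truth` records optima, widths and
#'   weights.
#' @export
simulate_selection_dataset <- function(n_samples, n_taxa, N = 1000,
                                       selection_strength = 5, m = 0.1,
                                       niche_width_mean = 0.7,
                                       mix_weights = 1, drift_noise = 0,
                                       phylo_signal = TRUE, n_guilds = 0,
                                       guild_noise = 0, seed = NULL,
                                       pool = NULL, pool_shape = 0.1,
                                       tree = NULL, metadata = NULL) {
  pn_simulate(n_samples, n_taxa, N, m,
              selection_strength = selection_strength,
              niche_width_mean = niche_width_mean,
              mix_weights = mix_weights, drift_noise = drift_noise,
              phylo_signal = phylo_signal, n_guilds = n_guilds,
              guild_noise = guild_noise, seed = seed, pool = pool,
              pool_shape = pool_shape, tree = tree, metadata = metadata)
}

#' Two-kingdom synthetic survey along a coastal gradient
#'
#' Emulates the scale of a 38-station cross-kingdom survey: two count tables
#' sharing one metadata table, one kingdom assembled mostly neutrally (the
#' eukaryote-like table) and one under stronger environmental selection (the
#' prokaryote-like table). Source pools are skewed enough that both abundant
#' (> 1% occurrence rule) and rare (summed < 0.5%) classes are populated,
#' with rare taxa in the majority. Taxa never observed across the survey are
#' dropped, leaving roughly 1,900-2,200 observed features per kingdom.
#'
#' @param seed Random seed.
#' @param n_samples Number of stations.
#' @param depth Reads per sample.
#' @param n_taxa Source-pool sizes of the two kingdoms; the defaults land
#'   near the study's retained feature counts after unseen taxa are
#'   dropped. Smaller values give fast smoke-scale fixtures.
#' @param selection_strength Selection tilt of the selection-mode kingdom.
#'
#' The eukaryote-like kingdom is assembled mostly neutrally: very weak
#' selection with phylogenetically random niche optima
#' (`phylo_signal = FALSE`), so phylogenetic turnover stays at its null
#' expectation. The prokaryote-like kingdom has stronger, phylogenetically
#' conserved selection, so gradient-extreme sample pairs show |beta-NTI|
#' well above 2. Both kingdoms carry synchronous within-guild population
#' fluctuations (blooms; `n_guilds`, `guild_noise`) -- the source of
#' modular co-occurrence structure -- plus per-taxon lognormal ecological
#' drift, which keeps the correlation networks sparse, as in real
#' surveys.
#' @return A list with elements `eukaryote` and `prokaryote` (each a
#'   `plankton_sim`) sharing one `metadata` table.
#' @export
simulate_cross_kingdom_fixture <- function(seed = 1, n_samples = 38,
                                           depth = 12000,
                                           selection_strength = 1.5,
                                           n_taxa = c(5200, 5000)) {
  metadata <- pn_make_metadata(n_samples, seed = derive_seed(seed, 99))
  euk <- pn_simulate(n_samples, n_taxa = n_taxa[1], N = depth, m = 0.1,
                     selection_strength = 0.3, phylo_signal = FALSE,
                     n_guilds = 14, guild_noise = 1.0, drift_noise = 0.8,
                     seed = derive_seed(seed, 1), metadata = metadata)
  prok <- pn_simulate(n_samples, n_taxa = n_taxa[2], N = depth, m = 0.1,
                      selection_strength = selection_strength,
                      phylo_signal = TRUE, n_guilds = 8, guild_noise = 1.4,
                      niche_width_mean = 0.6, drift_noise = 1.4,
                      seed = derive_seed(seed, 2), metadata = metadata)
  drop_unseen <- function(ds) {
    seen <- colSums(ds$table) > 0
    ds$table <- ds$table[, seen, drop = FALSE]
    ds$tree <- ape::keep.tip(ds$tree, colnames(ds$table))
    ds$truth$pool <- ds$truth$pool[seen]
    ds$truth$optima <- ds$truth$optima[seen]
    ds$truth$niche_widths <- ds$truth$niche_widths[seen]
    ds
  }
  list(eukaryote = drop_unseen(euk), prokaryote = drop_unseen(prok),
       metadata = metadata)
}
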