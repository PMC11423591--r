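#' Run the full analysis pipeline
#'
#' Orchestrates, for each kingdom and each sub-community class (all /
#' abundant / rare): feature filtering, optional rarefaction, abundance
#' classification, alpha diversity, Mantel tests of the Bray-Curtis matrix
#' against geographic and single-variable environmental distances, Levins
#' niche breadth, the neutral-model fit, null-model assembly inference
#' (beta-NTI + Raup-Crick + process fractions), network construction with
#' modules and node roles, and removal-based stability. Partial failures
#' (e.g. an empty abundance class or a hub-less network) degrade to logged
#' warnings, never silent omissions.
#'
#' @param config A named list, or path to a YAML/JSON file, with entries:
#'   * `simulate`: list passed to [simulate_cross_kingdom_fixture()]
#'     (`seed`, `n_samples`, `depth`), or
#'   * `input`: per-kingdom file paths (`table`, `tree`, `metadata`);
#'   * `out_dir`: optional directory for the artifact bundle;
#'   * `profile`: `"full"` (n_null 999, 100 removal reps) or `"ci"`
#'     (n_null 199, 30 reps);
#'   * `classes`: subset of `c("all", "abundant", "rare")`;
#'   * `stages`: subset of `c("diversity", "mantel", "niche", "ncm",
#'     "assembly", "network", "stability")`;
#'   * any [plankton_config()] field (e.g. `rarefaction_depth`, `r_min`,
#'     `seed`).
#' @return A nested list (the report bundle): one entry per kingdom with
#'   per-class results, plus `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stopf("config must be a list or a YAML/JSON path")

  profile <- config$profile %||% "full"
  if (!profile %in% c("full", "ci")) stopf("config$profile: unknown profile '%s'", profile)
  n_null <- config$n_null %||% if (profile == "ci") 199 else 999
  reps <- config$robustness_reps %||% if (profile == "ci") 30 else 100
  seed <- config$seed %||% 1L
  classes <- config$classes %||% c("all", "abundant", "rare")
  stages <- config$stages %||% c("diversity", "mantel", "niche", "ncm",
                                 "assembly", "network", "stability")
  cfg <- plankton_config(
    rarefaction_depth = config$rarefaction_depth,
    n_null = n_null, robustness_reps = reps, seed = seed,
    r_min = config$r_min %||% 0.6, q_max = config$q_max %||% 0.05,
    prevalence_min = config$prevalence_min %||% 0.5,
    remove_fraction = config$remove_fraction %||% 0.5)

  # --- assemble the per-kingdom datasets -------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    fx <- simulate_cross_kingdom_fixture(
      seed = sim$seed %||% seed,
      n_samples = sim$n_samples %||% 38,
      depth = sim$depth %||% 12000,
      selection_strength = sim$selection_strength %||% 5,
      n_taxa = sim$n_taxa %||% c(5200, 5000))
    datasets <- list(
      eukaryote = fx$eukaryote[c("table", "tree", "metadata")],
      prokaryote = fx$prokaryote[c("table", "tree", "metadata")])
  } else if (!is.null(config$input)) {
    inp <- config$input
    if (("assembly" %in% stages) &&
        any(!vapply(inp, function(k) !is.null(k$tree), logical(1)))) {
      bad <- names(inp)[vapply(inp, function(k) is.null(k$tree), logical(1))]
      stopf("config$input$%s$tree is required for the assembly stage", bad[1])
    }
    datasets <- lapply(inp, function(k) {
      load_dataset(k$table, k$tree, k$metadata %||% config$metadata,
                   samples_as_rows = k$samples_as_rows %||% TRUE)
    })
  } else {
    stopf("config must provide either 'simulate' or 'input'")
  }

  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit_json <- function(x, ...) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(x, file.path(out_dir, sprintf(...)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
    }
  }
  emit_tsv <- function(df, ...) {
    if (!is.null(out_dir)) {
      utils::write.table(df, file.path(out_dir, sprintf(...)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  bundle <- list()
  for (kingdom in names(datasets)) {
    ds <- datasets[[kingdom]]
    kres <- list()
    tab <- filter_features(ds$table)
    if (!is.null(cfg$rarefaction_depth)) {
      tab <- rarefy(tab, cfg$rarefaction_depth,
                    seed = derive_seed(seed, 11))
    }
    labels <- classify_abundance_groups(tab)
    kres$labels <- labels
    emit_tsv(labels, "%s_abundance_classes.tsv", kingdom)

    geo <- geographic_distance_matrix(ds$metadata)
    for (cls in classes) {
      feats <- if (cls == "all") labels$feature_id else
        labels$feature_id[labels$class == cls]
      if (length(feats) < 5) {
        warnf("%s/%s: only %d feature(s); class skipped", kingdom, cls,
              length(feats))
        next
      }
      sub <- tab[, feats, drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      cres <- list(n_features = length(feats), n_samples = nrow(sub))

      if ("diversity" %in% stages) {
        cres$diversity <- alpha_diversity(sub, ds$tree)
        emit_tsv(cres$diversity, "%s_%s_diversity.tsv", kingdom, cls)
      }
      if ("mantel" %in% stages) {
        bc <- bray_curtis_matrix(sub)
        keep_s <- rownames(sub)
        md <- ds$metadata[match(keep_s, ds$metadata$sample_id), ]
        geo_c <- stats::as.dist(as.matrix(geo)[keep_s, keep_s])
        env_vars <- setdiff(names(md)[vapply(md, is.numeric, logical(1))],
                            c("latitude", "longitude"))
        rows <- list(mantel_row("geographic_distance", bc, geo_c, cfg, seed))
        for (v in env_vars) {
          ok <- !is.na(md[[v]])
          if (sum(!ok) > 0) {
            pn_log("%s/%s: dropping %d sample(s) with missing %s", kingdom,
                   cls, sum(!ok), v)
          }
          dv <- stats::dist(scale(md[[v]][ok]))
          bcv <- stats::as.dist(as.matrix(bc)[ok, ok])
          rows <- c(rows, list(mantel_row(v, bcv, dv, cfg, seed)))
        }
        cres$mantel <- do.call(rbind, rows)
        emit_tsv(cres$mantel, "%s_%s_mantel.tsv", kingdom, cls)
      }
      if ("niche" %in% stages) {
        nb <- levins_niche_breadth(sub, labels[labels$feature_id %in%
                                                 colnames(sub), ])
        cres$niche <- nb$summary
        emit_tsv(nb$summary, "%s_%s_niche_breadth.tsv", kingdom, cls)
      }
      if ("ncm" %in% stages) {
        fit <- fit_ncm(sub)
        cres$ncm <- fit[c("m", "N", "Nm", "R2", "n_samples")]
        emit_json(cres$ncm, "%s_%s_ncm.json", kingdom, cls)
        emit_tsv(fit$freq, "%s_%s_ncm_freq.tsv", kingdom, cls)
      }
      if ("assembly" %in% stages) {
        bn <- beta_nti(sub, ds$tree, n_null = cfg$n_null,
                       seed = derive_seed(seed, 21))
        rc <- raup_crick_bray(sub, n_null = cfg$n_null,
                              seed = derive_seed(seed, 22))
        asm <- classify_assembly(bn, rc)
        cres$assembly <- asm
        emit_tsv(asm$pairs, "%s_%s_assembly_pairs.tsv", kingdom, cls)
        emit_json(as.list(asm$fractions), "%s_%s_assembly_fractions.json",
                  kingdom, cls)
      }
      kres[[cls]] <- cres
    }

    if ("network" %in% stages) {
      net <- tryCatch(
        build_network(tab, prevalence_min = cfg$prevalence_min,
                      method = cfg$cor_method, r_min = cfg$r_min,
                      q_max = cfg$q_max),
        error = function(e) {
          warnf("%s: network construction failed: %s", kingdom,
                conditionMessage(e))
          NULL
        })
      if (!is.null(net) && igraph::ecount(net) > 0) {
        mod <- detect_modules(net)
        metrics <- node_metrics(net, mod$membership)
        topo <- topology_summary(net, mod)
        kres$network <- list(graph = mod$network, metrics = metrics,
                             topology = topo)
        if (!is.null(out_dir)) {
          write_network(mod$network,
                        file.path(out_dir, paste0(kingdom, "_network.graphml")))
        }
        emit_tsv(metrics, "%s_node_metrics.tsv", kingdom)
        emit_json(unclass(topo), "%s_topology.json", kingdom)
        if ("stability" %in% stages) {
          rr <- robustness_random(mod$network, cfg$remove_fraction,
                                  reps = cfg$robustness_reps,
                                  seed = derive_seed(seed, 31))
          rt <- withCallingHandlers(
            robustness_targeted(mod$network, metrics,
                                reps = cfg$robustness_reps,
                                seed = derive_seed(seed, 32)),
            warning = function(w) {
              pn_log("%s: %s", kingdom, conditionMessage(w))
              invokeRestart("muffleWarning")
            })
          vul <- vulnerability(mod$network)
          nst <- min(10, igraph::vcount(mod$network) - 1)
          fr <- fragmentation_series(mod$network, n_steps = nst)
          kres$stability <- list(
            robustness_random = rr[c("mean", "sd", "n_removed")],
            robustness_targeted = rt[c("mean", "sd", "n_removed", "n_hubs")],
            vulnerability = vul$max,
            fragmentation = fr)
          emit_json(list(robustness_random = rr[c("mean", "sd")],
                         robustness_targeted = rt[c("mean", "sd", "n_hubs")],
                         vulnerability = vul$max, seed = seed),
                    "%s_stability.json", kingdom)
          emit_tsv(fr, "%s_fragmentation.tsv", kingdom)
        }
      }
    }
    bundle[[kingdom]] <- kres
  }

  bundle$provenance <- list(
    config = config[setdiff(names(config), "out_dir")],
    profile = profile, n_null = n_null, robustness_reps = reps,
    seed = seed,
    package_version = as.character(utils::packageVersion("planktonet")),
    timestamp = NULL)
  emit_json(bundle$provenance, "provenance.json")
  invisible(bundle)
}

mantel_row <- function(variable, d1, d2, cfg, seed) {
  mt <- mantel_test(d1, d2, n_perm = min(cfg$n_null, 999),
                    seed = derive_seed(seed, 41))
  data.frame(variable = variable, mantel_r = mt$statistic,
             p_value = mt$p_value, method = mt$method,
             stringsAsFactors = FALSE)
}
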