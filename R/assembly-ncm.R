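#' Fit the Sloan neutral community model
#'
#' The neutral model predicts that, in a metacommunity at stochastic balance
#' between immigration, birth, death and extinction, the relative abundance
#' of a taxon with metacommunity mean p follows
#' Beta(N m p, N m (1 - p)) in a local community of size N with migration
#' probability m. Its expected occurrence frequency across samples is the
#' probability of detecting it in N reads. Two detection treatments are
#' offered:
#' * `"binomial"` (default): exact finite-read detection,
#'   \deqn{\hat f(p) = 1 - B(a, b + N) / B(a, b)}
#'   with a = N m p, b = N m (1 - p) -- the beta-binomial probability of at
#'   least one read;
#' * `"threshold"`: the classic sharp detection limit d = 1/N,
#'   \deqn{\hat f(p) = 1 - I_d(a, b)}
#'   with I the regularised incomplete beta function.
#'
#' The single free parameter m is fitted to the observed occurrence
#' frequencies by bounded nonlinear least squares ([minpack.lm::nlsLM],
#' with an optimise fallback), and goodness of fit is
#' R\eqn{^2} = 1 - SSE/SST. 95% prediction bounds are Wilson binomial
#' intervals around the predicted frequencies.
#'
#' @param table Samples x features count matrix; a rarefied table (equal row
#'   sums) is preferred. At least 10 samples are recommended.
#' @param N Community size; defaults to the mean sample total.
#' @param detection `"binomial"` (exact read-sampling detection) or
#'   `"threshold"` (sharp limit at d = 1/N).
#' @return An object of class `ncm_fit`: list with `m`, `N`, `Nm`, `R2`,
#'   `detection_limit`, `n_samples`, `boundary` (TRUE when m hit a bound),
#'   and `freq` (per-taxon data.frame: `p`, `obs_freq`, `pred_freq`,
#'   `lower`, `upper`).
#' @export
fit_ncm <- function(table, N = NULL, detection = c("binomial", "threshold")) {
  detection <- match.arg(detection)
  assert_count_matrix(table)
  n_samples <- nrow(table)
  if (n_samples < 3) stopf("need >= 3 samples to fit the neutral model")
  if (is.null(N)) N <- mean(rowSums(table))
  d <- 1 / N
  rel <- relative_abundance(table)
  p <- colMeans(rel)
  f <- colMeans(table > 0)
  keep <- p > 0
  p <- p[keep]; f <- f[keep]

  pred_fun <- if (detection == "binomial") {
    function(m) {
      a <- N * m * p; b <- N * m * (1 - p)
      1 - exp(lbeta(a, b + N) - lbeta(a, b))
    }
  } else {
    function(m) {
      stats::pbeta(d, N * m * p, N * m * (1 - p), lower.tail = FALSE)
    }
  }
  sse <- function(m) sum((f - pred_fun(m))^2)

  m_hat <- NA_real_
  fit <- tryCatch(
    if (detection == "binomial") {
      minpack.lm::nlsLM(
        f ~ 1 - exp(lbeta(N * m * p, N * m * (1 - p) + N) -
                      lbeta(N * m * p, N * m * (1 - p))),
        start = list(m = 0.1), lower = 1e-6, upper = 1,
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(
        f ~ pbeta(d, N * m * p, N * m * (1 - p), lower.tail = FALSE),
        start = list(m = 0.1), lower = 1e-6, upper = 1,
        control = minpack.lm::nls.lm.control(maxiter = 500))
    },
    error = function(e) NULL)
  if (!is.null(fit)) m_hat <- unname(stats::coef(fit)[["m"]])
  if (!is.finite(m_hat)) {
    opt <- stats::optimize(sse, c(1e-6, 1))
    m_hat <- opt$minimum
  }
  boundary <- m_hat <= 1e-6 * 1.01 || m_hat >= 1 - 1e-9
  if (boundary) pn_log("neutral-model m estimate at parameter bound (m = %g)", m_hat)

  pred <- pred_fun(m_hat)
  sst <- sum((f - mean(f))^2)
  r2 <- 1 - sse(m_hat) / sst
  ci <- wilson_interval(pred, n_samples)

  structure(list(
    m = m_hat, N = N, Nm = N * m_hat, R2 = r2,
    detection = detection,
    detection_limit = d, n_samples = n_samples, boundary = boundary,
    freq = data.frame(feature_id = names(p), p = unname(p),
                      obs_freq = unname(f), pred_freq = unname(pred),
                      lower = ci$lower, upper = ci$upper,
                      stringsAsFactors = FALSE)
  ), class = "ncm_fit")
}

# Wilson score interval for a proportion estimated from n trials.
wilson_interval <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  samples: %d   taxa: %d   N: %.1f\n",
              x$n_samples, nrow(x$freq), x$N))
  cat(sprintf("  m = %.4g   Nm = %.1f   R2 = %.3f%s\n",
              x$m, x$Nm, x$R2,
              if (x$boundary) "   (m at bound)" else ""))
  invisible(x)
}
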