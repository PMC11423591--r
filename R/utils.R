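#' @keywords internal
"_PACKAGE"

#' @useDynLib planktonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Package-wide logger. Silenced with options(planktonet.quiet = TRUE);
# mirrored to a file when options(planktonet.logfile = <path>) is set.
pn_log <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  logfile <- getOption("planktonet.logfile")
  if (!is.null(logfile)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
        file = logfile, append = TRUE, sep = "")
  }
  if (!isTRUE(getOption("planktonet.quiet"))) {
    message("[planktonet] ", msg)
  }
  invisible(msg)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed, keeping within the 32-bit integer
# range so downstream set.seed() calls are portable.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count_matrix <- function(x, what = "abundance table") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("%s must be a numeric matrix (samples x features)", what)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("%s must carry sample (row) and feature (column) names", what)
  }
  if (anyDuplicated(rownames(x))) stopf("duplicate sample ids in %s", what)
  if (anyDuplicated(colnames(x))) stopf("duplicate feature ids in %s", what)
  if (any(x < 0)) stopf("%s contains negative counts", what)
  invisible(x)
}
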