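#' @useDynLib phenoconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Classed conditions so callers can distinguish failure modes programmatically.
pc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phenoconn_error")))
}
err_format     <- function(msg) pc_abort(msg, "phenoconn_format_error")
err_parse      <- function(msg) pc_abort(msg, "phenoconn_parse_error")
err_validation <- function(msg) pc_abort(msg, "phenoconn_validation_error")
err_capability <- function(msg) pc_abort(msg, "phenoconn_capability_error")

pc_log <- function(..., quiet = getOption("phenoconn.quiet", FALSE)) {
  if (!isTRUE(quiet)) message("[phenoconn] ", ...)
}

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage
#' (simulation, permutation test, extent calibration, ...) draws from its
#' own substream so that adding a stage never perturbs the others.  The
#' substream seed is a deterministic 31-bit hash of the master seed and the
#' stream name.
#'
#' @param seed master seed (single integer-valued number).
#' @param stream character stream name, e.g. `"permutation"`.
#' @return A single integer in `[0, 2^31)` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "permutation")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' Fisher z-transform of correlation coefficients
#'
#' `atanh(r)`, with correlations of exactly +/-1 clamped just inside the
#' open interval so the
#' transform stays finite (relevant for degenerate, noise-free series).
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return `atanh` of the clamped values.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
}

# Two-sided p from a t statistic.
t_pvalue <- function(t, df) 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)

# One-sided (upper tail) p: evidence for effect > 0.
t_pvalue_upper <- function(t, df) stats::pt(t, df = df, lower.tail = FALSE)

# Evaluate an expression with a temporary RNG state; restores (or removes)
# .Random.seed afterwards so package internals never disturb the caller's
# stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
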