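#' Entropy analysis parameters
#'
#' Bundle the parameters shared by the multiscale entropy (MSE) and
#' multiscale fuzzy entropy (MFE) calculations: the embedding dimension `m`,
#' the tolerance `r` expressed as a fraction of the signal's standard
#' deviation, the fuzzy membership exponent, and the scale range.
#'
#' The defaults (`m = 2`, `r = 0.15`, `fuzzy_power = 2`) are the standard
#' settings for skin blood-flux and oxygen-saturation complexity analysis.
#' `r_mode` controls whether the absolute tolerance `r * SD` is fixed from
#' the original (scale-1) series and reused at every scale — the classic MSE
#' convention, the default — or recomputed from each coarse-grained series.
#'
#' @param m embedding dimension (template length), a positive integer.
#' @param r tolerance as a fraction of the standard deviation; values outside
#'   `(0, 0.5]` trigger a warning but are accepted.
#' @param fuzzy_power exponent of the fuzzy membership function
#'   `exp(-(d/r)^fuzzy_power)`.
#' @param max_scale largest coarse-graining scale.
#' @param r_mode `"fixed_original_sd"` (default) or `"per_scale_sd"`.
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, r = 0.15, fuzzy_power = 2,
                           max_scale = 20L,
                           r_mode = c("fixed_original_sd", "per_scale_sd")) {
  r_mode <- match.arg(r_mode)
  m <- as.integer(m)
  max_scale <- as.integer(max_scale)
  stopifnot(is.finite(m), m >= 1L, is.finite(r), r > 0,
            is.finite(fuzzy_power), fuzzy_power > 0,
            is.finite(max_scale), max_scale >= 1L)
  if (r > 0.5)
    warning("tolerance r = ", r, " is outside the plausible range (0, 0.5]")
  structure(list(m = m, r = r, fuzzy_power = fuzzy_power,
                 max_scale = max_scale, r_mode = r_mode),
            class = "entropy_params")
}

#' Coarse-grain a time series
#'
#' Replace a series by the means of consecutive non-overlapping blocks of
#' length `tau` (the scale). The result has `floor(N / tau)` samples; any
#' leftover tail samples are discarded.
#'
#' @param x numeric vector.
#' @param tau block length (scale), a positive integer with `tau <= length(x)`.
#' @return Numeric vector of block means.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  n <- length(x)
  if (!is.finite(tau) || tau < 1L || tau > n)
    stop("`tau` must be an integer in [1, length(x)]")
  if (tau == 1L) return(as.numeric(x))
  k <- n %/% tau
  colMeans(matrix(x[seq_len(k * tau)], nrow = tau))
}

# Population SD (divisor N), fixed for determinism of the tolerance.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of length-`m` templates
#' whose Chebyshev distance is strictly below the absolute tolerance `r_abs`
#' and A counts the pairs still matching at length `m + 1`. Self-matches are
#' excluded; both counts run over the `N - m` templates whose extension to
#' length `m + 1` exists.
#'
#' When no pair matches at length `m + 1` (A = 0) the statistic is undefined
#' and `NA` is returned with a warning; when no pair matches even at length
#' `m` (B = 0) the tolerance is degenerate for this signal and an error is
#' thrown.
#'
#' @param x numeric vector of length at least `m + 2`.
#' @param m embedding dimension.
#' @param r_abs absolute tolerance (same units as `x`), positive.
#' @return A single number, or `NA` when the statistic is undefined.
#' @export
sample_entropy <- function(x, m = 2L, r_abs) {
  m <- as.integer(m)
  stopifnot(is.numeric(x), all(is.finite(x)),
            is.finite(r_abs), r_abs > 0, m >= 1L)
  if (length(x) < m + 2L)
    stop("series too short: need length >= m + 2 = ", m + 2L)
  ab <- sampen_counts(as.numeric(x), m, r_abs)
  if (ab[2L] == 0)
    stop("degenerate tolerance: no template pairs match at length m")
  if (ab[1L] == 0) {
    warning("sample entropy undefined (no matches at length m + 1); ",
            "returning NA")
    return(NA_real_)
  }
  -log(ab[1L] / ab[2L])
}

#' Fuzzy entropy
#'
#' A sample-entropy variant in which the hard tolerance threshold is replaced
#' by the smooth membership function `exp(-(d/r_abs)^n)` applied to templates
#' with their own mean removed. FuzzyEn = ln(phi_m) - ln(phi_{m+1}), where
#' phi is the mean similarity over ordered template pairs i != j.
#'
#' @inheritParams sample_entropy
#' @param n fuzzy power (membership exponent), positive.
#' @return A single non-negative number for non-degenerate input.
#' @export
fuzzy_entropy <- function(x, m = 2L, r_abs, n = 2) {
  m <- as.integer(m)
  stopifnot(is.numeric(x), all(is.finite(x)),
            is.finite(r_abs), r_abs > 0, is.finite(n), n > 0, m >= 1L)
  if (length(x) < m + 2L)
    stop("series too short: need length >= m + 2 = ", m + 2L)
  phi <- fuzzen_phi(as.numeric(x), m, r_abs, n)
  log(phi[1L]) - log(phi[2L])
}

#' Complexity area index
#'
#' The integral of an entropy-versus-scale curve over the scale axis
#' (unit spacing), evaluated with the composite trapezoid rule. Scales with
#' undefined entropy invalidate the index: `NA` anywhere yields `NA` rather
#' than an interpolated value, so a missing CAI is always visible downstream.
#'
#' @param values entropy value per scale (scales assumed consecutive,
#'   unit-spaced), length at least 2.
#' @return The trapezoidal integral, or `NA` if any value is missing.
#' @export
cai <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 scales to integrate")
  if (anyNA(values)) return(NA_real_)
  v <- as.numeric(values)
  n <- length(v)
  sum((v[-1L] + v[-n]) / 2)
}

entropy_curve <- function(x, params, kind) {
  stopifnot(inherits(params, "entropy_params"))
  x <- as.numeric(x)
  n <- length(x)
  m <- params$m
  if (n < m + 2L) stop("series too short for scale 1")
  max_scale <- params$max_scale
  if (n %/% max_scale < m + 2L) {
    max_scale <- max(1L, n %/% (m + 2L))
    warning("max_scale reduced to ", max_scale,
            " so that floor(N/tau) >= m + 2 at every scale")
  }
  sd0 <- pop_sd(x)
  if (sd0 == 0) stop("constant series: tolerance r * SD is zero")
  values <- vapply(seq_len(max_scale), function(tau) {
    y <- coarse_grain(x, tau)
    r_abs <- if (params$r_mode == "fixed_original_sd") params$r * sd0
             else params$r * pop_sd(y)
    if (r_abs == 0) return(NA_real_)
    tryCatch(
      if (kind == "MSE") sample_entropy(y, m, r_abs)
      else fuzzy_entropy(y, m, r_abs, params$fuzzy_power),
      error = function(e) NA_real_)
  }, numeric(1))
  structure(list(kind = kind,
                 scales = seq_len(max_scale),
                 values = values,
                 cai = if (max_scale >= 2L) cai(values) else NA_real_,
                 n_effective = n %/% seq_len(max_scale),
                 params = params),
            class = "entropy_curve")
}

#' Multiscale entropy and multiscale fuzzy entropy curves
#'
#' Compute sample entropy (`mse_curve`) or fuzzy entropy (`mfe_curve`) of
#' the coarse-grained series at every scale `1..max_scale`, together with
#' the complexity area index (CAI) summarising the curve. The absolute
#' tolerance is `r * SD` with the SD chosen per `params$r_mode`; the scale-1
#' value equals the plain entropy of the input. If any scale's entropy is
#' undefined the CAI is reported as `NA`.
#'
#' @param x numeric vector.
#' @param params an [entropy_params()] object.
#' @return An object of class `entropy_curve` with elements `kind`, `scales`,
#'   `values`, `cai` and `n_effective`.
#' @export
mse_curve <- function(x, params = entropy_params()) {
  entropy_curve(x, params, "MSE")
}

#' @rdname mse_curve
#' @export
mfe_curve <- function(x, params = entropy_params()) {
  entropy_curve(x, params, "MFE")
}

#' @export
print.entropy_curve <- function(x, ...) {
  cat(sprintf("%s curve over scales 1..%d  (m = %d, r = %g)\n",
              x$kind, max(x$scales), x$params$m, x$params$r))
  cat("  CAI:", if (is.na(x$cai)) "undefined" else format(x$cai), "\n")
  invisible(x)
}
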