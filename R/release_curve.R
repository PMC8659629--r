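#' Construct a cumulative release curve
#'
#' A `release_curve` holds one film's cumulative drug-release time series
#' together with the normalization metadata needed to express it as a release
#' fraction \eqn{M_t/M_\infty}. Values may be stored as released amounts
#' (mg/mL, normalized by `m_inf`) or directly as dimensionless fractions.
#'
#' @param times Sampling times in minutes; strictly increasing, all >= 0.
#' @param values Cumulative released amount (mg/mL) or release fraction,
#'   all >= 0. Fractions may exceed 1 by at most 0.05 (measurement noise).
#' @param sample_id Character label for the film.
#' @param value_kind `"amount"` (default) or `"fraction"`.
#' @param m_inf Asymptotic reference \eqn{M_\infty} (mg/mL) used to normalize
#'   amounts; required when `value_kind = "amount"`. Conventionally either the
#'   last observed cumulative value or the initially loaded drug mass.
#'
#' @return An object of class `release_curve`: a list with fields `sample_id`,
#'   `times`, `values`, `value_kind`, `m_inf`.
#' @seealso [release_fraction()], [fit_higuchi()], [fit_series()]
#' @export
#' @examples
#' rc <- release_curve(c(1, 5, 10), c(0.2, 0.5, 0.8),
#'                     sample_id = "F1", m_inf = 1)
#' release_fraction(rc)
release_curve <- function(times, values, sample_id = "sample",
                          value_kind = c("amount", "fraction"),
                          m_inf = NULL) {
  value_kind <- match.arg(value_kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop_invalid("times and values must have equal length")
  if (length(times) == 0L)
    stop_invalid("release curve must contain at least one observation")
  if (anyNA(times) || anyNA(values))
    stop_invalid("times and values must be finite, non-missing")
  if (any(times < 0))
    stop_invalid("times must all be >= 0")
  if (any(diff(times) <= 0))
    stop_invalid("times must be strictly increasing")
  if (any(values < 0))
    stop_invalid("released values must all be >= 0")
  if (value_kind == "fraction") {
    if (any(values > 1 + 0.05))
      stop_invalid("release fractions must not exceed 1 + 0.05 tolerance")
    if (!is.null(m_inf) && m_inf <= 0)
      stop_invalid("m_inf must be > 0")
  } else {
    if (is.null(m_inf))
      stop_invalid("m_inf is required when value_kind = \"amount\"")
    if (!is.finite(m_inf) || m_inf <= 0)
      stop_invalid("m_inf must be a positive finite number")
  }
  structure(
    list(sample_id = as.character(sample_id)[1L], times = times,
         values = values, value_kind = value_kind,
         m_inf = if (is.null(m_inf)) NA_real_ else as.numeric(m_inf)),
    class = "release_curve")
}

#' Release fraction of a curve
#'
#' Returns the dimensionless release fraction \eqn{f(t_i) = M_{t_i}/M_\infty}:
#' the stored values when `value_kind = "fraction"`, otherwise
#' `values / m_inf`.
#'
#' @param curve A [release_curve].
#' @return Numeric vector of fractions aligned with `curve$times`.
#' @export
release_fraction <- function(curve) {
  stopifnot(inherits(curve, "release_curve"))
  if (curve$value_kind == "fraction") curve$values else curve$values / curve$m_inf
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("Release curve '%s': %d observations, t in [%g, %g] min (%s",
              x$sample_id, length(x$times), min(x$times), max(x$times),
              x$value_kind))
  if (x$value_kind == "amount") cat(sprintf(", m_inf = %g mg/mL", x$m_inf))
  cat(")\n")
  invisible(x)
}

#' @export
as.data.frame.release_curve <- function(x, ...) {
  data.frame(time_min = x$times, released = x$values,
             fraction = release_fraction(x))
}
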