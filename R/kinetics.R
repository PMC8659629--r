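#' Film synthesis yield
#'
#' Gravimetric yield of a crosslinked film: the dry film weight as a
#' percentage of the total reactant weight in feed.
#'
#' @param dry_weight Dry film weight (g), >= 0.
#' @param total_reactant_weight Total reactant weight in feed (g), > 0.
#' @return Yield in percent.
#' @export
#' @examples
#' film_yield(0.861, 1.0)  # 86.1 %
film_yield <- function(dry_weight, total_reactant_weight) {
  if (any(total_reactant_weight <= 0))
    stop_invalid("total_reactant_weight must be > 0")
  if (any(dry_weight < 0))
    stop_invalid("dry_weight must be >= 0")
  100 * dry_weight / total_reactant_weight
}

#' Water swelling ratio
#'
#' Relative mass gain of a dry film after water uptake,
#' \eqn{Q(\%) = 100 (w_s - w_0)/w_0}. Negative values (deswelling) are
#' permitted.
#'
#' @param w_swollen Swollen weight (g).
#' @param w_dry Dry weight (g), > 0.
#' @return Swelling degree in percent.
#' @export
#' @examples
#' swelling_ratio(10.57, 1.0)  # 957 %
swelling_ratio <- function(w_swollen, w_dry) {
  if (any(w_dry <= 0)) stop_invalid("w_dry must be > 0")
  100 * (w_swollen - w_dry) / w_dry
}

#' Release (or loading) efficiency
#'
#' Percentage of the loaded drug that was released,
#' \eqn{100 \cdot released/loaded}.
#'
#' @param released Released amount (mg, or mg/mL when the source table mixes
#'   units), >= 0.
#' @param loaded Loaded amount (mg), > 0.
#' @return Efficiency in percent.
#' @export
release_efficiency <- function(released, loaded) {
  if (any(loaded <= 0)) stop_invalid("loaded must be > 0")
  if (any(released < 0)) stop_invalid("released must be >= 0")
  100 * released / loaded
}

#' Higuchi square-root release law
#'
#' Predicted release fraction under the Higuchi equation
#' \eqn{M_t/M_\infty = k_H \sqrt{t}}.
#'
#' @param t Time in minutes, >= 0 (vectorized).
#' @param k_h Higuchi constant in min^-1/2, >= 0.
#' @return Release fraction(s) `k_h * sqrt(t)`.
#' @export
#' @examples
#' higuchi_predict(100, 5e-3)  # 0.05
higuchi_predict <- function(t, k_h) {
  if (any(t < 0)) stop_invalid("t must be >= 0")
  if (any(k_h < 0)) stop_invalid("k_h must be >= 0")
  k_h * sqrt(t)
}

#' Truncated erfc-series solution for release from a slab
#'
#' Early/intermediate-time series solution of one-dimensional diffusion out of
#' a film of thickness \eqn{d} with diffusion coefficient \eqn{\sigma}:
#' \deqn{f(t) = 2\sqrt{\sigma t/d^2}\,\Big[\pi^{-1/2} +
#'   \sum_{n=1}^{N} (-1)^n\,\mathrm{erfc}\!\big(n d/(2\sqrt{\sigma t})\big)\Big]}
#' truncated at `truncation_n` terms. At `t = 0` the continuous limit
#' \eqn{f(0) = 0} is returned. With `truncation_n = 0` the expression reduces
#' to \eqn{(2/\sqrt{\pi})\sqrt{\sigma t/d^2}}, the square-root law with an
#' extra \eqn{\pi^{-1/2}} prefactor relative to the bare Higuchi form — the
#' two conventions coexist in the release literature and both are exposed
#' here as printed (see the methods vignette).
#'
#' @param t Time in minutes, >= 0 (vectorized).
#' @param sigma Diffusion coefficient in mm^2/min, > 0.
#' @param thickness_d Film thickness in mm, > 0.
#' @param truncation_n Number of erfc correction terms N >= 0 (default 2, the
#'   truncation at which long-time release curves are well described).
#' @return Release fraction(s) f(t).
#' @export
#' @examples
#' series_release(0.04, sigma = 1, thickness_d = 1, truncation_n = 2)
series_release <- function(t, sigma, thickness_d, truncation_n = 2L) {
  if (any(t < 0)) stop_invalid("t must be >= 0")
  if (sigma <= 0) stop_invalid("sigma must be > 0")
  if (thickness_d <= 0) stop_invalid("thickness_d must be > 0")
  truncation_n <- as.integer(truncation_n)
  if (truncation_n < 0L) stop_invalid("truncation_n must be >= 0")
  f <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    x <- sqrt(sigma * t[pos]) / thickness_d           # sqrt(sigma t)/d
    bracket <- rep(1 / sqrt(pi), sum(pos))
    if (truncation_n >= 1L) {
      for (n in seq_len(truncation_n)) {
        # erfc underflows to 0 for large arguments; no overflow possible
        bracket <- bracket + (-1)^n * erfc(n * thickness_d /
                                             (2 * sqrt(sigma * t[pos])))
      }
    }
    f[pos] <- 2 * x * bracket
  }
  f
}
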