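#' Diffusion coefficient from the Higuchi constant
#'
#' Converts a fitted Higuchi constant to a diffusion coefficient via the
#' film-thickness relation \eqn{k_H = 2\sqrt{\sigma}/d}, i.e.
#' \eqn{\sigma = (k_H d/2)^2} in mm^2/min, with the mm^2/s value obtained by
#' dividing by 60.
#'
#' @param k_h Higuchi constant in min^-1/2 (>= 0), or a [fit_higuchi] result.
#' @param thickness_d Film thickness d in mm, > 0.
#' @return An object of class `diffusion_estimate`: list with
#'   `sigma_mm2_per_min`, `sigma_mm2_per_s`, `thickness_d`, `source_k_h`.
#' @export
#' @examples
#' diffusion_from_higuchi(4.13e-3, 7.55)  # ~4.051e-6 mm^2/s
diffusion_from_higuchi <- function(k_h, thickness_d) {
  if (inherits(k_h, "higuchi_fit")) k_h <- k_h$k_h
  if (any(k_h < 0)) stop_invalid("k_h must be >= 0")
  if (any(thickness_d <= 0)) stop_invalid("thickness_d must be > 0")
  sigma_min <- (k_h * thickness_d / 2)^2
  structure(
    list(sigma_mm2_per_min = sigma_min, sigma_mm2_per_s = sigma_min / 60,
         thickness_d = thickness_d, source_k_h = k_h),
    class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("Diffusion estimate: D = %.4g mm^2/s (%.4g mm^2/min)\n",
              x$sigma_mm2_per_s[1], x$sigma_mm2_per_min[1]))
  cat(sprintf("  from k_H = %.4g min^-1/2, d = %g mm\n",
              x$source_k_h[1], x$thickness_d[1]))
  invisible(x)
}
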