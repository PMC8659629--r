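#' Stationary density profile
#'
#' One-dimensional stationary density of the structural-unit field,
#' \eqn{\rho(x) = z e^{i(kx+\Phi)} + \bar z e^{-i(kx+\Phi)}
#' = 2\,\mathrm{Re}\{z e^{i(kx+\Phi)}\}}, the general real solution of the
#' harmonic equation \eqn{\rho'' + k^2\rho = 0}.
#'
#' @param x Position in mm (vectorized).
#' @param k Wavenumber in mm^-1.
#' @param amp Complex amplitude z labelling the structural unit.
#' @param phase Phase offset \eqn{\Phi} in radians.
#' @return Real-valued density at `x`.
#' @export
#' @examples
#' stationary_density(0, k = 1, amp = 1)   # 2
#' stationary_density(1, k = pi, amp = 1)  # -2
stationary_density <- function(x, k, amp = 1 + 0i, phase = 0) {
  2 * Re(amp * exp(1i * (k * x + phase)))
}

#' Moebius (SL(2,R)) group element
#'
#' Real-coefficient fractional-linear map \eqn{z \mapsto (az+b)/(cz+d)},
#' the synchronization action between structural units. Coefficients must
#' satisfy \eqn{ad - bc \neq 0}; `normalize = TRUE` rescales to the
#' unimodular form \eqn{ad - bc = 1}.
#'
#' @param a,b,c,d Real group parameters.
#' @param normalize Rescale so that ad - bc = 1 (requires ad - bc > 0).
#' @return An object of class `mobius` (named list a, b, c, d).
#' @seealso [mobius_apply()], [mobius_compose()]
#' @export
mobius <- function(a, b, c, d, normalize = FALSE) {
  det <- a * d - b * c
  if (!is.finite(det) || det == 0)
    stop_invalid("Moebius parameters must satisfy ad - bc != 0")
  if (normalize) {
    if (det < 0)
      stop_invalid("normalization to ad - bc = 1 requires ad - bc > 0")
    s <- sqrt(det)
    a <- a / s; b <- b / s; c <- c / s; d <- d / s
  }
  structure(list(a = a, b = b, c = c, d = d), class = "mobius")
}

#' @export
print.mobius <- function(x, ...) {
  cat(sprintf("Moebius map z -> (%g z + %g)/(%g z + %g), det = %g\n",
              x$a, x$b, x$c, x$d, x$a * x$d - x$b * x$c))
  invisible(x)
}

#' Apply a Moebius transformation
#'
#' @param z Complex value(s).
#' @param g A [mobius] element.
#' @param eps Pole tolerance: an error is raised when `|cz + d| < eps`.
#' @return Transformed complex value(s) `(a z + b)/(c z + d)`.
#' @export
#' @examples
#' mobius_apply(1i, mobius(1, 1, 0, 1))  # 1 + 1i
mobius_apply <- function(z, g, eps = 1e-12) {
  stopifnot(inherits(g, "mobius"))
  den <- g$c * z + g$d
  if (any(Mod(den) < eps))
    stop_invalid("Moebius pole: |c z + d| below tolerance")
  (g$a * z + g$b) / den
}

#' Compose two Moebius transformations
#'
#' Returns the element acting as "first `g1`, then `g2`", i.e. the matrix
#' product g2 %*% g1.
#'
#' @param g2,g1 [mobius] elements.
#' @return A [mobius] element.
#' @export
mobius_compose <- function(g2, g1) {
  stopifnot(inherits(g1, "mobius"), inherits(g2, "mobius"))
  mobius(g2$a * g1$a + g2$b * g1$c,
         g2$a * g1$b + g2$b * g1$d,
         g2$c * g1$a + g2$d * g1$c,
         g2$c * g1$b + g2$d * g1$d)
}

#' Harmonic-map complex amplitude
#'
#' Solution of the Euler–Lagrange equations of the Poincare-metric harmonic
#' map, \deqn{z = i\,\frac{\cosh\chi - e^{-i\alpha}\sinh\chi}
#' {\cosh\chi + e^{-i\alpha}\sinh\chi}.}
#' Under the substitution \eqn{r = \coth\chi} and the phase identification
#' \eqn{\alpha = 2\omega t} this is, up to an overall sign, the oscillatory
#' release amplitude [z_pattern()]:
#' `z_pattern(r, omega, t) == -z_harmonic(acoth(r), 2*omega*t)`.
#'
#' @param chi Real hyperbolic coordinate (vectorized).
#' @param alpha Phase in radians (vectorized).
#' @param eps Pole tolerance on the denominator modulus.
#' @return Complex amplitude(s).
#' @export
#' @examples
#' z_harmonic(0, 1)     # i
#' z_harmonic(1, 0)     # i * exp(-2)
z_harmonic <- function(chi, alpha, eps = 1e-9) {
  den <- cosh(chi) + exp(-1i * alpha) * sinh(chi)
  if (any(Mod(den) < eps))
    stop_invalid("harmonic-map pole: denominator modulus below tolerance")
  1i * (cosh(chi) - exp(-1i * alpha) * sinh(chi)) / den
}

#' Oscillatory release amplitude
#'
#' Complex amplitude of the non-stationary release pattern at amplitude
#' coordinate `r` and interaction scale `omega`:
#' \deqn{z(r,\omega,t) = \frac{2r\sin(2\omega t)}{\Delta} +
#'   i\,\frac{1-r^2}{\Delta}, \qquad \Delta = 1 + r^2 + 2r\cos(2\omega t).}
#' The real part is the manifest (measurable) component of the release and
#' the imaginary part the non-manifest background. `z` is exactly periodic in
#' `t` with period \eqn{\pi/\omega}. Points where \eqn{|\Delta|} falls below
#' `eps` (the singular ring r = 1 at half-period phases) are masked as `NA`.
#'
#' @param r Dimensionless amplitude coordinate (\eqn{r = \coth\chi});
#'   vectorized.
#' @param omega Interaction-scale angular frequency (> 0), rad per time unit.
#' @param t Time (vectorized, recycled against `r`).
#' @param eps Singularity mask tolerance on \eqn{|\Delta|}.
#' @return Complex value(s); `NA_complex_` at masked singularities.
#' @export
#' @examples
#' z_pattern(0, 1, 0.3)    # i for any (omega, t)
#' z_pattern(0.5, 1, 0)    # i/3
z_pattern <- function(r, omega, t, eps = 1e-9) {
  if (any(omega <= 0)) stop_invalid("omega must be > 0")
  u <- 2 * omega * t
  delta <- 1 + r^2 + 2 * r * cos(u)
  z <- complex(real = 2 * r * sin(u) / delta,
               imaginary = (1 - r^2) / delta)
  z[abs(delta) < eps] <- NA_complex_
  z
}

#' Amplitude-modulus map over an (r, t) grid
#'
#' Evaluates \eqn{|z(r,\omega,t)|} on the outer grid `r_grid` x `t_grid` at a
#' fixed interaction scale `omega`. The default grid spans r in `[0, 0.99]`
#' (400 points, stopping short of the r = 1 singular ring) and four full
#' periods of t (800 points). Masked singularities propagate as `NA`.
#'
#' @param omega Interaction scale, > 0.
#' @param r_grid Amplitude-coordinate grid (non-empty).
#' @param t_grid Time grid (non-empty); default four periods `4*pi/omega`.
#' @return An object of class `pattern_map`: the |z| matrix (rows = r,
#'   columns = t) with attributes `r`, `t`, `omega`.
#' @export
#' @examples
#' m <- amplitude_map(5, r_grid = c(0, 0.5), t_grid = c(0, 0.1))
amplitude_map <- function(omega,
                          r_grid = seq(0, 0.99, length.out = 400L),
                          t_grid = seq(0, 4 * pi / omega, length.out = 800L)) {
  if (length(r_grid) == 0L || length(t_grid) == 0L)
    stop_invalid("r_grid and t_grid must be non-empty")
  m <- outer(r_grid, t_grid, function(r, t) Mod(z_pattern(r, omega, t)))
  structure(m, r = r_grid, t = t_grid, omega = omega,
            dimnames = NULL, class = c("pattern_map", "matrix"))
}

#' @export
print.pattern_map <- function(x, ...) {
  cat(sprintf("Amplitude map |z| at omega = %g: %d r-values x %d t-values, %d masked\n",
              attr(x, "omega"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' @export
plot.pattern_map <- function(x, ...) {
  image(attr(x, "t"), attr(x, "r"), t(unclass(x)), xlab = "t", ylab = "r",
        main = sprintf("|z|, omega = %g", attr(x, "omega")), ...)
  invisible(x)
}

#' Time traces of the release amplitude
#'
#' Extracts aligned time series of \eqn{|z|}, \eqn{\mathrm{Re}(z)} and
#' \eqn{\mathrm{Im}(z)} at fixed `r` and `omega`; \eqn{|z|^2 =
#' \mathrm{Re}^2 + \mathrm{Im}^2} holds at every sample.
#'
#' @param r Amplitude coordinate.
#' @param omega Interaction scale, > 0.
#' @param t_grid Time grid; default four periods at 2000 samples.
#' @return A data.frame with columns `t`, `abs_z`, `re_z`, `im_z`.
#' @export
time_traces <- function(r, omega,
                        t_grid = seq(0, 4 * pi / omega, length.out = 2000L)) {
  z <- z_pattern(r, omega, t_grid)
  data.frame(t = t_grid, abs_z = Mod(z), re_z = Re(z), im_z = Im(z))
}

#' Count local maxima of the amplitude modulus over one period
#'
#' Qualitative period-doubling diagnostic: the number of strict local maxima
#' of \eqn{|z(r,\omega,t)|} over a single period \eqn{\pi/\omega}, counted on
#' a dense uniform grid with periodic wrap-around. Near r = 0 the modulus is
#' nearly constant with a single shallow extremum; as r grows towards 1,
#' secondary maxima appear within the period.
#'
#' @param r Amplitude coordinate.
#' @param omega Interaction scale, > 0.
#' @param n_grid Samples per period (default 1e4).
#' @return Integer count of local maxima per period.
#' @export
peak_count <- function(r, omega, n_grid = 1e4) {
  if (omega <= 0) stop_invalid("omega must be > 0")
  # one period, endpoint excluded; wrap-around comparison keeps periodicity
  tt <- seq(0, pi / omega, length.out = n_grid + 1L)[-(n_grid + 1L)]
  y <- Mod(z_pattern(r, omega, tt))
  if (anyNA(y)) stop_invalid("masked singularity inside the period")
  prev <- c(y[length(y)], y[-length(y)])
  nxt <- c(y[-1L], y[1L])
  sum(y > prev & y > nxt)
}
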