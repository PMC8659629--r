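---
title: "Release kinetics and pattern dynamics: models, conventions, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Release kinetics and pattern dynamics: models, conventions, validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrokin)
```

## The manifest release model

A drug-loaded hydrogel film of thickness $d$ (mm) immersed in release medium
releases a cumulative amount $M_t$; normalized by the asymptotic reference
$M_\infty$ this gives the release fraction $f(t) = M_t/M_\infty \in [0, 1]$.
`hydrokin` treats release as one-dimensional diffusion out of a slab and
implements two laws for $f$:

**Higuchi square-root law** (burst phase):
$$f(t) = k_H \sqrt{t}, \qquad [k_H] = \mathrm{min}^{-1/2}.$$
`fit_higuchi()` estimates $k_H$ by least squares of $f$ on $\sqrt t$
*constrained through the origin* — the law has no intercept, so an
unconstrained fit would absorb burst curvature into a nuisance offset. The
closed-form slope is $\hat k_H = \sum_i f_i \sqrt{t_i} / \sum_i t_i$. The
default window is $t \le 30$ min, the burst phase; it is an argument, not a
constant, because burst duration varies between polymer systems.

**Truncated erfc-series solution** (all time scales):
$$f(t) = 2\sqrt{\frac{\sigma t}{d^2}}\left[\pi^{-1/2} +
\sum_{n=1}^{N}(-1)^n\,\mathrm{erfc}\!\left(\frac{n d}{2\sqrt{\sigma t}}\right)\right],$$
with $\sigma$ the diffusion coefficient (mm²/min) and $N$ the truncation
order (default $N = 2$, at which the long-time tail out to thousands of
minutes is already well described; higher $N$ changes the default grid's
values below $10^{-10}$). At $t = 0$ the continuous limit $f(0)=0$ is
returned directly, avoiding a $0/0$ in the erfc argument.

**Thickness relation.** Comparing the small-time limit with the Higuchi form
gives $k_H = 2\sqrt{\sigma}/d$, so `diffusion_from_higuchi()` computes
$\sigma = (k_H d/2)^2$ mm²/min and reports $D = \sigma/60$ mm²/s. This
relation de-empiricizes $k_H$: two films with equal $k_H$ but different
thickness have very different transport coefficients, which is why a panel's
release-efficiency ordering tracks $D$ rather than $k_H$.

### The $\pi$ inconsistency, kept on purpose

The two laws as implemented are mutually inconsistent by a factor
$\pi^{-1/2}$: the series' small-time limit is
$f \to (2/\sqrt\pi)\sqrt{\sigma t}/d$, while the bare Higuchi form lacks the
$\pi^{-1/2}$. Both are implemented exactly as written because the thickness
relation (no $\pi$) is what reproduces the reference panel's printed $D$
values. The consequence is a documented, tested property rather than a
silent correction: generating noise-free data from the series' small-time
form and fitting the bare square-root law recovers
$\hat\sigma/\sigma_{\mathrm{true}} = 1/\pi$ exactly. Users mixing the two
laws on real data should be aware their $\sigma$ estimates differ by
$\pi \approx 3.14\times$ depending on the route taken.

### Fitting and numerical choices

- erfc is evaluated as `2 * pnorm(x * sqrt(2), lower.tail = FALSE)`; it
  underflows to 0 for large arguments, so deep-series terms vanish cleanly
  with no overflow.
- `fit_series()` has a single free parameter; it is optimized with
  `stats::optimize()` on $\log_{10}\sigma$ over $\pm 3$ decades around the
  starting value (itself taken from a Higuchi pre-fit when possible). An
  optimum within $10^{-3}$ of the search boundary raises a fit-failure
  condition carrying the last iterate — a flat saturated curve does this,
  since its best $\sigma$ diverges.
- The reported "correlation factor" is the Pearson correlation between
  observed and fitted fractions over the fit window. This is one of several
  quantities called a correlation factor in the dissolution literature
  (others report $R^2$); it is a descriptive diagnostic here and is never
  asserted against published fit qualities.
- $M_\infty$ defaults to the last observed cumulative value when not
  supplied. Loaded mass is the physically cleaner reference, but published
  panels often mix mg (loaded) with mg/mL (released), making that quotient
  unit-inconsistent; both options are exposed (`m_inf` arguments).
- Degenerate inputs (all-zero curves, single points in window) return
  flagged results (`degenerate = TRUE`, $k_H = 0$ or $\sigma = 0$) rather
  than errors, so a panel run never aborts on one dead film.

## Non-manifest pattern dynamics

The oscillatory background dynamics of the polymer–drug system are carried
by a complex amplitude. The stationary density
$\rho(x) = 2\,\mathrm{Re}\{z\,e^{i(kx+\Phi)}\}$ solves
$\rho'' + k^2\rho = 0$; the constants upstream of $k^2$ (scale-transition
coefficients of the underlying multifractal description) are deliberately
lumped — only $k$ is exposed, because only $k$ is identifiable from the
density. Structural units synchronize under the SL(2,R) Moebius action
$z \mapsto (az+b)/(cz+d)$, and the non-stationary amplitude from the
harmonic-map principle is
$$z = i\,\frac{\cosh\chi - e^{-i\alpha}\sinh\chi}
{\cosh\chi + e^{-i\alpha}\sinh\chi}.$$

Expanding this with $c = \cosh\chi$, $s = \sinh\chi$ gives
$z = \frac{-2cs\sin\alpha + i}{c^2+s^2+2cs\cos\alpha}$, and dividing through
by $s^2$ with $r = \coth\chi$:
$$z = \frac{-2r\sin\alpha + i(r^2-1)}{1 + r^2 + 2r\cos\alpha}.$$
`z_pattern(r, omega, t)` implements the time-parameterized form with
$\alpha = 2\omega t$ and the opposite overall sign:
$\mathrm{Re}(z) = 2r\sin(2\omega t)/\Delta$,
$\mathrm{Im}(z) = (1-r^2)/\Delta$, $\Delta = 1+r^2+2r\cos(2\omega t)$. Two
conventions were genuinely open and are fixed as follows:

- **Sign/real-part reading.** A literal transcription of the
  time-parameterized equation puts $i$ on both terms, making
  $\mathrm{Re}(z) \equiv 0$ — contradicting the interpretation of
  $\mathrm{Re}(z)$ as the measurable release component. The reading above
  restores the real part and is pinned to the harmonic-map form by the
  tested identity `z_pattern(coth(chi), w, t) == -z_harmonic(chi, 2*w*t)`.
- **Phase mapping.** The transition to non-stationary states is sometimes
  written $\alpha = \omega t$; the algebra of the time-parameterized form
  uses $2\omega t$ throughout, and that is what the equivalence test
  enforces. The discrepancy is noted, not resolved.
- **$r$ domain.** $r = \coth\chi > 1$ for real $\chi > 0$, yet the default
  amplitude maps use $r \in [0, 0.99]$: both domains are valid for the
  formula (which is defined for all $r \ne$ the singular ring), and the
  sub-unit domain avoids the ring $r = 1$, where $\Delta \to 0$ at
  $2\omega t = \pi \;(\mathrm{mod}\; 2\pi)$. Singular points are masked
  (`NA`) at $|\Delta| < 10^{-9}$ rather than clipped.
- **Equivalence-test conditioning.** The harmonic-map equivalence is
  asserted to $10^{-10}$ on seeded draws with $\chi \in [0.1, 1.5]$ (i.e.
  $r \in [1.1, 10]$). Near the ring ($\chi \gtrsim 2.5$,
  $r - 1 \lesssim 10^{-2}$) the identity still holds analytically, but
  $\Delta \sim (r-1)^2$ amplifies trigonometric argument-reduction error by
  $\sim 10^3$ and a $10^{-10}$ comparison stops measuring the algebra.

`amplitude_map()` evaluates $|z|$ on an $(r, t)$ grid at fixed $\omega$
(default 400 × 800 over four periods) — the two free variables of the
formula; $\omega \in \{1, 5, 27, 31, 39\}$ spans the qualitative regimes
from burst-like through period-doubled and modulated to damped oscillation.
These regime labels are qualitative; published contour plots of this
quantity do not state axes or scales, so outputs here are structurally
analogous, never bit-reproductions.

**A property the amplitude does not have.** One might expect the
period-doubling regime to show up as extra local maxima of $|z|$ within a
period at large $r$. It does not: substituting $s = \cos(2\omega t)$,
critical points of $|z|^2$ satisfy $s^\ast = -(1+r^2)/(2r)$, and
$|s^\ast| \ge 1$ for every $r > 0$ (equality iff $r = 1$). So $|z|$ has
exactly one maximum per period, at $2\omega t = \pi$, for every $r \ne 1$ —
`peak_count()` confirms this and the test suite asserts it. The diagnostic
that does discriminate regimes is the trace frequency: a fixed observation
window holds proportionally more $|z|$ peaks at higher $\omega$.

`delay_embed()` reconstructs attractors from scalar traces with the
standard lagged-coordinate map. Embedding parameters are not identifiable
from published attractor figures; the defaults follow the quarter-period
heuristic (lag = period/4 in samples, dimension 3), and a sine embedded at
quarter-period lag must land on a circle to $10^{-6}$ — the geometric sanity
check for the lag convention.

## The synthetic-data generator

`make_release_curve()` emulates the study conditions the fitting stages are
meant for: a burst-dense, plateau-sparse sampling grid
$\{1,\dots,30\} \cup \{60, 120, 240, 480, 960, 1440, 2160, 2800\}$ min,
a forward model chosen from the two laws above, and additive i.i.d.
Gaussian noise on the fraction scale, clipped at 0. Defaults:

- `noise_sd = 0.01` fractions. No replicate variances are published for
  triplicate-averaged UV–VIS release assays of this kind; 1% of full scale
  is a realistic optical-absorbance figure and is the single noise knob.
- Panel draws: $\sigma$ log-uniform over $[0.181, 11.58]\times 10^{-6}$
  mm²/s and $d$ uniform over $[2.07, 9.14]$ mm — the spans of the reference
  film panel; $\sigma$ is log-uniform because the span covers two orders of
  magnitude.
- A `monotone` option applies a running maximum, since real cumulative
  assays are nondecreasing; it is off by default because monotonized noise
  is no longer i.i.d., which matters when checking noise-level recovery.

Generation is bit-reproducible under a seed and restores the caller's RNG
state. What the generator does *not* emulate: swelling-coupled (time-varying
$\sigma$) transport, drug–matrix binding, replicate structure, or sampling
jitter. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated noise model, not robustness to model
misspecification on real assays — with one deliberate exception: the
mismatched-generator test (series generator, square-root fitter) documents
the $1/\pi$ bias described above.

## Validation design and problem sizes

The test suite validates each stage against an independent route: the
series against a frozen 40-digit arbitrary-precision evaluation and a
second erfc implementation (`pracma::erfc`); the fitters against brute-force
grid searches and (for the through-origin slope) `lm(f ~ sqrt(t) - 1)`;
trace means against `integrate()`. Recovery experiments use 7-film panels
(38 time points each) at `noise_sd = 0.01`, seed 42 — at that size the full
suite runs in a few seconds while the median recovery error sits near 4%,
comfortably inside the 10% band asserted. The reference-panel conversion
check accepts 0.1% relative agreement where the printed coefficient carries
four significant digits, and printed-precision agreement where it carries
three (one film's printed value quantizes at 0.28%); one film's printed
coefficient is inconsistent with any rounding of its printed inputs by
~0.3% and is excluded, as the panel fixture's documentation notes.

## Known limitations

- The erfc-series is the early/intermediate-time expansion; for
  $\sigma t/d^2 \gg 1$ a Fourier-series solution converges faster, and the
  truncated series saturates below 1. Within the default grid and the
  reference panel's parameter ranges ($\sigma t/d^2 \le 0.45$) this is
  immaterial.
- `fit_series()` assumes constant $\sigma$ and fixed $d$; swelling films
  violate both.
- The pattern-dynamics layer is qualitative by construction: it supplies
  the dynamical objects (amplitudes, maps, traces, attractors), not
  estimators of $\omega$ or $r$ from data, and no chaos statistics
  (Lyapunov exponents) are computed.
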