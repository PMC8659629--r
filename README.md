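# hydrokin

Release-kinetics analysis for drug-loaded hydrogel films.

Thin polysaccharide hydrogel films (e.g. beta-cyclodextrin /
kappa-carrageenan networks loaded with metronidazole) release their drug in
two phases: a burst over roughly the first 30 minutes, then a slow approach
to a plateau over thousands of minutes. `hydrokin` is for experimentalists
and modellers who have cumulative-release time series and film metadata and
want physically interpretable transport parameters out of them. It provides:

- **Burst-phase fitting** with the Higuchi square-root law
  `M_t/M_inf = k_H * sqrt(t)`, as a through-origin least-squares fit of the
  release fraction on `sqrt(t)` (`fit_higuchi()`).
- **Diffusion-coefficient estimation** from the fitted constant via the
  film-thickness relation `k_H = 2 * sqrt(sigma) / d`, so
  `sigma = (k_H d / 2)^2` in mm²/min and `D = sigma / 60` in mm²/s
  (`diffusion_from_higuchi()`).
- **Long-time modelling** with the truncated erfc-series solution of slab
  diffusion,
  `f(t) = 2 sqrt(sigma t / d^2) [ pi^{-1/2} + sum_{n=1}^{N} (-1)^n erfc( n d / (2 sqrt(sigma t)) ) ]`,
  usually truncated at N = 2 (`series_release()`, `fit_series()`).
- **Release-pattern dynamics**: the complex oscillatory amplitude
  `z(r, omega, t)` of the underlying structural-unit dynamics, its SL(2,R)
  Moebius synchronization action, harmonic-map form, amplitude maps, time
  traces and delay-embedding attractor reconstruction (`z_pattern()`,
  `mobius_apply()`, `amplitude_map()`, `time_traces()`, `delay_embed()`).
- **A seeded synthetic-data generator** producing burst-plus-plateau curves
  with known ground truth, so every fitting stage can be validated by
  parameter recovery (`synthetic_spec()`, `make_release_curve()`,
  `make_film_panel()`, `recovery_report()`).
- **Panel orchestration**: `run_panel_analysis()` runs the whole chain per
  film, recomputes release efficiencies and reports a Spearman rank
  correlation between the diffusion coefficient and the release efficiency;
  `read_release_curve()` / `write_results()` handle the delimited-text
  formats. A reference characterization panel for seven films ships as a
  plain-text fixture (`bcd_cg_panel()`).

## Worked example

Generate a synthetic film whose true parameters mimic the thickest reference
film (k_H = 5.77e-3 min^-1/2, d = 9.14 mm), then recover the diffusion
coefficient:

```r
library(hydrokin)

k_true <- 5.77e-3; d <- 9.14
spec <- synthetic_spec(sigma_true = (k_true * d / 2)^2, thickness_d = d,
                       generator_model = "higuchi", noise_sd = 0.005,
                       seed = 42, sample_id = "demo")
rc <- make_release_curve(spec)

(hf <- fit_higuchi(rc))
#> Higuchi fit 'demo': k_H = 0.005713 min^-1/2 (window [0, 30] min, 30 points)
#>   correlation factor r = 0.6754

(de <- diffusion_from_higuchi(hf, d))
#> Diffusion estimate: D = 1.136e-05 mm^2/s (0.0006817 mm^2/min)
#>   from k_H = 0.005713 min^-1/2, d = 9.14 mm
```

The fitted slope (0.005713 vs the true 0.00577, about 1% off under 0.005
noise on fractions of at most 0.03 in the burst window) converts to
D = 1.136e-5 mm²/s against a ground truth of 1.159e-5 mm²/s. The same
conversion applied to the reference panel's printed constants reproduces its
printed coefficients:

```r
panel <- bcd_cg_panel()
diffusion_from_higuchi(panel$k_h_per_sqrt_min[1], panel$thickness_mm[1])
#> Diffusion estimate: D = 4.051e-06 mm^2/s (0.0002431 mm^2/min)
#>   from k_H = 0.00413 min^-1/2, d = 7.55 mm
```

See `vignette` source `vignettes/release-kinetics.Rmd` for the model
details, parameter conventions and validation design.

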