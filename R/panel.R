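#' Read a release curve from delimited text
#'
#' Expects a comma-separated file with header `time_min,released` (released
#' amounts, mg/mL) and/or a `fraction` column. Rows with unsorted times are
#' sorted with a warning; negative values or a malformed header raise a parse
#' error naming the offending line.
#'
#' @param path File path.
#' @param sample_id Label; defaults to the file name without extension.
#' @param m_inf Normalization reference for amount curves; defaults to the
#'   last observed cumulative value (with a notice), the usual stand-in when
#'   the loaded mass is unavailable or in different units.
#' @return A [release_curve].
#' @export
read_release_curve <- function(path, sample_id = NULL, m_inf = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!"time_min" %in% names(df))
    stop_invalid("parse error in ", path, ": header must contain 'time_min'")
  has_amt <- "released" %in% names(df)
  has_frac <- "fraction" %in% names(df)
  if (!has_amt && !has_frac)
    stop_invalid("parse error in ", path,
                 ": header must contain 'released' or 'fraction'")
  vals <- if (has_amt) df$released else df$fraction
  bad <- which(!is.finite(df$time_min) | !is.finite(vals) | vals < 0 |
                 df$time_min < 0)
  if (length(bad))
    stop_invalid("parse error in ", path, ": invalid value at data line ",
                 bad[1])
  if (is.unsorted(df$time_min, strictly = TRUE)) {
    warning("times in ", path, " are not sorted; sorting", call. = FALSE)
    df <- df[order(df$time_min), , drop = FALSE]
    vals <- if (has_amt) df$released else df$fraction
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (has_amt) {
    if (is.null(m_inf)) {
      m_inf <- vals[length(vals)]
      message("m_inf not given for ", sample_id,
              "; defaulting to last observed value (", m_inf, ")")
    }
    release_curve(df$time_min, vals, sample_id = sample_id,
                  value_kind = "amount", m_inf = m_inf)
  } else {
    release_curve(df$time_min, vals, sample_id = sample_id,
                  value_kind = "fraction")
  }
}

#' Write a release curve to delimited text
#'
#' Writes `time_min,released,fraction` at full double precision so that a
#' write/read round trip reproduces the values exactly.
#'
#' @param curve A [release_curve].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_release_curve <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  df <- data.frame(time_min = sprintf("%.17g", curve$times),
                   released = sprintf("%.17g", curve$values),
                   fraction = sprintf("%.17g", release_fraction(curve)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a panel results table
#'
#' Full-precision delimited output of a [run_panel_analysis()] results table
#' (columns `sample_id,k_h_per_sqrt_min,window_lo,window_hi,corr,
#' D_mm2_per_s,sigma_mm2_per_min,...`).
#'
#' @param results Data.frame of results.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference film panel (crosslinked cyclodextrin–carrageenan films F1–F7)
#'
#' Published characterization panel for seven beta-cyclodextrin /
#' kappa-carrageenan hydrogel films shipped as a plain-text fixture:
#' synthesis yields, maximum swelling degrees, metronidazole loading and
#' release amounts with efficiencies, fitted Higuchi constants, film
#' thicknesses, and the printed diffusion coefficients.
#'
#' @return Data.frame with one row per film F1–F7 and columns `sample_id`,
#'   `yield_pct`, `swelling_pct`, `loaded_mg`, `loaded_eff_pct`,
#'   `released_max` (mg/mL), `released_eff_pct`, `k_h_per_sqrt_min`,
#'   `thickness_mm`, `D_printed_mm2_per_s`.
#' @export
#' @examples
#' panel <- bcd_cg_panel()
#' diffusion_from_higuchi(panel$k_h_per_sqrt_min[1], panel$thickness_mm[1])
bcd_cg_panel <- function() {
  read.csv(system.file("extdata", "bcd_cg_films.csv", package = "hydrokin"))
}

#' End-to-end panel analysis
#'
#' For each film: fits the Higuchi constant over the burst window, converts
#' it to a diffusion coefficient via the thickness relation, and fits the
#' erfc-series model over the full time range for the long-time description.
#' Films without a thickness entry are skipped with a warning. When the film
#' table carries `loaded_mg` and `released_max`, release efficiencies are
#' recomputed and a Spearman rank correlation between the diffusion
#' coefficient and the release efficiency is reported (the published
#' comparison is an ordering claim, so a rank statistic is used).
#'
#' @param curves Named list of [release_curve]s (names = sample ids).
#' @param films Data.frame with `sample_id`, `thickness_mm`, and optionally
#'   `loaded_mg`, `released_max`.
#' @param window Higuchi fit window in minutes, default `c(0, 30)`.
#' @param truncation_n Series truncation, default 2.
#' @return An object of class `panel_analysis`: list with `results` (one row
#'   per analysed film: `sample_id`, `k_h_per_sqrt_min`, `window_lo`,
#'   `window_hi`, `corr`, `D_mm2_per_s`, `sigma_mm2_per_min`,
#'   `series_sigma_mm2_per_min`, `series_corr`, `efficiency_pct`,
#'   `degenerate`), `spearman_D_vs_efficiency`, and `skipped`.
#' @export
run_panel_analysis <- function(curves, films, window = c(0, 30),
                               truncation_n = 2L) {
  if (length(curves) == 0L) stop_invalid("empty panel: no curves supplied")
  if (is.null(names(curves)) || any(names(curves) == ""))
    stop_invalid("curves must be a named list (names = sample ids)")
  if (!all(c("sample_id", "thickness_mm") %in% names(films)))
    stop_invalid("films table needs columns sample_id and thickness_mm")
  rows <- list()
  skipped <- character(0)
  for (id in names(curves)) {
    i <- match(id, films$sample_id)
    d <- if (is.na(i)) NA_real_ else films$thickness_mm[i]
    if (is.na(d) || d <= 0) {
      warning("skipping '", id, "': no usable thickness", call. = FALSE)
      skipped <- c(skipped, id)
      next
    }
    hf <- fit_higuchi(curves[[id]], window = window)
    de <- diffusion_from_higuchi(hf, d)
    sf <- tryCatch(
      fit_series(curves[[id]], d, truncation_n = truncation_n,
                 sigma_init = max(de$sigma_mm2_per_min, 1e-12)),
      hydrokin_fit_failure = function(e) NULL)
    eff <- if (all(c("loaded_mg", "released_max") %in% names(films)))
      release_efficiency(films$released_max[i], films$loaded_mg[i])
    else NA_real_
    rows[[id]] <- data.frame(
      sample_id = id, k_h_per_sqrt_min = hf$k_h, window_lo = window[1],
      window_hi = window[2], corr = hf$corr,
      D_mm2_per_s = de$sigma_mm2_per_s,
      sigma_mm2_per_min = de$sigma_mm2_per_min,
      series_sigma_mm2_per_min = if (is.null(sf)) NA_real_ else sf$sigma,
      series_corr = if (is.null(sf)) NA_real_ else sf$corr,
      efficiency_pct = eff, degenerate = hf$degenerate)
  }
  if (length(rows) == 0L) stop_invalid("no film could be analysed")
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  rho <- if (sum(!is.na(results$efficiency_pct)) >= 3)
    cor(results$D_mm2_per_s, results$efficiency_pct, method = "spearman",
        use = "complete.obs")
  else NA_real_
  structure(list(results = results, spearman_D_vs_efficiency = rho,
                 skipped = skipped),
            class = "panel_analysis")
}

#' @export
print.panel_analysis <- function(x, ...) {
  cat(sprintf("Panel analysis: %d film(s) analysed, %d skipped\n",
              nrow(x$results), length(x$skipped)))
  print(x$results, digits = 4)
  if (!is.na(x$spearman_D_vs_efficiency))
    cat(sprintf("Spearman rank correlation D vs release efficiency: %.3f\n",
                x$spearman_D_vs_efficiency))
  invisible(x)
}
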