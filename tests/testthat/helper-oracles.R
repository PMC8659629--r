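# Independent oracles: deliberately avoid the package's own code paths.
# The series uses pracma::erfc (vs the package's pnorm-based erfc) and the
# fitters are brute-force grid searches (vs closed form / optimize).

series_oracle <- function(t, sigma, d, N) {
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    br <- 1 / sqrt(pi)
    if (N >= 1) for (n in 1:N)
      br <- br + (-1)^n * pracma::erfc(n * d / (2 * sqrt(sigma * ti)))
    2 * sqrt(sigma * ti) / d * br
  }, numeric(1))
}

# brute-force through-origin Higuchi slope: grid search on k
grid_kh_oracle <- function(t, f, k_lo, k_hi, len = 200001L) {
  ks <- seq(k_lo, k_hi, length.out = len)
  ssr <- vapply(ks, function(k) sum((f - k * sqrt(t))^2), numeric(1))
  ks[which.min(ssr)]
}

# brute-force series fit: log-spaced grid search on sigma
grid_sigma_oracle <- function(t, f, d, N, s_lo, s_hi, len = 4001L) {
  ss <- 10^seq(log10(s_lo), log10(s_hi), length.out = len)
  ssr <- vapply(ss, function(s) sum((f - series_oracle(t, s, d, N))^2),
                numeric(1))
  ss[which.min(ssr)]
}
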