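# complementary error function via the normal CDF: erfc(x) = 2*P(Z > x*sqrt(2)).
# Underflows cleanly to 0 for large x, which the series evaluation relies on.
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so seeded generators never perturb the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_invalid <- function(...) {
  stop(structure(class = c("hydrokin_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
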