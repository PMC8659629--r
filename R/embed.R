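#' Time-delay embedding of a scalar series
#'
#' Reconstructs a trajectory in lag space: point k is
#' `(s[k], s[k+lag], ..., s[k+(dim-1)*lag])`. The number of points is
#' `length(series) - (dim - 1) * lag`. A common default for oscillatory
#' series is a quarter-period lag with `dim = 3`.
#'
#' @param series Real numeric sequence.
#' @param lag Delay in samples, >= 1.
#' @param dim Embedding dimension, >= 2.
#' @return An object of class `delay_embedding`: a numeric matrix with
#'   columns `e1..e<dim>` and attributes `lag`, `dim`.
#' @export
#' @examples
#' delay_embed(1:5, lag = 1, dim = 2)
delay_embed <- function(series, lag, dim = 3L) {
  series <- as.numeric(series)
  lag <- as.integer(lag)
  dim <- as.integer(dim)
  if (lag < 1L) stop_invalid("lag must be >= 1 sample")
  if (dim < 2L) stop_invalid("dim must be >= 2")
  n_pts <- length(series) - (dim - 1L) * lag
  if (n_pts < 1L)
    stop_invalid("series too short: need length > (dim - 1) * lag")
  m <- vapply(seq_len(dim) - 1L,
              function(j) series[seq_len(n_pts) + j * lag],
              numeric(n_pts))
  if (n_pts == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- paste0("e", seq_len(dim))
  # "dim" is reserved for array dimensions; store the embedding dim as edim
  structure(m, lag = lag, edim = dim,
            class = c("delay_embedding", "matrix", "array"))
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat(sprintf("Delay embedding: %d points, dim = %d, lag = %d samples\n",
              nrow(x), attr(x, "edim"), attr(x, "lag")))
  print(head(unclass(x)))
  invisible(x)
}

#' @export
plot.delay_embedding <- function(x, ...) {
  plot.default(x[, 1L], x[, 2L], type = "l", xlab = "e1", ylab = "e2",
               main = sprintf("Delay embedding (lag %d)", attr(x, "lag")), ...)
  invisible(x)
}
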