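#' Gamma short-term memory of a rate stream
#'
#' A gamma memory is a cascade of leaky integrators providing a trainable-
#' depth short-term memory of its input. Stage 0 is the current input
#' `x(t)`; stage `k >= 1` follows
#' `y_k(t) = (1 - mu) y_k(t-1) + mu y_{k-1}(t-1)`.
#' At `mu = 1` the cascade degenerates to a pure tap-delay line (stage `k`
#' holds the input delayed `k` steps); smaller `mu` trades temporal
#' resolution for memory depth. The Actor's neural state is the
#' concatenation of the `K` stage outputs (stages `0 .. K-1`) over all
#' units, giving an embedding of dimension `n_units * K`.
#'
#' @param n_units input dimensionality (number of units).
#' @param K memory order (number of taps, >= 1).
#' @param mu gamma parameter in (0, 1].
#' @return an object of class `gamma_memory` with matrix field `Y`
#'   (`n_units x K`, one column per stage).
#' @export
gamma_memory <- function(n_units, K = 3, mu = 0.6) {
  stopifnot(K >= 1, mu > 0, mu <= 1)
  structure(list(Y = matrix(0, n_units, K), n_units = n_units,
                 K = K, mu = mu),
            class = "gamma_memory")
}

#' @rdname gamma_memory
#' @param gm a `gamma_memory`.
#' @param x current input vector (length `n_units`).
#' @return `gamma_step` returns the updated memory.
#' @export
gamma_step <- function(gm, x) {
  stopifnot(length(x) == gm$n_units)
  old <- gm$Y
  gm$Y[, 1] <- x
  if (gm$K > 1)
    for (k in 2:gm$K)
      gm$Y[, k] <- (1 - gm$mu) * old[, k] + gm$mu * old[, k - 1]
  gm
}

#' @rdname gamma_memory
#' @return `gamma_state` returns the current embedding as a numeric vector
#'   (unit-major: all stages of unit 1, then unit 2, ...).
#' @export
gamma_state <- function(gm) as.vector(t(gm$Y))

#' Embed a whole rate stream through a gamma memory
#'
#' Feeds the columns of `stream` through a fresh [gamma_memory()] and
#' returns either the final embedding or the full embedded stream. Streams
#' shorter than the memory depth simply start from the zero state.
#'
#' @param stream numeric matrix, units x time (successive rate vectors).
#' @param K,mu memory order and gamma parameter.
#' @param all if `TRUE` return the `(n_units * K) x T` matrix of embeddings
#'   at every step; otherwise the final embedding vector.
#' @return numeric vector or matrix of gamma-stage outputs.
#' @export
gamma_embed <- function(stream, K = 3, mu = 0.6, all = FALSE) {
  stream <- as.matrix(stream)
  gm <- gamma_memory(nrow(stream), K, mu)
  if (all) {
    out <- matrix(0, nrow(stream) * K, ncol(stream))
    for (t in seq_len(ncol(stream))) {
      gm <- gamma_step(gm, stream[, t])
      out[, t] <- gamma_state(gm)
    }
    out
  } else {
    for (t in seq_len(ncol(stream))) gm <- gamma_step(gm, stream[, t])
    gamma_state(gm)
  }
}
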