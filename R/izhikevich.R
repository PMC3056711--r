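#' Izhikevich neuron state
#'
#' State of the two-variable Izhikevich spiking model
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)`, with the
#' reset `v <- c`, `u <- u + d` whenever `v >= 30`. Defaults are the
#' canonical regular-spiking (RS) cortical parameter set.
#'
#' @param v membrane potential (mV-like model units).
#' @param u recovery variable; defaults to `b * v`.
#' @param a,b,c,d model constants (RS: 0.02, 0.2, -65, 8).
#' @return an object of class `izh_state`.
#' @export
izh_state <- function(v = -65, u = NULL, a = 0.02, b = 0.2, c = -65, d = 8) {
  structure(list(v = v, u = u %||% (b * v), a = a, b = b, c = c, d = d),
            class = "izh_state")
}

#' Advance an Izhikevich neuron one time step
#'
#' Single fixed step of length `dt` seconds, using the customary two
#' half-steps for the membrane equation. The ensemble synthesizer runs the
#' identical update in compiled code; this scalar version defines the
#' reference semantics and serves small-scale exploration.
#'
#' @param state an [izh_state()].
#' @param I input current for this step (model units).
#' @param dt step length in seconds (> 0); the model's natural time unit is
#'   ms, so `dt = 0.001` is the standard choice.
#' @return `list(state = <izh_state>, spiked = <logical>)`.
#' @examples
#' s <- izh_state()
#' step_izhikevich(s, I = 10)$spiked
#' @export
step_izhikevich <- function(state, I, dt = 0.001) {
  stopifnot(inherits(state, "izh_state"), dt > 0)
  h <- dt * 1000 # ms
  v <- state$v
  u <- state$u
  v <- v + 0.5 * h * (0.04 * v * v + 5 * v + 140 - u + I)
  v <- v + 0.5 * h * (0.04 * v * v + 5 * v + 140 - u + I)
  u <- u + h * state$a * (state$b * v - u)
  spiked <- v >= 30
  if (spiked) {
    v <- state$c
    u <- u + state$d
  }
  state$v <- v
  state$u <- u
  list(state = state, spiked = spiked)
}
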