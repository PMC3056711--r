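#' Cosine oracle evaluative feedback
#'
#' The simulator's reward-expectation oracle: the cosine of the angle
#' between the executed movement and the direct path to the target.
#' Movements toward the target map to positive values (maximally +1 when
#' collinear), movements away to negative values (-1 when opposite). The
#' degenerate cases - a zero movement (e.g. a boundary-clamped step) or a
#' position already at the target - return a neutral 0 rather than failing
#' mid-trial.
#'
#' @param move executed movement vector.
#' @param position position before the movement.
#' @param target target position.
#' @return scalar in `[-1, 1]`.
#' @export
oracle_feedback <- function(move, position, target) {
  v <- target - position
  nm <- sqrt(sum(move^2))
  nv <- sqrt(sum(v^2))
  if (nm < 1e-12 || nv < 1e-12) return(0)
  sum(move * v) / (nm * nv)
}

#' Temporal-difference-like error from reward expectation
#'
#' First difference of the scalar reward expectation, an instantaneous
#' estimate of its gradient: positive while the expectation is rising
#' (goal approach), negative while it falls.
#'
#' @param v_now,v_prev reward expectation at the current / previous step.
#' @return scalar feedback value.
#' @export
td_error <- function(v_now, v_prev) {
  stopifnot(is.finite(v_now), is.finite(v_prev))
  v_now - v_prev
}

#' Label trajectory steps as rewarding or aversive
#'
#' Step `t` is labelled `+1` (rewarding state) iff the distance to the
#' target decreased from position `t` to `t+1`, else `-1` (aversive).
#' These labels are the training targets of the Critic.
#'
#' @param trajectory numeric matrix of positions, one row per step.
#' @param target numeric target position.
#' @return integer vector of `+1` / `-1`, one per movement (length
#'   `nrow(trajectory) - 1`).
#' @export
label_states <- function(trajectory, target) {
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) < 2) stop("trajectory must have at least 2 positions")
  d <- sqrt(rowSums(sweep(trajectory, 2, target)^2))
  ifelse(diff(d) < 0, 1L, -1L)
}

#' Surrogate random feedback
#'
#' Replaces the Critic with an information-free control: independent fair
#' draws of +1 / -1 per step, destroying any true evaluative structure.
#'
#' @param n number of draws.
#' @return integer vector of `+1` / `-1`.
#' @export
surrogate_feedback <- function(n = 1) {
  sample(c(-1L, 1L), n, replace = TRUE)
}

#' Tap-delay MLP Critic
#'
#' The Critic estimates the scalar evaluative feedback from NAcc ensemble
#' rates: `n_taps` delayed copies of the rate vector feed a multilayer
#' perceptron with `H` tanh hidden units and one linear output, thresholded
#' at zero to emit +1 (rewarding) or -1 (aversive).
#'
#' @param n_units number of NAcc units.
#' @param n_taps input delay-line length.
#' @param H hidden-layer size.
#' @param threshold decision threshold on the linear output.
#' @param init_range half-width of the uniform weight initialization.
#' @param seed optional RNG seed.
#' @return an object of class `critic_model`.
#' @export
init_critic <- function(n_units, n_taps = 3, H = 5, threshold = 0,
                        init_range = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- n_units * n_taps
  r <- init_range
  structure(list(W_h = matrix(runif(H * p, -r, r), H, p),
                 b_h = runif(H, -r, r),
                 w_o = runif(H, -r, r), b_o = runif(1, -r, r),
                 n_units = n_units, n_taps = n_taps, H = H,
                 threshold = threshold),
            class = "critic_model")
}

#' @export
print.critic_model <- function(x, ...) {
  cat(sprintf("<critic_model> %d units x %d taps -> %d tanh hidden -> 1 linear\n",
              x$n_units, x$n_taps, x$H))
  invisible(x)
}

# Linear output of the critic for a flattened tap window.
critic_output <- function(model, x) {
  phi <- tanh(model$W_h %*% x + model$b_h)
  as.numeric(model$w_o %*% phi + model$b_o)
}

#' Thresholded Critic feedback
#'
#' Maps the last `n_taps` NAcc rate vectors to +1 if the Critic's linear
#' output exceeds its threshold, else -1 (an output exactly at threshold is
#' conservatively mapped to -1, i.e. not reinforced).
#'
#' @param model an [init_critic()] model.
#' @param window numeric matrix `n_units x n_taps`, most recent bin in the
#'   first column.
#' @return `+1` or `-1`.
#' @export
critic_feedback <- function(model, window) {
  window <- as.matrix(window)
  if (nrow(window) != model$n_units || ncol(window) != model$n_taps)
    stop("window must be ", model$n_units, " units x ", model$n_taps, " taps")
  if (critic_output(model, as.vector(window)) > model$threshold) 1L else -1L
}

# Build the tap-delayed design matrix for per-bin rate vectors, delaying
# only within trials (bins before a trial's start pad with zeros).
tap_design <- function(values, trials, n_taps) {
  p <- nrow(values)
  nb <- ncol(values)
  X <- matrix(0, p * n_taps, nb)
  for (tp in seq_len(n_taps)) {
    idx <- seq_len(nb) - (tp - 1)
    ok <- idx >= 1
    ok[ok] <- trials[idx[ok]] == trials[ok]
    rows <- (tp - 1) * p + seq_len(p)
    X[rows, ok] <- values[, idx[ok], drop = FALSE]
  }
  X
}

#' Train the Critic by error backpropagation
#'
#' Fits the tap-delay MLP to per-bin rewarding/aversive labels by
#' stochastic gradient descent on the squared error of the linear output.
#' Trials are split in half at random - half for training, half for testing
#' - so that accuracy is measured on held-out trials (no temporal leakage).
#'
#' @param rates a [rate_matrix()] (or plain units x bins matrix) of NAcc
#'   binned counts.
#' @param labels per-bin labels, `+1` / `-1`.
#' @param trials per-bin trial identifiers (taps do not cross trial
#'   boundaries and the train/test split is by trial).
#' @param n_taps,H architecture of [init_critic()].
#' @param epochs training passes over the training bins.
#' @param lr SGD learning rate.
#' @param seed optional RNG seed (weights, split and shuffling).
#' @return `list(model, accuracy, train_accuracy, baseline, test_trials)`
#'   where `accuracy` is held-out sign agreement in percent and `baseline`
#'   the accuracy of always guessing the majority training label.
#' @export
train_critic <- function(rates, labels, trials, n_taps = 3, H = 5,
                         epochs = 30, lr = 0.01, seed = NULL) {
  values <- if (inherits(rates, "rate_matrix")) rates$values else as.matrix(rates)
  nb <- ncol(values)
  stopifnot(length(labels) == nb, length(trials) == nb)
  if (!is.null(seed)) set.seed(seed)
  if (length(unique(labels)) < 2)
    warning("labels contain a single class; accuracy is reported against ",
            "the constant baseline")
  X <- tap_design(values, trials, n_taps)
  ids <- unique(trials)
  test_ids <- sample(ids, floor(length(ids) / 2))
  is_test <- trials %in% test_ids
  model <- init_critic(nrow(values), n_taps = n_taps, H = H)
  tr <- which(!is_test)
  for (ep in seq_len(epochs)) {
    for (i in sample(tr)) {
      x <- X[, i]
      phi <- tanh(model$W_h %*% x + model$b_h)
      y <- as.numeric(model$w_o %*% phi + model$b_o)
      e <- labels[i] - y
      delta_h <- (model$w_o * e) * (1 - phi^2)
      model$w_o <- model$w_o + lr * e * as.numeric(phi)
      model$b_o <- model$b_o + lr * e
      model$W_h <- model$W_h + lr * (delta_h %*% t(x))
      model$b_h <- model$b_h + lr * as.numeric(delta_h)
    }
  }
  pred <- apply(X, 2, function(x)
    if (critic_output(model, x) > model$threshold) 1L else -1L)
  acc <- function(sel) 100 * mean(pred[sel] == labels[sel])
  maj <- if (mean(labels[tr] == 1) >= 0.5) 1L else -1L
  list(model = model,
       accuracy = acc(is_test),
       train_accuracy = acc(!is_test),
       baseline = 100 * mean(labels[is_test] == maj),
       test_trials = test_ids)
}
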