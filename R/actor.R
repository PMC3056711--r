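#' Initialize the Actor network
#'
#' The Actor is a time-delay neural network mapping the gamma-memory
#' embedding of the M1 rate stream to one value per discrete action: a
#' hidden layer of `H` tanh units (the feature map `phi(s)`) followed by
#' one linear output unit per action. All weights and biases draw uniformly
#' from `[-init_range, init_range]` (default 0.5, a naive decoder).
#'
#' @param n_units number of M1 units feeding the embedding.
#' @param n_actions number of discrete actions (output units).
#' @param K gamma-memory order (taps per unit).
#' @param H hidden-layer size.
#' @param mu gamma parameter of the input memory.
#' @param init_range half-width of the uniform weight initialization.
#' @param hidden_update which feedback sign routes the error on to the
#'   hidden weights: `"negative"` (default; aversive feedback reshapes the
#'   feature space, rewarding feedback only reinforces the chosen output
#'   row) or `"positive"` (the swapped convention).
#' @param pos_rate_scale factor applied to the learning rate on the
#'   rewarding branch (`eps > 0`). Values below 1 make reinforcement of an
#'   already-chosen action gentler than the unlearning driven by aversive
#'   feedback, bounding how entrenched an action value can become while it
#'   keeps being selected (greedy selection needs the chosen action to win
#'   the argmax, not to accumulate value without limit).
#' @param input_scale divisor applied to the embedding before the hidden
#'   layer. Binned spike counts of driven units run around 4-6 per 100 ms;
#'   scaling them near unit range keeps the tanh layer out of deep
#'   saturation, where all states would alias to the same sign pattern and
#'   the backpropagated gradient vanishes.
#' @param hidden_rate_scale factor applied to the learning rate of the
#'   hidden-layer update branch; values below 1 slow the reshaping of the
#'   feature space relative to the output rows, protecting the state
#'   separation the random initial projection provides.
#' @param seed optional RNG seed.
#' @return an object of class `actor_model`.
#' @export
init_actor <- function(n_units, n_actions = 4, K = 3, H = 5, mu = 0.6,
                       init_range = 0.5,
                       hidden_update = c("negative", "positive"),
                       pos_rate_scale = 1, input_scale = 1,
                       hidden_rate_scale = 1, seed = NULL) {
  stopifnot(n_units >= 1, n_actions >= 1, K >= 1, H >= 1)
  hidden_update <- match.arg(hidden_update)
  if (!is.null(seed)) set.seed(seed)
  p <- n_units * K
  r <- init_range
  structure(list(
    W_h = matrix(runif(H * p, -r, r), H, p),
    b_h = runif(H, -r, r),
    W_o = matrix(runif(n_actions * H, -r, r), n_actions, H),
    b_o = runif(n_actions, -r, r),
    n_units = n_units, n_actions = n_actions, K = K, H = H, mu = mu,
    hidden_update = hidden_update, pos_rate_scale = pos_rate_scale,
    input_scale = input_scale, hidden_rate_scale = hidden_rate_scale),
    class = "actor_model")
}

#' @export
print.actor_model <- function(x, ...) {
  cat(sprintf(
    "<actor_model> %d units x %d taps -> %d tanh hidden -> %d actions\n",
    x$n_units, x$K, x$H, x$n_actions))
  invisible(x)
}

# Forward pass returning both the action values and the hidden features.
actor_forward <- function(model, state) {
  if (length(state) != ncol(model$W_h))
    stop("state dimension ", length(state), " does not match the model (",
         ncol(model$W_h), ")")
  s <- state / (model$input_scale %||% 1)
  phi <- tanh(model$W_h %*% s + model$b_h)
  list(values = as.numeric(model$W_o %*% phi + model$b_o), phi = phi, s = s)
}

#' Action values for a neural state
#'
#' Computes `Q(s, a) = W_o[a, ] . phi(s) + b_o[a]` with
#' `phi(s) = tanh(W_h s + b_h)` for every action.
#'
#' @param model an [init_actor()] model.
#' @param state numeric embedding vector (length `n_units * K`).
#' @return numeric vector of one value per action.
#' @export
action_values <- function(model, state) actor_forward(model, state)$values

#' Greedy action selection
#'
#' Returns the index of the highest-valued action; ties (within `tol`) are
#' broken uniformly at random with the current RNG stream.
#'
#' @param values numeric action values.
#' @param tol tie tolerance.
#' @return integer action index.
#' @export
select_action <- function(values, tol = 1e-12) {
  if (any(!is.finite(values))) stop("action values must be finite")
  best <- which(values >= max(values) - tol)
  if (length(best) == 1) best else best[sample.int(length(best), 1)]
}

#' Reinforcement update of the Actor
#'
#' Applies the asymmetric per-step adaptation rule: the output weights of
#' the chosen action move along `eta * eps * phi(s)` (all other output rows
#' are untouched), and the error backpropagates through the tanh layer to
#' the hidden weights only in the branch designated by the model's
#' `hidden_update` convention (default: when `eps < 0`). With `eta = 0` the
#' model is returned unchanged.
#'
#' @param model an [init_actor()] model.
#' @param state the embedding the action was selected from.
#' @param action chosen action index.
#' @param eps scalar evaluative feedback.
#' @param eta learning rate (>= 0).
#' @return the updated model.
#' @export
update_actor <- function(model, state, action, eps, eta) {
  if (!is.finite(eps)) stop("non-finite evaluative feedback")
  stopifnot(eta >= 0, action >= 1, action <= model$n_actions)
  if (eta == 0 || eps == 0) return(model)
  if (eps > 0) eta <- eta * (model$pos_rate_scale %||% 1)
  fw <- actor_forward(model, state)
  phi <- fw$phi
  hidden_branch <- if (model$hidden_update == "negative") eps < 0 else eps > 0
  if (hidden_branch) {
    # backprop through the chosen action's output row, pre-update weights
    eta_h <- eta * (model$hidden_rate_scale %||% 1)
    delta_h <- (model$W_o[action, ] * eps) * (1 - phi^2)
    model$W_h <- model$W_h + eta_h * (delta_h %*% t(fw$s))
    model$b_h <- model$b_h + eta_h * as.numeric(delta_h)
  }
  model$W_o[action, ] <- model$W_o[action, ] + eta * eps * as.numeric(phi)
  model$b_o[action] <- model$b_o[action] + eta * eps
  model
}

#' Learning-rate schedule with consolidation annealing
#'
#' As the decoder solves the task consistently the learning rate is
#' annealed toward zero, freezing (consolidating) the control policy; the
#' introduction of a new task resets the rate and adaptation resumes.
#'
#' @param eta0 initial learning rate.
#' @param anneal_factor multiplicative decay applied per consolidation
#'   event (a success while the current success streak has reached
#'   `streak_len`).
#' @param streak_len number of consecutive successes that counts as having
#'   learned the task.
#' @param floor minimum learning rate during consolidation.
#' @return an object of class `learning_schedule`.
#' @export
learning_schedule <- function(eta0 = 0.2, anneal_factor = 0.8,
                              streak_len = 10, floor = 0) {
  stopifnot(eta0 >= 0, anneal_factor >= 0, anneal_factor <= 1, floor >= 0)
  structure(list(eta0 = eta0, eta = eta0, anneal_factor = anneal_factor,
                 streak_len = streak_len, floor = floor, streak = 0L),
            class = "learning_schedule")
}

#' Advance a learning schedule
#'
#' @param schedule a [learning_schedule()].
#' @param event `"success_streak"` multiplies `eta` by the anneal factor
#'   (not below `floor`); `"new_task"` and `"reset"` restore `eta0` and
#'   clear the streak counter.
#' @return the updated schedule.
#' @export
anneal <- function(schedule, event = c("success_streak", "new_task", "reset")) {
  event <- match.arg(event)
  if (event == "success_streak") {
    schedule$eta <- max(schedule$floor, schedule$eta * schedule$anneal_factor)
  } else {
    schedule$eta <- schedule$eta0
    schedule$streak <- 0L
  }
  schedule
}
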