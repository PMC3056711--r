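#' Default experiment configuration
#'
#' One nested list holding every tunable default of the closed-loop
#' simulator: world geometry, M1 synthesizer drive, Actor/Critic
#' architecture, learning-rate schedule, trial protocol and logging. Any
#' subset can be overridden via a YAML config file ([load_config()]) or by
#' editing the list.
#'
#' @return a named nested list (class `bmirl_config`).
#' @export
default_config <- function() {
  structure(list(
    world = list(type = "grid", n = 20, spacing = 0.1, success_radius = 0.1),
    reach = list(step_size = 0.1, extent = 2),
    synth = list(mode = "izhikevich", n_units = 12, baseline_current = 1,
                 drive_current = 40, noise_sd = 1, dt = 0.001,
                 baseline_rate = 1, driven_rate = 70),
    actor = list(K = 3, H = 8, mu = 1, init_range = 0.5,
                 hidden_update = "negative", pos_rate_scale = 0.25,
                 input_scale = 5, hidden_rate_scale = 0.1),
    learning = list(eta0 = 0.2, anneal_factor = 0.8, streak_len = 10,
                    floor = 0),
    trial = list(max_steps = 50, n_trials = 100),
    bin_width = 0.1,
    seq = list(epoch_len = 100, accuracy_criterion = 90, max_epochs = 3,
               random_epochs = 2),
    log = list(snapshots = TRUE)
  ), class = "bmirl_config")
}

action_names <- function(world) {
  if (inherits(world, "grid_world_2d")) names(world$actions)
  else colnames(world$actions)
}

empty_log <- function() {
  structure(list(
    trials = data.frame(trial = integer(), target = integer(),
                        success = logical(), steps = integer(),
                        eta = numeric()),
    steps = data.frame(trial = integer(), step = integer(),
                       action = integer(), feedback = numeric(),
                       eta = numeric()),
    values = NULL, snapshots = NULL, meta = list()),
    class = "experiment_log")
}

#' Concatenate experiment logs
#'
#' @param ... `experiment_log` objects with contiguous trial indices.
#' @return one combined `experiment_log`.
#' @export
bind_logs <- function(...) {
  logs <- list(...)
  out <- logs[[1]]
  for (l in logs[-1]) {
    out$trials <- rbind(out$trials, l$trials)
    out$steps <- rbind(out$steps, l$steps)
    out$values <- rbind(out$values, l$values)
    out$snapshots <- rbind(out$snapshots, l$snapshots)
  }
  out
}

#' @export
print.experiment_log <- function(x, ...) {
  cat(sprintf("<experiment_log> %d trials (%d successes), %d steps\n",
              nrow(x$trials), sum(x$trials$success), nrow(x$steps)))
  invisible(x)
}

#' Run the Actor in closed loop with the synthetic user
#'
#' The perception-action-reward cycle of the simulator, one call per block
#' of trials. Per step: the simulated user intends the direction toward the
#' active target ([intended_command()]); the M1 synthesizer encodes the
#' intent as 100 ms of ensemble spiking; the counts pass through the
#' gamma memory into the Actor, which greedily selects an action; the world
#' applies it; the critic source emits the scalar evaluative feedback; and
#' the Actor updates. A trial ends on target capture or after `max_steps`
#' steps; consecutive successes past the schedule's streak length anneal
#' the learning rate (consolidation).
#'
#' @param actor an [init_actor()] model (its `n_actions` must match the
#'   world's alphabet, its `n_units` the synthesizer's ensemble).
#' @param schedule a [learning_schedule()].
#' @param world a [grid_world()] or [reach_world()].
#' @param synth an [m1_synthesizer()].
#' @param targets integer vector of per-trial target indices.
#' @param config a [default_config()]-style list.
#' @param critic feedback source: `"oracle"` (cosine of movement vs direct
#'   path), `"sign"` (+1 when the step reduced the distance to the target,
#'   else -1 - the thresholded rewarding/aversive state labelling used for
#'   the two-lever reaching task), `"surrogate"` (random +-1) or `"model"`
#'   (a trained [init_critic()] reading synthetic NAcc rates).
#' @param critic_model,nacc_profiles required when `critic = "model"`.
#' @param trial_offset index of the last trial of the preceding block
#'   (for contiguous logs across blocks).
#' @return `list(log, actor, schedule, synth, world)`; the returned
#'   components carry the adapted state so blocks can be chained.
#' @export
run_closed_loop <- function(actor, schedule, world, synth, targets,
                            config = default_config(),
                            critic = c("oracle", "sign", "surrogate", "model"),
                            critic_model = NULL, nacc_profiles = NULL,
                            trial_offset = 0L) {
  critic <- match.arg(critic)
  acts <- action_names(world)
  if (actor$n_actions != length(acts))
    stop("actor has ", actor$n_actions, " actions but the world alphabet has ",
         length(acts))
  if (actor$n_units != synth$n_units)
    stop("actor expects ", actor$n_units, " units, synthesizer has ",
         synth$n_units)
  if (critic == "model") {
    if (is.null(critic_model) || is.null(nacc_profiles))
      stop("critic = 'model' needs critic_model and nacc_profiles")
    if (critic_model$n_units != length(nacc_profiles))
      stop("critic_model and nacc_profiles disagree on the NAcc ensemble size")
  }
  n_tr <- length(targets)
  max_steps <- config$trial$max_steps
  radius <- config$world$success_radius
  bw <- config$bin_width
  snap <- isTRUE(config$log$snapshots)

  tr_target <- integer(n_tr); tr_succ <- logical(n_tr)
  tr_steps <- integer(n_tr); tr_eta <- numeric(n_tr)
  step_rows <- vector("list", n_tr)
  val_rows <- vector("list", n_tr)
  snaps <- if (snap) matrix(NA_real_, n_tr, length(actor$W_o) +
                              length(actor$b_o)) else NULL

  for (k in seq_len(n_tr)) {
    world$active_target <- targets[k]
    world$position <- world$start
    tgt <- target_position(world)
    gm <- gamma_memory(actor$n_units, actor$K, actor$mu)
    if (critic == "model")
      nacc_win <- matrix(0, critic_model$n_units, critic_model$n_taps)
    succ <- FALSE
    sm <- matrix(0, max_steps, 3) # action, feedback, eta
    vm <- matrix(0, max_steps, actor$n_actions)
    s_used <- max_steps
    for (s in seq_len(max_steps)) {
      cmd <- intended_command(world)
      gen <- m1_generate(synth, cmd, bw)
      synth <- gen$synth
      gm <- gamma_step(gm, gen$counts)
      st <- gamma_state(gm)
      fw <- actor_forward(actor, st)
      a <- select_action(fw$values)
      old <- world_position(world)
      world <- apply_action(world, acts[a])
      new <- world_position(world)
      eps <- switch(critic,
        # The oracle emits the per-step gradient of reward expectation:
        # the realized decrease in distance to the target normalized by
        # the step length. This equals the cosine of the angle between
        # the movement and the direct path in the small-step limit, and
        # at step resolution it correctly scores zero-progress moves
        # (orthogonal oscillations, overshoot zig-zags) as aversive. A
        # boundary-clamped action produces no displacement and is scored
        # maximally aversive so the greedy policy cannot deadlock at a
        # wall (a neutral 0 would repeat the same clamped action forever).
        oracle = {
          mv <- sqrt(sum((new - old)^2))
          if (mv < 1e-12) -1
          else (sqrt(sum((old - tgt)^2)) - sqrt(sum((new - tgt)^2))) / mv
        },
        sign = if (sqrt(sum((new - tgt)^2)) < sqrt(sum((old - tgt)^2)))
                 1 else -1,
        surrogate = as.numeric(surrogate_feedback(1)),
        model = {
          dd <- sqrt(sum((new - tgt)^2)) - sqrt(sum((old - tgt)^2))
          g <- approach_gain(dd)
          rates <- vapply(nacc_profiles, function(p)
            max(0, p$baseline_rate + profile_sign(p) * p$modulation_depth * g),
            numeric(1))
          counts <- rpois(length(rates), rates * bw)
          nacc_win <- cbind(counts, nacc_win[, -ncol(nacc_win), drop = FALSE])
          as.numeric(critic_feedback(critic_model, nacc_win))
        })
      actor <- update_actor(actor, st, a, eps, schedule$eta)
      sm[s, ] <- c(a, eps, schedule$eta)
      vm[s, ] <- fw$values
      if (sqrt(sum((new - tgt)^2)) <= radius + 1e-12) {
        succ <- TRUE
        s_used <- s
        break
      }
    }
    if (succ) {
      schedule$streak <- schedule$streak + 1L
      if (schedule$streak >= schedule$streak_len)
        schedule <- anneal(schedule, "success_streak")
    } else schedule$streak <- 0L
    tr_target[k] <- targets[k]; tr_succ[k] <- succ
    tr_steps[k] <- s_used; tr_eta[k] <- schedule$eta
    step_rows[[k]] <- cbind(trial_offset + k, seq_len(s_used),
                            sm[seq_len(s_used), , drop = FALSE])
    val_rows[[k]] <- vm[seq_len(s_used), , drop = FALSE]
    if (snap) snaps[k, ] <- c(actor$W_o, actor$b_o)
  }
  sr <- do.call(rbind, step_rows)
  log <- structure(list(
    trials = data.frame(trial = trial_offset + seq_len(n_tr),
                        target = tr_target, success = tr_succ,
                        steps = tr_steps, eta = tr_eta),
    steps = data.frame(trial = as.integer(sr[, 1]), step = as.integer(sr[, 2]),
                       action = as.integer(sr[, 3]), feedback = sr[, 4],
                       eta = sr[, 5]),
    values = do.call(rbind, val_rows),
    snapshots = snaps,
    meta = list(critic = critic, n_actions = actor$n_actions)),
    class = "experiment_log")
  list(log = log, actor = actor, schedule = schedule, synth = synth,
       world = world)
}

#' Speed and accuracy of one 100-trial epoch
#'
#' Speed is the number of trials to converge to a consistently successful
#' policy: the index of the first trial after which every remaining trial
#' of the first 50 succeeds (`NA` if trial 50 itself fails). Accuracy is
#' the percent of successful trials among trials 51-100; for an epoch that
#' did not converge within the first 50 trials it is computed over all 100
#' trials (performance during adaptation).
#'
#' @param success logical success flags of the epoch (>= 100 trials; the
#'   first 100 are used).
#' @return an object of class `speed_accuracy`:
#'   `list(speed, accuracy, converged)`.
#' @export
compute_speed_accuracy <- function(success) {
  if (is.data.frame(success)) success <- success$success
  if (length(success) < 100) stop("an epoch needs at least 100 trials")
  s <- success[1:100]
  fails <- which(!s[1:50])
  if (length(fails) == 0) {
    speed <- 1L
  } else if (max(fails) == 50L) {
    speed <- NA_integer_
  } else {
    speed <- max(fails) + 1L
  }
  converged <- !is.na(speed)
  accuracy <- if (converged) 100 * mean(s[51:100]) else 100 * mean(s)
  structure(list(speed = speed, accuracy = accuracy, converged = converged),
            class = "speed_accuracy")
}

#' @export
print.speed_accuracy <- function(x, ...) {
  cat(sprintf("speed: %s trials, accuracy: %.1f%%%s\n",
              ifelse(is.na(x$speed), "none", x$speed), x$accuracy,
              if (x$converged) "" else " (during adaptation)"))
  invisible(x)
}

# Shared setup of the 2D grid experiments: block-tuned 12-unit ensemble,
# naive actor, fresh schedule.
setup_grid <- function(config) {
  world <- grid_world(n = config$world$n, spacing = config$world$spacing)
  tuning <- make_tuning_map(config$synth$n_units, action_names(world),
                            scheme = "block")
  synth <- m1_synthesizer(tuning, mode = config$synth$mode,
                          baseline_current = config$synth$baseline_current,
                          drive_current = config$synth$drive_current,
                          noise_sd = config$synth$noise_sd,
                          dt = config$synth$dt,
                          baseline_rate = config$synth$baseline_rate,
                          driven_rate = config$synth$driven_rate)
  actor <- init_actor(config$synth$n_units, n_actions = 4,
                      K = config$actor$K, H = config$actor$H,
                      mu = config$actor$mu,
                      init_range = config$actor$init_range,
                      hidden_update = config$actor$hidden_update,
                      pos_rate_scale = config$actor$pos_rate_scale,
                      input_scale = config$actor$input_scale,
                      hidden_rate_scale = config$actor$hidden_rate_scale)
  schedule <- learning_schedule(config$learning$eta0,
                                config$learning$anneal_factor,
                                config$learning$streak_len,
                                config$learning$floor)
  list(world = world, synth = synth, actor = actor, schedule = schedule)
}

#' Sequential novel-target experiment
#'
#' The environmental-change protocol: four corner targets presented
#' sequentially (1 upper-right, 2 lower-left, 3 upper-left, 4 lower-right),
#' 100-trial epochs each, starting from a naive Actor and warm-starting the
#' weights at every new target; an epoch whose accuracy falls below the
#' criterion is repeated (up to `seq$max_epochs` per target). Afterwards a
#' random phase presents one of the four targets per trial; at least
#' `seq$random_epochs` epochs are run (the later ones measure consolidated
#' switching performance). The learning rate is reset at the introduction
#' of each new task and annealed to zero upon consistent success.
#'
#' @param config a [default_config()]-style list.
#' @param seed master RNG seed of the run.
#' @return `list(log, metrics, actor, schedule)`; `metrics` is a data frame
#'   with one row per epoch (`phase`, `epoch`, `first_trial`, `speed`,
#'   `accuracy`).
#' @export
run_sequential_targets <- function(config = default_config(), seed = 1) {
  set.seed(seed)
  st <- setup_grid(config)
  epoch_len <- config$seq$epoch_len
  crit <- config$seq$accuracy_criterion
  logs <- list()
  metrics <- NULL
  offset <- 0L
  phases <- c(as.list(1:4), list("random"))
  for (ph in phases) {
    random <- identical(ph, "random")
    if (offset > 0) st$schedule <- anneal(st$schedule, "new_task")
    epoch <- 0L
    repeat {
      epoch <- epoch + 1L
      tgts <- if (random) sample.int(4, epoch_len, replace = TRUE)
              else rep(as.integer(ph), epoch_len)
      res <- run_closed_loop(st$actor, st$schedule, st$world, st$synth,
                             tgts, config, critic = "oracle",
                             trial_offset = offset)
      st$actor <- res$actor; st$schedule <- res$schedule
      st$synth <- res$synth
      logs[[length(logs) + 1]] <- res$log
      sa <- compute_speed_accuracy(res$log$trials$success)
      metrics <- rbind(metrics, data.frame(
        phase = if (random) "random" else paste0("target", ph),
        epoch = epoch, first_trial = offset + 1L,
        speed = sa$speed, accuracy = sa$accuracy))
      offset <- offset + epoch_len
      done <- if (random)
        epoch >= config$seq$random_epochs &&
          (sa$accuracy >= crit || epoch >= config$seq$max_epochs)
      else sa$accuracy >= crit || epoch >= config$seq$max_epochs
      if (done) break
    }
  }
  list(log = do.call(bind_logs, logs), metrics = metrics,
       actor = st$actor, schedule = st$schedule)
}

#' Tuning-map reorganization experiment
#'
#' The neural-plasticity protocol: a naive decoder learns the four-target
#' random task with the block tuning map for 100 trials; at trial 100 the
#' preferred direction of every synthetic M1 unit is shuffled (a seeded
#' permutation), the learning rate is reset (the remapping is treated as a
#' new task), and the run continues to trial 300.
#'
#' @inheritParams run_sequential_targets
#' @return `list(log, regain_trial, map_before, map_after, actor)`;
#'   `regain_trial` is the first trial index after the shuffle from which
#'   every trial through 300 succeeds (`NA` if performance never stays
#'   perfect).
#' @export
run_reorganization <- function(config = default_config(), seed = 1) {
  set.seed(seed)
  st <- setup_grid(config)
  n1 <- config$seq$epoch_len
  map_before <- st$synth$tuning
  res1 <- run_closed_loop(st$actor, st$schedule, st$world, st$synth,
                          sample.int(4, n1, replace = TRUE), config,
                          critic = "oracle")
  st$actor <- res1$actor; st$synth <- res1$synth
  st$synth$tuning <- shuffle_tuning_map(st$synth$tuning)
  st$schedule <- anneal(res1$schedule, "new_task")
  res2 <- run_closed_loop(st$actor, st$schedule, st$world, st$synth,
                          sample.int(4, 2 * n1, replace = TRUE), config,
                          critic = "oracle", trial_offset = n1)
  log <- bind_logs(res1$log, res2$log)
  s <- log$trials$success
  post <- (n1 + 1):length(s)
  ok <- post[vapply(post, function(i) all(s[i:length(s)]), logical(1))]
  list(log = log, regain_trial = if (length(ok)) ok[1] else NA_integer_,
       map_before = map_before, map_after = st$synth$tuning,
       actor = res2$actor)
}

#' Single-target 3D reaching run
#'
#' Closed-loop adaptation of a naive 12-action Actor in the two-lever 3D
#' workspace, driven by the chosen feedback source. Used for the surrogate
#' analysis: a matched pair of runs differing only in the critic source
#' quantifies how much of the decoder's competence rests on genuine
#' evaluative information.
#'
#' @inheritParams run_sequential_targets
#' @param critic `"sign"` (the thresholded rewarding/aversive state
#'   feedback of the two-lever task) or `"surrogate"`.
#' @param n_trials number of trials (default 40).
#' @return `list(log, actor, world)`.
#' @export
run_reach3d <- function(config = default_config(), seed = 1,
                        critic = c("sign", "surrogate"), n_trials = 40) {
  critic <- match.arg(critic)
  set.seed(seed)
  world <- reach_world(step_size = config$reach$step_size,
                       extent = config$reach$extent)
  dirs <- action_names(world)
  tuning <- make_tuning_map(length(dirs), dirs, scheme = "block")
  synth <- m1_synthesizer(tuning, mode = config$synth$mode,
                          baseline_current = config$synth$baseline_current,
                          drive_current = config$synth$drive_current,
                          noise_sd = config$synth$noise_sd,
                          dt = config$synth$dt,
                          baseline_rate = config$synth$baseline_rate,
                          driven_rate = config$synth$driven_rate)
  actor <- init_actor(length(dirs), n_actions = length(dirs),
                      K = config$actor$K, H = config$actor$H,
                      mu = config$actor$mu,
                      init_range = config$actor$init_range,
                      hidden_update = config$actor$hidden_update,
                      pos_rate_scale = config$actor$pos_rate_scale,
                      input_scale = config$actor$input_scale,
                      hidden_rate_scale = config$actor$hidden_rate_scale)
  schedule <- learning_schedule(config$learning$eta0,
                                config$learning$anneal_factor,
                                config$learning$streak_len,
                                config$learning$floor)
  cfg <- config
  cfg$world$success_radius <- config$reach$step_size
  res <- run_closed_loop(actor, schedule, world, synth,
                         rep(1L, n_trials), cfg, critic = critic)
  list(log = res$log, actor = res$actor, world = res$world)
}

#' @rdname run_reach3d
#' @export
run_surrogate <- function(config = default_config(), seed = 1,
                          n_trials = 40) {
  run_reach3d(config, seed, critic = "surrogate", n_trials = n_trials)
}
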