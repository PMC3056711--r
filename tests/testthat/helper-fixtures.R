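# Shared fixtures and a cache for the heavy closed-loop runs so that the
# acceptance checks and the property tests can reuse the same simulations.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

ACCEPT_SEEDS <- 1:20

# Fast config for plumbing tests: Poisson emission, no snapshots.
fast_cfg <- function(...) {
  cfg <- default_config()
  cfg$synth$mode <- "poisson"
  cfg$log$snapshots <- FALSE
  utils::modifyList(cfg, list(...))
}

grid_components <- function(cfg = default_config()) {
  world <- grid_world(n = cfg$world$n, spacing = cfg$world$spacing)
  tuning <- make_tuning_map(cfg$synth$n_units,
                            c("left", "right", "up", "down"), "block")
  synth <- m1_synthesizer(tuning, mode = cfg$synth$mode,
                          baseline_current = cfg$synth$baseline_current,
                          drive_current = cfg$synth$drive_current,
                          noise_sd = cfg$synth$noise_sd, dt = cfg$synth$dt,
                          baseline_rate = cfg$synth$baseline_rate,
                          driven_rate = cfg$synth$driven_rate)
  actor <- init_actor(cfg$synth$n_units, n_actions = 4, K = cfg$actor$K,
                      H = cfg$actor$H, mu = cfg$actor$mu,
                      init_range = cfg$actor$init_range,
                      hidden_update = cfg$actor$hidden_update,
                      pos_rate_scale = cfg$actor$pos_rate_scale,
                      input_scale = cfg$actor$input_scale,
                      hidden_rate_scale = cfg$actor$hidden_rate_scale)
  schedule <- learning_schedule(cfg$learning$eta0, cfg$learning$anneal_factor,
                                cfg$learning$streak_len, cfg$learning$floor)
  list(world = world, synth = synth, actor = actor, schedule = schedule)
}

# Single-target (upper-right) naive run, 100 trials, oracle feedback.
target1_run <- function(seed, cfg = default_config()) {
  cached(paste0("t1_", seed), {
    set.seed(seed)
    st <- grid_components(cfg)
    run_closed_loop(st$actor, st$schedule, st$world, st$synth,
                    rep(1L, 100), cfg)$log
  })
}

reorg_run <- function(seed) {
  cached(paste0("reorg_", seed), run_reorganization(seed = seed))
}

seq_run <- function(seed) {
  cached(paste0("seq_", seed), run_sequential_targets(seed = seed))
}

reach_pair <- function(seed) {
  cached(paste0("pair_", seed), list(
    oracle = run_reach3d(seed = seed, critic = "sign"),
    surrogate = run_surrogate(seed = seed)))
}

# A mixed population of NAcc profiles with known planted categories.
planted_profiles <- function(n = 60, depth = 5) {
  cats <- sample(c("dual-nonselective", "dual-selective", "uni-selective"),
                 n, replace = TRUE)
  lapply(cats, function(cc)
    nacc_profile(cc, baseline_rate = 10, modulation_depth = depth,
                 side_preference = if (cc != "dual-nonselective")
                   sample(c("left", "right"), 1) else NULL,
                 response = sample(c("excited", "inhibited"), 1)))
}

# Grid random-walk trajectories with NAcc rates and rewarding/aversive
# labels, the training material of the Critic.
critic_training_data <- function(n_trials = 40, n_steps = 30, depth = 5,
                                 n_units = 20) {
  profs <- lapply(seq_len(n_units), function(i)
    nacc_profile("dual-nonselective", baseline_rate = 10,
                 modulation_depth = depth,
                 response = sample(c("excited", "inhibited"), 1)))
  rates <- NULL; labels <- NULL; trials <- NULL
  for (k in seq_len(n_trials)) {
    pos <- c(1, 1)
    traj <- matrix(0, n_steps + 1, 2)
    traj[1, ] <- pos
    for (s in seq_len(n_steps)) {
      pos <- pos + sample(list(c(0.1, 0), c(-0.1, 0),
                               c(0, 0.1), c(0, -0.1)), 1)[[1]]
      traj[s + 1, ] <- pos
    }
    r <- synth_nacc(traj, c(0, 0), profs, integrate = FALSE)
    cnt <- bin_spikes(r, 0.1)$values
    lab <- c(-1L, label_states(traj, c(0, 0)))
    rates <- cbind(rates, cnt)
    labels <- c(labels, lab)
    trials <- c(trials, rep(k, ncol(cnt)))
  }
  list(rates = rates, labels = labels, trials = trials)
}
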