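#' NAcc response profile
#'
#' Describes how a synthetic nucleus-accumbens unit modulates its firing
#' with goal approach, following the three response classes observed in
#' accumbal recordings during two-target reaching:
#'
#' * `dual-nonselective` - responds with the same sign for both targets;
#' * `dual-selective` - excited for one target and inhibited for the other
#'   (requires a `side_preference`);
#' * `uni-selective` - responds for one target only.
#'
#' @param category one of the three classes above.
#' @param baseline_rate baseline firing rate in Hz (> 0).
#' @param modulation_depth peak rate change in Hz (>= 0).
#' @param side_preference target label (e.g. `"left"`) the unit prefers;
#'   required for the selective classes.
#' @param response `"excited"` or `"inhibited"`: sign of the response on the
#'   preferred side (and, for dual-nonselective units, on both sides).
#'   Accumbal units most often decrease firing during goal approach, so the
#'   default is `"inhibited"`.
#' @return an object of class `nacc_profile`.
#' @export
nacc_profile <- function(category = c("dual-nonselective", "dual-selective",
                                      "uni-selective"),
                         baseline_rate = 10, modulation_depth = 5,
                         side_preference = NULL,
                         response = c("inhibited", "excited")) {
  category <- match.arg(category)
  response <- match.arg(response)
  stopifnot(baseline_rate > 0, modulation_depth >= 0)
  if (category != "dual-nonselective" && is.null(side_preference))
    stop(category, " profiles require a side_preference")
  structure(list(category = category, baseline_rate = baseline_rate,
                 modulation_depth = modulation_depth,
                 side_preference = side_preference, response = response),
            class = "nacc_profile")
}

# Signed response of a profile on a given trial side: +1 excited,
# -1 inhibited, 0 unresponsive. With side = NULL (single-goal settings,
# e.g. closed-loop navigation) every profile responds with its own sign.
profile_sign <- function(profile, side = NULL) {
  s <- if (profile$response == "excited") 1 else -1
  if (is.null(side) || profile$category == "dual-nonselective") return(s)
  on_pref <- identical(side, profile$side_preference)
  switch(profile$category,
         "dual-selective" = if (on_pref) s else -s,
         "uni-selective" = if (on_pref) s else 0)
}

#' Goal-approach gain
#'
#' Logistic map from the signed per-step change in distance-to-target to a
#' reward-expectation gain in `[-1, 1]`: approaching (distance decreasing)
#' gives positive gain, retreating negative, holding still zero.
#'
#' @param delta_d per-step change in Euclidean distance to the target
#'   (same spatial units as the workspace).
#' @param scale typical step length; `delta_d` is normalized by it.
#' @param slope logistic steepness.
#' @return numeric in `[-1, 1]`.
#' @export
approach_gain <- function(delta_d, scale = 0.1, slope = 2) {
  2 * plogis(-slope * delta_d / scale) - 1
}

#' Synthesize NAcc activity along a trajectory
#'
#' Each unit's rate over bin `t` is
#' `baseline + sign * modulation_depth * E_t`, where `sign` is the
#' profile's response sign (see [nacc_profile()]) and the drive `E_t`
#' follows the unit's reward expectation. With `integrate = TRUE` (the
#' default) `E_t` is the bounded running sum of the per-step
#' [approach_gain()], so a sustained approach ramps the rate up toward its
#' peak and a sustained retreat ramps it down - the perievent signature of
#' goal-approach modulation. With `integrate = FALSE`, `E_t` is the
#' instantaneous gain itself (the gradient of reward expectation), the
#' signal a feedback-estimating Critic trains against. Rates are floored
#' at zero and spikes emitted as an inhomogeneous Poisson process at bin
#' resolution.
#'
#' @param trajectory numeric matrix, one row per time bin, of positions.
#' @param target numeric position of the goal (same coordinate frame).
#' @param profiles list of [nacc_profile()] objects, one per unit.
#' @param bin_width duration of each trajectory bin in seconds.
#' @param side optional trial side label passed to the selective profiles.
#' @param scale,slope parameters of [approach_gain()].
#' @param integrate drive mode, see Details.
#' @param kappa integration gain per step (`integrate = TRUE`).
#' @return a [spike_raster()]; the realized per-bin rates (Hz) are attached
#'   as attribute `"rates"` (units x bins).
#' @export
synth_nacc <- function(trajectory, target, profiles, bin_width = 0.1,
                       side = NULL, scale = 0.1, slope = 2,
                       integrate = TRUE, kappa = 0.2) {
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) == 0) stop("empty trajectory")
  d <- sqrt(rowSums(sweep(trajectory, 2, target)^2))
  g <- c(0, approach_gain(diff(d), scale = scale, slope = slope))
  if (integrate) { # clamped accumulation (no hysteresis past the bounds)
    acc <- 0
    for (t in seq_along(g)) g[t] <- acc <- min(1, max(-1, acc + kappa * g[t]))
  }
  nb <- length(g)
  rates <- t(vapply(profiles, function(p) {
    pmax(0, p$baseline_rate + profile_sign(p, side) * p$modulation_depth * g)
  }, numeric(nb)))
  spikes <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    counts <- rpois(nb, rates[i, ] * bin_width)
    t0 <- rep((seq_len(nb) - 1) * bin_width, counts)
    spikes[[i]] <- sort(t0 + runif(length(t0), 0, bin_width))
  }
  r <- spike_raster(spikes, unit_ids = seq_along(profiles),
                    t_start = 0, t_end = nb * bin_width)
  attr(r, "rates") <- rates
  r
}

#' Synthesize a two-target NAcc recording session
#'
#' Emulates a cued two-lever reaching session for the perievent analysis
#' and Critic training: each trial has a 2 s pre-cue baseline, then a
#' goal-approach period ending at the lever press during which each unit's
#' rate ramps linearly from baseline to `baseline + sign * modulation_depth`
#' (the ramping reward-expectation signature of goal approach).
#'
#' @param profiles list of [nacc_profile()] objects.
#' @param n_trials_per_side trials per side; sides `"left"`/`"right"` are
#'   interleaved at random.
#' @param approach_dur cue-to-press duration in seconds.
#' @param baseline_dur baseline window ahead of the cue in seconds.
#' @param iti inter-trial gap in seconds.
#' @param bin_width emission resolution in seconds.
#' @return `list(raster = <spike_raster>, events = <data.frame>)` where
#'   `events` has columns `trial`, `side`, `cue_time`, `press_time`.
#' @export
synth_nacc_session <- function(profiles, n_trials_per_side = 50,
                               approach_dur = 2, baseline_dur = 2,
                               iti = 4, bin_width = 0.1) {
  sides <- sample(rep(c("left", "right"), n_trials_per_side))
  n_tr <- length(sides)
  trial_len <- baseline_dur + approach_dur + iti
  cue <- baseline_dur + trial_len * (seq_len(n_tr) - 1)
  press <- cue + approach_dur
  total <- trial_len * n_tr
  nb <- round(total / bin_width)
  bt <- (seq_len(nb) - 0.5) * bin_width # bin centers
  spikes <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    rate <- rep(p$baseline_rate, nb)
    for (k in seq_len(n_tr)) {
      sel <- bt >= cue[k] & bt < press[k]
      ramp <- (bt[sel] - cue[k]) / approach_dur
      rate[sel] <- rate[sel] + profile_sign(p, sides[k]) *
        p$modulation_depth * ramp
    }
    counts <- rpois(nb, pmax(0, rate) * bin_width)
    t0 <- rep((seq_len(nb) - 1) * bin_width, counts)
    spikes[[i]] <- sort(t0 + runif(length(t0), 0, bin_width))
  }
  raster <- spike_raster(spikes, unit_ids = seq_along(profiles),
                         t_start = 0, t_end = total)
  list(raster = raster,
       events = data.frame(trial = seq_len(n_tr), side = sides,
                           cue_time = cue, press_time = press))
}
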