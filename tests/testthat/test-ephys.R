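test_that("perievent counts conserve the aligned spikes", {
  r <- spike_raster(list(c(1.0, 2.5, 5.95, 6.2, 9.9)), t_start = 0,
                    t_end = 12)
  events <- c(6, 10)
  p <- perievent_histogram(r, events, window = c(-4, 0), bin_width = 0.1)
  expect_equal(dim(p$per_trial_counts), c(2, 40))
  # spikes in [2, 6) for the first press, [6, 10) for the second
  expect_equal(rowSums(p$per_trial_counts), c(2, 2))
  expect_equal(sum(p$per_trial_counts),
               sum(r$spikes[[1]] >= 2 & r$spikes[[1]] < 10))
  expect_equal(p$mean_rate, colMeans(p$per_trial_counts) / 0.1)
})

test_that("the press instant is excluded by the half-open window", {
  events <- c(5, 20)
  r <- spike_raster(list(events), t_start = 0, t_end = 25)
  p <- perievent_histogram(r, events, window = c(-4, 0))
  expect_equal(sum(p$per_trial_counts), 0)
})

test_that("events without enough pre-event data are dropped with a warning", {
  r <- spike_raster(list(c(1, 2, 3)), t_start = 0, t_end = 10)
  expect_warning(p <- perievent_histogram(r, c(2, 8), window = c(-4, 0)),
                 "dropped")
  expect_equal(p$n_trials, 1)
})

test_that("a homogeneous Poisson unit has a flat perievent rate", {
  set.seed(91)
  rate <- 12
  dur <- 2200
  spikes <- sort(runif(rpois(1, rate * dur), 0, dur))
  r <- spike_raster(list(spikes), t_start = 0, t_end = dur)
  events <- seq(10, dur - 10, length.out = 200)
  p <- perievent_histogram(r, events, window = c(-4, 0))
  se <- sd(p$per_trial_counts[, 1]) / sqrt(p$n_trials) / p$bin_width
  expect_true(all(abs(p$mean_rate - rate) < 3 * max(se, 0.5)))
})

test_that("planted response profiles map to their categories", {
  set.seed(92)
  profs <- list(
    nacc_profile("dual-nonselective", modulation_depth = 8,
                 response = "inhibited"),
    nacc_profile("dual-selective", modulation_depth = 8,
                 side_preference = "left", response = "excited"),
    nacc_profile("uni-selective", modulation_depth = 8,
                 side_preference = "left", response = "inhibited"))
  ses <- synth_nacc_session(profs, n_trials_per_side = 40)
  cats <- categorize_session(ses$raster, ses$events)
  expect_equal(cats[[1]]$label, "dual-nonselective")
  expect_equal(cats[[1]]$left, "inhibited")
  expect_equal(cats[[2]]$label, "dual-selective")
  expect_equal(cats[[2]]$left, "excited")
  expect_equal(cats[[2]]$right, "inhibited")
  expect_equal(cats[[3]]$label, "uni-selective")
  ev <- ses$events
  expect_error(categorize_neuron(ses$raster, 1,
                                 ev$press_time[ev$side == "left"][1:3],
                                 ev$press_time[ev$side == "right"],
                                 ev$cue_time[ev$side == "left"][1:3],
                                 ev$cue_time[ev$side == "right"]),
               "left")
})

test_that("null units are overwhelmingly nonresponsive", {
  # the KS test on pooled tied counts is conservative, so the realized
  # per-side false-positive rate sits at or below the nominal alpha
  set.seed(93)
  n <- 60
  labels <- character(n)
  fp <- 0
  for (i in seq_len(n)) {
    prof <- list(nacc_profile("dual-nonselective", modulation_depth = 0))
    ses <- synth_nacc_session(prof, n_trials_per_side = 20)
    ct <- categorize_session(ses$raster, ses$events)[[1]]
    labels[i] <- ct$label
    fp <- fp + (ct$left != "none") + (ct$right != "none")
  }
  expect_gte(mean(labels == "nonresponsive"), 0.94)
  alpha <- 0.05
  expect_lte(fp / (2 * n), alpha + 3 * sqrt(alpha * (1 - alpha) / (2 * n)))
})

test_that("population summaries report responsive and category fractions", {
  expect_equal(population_summary(rep("nonresponsive", 5))$responsive_fraction,
               0)
  one <- population_summary(c("nonresponsive", "uni-selective"))
  expect_equal(one$responsive_fraction, 0.5)
  expect_equal(unname(one$category_fractions["uni-selective"]), 1)
  expect_error(population_summary(character(0)), "no categories")
})
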