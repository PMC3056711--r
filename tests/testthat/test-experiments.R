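test_that("speed and accuracy follow the epoch metric definitions", {
  s <- rep(TRUE, 100); s[1:2] <- FALSE
  m <- compute_speed_accuracy(s)
  expect_equal(m$speed, 3L)
  expect_equal(m$accuracy, 100)
  all_fail <- compute_speed_accuracy(rep(FALSE, 100))
  expect_true(is.na(all_fail$speed))
  expect_equal(all_fail$accuracy, 0)
  late <- rep(TRUE, 100); late[60:61] <- FALSE
  m2 <- compute_speed_accuracy(late)
  expect_equal(m2$speed, 1L)
  expect_equal(m2$accuracy, 96)
  # alternating failures: converged only at the very last trial of 50
  alt <- rep(c(FALSE, TRUE), 50)
  m3 <- compute_speed_accuracy(alt)
  expect_equal(m3$speed, 50L)
  expect_equal(m3$accuracy, 50)
  # non-converged epoch (trial 50 fails): accuracy over all 100 trials
  nc <- rep(c(TRUE, FALSE), 50)
  m4 <- compute_speed_accuracy(nc)
  expect_true(is.na(m4$speed))
  expect_equal(m4$accuracy, 50)
  expect_error(compute_speed_accuracy(rep(TRUE, 99)), "at least 100")
})

test_that("component mismatches fail before the first trial", {
  cfg <- fast_cfg()
  st <- grid_components(cfg)
  bad_actor <- init_actor(12, n_actions = 12)
  expect_error(run_closed_loop(bad_actor, st$schedule, st$world, st$synth,
                               1L, cfg), "alphabet")
  bad_actor2 <- init_actor(6, n_actions = 4)
  expect_error(run_closed_loop(bad_actor2, st$schedule, st$world, st$synth,
                               1L, cfg), "units")
  expect_error(run_closed_loop(st$actor, st$schedule, st$world, st$synth,
                               1L, cfg, critic = "model"), "critic_model")
})

test_that("closed-loop runs are deterministic under a fixed master seed", {
  cfg <- fast_cfg()
  run_once <- function() {
    set.seed(77)
    st <- grid_components(cfg)
    run_closed_loop(st$actor, st$schedule, st$world, st$synth,
                    rep(1L, 10), cfg)$log
  }
  expect_identical(run_once(), run_once())
})

test_that("a frozen model replays an identical action sequence", {
  cfg <- fast_cfg()
  cfg$learning$eta0 <- 0
  run_once <- function() {
    set.seed(78)
    st <- grid_components(cfg)
    run_closed_loop(st$actor, st$schedule, st$world, st$synth,
                    rep(1L, 5), cfg)
  }
  r1 <- run_once(); r2 <- run_once()
  expect_identical(r1$log$steps$action, r2$log$steps$action)
  # eta = 0 leaves the model bit-identical through a whole run
  set.seed(78)
  st <- grid_components(cfg)
  expect_identical(run_once()$actor, st$actor)
})

test_that("an oracle-driven run acquires the target and logs coherently", {
  cfg <- fast_cfg()
  set.seed(79)
  st <- grid_components(cfg)
  res <- run_closed_loop(st$actor, st$schedule, st$world, st$synth,
                         rep(1L, 30), cfg)
  tr <- res$log$trials
  expect_gte(sum(tr$success), 1)
  expect_equal(tr$trial, 1:30)
  expect_true(all(tr$steps[tr$success] <= cfg$trial$max_steps))
  expect_equal(nrow(res$log$steps), sum(tr$steps))
  expect_equal(nrow(res$log$values), nrow(res$log$steps))
})

test_that("epochs are repeated while the accuracy criterion is missed", {
  # an impossible task (1-step budget) forces every epoch below criterion
  cfg <- fast_cfg()
  cfg$trial$max_steps <- 1
  cfg$seq$epoch_len <- 100
  res <- run_sequential_targets(cfg, seed = 80)
  m <- res$metrics
  for (ph in paste0("target", 1:4))
    expect_equal(sum(m$phase == ph), cfg$seq$max_epochs)
  expect_equal(sum(m$phase == "random"), cfg$seq$max_epochs)
  expect_true(all(m$accuracy < cfg$seq$accuracy_criterion))
})

test_that("the reorganization run shuffles the map and resets the rate", {
  cfg <- fast_cfg()
  cfg$seq$epoch_len <- 30 # desk-scale check of the protocol mechanics
  res <- run_reorganization(cfg, seed = 81)
  expect_equal(nrow(res$log$trials), 90)
  expect_equal(sort(res$map_after$preferred),
               sort(res$map_before$preferred))
  expect_true(any(res$map_after$preferred != res$map_before$preferred))
  # learning rate is reset at the perturbation trial
  expect_equal(res$log$trials$eta[31], cfg$learning$eta0)
})

test_that("experiment logs round trip through JSON lines", {
  cfg <- fast_cfg(log = list(snapshots = TRUE))
  set.seed(82)
  st <- grid_components(cfg)
  res <- run_closed_loop(st$actor, st$schedule, st$world, st$synth,
                         rep(2L, 4), cfg)
  f <- tempfile(fileext = ".jsonl")
  write_log(res$log, f)
  back <- read_log(f)
  expect_equal(back$trials, res$log$trials)
  expect_equal(back$steps, res$log$steps)
  expect_equal(back$snapshots, res$log$snapshots, ignore_attr = TRUE)
  # corrupted line reported by number
  txt <- readLines(f)
  txt[3] <- substr(txt[3], 1, 10)
  writeLines(txt, f)
  expect_error(read_log(f), "line 3")
})
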