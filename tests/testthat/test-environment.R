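test_that("grid actions move one node and clamp at boundaries", {
  w <- grid_world()
  expect_equal(w$position, c(10, 10))
  expect_equal(apply_action(w, "up")$position, c(10, 11))
  w$position <- c(0, 19)
  expect_equal(apply_action(w, "left")$position, c(0, 19))
  expect_equal(apply_action(w, "up")$position, c(0, 19))
  expect_error(apply_action(w, "north"), "unknown action")
})

test_that("the reach world has 12 unit directions including the target diagonal", {
  w <- reach_world()
  expect_equal(ncol(w$actions), 12)
  expect_equal(unname(colSums(w$actions^2)), rep(1, 12), tolerance = 1e-12)
  w2 <- apply_action(w, "forward-right-up")
  expect_equal(w2$position, 0.1 * c(1, 1, 1) / sqrt(3))
  expect_error(reach_world(target = c(0, 0, 0), nontarget = c(0, 0, 0)),
               "must differ")
})

test_that("positions stay inside the workspace under random action sequences", {
  set.seed(41)
  w <- grid_world()
  for (i in 1:300) {
    w <- apply_action(w, sample(names(w$actions), 1))
    expect_true(all(w$position >= 0 & w$position <= 19))
  }
  r <- reach_world(extent = 0.5)
  for (i in 1:300) {
    r <- apply_action(r, sample(colnames(r$actions), 1))
    expect_true(all(abs(r$position) <= 0.5 + 1e-12))
  }
})

test_that("following the intended command reaches a corner in Manhattan steps", {
  w <- grid_world()
  w$active_target <- 1L
  steps <- 0
  while (length(cmd <- intended_command(w)) > 0) {
    w <- apply_action(w, cmd[1])
    steps <- steps + 1
  }
  expect_equal(steps, 18) # (19-10) + (19-10), well under the 50-step budget
})

test_that("trial outcomes follow the capture rule", {
  tgt <- c(1.9, 1.9)
  traj <- rbind(matrix(1, 12, 2), tgt) # reaches at step 12
  out <- trial_outcome(traj, tgt, max_steps = 50, success_radius = 0.1)
  expect_true(out$success)
  expect_equal(out$steps_used, 12)
  miss <- matrix(1, 51, 2)
  out2 <- trial_outcome(miss, tgt, max_steps = 50, success_radius = 0.1)
  expect_false(out2$success)
  expect_equal(out2$steps_used, 50)
  out3 <- trial_outcome(rbind(tgt), tgt)
  expect_true(out3$success)
  expect_equal(out3$steps_used, 0)
})

test_that("target schedules expand plans and balance the random phase", {
  plan <- list(list(target = 1, n = 100), list(target = 2, n = 100),
               list(target = 3, n = 100), list(target = 4, n = 100),
               list(target = "random", n = 100))
  set.seed(42)
  s <- sequential_target_schedule(plan)
  expect_length(s, 500)
  expect_equal(s[1:400], rep(1:4, each = 100))
  expect_equal(sequential_target_schedule(list(list(target = 1, n = 1))), 1L)
  set.seed(43)
  r <- sequential_target_schedule(list(list(target = "random", n = 4000)))
  freq <- table(r) / 4000
  expect_true(all(abs(freq - 0.25) < 0.05 * 0.25)) # within 5% of 1/4
  expect_error(sequential_target_schedule(list()), "empty epoch plan")
})
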