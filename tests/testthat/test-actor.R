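test_that("naive actors initialize uniformly in [-0.5, 0.5], reproducibly", {
  a <- init_actor(12, n_actions = 4, seed = 7)
  w <- c(a$W_h, a$b_h, a$W_o, a$b_o)
  expect_true(all(w >= -0.5 & w <= 0.5))
  b <- init_actor(12, n_actions = 4, seed = 7)
  expect_identical(a, b)
  c2 <- init_actor(12, n_actions = 4, seed = 8)
  expect_true(any(c2$W_h != a$W_h))
})

test_that("action values follow the two-layer algebra", {
  a <- init_actor(2, n_actions = 3, K = 1, H = 4, seed = 1)
  s <- c(0.5, -1)
  expect_equal(action_values(a, s),
               as.numeric(a$W_o %*% tanh(a$W_h %*% (s / a$input_scale) +
                                           a$b_h) + a$b_o))
  # zero state: bias-only values
  expect_equal(action_values(a, c(0, 0)),
               as.numeric(a$W_o %*% tanh(a$b_h) + a$b_o))
  # output layer is linear: doubling one row doubles that action's
  # bias-free value and leaves the others untouched
  a0 <- a; a0$b_o <- rep(0, 3)
  a2 <- a0; a2$W_o[2, ] <- 2 * a2$W_o[2, ]
  v1 <- action_values(a0, s); v2 <- action_values(a2, s)
  expect_equal(v2[2], 2 * v1[2])
  expect_equal(v2[-2], v1[-2])
  # purity
  expect_identical(action_values(a, s), action_values(a, s))
  expect_error(action_values(a, c(1, 2, 3)), "dimension")
})

test_that("greedy selection takes the argmax and breaks ties uniformly", {
  expect_equal(select_action(c(0.1, 0.9, 0.3)), 2)
  expect_equal(select_action(5), 1)
  set.seed(61)
  picks <- replicate(3000, select_action(c(1, 1, 1)))
  expect_true(all(abs(table(picks) / 3000 - 1 / 3) < 0.05))
  expect_error(select_action(c(1, NA)), "finite")
})

test_that("the update touches only the chosen output row when eps >= 0", {
  a <- init_actor(3, n_actions = 4, K = 2, H = 5, seed = 2)
  s <- rnorm(6)
  up <- update_actor(a, s, 3, eps = 0.8, eta = 0.1)
  expect_identical(up$W_h, a$W_h)
  expect_identical(up$b_h, a$b_h)
  expect_identical(up$W_o[-3, ], a$W_o[-3, ])
  expect_identical(up$b_o[-3], a$b_o[-3])
  expect_false(all(up$W_o[3, ] == a$W_o[3, ]))
  # aversive feedback backpropagates into the hidden layer
  dn <- update_actor(a, s, 3, eps = -0.8, eta = 0.1)
  expect_false(all(dn$W_h == a$W_h))
  expect_identical(dn$W_o[-3, ], a$W_o[-3, ])
  # degenerate cases leave the model bit-identical
  expect_identical(update_actor(a, s, 3, eps = 0, eta = 0.1), a)
  expect_identical(update_actor(a, s, 3, eps = 0.5, eta = 0), a)
  expect_error(update_actor(a, s, 3, eps = NaN, eta = 0.1), "non-finite")
})

test_that("the swapped branch convention routes hidden updates on reward", {
  a <- init_actor(3, n_actions = 2, K = 1, H = 3,
                  hidden_update = "positive", seed = 3)
  s <- rnorm(3)
  up <- update_actor(a, s, 1, eps = 0.5, eta = 0.1)
  expect_false(all(up$W_h == a$W_h))
  dn <- update_actor(a, s, 1, eps = -0.5, eta = 0.1)
  expect_identical(dn$W_h, a$W_h)
})

test_that("a rewarded action's value rises and wins a single-state bandit", {
  set.seed(62)
  a <- init_actor(4, n_actions = 4, K = 1, H = 5, seed = 62)
  s <- abs(rnorm(4)) + 1
  target_action <- 2
  v0 <- action_values(a, s)[target_action]
  a1 <- update_actor(a, s, target_action, eps = 1, eta = 0.1)
  expect_gt(action_values(a1, s)[target_action], v0)
  # oracle feedback (+1 for the rewarded arm, -1 otherwise): the rewarded
  # arm must become and stay the greedy choice within 200 steps
  m <- a
  for (i in 1:200) {
    ch <- select_action(action_values(m, s))
    m <- update_actor(m, s, ch, eps = if (ch == target_action) 1 else -1,
                      eta = 0.1)
  }
  expect_equal(select_action(action_values(m, s)), target_action)
})

test_that("learning schedules anneal on streaks and reset on new tasks", {
  sch <- learning_schedule(eta0 = 0.2, anneal_factor = 0.8)
  etas <- numeric(6)
  for (i in 1:6) {
    sch <- anneal(sch, "success_streak")
    etas[i] <- sch$eta
  }
  expect_true(all(diff(etas) < 0))
  expect_equal(etas[6], 0.2 * 0.8^6)
  sch <- anneal(sch, "new_task")
  expect_equal(sch$eta, 0.2)
  fresh <- learning_schedule(eta0 = 0.2)
  expect_equal(anneal(fresh, "reset")$eta, fresh$eta)
  flo <- learning_schedule(eta0 = 0.1, anneal_factor = 0, floor = 0.01)
  expect_equal(anneal(flo, "success_streak")$eta, 0.01)
})
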