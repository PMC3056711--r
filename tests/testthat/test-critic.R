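test_that("the cosine oracle is signed, bounded and scale invariant", {
  tgt <- c(1, 1)
  expect_equal(oracle_feedback(c(1, 1), c(0, 0), tgt), 1)
  expect_equal(oracle_feedback(c(-1, -1), c(0, 0), tgt), -1)
  expect_equal(oracle_feedback(c(1, -1), c(0, 0), tgt), 0)
  # degenerate cases are neutral, never an error
  expect_equal(oracle_feedback(c(0, 0), c(0, 0), tgt), 0)
  expect_equal(oracle_feedback(c(1, 0), tgt, tgt), 0)
  set.seed(71)
  for (i in 1:50) {
    mv <- rnorm(2); pos <- rnorm(2); tg <- rnorm(2)
    f <- oracle_feedback(mv, pos, tg)
    expect_true(f >= -1 && f <= 1)
    expect_equal(oracle_feedback(runif(1, 0.1, 10) * mv, pos, tg), f)
  }
})

test_that("td_error is the first difference of reward expectation", {
  expect_equal(td_error(0.8, 0.5), 0.3)
  expect_equal(td_error(0.4, 0.4), 0)
  expect_error(td_error(Inf, 0))
  # along a straight approach the synthetic reward expectation rises
  traj <- cbind(seq(2, 0.1, length.out = 20), seq(2, 0.1, length.out = 20))
  d <- sqrt(rowSums(traj^2))
  v <- approach_gain(c(0, diff(d)))
  expect_true(all(v[-1] > 0))
})

test_that("state labels track the sign of the distance change", {
  tgt <- c(0, 0)
  appr <- cbind(5:1, 5:1)
  expect_equal(label_states(appr, tgt), rep(1L, 4))
  expect_equal(label_states(appr[5:1, ], tgt), rep(-1L, 4))
  mixed <- rbind(c(2, 2), c(1, 2), c(2, 2))
  expect_equal(label_states(mixed, tgt), c(1L, -1L))
  expect_error(label_states(rbind(c(1, 1)), tgt), "at least 2")
})

test_that("labels agree with the cosine oracle sign on grid steps", {
  # brute force over all four single-node moves from random grid positions:
  # whenever the cosine is nonzero its sign matches the approach label; an
  # exactly orthogonal step on the integer grid always increases distance
  set.seed(72)
  moves <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  tgt <- c(0, 0)
  for (i in 1:100) {
    pos <- sample.int(19, 2)
    for (mv in moves) {
      f <- oracle_feedback(mv, pos, tgt)
      lab <- label_states(rbind(pos, pos + mv), tgt)
      if (abs(f) > 1e-12) expect_equal(sign(f), as.numeric(lab))
      else expect_equal(lab, -1L)
    }
  }
})

test_that("surrogate feedback is a reproducible fair coin", {
  set.seed(73)
  x <- surrogate_feedback(1e4)
  expect_true(all(x %in% c(-1L, 1L)))
  expect_lt(abs(mean(x)), 0.05)
  ac <- cor(x[-1], x[-length(x)])
  expect_lt(abs(ac), 3 / sqrt(length(x)))
  set.seed(73)
  expect_identical(surrogate_feedback(1e4), x)
})

test_that("critic feedback thresholds the linear output at zero", {
  m <- init_critic(4, n_taps = 3, H = 5, seed = 74)
  m$W_h[] <- 0; m$b_h[] <- 0; m$w_o[] <- 0
  win <- matrix(0, 4, 3)
  m$b_o <- 0.7
  expect_equal(critic_feedback(m, win), 1L)
  m$b_o <- -0.2
  expect_equal(critic_feedback(m, win), -1L)
  m$b_o <- 0 # exactly at threshold: conservative, not reinforced
  expect_equal(critic_feedback(m, win), -1L)
  expect_error(critic_feedback(m, matrix(0, 4, 2)), "taps")
})

test_that("backpropagation learns the rewarding/aversive mapping", {
  set.seed(75)
  dat <- critic_training_data(n_trials = 40, depth = 8)
  fit <- train_critic(dat$rates, dat$labels, dat$trials, seed = 75)
  expect_gte(fit$accuracy, 90)
  # permuted labels: held-out accuracy compatible with chance
  perm <- train_critic(dat$rates, sample(dat$labels), dat$trials, seed = 75)
  n_test <- sum(dat$trials %in% perm$test_trials)
  expect_lt(abs(perm$accuracy - 50), 300 * sqrt(0.25 / n_test))
})

test_that("degenerate critic training inputs are handled explicitly", {
  set.seed(76)
  rates <- matrix(rpois(10 * 60, 1), 10, 60)
  trials <- rep(1:6, each = 10)
  expect_warning(train_critic(rates, rep(1, 60), trials, epochs = 1),
                 "single class")
  # zero epochs: the returned model is the random initialization and the
  # reported accuracy is exactly that model's accuracy
  labels <- rep(c(1, -1), 30)
  fit0 <- train_critic(rates, labels, trials, epochs = 0, seed = 76)
  X <- bmirl:::tap_design(rates, trials, fit0$model$n_taps)
  pred <- apply(X, 2, function(x)
    if (bmirl:::critic_output(fit0$model, x) > 0) 1L else -1L)
  sel <- trials %in% fit0$test_trials
  expect_equal(fit0$accuracy, 100 * mean(pred[sel] == labels[sel]))
})
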