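# Mini-batch stochastic gradient ascent.

test_that("learning-rate schedule is the decaying power law", {
  expect_equal(learning_rate(0), 1)
  expect_equal(learning_rate(999), 1000^(-0.6), tolerance = 1e-12)
  lr <- learning_rate(0:50)
  expect_true(all(diff(lr) < 0))
  expect_equal(learning_rate(3, lr_exponent = 0, lr_scale = 0.2), 0.2)
})

test_that("a full-dataset batch reproduces the full-gradient ascent step", {
  p <- three_state(R = 1, seed = 30)
  dat <- simulate_panel(sim_config(6, p, t_max = 5), seed = 8)
  ctrl <- ctmm_control(lr_scale = 1e-3, scale = "log_q0")
  th <- params_to_theta(p, "log_q0")
  stepped <- minibatch_step(dat, th, p, batch = 1:6, d = 0, control = ctrl)
  g <- as.numeric(ctmm_score(dat, p, scale = "log_q0"))
  expect_equal(unname(stepped), unname(th + 1e-3 * g), tolerance = 1e-12)
  expect_error(minibatch_step(dat, th, p, batch = c(1, 99), d = 0, ctrl),
               "unknown subject")
})

test_that("averaging half-batches over all splits recovers the full-gradient step", {
  # 4-subject toy: mean over all (4 choose 2) half-batches of the scaled
  # batch gradient equals the full gradient exactly (linearity)
  p <- two_state(0.5, 0.4)
  dat <- simulate_panel(sim_config(4, p, t_max = 4), seed = 9)
  ctrl <- ctmm_control(lr_scale = 2e-3)
  th <- params_to_theta(p, "log_q0")
  full <- minibatch_step(dat, th, p, batch = 1:4, d = 0, control = ctrl)
  combos <- utils::combn(4, 2)
  steps <- apply(combos, 2, function(b)
    minibatch_step(dat, th, p, batch = b, d = 0, control = ctrl, M = 4))
  expect_equal(rowMeans(steps), unname(full), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("initialization policies honour their distributions and are reproducible", {
  ss <- state_space(1:4)
  st <- all_transitions(ss)
  p <- ctmm_params(rep(1, nrow(st)), matrix(0, nrow(st), 1), st,
                   covariate_names = "z1")
  ctrl <- ctmm_control(scale = "raw")
  set.seed(1)
  draws <- replicate(400, init_parameters("distance_decay_normal", p, control = ctrl))
  q0_rows <- seq(1, nrow(draws), by = 2)
  expect_true(all(draws[q0_rows, ] > 0))
  # adjacent transitions (|i-j| = 1) draw from the positive part of
  # Normal(1, 1), whose mean is 1 + dnorm(1)/pnorm(1) ~ 1.288
  idx <- sctmm:::structure_index(st)
  adj <- which(abs(idx[, 1] - idx[, 2]) == 1)
  m <- mean(draws[q0_rows[adj], ])
  expect_equal(m, 1 + dnorm(1) / pnorm(1), tolerance = 0.05)
  beta_draws <- draws[-q0_rows, ]
  expect_true(all(abs(beta_draws) <= 1))
  set.seed(7); a <- init_parameters("distance_decay_normal", p, control = ctrl)
  set.seed(7); b <- init_parameters("distance_decay_normal", p, control = ctrl)
  expect_identical(a, b)
  expect_error(init_parameters("user", p, control = ctrl), "init")
})

test_that("fits are deterministic under a fixed seed", {
  p <- two_state(0.5, 0.4)
  dat <- simulate_panel(sim_config(30, p, t_max = 5), seed = 11)
  ctrl <- ctmm_control(restarts = 2, max_iters = 40, batch_size = 10)
  f1 <- ctmm_fit(dat, p$structure, control = ctrl, seed = 99)
  f2 <- ctmm_fit(dat, p$structure, control = ctrl, seed = 99)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$restart_index, f2$restart_index)
})

test_that("the winning restart improves on its initialization", {
  p <- two_state(0.6, 0.3)
  dat <- simulate_panel(sim_config(40, p, t_max = 6), seed = 12)
  set.seed(13)
  init <- init_parameters("distance_decay_normal", p, control = ctmm_control())
  fit <- ctmm_fit(dat, p$structure, control = ctmm_control(restarts = 1, max_iters = 80,
                                                           batch_size = 20),
                  init = init, seed = 13)
  ll0 <- as.numeric(ctmm_loglik(dat, theta_to_params(init, p, "log_q0")))
  expect_gte(fit$loglik, ll0)
  # log-q0 optimization keeps every intensity strictly positive
  expect_true(all(fit$params_hat$q0 > 0))
})

test_that("full-batch SGD agrees with a quasi-Newton reference on a toy model", {
  set.seed(15)
  truth <- two_state(0.5, 0.3, beta = matrix(c(0.5, -0.3), 2, 1),
                     covariate_names = "z1")
  dat <- simulate_panel(sim_config(60, truth, t_max = 4, dummy_interval = 0.5), seed = 16)
  nll <- function(th) -as.numeric(ctmm_loglik(dat, theta_to_params(th, truth, "log_q0")))
  ngr <- function(th) -as.numeric(ctmm_score(dat, theta_to_params(th, truth, "log_q0"),
                                             scale = "log_q0"))
  th0 <- params_to_theta(truth, "log_q0")
  ref <- optim(th0, nll, ngr, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  fit <- ctmm_fit(dat, truth$structure, covariates = "z1",
                  control = ctmm_control(batch_size = 60, restarts = 1,
                                         max_iters = 2000, lr_exponent = 0,
                                         lr_scale = NULL, tol = 1e-9),
                  init = th0, seed = 17)
  expect_lt(max(abs(fit$theta_hat - ref$par)), 1e-3)
})

test_that("warmstart policy returns a usable estimate", {
  p <- two_state(0.5, 0.4)
  dat <- simulate_panel(sim_config(30, p, t_max = 5), seed = 18)
  set.seed(19)
  th <- init_parameters("warmstart_subsample", p, data = dat,
                        control = ctmm_control(warmstart_size = 20,
                                               warmstart_iters = 50,
                                               batch_size = 20))
  expect_length(th, 2)
  expect_true(all(is.finite(th)))
  ll_warm <- as.numeric(ctmm_loglik(dat, theta_to_params(th, p, "log_q0")))
  set.seed(19)
  ll_rand <- as.numeric(ctmm_loglik(
    dat, theta_to_params(init_parameters("distance_decay_normal", p,
                                         control = ctmm_control()), p, "log_q0")))
  expect_gte(ll_warm, ll_rand)
})
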