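# Hessians, Wald intervals, hazard ratios.

test_that("second directional derivative of Exp matches oracles", {
  set.seed(31)
  # A = 0 with no curvature: symmetrized product (series oracle closed form)
  E1 <- matrix(rnorm(9), 3, 3); E2 <- matrix(rnorm(9), 3, 3)
  expect_lt(max(abs(second_frechet_expm(matrix(0, 3, 3), E1, E2) -
                    (E1 %*% E2 + E2 %*% E1) / 2)), 1e-12)
  # 1x1 scalar second derivative of e^{a(theta)}
  expect_equal(second_frechet_expm(matrix(1.3), matrix(2), matrix(3), matrix(0.5))[1, 1],
               (2 * 3 + 0.5) * exp(1.3), tolerance = 1e-10)
  # random generators vs second-order finite differences
  for (i in 1:10) {
    A <- rand_generator(3) * runif(1, 0.2, 1.2)
    E1 <- matrix(rnorm(9), 3, 3); E2 <- matrix(rnorm(9), 3, 3)
    expect_lt(max(abs(second_frechet_expm(A, E1, E2) - fd_second_frechet(A, E1, E2))),
              1e-4)
  }
  expect_error(second_frechet_expm(matrix(0, 2, 2), matrix(0, 3, 3), matrix(0, 2, 2)),
               "square")
})

test_that("block-matrix Hessian matches the analytic two-state closed form", {
  # one-way chain, raw scale: n00 stay-intervals and n01 jump-intervals of
  # equal length tau give loglik n00 * (-q tau) + n01 * log(1 - e^{-q tau})
  q <- 0.4; tau <- 1.5; n00 <- 5; n01 <- 3
  p <- one_way(a = q)
  stays <- lapply(seq_len(n00), function(i)
    panel_from(c(0, tau), c(0, 0), subject_id = i))
  jumps <- lapply(seq_len(n01), function(i)
    panel_from(c(0, tau), c(0, 1), subject_id = n00 + i))
  dat <- dplyr::bind_rows(c(stays, jumps))
  H <- ctmm_hessian(dat, p, method = "pade", scale = "raw")$H
  # analytic: d2/dq2 [n01 log(1 - e^{-q tau})] (stay part is linear in q)
  u <- exp(-q * tau)
  analytic <- -n01 * tau^2 * u / (1 - u)^2
  expect_equal(H[1, 1], analytic, tolerance = 1e-9)
})

test_that("Hessians are symmetric and match dense finite differences of the score", {
  set.seed(33)
  p <- three_state(R = 1)
  dat <- simulate_panel(sim_config(25, p, t_max = 6, dummy_interval = 1), seed = 34)
  for (scale in c("raw", "log_q0")) {
    H <- ctmm_hessian(dat, p, method = "pade", scale = scale)$H
    expect_lt(max(abs(H - t(H))) / max(abs(H)), 1e-6)
    th <- params_to_theta(p, scale)
    Hn <- matrix(0, length(th), length(th))
    h <- 1e-5
    for (i in seq_along(th)) {
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      Hn[i, ] <- (as.numeric(ctmm_score(dat, theta_to_params(tp, p, scale), scale = scale)) -
                  as.numeric(ctmm_score(dat, theta_to_params(tm, p, scale), scale = scale))) / (2 * h)
    }
    Hn <- (Hn + t(Hn)) / 2
    expect_lt(max(abs(H - Hn)) / max(abs(Hn)), 1e-3)
  }
})

test_that("power-series Hessian differentiates the truncated kernel exactly", {
  # scalar chain: a stay has truncated entry 1 - q tau + (q tau)^2 / 2,
  # a jump has q tau - (q tau)^2 / 2; symbolic second derivative oracle
  q <- 0.7; tau <- 0.8
  p <- one_way(a = q)
  dat <- dplyr::bind_rows(panel_from(c(0, tau, 2 * tau), c(0, 0, 0), 1),
                          panel_from(c(0, tau), c(0, 1), 2))
  Hw <- ctmm_hessian(dat, p, method = "power_series", scale = "raw")$H
  f <- function(q) 2 * log(1 - q * tau + (q * tau)^2 / 2) +
    log(q * tau - (q * tau)^2 / 2)
  h <- 1e-5
  expect_equal(Hw[1, 1], (f(q + h) - 2 * f(q) + f(q - h)) / h^2, tolerance = 1e-4)
})

test_that("power-series Hessian converges to the exact one as intervals shrink", {
  set.seed(35)
  p <- three_state(R = 1)
  dat <- simulate_panel(sim_config(10, p, t_max = 3, dummy_interval = 0.4), seed = 36)
  err <- vapply(c(1, 0.5, 0.25), function(scl) {
    d <- dat; d$time <- d$time * scl  # same paths on a compressed clock
    Hp <- ctmm_hessian(d, p, method = "pade", scale = "raw")$H
    Hw <- ctmm_hessian(d, p, method = "power_series", scale = "raw")$H
    max(abs(Hp - Hw))
  }, numeric(1))
  # truncation error contracts under interval halving; jump intervals,
  # whose leading Hessian term is O(1) in tau, make the absolute
  # difference O(tau^2), i.e. roughly a factor 4 per halving
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)
})

test_that("Wald report: delta-method intervals, SE scaling and rejection flags", {
  set.seed(37)
  truth <- two_state(0.5, 0.3, beta = matrix(c(0.4, 0), 2, 1), covariate_names = "z1")
  dat <- simulate_panel(sim_config(120, truth, t_max = 8), seed = 38)
  fit <- ctmm_fit(dat, truth$structure, covariates = "z1",
                  control = ctmm_control(restarts = 1, max_iters = 150, batch_size = 60),
                  seed = 39)
  ci <- ctmm_ci(dat, fit)
  expect_true(all(ci$conf.low <= ci$estimate & ci$estimate <= ci$conf.high))
  expect_true(all(ci$conf.low[ci$type == "q0"] > 0))  # exp-transformed intervals
  expect_equal(ci$reject, abs(ci$statistic) > qnorm(0.975))
  # duplicating every subject doubles the information: SEs shrink by sqrt(2)
  dat2 <- dat
  dat2$subject_id <- dat2$subject_id + max(dat$subject_id)
  both <- dplyr::bind_rows(dat, dat2)
  fit2 <- fit
  ci2 <- ctmm_ci(both, fit)
  expect_equal(ci$std.error / ci2$std.error, rep(sqrt(2), nrow(ci)), tolerance = 0.05)
})

test_that("hazard ratios transform coefficient intervals", {
  ci <- tibble::tibble(term = c("q0(0->1)", "beta(0->1,z1)"),
                       type = c("q0", "beta"), transition = "0->1",
                       covariate = c(NA, "z1"), estimate = c(0.5, 0),
                       std.error = c(0.05, 0.2), statistic = c(10, 0),
                       conf.low = c(0.41, -0.392), conf.high = c(0.61, 0.392),
                       reject = c(TRUE, FALSE))
  hr <- hazard_ratios(ci)
  expect_equal(hr$hr, 1)                       # beta = 0 -> HR 1
  expect_lt(hr$conf.low, 1); expect_gt(hr$conf.high, 1)
  # negative covariate value flips and re-orders the interval
  hr2 <- hazard_ratios(ci, at = c(z1 = -2))
  expect_equal(hr2$conf.low, exp(-2 * 0.392), tolerance = 1e-12)
  expect_true(hr2$conf.low <= hr2$conf.high)
  expect_error(hazard_ratios(ci[ci$type == "q0", ]), "no coefficients")
})

test_that("hessian objects report conditioning and definiteness", {
  set.seed(40)
  truth <- two_state(0.5, 0.3)
  dat <- simulate_panel(sim_config(60, truth, t_max = 8), seed = 41)
  fit <- ctmm_fit(dat, truth$structure,
                  control = ctmm_control(restarts = 1, max_iters = 100, batch_size = 30),
                  seed = 42)
  h <- ctmm_hessian(dat, fit)
  expect_true(h$positive_definite)   # observed information at a maximum
  expect_true(is.finite(h$rcond))
  expect_identical(dim(h$H), c(2L, 2L))
})
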