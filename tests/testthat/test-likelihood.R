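# Log-likelihood and exact score via block-matrix Frechet derivatives.

test_that("Frechet derivative of Exp matches closed forms and finite differences", {
  # A = 0: the integrand collapses to the direction itself
  E <- matrix(rnorm(9), 3, 3)
  expect_equal(frechet_derivative_expm(matrix(0, 3, 3), E), E, tolerance = 1e-12)
  # 1x1 scalar chain rule
  expect_equal(frechet_derivative_expm(matrix(1.3), matrix(2))[1, 1],
               2 * exp(1.3), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    A <- rand_generator(3) * runif(1, 0.2, 1.5)
    E <- matrix(rnorm(9), 3, 3)
    expect_lt(max(abs(frechet_derivative_expm(A, E) - fd_frechet(A, E))), 1e-6)
  }
  expect_error(frechet_derivative_expm(matrix(0, 2, 2), matrix(0, 3, 3)), "square")
})

test_that("Frechet derivative is linear in its direction argument", {
  set.seed(6)
  A <- rand_generator(4) * 0.8
  E1 <- matrix(rnorm(16), 4, 4); E2 <- matrix(rnorm(16), 4, 4)
  lhs <- frechet_derivative_expm(A, 2.5 * E1 - 1.3 * E2)
  rhs <- 2.5 * frechet_derivative_expm(A, E1) - 1.3 * frechet_derivative_expm(A, E2)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("interval generator derivatives match their closed forms and finite differences", {
  set.seed(8)
  p <- three_state(R = 2)
  tau <- 0.9
  # q0 derivative with beta = 0: tau at (i, j), -tau at (i, i)
  p0 <- ctmm_params(p$q0, matrix(0, 6, 2), p$structure, covariate_names = c("z1", "z2"))
  D <- interval_dQ(p0, c(0.4, -0.2), tau, which = 1)   # q0 of transition 1 (0->1)
  expect_equal(D[1, 2], tau)
  expect_equal(D[1, 1], -tau)
  expect_equal(sum(abs(D)), 2 * tau)
  # beta derivative with z_r = 0 vanishes
  Db <- interval_dQ(p, c(0, 0.3), tau, which = 2)       # beta(0->1, z1), z1 = 0
  expect_equal(Db, matrix(0, 3, 3))
  # finite difference over every parameter, both scales
  z <- c(0.4, -0.7)
  for (scale in c("raw", "log_q0")) {
    th <- params_to_theta(p, scale)
    for (w in seq_along(th)) {
      h <- 1e-7
      tp <- th; tp[w] <- tp[w] + h
      tm <- th; tm[w] <- tm[w] - h
      fd <- (build_intensity_matrix(theta_to_params(tp, p, scale), z) -
             build_intensity_matrix(theta_to_params(tm, p, scale), z)) * tau / (2 * h)
      expect_lt(max(abs(interval_dQ(p, z, tau, w, scale) - unname(fd))), 1e-6)
    }
  }
})

test_that("log-likelihood matches closed forms on two-state chains", {
  # one-way chain, single 0 -> 0 interval: log e^{-a tau} = -1
  p <- one_way(a = 0.5)
  dat <- panel_from(c(0, 2), c(0, 0))
  expect_equal(as.numeric(ctmm_loglik(dat, p)), -1, tolerance = 1e-12)
  # absorbing state: probability 1 per interval
  dat_abs <- panel_from(c(0, 1, 2, 5), c(1, 1, 1, 1))
  expect_equal(as.numeric(ctmm_loglik(dat_abs, p)), 0)
  # additivity over subjects
  p3 <- three_state(R = 1, seed = 2)
  d1 <- simulate_panel(sim_config(1, p3, t_max = 5), seed = 3)
  d2 <- simulate_panel(sim_config(1, p3, t_max = 5), seed = 4)
  d2$subject_id <- 2
  both <- dplyr::bind_rows(d1, d2)
  expect_equal(as.numeric(ctmm_loglik(both, p3)),
               as.numeric(ctmm_loglik(d1, p3)) + as.numeric(ctmm_loglik(d2, p3)))
  # permutation invariance
  perm <- dplyr::bind_rows(d2, d1)
  expect_equal(as.numeric(ctmm_loglik(perm, p3)), as.numeric(ctmm_loglik(both, p3)))
})

test_that("score matches closed forms, additivity and finite differences", {
  # scalar case: d/dq log e^{-q tau} = -tau (raw scale)
  p <- one_way(a = 0.5)
  dat <- panel_from(c(0, 2), c(0, 0))
  expect_equal(unname(as.numeric(ctmm_score(dat, p, scale = "raw"))), -2,
               tolerance = 1e-10)
  # duplicated trajectory doubles the score
  p3 <- three_state(R = 1, seed = 9)
  d1 <- simulate_panel(sim_config(1, p3, t_max = 6), seed = 5)
  d2 <- d1; d2$subject_id <- 2
  g1 <- as.numeric(ctmm_score(d1, p3, scale = "raw"))
  g2 <- as.numeric(ctmm_score(dplyr::bind_rows(d1, d2), p3, scale = "raw"))
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
  # finite differences on random small instances
  set.seed(10)
  for (R in c(0, 1, 2)) {
    p <- three_state(R = R)
    dat <- simulate_panel(sim_config(8, p, t_max = 5, dummy_interval = 1), seed = R + 1)
    for (scale in c("raw", "log_q0")) {
      g <- as.numeric(ctmm_score(dat, p, scale = scale))
      gn <- fd_score(dat, p, scale)
      expect_lt(max(abs(g - gn) / pmax(abs(gn), 1)), 1e-5)
    }
  }
})

test_that("raw and log-scale gradients obey the chain rule", {
  p <- three_state(R = 2, seed = 14)
  dat <- simulate_panel(sim_config(10, p, t_max = 5), seed = 6)
  g_raw <- as.numeric(ctmm_score(dat, p, scale = "raw"))
  g_log <- as.numeric(ctmm_score(dat, p, scale = "log_q0"))
  th <- params_to_theta(p, "raw")
  q0_slots <- seq(1, length(th), by = 1 + 2)
  expect_equal(unname(g_log[q0_slots]), unname(g_raw[q0_slots] * th[q0_slots]),
               tolerance = 1e-10)
  expect_equal(g_log[-q0_slots], g_raw[-q0_slots])
})

test_that("log-likelihood is invariant to consistent state relabelling", {
  p <- three_state(R = 1, seed = 17)
  dat <- simulate_panel(sim_config(10, p, t_max = 5), seed = 7)
  # relabel states 0,1,2 -> 2,0,1 with consistently permuted parameters
  perm <- c(2, 0, 1)  # new label of old state i
  ss2 <- state_space(0:2)
  st2 <- transition_structure(perm[sctmm:::state_index(p$state_space, p$structure$from) + 1],
                              perm[sctmm:::state_index(p$state_space, p$structure$to) + 1],
                              ss2)
  p2 <- ctmm_params(unname(p$q0), p$beta, st2, covariate_names = p$covariate_names)
  dat2 <- dat
  dat2$state <- perm[dat$state + 1]
  expect_equal(as.numeric(ctmm_loglik(dat2, p2)), as.numeric(ctmm_loglik(dat, p)),
               tolerance = 1e-12)
})

test_that("structurally impossible observed transitions are flagged, not silent", {
  p <- one_way(a = 0.5)           # 1 -> 0 is impossible
  dat <- panel_from(c(0, 1), c(1, 0))
  ll <- ctmm_loglik(dat, p)
  expect_equal(attr(ll, "n_floored"), 1)
  expect_true(as.numeric(ll) < -600)  # log of the 1e-300 floor
  g <- ctmm_score(dat, p)
  expect_true(attr(g, "degenerate"))
  expect_false(any(is.finite(g)))
  # non-increasing times are an input error
  expect_error(ctmm_loglik(panel_from(c(0, 0), c(0, 0)), p), "non-increasing")
})
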