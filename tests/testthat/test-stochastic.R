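test_that("pure birth events are Poisson-distributed", {
  q <- birth_death_params(beta = 1, delta = 1e-9)  # dilution negligible
  net <- build_network("open_loop_dephos", q, 0)
  ns <- ssa_ensemble(net, t_probe = 50, n_runs = 10000, seed = 3)
  row <- ns[ns$species == "PH", ]
  expect_lt(abs(row$mean - 50), 3 * row$se_mean)
  expect_lt(abs(row$variance / row$mean - 1), 0.05)
})

test_that("stationary birth-death statistics match the Poisson law", {
  q <- birth_death_params(beta = 2, delta = 0.02)  # mean = variance = 100
  net <- build_network("open_loop_dephos", q, 0)
  ns <- ssa_ensemble(net, t_probe = 400, n_runs = 3000, seed = 11)
  row <- ns[ns$species == "PH", ]
  expect_lt(abs(row$mean - 100), 3 * row$se_mean)
  expect_lt(abs(row$variance - 100), 10)
  expect_lt(abs(row$cv - 0.1), 3 * row$se_cv)
})

test_that("the event sequence is reproducible for a fixed seed", {
  p <- nominal_params()
  net <- build_network("wild_type", p, 2)
  a <- ssa_simulate(net, t_end = 30, seed = 9)
  b <- ssa_simulate(net, t_end = 30, seed = 9)
  expect_identical(a$time, b$time)
  expect_identical(a$state, b$state)
  d <- ssa_simulate(net, t_end = 30, seed = 10)
  expect_false(identical(a$time, d$time))
  # piecewise-constant integer states
  expect_true(all(a$state == round(a$state)))
  expect_error(ssa_simulate(net, x0 = rep(0.5, 5), t_end = 1, seed = 1),
               "integer")
})

test_that("SSA guards against runaway event budgets", {
  p <- nominal_params()
  net <- build_network("wild_type", p, 10)
  expect_error(ssa_simulate(net, t_end = 1000, seed = 1, max_events = 100),
               "event budget")
})

test_that("LNA reproduces exact moments of linear networks", {
  # birth-death: stationary variance equals the mean (Poisson)
  q <- birth_death_params(beta = 2, delta = 0.02)
  net <- build_network("open_loop_dephos", q, 0)
  mom <- lna_moments(net, t_grid = c(0, 2000))
  i <- match("PH", net$species)
  expect_equal(unname(mom$mean[2, "PH"]), 100, tolerance = 1e-6)
  expect_equal(mom$cov[i, i, 2], 100, tolerance = 1e-4)
  # two-species linear cascade: stationary covariance solves the algebraic
  # Lyapunov equation (independent Kronecker-product solve)
  q2 <- rate_params(kap_max = 0.5, Kda = 1, kt = 0, kp = 0, ktc = 0, kpc = 0,
                    beta_HK = 1, beta_RR = 0, delta = 0.01, kout_max = 0)
  net2 <- build_network("wild_type", q2, I = 1e9)  # saturated kap ~ kap_max
  mom2 <- lna_moments(net2, t_grid = c(0, 5000))
  k <- length(mom2$time)
  ss <- mom2$mean[k, ]
  J <- tcsfb:::rhs_jacobian(net2, ss)
  D <- net2$stoich %*% (propensities(net2, ss) * t(net2$stoich))
  n <- nrow(J)
  Sig_alg <- matrix(solve(J %x% diag(n) + diag(n) %x% J, -as.numeric(D)), n, n)
  idx <- match(c("HK", "HKp"), net2$species)
  dev <- max(abs(mom2$cov[idx, idx, k] - Sig_alg[idx, idx]))
  expect_lt(dev / max(abs(Sig_alg[idx, idx])), 1e-5)
})

test_that("the LNA mean equals the deterministic trajectory", {
  p <- nominal_params()
  net <- build_network("closed_loop_phos_seq", p, 2)
  tg <- seq(0, 500, 100)
  mom <- lna_moments(net, t_grid = tg)
  det <- simulate_network(net, t_end = 500, times = tg)
  expect_rel_equal(mom$mean[-1, ], det$state[-1, ], 1e-5)
})

test_that("LNA covariances stay symmetric positive semidefinite", {
  p <- nominal_params()
  p$P <- 1
  net <- build_network("closed_loop_phos_seq", p, 10)
  mom <- lna_moments(net, t_grid = seq(0, 1000, 250))
  for (k in 2:5) {
    Sig <- mom$cov[, , k]
    expect_equal(Sig, t(Sig))
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
  }
})

test_that("cv-vs-mean tables coincide with the wild type at zero feedback", {
  sc <- scenario("noise")
  sc$inducer_grid <- c(2, 10)
  sc$P_grid <- c(0, 1)
  tab <- cv_vs_mean_curve(sc, t_probe = 1000)
  wt <- tab[tab$architecture == "wild_type", ]
  cl0 <- tab[tab$architecture == "closed_loop_phos_seq" & tab$P == 0, ]
  expect_equal(cl0$mean[order(cl0$I_mM)], wt$mean[order(wt$I_mM)],
               tolerance = 1e-6)
  expect_equal(cl0$cv[order(cl0$I_mM)], wt$cv[order(wt$I_mM)],
               tolerance = 1e-6)
  # sorted by mean, with cv defined everywhere on this grid
  expect_false(is.unsorted(tab$mean))
  expect_true(all(is.finite(tab$cv)))
})
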