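p <- nominal_params()

test_that("closed-form steady states have the documented structure", {
  # without sequestration protein the two motifs coincide (duality at zero)
  expect_identical(rrp_star_phos_seq(p, 2), rrp_star_dephos(p, 2))
  # strictly decreasing in the sequestration totals
  vals_sr <- vapply(c(0, 5, 10, 20), function(b) {
    q <- p
    q$beta_SR <- b
    rrp_star_phos_seq(q, 2)
  }, numeric(1))
  expect_true(all(diff(vals_sr) < 0))
  vals_ph <- vapply(c(0, 0.05, 0.2, 1), function(b) {
    q <- p
    q$beta_PH <- b
    rrp_star_dephos(q, 2)
  }, numeric(1))
  expect_true(all(diff(vals_ph) < 0))
  # bound: each bracketed factor is at most one
  for (I in c(0.1, 1, 10)) {
    kap <- autophosphorylation_rate(I, p)
    expect_lte(rrp_star_phos_seq(p, I), kap / p$kp + 1e-12)
    expect_lte(rrp_star_dephos(p, I), kap / p$kp + 1e-12)
  }
  q <- p
  q$kp <- 0
  expect_error(rrp_star_phos_seq(q, 1), "kp = 0")
})

test_that("the two motifs are algebraically dual under the matched scaling", {
  # ktc SR_tot = kpc PH_tot (kt RR_tot + delta)/(kp HK_tot + delta) makes the
  # two closed forms identical
  for (s in 1:50) {
    q <- perturb_params(nominal_params(), 0.5, seed = s)
    q$beta_PH <- stats::runif(1, 0, 2)
    tot <- derived_totals(q)
    sr_tot <- q$kpc * tot[["PH_tot"]] *
      (q$kt * tot[["RR_tot"]] + q$delta) / (q$kp * tot[["HK_tot"]] + q$delta) / q$ktc
    qs <- q
    qs$beta_SR <- sr_tot * q$delta
    qs$beta_PH <- 0
    qd <- q
    qd$beta_SR <- 0
    expect_rel_equal(rrp_star_phos_seq(qs, 2), rrp_star_dephos(qd, 2), 1e-10)
  }
})

test_that("closed forms agree with the full model in the valid regime", {
  for (b_sr in c(0, 10)) {
    q <- p
    q$beta_SR <- b_sr
    rep <- check_assumptions(q, 10, "phos_seq")
    expect_true(rep$valid)
    expect_lt(rep$relative_error, 0.05)
  }
  q <- p
  q$beta_PH <- 0.03
  rep <- check_assumptions(q, 10, "dephos")
  expect_true(rep$valid)
  expect_lt(rep$relative_error, 0.05)
})

test_that("assumption diagnostics flag the dilution-dominated regime", {
  q <- p
  q$kt <- q$kt * 1e-4
  q$kp <- q$kp * 1e-4
  rep <- check_assumptions(q, 10, "phos_seq")
  expect_false(rep$valid)
  expect_true(all(c("rr_frac", "rate_ineq") %in% names(rep$assumption_ratios)))
  expect_lt(rep$assumption_ratios[["rate_ineq"]], 10)
})

test_that("resource-competition steady state matches its ODE and limits", {
  rp <- list(T_Y = 2, T_S = 1, beta_Y = 3, beta_S = 2, J_Y = 0.2, J_S = 0.4,
             delta = 0.05)
  # no competition: basal expression K_Y * beta_Y
  rp0 <- rp
  rp0$J_Y <- rp0$J_S <- 0
  expect_equal(resource_steady_state(rp0), rp$T_Y / rp$delta * rp$beta_Y)
  # strictly decreasing in the competitor's expression rate
  vals <- vapply(c(0, 1, 4, 10), function(b) {
    r <- rp
    r$beta_S <- b
    resource_steady_state(r)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # long-time limit of the two-species ODE (independent integration oracle)
  out <- deSolve::ode(y = c(Y = 0, S = 0), times = c(0, 2000),
                      func = function(t, y, parms) list(resource_rhs(y, rp)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(out[2, "Y"]), resource_steady_state(rp), tolerance = 1e-8)
})

test_that("the algebraic stability condition matches the Jacobian spectrum", {
  # trivially stable when nothing is phosphorylated
  tot <- derived_totals(p)
  ss0 <- c(HK = unname(tot["HK_tot"]), RR = unname(tot["RR_tot"]))
  cond0 <- local_stability_condition(ss0, p, 0)
  expect_true(cond0$stable)
  expect_true(cond0$sufficient)
  # random parameter scan: condition <=> negative real parts of the reduced
  # 2-state Jacobian (eigenvalue oracle), and sufficient => main condition
  n_agree <- 0
  for (s in 1:50) {
    q <- perturb_params(nominal_params(), 0.6, seed = 100 + s)
    q$beta_SR <- 0
    ss <- tcsfb:::reduced_steady_state(q, 2)
    cond <- local_stability_condition(ss[c("HK", "RR")], q, 2)
    J <- reduced_jacobian_wt <- local({
      jac <- tcsfb:::reduced_jacobian(ss, q, 2, beta_SR = 0)
      jac[1:2, 1:2]
    })
    eig_stable <- max(Re(eigen(J, only.values = TRUE)$values)) < 0
    if (cond$stable) expect_true(eig_stable)
    if (cond$sufficient) expect_true(cond$stable)
    n_agree <- n_agree + (cond$stable == eig_stable)
  }
  expect_gte(n_agree, 49)  # trace is always negative here, so det decides
})

test_that("the reduced model is cooperative and a broken sign is caught", {
  chk <- monotone_structure_check(p, 2, beta_SR = 10, n_sample = 500, seed = 1)
  expect_true(chk$monotone)
  expect_null(chk$witness)
  bad_jac <- function(x) {
    J <- tcsfb:::reduced_jacobian(x, p, 2, beta_SR = 10)
    J[1, 2] <- -abs(J[1, 2]) - 1e-6
    J
  }
  chk_bad <- monotone_structure_check(p, 2, beta_SR = 10, n_sample = 500,
                                      seed = 1, jac = bad_jac)
  expect_false(chk_bad$monotone)
  expect_length(chk_bad$witness, 3)
})

test_that("ordered initial conditions stay ordered along the flow", {
  tot <- derived_totals(p)
  box <- c(tot[["HK_tot"]], tot[["RR_tot"]], 10 / p$delta)
  set.seed(42)
  for (i in 1:20) {
    lo <- runif(3) * box * 0.5
    hi <- lo + runif(3) * (box - lo)
    s_lo <- simulate_reduced(lo, p, 2, t_end = 2000, beta_SR = 10)
    s_hi <- simulate_reduced(hi, p, 2, t_end = 2000, beta_SR = 10)
    expect_true(all(s_hi$state - s_lo$state >= -1e-7))
  }
})

test_that("corner trajectories converge to a common globally attractive point", {
  cc <- corner_convergence(p, 2, beta_SR = 10)
  expect_true(cc$attractive)
  expect_lt(cc$gap, 1e-6)
  expect_length(cc$x_star, 3)
})

test_that("steady-state RR rises monotonically with the SR production rate", {
  scan <- beta_sr_scan(p, 2, beta_SR_grid = c(0, 2, 5, 10, 20, 40))
  expect_true(all(diff(scan$RR_star) > 0))
  expect_true(all(diff(scan$RRp_star) < 0))
})
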