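p1 <- nominal_params()
p1$P <- 1

# one frequency-domain transfer evaluation, independent of the package's
tf_at <- function(A, B, C, w) C %*% solve(diag(1i * w, nrow(A)) - A, B)

test_that("process linearization matches finite differences at the operating point", {
  proc <- linearize_process("closed_loop_phos_seq", p1, 2)
  expect_lt(proc$residual, 1e-8)
  expect_lt(sum(diag(proc$A)), 0)
  x <- proc$x_star
  u <- proc$u_star
  eps <- 1e-6
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    dx <- x
    dx[j] <- dx[j] + h
    fd <- (proc$f(dx, u) - proc$f(x, u)) / h
    expect_rel_equal(fd, proc$A[, j], 1e-5)
  }
  h <- eps * max(1, abs(u))
  expect_rel_equal((proc$f(x, u + h) - proc$f(x, u)) / h, as.numeric(proc$B_u), 1e-5)
})

test_that("controller linearization matches finite differences", {
  for (arch in c("closed_loop_phos_seq", "closed_loop_dephos")) {
    proc <- linearize_process(arch, p1, 2)
    ctrl <- linearize_controller(proc)
    xc <- ctrl$xc_star
    y <- proc$x_star
    eps <- 1e-6
    for (j in seq_along(xc)) {
      h <- eps * max(1, abs(xc[j]))
      dxc <- xc
      dxc[j] <- dxc[j] + h
      fd <- (ctrl$g(dxc, y) - ctrl$g(xc, y)) / h
      expect_rel_equal(fd, ctrl$A[, j], 1e-5)
    }
    for (j in seq_along(y)) {
      h <- eps * max(1, abs(y[j]))
      dy <- y
      dy[j] <- dy[j] + h
      fd <- (ctrl$g(xc, dy) - ctrl$g(xc, y)) / h
      expect_rel_equal(fd, ctrl$B[, j], 1e-4)
    }
  }
})

test_that("the closed-loop linearization is stable at nominal parameters", {
  proc <- linearize_process("closed_loop_phos_seq", p1, 2)
  ctrl <- linearize_controller(proc)
  Acl <- rbind(cbind(proc$A, proc$B_u %*% ctrl$C),
               cbind(ctrl$B %*% proc$C, ctrl$A))
  expect_lt(max(Re(eigen(Acl, only.values = TRUE)$values)), 0)
})

test_that("zero feedback strength silences the controller", {
  p0 <- nominal_params()
  p0$P <- 0
  proc <- linearize_process("closed_loop_phos_seq", p0, 2)
  ctrl <- linearize_controller(proc)
  expect_true(all(abs(ctrl$B) < 1e-12))
  for (w in c(1e-4, 1e-2, 1)) {
    expect_lt(max(Mod(tf_at(ctrl$A, ctrl$B, ctrl$C, w))), 1e-12)
  }
})

test_that("the phosphatase controller is first order with gain P h'/(jw + delta)", {
  proc <- linearize_process("closed_loop_dephos", p1, 2)
  ctrl <- linearize_controller(proc)
  rrp <- unname(proc$operating_point["RRp"])
  hp <- p1$P * tcsfb:::output_initiation_grad(rrp, p1)
  for (w in c(1e-4, 1e-2, 0.5)) {
    K <- tf_at(ctrl$A, ctrl$B, ctrl$C, w)
    expect_equal(K[1, 2], hp / (1i * w + p1$delta), tolerance = 1e-10)
    expect_identical(K[1, 1], 0 + 0i)
  }
})

test_that("the controller's dc gain scales linearly with feedback strength", {
  proc <- linearize_process("closed_loop_phos_seq", p1, 2)
  ctrl1 <- linearize_controller(proc)
  proc2 <- proc
  proc2$params$P <- 2 * p1$P  # same operating point, doubled gain
  ctrl2 <- linearize_controller(proc2)
  expect_equal(ctrl2$B[, 2], 2 * ctrl1$B[, 2], tolerance = 1e-12)
})

test_that("open loop gives S = I and all channels roll off to unity", {
  proc <- linearize_process("closed_loop_phos_seq", p1, 2)
  fr0 <- sensitivity_response(proc, NULL, omega = c(1e-4, 1e-2, 1))
  expect_equal(fr0$magnitude, rep(1, 3), tolerance = 1e-12)
  ctrl <- linearize_controller(proc)
  fr_hi <- sensitivity_response(proc, ctrl, omega = c(1e5, 1e6))
  expect_rel_equal(fr_hi$magnitude, c(1, 1), 1e-3)
})

test_that("the return-difference identity holds on the grid", {
  proc <- linearize_process("closed_loop_phos_seq", p1, 2)
  ctrl <- linearize_controller(proc)
  om <- 10^seq(-4, 1, by = 0.5)
  fr <- sensitivity_response(proc, ctrl, om)
  for (k in seq_along(om)) {
    G <- tf_at(proc$A, proc$B_u, proc$C, om[k])
    K <- tf_at(ctrl$A, ctrl$B, ctrl$C, om[k])
    resid <- fr$S[, , k] %*% (diag(2) - G %*% K) - diag(2)
    expect_lt(max(Mod(resid)), 1e-10)
  }
})

test_that("the grid maximum is refinement-stable and consistent", {
  om_fine <- default_omega_grid()
  om_coarse <- 10^seq(-6, 2, by = 1 / 100)
  gm_f <- sensitivity_grid_max("closed_loop_phos_seq", nominal_params(),
                               I_list = 2, P_list = 1, omega = om_fine)
  gm_c <- sensitivity_grid_max("closed_loop_phos_seq", nominal_params(),
                               I_list = 2, P_list = 1, omega = om_coarse)
  expect_rel_equal(gm_c$hinf, gm_f$hinf, 1e-3)
  # single-point grids reduce to the per-response grid maximum
  proc <- linearize_process("closed_loop_phos_seq", p1, 2)
  ctrl <- linearize_controller(proc)
  fr <- sensitivity_response(proc, ctrl, om_fine)
  expect_rel_equal(gm_f$hinf, fr$hinf, 1e-3)
  expect_gte(gm_f$hinf, fr$hinf)
})
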