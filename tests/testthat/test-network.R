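p <- nominal_params()

test_that("autophosphorylation rate is Michaelis-Menten in the inducer", {
  expect_identical(autophosphorylation_rate(0, p), 0)
  expect_equal(autophosphorylation_rate(p$Kda, p), p$kap_max / 2)
  expect_gte(autophosphorylation_rate(99 * p$Kda, p), 0.99 * p$kap_max)
  expect_error(autophosphorylation_rate(-1, p), ">= 0")
  I <- seq(0, 50, length.out = 200)
  r <- autophosphorylation_rate(I, p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= p$kap_max))
})

test_that("output initiation rate is a bounded Hill function of RRp", {
  expect_identical(output_initiation_rate(0, p), 0)
  expect_equal(output_initiation_rate(p$Kdr, p), p$kout_max / 2)
  p4 <- p
  p4$n <- 2 * p$n
  # below the half-max point, higher cooperativity lowers the output
  expect_lt(output_initiation_rate(p$Kdr / 2, p4),
            output_initiation_rate(p$Kdr / 2, p))
  expect_error(output_initiation_rate(-0.1, p), ">= 0")
  x <- seq(0, 500, length.out = 300)
  r <- output_initiation_rate(x, p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= p$kout_max))
})

test_that("network construction validates its inputs", {
  expect_error(build_network("no_such", p, 1))
  pna <- p
  pna$P <- NA_real_
  expect_error(build_network("closed_loop_phos_seq", pna, 1), "P is undefined")
  expect_error(build_network("molecular_seq_feedback", p, 1), "k_bind")
  expect_error(build_network("transcriptional_feedback", p, 1), "K_tf")
  expect_error(build_network("wild_type", p, -1), ">= 0")
})

test_that("phosphotransfer reactions conserve the kinase total", {
  net <- build_network("wild_type", p, 5)
  set.seed(1)
  for (i in 1:20) {
    x <- runif(length(net$species)) * c(100, 100, 1000, 1000, 4000)
    f <- ode_rhs(net, x)
    # d(HK + HKp)/dt depends only on production and dilution
    expect_equal(unname(f["HK"] + f["HKp"]),
                 p$beta_HK - p$delta * (x[1] + x[2]), tolerance = 1e-10)
    expect_equal(unname(f["RR"] + f["RRp"]),
                 p$beta_RR - p$delta * (x[3] + x[4]), tolerance = 1e-10)
  }
})

test_that("zero feedback collapses every closed-loop architecture onto the wild type", {
  p0 <- p
  p0$P <- 0
  p0$k_bind <- 1e-3
  p0$K_tf <- 50
  wt <- build_network("wild_type", p0, 2)
  set.seed(2)
  for (arch in c("closed_loop_phos_seq", "closed_loop_dephos",
                 "molecular_seq_feedback", "transcriptional_feedback")) {
    net <- build_network(arch, p0, 2)
    for (i in 1:10) {
      xw <- runif(5) * c(100, 10, 1000, 100, 4000)
      xa <- c(xw, numeric(length(net$species) - 5))  # extra species at zero
      fw <- ode_rhs(wt, xw)
      fa <- ode_rhs(net, xa)
      expect_equal(unname(fa[names(fw)]), unname(fw), tolerance = 1e-12,
                   label = paste(arch, "RHS on shared species"))
    }
  }
})

test_that("an inert crosstalk kinase leaves the dynamics untouched", {
  px <- nominal_params(crosstalk = TRUE)
  px$X_tot <- 0  # X present but absent in copy number
  net_x <- build_network("wild_type", px, 2)
  net_0 <- build_network("wild_type", p, 2)
  expect_true(all(c("X", "Xp") %in% net_x$species))
  t1 <- simulate_network(net_x, t_end = 2000)
  t0 <- simulate_network(net_0, t_end = 2000)
  expect_rel_equal(t1$state[, "Output"], t0$state[, "Output"], 1e-6)
})

test_that("the right-hand side matches the reaction bookkeeping", {
  net <- build_network("wild_type", p, 2)
  # at the zero state only production reactions fire
  f0 <- ode_rhs(net, numeric(5))
  expect_equal(unname(f0), c(p$beta_HK, 0, p$beta_RR, 0, 0))
  expect_error(ode_rhs(net, numeric(3)), "dimension")
  expect_error(ode_rhs(net, c(-5, 0, 0, 0, 0)), "negative state")
  # numerically found steady state is a root of the RHS
  ss <- steady_state(net)
  expect_lt(sqrt(sum(ode_rhs(net, ss)^2)), 1e-8)
})

test_that("simulated trajectories are differentially consistent with the RHS", {
  net <- build_network("closed_loop_phos_seq", p, 5)
  tr <- simulate_network(net, t_end = 50, times = seq(0, 50, 0.01))
  i <- seq(1000, 4000, by = 500)  # interior times
  for (sp in c("RRp", "Output", "SR")) {
    fd <- (tr$state[i + 1, sp] - tr$state[i - 1, sp]) / 0.02
    an <- vapply(i, function(k) ode_rhs(net, tr$state[k, ])[sp], numeric(1))
    expect_rel_equal(fd, an, 1e-3)
  }
})

test_that("propensities are nonnegative on the nonnegative orthant", {
  pk <- p
  pk$k_bind <- 1e-3
  pk$K_tf <- 50
  pk$kap_X <- 0.08
  set.seed(3)
  for (arch in architectures()) {
    net <- build_network(arch, pk, 2)
    for (i in 1:20) {
      x <- runif(length(net$species)) * 1000
      expect_true(all(propensities(net, x) >= 0))
    }
  }
})

test_that("full-model trajectories stay nonnegative from nonnegative starts", {
  for (s in 1:5) {
    q <- perturb_params(nominal_params(), 0.4, seed = s)
    q$P <- 1
    net <- build_network("closed_loop_phos_seq", q, 2)
    tr <- simulate_network(net, t_end = 3000)
    expect_gt(min(tr$state), -1e-8)
  }
})

test_that("network text export lists species and every reaction", {
  net <- build_network("closed_loop_phos_seq", p, 2)
  path <- withr::local_tempfile(fileext = ".txt")
  export_network(net, path)
  lines <- readLines(path)
  expect_true(any(grepl("^species:", lines)))
  expect_length(grep("->", lines), ncol(net$stoich))
  expect_true(any(grepl("hill", lines)))
})
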