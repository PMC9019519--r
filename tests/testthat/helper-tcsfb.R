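# shared test utilities: relative comparison and a synthetic trajectory
# object for signal-shape tests

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected), 1e-12)),
              label = sprintf("max relative deviation %.3g (tol %.3g)",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), 1e-12)), tol))
}

# trajectory carrying an analytic test signal in the Output column
synthetic_trajectory <- function(time, y) {
  state <- matrix(y, ncol = 1, dimnames = list(NULL, "Output"))
  structure(list(time = time, state = state, network = NULL),
            class = "trajectory")
}

# birth-death-only parameterization: every reaction silenced except the
# production and dilution of the phosphatase PH
birth_death_params <- function(beta = 2, delta = 0.02) {
  rate_params(kap_max = 0, kt = 0, kp = 0, ktc = 0, kpc = 0,
              beta_HK = 0, beta_RR = 0, beta_PH = beta, delta = delta,
              kout_max = 0)
}
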