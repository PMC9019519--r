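test_that("nominal parameters satisfy their invariants and provenance contract", {
  p <- nominal_params()
  expect_s3_class(p, "rate_params")
  expect_silent(validate_params(p))
  expect_gt(p$delta, 0)
  expect_gte(p$n, 1)
  tot <- derived_totals(p)
  expect_identical(unname(tot["HK_tot"]), p$beta_HK / p$delta)
  expect_identical(unname(tot["RR_tot"]), p$beta_RR / p$delta)
  expect_true(all(is.finite(tot)) && all(tot >= 0))
  prov <- attr(p, "provenance")
  expect_setequal(names(prov), names(p))
  # crosstalk off by default; enabling it uses the published rate and flags it
  expect_identical(p$kap_X, 0)
  px <- nominal_params(crosstalk = TRUE)
  expect_identical(px$kap_X, 0.08)
  expect_identical(unname(attr(px, "provenance")["kap_X"]), "literature")
  # every other value is the package's documented default
  expect_true(all(attr(px, "provenance")[setdiff(names(px), c("kap_X", "k_bind", "K_tf"))] == "default"))
})

test_that("parameter validation rejects broken rate sets", {
  p <- nominal_params()
  p$delta <- 0
  expect_error(validate_params(p), "delta")
  p <- nominal_params()
  p$kt <- -1
  expect_error(validate_params(p), "negative")
  p <- nominal_params()
  p$n <- 0.5
  expect_error(validate_params(p), "n")
})

test_that("perturbation is deterministic, median-preserving and invariant-safe", {
  base <- nominal_params()
  expect_error(perturb_params(base, 0, seed = 1), "positive")
  expect_error(perturb_params(base, -1, seed = 1), "positive")
  a <- perturb_params(base, 0.5, seed = 42)
  b <- perturb_params(base, 0.5, seed = 42)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(a$kt, perturb_params(base, 0.5, seed = 43)$kt))
  # vanishing noise recovers the base set
  tiny <- perturb_params(base, 1e-9, seed = 5)
  expect_rel_equal(tiny$kt, base$kt, 1e-6)
  # sample moments: sd of log(kt) across draws matches the requested scale,
  # and the median multiplicative factor is 1 within Monte-Carlo error
  draws <- vapply(1:1000, function(s) perturb_params(base, 0.5, seed = s)$kt,
                  numeric(1))
  expect_lt(abs(sd(log(draws)) - 0.5), 0.05)
  expect_lt(abs(median(draws) / base$kt - 1), 0.1)
  for (s in 1:25) expect_silent(validate_params(perturb_params(base, 0.7, seed = s)))
})

test_that("perturbation does not disturb the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(perturb_params(nominal_params(), 0.5, seed = 99))
  expect_identical(before, .Random.seed)
})

test_that("named scenarios expose the documented grids and reject unknown names", {
  sc <- scenario("sensitivity")
  expect_identical(sc$inducer_grid, c(0.5, 1, 2, 5, 10))
  expect_identical(sc$P_grid, c(0.1, 0.4, 0.7, 1))
  expect_identical(scenario("tunability")$P_grid, c(0.1, 0.4, 0.7, 1))
  expect_identical(scenario("sensitivity_comparison")$inducer_grid,
                   c(0.1, 1, 2, 5, 10))
  wt <- scenario("wild_type")
  expect_identical(wt$params$beta_SR, 0)
  expect_identical(wt$params$beta_PH, 0)
  expect_error(scenario("nope"), "known scenarios")
  # grids strictly increasing and seed recorded
  for (nm in c("wild_type", "tunability", "noise", "sensitivity", "crosstalk")) {
    s <- scenario(nm, seed = 11)
    expect_false(is.unsorted(s$inducer_grid, strictly = TRUE))
    expect_identical(s$seed, 11L)
  }
})

test_that("scenario YAML serialization round-trips losslessly", {
  sc <- scenario("noise", seed = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_identical(back$name, sc$name)
  expect_identical(back$architecture, sc$architecture)
  expect_equal(unclass(back$params)[], unclass(sc$params)[], tolerance = 1e-12)
  expect_equal(back$inducer_grid, sc$inducer_grid, tolerance = 1e-12)
  expect_identical(back$seed, sc$seed)
})
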