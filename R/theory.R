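#' Closed-form steady state of RRp: phosphorylation sequestration
#'
#' Closed-form approximation of the phosphorylated response regulator's
#' steady state for the phosphorylation-sequestration motif (`beta_PH = 0`):
#' \deqn{[RR_p]^* = \frac{k_{ap}}{k_p}\cdot
#'   \frac{k_t RR_{tot}}{k_t RR_{tot} + k_{tc} SR_{tot} + \delta}\cdot
#'   \frac{k_p HK_{tot}}{k_p HK_{tot} + \delta}}
#' valid when phosphorylated fractions are small and the transfer rates
#' dominate the autophosphorylation drive (see [check_assumptions()]).
#'
#' @param params a [rate_params()] object.
#' @param I inducer concentration (mM).
#' @return approximate steady-state RRp (molecules).
#' @export
rrp_star_phos_seq <- function(params, I) {
  validate_params(params)
  if (params$kp == 0) stop("kp = 0: closed-form steady state undefined")
  kap <- autophosphorylation_rate(I, params)
  tot <- derived_totals(params)
  d <- params$delta
  (kap / params$kp) *
    (params$kt * tot[["RR_tot"]] /
       (params$kt * tot[["RR_tot"]] + params$ktc * tot[["SR_tot"]] + d)) *
    (params$kp * tot[["HK_tot"]] / (params$kp * tot[["HK_tot"]] + d))
}

#' Closed-form steady state of RRp: dephosphorylation enhancement
#'
#' Dual closed form for the added-phosphatase motif (`beta_SR = 0`):
#' \deqn{[RR_p]^* = \frac{k_{ap}}{k_p}\cdot
#'   \frac{k_t RR_{tot}}{k_t RR_{tot} + \delta}\cdot
#'   \frac{k_p HK_{tot}}{\delta + k_{pc} PH_{tot} + k_p HK_{tot}}}
#'
#' @inheritParams rrp_star_phos_seq
#' @return approximate steady-state RRp (molecules).
#' @export
rrp_star_dephos <- function(params, I) {
  validate_params(params)
  if (params$kp == 0) stop("kp = 0: closed-form steady state undefined")
  kap <- autophosphorylation_rate(I, params)
  tot <- derived_totals(params)
  d <- params$delta
  (kap / params$kp) *
    (params$kt * tot[["RR_tot"]] / (params$kt * tot[["RR_tot"]] + d)) *
    (params$kp * tot[["HK_tot"]] /
       (d + params$kpc * tot[["PH_tot"]] + params$kp * tot[["HK_tot"]]))
}

#' Check validity assumptions of the closed-form steady states
#'
#' Evaluates both sides of each assumption behind the closed forms and
#' compares the approximation against the numerically computed full-model
#' steady state. The assumptions are (i) small phosphorylated fractions,
#' `[RR_p] << [RR_sum]` (and `[SR_p] << [SR_sum]` for the sequestration
#' motif), evaluated at the full-model steady state, and (ii) the rate
#' inequality: for phosphorylation sequestration
#' `delta + kt RR_tot + ktc SR_tot >> kap (delta + kt HK_tot)/(delta + kp HK_tot)`,
#' for dephosphorylation enhancement
#' `delta + kt RR_tot >> kap (delta + kpc PH_tot + kt HK_tot)/(delta + kpc PH_tot + kp HK_tot)`.
#' "Much larger" is operationalized as a ratio exceeding `margin` (default
#' 10x, configurable); ratios are reported numerically, not just as booleans.
#'
#' @param params a [rate_params()] object.
#' @param I inducer concentration (mM).
#' @param motif `"phos_seq"` or `"dephos"`.
#' @param margin required left/right ratio for "much larger".
#' @return object of class `approx_report`: list with `approx_value`,
#'   `full_value`, `relative_error`, `assumption_ratios` (named numeric) and
#'   `valid` (`TRUE` iff every ratio exceeds `margin`).
#' @export
check_assumptions <- function(params, I, motif = c("phos_seq", "dephos"),
                              margin = 10) {
  motif <- match.arg(motif)
  validate_params(params)
  tot <- derived_totals(params)
  d <- params$delta
  kap <- autophosphorylation_rate(I, params)
  arch <- if (motif == "phos_seq") {
    if (tot["SR_tot"] > 0) "open_loop_phos_seq" else "wild_type"
  } else {
    if (tot["PH_tot"] > 0) "open_loop_dephos" else "wild_type"
  }
  net <- build_network(arch, params, I)
  ss <- steady_state(net)
  rr_sum <- ss["RR"] + ss["RRp"]
  ratios <- c(rr_frac = unname(rr_sum / max(ss["RRp"], .Machine$double.eps)))
  if (motif == "phos_seq") {
    if (tot["SR_tot"] > 0) {
      sr_sum <- ss["SR"] + ss["SRp"]
      ratios["sr_frac"] <- unname(sr_sum / max(ss["SRp"], .Machine$double.eps))
    }
    lhs <- d + params$kt * tot[["RR_tot"]] + params$ktc * tot[["SR_tot"]]
    rhs <- kap * (d + params$kt * tot[["HK_tot"]]) / (d + params$kp * tot[["HK_tot"]])
    approx <- rrp_star_phos_seq(params, I)
  } else {
    lhs <- d + params$kt * tot[["RR_tot"]]
    rhs <- kap * (d + params$kpc * tot[["PH_tot"]] + params$kt * tot[["HK_tot"]]) /
      (d + params$kpc * tot[["PH_tot"]] + params$kp * tot[["HK_tot"]])
    approx <- rrp_star_dephos(params, I)
  }
  ratios["rate_ineq"] <- lhs / max(rhs, .Machine$double.eps)
  full <- unname(ss["RRp"])
  rel_err <- abs(approx - full) / max(full, .Machine$double.eps)
  structure(list(approx_value = approx, full_value = full,
                 relative_error = rel_err, assumption_ratios = ratios,
                 margin = margin, valid = all(ratios > margin)),
            class = "approx_report")
}

#' @export
print.approx_report <- function(x, ...) {
  cat(sprintf("<approx_report> approx %.4g vs full %.4g (rel. err. %.3g); valid: %s\n",
              x$approx_value, x$full_value, x$relative_error, x$valid))
  cat("  assumption ratios (require >", x$margin, "):\n")
  for (nm in names(x$assumption_ratios)) {
    cat(sprintf("    %-10s %.3g\n", nm, x$assumption_ratios[[nm]]))
  }
  invisible(x)
}

#' Steady state under shared-resource (transcription/translation) sequestration
#'
#' Closed-form steady state of a protein Y whose expression competes with a
#' sequestration protein S for a shared resource pool:
#' `Y* = K_Y * beta_Y / (1 + J_Y beta_Y + J_S beta_S)`, with `K_Y = T_Y/delta`
#' the lumped basal expression.
#'
#' @param rp named list with `T_Y`, `T_S`, `beta_Y`, `beta_S`, `J_Y`, `J_S`,
#'   `delta` (all >= 0, `delta > 0`).
#' @return steady-state Y (same concentration units as `T_Y/delta`).
#' @export
resource_steady_state <- function(rp) {
  need <- c("T_Y", "beta_Y", "beta_S", "J_Y", "J_S", "delta")
  if (!all(need %in% names(rp))) {
    stop("rp must contain: ", paste(need, collapse = ", "))
  }
  vals <- unlist(rp[need])
  if (any(vals < 0) || rp$delta <= 0) stop("resource parameters must be >= 0 with delta > 0")
  K_Y <- rp$T_Y / rp$delta
  K_Y * rp$beta_Y / (1 + rp$J_Y * rp$beta_Y + rp$J_S * rp$beta_S)
}

#' Right-hand side of the two-protein resource-competition model
#'
#' The ODE pair whose long-time limit [resource_steady_state()] reproduces.
#'
#' @inheritParams resource_steady_state
#' @param y numeric vector `c(Y, S)`.
#' @return derivative vector.
#' @export
resource_rhs <- function(y, rp) {
  den <- 1 + rp$J_Y * rp$beta_Y + rp$J_S * rp$beta_S
  c(Y = rp$T_Y * rp$beta_Y / den - rp$delta * y[1],
    S = rp$T_S * rp$beta_S / den - rp$delta * y[2])
}

# --- reduced (totals-eliminated) model --------------------------------------

#' Right-hand side of the reduced sequestration model
#'
#' The three-state reduction of the phosphorylation-sequestration system in
#' the unphosphorylated coordinates `(HK, RR, SR)`, obtained by eliminating
#' the phosphorylated forms through the totals `HK_tot = beta_HK/delta` etc.
#' `beta_SR` may be overridden to scan the sequestration production rate.
#'
#' @param state numeric `c(HK, RR, SR)`.
#' @param params a [rate_params()] object.
#' @param I inducer concentration (mM).
#' @param beta_SR optional override of the SR production rate.
#' @return derivative vector `c(HK, RR, SR)`.
#' @export
reduced_rhs <- function(state, params, I, beta_SR = params$beta_SR) {
  kap <- autophosphorylation_rate(I, params)
  tot <- derived_totals(params)
  HKt <- tot[["HK_tot"]]; RRt <- tot[["RR_tot"]]
  SRt <- beta_SR / params$delta
  HK <- state[1]; RR <- state[2]; SR <- state[3]
  d <- params$delta
  c(HK = params$beta_HK - d * HK - kap * HK +
      params$kt * (HKt - HK) * RR + params$ktc * (HKt - HK) * SR,
    RR = params$beta_RR - d * RR - params$kt * (HKt - HK) * RR +
      params$kp * HK * (RRt - RR),
    SR = beta_SR - d * SR - params$ktc * (HKt - HK) * SR +
      params$kpc * HK * (SRt - SR))
}

reduced_jacobian <- function(state, params, I, beta_SR = params$beta_SR) {
  kap <- autophosphorylation_rate(I, params)
  tot <- derived_totals(params)
  HKt <- tot[["HK_tot"]]; RRt <- tot[["RR_tot"]]
  SRt <- beta_SR / params$delta
  HK <- state[1]; RR <- state[2]; SR <- state[3]
  d <- params$delta; kt <- params$kt; kp <- params$kp
  ktc <- params$ktc; kpc <- params$kpc
  matrix(c(
    -d - kap - kt * RR - ktc * SR, kt * (HKt - HK), ktc * (HKt - HK),
    kt * RR + kp * (RRt - RR), -d - kt * (HKt - HK) - kp * HK, 0,
    ktc * SR + kpc * (SRt - SR), 0, -d - ktc * (HKt - HK) - kpc * HK),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("HK", "RR", "SR"), c("HK", "RR", "SR")))
}

#' Simulate the reduced sequestration model
#'
#' @inheritParams reduced_rhs
#' @param x0 initial state `c(HK, RR, SR)`.
#' @param t_end horizon (min).
#' @param times optional output times.
#' @return list with `time` and `state` (time x 3 matrix).
#' @export
simulate_reduced <- function(x0, params, I, t_end, beta_SR = params$beta_SR,
                             times = NULL) {
  if (is.null(times)) times <- seq(0, t_end, length.out = 201)
  func <- function(t, y, parms) list(reduced_rhs(y, params, I, beta_SR))
  out <- deSolve::ode(y = stats::setNames(x0, c("HK", "RR", "SR")),
                      times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  list(time = out[, 1], state = unname(as.matrix(out[, -1])))
}

reduced_steady_state <- function(params, I, beta_SR = params$beta_SR,
                                 x0 = c(0, 0, 0), t_settle = 1e5) {
  sim <- simulate_reduced(x0, params, I, t_settle, beta_SR,
                          times = c(0, t_settle))
  x <- sim$state[2, ]
  for (it in 1:50) {
    f <- reduced_rhs(x, params, I, beta_SR)
    if (sqrt(sum(f^2)) < 1e-12) break
    J <- reduced_jacobian(x, params, I, beta_SR)
    x <- x - solve(J, f)
  }
  stats::setNames(x, c("HK", "RR", "SR"))
}

#' Local stability condition of the natural two-component system
#'
#' Evaluates, at a wild-type (`beta_SR = 0`) steady state of the reduced
#' model, the algebraic local-stability condition
#' \deqn{(\delta+k_{ap}+k_t[RR]^*)(\delta+k_t[HK_p]^*+k_p[HK]^*) >
#'   k_t[HK_p]^*(k_t[RR]^*+k_p[RR_p]^*)}
#' with `[HK_p]* = HK_tot - [HK]*`, `[RR_p]* = RR_tot - [RR]*`, together with
#' the simpler sufficient condition `1 > [HK_p]*/HK_tot + [RR_p]*/RR_tot`.
#'
#' @param ss named steady state with entries `HK` and `RR` (reduced
#'   coordinates); entries must lie within the totals box.
#' @param params a [rate_params()] object.
#' @param I inducer concentration (mM).
#' @return list with `stable` (main condition), `sufficient` (simplified
#'   condition) and `margin` (left minus right side of the main condition).
#' @export
local_stability_condition <- function(ss, params, I) {
  tot <- derived_totals(params)
  HK <- unname(ss["HK"]); RR <- unname(ss["RR"])
  if (is.na(HK) || is.na(RR)) stop("ss must carry named entries HK and RR")
  if (HK < -1e-9 || HK > tot[["HK_tot"]] + 1e-6 * (1 + tot[["HK_tot"]]) ||
      RR < -1e-9 || RR > tot[["RR_tot"]] + 1e-6 * (1 + tot[["RR_tot"]])) {
    stop("steady state inconsistent with totals box")
  }
  kap <- autophosphorylation_rate(I, params)
  HKp <- tot[["HK_tot"]] - HK
  RRp <- tot[["RR_tot"]] - RR
  d <- params$delta; kt <- params$kt; kp <- params$kp
  lhs <- (d + kap + kt * RR) * (d + kt * HKp + kp * HK)
  rhs <- kt * HKp * (kt * RR + kp * RRp)
  list(stable = lhs > rhs,
       sufficient = 1 > HKp / tot[["HK_tot"]] + RRp / tot[["RR_tot"]],
       margin = lhs - rhs)
}

#' Numerical monotone-structure check
#'
#' Verifies on sampled states of the box S (`0 <= HK <= HK_tot`, etc.) that
#' the off-diagonal entries of the reduced-model Jacobian are all nonnegative,
#' i.e. the system is cooperative with respect to the positive orthant - the
#' structural property that rules out stable limit cycles and orders
#' steady-state responses. Returns a witness state when the sign pattern is
#' broken.
#'
#' @param params a [rate_params()] object.
#' @param I inducer concentration (mM).
#' @param beta_SR SR production rate of the reduced model.
#' @param n_sample number of sampled states (documented default 1000).
#' @param seed integer seed for the state sample.
#' @param jac optional replacement Jacobian function `(state) -> 3x3 matrix`
#'   (used to demonstrate failure on sign-broken systems).
#' @return list with `monotone` (logical) and `witness` (state or `NULL`).
#' @export
monotone_structure_check <- function(params, I, beta_SR = params$beta_SR,
                                     n_sample = 1000, seed = 1, jac = NULL) {
  tot <- derived_totals(params)
  box <- c(tot[["HK_tot"]], tot[["RR_tot"]], max(beta_SR / params$delta, 1))
  rng <- local_rng(seed)
  if (is.null(jac)) {
    jac <- function(x) reduced_jacobian(x, params, I, beta_SR)
  }
  off <- !diag(3)
  for (i in seq_len(n_sample)) {
    x <- rng$unif(3) * box
    J <- jac(x)
    if (any(J[off] < -1e-12)) {
      return(list(monotone = FALSE, witness = stats::setNames(x, c("HK", "RR", "SR"))))
    }
  }
  list(monotone = TRUE, witness = NULL)
}

#' Corner-trajectory global-attractivity diagnostic
#'
#' Integrates the reduced model from the two corner states of the box S
#' (the origin and `(HK_tot, RR_tot, SR_tot)`). If both trajectories converge
#' to the same point, that point is globally attractive in S (a consequence
#' of monotonicity).
#'
#' @inheritParams reduced_rhs
#' @param t_end horizon for convergence (min).
#' @param tol relative distance under which the two endpoints are declared
#'   equal.
#' @return list with `attractive` (logical), `x_star` (common limit when
#'   attractive), `gap` (relative endpoint distance).
#' @export
corner_convergence <- function(params, I, beta_SR = params$beta_SR,
                               t_end = 1e5, tol = 1e-6) {
  tot <- derived_totals(params)
  SRt <- beta_SR / params$delta
  top <- c(tot[["HK_tot"]], tot[["RR_tot"]], SRt)
  s1 <- simulate_reduced(c(0, 0, 0), params, I, t_end, beta_SR,
                         times = c(0, t_end))
  s2 <- simulate_reduced(top, params, I, t_end, beta_SR, times = c(0, t_end))
  e1 <- s1$state[2, ]; e2 <- s2$state[2, ]
  gap <- sqrt(sum((e1 - e2)^2)) / (1 + sqrt(sum(e1^2)))
  list(attractive = gap < tol,
       x_star = if (gap < tol) stats::setNames((e1 + e2) / 2, c("HK", "RR", "SR")) else NULL,
       gap = gap)
}

#' Steady-state monotonicity scan in the SR production rate
#'
#' Computes reduced-model steady states over a grid of `beta_SR` values and
#' reports the steady-state `[RR]` (which increases with sequestration) and
#' `[RR_p] = RR_tot - [RR]` (which decreases).
#'
#' @inheritParams reduced_rhs
#' @param beta_SR_grid increasing grid of SR production rates.
#' @return data.frame with columns `beta_SR`, `RR_star`, `RRp_star`.
#' @export
beta_sr_scan <- function(params, I, beta_SR_grid) {
  res <- vapply(beta_SR_grid, function(b) {
    ss <- reduced_steady_state(params, I, beta_SR = b)
    ss[["RR"]]
  }, numeric(1))
  data.frame(beta_SR = beta_SR_grid, RR_star = res,
             RRp_star = derived_totals(params)[["RR_tot"]] - res)
}
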