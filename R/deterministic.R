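#' Integrate a network ODE
#'
#' Deterministic trajectory of the mass-action/Hill rate equations using a
#' stiff integrator (`deSolve::ode`, `lsoda`) with tight tolerances
#' (`rtol = 1e-8`, `atol = 1e-10` by default): phosphotransfer rates exceed
#' dilution by orders of magnitude, making the system stiff.
#'
#' @param network a [build_network()] object.
#' @param x0 initial state; defaults to [initial_state()].
#' @param t_end end time (min), > 0.
#' @param times optional explicit output time grid (min).
#' @param rtol,atol solver tolerances.
#' @return object of class `trajectory`: list with `time` (min), `state`
#'   (time x species matrix) and `network`.
#' @export
simulate_network <- function(network, x0 = initial_state(network), t_end,
                             times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = 201)
  }
  if (length(x0) != length(network$species)) stop("x0 dimension mismatch")
  x0 <- stats::setNames(as.numeric(x0), network$species)
  func <- function(t, y, parms) list(ode_rhs(network, y))
  out <- deSolve::ode(y = x0, times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    diag <- utils::capture.output(deSolve::diagnostics.deSolve(out))
    stop("ODE integration failed (istate = ", attr(out, "istate")[1], "): ",
         paste(trimws(diag[nzchar(diag)]), collapse = "; "))
  }
  state <- unname(as.matrix(out[, -1, drop = FALSE]))
  colnames(state) <- network$species
  if (any(!is.finite(state))) stop("ODE integration produced non-finite states")
  structure(list(time = out[, 1], state = state, network = network),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d time points over [%g, %g] min, species: %s\n",
              x$network$architecture, length(x$time), min(x$time), max(x$time),
              paste(colnames(x$state), collapse = ", ")))
  invisible(x)
}

# Damped Newton root polishing of ode_rhs. Uses a Moore-Penrose solve so that
# conserved quantities (e.g. the crosstalk kinase total) stay fixed: the
# residual has no component along the stoichiometric left null space, and the
# pseudo-inverse step none either.
newton_polish <- function(network, x, tol = 1e-10, maxit = 50) {
  f <- ode_rhs(network, pmax(x, 0))
  for (it in seq_len(maxit)) {
    if (sqrt(sum(f^2)) < tol) break
    J <- rhs_jacobian(network, x)
    step <- tryCatch(as.numeric(pracma::pinv(J) %*% f),
                     error = function(e) rep(NA_real_, length(x)))
    if (any(!is.finite(step))) break
    lambda <- 1
    repeat {
      xn <- pmax(x - lambda * step, 0)
      fn <- ode_rhs(network, xn)
      if (sqrt(sum(fn^2)) < sqrt(sum(f^2)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- pmax(x - lambda * step, 0)
    f <- ode_rhs(network, x)
  }
  list(x = stats::setNames(x, network$species), residual = sqrt(sum(f^2)))
}

#' Steady state of a network
#'
#' Two-stage computation: long stiff integration (default settling horizon
#' `1e5` min) from `x0`, followed by damped-Newton polishing of the ODE
#' right-hand side. Fails loudly when the polished residual norm exceeds
#' `tol`.
#'
#' @param network a [build_network()] object.
#' @param x0 initial state for the settling integration.
#' @param t_settle settling horizon (min).
#' @param tol required residual 2-norm of the right-hand side.
#' @return named steady-state vector with attributes `residual` and
#'   `converged`.
#' @export
steady_state <- function(network, x0 = initial_state(network), t_settle = 1e5,
                         tol = 1e-10) {
  traj <- simulate_network(network, x0, t_end = t_settle,
                           times = c(0, t_settle / 2, t_settle))
  xT <- traj$state[nrow(traj$state), ]
  pol <- newton_polish(network, xT, tol = tol)
  if (!is.finite(pol$residual) || pol$residual > tol) {
    stop(sprintf(paste0("steady_state did not converge for %s at I = %g ",
                        "(residual %.3e after integration to t = %g and Newton ",
                        "polishing); consider a longer t_settle"),
                 network$architecture, network$inducer, pol$residual, t_settle))
  }
  structure(pol$x, residual = pol$residual, converged = TRUE)
}

#' Dose-response curves for a scenario
#'
#' One steady-state output curve per (architecture, feedback strength) pair
#' over the scenario's inducer grid. For open-loop architectures the `P` grid
#' is ignored (a single curve at the scenario's constitutive `beta_SR` /
#' `beta_PH`); the wild type is a single curve.
#'
#' @param sc a [scenario()] object.
#' @param species which species' steady-state level to report.
#' @return data.frame of class `dose_response` with columns `architecture`,
#'   `P`, `I_mM`, `species`, `value`, `units`.
#' @export
dose_response <- function(sc, species = "Output") {
  validate_scenario(sc)
  rows <- list()
  for (arch in sc$architecture) {
    P_vals <- if (arch %in% c("wild_type", "open_loop_phos_seq", "open_loop_dephos"))
      NA_real_ else sc$P_grid
    for (P in P_vals) {
      params <- sc$params
      if (!is.na(P)) params$P <- P
      val <- vapply(sc$inducer_grid, function(I) {
        net <- build_network(arch, params, I)
        ss <- tryCatch(steady_state(net), error = function(e) {
          stop("dose_response failed at (architecture = ", arch, ", I = ", I,
               ", P = ", P, "): ", conditionMessage(e))
        })
        unname(ss[species])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        architecture = arch, P = P, I_mM = sc$inducer_grid, species = species,
        value = val, units = "molecules", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dose_response", class(out))
  attr(out, "scenario") <- sc$name
  out
}

#' Fractional overshoot of a settled trajectory
#'
#' `(max over time - final value) / final value`, floored at 0. The
#' trajectory must be settled: the species must vary by less than
#' `settle_tol` (relative) over the final 10 percent of the time window.
#'
#' @param traj a [simulate_network()] trajectory.
#' @param species species label.
#' @param settle_tol relative variation allowed in the final window.
#' @return nonnegative fraction (dimensionless).
#' @export
overshoot <- function(traj, species = "Output", settle_tol = 1e-3) {
  stopifnot(inherits(traj, "trajectory"))
  y <- traj$state[, species]
  t <- traj$time
  tail_idx <- which(t >= t[1] + 0.9 * (t[length(t)] - t[1]))
  yf <- y[length(y)]
  if (yf <= 0) stop("final value is not positive; overshoot undefined")
  if (diff(range(y[tail_idx])) / yf > settle_tol) {
    stop("trajectory not settled in the final 10% window; increase t_end")
  }
  max(0, (max(y) - yf) / yf)
}

#' Step-response overshoot comparison of feedback architectures
#'
#' Simulates the response to a step of inducer from the zero state and
#' reports the fractional overshoot of the output for each architecture in
#' the scenario.
#'
#' @param sc a [scenario()] object (typically `scenario("step")`).
#' @param t_end simulation horizon (min).
#' @return data.frame with columns `architecture`, `P`, `I_mM`, `overshoot`.
#' @export
step_response <- function(sc, t_end = 5000) {
  validate_scenario(sc)
  I <- max(sc$inducer_grid)
  P <- max(sc$P_grid)
  params <- sc$params
  params$P <- P
  params <- match_comparison_feedback(params, P = P)
  res <- lapply(sc$architecture, function(arch) {
    net <- build_network(arch, params, I)
    traj <- simulate_network(net, t_end = t_end,
                             times = seq(0, t_end, length.out = 2001))
    data.frame(architecture = arch, P = P, I_mM = I,
               overshoot = overshoot(traj), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
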