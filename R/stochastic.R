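# Pack the network's propensity descriptors into the flat encoding the
# compiled SSA kernel understands.
ssa_encoding <- function(network) {
  type_code <- c(const = 0L, uni = 1L, bi = 2L, hill = 3L, repress = 4L)
  R <- length(network$reactions)
  enc <- list(type = integer(R), rate = numeric(R), s1 = integer(R),
              s2 = integer(R), e1 = numeric(R), e2 = numeric(R))
  for (j in seq_len(R)) {
    r <- network$reactions[[j]]
    enc$type[j] <- type_code[[r$type]]
    enc$rate[j] <- r$rate
    enc$s1[j] <- if (length(r$s) >= 1) r$s[1] - 1L else -1L
    enc$s2[j] <- if (length(r$s) >= 2) r$s[2] - 1L else -1L
    if (r$type == "hill") {
      enc$e1[j] <- r$extra[["Kd"]]; enc$e2[j] <- r$extra[["n"]]
    } else if (r$type == "repress") {
      enc$e1[j] <- r$extra[["K"]]
    }
  }
  enc
}

check_integer_state <- function(network, x0) {
  if (length(x0) != length(network$species)) stop("x0 dimension mismatch")
  if (any(x0 < 0) || any(x0 != round(x0))) {
    stop("SSA initial state must be nonnegative integer copy numbers")
  }
  as.numeric(round(x0))
}

#' Exact stochastic simulation (direct Gillespie method)
#'
#' Samples one realization of the chemical master equation for the network
#' using the direct method, in copy-number units (system size fixed at
#' `Omega = 1`, i.e. the deterministic concentration scale is read as copy
#' numbers). The trajectory is piecewise constant with integer states.
#'
#' @param network a [build_network()] object.
#' @param x0 integer initial copy numbers (default [initial_state()]).
#' @param t_end end time (min).
#' @param seed integer seed; the same seed reproduces the identical event
#'   sequence.
#' @param max_events guard on the recorded event count.
#' @return object of class `trajectory` with event times and states (the
#'   state at `t_end` is the last recorded state).
#' @export
ssa_simulate <- function(network, x0 = initial_state(network), t_end, seed,
                         max_events = 5e6) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0)
  x0 <- check_integer_state(network, x0)
  enc <- ssa_encoding(network)
  res <- .ssa_path(network$stoich, enc$type, enc$rate, enc$s1, enc$s2,
                   enc$e1, enc$e2, x0, t_end, as.double(seed),
                   as.integer(max_events))
  state <- res$state
  colnames(state) <- network$species
  structure(list(time = res$time, state = state, network = network,
                 seed = as.integer(seed)),
            class = "trajectory")
}

#' Ensemble of SSA end states and noise summary
#'
#' Runs `n_runs` independent realizations (one counter-based random stream
#' per `(seed, run)` pair) to `t_probe` and summarizes mean, variance and
#' coefficient of variation per species, with standard errors.
#'
#' The standard error of the cv uses the normal-theory delta-method formula
#' `se(cv) = cv * sqrt(1/(2 n) + cv^2/n)`.
#'
#' @param network a [build_network()] object.
#' @param x0 integer initial copy numbers.
#' @param t_probe probe time (min).
#' @param n_runs number of realizations (>= 2).
#' @param seed integer seed.
#' @return data.frame of class `noise_summary` with one row per species:
#'   `species`, `time`, `mean`, `variance`, `cv`, `se_mean`, `se_cv`,
#'   `method`, `n_runs`, `seed`. For all-zero species the cv is `NA` and
#'   `cv_defined` is `FALSE` (flagged, not propagated).
#' @export
ssa_ensemble <- function(network, x0 = initial_state(network), t_probe,
                         n_runs, seed) {
  stopifnot(inherits(network, "reaction_network"), n_runs >= 2)
  x0 <- check_integer_state(network, x0)
  enc <- ssa_encoding(network)
  fin <- .ssa_final_states(network$stoich, enc$type, enc$rate, enc$s1, enc$s2,
                           enc$e1, enc$e2, x0, t_probe, as.integer(n_runs),
                           as.double(seed))
  m <- colMeans(fin)
  v <- apply(fin, 2, stats::var)
  cv <- ifelse(m > 0, sqrt(v) / m, NA_real_)
  out <- data.frame(
    species = network$species, time = t_probe, mean = m, variance = v,
    cv = cv, se_mean = sqrt(v / n_runs),
    se_cv = ifelse(is.na(cv), NA_real_, cv * sqrt(1 / (2 * n_runs) + cv^2 / n_runs)),
    cv_defined = !is.na(cv), method = "SSA", n_runs = n_runs,
    seed = as.integer(seed), stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("noise_summary", class(out))
  attr(out, "final_states") <- fin
  out
}

#' Linear noise approximation: mean and covariance trajectories
#'
#' Integrates the macroscopic rate equation for the mean together with the
#' time-varying Lyapunov equation for the covariance,
#' `dSigma/dt = J Sigma + Sigma J' + D`, where `J` is the Jacobian of the
#' deterministic right-hand side and `D = S diag(a) S'` is the diffusion
#' matrix built from the stoichiometry `S` and propensities `a`. The
#' covariance is checked to stay symmetric positive semidefinite within
#' `psd_tol` at all saved times.
#'
#' @param network a [build_network()] object.
#' @param x0 initial mean (default [initial_state()]); initial covariance is
#'   zero (deterministic initial condition).
#' @param t_grid output time grid (min), starting at 0.
#' @param psd_tol tolerance on negative covariance eigenvalues, relative to
#'   the largest eigenvalue.
#' @return list of class `lna_moments` with `time`, `mean` (time x species),
#'   `cov` (species x species x time array).
#' @export
lna_moments <- function(network, x0 = initial_state(network), t_grid,
                        psd_tol = 1e-8) {
  stopifnot(inherits(network, "reaction_network"))
  ns <- length(network$species)
  S <- network$stoich
  ix <- which(lower.tri(matrix(0, ns, ns), diag = TRUE))
  unpack <- function(v) {
    Sig <- matrix(0, ns, ns)
    Sig[ix] <- v
    Sig <- Sig + t(Sig) - diag(diag(Sig))
    Sig
  }
  func <- function(t, y, parms) {
    x <- y[1:ns]
    Sig <- unpack(y[-(1:ns)])
    a <- propensities(network, x)
    J <- S %*% propensity_jacobian(network, x)
    D <- S %*% (a * t(S))
    dSig <- J %*% Sig + Sig %*% t(J) + D
    list(c(as.numeric(S %*% a), dSig[ix]))
  }
  y0 <- c(as.numeric(x0), numeric(length(ix)))
  out <- deSolve::ode(y = y0, times = t_grid, func = func, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-8)
  if (attr(out, "istate")[1] < 0) stop("LNA integration failed")
  mean_traj <- out[, 2:(ns + 1), drop = FALSE]
  colnames(mean_traj) <- network$species
  covs <- array(0, c(ns, ns, length(t_grid)),
                dimnames = list(network$species, network$species, NULL))
  for (k in seq_along(t_grid)) {
    Sig <- unpack(out[k, -(1:(ns + 1))])
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -psd_tol * max(abs(ev), 1)) {
      stop(sprintf("LNA covariance lost positive semidefiniteness at t = %g (min eigenvalue %.3e)",
                   t_grid[k], min(ev)))
    }
    covs[, , k] <- Sig
  }
  structure(list(time = t_grid, mean = mean_traj, cov = covs,
                 network = network), class = "lna_moments")
}

#' LNA noise summary at a probe time
#'
#' @param network a [build_network()] object.
#' @param x0 initial mean.
#' @param t_probe probe time (min).
#' @return `noise_summary` data.frame (method `"LNA"`).
#' @export
lna_noise_summary <- function(network, x0 = initial_state(network), t_probe) {
  mom <- lna_moments(network, x0, t_grid = c(0, t_probe / 2, t_probe))
  k <- length(mom$time)
  m <- mom$mean[k, ]
  v <- diag(mom$cov[, , k])
  cv <- ifelse(m > 0, sqrt(pmax(v, 0)) / m, NA_real_)
  out <- data.frame(
    species = network$species, time = t_probe, mean = m, variance = v,
    cv = cv, se_mean = 0, se_cv = 0, cv_defined = !is.na(cv), method = "LNA",
    n_runs = NA_integer_, seed = NA_integer_, stringsAsFactors = FALSE,
    row.names = NULL)
  class(out) <- c("noise_summary", class(out))
  out
}

#' Coefficient-of-variation versus mean output curve
#'
#' For every (architecture, P, I) combination of the scenario, computes the
#' LNA mean and coefficient of variation of the output at `t_probe`
#' (default 1000 min) starting from the zero state, and returns the table
#' sorted by mean output.
#'
#' @param sc a [scenario()] object (typically `scenario("noise")`).
#' @param t_probe probe time (min).
#' @param species species to summarize.
#' @return data.frame with columns `architecture`, `P`, `I_mM`, `mean`, `cv`,
#'   `units`.
#' @export
cv_vs_mean_curve <- function(sc, t_probe = 1000, species = "Output") {
  validate_scenario(sc)
  rows <- list()
  for (arch in sc$architecture) {
    P_vals <- if (arch %in% c("wild_type", "open_loop_phos_seq", "open_loop_dephos"))
      NA_real_ else sc$P_grid
    for (P in P_vals) {
      params <- sc$params
      if (!is.na(P)) params$P <- P
      for (I in sc$inducer_grid) {
        net <- build_network(arch, params, I)
        ns <- lna_noise_summary(net, t_probe = t_probe)
        row <- ns[ns$species == species, ]
        rows[[length(rows) + 1L]] <- data.frame(
          architecture = arch, P = P, I_mM = I, mean = row$mean, cv = row$cv,
          units = "molecules", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$mean), , drop = FALSE]
}
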