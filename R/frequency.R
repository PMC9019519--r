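# hill activation h(x) and derivative, with the output promoter's constants
h_fun <- function(x, params) output_initiation_rate(x, params)
h_grad <- function(x, params) output_initiation_grad(x, params)

#' Linearize the process (two-component system) around its steady state
#'
#' Splits the closed loop into a process (the two-component system) and a
#' controller (the sequestration motif) and linearizes the process at the
#' closed-loop steady state. Around the steady state the totals are exact
#' (`[HK_sum] = HK_tot`, `[RR_sum] = RR_tot`), so the process states are
#' `([HK], [RR_p])` for the sequestration and phosphatase feedbacks. For the
#' comparison feedbacks the kinase total is not conserved and the process
#' keeps three states `([HK], [HK_p], [RR_p])`.
#'
#' The controlled input `u` is the controller's output species (`[SR]`,
#' `[PH]`, the annihilator `[A]` or the repressor `[TF]`); the external input
#' `z` is the inducer channel entering through the autophosphorylation rate;
#' the measured outputs `y` are the process states.
#'
#' @param architecture one of `closed_loop_phos_seq`, `closed_loop_dephos`,
#'   `molecular_seq_feedback`, `transcriptional_feedback`.
#' @param params a [rate_params()] object (comparison feedbacks need their
#'   matched constant).
#' @param I inducer concentration (mM).
#' @param seq_phos_only molecular sequestration variant binding only the
#'   phosphorylated kinase.
#' @return object of class `linearized_system`: list with `A`, `B_u`, `B_z`,
#'   `C` (identity on the process states), `operating_point` (full-network
#'   steady state), `states`, `f` (the nonlinear process right-hand side
#'   `f(x, u)`, for finite-difference verification) and `residual`.
#' @export
linearize_process <- function(architecture, params, I, seq_phos_only = FALSE) {
  architecture <- match.arg(architecture,
                            c("closed_loop_phos_seq", "closed_loop_dephos",
                              "molecular_seq_feedback", "transcriptional_feedback"))
  net <- build_network(architecture, params, I, seq_phos_only = seq_phos_only)
  ss <- steady_state(net)
  # conservation laws (e.g. the crosstalk kinase total) contribute a zero
  # eigenvalue; anything significantly positive means an unstable point
  ev <- eigen(rhs_jacobian(net, ss), only.values = TRUE)$values
  if (max(Re(ev)) > 1e-8) {
    stop("closed-loop steady state is not stable; linearization refused")
  }
  p <- params
  kap <- autophosphorylation_rate(I, p)
  tot <- derived_totals(p)
  HKt <- tot[["HK_tot"]]; RRt <- tot[["RR_tot"]]
  HK <- unname(ss["HK"]); RRp <- unname(ss["RRp"])
  if (architecture %in% c("closed_loop_phos_seq", "closed_loop_dephos")) {
    u_star <- unname(ss[if (architecture == "closed_loop_phos_seq") "SR" else "PH"])
    if (architecture == "closed_loop_phos_seq") {
      f <- function(x, u) {
        c(p$beta_HK + (p$kt * (RRt - x[2]) + p$ktc * u) * (HKt - x[1]) -
            (kap + p$delta) * x[1],
          -p$delta * x[2] + p$kt * (HKt - x[1]) * (RRt - x[2]) -
            p$kp * x[1] * x[2])
      }
      A <- matrix(c(
        -(p$kt * (RRt - RRp) + p$ktc * u_star) - kap - p$delta,
        -p$kt * (HKt - HK),
        -p$kt * (RRt - RRp) - p$kp * RRp,
        -p$delta - p$kt * (HKt - HK) - p$kp * HK), 2, 2, byrow = TRUE)
      B_u <- matrix(c(p$ktc * (HKt - HK), 0), 2, 1)
    } else {
      f <- function(x, u) {
        c(p$beta_HK - (kap + p$delta) * x[1] +
            p$kt * (HKt - x[1]) * (RRt - x[2]),
          -p$delta * x[2] + p$kt * (HKt - x[1]) * (RRt - x[2]) -
            (p$kp * x[1] + p$kpc * u) * x[2])
      }
      A <- matrix(c(
        -kap - p$delta - p$kt * (RRt - RRp),
        -p$kt * (HKt - HK),
        -p$kt * (RRt - RRp) - p$kp * RRp,
        -p$delta - p$kt * (HKt - HK) - p$kp * HK - p$kpc * u_star),
        2, 2, byrow = TRUE)
      B_u <- matrix(c(0, -p$kpc * RRp), 2, 1)
    }
    B_z <- matrix(c(-HK, 0), 2, 1)
    states <- c("HK", "RRp")
    x_star <- c(HK, RRp)
  } else {
    HKp <- unname(ss["HKp"])
    u_star <- unname(ss[if (architecture == "molecular_seq_feedback") "A" else "TF"])
    if (architecture == "molecular_seq_feedback") {
      g1 <- if (seq_phos_only) 0 else p$k_bind
      f <- function(x, u) {
        c(p$beta_HK - p$delta * x[1] - kap * x[1] +
            p$kt * x[2] * (RRt - x[3]) - g1 * u * x[1],
          kap * x[1] - p$delta * x[2] - p$kt * x[2] * (RRt - x[3]) -
            p$k_bind * u * x[2],
          p$kt * x[2] * (RRt - x[3]) - p$kp * x[1] * x[3] - p$delta * x[3])
      }
      A <- matrix(c(
        -p$delta - kap - g1 * u_star, p$kt * (RRt - RRp), -p$kt * HKp,
        kap, -p$delta - p$kt * (RRt - RRp) - p$k_bind * u_star, p$kt * HKp,
        -p$kp * RRp, p$kt * (RRt - RRp),
        -p$kt * HKp - p$kp * HK - p$delta), 3, 3, byrow = TRUE)
      B_u <- matrix(c(-g1 * HK, -p$k_bind * HKp, 0), 3, 1)
    } else {
      rep_fac <- 1 / (1 + u_star / p$K_tf)
      f <- function(x, u) {
        c(p$beta_HK / (1 + u / p$K_tf) - p$delta * x[1] - kap * x[1] +
            p$kt * x[2] * (RRt - x[3]),
          kap * x[1] - p$delta * x[2] - p$kt * x[2] * (RRt - x[3]),
          p$kt * x[2] * (RRt - x[3]) - p$kp * x[1] * x[3] - p$delta * x[3])
      }
      A <- matrix(c(
        -p$delta - kap, p$kt * (RRt - RRp), -p$kt * HKp,
        kap, -p$delta - p$kt * (RRt - RRp), p$kt * HKp,
        -p$kp * RRp, p$kt * (RRt - RRp),
        -p$kt * HKp - p$kp * HK - p$delta), 3, 3, byrow = TRUE)
      B_u <- matrix(c(-p$beta_HK / p$K_tf * rep_fac^2, 0, 0), 3, 1)
    }
    B_z <- matrix(c(-HK, HK, 0), 3, 1)
    states <- c("HK", "HKp", "RRp")
    x_star <- c(HK, HKp, RRp)
  }
  dimnames(A) <- list(states, states)
  structure(list(A = A, B_u = B_u, B_z = B_z, C = diag(length(states)),
                 states = states, x_star = x_star, u_star = u_star,
                 operating_point = ss, f = f,
                 residual = sqrt(sum(f(x_star, u_star)^2)),
                 architecture = architecture, inducer = I, params = params,
                 seq_phos_only = seq_phos_only),
            class = "linearized_system")
}

#' Linearize the controller (sequestration motif) around the operating point
#'
#' Controller state-space models, with the feedback strength `P` scaling the
#' production gain: the second response regulator controller has states
#' `([SR], [SR_sum])`, the phosphatase controller the single state `[PH]`
#' (first order: `K(jw) = P h'([RR_p]*)/(jw + delta)`), the comparison
#' controllers the single annihilator/repressor state. Inputs are the process
#' outputs `y`, the output is the controlled input `u` fed back to the
#' process.
#'
#' @param process a [linearize_process()] object (fixes the architecture and
#'   operating point).
#' @return object of class `linearized_system` with `A`, `B` (inputs `y`),
#'   `C` (output `u`), and `g`, the nonlinear controller right-hand side
#'   `g(xc, y)` for finite-difference verification.
#' @export
linearize_controller <- function(process) {
  stopifnot(inherits(process, "linearized_system"))
  p <- process$params
  ss <- process$operating_point
  tot <- derived_totals(p)
  HKt <- tot[["HK_tot"]]
  HK <- unname(ss["HK"]); RRp <- unname(ss["RRp"])
  hp <- p$P * h_grad(RRp, p)
  arch <- process$architecture
  if (arch == "closed_loop_phos_seq") {
    SR <- unname(ss["SR"]); SRsum <- SR + unname(ss["SRp"])
    g <- function(xc, y) {
      c(p$P * h_fun(y[2], p) - p$delta * xc[1] -
          p$ktc * (HKt - y[1]) * xc[1] + p$kpc * y[1] * (xc[2] - xc[1]),
        p$P * h_fun(y[2], p) - p$delta * xc[2])
    }
    A <- matrix(c(-p$delta - p$ktc * (HKt - HK) - p$kpc * HK, p$kpc * HK,
                  0, -p$delta), 2, 2, byrow = TRUE)
    B <- matrix(c(p$ktc * SR + p$kpc * (SRsum - SR), hp,
                  0, hp), 2, 2, byrow = TRUE)
    C <- matrix(c(1, 0), 1, 2)
    xc_star <- c(SR, SRsum)
  } else if (arch == "closed_loop_dephos") {
    PH <- unname(ss["PH"])
    g <- function(xc, y) p$P * h_fun(y[2], p) - p$delta * xc[1]
    A <- matrix(-p$delta, 1, 1)
    B <- matrix(c(0, hp), 1, 2)
    C <- matrix(1, 1, 1)
    xc_star <- PH
  } else if (arch == "molecular_seq_feedback") {
    A_star <- unname(ss["A"])
    HKp <- unname(ss["HKp"])
    gb <- if (isTRUE(process$seq_phos_only)) 0 else p$k_bind
    g <- function(xc, y) {
      p$P * h_fun(y[3], p) - p$delta * xc[1] -
        gb * xc[1] * y[1] - p$k_bind * xc[1] * y[2]
    }
    A <- matrix(-p$delta - gb * HK - p$k_bind * HKp, 1, 1)
    B <- matrix(c(-gb * A_star, -p$k_bind * A_star, hp), 1, 3)
    C <- matrix(1, 1, 1)
    xc_star <- A_star
  } else {
    TF <- unname(ss["TF"])
    g <- function(xc, y) p$P * h_fun(y[3], p) - p$delta * xc[1]
    A <- matrix(-p$delta, 1, 1)
    B <- matrix(c(0, 0, hp), 1, 3)
    C <- matrix(1, 1, 1)
    xc_star <- TF
  }
  structure(list(A = A, B = B, C = C, g = g, xc_star = xc_star,
                 architecture = arch, P = p$P),
            class = "linearized_system")
}

# transfer function C (jw I - A)^{-1} B at one frequency
tf_eval <- function(A, B, C, omega) {
  n <- nrow(A)
  M <- diag(complex(real = 0, imaginary = omega), n) - A
  C %*% solve(M, B)
}

#' Default log-spaced frequency grid
#'
#' 1e-6 to 1e2 rad/min, 200 points per decade.
#' @return numeric vector of frequencies (rad/min).
#' @export
default_omega_grid <- function() 10^seq(-6, 2, by = 1 / 200)

#' Sensitivity and complementary response on a frequency grid
#'
#' Computes, at every frequency, the sensitivity matrix
#' `S(jw) = (I - G_yu(jw) K(jw))^{-1}` and the closed-loop input response
#' `T(jw) = S(jw) G_yz(jw)`, where `G_yu`, `G_yz` are the process transfer
#' functions from controlled input and inducer channel to the outputs and
#' `K` is the controller. No extra sign is injected: the loop is closed
#' exactly as `Y = T Z + S W`. Magnitudes are spectral (largest singular
#' value) norms. The defining identity `S (I - G_yu K) = I` is verified to
#' `1e-10` at every frequency.
#'
#' @param process a [linearize_process()] object.
#' @param controller a [linearize_controller()] object (or `NULL` for the
#'   open loop, giving `S = I`).
#' @param omega frequency grid (rad/min).
#' @return object of class `frequency_response`: list with `omega`, `S`, `T`
#'   (arrays ny x ny(/1) x length(omega)), `magnitude` (`||S||_2` per
#'   frequency), `T_magnitude`, and `hinf` (grid maximum of the sensitivity
#'   magnitude).
#' @export
sensitivity_response <- function(process, controller, omega = default_omega_grid()) {
  ny <- nrow(process$A)
  Smat <- array(complex(real = 0), c(ny, ny, length(omega)))
  Tmat <- array(complex(real = 0), c(ny, ncol(process$B_z), length(omega)))
  mag <- numeric(length(omega))
  magT <- numeric(length(omega))
  for (k in seq_along(omega)) {
    w <- omega[k]
    G_yu <- tf_eval(process$A, process$B_u, process$C, w)
    G_yz <- tf_eval(process$A, process$B_z, process$C, w)
    K <- if (is.null(controller)) matrix(0, 1, ny) else
      tf_eval(controller$A, controller$B, controller$C, w)
    L <- diag(ny) - G_yu %*% K
    rc <- rcond(L)
    if (!is.finite(rc) || rc < 1e-12) {
      stop(sprintf("return difference (I - G_yu K) is near-singular at omega = %g rad/min", w))
    }
    S <- solve(L)
    if (max(Mod(S %*% L - diag(ny))) > 1e-10) {
      stop(sprintf("sensitivity identity violated at omega = %g rad/min", w))
    }
    Tk <- S %*% G_yz
    Smat[, , k] <- S
    Tmat[, , k] <- Tk
    mag[k] <- max(svd(S)$d)
    magT[k] <- max(svd(Tk)$d)
  }
  structure(list(omega = omega, S = Smat, T = Tmat, magnitude = mag,
                 T_magnitude = magT, hinf = max(mag),
                 omega_at_hinf = omega[which.max(mag)]),
            class = "frequency_response")
}

# scalar ||S(jw)||_2 for one (process, controller) at one frequency
sensitivity_magnitude_at <- function(process, controller, w) {
  ny <- nrow(process$A)
  G_yu <- tf_eval(process$A, process$B_u, process$C, w)
  K <- tf_eval(controller$A, controller$B, controller$C, w)
  max(svd(solve(diag(ny) - G_yu %*% K))$d)
}

#' Grid maximum of the sensitivity magnitude
#'
#' Maximum over inducer concentrations, feedback strengths and frequencies of
#' the spectral norm of the sensitivity function, with one golden-section
#' refinement pass (via [stats::optimize()]) around the grid argmax to guard
#' against peak aliasing.
#'
#' @param architecture a closed-loop architecture label.
#' @param params a [rate_params()] object.
#' @param I_list inducer grid (mM).
#' @param P_list feedback-strength grid.
#' @param omega frequency grid (rad/min).
#' @param seq_phos_only molecular-sequestration variant flag.
#' @return list with `hinf` (the maximum), `argmax` (list `I`, `P`, `omega`)
#'   and `per_point` (data.frame of the per-(I,P) grid maxima).
#' @export
sensitivity_grid_max <- function(architecture, params, I_list, P_list,
                                 omega = default_omega_grid(),
                                 seq_phos_only = FALSE) {
  stopifnot(length(I_list) > 0, length(P_list) > 0)
  rows <- list()
  best <- list(hinf = -Inf)
  for (I in I_list) {
    for (P in P_list) {
      pp <- params
      pp$P <- P
      proc <- linearize_process(architecture, pp, I, seq_phos_only = seq_phos_only)
      ctrl <- linearize_controller(proc)
      fr <- sensitivity_response(proc, ctrl, omega)
      k <- which.max(fr$magnitude)
      # refine the peak within the bracketing grid interval
      lo <- omega[max(1, k - 1)]; hi <- omega[min(length(omega), k + 1)]
      opt <- stats::optimize(function(w) sensitivity_magnitude_at(proc, ctrl, w),
                             lower = lo, upper = hi, maximum = TRUE,
                             tol = .Machine$double.eps^0.5)
      hinf <- max(fr$hinf, opt$objective)
      w_at <- if (opt$objective >= fr$hinf) opt$maximum else fr$omega_at_hinf
      rows[[length(rows) + 1L]] <- data.frame(I_mM = I, P = P, hinf = hinf,
                                              omega = w_at)
      if (hinf > best$hinf) best <- list(hinf = hinf, I = I, P = P, omega = w_at)
    }
  }
  list(hinf = best$hinf, argmax = list(I = best$I, P = best$P, omega = best$omega),
       per_point = do.call(rbind, rows))
}
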