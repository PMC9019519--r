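#' Inducer-dependent autophosphorylation rate
#'
#' Michaelis-Menten dependence of the histidine-kinase autophosphorylation
#' rate on the inducer: `kap(I) = kap_max * I / (I + Kda)`. Monotone
#' nondecreasing in `I` and bounded by `kap_max`.
#'
#' @param I inducer concentration (mM), scalar or vector, `>= 0`.
#' @param params a [rate_params()] object.
#' @return rate (1/min), same length as `I`.
#' @export
autophosphorylation_rate <- function(I, params) {
  if (any(I < 0)) stop("inducer concentration must be >= 0")
  params$kap_max * I / (I + params$Kda)
}

#' RRp-dependent output initiation rate
#'
#' Hill activation of the output promoter by the phosphorylated response
#' regulator: `kout(x) = kout_max * (x/Kdr)^n / ((x/Kdr)^n + 1)`. Monotone
#' nondecreasing and bounded by `kout_max`.
#'
#' @param rrp phosphorylated response regulator level (molecules), `>= 0`.
#' @param params a [rate_params()] object.
#' @return rate (molecules/min), same length as `rrp`.
#' @export
output_initiation_rate <- function(rrp, params) {
  if (any(rrp < 0)) stop("response regulator level must be >= 0")
  u <- (rrp / params$Kdr)^params$n
  params$kout_max * u / (u + 1)
}

# derivative of output_initiation_rate with respect to rrp
output_initiation_grad <- function(rrp, params) {
  x <- pmax(rrp, 0)
  K <- params$Kdr
  n <- params$n
  u <- (x / K)^n
  # d/dx [u/(1+u)] = n u / (x (1+u)^2); finite limit 0 at x = 0 for n > 1
  g <- ifelse(x > 0, params$kout_max * n * u / (x * (1 + u)^2),
              ifelse(n == 1, params$kout_max / K, 0))
  g
}

# --- internal reaction constructors -----------------------------------------
# A reaction is a list: name, type, rate, s (state indices the propensity
# reads), extra (named numeric), and the stoichiometry change `nu` as a named
# integer vector. Types:
#   const   a = rate
#   uni     a = rate * x[s1]
#   bi      a = rate * x[s1] * x[s2]
#   hill    a = rate * (x[s1]/Kd)^n / ((x[s1]/Kd)^n + 1)
#   repress a = rate / (1 + x[s1]/K)
rxn <- function(name, type, rate, s = character(), extra = numeric(), nu) {
  list(name = name, type = type, rate = rate, s = s, extra = extra, nu = nu)
}

#' Build the reaction network for an architecture
#'
#' Constructs species list, integer stoichiometry matrix and propensity
#' descriptors for one architecture. The same network object is the single
#' source of truth for the deterministic ODE ([ode_rhs()], [simulate_network()]),
#' the Gillespie simulator ([ssa_simulate()]) and the linear noise
#' approximation ([lna_moments()]).
#'
#' Architectures:
#' \describe{
#'   \item{`wild_type`}{HK/RR core with Hill-activated output.}
#'   \item{`open_loop_phos_seq`}{adds the second response regulator SR with
#'     constitutive production `beta_SR`.}
#'   \item{`open_loop_dephos`}{adds the phosphatase PH with constitutive
#'     production `beta_PH`.}
#'   \item{`closed_loop_phos_seq`}{dichotomous feedback: SR produced at rate
#'     `P * kout(RRp)` from the output promoter.}
#'   \item{`closed_loop_dephos`}{dichotomous feedback through the phosphatase:
#'     PH produced at `P * kout(RRp)`.}
#'   \item{`molecular_seq_feedback`}{comparison feedback: an annihilator
#'     species A produced at `P * kout(RRp)` binds HK and HKp irreversibly at
#'     rate `k_bind` (or only HKp if `seq_phos_only = TRUE`).}
#'   \item{`transcriptional_feedback`}{comparison feedback: a repressor TF
#'     produced at `P * kout(RRp)` multiplies HK production by
#'     `1/(1 + TF/K_tf)`.}
#' }
#' If `kap_X > 0` the crosstalk kinase X (conserved total `X_tot`, constant
#' phosphorylation rate `kap_X`) is appended; X phosphorylates and
#' dephosphorylates RR - and SR where present - at the same rates as HK.
#' A constitutive output leak is added when `leak > 0`.
#'
#' @param architecture one of [architectures()].
#' @param params a [rate_params()] object; closed-loop and comparison
#'   architectures require `P`, and the comparison architectures require their
#'   matched constant (`k_bind` / `K_tf`) to be set.
#' @param I inducer concentration (mM).
#' @param seq_phos_only logical, `molecular_seq_feedback` only: annihilate
#'   only the phosphorylated kinase.
#' @return object of class `reaction_network`: list with `species`, `stoich`
#'   (species x reactions integer matrix), `reactions` (propensity
#'   descriptors), `params`, `inducer`, `architecture`.
#' @export
build_network <- function(architecture, params, I, seq_phos_only = FALSE) {
  architecture <- match.arg(architecture, architectures())
  closed <- architecture %in% c("closed_loop_phos_seq", "closed_loop_dephos",
                                "molecular_seq_feedback", "transcriptional_feedback")
  if (closed && (!is.finite(params$P) || params$P < 0)) {
    stop("closed-loop architecture requested but feedback strength P is undefined")
  }
  validate_params(params)
  if (length(I) != 1 || I < 0) stop("inducer I must be a single value >= 0")
  p <- params
  kap <- autophosphorylation_rate(I, p)
  rl <- list()
  add <- function(...) rl[[length(rl) + 1L]] <<- rxn(...)

  # core two-component system
  if (architecture == "transcriptional_feedback") {
    if (is.na(p$K_tf)) stop("transcriptional_feedback requires a matched K_tf; see match_comparison_feedback()")
    add("prod_HK", "repress", p$beta_HK, "TF", c(K = p$K_tf), c(HK = 1L))
  } else {
    add("prod_HK", "const", p$beta_HK, nu = c(HK = 1L))
  }
  add("prod_RR", "const", p$beta_RR, nu = c(RR = 1L))
  add("autophos", "uni", kap, "HK", nu = c(HK = -1L, HKp = 1L))
  add("transfer_RR", "bi", p$kt, c("HKp", "RR"),
      nu = c(HKp = -1L, RR = -1L, HK = 1L, RRp = 1L))
  add("dephos_RR", "bi", p$kp, c("HK", "RRp"), nu = c(RRp = -1L, RR = 1L))
  add("prod_Output", "hill", p$kout_max, "RRp",
      c(Kd = p$Kdr, n = p$n), c(Output = 1L))
  if (p$leak > 0) add("leak_Output", "const", p$leak, nu = c(Output = 1L))
  for (sp in c("HK", "HKp", "RR", "RRp", "Output")) {
    add(paste0("dil_", sp), "uni", p$delta, sp, nu = stats::setNames(-1L, sp))
  }

  has_SR <- architecture %in% c("open_loop_phos_seq", "closed_loop_phos_seq")
  has_PH <- architecture %in% c("open_loop_dephos", "closed_loop_dephos")

  if (has_SR) {
    if (architecture == "closed_loop_phos_seq") {
      add("prod_SR", "hill", p$P * p$kout_max, "RRp",
          c(Kd = p$Kdr, n = p$n), c(SR = 1L))
    } else {
      add("prod_SR", "const", p$beta_SR, nu = c(SR = 1L))
    }
    add("transfer_SR", "bi", p$ktc, c("HKp", "SR"),
        nu = c(HKp = -1L, SR = -1L, HK = 1L, SRp = 1L))
    add("dephos_SR", "bi", p$kpc, c("HK", "SRp"), nu = c(SRp = -1L, SR = 1L))
    add("dil_SR", "uni", p$delta, "SR", nu = c(SR = -1L))
    add("dil_SRp", "uni", p$delta, "SRp", nu = c(SRp = -1L))
  }
  if (has_PH) {
    if (architecture == "closed_loop_dephos") {
      add("prod_PH", "hill", p$P * p$kout_max, "RRp",
          c(Kd = p$Kdr, n = p$n), c(PH = 1L))
    } else {
      add("prod_PH", "const", p$beta_PH, nu = c(PH = 1L))
    }
    add("dephos_RR_PH", "bi", p$kpc, c("PH", "RRp"), nu = c(RRp = -1L, RR = 1L))
    add("dil_PH", "uni", p$delta, "PH", nu = c(PH = -1L))
  }
  if (architecture == "molecular_seq_feedback") {
    if (is.na(p$k_bind)) stop("molecular_seq_feedback requires a matched k_bind; see match_comparison_feedback()")
    add("prod_A", "hill", p$P * p$kout_max, "RRp",
        c(Kd = p$Kdr, n = p$n), c(A = 1L))
    if (!seq_phos_only) {
      add("bind_A_HK", "bi", p$k_bind, c("A", "HK"), nu = c(A = -1L, HK = -1L))
    }
    add("bind_A_HKp", "bi", p$k_bind, c("A", "HKp"), nu = c(A = -1L, HKp = -1L))
    add("dil_A", "uni", p$delta, "A", nu = c(A = -1L))
  }
  if (architecture == "transcriptional_feedback") {
    add("prod_TF", "hill", p$P * p$kout_max, "RRp",
        c(Kd = p$Kdr, n = p$n), c(TF = 1L))
    add("dil_TF", "uni", p$delta, "TF", nu = c(TF = -1L))
  }

  if (p$kap_X > 0) {
    # crosstalk kinase: conserved total, constant phosphorylation drive
    add("phos_X", "uni", p$kap_X, "X", nu = c(X = -1L, Xp = 1L))
    add("transfer_RR_X", "bi", p$kt, c("Xp", "RR"),
        nu = c(Xp = -1L, RR = -1L, X = 1L, RRp = 1L))
    add("dephos_RR_X", "bi", p$kp, c("X", "RRp"), nu = c(RRp = -1L, RR = 1L))
    if (has_SR) {
      add("transfer_SR_X", "bi", p$ktc, c("Xp", "SR"),
          nu = c(Xp = -1L, SR = -1L, X = 1L, SRp = 1L))
      add("dephos_SR_X", "bi", p$kpc, c("X", "SRp"), nu = c(SRp = -1L, SR = 1L))
    }
  }

  species <- c("HK", "HKp", "RR", "RRp", "Output",
               if (has_SR) c("SR", "SRp"), if (has_PH) "PH",
               if (architecture == "molecular_seq_feedback") "A",
               if (architecture == "transcriptional_feedback") "TF",
               if (p$kap_X > 0) c("X", "Xp"))
  stoich <- matrix(0L, length(species), length(rl),
                   dimnames = list(species, vapply(rl, `[[`, "", "name")))
  for (j in seq_along(rl)) {
    stoich[names(rl[[j]]$nu), j] <- rl[[j]]$nu
    rl[[j]]$s <- match(rl[[j]]$s, species)  # resolve indices once
  }
  structure(list(species = species, stoich = stoich, reactions = rl,
                 params = p, inducer = I, architecture = architecture,
                 seq_phos_only = seq_phos_only),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %s, I = %g mM: %d species, %d reactions\n",
              x$architecture, x$inducer, length(x$species), ncol(x$stoich)))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Default initial state for a network
#'
#' All species start at zero except the conserved crosstalk kinase, which
#' starts unphosphorylated at `X_tot`.
#'
#' @param network a [build_network()] object.
#' @return named numeric state vector.
#' @export
initial_state <- function(network) {
  x0 <- stats::setNames(numeric(length(network$species)), network$species)
  if ("X" %in% network$species) x0["X"] <- network$params$X_tot
  x0
}

#' Reaction propensities at a state
#'
#' Negative state entries (stiff-solver micro-undershoot) are clamped at 0
#' before rates are evaluated; entries below `-1e-12` in SSA integer states
#' are rejected upstream.
#'
#' @param network a [build_network()] object.
#' @param state numeric state vector, length equal to the species count.
#' @return numeric vector of per-reaction propensities (>= 0).
#' @export
propensities <- function(network, state) {
  if (length(state) != length(network$species)) {
    stop("state dimension (", length(state), ") does not match network species count (",
         length(network$species), ")")
  }
  x <- pmax(as.numeric(state), 0)
  vapply(network$reactions, function(r) {
    switch(r$type,
      const = r$rate,
      uni = r$rate * x[r$s[1]],
      bi = r$rate * x[r$s[1]] * x[r$s[2]],
      hill = {
        u <- (x[r$s[1]] / r$extra[["Kd"]])^r$extra[["n"]]
        r$rate * u / (u + 1)
      },
      repress = r$rate / (1 + x[r$s[1]] / r$extra[["K"]]))
  }, numeric(1))
}

# Jacobian of the propensity vector with respect to the state (analytic).
propensity_jacobian <- function(network, state) {
  x <- pmax(as.numeric(state), 0)
  J <- matrix(0, length(network$reactions), length(network$species))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    switch(r$type,
      const = NULL,
      uni = J[j, r$s[1]] <- r$rate,
      bi = {
        J[j, r$s[1]] <- r$rate * x[r$s[2]]
        J[j, r$s[2]] <- r$rate * x[r$s[1]]
      },
      hill = {
        hp <- list(Kdr = r$extra[["Kd"]], n = r$extra[["n"]], kout_max = r$rate)
        J[j, r$s[1]] <- output_initiation_grad(x[r$s[1]], hp)
      },
      repress = {
        K <- r$extra[["K"]]
        J[j, r$s[1]] <- -r$rate / (K * (1 + x[r$s[1]] / K)^2)
      })
  }
  J
}

#' Deterministic right-hand side of the network ODE
#'
#' Mass-action/Hill rate equations: `dx/dt = stoich %*% propensities(x)`.
#'
#' @param network a [build_network()] object.
#' @param state numeric state vector (nonnegative; entries below `-1e-12`
#'   are rejected, smaller undershoots are clamped).
#' @return named derivative vector (molecules/min).
#' @export
ode_rhs <- function(network, state) {
  bad <- state < -1e-6 * (1 + max(abs(state)))
  if (any(bad)) {
    stop("negative state component(s): ",
         paste(network$species[bad], collapse = ", "))
  }
  a <- propensities(network, state)
  stats::setNames(as.numeric(network$stoich %*% a), network$species)
}

# Jacobian of ode_rhs (analytic; used by LNA and the linearization module)
rhs_jacobian <- function(network, state) {
  network$stoich %*% propensity_jacobian(network, state)
}

#' Export a network as structured text
#'
#' Writes a plain-text, SBML-like description (species, reactions with
#' stoichiometry and rate laws) for interoperability.
#'
#' @param network a [build_network()] object.
#' @param path file path; when missing, the text lines are returned.
#' @return character vector of lines (invisibly when written to a file).
#' @export
export_network <- function(network, path) {
  fmt_side <- function(nu, sgn) {
    ids <- names(nu)[sign(nu) == sgn]
    if (length(ids) == 0) "0" else
      paste(vapply(ids, function(s) {
        k <- abs(nu[[s]])
        if (k == 1) s else paste0(k, " ", s)
      }, ""), collapse = " + ")
  }
  lines <- c(sprintf("# reaction network: %s (I = %g mM)", network$architecture,
                     network$inducer),
             "units: time=min, species=molecules, inducer=mM",
             paste("species:", paste(network$species, collapse = " ")),
             "reactions:")
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    law <- switch(r$type,
      const = sprintf("%g", r$rate),
      uni = sprintf("%g * [%s]", r$rate, network$species[r$s[1]]),
      bi = sprintf("%g * [%s] * [%s]", r$rate, network$species[r$s[1]],
                   network$species[r$s[2]]),
      hill = sprintf("%g * hill([%s]; Kd=%g, n=%g)", r$rate,
                     network$species[r$s[1]], r$extra[["Kd"]], r$extra[["n"]]),
      repress = sprintf("%g / (1 + [%s]/%g)", r$rate,
                        network$species[r$s[1]], r$extra[["K"]]))
    nu <- network$stoich[, j]
    nu <- nu[nu != 0]
    lines <- c(lines, sprintf("  %-16s %s -> %s ; rate = %s", r$name,
                              fmt_side(nu, -1), fmt_side(nu, 1), law))
  }
  if (!missing(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
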