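#' Architectures known to the network builder
#'
#' @return character vector of architecture labels.
#' @export
architectures <- function() {
  c("wild_type", "open_loop_phos_seq", "open_loop_dephos",
    "closed_loop_phos_seq", "closed_loop_dephos",
    "molecular_seq_feedback", "transcriptional_feedback")
}

scenario_names <- function() {
  c("wild_type", "tunability", "noise", "sensitivity", "sensitivity_comparison",
    "step", "crosstalk")
}

#' Named analysis scenarios
#'
#' A scenario packages the architecture set, parameter set, inducer grid,
#' feedback-strength grid and seed for one of the package's standard
#' computational experiments:
#' \describe{
#'   \item{`wild_type`}{the natural two-component system alone, dose-response
#'     over a log-spaced inducer grid.}
#'   \item{`tunability`}{dose-response comparison of wild type, open-loop
#'     sequestration and closed-loop dichotomous feedback, `P` in
#'     0.1/0.4/0.7/1, dense log-spaced inducer grid (25 points per decade).}
#'   \item{`noise`}{intrinsic-noise (cv vs mean) scan of wild type and closed
#'     loop on the discrete inducer grid 0.5/1/2/5/10 mM.}
#'   \item{`sensitivity`}{sensitivity-function robustness scan of the
#'     dichotomous feedback on inducer grid 0.5/1/2/5/10 mM and feedback
#'     strengths 0.1/0.4/0.7/1.}
#'   \item{`sensitivity_comparison`}{same scan for the transcriptional and
#'     molecular-sequestration comparison feedbacks, inducer grid
#'     0.1/1/2/5/10 mM.}
#'   \item{`step`}{step-response (overshoot) comparison of the feedback
#'     architectures at `P = 1`, `I = 10` mM.}
#'   \item{`crosstalk`}{crosstalk-reduction scan with the extra kinase X
#'     (`kap_X = 0.08` 1/min) over feedback strengths 0/0.1/0.4/0.7/1.}
#' }
#'
#' @param name one of `scenario_names()`.
#' @param seed integer seed recorded in the scenario (and so in outputs).
#' @return an object of class `scenario`: list with `name`, `architecture`
#'   (character vector), `params` ([rate_params()]), `inducer_grid` (mM),
#'   `P_grid`, `seed`.
#' @examples
#' scenario("sensitivity")$inducer_grid
#' @export
scenario <- function(name, seed = 1L) {
  if (!is.character(name) || length(name) != 1 || !(name %in% scenario_names())) {
    stop("unknown scenario '", name, "'; known scenarios: ",
         paste(scenario_names(), collapse = ", "))
  }
  params <- nominal_params()
  dense_grid <- log_grid(0.01, 10, per_decade = 25)
  sc <- switch(name,
    wild_type = list(architecture = "wild_type", params = params,
                     inducer_grid = dense_grid, P_grid = 0),
    tunability = {
      # open-loop SR production matched to the P = 1 closed-loop plateau
      params$beta_SR <- 19.2
      list(architecture = c("wild_type", "open_loop_phos_seq",
                            "closed_loop_phos_seq"),
           params = params, inducer_grid = dense_grid,
           P_grid = c(0.1, 0.4, 0.7, 1))
    },
    noise = list(architecture = c("wild_type", "closed_loop_phos_seq"),
                 params = params, inducer_grid = c(0.5, 1, 2, 5, 10),
                 P_grid = c(0.1, 0.4, 0.7, 1)),
    sensitivity = list(architecture = "closed_loop_phos_seq", params = params,
                       inducer_grid = c(0.5, 1, 2, 5, 10),
                       P_grid = c(0.1, 0.4, 0.7, 1)),
    sensitivity_comparison = list(
      architecture = c("transcriptional_feedback", "molecular_seq_feedback"),
      params = params, inducer_grid = c(0.1, 1, 2, 5, 10),
      P_grid = c(0.1, 0.4, 0.7, 1)),
    step = list(architecture = c("closed_loop_phos_seq", "closed_loop_dephos",
                                 "molecular_seq_feedback",
                                 "transcriptional_feedback"),
                params = params, inducer_grid = 10, P_grid = 1),
    crosstalk = {
      params <- nominal_params(crosstalk = TRUE)
      list(architecture = c("wild_type", "closed_loop_phos_seq"),
           params = params,
           inducer_grid = c(0, log_grid(0.01, 10, per_decade = 5)),
           P_grid = c(0, 0.1, 0.4, 0.7, 1))
    })
  sc$name <- name
  sc$seed <- as.integer(seed)
  class(sc) <- "scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  if (length(sc$inducer_grid) == 0 || length(sc$P_grid) == 0) {
    stop("scenario grids must be non-empty")
  }
  if (is.unsorted(sc$inducer_grid, strictly = TRUE) ||
      is.unsorted(sc$P_grid, strictly = TRUE)) {
    stop("scenario grids must be strictly increasing")
  }
  if (length(sc$seed) != 1 || is.na(sc$seed)) stop("scenario seed must be a fixed integer")
  validate_params(sc$params)
  invisible(sc)
}

#' Log-spaced grid
#'
#' @param from,to positive endpoints.
#' @param per_decade points per decade (the default for dose-response curves
#'   is 25).
#' @return numeric vector including both endpoints.
#' @export
log_grid <- function(from, to, per_decade = 25) {
  stopifnot(from > 0, to > from)
  n <- max(2L, ceiling(log10(to / from) * per_decade) + 1L)
  10^seq(log10(from), log10(to), length.out = n)
}

#' Serialize / deserialize a scenario as YAML
#'
#' Scenario files carry explicit units (`units:` block) and the full
#' parameter set with its provenance flags, and round-trip losslessly.
#'
#' @param sc a [scenario()] object.
#' @param path file path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario` returns
#'   the reconstructed `scenario`.
#' @export
write_scenario <- function(sc, path) {
  validate_scenario(sc)
  obj <- list(
    name = sc$name,
    architecture = sc$architecture,
    units = list(time = "min", inducer = "mM", species = "molecules"),
    params = unclass(sc$params)[],
    provenance = as.list(attr(sc$params, "provenance")),
    inducer_grid = sc$inducer_grid,
    P_grid = sc$P_grid,
    seed = sc$seed)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  params <- do.call(rate_params, obj$params)
  attr(params, "provenance") <- unlist(obj$provenance)
  sc <- list(name = obj$name, architecture = obj$architecture, params = params,
             inducer_grid = as.numeric(obj$inducer_grid),
             P_grid = as.numeric(obj$P_grid), seed = as.integer(obj$seed))
  class(sc) <- "scenario"
  validate_scenario(sc)
  sc
}
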