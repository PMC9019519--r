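#' Match comparison-feedback constants to the dichotomous dose-response
#'
#' The molecular-sequestration and transcriptional comparison feedbacks each
#' carry one free constant (the annihilation rate `k_bind`, the repression
#' constant `K_tf`). Following the convention of picking feedback-loop
#' strengths so that the dose-response curves of the architectures
#' approximately match, this routine fits each constant by least squares of
#' the log steady-state output against the dichotomous (closed-loop
#' phosphorylation sequestration) curve over an inducer grid, at the given
#' feedback strength.
#'
#' @param params a [rate_params()] object; constants that are already set
#'   (non-`NA`) are left untouched.
#' @param I_grid inducer grid used for the match (mM).
#' @param P feedback strength at which the curves are matched.
#' @param which which constants to fit.
#' @return `params` with the fitted constants filled in and their provenance
#'   set to `"matched"`.
#' @export
match_comparison_feedback <- function(params, I_grid = c(0.1, 1, 2, 5, 10),
                                      P = 1, which = c("k_bind", "K_tf")) {
  which <- match.arg(which, several.ok = TRUE)
  pp <- params
  pp$P <- P
  ref <- vapply(I_grid, function(I) {
    ss <- steady_state(build_network("closed_loop_phos_seq", pp, I))
    unname(ss["Output"])
  }, numeric(1))
  curve_for <- function(arch, par_name, value) {
    q <- pp
    q[[par_name]] <- value
    vapply(I_grid, function(I) {
      ss <- tryCatch(steady_state(build_network(arch, q, I)),
                     error = function(e) NULL)
      if (is.null(ss)) return(NA_real_)
      unname(ss["Output"])
    }, numeric(1))
  }
  obj <- function(arch, par_name) {
    function(log10v) {
      out <- curve_for(arch, par_name, 10^log10v)
      if (any(!is.finite(out)) || any(out <= 0)) return(1e6)
      sum((log(out) - log(ref))^2)
    }
  }
  prov <- attr(params, "provenance")
  if ("k_bind" %in% which && is.na(params$k_bind)) {
    fit <- stats::optimize(obj("molecular_seq_feedback", "k_bind"),
                           lower = -6, upper = 1)
    params$k_bind <- 10^fit$minimum
    prov["k_bind"] <- "matched"
  }
  if ("K_tf" %in% which && is.na(params$K_tf)) {
    fit <- stats::optimize(obj("transcriptional_feedback", "K_tf"),
                           lower = -2, upper = 5)
    params$K_tf <- 10^fit$minimum
    prov["K_tf"] <- "matched"
  }
  attr(params, "provenance") <- prov
  params
}
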