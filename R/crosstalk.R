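#' Crosstalk-reduction scan
#'
#' Quantifies how feedback architectures suppress the response caused by an
#' extra histidine kinase X that phosphorylates the response regulator (and
#' the sequestration regulator, where present) at the same rates as HK, with
#' a constant phosphorylation drive `kap_X`. For each feedback strength (plus
#' the wild type) the basal steady-state output (`I = 0`), the maximal output
#' (top of the inducer grid) and the max- and basal-normalized dose-response
#' curves are reported.
#'
#' @param params a [rate_params()] object with `kap_X > 0`.
#' @param P_list feedback strengths to scan (`0` rows reproduce the wild
#'   type's response exactly).
#' @param I_grid inducer grid (mM); must contain 0 (basal) and its maximum is
#'   used as "saturating".
#' @param architecture feedback architecture for the closed-loop rows.
#' @param seq_phos_only molecular-sequestration variant flag.
#' @return object of class `crosstalk_report`: data.frame with columns
#'   `architecture`, `P`, `I_mM`, `output`, `basal_output`, `max_output`,
#'   `max_normalized`, `basal_normalized`, `units`.
#' @export
crosstalk_scan <- function(params, P_list, I_grid,
                           architecture = "closed_loop_phos_seq",
                           seq_phos_only = FALSE) {
  validate_params(params)
  if (params$kap_X <= 0) stop("crosstalk_scan requires kap_X > 0")
  if (!any(I_grid == 0)) I_grid <- c(0, I_grid)
  I_grid <- sort(unique(I_grid))
  one_curve <- function(arch, P) {
    pp <- params
    pp$P <- if (is.na(P)) 0 else max(P, 0)
    out <- vapply(I_grid, function(I) {
      net <- build_network(arch, pp, I, seq_phos_only = seq_phos_only)
      unname(steady_state(net)["Output"])
    }, numeric(1))
    basal <- out[I_grid == 0]
    maxo <- out[which.max(I_grid)]
    data.frame(architecture = arch, P = P, I_mM = I_grid, output = out,
               basal_output = basal, max_output = maxo,
               max_normalized = out / maxo, basal_normalized = out / basal,
               units = "molecules", stringsAsFactors = FALSE)
  }
  rows <- list(one_curve("wild_type", NA_real_))
  for (P in P_list) {
    rows[[length(rows) + 1L]] <- if (P == 0 && architecture %in%
        c("closed_loop_phos_seq", "closed_loop_dephos")) {
      r <- one_curve(architecture, 0)
      r
    } else {
      one_curve(architecture, P)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("crosstalk_report", class(out))
  out
}

#' Crosstalk scan with a constitutive output leak
#'
#' Adds an RRp- and inducer-independent basal production term to the output
#' promoter and repeats [crosstalk_scan()]. With a dominant leak the basal
#' output approaches `leak/delta` for every feedback strength, so basal
#' expression becomes feedback-independent.
#'
#' @param params a [rate_params()] object with `kap_X > 0`.
#' @param leak constitutive output production rate (molecules/min), >= 0.
#' @param P_list feedback strengths.
#' @param I_grid inducer grid (mM).
#' @param architecture feedback architecture for the closed-loop rows.
#' @return a `crosstalk_report` data.frame (see [crosstalk_scan()]).
#' @export
basal_leak_variant <- function(params, leak, P_list, I_grid,
                               architecture = "closed_loop_phos_seq") {
  if (leak < 0) stop("leak must be >= 0")
  params$leak <- leak
  crosstalk_scan(params, P_list, I_grid, architecture = architecture)
}
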