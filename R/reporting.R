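#' Run configuration for the pipeline commands
#'
#' @param command one of `dose_response`, `step`, `noise`, `sensitivity`,
#'   `crosstalk`, `theory`.
#' @param scenario name of a [scenario()]; command-specific defaults are
#'   taken from it.
#' @param seed integer seed.
#' @param out_csv,out_json output paths (`NULL` to skip writing).
#' @param options named list of command-specific overrides (e.g. `t_probe`,
#'   `n_runs`, `motif`, `I`).
#' @return object of class `run_config`.
#' @export
run_config <- function(command, scenario = NULL, seed = 1L, out_csv = NULL,
                       out_json = NULL, options = list()) {
  command <- match.arg(command, c("dose_response", "step", "noise",
                                  "sensitivity", "crosstalk", "theory"))
  if (!is.null(scenario) && !(scenario %in% scenario_names())) {
    stop("config error: unknown scenario '", scenario, "'")
  }
  if (length(seed) != 1 || is.na(suppressWarnings(as.integer(seed)))) {
    stop("config error: seed must be a single integer")
  }
  structure(list(command = command, scenario = scenario,
                 seed = as.integer(seed), out_csv = out_csv,
                 out_json = out_json, options = options),
            class = "run_config")
}

#' Serialize / parse a run configuration (lossless round-trip)
#'
#' @param config a [run_config()] object.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the reconstructed config.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  run_config(command = obj$command, scenario = obj$scenario,
             seed = obj$seed, out_csv = obj$out_csv, out_json = obj$out_json,
             options = if (is.null(obj$options)) list() else obj$options)
}

# order-independent content hash (FNV-1a over the serialized object) for the
# provenance block; no cryptographic strength intended
config_hash <- function(config) {
  core <- unclass(config)
  core$out_csv <- core$out_json <- NULL  # hash the scientific content only
  raw <- serialize(core, NULL, version = 2)
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Execute a pipeline command
#'
#' Dispatches a [run_config()] to the corresponding analysis, writes the CSV
#' table (comma-separated, UTF-8, '.' decimal, header row, explicit unit
#' columns) and a JSON summary with a provenance block (package version,
#' config hash, seed). Identical configs produce byte-identical outputs.
#'
#' @param config a [run_config()] object.
#' @return list with `table` (the result data.frame) and `summary` (the JSON
#'   summary list), invisibly.
#' @export
run_command <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc_name <- config$scenario
  opt <- config$options
  res <- switch(config$command,
    dose_response = {
      sc <- scenario(if (is.null(sc_name)) "tunability" else sc_name, seed = config$seed)
      tab <- dose_response(sc)
      list(table = tab, summary = list(
        n_curves = length(unique(paste(tab$architecture, tab$P)))))
    },
    step = {
      sc <- scenario(if (is.null(sc_name)) "step" else sc_name, seed = config$seed)
      tab <- step_response(sc)
      list(table = cbind(tab, units = "fraction"),
           summary = list(overshoot = stats::setNames(
             as.list(tab$overshoot), tab$architecture)))
    },
    noise = {
      sc <- scenario(if (is.null(sc_name)) "noise" else sc_name, seed = config$seed)
      t_probe <- if (is.null(opt$t_probe)) 1000 else opt$t_probe
      tab <- cv_vs_mean_curve(sc, t_probe = t_probe)
      tab$time_min <- t_probe
      list(table = tab, summary = list(t_probe_min = t_probe,
                                       cv_range = range(tab$cv)))
    },
    sensitivity = {
      sc <- scenario(if (is.null(sc_name)) "sensitivity" else sc_name,
                     seed = config$seed)
      gm <- sensitivity_grid_max(sc$architecture[1], sc$params,
                                 sc$inducer_grid, sc$P_grid)
      tab <- cbind(architecture = sc$architecture[1], gm$per_point,
                   units = "dimensionless")
      list(table = tab, summary = list(hinf = gm$hinf, argmax = gm$argmax))
    },
    crosstalk = {
      sc <- scenario(if (is.null(sc_name)) "crosstalk" else sc_name,
                     seed = config$seed)
      tab <- crosstalk_scan(sc$params, sc$P_grid, sc$inducer_grid)
      list(table = tab, summary = list(
        basal_over_max = stats::setNames(
          as.list(unique(tab[, c("architecture", "P", "basal_output",
                                 "max_output")])$basal_output /
                    unique(tab[, c("architecture", "P", "basal_output",
                                   "max_output")])$max_output),
          paste0(unique(tab[, c("architecture", "P")])$architecture, "_P",
                 unique(tab[, c("architecture", "P")])$P))))
    },
    theory = {
      params <- nominal_params()
      motif <- if (is.null(opt$motif)) "phos_seq" else opt$motif
      I <- if (is.null(opt$I)) 2 else opt$I
      rep <- check_assumptions(params, I, motif = motif)
      tab <- data.frame(motif = motif, I_mM = I,
                        approx_value = rep$approx_value,
                        full_value = rep$full_value,
                        relative_error = rep$relative_error,
                        valid = rep$valid, units = "molecules",
                        stringsAsFactors = FALSE)
      list(table = tab, summary = list(
        value = rep$approx_value, relative_error = rep$relative_error,
        assumptions = as.list(rep$assumption_ratios), valid = rep$valid))
    })
  prov <- list(package = "tcsfb",
               version = as.character(utils::packageVersion("tcsfb")),
               command = config$command, config_hash = config_hash(config),
               seed = config$seed)
  res$summary <- c(res$summary, list(provenance = prov))
  if (!is.null(config$out_csv)) {
    utils::write.csv(res$table, config$out_csv, row.names = FALSE)
  }
  if (!is.null(config$out_json)) {
    jsonlite::write_json(res$summary, config$out_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(res)
}
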