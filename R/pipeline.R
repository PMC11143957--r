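#' Load a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [run_fit()] / [run_pipeline()].
#' @return A named list.
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  yaml::read_yaml(path)
}

.config_defaults <- list(
  model = "full",
  schema = NULL,
  propagate_mz = TRUE,
  seed = 1L,
  restarts = 2L,
  bootstrap = list(enabled = FALSE, n_reps = 10000L,
                   levels = c(0.95, 0.992), jobs = 1L),
  out = NULL)

#' Fit the transmission model from a configuration and write a report
#'
#' End-to-end single-model run: read (or accept) the family table, apply
#' MZ genotype propagation, fit the requested model (`"full"` or
#' `"no-nurture"`), fit the saturated and baseline reference models,
#' compute the LRT against the saturated model, fit indices, the nurture
#' LRT (full vs. no-nurture, when fitting the full model), the variance
#' decomposition, and optionally bootstrap intervals. The report echoes
#' the configuration, package version and seed for reproducibility, and is
#' written as JSON when `config$out` is set.
#'
#' @param config Named list (or path to a YAML file) with elements `data`
#'   (path to a family CSV, or a data frame), optional `schema` column
#'   map, `model` (`"full"` or `"no-nurture"`), `propagate_mz`, `seed`,
#'   `restarts`, `bootstrap` (list: `enabled`, `n_reps`, `levels`,
#'   `jobs`), `out` (optional JSON output path).
#' @return The report, invisibly (a nested list).
#' @examples
#' fam <- simulate_families(60, 90, seed = 4)
#' rep <- run_fit(list(data = fam, seed = 4))
#' rep$decomposition$r2_total_pct
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  config <- modifyList(.config_defaults, config)
  if (is.null(config$data)) stop("config$data is required")
  if (!config$model %in% c("full", "no-nurture"))
    stop("model must be 'full' or 'no-nurture'")
  records <- if (is.data.frame(config$data)) {
    dat <- config$data
    if (!is.null(config$schema)) {
      schema <- unlist(config$schema)
      missing_cols <- setdiff(schema, names(dat))
      if (length(missing_cols))
        stop("column(s) named in schema not found in data: ",
             paste(missing_cols, collapse = ", "))
      for (canon in names(schema))
        names(dat)[names(dat) == schema[[canon]]] <- canon
    }
    validate_family_records(dat)
  } else {
    read_family_table(config$data, schema = config$schema, quiet = TRUE)
  }
  if (isTRUE(config$propagate_mz))
    records <- propagate_mz_genotypes(records, quiet = TRUE)

  set.seed(config$seed)
  warnings_seen <- character()
  wh <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  fit <- withCallingHandlers(
    fit_transmission(records, restarts = config$restarts), warning = wh)
  target <- if (config$model == "full") fit else
    withCallingHandlers(
      fit_no_nurture(records, restarts = config$restarts), warning = wh)
  sat <- withCallingHandlers(fit_saturated(records), warning = wh)
  base <- withCallingHandlers(fit_baseline(records), warning = wh)
  lrt_sat <- lr_test(sat, target)
  idx <- fit_indices(target, sat, base)
  nurture_lrt <- if (config$model == "full") {
    red <- withCallingHandlers(
      fit_no_nurture(records, restarts = config$restarts), warning = wh)
    lr_test(fit, red)
  } else NULL
  dec <- variance_decomposition(target$params)

  boot <- NULL
  bcfg <- config$bootstrap
  if (isTRUE(bcfg$enabled)) {
    boot <- withCallingHandlers(
      bootstrap_transmission(records, n_reps = bcfg$n_reps,
                             levels = bcfg$levels, seed = config$seed,
                             base_fit = fit, jobs = bcfg$jobs %||% 1L,
                             keep_samples = FALSE),
      warning = wh)
  }

  report <- list(
    package = "pgstransmit",
    version = as.character(packageVersion("pgstransmit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[c("model", "propagate_mz", "seed", "restarts")],
    n_families = target$n_families,
    n_mz = target$n_mz, n_dz = target$n_dz,
    model = list(
      name = target$model,
      converged = target$converged,
      boundary = target$boundary,
      loglik = target$loglik,
      n_free = target$n_free,
      estimates = unclass(target$params)),
    standardized = as.list(standardize_effects(target$params)),
    decomposition = list(
      r2_total_pct = round(100 * dec$r2_total, 1),
      r2_gt_pct = round(100 * dec$r2_gt, 1),
      r2_gn_pct = round(100 * dec$r2_gn, 1),
      r2_total = dec$r2_total, r2_gt = dec$r2_gt, r2_gn = dec$r2_gn,
      v_phen = dec$v_phen),
    lrt_saturated = unclass(lrt_sat),
    fit_indices = unclass(idx),
    nurture_lrt = if (!is.null(nurture_lrt)) unclass(nurture_lrt),
    bootstrap = if (!is.null(boot)) list(
      n_reps = boot$n_reps, levels = boot$levels,
      n_failed = boot$n_failed,
      intervals = lapply(boot$intervals, function(ci)
        apply(ci, 2, as.list)),
      significant = lapply(boot$significant, as.list))
    else list(available = FALSE),
    warnings = warnings_seen)
  if (!is.null(config$out)) {
    dir.create(dirname(config$out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, config$out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(report)
}

#' Run the transmission model over several PGS/phenotype combinations
#'
#' Mirrors a study design where the same model is fitted once per
#' combination of polygenic score, phenotype dimension and developmental
#' period (e.g. 2 PGS x 2 dimensions x 2 periods = 8 models). Each entry
#' of `config$combinations` is a named column map (`schema`) selecting the
#' PGS and phenotype columns for that run; every combination is fitted
#' independently with [run_fit()].
#'
#' @param config As [run_fit()], plus `combinations`: a named list of
#'   schema maps. When absent, a single [run_fit()] is performed.
#' @return Invisibly, a list with one report per combination.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  if (is.null(config$combinations)) {
    rep <- run_fit(config)
    return(invisible(list(reports = list(default = rep))))
  }
  combos <- config$combinations
  if (is.null(names(combos)) || any(names(combos) == ""))
    stop("config$combinations must be a named list of schema maps")
  out_base <- config$out
  reports <- lapply(names(combos), function(nm) {
    cfg <- config
    cfg$combinations <- NULL
    cfg$schema <- combos[[nm]]
    cfg$out <- if (!is.null(out_base))
      file.path(dirname(out_base),
                paste0(sub("\\.json$", "", basename(out_base)),
                       "_", nm, ".json"))
    run_fit(cfg)
  })
  names(reports) <- names(combos)
  invisible(list(reports = reports))
}
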