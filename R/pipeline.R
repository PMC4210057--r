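#' @title Pipeline orchestration: simulate, fit, select, report
#' @name run_pipeline
#' @description Runs the analysis stages from a single JSON config and
#' writes plain CSV/JSON artifacts plus a run manifest into `out_dir`.
#' Stage dependencies are checked (`fit` needs the simulated or supplied
#' data, `report` needs a fit); failures abort with a stage-named condition.
#'
#' Config keys (all optional, defaults in parentheses): `seed` (1);
#' `simulate`: arguments of [sim_config()] except functions and tables;
#' `model`: `pollutants` (`["NOx","O3"]`), `n_basis_time` (20),
#' `n_basis_temp` (10), `degree` (3); `select`: `enabled` (false),
#' `strategy` ("all_subsets"), `alpha` (0.05); `control`: tolerances of
#' [fit_star()].
NULL

.adstar_error <- function(class, msg) {
  stop(structure(class = c(class, "adstar_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      .adstar_error("adstar_config_error", sprintf("config file not found: %s", config))
    config <- tryCatch(jsonlite::read_json(config, simplifyVector = TRUE),
                       error = function(e)
                         .adstar_error("adstar_config_error",
                                       paste("config is not valid JSON:", conditionMessage(e))))
  }
  if (!is.list(config)) .adstar_error("adstar_config_error", "config must be a list or JSON file")
  known <- c("seed", "simulate", "model", "select", "control")
  bad <- setdiff(names(config), known)
  if (length(bad))
    .adstar_error("adstar_config_error",
                  sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  config
}

#' Run the analysis pipeline
#'
#' @param config path to a JSON config file, or an equivalent list.
#' @param out_dir output directory (created if missing).
#' @param stages subset of `c("simulate", "fit", "select", "report")`.
#' @param seed optional override of the config seed.
#' @param data optional list with `panel`, `covariates`, `calendar`, `graph`
#'   to use instead of the `simulate` stage's output (for real data).
#' @return the run manifest (invisibly a list, also written as
#'   `manifest.json`), with elements `artifacts`, `fit`, `selection` where
#'   applicable.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("adstar_run_"),
                         stages = c("simulate", "fit", "select", "report"),
                         seed = NULL, data = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- .read_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("adstar")),
                   seed = cfg$seed, config_hash = .hash_config(cfg),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = stages, artifacts = list())
  art <- function(name, path) manifest$artifacts[[name]] <<- path

  if ("simulate" %in% stages) {
    sim_args <- cfg$simulate %||% list()
    sim_args$seed <- cfg$seed
    sc <- do.call(sim_config, sim_args)
    data <- generate_panel(sc)
    utils::write.csv(data$panel, file.path(out_dir, "panel.csv"), row.names = FALSE)
    utils::write.csv(data$covariates, file.path(out_dir, "covariates.csv"), row.names = FALSE)
    write_calendar(data$calendar, file.path(out_dir, "calendar.csv"))
    write_adjacency(data$graph, file.path(out_dir, "adjacency.txt"))
    truth <- data$truth
    truth$eta <- NULL; truth$temp_effect <- NULL; truth$time_effect <- NULL
    truth$f_temp <- NULL
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    for (f in c("panel.csv", "covariates.csv", "calendar.csv",
                "adjacency.txt", "truth.json")) art(f, file.path(out_dir, f))
  }
  if (any(c("fit", "select", "report") %in% stages) && is.null(data))
    .adstar_error("adstar_dependency_error",
                  "stage 'fit' needs data: run 'simulate' first or pass `data`")

  fit <- NULL
  spec <- do.call(model_spec, utils::modifyList(
    list(pollutants = c("NOx", "O3")), cfg$model %||% list()))
  ctl <- cfg$control %||% list()

  if ("fit" %in% stages) {
    fit <- tryCatch(
      fit_star(build_design(data$panel, data$covariates, data$calendar,
                            data$graph, spec), control = ctl),
      error = function(e) {
        if (inherits(e, "adstar_error")) stop(e)
        .adstar_error("adstar_convergence_error",
                      paste("stage 'fit' failed:", conditionMessage(e)))
      })
    coefs <- data.frame(term = names(fit$coefficients),
                        estimate = unname(fit$coefficients),
                        se = unname(fit$se))
    utils::write.csv(coefs, file.path(out_dir, "coefficients.csv"), row.names = FALSE)
    diag <- list(loglik = fit$loglik, aic = fit$aic, edf = as.list(fit$edf),
                 edf_total = fit$edf_total, variances = as.list(fit$variances),
                 inner_iter = fit$inner_iter, outer_iter = fit$outer_iter,
                 converged = fit$converged, grad_norm = fit$grad_norm)
    jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    art("coefficients.csv", file.path(out_dir, "coefficients.csv"))
    art("diagnostics.json", file.path(out_dir, "diagnostics.json"))
  }

  if ("select" %in% stages) {
    sl <- cfg$select %||% list()
    sel <- select_pollutants(data$panel, data$covariates, data$calendar,
                             data$graph, base_spec = spec,
                             strategy = sl$strategy %||% "all_subsets",
                             alpha = sl$alpha %||% 0.05, control = ctl)
    utils::write.csv(sel$table, file.path(out_dir, "candidates.csv"), row.names = FALSE)
    jsonlite::write_json(list(selected = sel$selected, message = sel$message),
                         file.path(out_dir, "selected.json"), auto_unbox = TRUE)
    art("candidates.csv", file.path(out_dir, "candidates.csv"))
    art("selected.json", file.path(out_dir, "selected.json"))
    manifest$selection <- sel$selected
  }

  if ("report" %in% stages) {
    if (is.null(fit))
      .adstar_error("adstar_dependency_error", "stage 'report' needs a fit: include stage 'fit'")
    utils::write.csv(effect_report(fit), file.path(out_dir, "effects.csv"),
                     row.names = FALSE)
    art("effects.csv", file.path(out_dir, "effects.csv"))
    if (spec$use_spatial) {
      utils::write.csv(spatial_effect_map(fit), file.path(out_dir, "spatial.csv"),
                       row.names = FALSE)
      art("spatial.csv", file.path(out_dir, "spatial.csv"))
    }
    for (tm in c("f_time", "f_temp")) {
      if (!any(vapply(fit$blocks, function(b) b$name == tm, TRUE))) next
      utils::write.csv(smoother_curve(fit, tm),
                       file.path(out_dir, paste0("smoother_", tm, ".csv")),
                       row.names = FALSE)
      art(paste0("smoother_", tm, ".csv"),
          file.path(out_dir, paste0("smoother_", tm, ".csv")))
    }
    utils::write.csv(episode_pollutant_summary(data$covariates, data$calendar),
                     file.path(out_dir, "episode_summary.csv"), row.names = FALSE)
    art("episode_summary.csv", file.path(out_dir, "episode_summary.csv"))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$input_digests <- tryCatch(
    as.list(tools::md5sum(unlist(manifest$artifacts))), error = function(e) NULL)
  mf <- manifest
  mf$fit <- NULL
  jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$fit <- fit
  manifest$data <- data
  manifest$out_dir <- out_dir
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable hash of the config: md5 of its canonical JSON serialization
.hash_config <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- cfg[order(names(cfg))]
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
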