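# End-to-end orchestration: estimator comparison across exposures,
# mediation for exposures with mediators, and the Dragonnet + conformal
# individual-treatment-effect analysis for the antiplatelet treatment.
# Stage failures are recorded in the run manifest without aborting the
# remaining stages, mirroring how a multi-estimator comparison is actually
# run.

#' Configure a full analysis run
#'
#' @param cohort a \code{\link{cohort_spec}} (the cohort is generated) or a
#'   path to a cohort CSV in the package schema.
#' @param exposures risk-factor exposures to analyse.
#' @param estimators subset of \code{"naive"}, \code{"logistic-or"},
#'   \code{"sps"}, \code{"ipw"}, \code{"dre"}, \code{"dml-linear"},
#'   \code{"dml-nonlinear"}, \code{"dragonnet"}.
#' @param mediation run natural direct/indirect effect decomposition for
#'   exposures with mediators.
#' @param ite run the Dragonnet + nested conformal ITE analysis for the
#'   antiplatelet treatment.
#' @param out_dir output directory (created if absent); \code{NULL}
#'   disables file output.
#' @param seed global seed propagated to every stochastic component.
#' @param bootstrap_B bootstrap replicates for estimator confidence
#'   intervals (0 disables CIs).
#' @param dragonnet,conformal,dml per-module configuration objects.
#' @param ite_plot also write a box-plot PDF of the stratified ITE summary.
#' @return an object of class \code{analysis_config}.
#' @export
analysis_config <- function(cohort = default_cohort_spec(n = 20000),
                            exposures = c("af", "ht", "dm", "dlp"),
                            estimators = c("naive", "logistic-or", "sps",
                                           "ipw", "dre", "dml-linear",
                                           "dml-nonlinear"),
                            mediation = TRUE, ite = TRUE, out_dir = NULL,
                            seed = 1L, bootstrap_B = 0L,
                            dragonnet = NULL, conformal = NULL, dml = NULL,
                            ite_plot = FALSE) {
  known <- c("naive", "logistic-or", "sps", "ipw", "dre", "dml-linear",
             "dml-nonlinear", "dragonnet")
  bad <- setdiff(estimators, known)
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "))
  if (!length(estimators)) stop("at least one estimator is required")
  structure(list(cohort = cohort, exposures = exposures,
                 estimators = estimators, mediation = mediation, ite = ite,
                 out_dir = out_dir, seed = as.integer(seed),
                 bootstrap_B = as.integer(bootstrap_B),
                 dragonnet = dragonnet, conformal = conformal, dml = dml,
                 ite_plot = ite_plot),
            class = "analysis_config")
}

run_estimator <- function(name, cohort, exposure, adjustment, config) {
  B <- config$bootstrap_B
  ci <- B > 0L
  switch(name,
    "naive" = naive_difference(cohort, exposure),
    "logistic-or" = logistic_or_baseline(cohort, exposure, adjustment),
    "sps" = sps_ate(cohort, exposure, adjustment, ci = ci, B = max(B, 100L),
                    seed = config$seed),
    "ipw" = ipw_ate(cohort, exposure, adjustment, ci = ci, B = max(B, 100L),
                    seed = config$seed),
    "dre" = dre_ate(cohort, exposure, adjustment, ci = ci, B = max(B, 100L),
                    seed = config$seed),
    "dml-linear" = dml_ate(cohort, exposure, adjustment,
                           config = dml_config(variant = "linear",
                                               seed = config$seed)),
    "dml-nonlinear" = dml_ate(cohort, exposure, adjustment,
                              config = dml_config(variant = "nonlinear",
                                                  seed = config$seed)),
    "dragonnet" = {
      dcfg <- config$dragonnet %||% dragonnet_config(seed = config$seed)
      model <- fit_dragonnet(cohort, exposure = exposure, config = dcfg)
      preds <- predict_potential_outcomes(model, cohort)
      dragonnet_ate(preds, cohort, exposure = exposure)
    },
    stop("unknown estimator ", name))
}

#' Run the full analysis
#'
#' For each exposure, derives the backdoor adjustment set from the stroke
#' diagram and runs the requested estimators; runs mediation for exposures
#' with mediators; fits Dragonnet and the nested conformal procedure for
#' the antiplatelet treatment; writes the tidy effects table, per-patient
#' ITE table, stratified summary and a machine-readable JSON manifest
#' (config echo and hash, seeds, package version, per-stage status).  A
#' failing stage is recorded in the manifest and the remaining stages
#' continue.
#'
#' @param config an \code{\link{analysis_config}}.
#' @return invisibly, a list of class \code{analysis_result} with elements
#'   \code{effects} (tidy data frame), \code{mediation}, \code{ite}
#'   (intervals, summary, dragonnet ATE/risk ratio), \code{manifest}.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  t_start <- Sys.time()
  errors <- list()
  note_error <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    message("stage '", stage, "' failed: ", conditionMessage(e))
    NULL
  }
  cohort <- if (inherits(config$cohort, "cohort_spec"))
    generate_cohort(config$cohort)$cohort
  else read_cohort(config$cohort)
  dag <- stroke_dag()
  results <- list()
  for (exposure in config$exposures) {
    adjustment <- backdoor_adjustment_set(dag, exposure, "y")
    for (est in config$estimators) {
      stage <- paste(est, exposure, sep = ":")
      r <- tryCatch(run_estimator(est, cohort, exposure, adjustment, config),
                    error = function(e) note_error(stage, e))
      if (!is.null(r)) results[[stage]] <- r
    }
  }
  effects <- effect_comparison_table(results)
  med <- NULL
  if (config$mediation) {
    with_med <- intersect(config$exposures, c("ht", "dm", "dlp"))
    med <- lapply(stats::setNames(with_med, with_med), function(x)
      tryCatch(mediation_effects(cohort, x, dag = dag,
                                 ci = config$bootstrap_B > 0L,
                                 B = max(config$bootstrap_B, 100L),
                                 seed = config$seed),
               error = function(e) note_error(paste0("mediation:", x), e)))
    for (x in names(med)) {
      m <- med[[x]]
      if (is.null(m)) next
      effects <- rbind(effects,
                       data.frame(estimator = c("nde", "nie"), exposure = x,
                                  scale = "risk-difference",
                                  point = c(m$nde, m$nie),
                                  ci_low = if (!is.null(m$ci))
                                    m$ci["ci_low", c("nde", "nie")]
                                  else NA_real_,
                                  ci_high = if (!is.null(m$ci))
                                    m$ci["ci_high", c("nde", "nie")]
                                  else NA_real_))
    }
  }
  ite <- NULL
  if (config$ite) {
    ite <- tryCatch({
      dcfg <- config$dragonnet %||% dragonnet_config(seed = config$seed)
      ccfg <- config$conformal %||% conformal_config(seed = config$seed)
      model <- fit_dragonnet(cohort, exposure = "t", config = dcfg)
      preds <- predict_potential_outcomes(model, cohort)
      intervals <- nested_ite_intervals(cohort, ccfg,
                                        point = preds$y1_hat - preds$y0_hat)
      summary <- stratified_ite_summary(intervals, cohort)
      list(model = model, predictions = preds, intervals = intervals,
           summary = summary,
           ate = dragonnet_ate(preds, cohort),
           risk_ratio = causal_risk_ratio(preds, seed = config$seed))
    }, error = function(e) note_error("ite", e))
  }
  manifest <- list(
    package = "strokeITE",
    version = as.character(utils::packageVersion("strokeITE")),
    created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    n = nrow(cohort),
    exposures = config$exposures,
    estimators = config$estimators,
    elapsed_s = as.numeric(Sys.time() - t_start, units = "secs"),
    errors = errors)
  out <- structure(list(effects = effects, mediation = med, ite = ite,
                        manifest = manifest, cohort = cohort),
                   class = "analysis_result")
  if (!is.null(config$out_dir)) write_analysis(out, config)
  invisible(out)
}

write_analysis <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(config$out_dir, ...)
  write_csv17(result$effects, f("effects.csv"))
  if (!is.null(result$ite)) {
    export_ite_intervals(result$ite$intervals, f("ite_intervals.csv"))
    export_ite_summary(result$ite$summary, f("ite_summary.csv"))
    if (isTRUE(config$ite_plot)) {
      grDevices::pdf(f("ite_summary.pdf"), width = 7, height = 5)
      plot(result$ite$summary)
      grDevices::dev.off()
    }
  }
  cfg_json <- f("config.json")
  cfg_echo <- config
  cfg_echo$cohort <- if (inherits(config$cohort, "cohort_spec"))
    unclass(config$cohort) else config$cohort
  for (k in c("dragonnet", "conformal", "dml"))
    if (!is.null(cfg_echo[[k]])) cfg_echo[[k]] <- unclass(cfg_echo[[k]])
  jsonlite::write_json(unclass(cfg_echo), cfg_json, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- result$manifest
  manifest$config_md5 <- unname(tools::md5sum(cfg_json))
  manifest$files <- list.files(config$out_dir)
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  validate_outputs(config$out_dir)
  invisible(config$out_dir)
}

# schema validation of the written bundle; errors on malformed output
validate_outputs <- function(out_dir) {
  eff <- utils::read.csv(file.path(out_dir, "effects.csv"))
  need <- c("estimator", "exposure", "scale", "point", "ci_low", "ci_high")
  stopifnot(identical(names(eff), need))
  itf <- file.path(out_dir, "ite_intervals.csv")
  if (file.exists(itf)) {
    iv <- utils::read.csv(itf)
    stopifnot(identical(names(iv),
                        c("patient_id", "point", "lo", "hi", "treated")),
              all(iv$lo <= iv$point + 1e-12),
              all(iv$point <= iv$hi + 1e-12))
  }
  invisible(TRUE)
}

#' Tidy estimator-comparison table
#'
#' Binds a list of \code{\link{effect_estimate}} objects into one row per
#' exposure-estimator pair.
#'
#' @param results list of \code{effect_estimate} objects.
#' @return data frame with columns \code{estimator}, \code{exposure},
#'   \code{scale}, \code{point}, \code{ci_low}, \code{ci_high}.
#' @export
effect_comparison_table <- function(results) {
  if (!length(results))
    return(data.frame(estimator = character(0), exposure = character(0),
                      scale = character(0), point = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0)))
  do.call(rbind, lapply(unname(results), function(r)
    data.frame(estimator = r$estimator, exposure = r$exposure,
               scale = r$scale, point = r$point,
               ci_low = r$ci_low, ci_high = r$ci_high)))
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("analysis_result:", nrow(x$effects), "effect rows; seed",
      x$manifest$seed, "\n")
  print(x$effects, digits = 4)
  if (!is.null(x$ite)) {
    cat("\nITE summary (untreated patients):\n")
    print(as.data.frame(x$ite$summary), digits = 3)
  }
  invisible(x)
}
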