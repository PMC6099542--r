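#' Run the full quantification pipeline
#'
#' Orchestrates the stages end to end: obtain data (generate a synthetic
#' cohort, or read TAC + plasma CSV tables), calibrate parent-fraction
#' models, metabolite-correct the brain TACs, build the arterial input
#' function, fit the kinetic model per subject, apply the %SE exclusion
#' rule, and summarize the groups. Outputs (per-subject `fits.csv`, group
#' `summary.csv`, `pf_models.csv`, `MANIFEST.txt`, `log.txt`) are written
#' under `out_dir`. Identical config and seed give identical outputs.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{generator}{a `generator_config` for synthetic mode, or NULL}
#'     \item{tac_path, plasma_path}{CSV paths for measured-data mode
#'       (used when `generator` is NULL); subject group is taken from the
#'       `subject_id` prefix before `_`}
#'     \item{pf_points}{PF calibration points as in [default_pf_points()]}
#'     \item{exclusion_threshold}{%SE exclusion threshold, default 50}
#'     \item{vB}{fixed blood volume fraction, default 0.05}
#'     \item{out_dir}{output directory}
#'   }
#' @return invisibly, a list with `fits`, `exclusion`, `summary`,
#'   `pf_plasma`, `pf_brain`, and the output paths.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  threshold <- config$exclusion_threshold %||% 50
  if (threshold <= 0) stop("exclusion threshold must be positive")
  vB <- config$vB %||% 0.05
  pf_points <- config$pf_points %||% default_pf_points()

  stages_done <- character(0)
  log_lines <- c(
    paste0("petkin ", as.character(utils::packageVersion("petkin"))),
    paste0("R ", R.version.string),
    paste0("run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("exclusion_threshold = ", threshold),
    paste0("vB = ", vB),
    "weights = duration; bounds = [0, 10]; multi-start = 0.01/0.1/1")
  finish_manifest <- function(complete, failed_stage = NULL) {
    lines <- c(paste0("complete: ", if (complete) "yes" else "NO"),
               paste0("stages_done: ", paste(stages_done, collapse = ", ")))
    if (!is.null(failed_stage))
      lines <- c(lines, paste0("failed_stage: ", failed_stage))
    writeLines(lines, file.path(out_dir, "MANIFEST.txt"))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      finish_manifest(FALSE, name)
      writeLines(c(log_lines, paste0("ERROR in stage ", name, ": ",
                                     conditionMessage(e))),
                 file.path(out_dir, "log.txt"))
      stop("pipeline failed in stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    stages_done <<- c(stages_done, name)
    res
  }

  # --- data -----------------------------------------------------------------
  data <- stage("data", {
    if (!is.null(config$generator)) {
      cohort <- generate_cohort(config$generator)
      log_lines <- c(log_lines,
                     paste0("mode = synthetic, base_seed = ",
                            cohort$config$base_seed))
      list(tacs = lapply(cohort$subjects, `[[`, "tac_noisy"),
           groups = vapply(cohort$subjects, `[[`, "", "group"),
           ids = vapply(cohort$subjects, `[[`, "", "subject_id"),
           plasma = cohort$plasma)
    } else {
      if (is.null(config$tac_path) || !file.exists(config$tac_path))
        stop("TAC table not found: ", config$tac_path)
      tacs <- read_tac_table(config$tac_path)
      list(tacs = tacs,
           groups = sub("_.*$", "", vapply(tacs, `[[`, "", "subject_id")),
           ids = vapply(tacs, `[[`, "", "subject_id"),
           plasma = NULL)
    }
  })

  # --- metabolism -----------------------------------------------------------
  pf <- stage("metabolism", {
    list(plasma = pf_calibrate(pf_points$plasma$time_min,
                               pf_points$plasma$fraction, "plasma"),
         brain = pf_calibrate(pf_points$brain$time_min,
                              pf_points$brain$fraction, "brain"))
  })
  corrected <- stage("metabolism", lapply(data$tacs, correct_tac_for_metabolites,
                                          brain_pf = pf$brain))

  # --- input function -------------------------------------------------------
  aif <- stage("input_function", {
    plasma <- data$plasma
    if (is.null(plasma)) {
      if (is.null(config$plasma_path) || !file.exists(config$plasma_path))
        stop("plasma table not found: ", config$plasma_path)
      plasma <- read_plasma_table(config$plasma_path)
    }
    build_aif(plasma, pf$plasma)
  })

  # --- fitting --------------------------------------------------------------
  fits <- stage("fit", lapply(corrected, fit_tac, aif = aif, vB = vB))
  exclusion <- stage("exclude", apply_exclusion(fits, threshold))
  fit_df <- write_fit_table(fits, data$ids,
                            vapply(data$tacs, `[[`, "", "region"),
                            file.path(out_dir, "fits.csv"),
                            exclusion = exclusion)

  # --- summary --------------------------------------------------------------
  summary_df <- stage("summarize", {
    keep <- exclusion$reasons == ""
    is_ctrl <- data$groups == "control"
    aucs <- vapply(data$tacs, auc_trapezoid, numeric(1L))
    summarize_groups(fits[keep & is_ctrl], fits[keep & !is_ctrl],
                     auc_control = aucs[keep & is_ctrl],
                     auc_lps = aucs[keep & !is_ctrl])
  })
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(compartment = c("plasma", "brain"),
               a = c(pf$plasma$a, pf$brain$a),
               t50 = c(pf$plasma$t50, pf$brain$t50),
               n = c(pf$plasma$n, pf$brain$n)),
    file.path(out_dir, "pf_models.csv"), row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  finish_manifest(TRUE)

  invisible(list(fits = fits, exclusion = exclusion, summary = summary_df,
                 pf_plasma = pf$plasma, pf_brain = pf$brain, aif = aif,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
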