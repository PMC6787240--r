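#' Pipeline configuration
#'
#' Bundles every tunable of the per-patient pipeline and the cohort
#' statistics: the isocontour fraction (0.80 = IC80), the CSF margin
#' cutoff (2400 x 1e-6 mm^2/s), the classifier thresholds (TBRmax > 2,
#' ADCmean > 1254), the midline location, and bootstrap settings for the
#' biparametric envelope.
#'
#' @param isocontour_fraction Fraction of the lesion maximum delimiting
#'   the VOI, in (0, 1).
#' @param csf_cutoff ADC cutoff for margin adaptation (10^-6 mm^2/s).
#' @param theta_tbr,theta_adc Classifier thresholds.
#' @param midline_world_x World x of the mid-sagittal plane, mm.
#' @param boot,boot_seed Bootstrap resamples and seed for
#'   [bivariate_roc()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(isocontour_fraction = 0.80,
                            csf_cutoff = 2400,
                            theta_tbr = 2, theta_adc = 1254,
                            midline_world_x = 0,
                            boot = 2000, boot_seed = 1L) {
  if (isocontour_fraction <= 0 || isocontour_fraction >= 1)
    stop("`isocontour_fraction` must lie in (0, 1)")
  if (!is.finite(theta_tbr) || !is.finite(theta_adc))
    stop("classifier thresholds must be finite")
  structure(
    list(isocontour_fraction = isocontour_fraction,
         csf_cutoff = csf_cutoff,
         theta_tbr = theta_tbr, theta_adc = theta_adc,
         midline_world_x = midline_world_x,
         boot = boot, boot_seed = as.integer(boot_seed)),
    class = "pipeline_config")
}

#' Run the full per-patient pipeline
#'
#' Composes segmentation, transfer, margin adaptation, background
#' mirroring and quantification for one SUV/ADC pair: IC80 hot components
#' on the SUV volume, prominent-lesion selection, local isocontour VOI,
#' nearest-neighbour transfer to the ADC grid, CSF margin adaptation,
#' representative-slice mirrored background ROI (measured at the same
#' anatomical locus on both grids), and the metric set. Deterministic
#' given inputs and configuration.
#'
#' @param config A [pipeline_config()].
#' @param suv,adc `scalar_volume`s, or paths to NIfTI files.
#' @param patient_id Identifier carried into the metrics.
#' @param brain_mask Optional logical array on the SUV grid; defaults to
#'   the positive-valued voxels (phantoms are zero outside the brain).
#' @param exclusion_mask Optional logical array on the ADC grid (e.g. a
#'   resection cavity) removed during margin adaptation.
#' @param reference_point_mm Optional world point for prominent-lesion
#'   tie-breaking.
#' @return A `lesion_metrics` object; attribute `"provenance"` records
#'   seed voxel, absolute threshold, VOI sizes and background location.
#' @export
run_patient <- function(config, suv, adc, patient_id = NA_character_,
                        brain_mask = NULL, exclusion_mask = NULL,
                        reference_point_mm = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(suv)) suv <- read_volume(suv, "SUV")
  if (is.character(adc)) adc <- read_volume(adc, "ADC")
  if (is.null(brain_mask)) brain_mask <- suv$data > 0

  comps <- find_hot_components(suv, brain_mask, config$isocontour_fraction)
  lesion <- select_prominent_lesion(comps, reference_point_mm, suv)
  voi_suv <- isocontour_voi(suv, lesion, grid_id = "suv")

  voi_adc <- transfer_voi(voi_suv, suv, adc, grid_id = "adc")
  voi_adc <- adapt_margins(voi_adc, adc, csf_cutoff = config$csf_cutoff,
                           exclusion_mask = exclusion_mask)

  k <- representative_slice(suv, voi_suv)
  bg_suv <- mirror_background_roi(suv, voi_suv, k,
                                  midline_world_x = config$midline_world_x,
                                  brain_mask = brain_mask)
  bg_roi_as_voi <- lesion_voi(bg_suv$voxels, grid_id = "suv")
  bg_adc <- transfer_voi(bg_roi_as_voi, suv, adc, grid_id = "adc")

  metrics <- compute_metrics(suv, adc, voi_suv, voi_adc, bg_suv, bg_adc,
                             patient_id = patient_id)
  attr(metrics, "provenance") <- list(
    seed_voxel = voi_suv$seed_voxel,
    absolute_threshold = voi_suv$absolute_threshold,
    voi_suv_voxels = nrow(voi_suv$voxels),
    voi_adc_voxels = nrow(voi_adc$voxels),
    representative_slice = k,
    background_center_mm = bg_suv$center_mm,
    n_components = length(comps))
  metrics
}

#' Run the pipeline over a cohort and compute cohort statistics
#'
#' Applies [run_patient()] to every row of a cohort manifest, collects
#' the per-patient metrics, and — when labels are present and both groups
#' non-degenerate — computes the cohort statistics: the four group
#' comparisons (ADCmean, rADCmean, TBR80mean, TBRmax), univariate ROC
#' curves with Youden cutoffs for ADCmean and TBRmax, the biparametric
#' OR-rule envelope, ROC comparisons, and diagnostic measures of the
#' fixed rules. Per-patient failures are logged and reported, not fatal.
#'
#' @param config A [pipeline_config()].
#' @param manifest Data frame with columns `patient_id`, `suv_path`,
#'   `adc_path` and optionally `group` (`REC`/`PTRE`), or the path to such
#'   a CSV (as written by [generate_cohort()]).
#' @param metrics_csv Optional path: write the per-patient metric rows.
#' @param report_json Optional path: write the cohort report as JSON.
#' @return An object of class `cohort_report`: `metrics` (data frame),
#'   `comparisons`, `roc`, `cutoffs`, `envelope`, `roc_comparisons`,
#'   `diagnostics`, `failures`, `degenerate`.
#' @export
run_cohort <- function(config, manifest, metrics_csv = NULL,
                       report_json = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0L) stop("empty cohort manifest")
  if (anyDuplicated(manifest$patient_id))
    stop("`patient_id` values must be unique")

  rows <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    m <- tryCatch(
      run_patient(config, r$suv_path, r$adc_path, patient_id = r$patient_id),
      error = function(e) e)
    if (inherits(m, "error")) {
      failures[[length(failures) + 1L]] <-
        list(patient_id = r$patient_id, message = conditionMessage(m))
      message(sprintf("fetadc: patient %s failed: %s",
                      r$patient_id, conditionMessage(m)))
    } else {
      rows[[length(rows) + 1L]] <- as.data.frame(m)
    }
  }
  if (length(rows) == 0L) stop("no patient could be processed")
  metrics <- do.call(rbind, rows)
  if (!is.null(manifest$group))
    metrics$group <- manifest$group[match(metrics$patient_id,
                                          manifest$patient_id)]
  if (!is.null(metrics_csv))
    utils::write.csv(metrics, metrics_csv, row.names = FALSE)

  report <- structure(
    list(metrics = metrics, comparisons = NULL, roc = NULL, cutoffs = NULL,
         envelope = NULL, roc_comparisons = NULL, diagnostics = NULL,
         failures = failures, degenerate = TRUE, config = config),
    class = "cohort_report")

  has_groups <- !is.null(metrics$group) &&
    all(c(sum(metrics$group == "REC"), sum(metrics$group == "PTRE")) >= 2)
  if (!has_groups) {
    report$degenerate_reason <-
      "fewer than 2 patients per group: t-tests and ROC analysis are degenerate"
    finish_report(report, report_json)
    return(report)
  }
  report$degenerate <- FALSE

  g <- metrics$group
  grab <- function(col) split(metrics[[col]], g)
  report$comparisons <- lapply(
    c(adc_mean = "adc_mean", radc_mean = "radc_mean",
      tbr80_mean = "tbr80_mean", tbr_max = "tbr_max"),
    function(col) {
      v <- grab(col)
      independent_t_test(v$REC, v$PTRE, metric = col)
    })

  report$roc <- list(
    adc_mean = empirical_roc(metrics$adc_mean, g, metric = "adc_mean"),
    tbr_max = empirical_roc(metrics$tbr_max, g, metric = "tbr_max"))
  report$cutoffs <- lapply(report$roc, youden_cutoff)
  report$envelope <- bivariate_roc(metrics$tbr_max, metrics$adc_mean, g,
                                   boot = config$boot,
                                   boot_seed = config$boot_seed)
  report$roc_comparisons <- list(
    adc_vs_tbr = compare_roc(report$roc$adc_mean, report$roc$tbr_max,
                             paired = TRUE))

  rule <- classifier_rule(config$theta_tbr, config$theta_adc)
  preds <- vapply(seq_len(nrow(metrics)), function(i)
    classify_biparametric(metrics[i, ], rule), character(1))
  report$diagnostics <- list(
    biparametric = diagnostic_measures(preds, g),
    tbr_only = diagnostic_measures(
      ifelse(metrics$tbr_max > config$theta_tbr, "REC", "PTRE"), g),
    adc_only = diagnostic_measures(
      ifelse(metrics$adc_mean > config$theta_adc, "REC", "PTRE"), g))
  report$rule <- rule

  finish_report(report, report_json)
  report
}

finish_report <- function(report, report_json) {
  if (is.null(report_json)) return(invisible(NULL))
  ser <- unclass(report)
  ser$metrics <- NULL; ser$config <- NULL
  ser$roc <- lapply(ser$roc, function(r)
    unclass(r)[c("metric", "auc", "auc_se", "ci95", "p_value", "n_pos",
                 "n_neg")])
  ser$comparisons <- lapply(ser$comparisons, unclass)
  ser$envelope <- if (!is.null(ser$envelope))
    unclass(ser$envelope)[c("auc", "auc_se", "ci95", "n_pos", "n_neg")]
  ser$diagnostics <- lapply(ser$diagnostics, unclass)
  ser$rule <- if (!is.null(ser$rule)) unclass(ser$rule)
  jsonlite::write_json(ser, report_json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(NULL)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d patients processed, %d failed\n",
              nrow(x$metrics), length(x$failures)))
  if (x$degenerate) {
    cat("  ", x$degenerate_reason, "\n", sep = "")
    return(invisible(x))
  }
  for (cmp in x$comparisons) print(cmp)
  for (r in x$roc) print(r)
  print(x$envelope)
  cat("  biparametric rule: "); print(x$rule)
  print(x$diagnostics$biparametric)
  invisible(x)
}

#' @export
summary.cohort_report <- function(object, ...) {
  m <- object$metrics
  if (!is.null(m$group)) {
    agg <- stats::aggregate(
      m[c("adc_mean", "radc_mean", "tbr80_mean", "tbr_max", "suv_max",
          "suv80_mean", "suv_bg", "adc_bg")],
      by = list(group = m$group), FUN = mean)
    print(agg, row.names = FALSE)
  }
  invisible(object)
}

#' Simulate a calibrated cohort and extract metrics fully in memory
#'
#' Convenience composition used for calibration-recovery studies: draws
#' per-patient phantom specifications from the group calibrations,
#' renders each phantom, runs the full per-patient pipeline, and returns
#' the metric rows together with the generator's truth values — without
#' touching the filesystem.
#'
#' @param calibrations Named list with `group_calibration` elements `REC`
#'   and `PTRE`.
#' @param n_rec,n_ptre Patients per group.
#' @param seed Master seed (controls the whole cohort).
#' @param config A [pipeline_config()].
#' @param ... Geometry/noise overrides forwarded to
#'   [sample_patient_spec()].
#' @return Data frame: metric columns as in [run_cohort()] plus `group`,
#'   `true_tbrmax`, `true_core_adc`; failed patients are dropped with a
#'   message (count in attribute `"n_failed"`).
#' @export
simulate_cohort_metrics <- function(calibrations, n_rec, n_ptre, seed,
                                    config = pipeline_config(), ...) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n_rec + n_ptre)
  groups <- rep(c("REC", "PTRE"), c(n_rec, n_ptre))
  ids <- c(sprintf("REC_%03d", seq_len(n_rec)),
           sprintf("PTRE_%03d", seq_len(n_ptre)))
  rows <- list(); n_failed <- 0L
  for (i in seq_along(ids)) {
    spec <- sample_patient_spec(calibrations[[groups[i]]], seeds[i], ...)
    vols <- render_phantom(spec)
    m <- tryCatch(
      run_patient(config, vols$suv, vols$adc, patient_id = ids[i]),
      error = function(e) e)
    if (inherits(m, "error")) {
      n_failed <- n_failed + 1L
      message(sprintf("fetadc: phantom %s failed: %s",
                      ids[i], conditionMessage(m)))
      next
    }
    df <- as.data.frame(m)
    df$group <- groups[i]
    df$true_tbrmax <- spec$truth$tbrmax
    df$true_core_adc <- spec$truth$core_adc_mean
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  out
}
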