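#' Published cut-point sets for typically developing children
#'
#' Packaged reference boundaries (counts per minute) from existing
#' ActiGraph calibration studies in typically developing children, for
#' comparison against newly calibrated sets.  Studies reporting only an
#' MVPA boundary, or a combined sedentary + light bound, carry the
#' detail in `note`; missing boundaries are `NA`, never zero.
#'
#' @return data frame with columns `study`, `year`, `axis`,
#'   `sedentary_upper_cpm`, `moderate_lower_cpm`, `moderate_upper_cpm`,
#'   `vigorous_lower_cpm`, `mvpa_lower_cpm`, `note`.
#' @export
reference_cutpoints <- function() {
  path <- system.file("extdata", "reference_cutpoints.csv",
                      package = "accelcal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Compare a calibrated cut-point set against reference sets
#'
#' For each reference study on the same axis, reports the difference
#' (reference minus calibrated, cpm) in the sedentary upper, moderate
#' lower and vigorous lower boundaries, plus `moderate_gap` (the
#' reference moderate lower bound minus the calibrated moderate upper
#' bound) and a `misclassification_flag` raised when that gap is
#' positive: activity the calibrated set calls moderate would then fall
#' entirely below the reference study's moderate range.
#'
#' @param cutpoints a [cutpoint_set()] (boundaries carried in cpm).
#' @param references data frame in the layout of [reference_cutpoints()].
#' @return data frame, one row per reference study on the same axis.
#' @export
compare_to_reference <- function(cutpoints, references = reference_cutpoints()) {
  assert_that(inherits(cutpoints, "cutpoint_set"), "invalid cutpoints")
  ref <- references[references$axis == cutpoints$axis, , drop = FALSE]
  data.frame(
    study = ref$study, year = ref$year, axis = ref$axis,
    d_sedentary_upper = ref$sedentary_upper_cpm - cutpoints$sedentary_upper_cpm,
    d_moderate_lower = ref$moderate_lower_cpm - cutpoints$moderate_lower_cpm,
    d_vigorous_lower = ref$vigorous_lower_cpm - cutpoints$vigorous_lower_cpm,
    moderate_gap = ref$moderate_lower_cpm - cutpoints$moderate_upper_cpm,
    misclassification_flag = !is.na(ref$moderate_lower_cpm) &
      ref$moderate_lower_cpm > cutpoints$moderate_upper_cpm,
    row.names = NULL
  )
}

#' Express a calibrated cut-point set as a reference-table row
#'
#' Useful for placing a newly calibrated set alongside
#' [reference_cutpoints()] or for self-comparison.
#'
#' @param cutpoints a [cutpoint_set()].
#' @param study,year labels for the row.
#' @return one-row data frame in the [reference_cutpoints()] layout.
#' @export
as_reference <- function(cutpoints, study = "current", year = NA_integer_) {
  data.frame(study = study, year = year, axis = cutpoints$axis,
             sedentary_upper_cpm = cutpoints$sedentary_upper_cpm,
             moderate_lower_cpm = cutpoints$moderate_lower_cpm,
             moderate_upper_cpm = cutpoints$moderate_upper_cpm,
             vigorous_lower_cpm = cutpoints$vigorous_lower_cpm,
             mvpa_lower_cpm = cutpoints$mvpa_lower_cpm,
             note = "")
}

#' Recruitment rate as a percentage
#'
#' @param enrolled number of children taking part.
#' @param invited number of information packs handed out.
#' @return percentage on 0-100.
#' @examples
#' recruitment_rate(50, 86)  # 58.14%
#' @export
recruitment_rate <- function(enrolled, invited) {
  assert_that(invited > 0 && enrolled >= 0 && enrolled <= invited,
              "need 0 <= enrolled <= invited")
  100 * enrolled / invited
}

#' Observations per minute of a momentary time-sampling scheme
#'
#' @param interval_s seconds per observation interval (observe + record).
#' @return observations per minute (3 for the 20-s SOFIT cadence).
#' @export
observations_per_minute <- function(interval_s = 20) {
  assert_that(interval_s > 0, "interval must be positive")
  60 / interval_s
}

#' Minutes represented by a number of 20-s analysis epochs
#'
#' @param n_epochs count of 20-s epochs.
#' @return minutes (`n_epochs / 3`).
#' @export
minutes_from_epochs <- function(n_epochs) {
  assert_that(all(n_epochs >= 0), "epoch counts must be nonnegative")
  n_epochs / 3
}

# SOFIT category -> reported intensity of the criterion measure
category_intensity <- c("sedentary", "sedentary", "light", "moderate", "vigorous")

#' Minutes per intensity implied by the observation criterion
#'
#' Maps each aligned epoch's criterion category to an intensity
#' (1, 2 sedentary; 3 light; 4 moderate; 5 vigorous) and accumulates
#' minutes at 3 epochs per minute.  Minutes across intensities always
#' sum to the total aligned minutes.
#'
#' @param aligned data frame with a `category` column of 20-s epochs.
#' @return data frame with columns `intensity`, `n_epochs`, `minutes`.
#' @export
criterion_minutes <- function(aligned) {
  lev <- c("sedentary", "light", "moderate", "vigorous")
  f <- factor(category_intensity[aligned$category], levels = lev)
  n <- as.integer(table(f))
  data.frame(intensity = lev, n_epochs = n, minutes = minutes_from_epochs(n))
}

#' Percentage of session time in each observation category
#'
#' Per-session composition of valid observation records over the five
#' SOFIT categories; each row sums to 100 (up to rounding only if you
#' round it).
#'
#' @param sofit data frame from [read_sofit_log()] or a simulated study.
#' @return data frame with columns `session`, `n_intervals`, and
#'   `lying_down`, `sitting`, `standing`, `walking`, `very_active`
#'   percentages.
#' @export
session_category_percentages <- function(sofit) {
  keep <- sofit[sofit$valid, , drop = FALSE]
  out <- lapply(split(keep, keep$session), function(d) {
    pct <- 100 * tabulate(d$category, 5L) / nrow(d)
    data.frame(session = d$session[1], n_intervals = nrow(d),
               lying_down = pct[1], sitting = pct[2], standing = pct[3],
               walking = pct[4], very_active = pct[5])
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$session), , drop = FALSE]
}

#' Run a complete calibration study end to end
#'
#' Orchestrates simulate -> reintegrate -> align -> screen -> split ->
#' calibrate -> cross-validate as one reproducible run, writing every
#' intermediate artifact plus report tables (per-session category
#' percentages, minutes per intensity for each group, cut points with
#' ROC provenance, agreement tables) and a manifest that fully
#' determines the outputs (configuration and seeds; no timestamps), so
#' re-running with the same configuration reproduces the run byte for
#' byte.
#'
#' @param config a [simulation_config()]; its `seed` drives all
#'   randomness.
#' @param out_dir output directory (created).
#' @param per_session held-out participants per session.
#' @param split_seed seed for the calibration/validation split; defaults
#'   to a value derived from `config$seed`.
#' @param axes which axes to calibrate.
#' @param rules a [screen_rules()].
#' @param start_offset_intervals observation/count alignment offset.
#' @param moderate_includes_vigorous passed to [cross_validate()].
#' @return invisibly, an object of class `study_run`: list with the
#'   split data, `cutpoints`, `agreement`, `session_summary`, `minutes`,
#'   `comparison` and `manifest`.
#' @export
run_study <- function(config = simulation_config(), out_dir,
                      per_session = 2L, split_seed = NULL,
                      axes = c("vertical", "vm"), rules = screen_rules(),
                      start_offset_intervals = 0L,
                      moderate_includes_vigorous = FALSE) {
  assert_that(!missing(out_dir), "out_dir is required")
  axes <- match.arg(axes, several.ok = TRUE)
  split_seed <- split_seed %||% derive_seed(config$seed %||% 0L, 0L, 3L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE, quote = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_accelcal("stage '", name, "' failed: ", conditionMessage(e)))
  }

  sim <- stage("simulate", simulate_study(config))
  write_simulated_data(sim, out_dir)
  counts20 <- stage("reintegrate", sum_to_20s(sim$counts))
  aligned <- stage("align", align_epochs(counts20, sim$sofit,
                                         start_offset_intervals))
  scr <- stage("screen", screen_epochs(aligned, rules))
  sp <- stage("split", split_calibration_validation(scr$retained, per_session,
                                                    split_seed))
  wcsv(scr$retained, "aligned.csv")
  wcsv(scr$report, "exclusions.csv")
  jsonlite::write_json(sp$manifest, file.path(out_dir, "split.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cutpoints <- list(); agreement <- list(); comparison <- list()
  for (axis in axes) {
    cp <- stage(paste0("calibrate_", axis),
                calibrate_axis(sp$calibration, axis))
    cutpoints[[axis]] <- cp
    write_cutpoints(cp, file.path(out_dir, paste0("cutpoints_", axis, ".json")))
    for (int in names(cp$roc))
      wcsv(cp$roc[[int]]$points, paste0("roc_", axis, "_", int, ".csv"))
    if (nrow(sp$validation) > 0) {
      ag <- stage(paste0("validate_", axis),
                  cross_validate(sp$validation, cp,
                                 moderate_includes_vigorous =
                                   moderate_includes_vigorous))
      agreement[[axis]] <- ag
      wcsv(as.data.frame(ag), paste0("agreement_", axis, ".csv"))
    }
    comparison[[axis]] <- compare_to_reference(cp)
    wcsv(comparison[[axis]], paste0("comparison_", axis, ".csv"))
  }

  session_summary <- session_category_percentages(sim$sofit)
  wcsv(session_summary, "session_summary.csv")
  minutes <- rbind(
    data.frame(group = "calibration", criterion_minutes(sp$calibration)),
    data.frame(group = "validation", criterion_minutes(sp$validation)))
  wcsv(minutes, "minutes_by_intensity.csv")

  manifest <- list(
    package = "accelcal",
    config = config[setdiff(names(config), c("phase_plan",
                                             "category_count_params"))],
    phase_plan = config$phase_plan,
    category_count_params = config$category_count_params,
    split_seed = split_seed,
    axes = axes,
    n_epochs_10s = nrow(sim$counts),
    n_intervals_aligned = nrow(aligned),
    n_intervals_retained = nrow(scr$retained),
    dropped_at_alignment = as.list(attr(aligned, "dropped")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(list(
    calibration = sp$calibration, validation = sp$validation,
    cutpoints = cutpoints, agreement = agreement,
    session_summary = session_summary, minutes = minutes,
    comparison = comparison, manifest = manifest, out_dir = out_dir),
    class = "study_run"))
}

#' @export
print.study_run <- function(x, ...) {
  cat("Calibration study run ->", x$out_dir, "\n")
  cat(sprintf("  calibration: %d epochs / %d participants; validation: %d epochs / %d participants\n",
              nrow(x$calibration), length(unique(x$calibration$participant)),
              nrow(x$validation), length(unique(x$validation$participant))))
  for (axis in names(x$cutpoints)) print(x$cutpoints[[axis]])
  invisible(x)
}
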