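#' Binary coding scheme mapping SOFIT categories to intensity classes
#'
#' The positive category sets used for each per-intensity ROC analysis:
#' sedentary {1, 2} (lying down, sitting), moderate {4, 5} (walking,
#' very active), vigorous {5} (very active), and MVPA {4, 5} (an alias
#' of the moderate coding).  The complement of each set is the negative
#' class, so every category is assigned.
#'
#' @return named list of class `binary_coding_scheme`.
#' @export
binary_coding_scheme <- function() {
  structure(list(sedentary = c(1L, 2L), moderate = c(4L, 5L),
                 vigorous = 5L, mvpa = c(4L, 5L)),
            class = "binary_coding_scheme")
}

#' Convert observation categories to a binary criterion label
#'
#' @param category integer vector of SOFIT categories (1-5).
#' @param intensity one of `"sedentary"`, `"moderate"`, `"vigorous"`,
#'   `"mvpa"`.
#' @param scheme a [binary_coding_scheme()].
#' @return integer vector of 0/1 labels (1 = positive for the intensity).
#' @examples
#' binarize(2, "sedentary")  # 1
#' binarize(3, "moderate")   # 0
#' @export
binarize <- function(category, intensity, scheme = binary_coding_scheme()) {
  assert_that(length(intensity) == 1 && intensity %in% names(scheme),
              "unknown intensity: ", paste(intensity, collapse = ", "))
  assert_that(all(category %in% 1:5), "categories must be in 1..5")
  as.integer(category %in% scheme[[intensity]])
}

# direction of positivity per intensity (inferred from the inequality
# conventions in published cut-point tables: sedentary <=, others >=)
intensity_direction <- function(intensity) {
  if (intensity == "sedentary") "positive-low" else "positive-high"
}

#' Construct a hierarchical cut-point set for one axis
#'
#' Boundaries are stored in counts/20-s (the analysis unit of record)
#' and in counts per minute.  The moderate upper bound is defined
#' hierarchically as `vigorous_lower - 1`; on the cpm scale it is
#' likewise `vigorous_lower_cpm - 1` (not 3 times the 20-s moderate
#' upper bound), matching the reporting convention for contiguous
#' published cut-point ranges.
#'
#' @param axis `"vertical"` or `"vm"`.
#' @param sedentary_upper,moderate_lower,vigorous_lower boundaries in
#'   counts/20-s; must satisfy
#'   `sedentary_upper < moderate_lower <= vigorous_lower - 1`.
#' @param roc optional named list of `roc_analysis` provenance objects.
#' @return object of class `cutpoint_set`.
#' @export
cutpoint_set <- function(axis, sedentary_upper, moderate_lower,
                         vigorous_lower, roc = NULL) {
  assert_that(axis %in% c("vertical", "vm"), "axis must be vertical or vm")
  b <- c(sedentary_upper, moderate_lower, vigorous_lower)
  assert_that(all(is.finite(b)) && all(b >= 0), "boundaries must be finite and nonnegative")
  moderate_upper <- vigorous_lower - 1
  assert_that(sedentary_upper < moderate_lower &&
                moderate_lower <= moderate_upper &&
                moderate_upper < vigorous_lower,
              "non-monotone calibration: boundaries must satisfy ",
              "sedentary_upper < moderate_lower <= moderate_upper < vigorous_lower")
  structure(list(
    axis = axis,
    sedentary_upper = sedentary_upper,
    moderate_lower = moderate_lower,
    moderate_upper = moderate_upper,
    vigorous_lower = vigorous_lower,
    mvpa_lower = moderate_lower,
    sedentary_upper_cpm = counts20_to_cpm(sedentary_upper),
    moderate_lower_cpm = counts20_to_cpm(moderate_lower),
    moderate_upper_cpm = counts20_to_cpm(vigorous_lower) - 1,
    vigorous_lower_cpm = counts20_to_cpm(vigorous_lower),
    mvpa_lower_cpm = counts20_to_cpm(moderate_lower),
    roc = roc
  ), class = "cutpoint_set")
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat(sprintf("Cut points (%s axis)\n", x$axis))
  cat(sprintf("  sedentary: <= %s counts/20-s (<= %s cpm)\n",
              format(x$sedentary_upper), format(x$sedentary_upper_cpm)))
  cat(sprintf("  moderate:  %s-%s counts/20-s (%s-%s cpm)\n",
              format(x$moderate_lower), format(x$moderate_upper),
              format(x$moderate_lower_cpm), format(x$moderate_upper_cpm)))
  cat(sprintf("  vigorous:  >= %s counts/20-s (>= %s cpm)\n",
              format(x$vigorous_lower), format(x$vigorous_lower_cpm)))
  if (!is.null(x$roc)) {
    for (nm in names(x$roc)) {
      r <- x$roc[[nm]]
      cat(sprintf("  [%s] AUC %.2f (%.2f-%.2f, %s), sens %.2f, spec %.2f\n",
                  nm, r$auc, r$auc_ci95[1], r$auc_ci95[2], r$auc_label,
                  r$optimal$sensitivity, r$optimal$specificity))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.cutpoint_set <- function(x, ...) {
  data.frame(axis = x$axis,
             intensity = c("sedentary", "moderate", "vigorous", "mvpa"),
             lower_counts_20s = c(0, x$moderate_lower, x$vigorous_lower,
                                  x$mvpa_lower),
             upper_counts_20s = c(x$sedentary_upper, x$moderate_upper, NA, NA),
             lower_cpm = c(0, x$moderate_lower_cpm, x$vigorous_lower_cpm,
                           x$mvpa_lower_cpm),
             upper_cpm = c(x$sedentary_upper_cpm, x$moderate_upper_cpm, NA, NA))
}

#' Calibrate a hierarchical cut-point set for one axis
#'
#' Runs the three ROC analyses on the calibration epochs (sedentary,
#' positive-low, positive categories {1, 2}; moderate, positive-high,
#' {4, 5}; vigorous, positive-high, {5}), selects each Youden-optimal
#' threshold, and assembles the hierarchical set with
#' `moderate_upper = vigorous_lower - 1`.  The MVPA boundary coincides
#' with the moderate lower boundary: the moderate ROC with positives
#' {4, 5} is mathematically the MVPA-versus-rest analysis, so no fourth
#' ROC is run.
#'
#' @param aligned calibration epochs from [align_epochs()] /
#'   [screen_epochs()].
#' @param axis `"vertical"` or `"vm"` (which 20-s count column to use).
#' @param scheme a [binary_coding_scheme()].
#' @return a [cutpoint_set()] with per-boundary `roc_analysis` provenance.
#' @export
calibrate_axis <- function(aligned, axis = c("vertical", "vm"),
                           scheme = binary_coding_scheme()) {
  axis <- match.arg(axis)
  assert_that(nrow(aligned) > 0, "calibration set is empty")
  counts <- aligned[[paste0(axis, "_counts_20s")]]
  assert_that(!is.null(counts), "aligned data lacks the ", axis, " count column")
  roc <- list()
  for (intensity in c("sedentary", "moderate", "vigorous")) {
    labels <- binarize(aligned$category, intensity, scheme)
    assert_that(sum(labels == 1) > 0 && sum(labels == 0) > 0,
                "intensity ", intensity,
                " is not represented in both classes of the calibration data")
    roc[[intensity]] <- roc_analysis(counts, labels,
                                     intensity_direction(intensity),
                                     intensity = intensity, axis = axis)
  }
  cutpoint_set(axis,
               sedentary_upper = roc$sedentary$optimal$threshold,
               moderate_lower = roc$moderate$optimal$threshold,
               vigorous_lower = roc$vigorous$optimal$threshold,
               roc = roc)
}

#' Serialize a cut-point set (with ROC provenance summaries) to JSON
#'
#' @param x a `cutpoint_set`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cutpoints <- function(x, path) {
  assert_that(inherits(x, "cutpoint_set"), "x must be a cutpoint_set")
  roc_sum <- lapply(x$roc, function(r) list(
    intensity = r$intensity, direction = r$direction, auc = r$auc,
    auc_se = r$auc_se, auc_ci95 = as.numeric(r$auc_ci95),
    auc_label = r$auc_label, threshold = r$optimal$threshold,
    sensitivity = r$optimal$sensitivity, specificity = r$optimal$specificity,
    youden_j = r$optimal$youden_j))
  obj <- x[setdiff(names(x), "roc")]
  obj$roc <- roc_sum
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cut-point set written by [write_cutpoints()]
#'
#' @param path JSON file.
#' @return a `cutpoint_set` (without full ROC point lists).
#' @export
read_cutpoints <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutpoint_set(obj$axis, obj$sedentary_upper, obj$moderate_lower,
               obj$vigorous_lower, roc = NULL)
}
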