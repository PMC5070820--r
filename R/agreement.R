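#' Classify 20-s counts into four intensity classes
#'
#' Applies a hierarchical cut-point set: sedentary when
#' `counts <= sedentary_upper`; light when strictly between the
#' sedentary upper and moderate lower boundaries (light is residual);
#' moderate on `[moderate_lower, moderate_upper]`; vigorous when
#' `counts >= vigorous_lower`.  Every count receives exactly one label.
#'
#' @param counts nonnegative numeric 20-s counts.
#' @param cutpoints a [cutpoint_set()].
#' @return character vector over
#'   `c("sedentary", "light", "moderate", "vigorous")`.
#' @export
classify_intensity <- function(counts, cutpoints) {
  assert_that(inherits(cutpoints, "cutpoint_set"), "invalid cutpoints")
  assert_that(all(counts >= 0), "counts must be nonnegative")
  ifelse(counts <= cutpoints$sedentary_upper, "sedentary",
         ifelse(counts < cutpoints$moderate_lower, "light",
                ifelse(counts < cutpoints$vigorous_lower, "moderate",
                       "vigorous")))
}

#' Construct a 2x2 accelerometer-versus-criterion confusion table
#'
#' @param tp,fn,fp,tn nonnegative integer cell counts (tp: both
#'   positive; fn: criterion positive, prediction negative; fp:
#'   prediction positive, criterion negative; tn: both negative).
#' @return object of class `confusion_2x2`.
#' @export
confusion_2x2 <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  assert_that(is_count(cells), "cells must be nonnegative integers")
  assert_that(sum(cells) > 0, "empty confusion table")
  structure(as.list(cells), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(prediction = c("positive", "negative"),
                              criterion = c("positive", "negative")))
  print(m)
  invisible(x)
}

# predicted four-way labels counted positive for each intensity row
predicted_positive_set <- function(intensity, moderate_includes_vigorous = FALSE) {
  switch(intensity,
         sedentary = "sedentary",
         moderate = if (moderate_includes_vigorous) c("moderate", "vigorous")
                    else "moderate",
         vigorous = "vigorous",
         mvpa = c("moderate", "vigorous"),
         stop_accelcal("unknown intensity: ", intensity))
}

#' Tally predicted intensities against criterion categories
#'
#' Predicted positive is membership of the four-way classification in
#' the intensity's predicted-positive set; criterion positive is
#' [binarize()] of the observation category.  For the moderate row the
#' default counts only predicted-moderate epochs as positive (the
#' criterion positives are categories {4, 5} regardless); set
#' `moderate_includes_vigorous = TRUE` to also count predicted-vigorous
#' epochs, the alternative pairing.
#'
#' @param predicted character vector from [classify_intensity()].
#' @param categories integer criterion categories (1-5), same length.
#' @param intensity `"sedentary"`, `"moderate"`, `"vigorous"` or `"mvpa"`.
#' @param scheme a [binary_coding_scheme()].
#' @param moderate_includes_vigorous see above.
#' @return a [confusion_2x2()].
#' @export
binary_confusion <- function(predicted, categories, intensity,
                             scheme = binary_coding_scheme(),
                             moderate_includes_vigorous = FALSE) {
  assert_that(length(predicted) == length(categories),
              "predicted/criterion length mismatch")
  pred_pos <- predicted %in%
    predicted_positive_set(intensity, moderate_includes_vigorous)
  crit_pos <- binarize(categories, intensity, scheme) == 1L
  confusion_2x2(tp = sum(pred_pos & crit_pos),
                fn = sum(!pred_pos & crit_pos),
                fp = sum(pred_pos & !crit_pos),
                tn = sum(!pred_pos & !crit_pos))
}

#' Sensitivity, specificity and total agreement of a confusion table
#'
#' Percentages on 0-100.  A ratio with an empty margin (no criterion
#' positives for sensitivity, no criterion negatives for specificity) is
#' returned as `NA` and named in `flags` rather than silently reported
#' as zero.
#'
#' @param table a [confusion_2x2()].
#' @return list with `sensitivity`, `specificity`, `total_agreement`
#'   (percent) and `flags` (character vector of undefined ratios).
#' @export
agreement_stats <- function(table) {
  assert_that(inherits(table, "confusion_2x2"), "table must be a confusion_2x2")
  n <- table$tp + table$fn + table$fp + table$tn
  flags <- character()
  if (table$tp + table$fn > 0) sens <- 100 * table$tp / (table$tp + table$fn)
  else { sens <- NA_real_; flags <- c(flags, "sensitivity_undefined") }
  if (table$tn + table$fp > 0) spec <- 100 * table$tn / (table$tn + table$fp)
  else { spec <- NA_real_; flags <- c(flags, "specificity_undefined") }
  list(sensitivity = sens, specificity = spec,
       total_agreement = 100 * (table$tp + table$tn) / n, flags = flags)
}

#' Cohen's kappa with asymptotic standard error for a 2x2 table
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with
#' observed agreement `po = (tp + tn)/N` and chance agreement
#' `pe = [(tp+fn)(tp+fp) + (fp+tn)(fn+tn)] / N^2`.  The standard error
#' is the large-sample formula of Fleiss, Cohen and Everitt for the
#' estimated kappa.
#'
#' @param table a [confusion_2x2()].
#' @return list with `kappa`, `se`, `po`, `pe`.
#' @examples
#' cohen_kappa(confusion_2x2(45, 5, 10, 40))  # kappa 0.70
#' @export
cohen_kappa <- function(table) {
  assert_that(inherits(table, "confusion_2x2"), "table must be a confusion_2x2")
  n <- table$tp + table$fn + table$fp + table$tn
  p <- matrix(c(table$tp, table$fn, table$fp, table$tn), 2, 2) / n
  # rows: prediction (+,-); columns: criterion (+,-)
  prow <- rowSums(p); pcol <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(prow * pcol)
  assert_that(pe < 1, "kappa undefined: degenerate margins (pe = 1)")
  kappa <- (po - pe) / (1 - pe)
  a <- sum(diag(p) * (1 - (prow + pcol) * (1 - kappa))^2)
  off <- which(row(p) != col(p))
  b <- (1 - kappa)^2 *
    sum(p[off] * (pcol[row(p)[off]] + prow[col(p)[off]])^2)
  cc <- (kappa - pe * (1 - kappa))^2
  var_k <- (a + b - cc) / (n * (1 - pe)^2)
  list(kappa = kappa, se = sqrt(max(var_k, 0)), po = po, pe = pe)
}

#' Interpret a kappa value on the Landis-Koch scale
#'
#' `< .00` less than chance, `.00-.20` slight, `.21-.40` fair,
#' `.41-.60` moderate, `.61-.80` substantial, `.81-1.00` almost perfect
#' (band upper ends inclusive, as printed).
#'
#' @param kappa numeric, at most 1.
#' @return character label.
#' @export
interpret_kappa <- function(kappa) {
  assert_that(all(kappa <= 1), "kappa cannot exceed 1")
  ifelse(kappa < 0, "less than chance",
         ifelse(kappa <= 0.20, "slight",
                ifelse(kappa <= 0.40, "fair",
                       ifelse(kappa <= 0.60, "moderate",
                              ifelse(kappa <= 0.80, "substantial",
                                     "almost perfect")))))
}

#' Cross-validate a cut-point set on held-out epochs
#'
#' Classifies each held-out 20-s epoch with the cut points and computes,
#' for sedentary, moderate, vigorous and MVPA, the classification
#' agreement against the observation criterion: sensitivity,
#' specificity, total agreement, and Cohen's kappa with its standard
#' error and Landis-Koch label.  MVPA uses predicted positive
#' `counts >= moderate_lower` and criterion positives {4, 5}.  Epochs
#' are pooled across participants.
#'
#' @param validation held-out aligned epochs.
#' @param cutpoints a [cutpoint_set()].
#' @param scheme a [binary_coding_scheme()].
#' @param moderate_includes_vigorous passed to [binary_confusion()] for
#'   the moderate row.
#' @return data frame of class `agreement_results` with one row per
#'   intensity: `axis`, `intensity`, `sensitivity`, `specificity`,
#'   `total_agreement`, `kappa`, `kappa_se`, `kappa_label`, `flags`.
#' @export
cross_validate <- function(validation, cutpoints,
                           scheme = binary_coding_scheme(),
                           moderate_includes_vigorous = FALSE) {
  assert_that(nrow(validation) > 0, "validation set is empty")
  counts <- validation[[paste0(cutpoints$axis, "_counts_20s")]]
  assert_that(!is.null(counts), "validation data lacks the ", cutpoints$axis,
              " count column")
  predicted <- classify_intensity(counts, cutpoints)
  rows <- lapply(c("sedentary", "moderate", "vigorous", "mvpa"), function(int) {
    tab <- binary_confusion(predicted, validation$category, int, scheme,
                            moderate_includes_vigorous)
    st <- agreement_stats(tab)
    kp <- tryCatch(cohen_kappa(tab),
                   error = function(e) list(kappa = NA_real_, se = NA_real_))
    data.frame(axis = cutpoints$axis, intensity = int,
               sensitivity = st$sensitivity, specificity = st$specificity,
               total_agreement = st$total_agreement,
               kappa = kp$kappa, kappa_se = kp$se,
               kappa_label = if (is.na(kp$kappa)) NA_character_
                             else interpret_kappa(kp$kappa),
               flags = paste(st$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_results", class(out))
  out
}

#' @export
print.agreement_results <- function(x, ...) {
  y <- as.data.frame(x)
  y$sensitivity <- round(y$sensitivity)
  y$specificity <- round(y$specificity)
  y$total_agreement <- round(y$total_agreement)
  y$kappa <- round(y$kappa, 2)
  y$kappa_se <- round(y$kappa_se, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
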