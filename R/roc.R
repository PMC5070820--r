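#' Exhaustive ROC points over all candidate thresholds
#'
#' One point per candidate threshold, where the candidates are every
#' distinct observed count plus the two degenerate endpoints (`-Inf`,
#' `Inf`) at which all epochs are classified into one class.
#' Comparisons are inclusive at the threshold: under
#' `"positive-low"` an epoch is called positive when `count <= t`
#' (sedentary convention), under `"positive-high"` when `count >= t`
#' (moderate/vigorous convention), so reported thresholds are observed
#' count values, the convention used when boundaries are published.
#'
#' @param counts nonnegative numeric epoch counts.
#' @param labels binary criterion labels (1 = positive), same length.
#' @param direction `"positive-low"` or `"positive-high"`.
#' @return data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, `youden_j`, with the direction stored as an
#'   attribute.
#' @export
roc_points <- function(counts, labels,
                       direction = c("positive-low", "positive-high")) {
  direction <- match.arg(direction)
  assert_that(length(counts) == length(labels), "counts/labels length mismatch")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  assert_that(n_pos > 0 && n_neg > 0, "both classes required")
  u <- sort(unique(counts))
  pos_at <- vapply(u, function(v) sum(counts == v & labels == 1), 0)
  neg_at <- vapply(u, function(v) sum(counts == v & labels == 0), 0)
  cpos <- cumsum(pos_at); cneg <- cumsum(neg_at)
  if (direction == "positive-low") {
    tp <- c(0, cpos, n_pos)            # predicted positive: count <= t
    fp <- c(0, cneg, n_neg)
  } else {
    tp <- c(n_pos, n_pos - c(0, cpos[-length(u)]), 0)  # count >= t
    fp <- c(n_neg, n_neg - c(0, cneg[-length(u)]), 0)
  }
  thr <- c(-Inf, u, Inf)
  sens <- tp / n_pos
  spec <- (n_neg - fp) / n_neg
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec,
                    youden_j = sens + spec - 1)
  attr(out, "direction") <- direction
  out
}

#' Select the Youden-optimal ROC point
#'
#' Maximizes J = sensitivity + specificity - 1.  Ties in J are broken in
#' favour of higher sensitivity (the screening convention), then by the
#' more inclusive threshold (higher under `"positive-low"`, lower under
#' `"positive-high"`).  The tie-break actually applied is recorded in
#' the `tie_break` attribute of the result.
#'
#' @param points data frame from [roc_points()].
#' @param direction direction of positivity; defaults to the attribute
#'   carried by `points`.
#' @return single-row data frame (the optimal point) with attribute
#'   `tie_break` (`"none"`, `"sensitivity"` or `"threshold"`).
#' @export
youden_optimal <- function(points, direction = attr(points, "direction")) {
  assert_that(nrow(points) >= 1, "no ROC points")
  assert_that(direction %in% c("positive-low", "positive-high"),
              "unknown direction")
  eps <- 1e-12
  cand <- points[points$youden_j > max(points$youden_j) - eps, , drop = FALSE]
  tie_break <- "none"
  if (nrow(cand) > 1) {
    tie_break <- "sensitivity"
    cand <- cand[cand$sensitivity > max(cand$sensitivity) - eps, , drop = FALSE]
  }
  if (nrow(cand) > 1) {
    tie_break <- "threshold"
    pick <- if (direction == "positive-low") which.max(cand$threshold)
            else which.min(cand$threshold)
    cand <- cand[pick, , drop = FALSE]
  }
  out <- cand[1, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tie_break") <- tie_break
  if (tie_break != "none")
    message("youden_optimal: tie in J resolved by ", tie_break)
  out
}

#' Area under the ROC curve with Hanley-McNeil confidence interval
#'
#' The AUC is computed as the pairwise-comparison (rank-sum) probability
#' that a randomly chosen positive epoch lies on the positive side of a
#' randomly chosen negative epoch, ties counted one half.  The standard
#' error uses the Hanley-McNeil formula and the 95% interval is the
#' normal approximation clipped to [0, 1].
#'
#' @inheritParams roc_points
#' @return list with `auc`, `se`, `ci95` (length-2 vector).
#' @export
roc_auc <- function(counts, labels,
                    direction = c("positive-low", "positive-high")) {
  direction <- match.arg(direction)
  assert_that(length(counts) == length(labels), "counts/labels length mismatch")
  n1 <- sum(labels == 1); n2 <- sum(labels == 0)
  assert_that(n1 > 0 && n2 > 0, "both classes required")
  r <- rank(counts)
  auc_high <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  A <- if (direction == "positive-high") auc_high else 1 - auc_high
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n2 - 1) * (Q2 - A^2)) /
               (n1 * n2))
  ci <- pmin(pmax(A + c(-1, 1) * 1.96 * se, 0), 1)
  list(auc = A, se = se, ci95 = ci)
}

#' Interpret an AUC value on the conventional accuracy scale
#'
#' `>= .90` excellent, `.80-.89` good, `.70-.79` fair, `< .70` poor.
#'
#' @param auc numeric in [0, 1].
#' @return character label.
#' @export
interpret_auc <- function(auc) {
  assert_that(all(auc >= 0 & auc <= 1), "AUC must be in [0, 1]")
  ifelse(auc >= 0.90, "excellent",
         ifelse(auc >= 0.80, "good",
                ifelse(auc >= 0.70, "fair", "poor")))
}

#' Full ROC analysis for one intensity and axis
#'
#' Bundles the exhaustive ROC sweep, the Youden-optimal operating point,
#' and the AUC with its Hanley-McNeil confidence interval.
#'
#' @inheritParams roc_points
#' @param intensity intensity name (bookkeeping only).
#' @param axis `"vertical"` or `"vm"` (bookkeeping only).
#' @return object of class `roc_analysis`: list with `intensity`, `axis`,
#'   `direction`, `points`, `auc`, `auc_se`, `auc_ci95`, `auc_label`,
#'   `optimal` (one-row data frame), `optimal_cpm`.
#' @export
roc_analysis <- function(counts, labels,
                         direction = c("positive-low", "positive-high"),
                         intensity = NA_character_, axis = NA_character_) {
  direction <- match.arg(direction)
  pts <- roc_points(counts, labels, direction)
  opt <- suppressMessages(youden_optimal(pts, direction))
  a <- roc_auc(counts, labels, direction)
  structure(list(intensity = intensity, axis = axis, direction = direction,
                 points = pts, auc = a$auc, auc_se = a$se, auc_ci95 = a$ci95,
                 auc_label = interpret_auc(a$auc), optimal = opt,
                 optimal_cpm = if (is.finite(opt$threshold))
                   counts20_to_cpm(opt$threshold) else NA_real_),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("ROC analysis: %s (%s axis, %s)\n",
              x$intensity, x$axis, x$direction))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f, %s)\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$auc_label))
  cat(sprintf("  Youden-optimal threshold %s counts/20-s (%s cpm): sensitivity %.3f, specificity %.3f, J = %.3f\n",
              format(x$optimal$threshold), format(x$optimal_cpm),
              x$optimal$sensitivity, x$optimal$specificity,
              x$optimal$youden_j))
  invisible(x)
}

#' Plot a ROC curve with its Youden-optimal point
#'
#' @param x a `roc_analysis`.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.roc_analysis <- function(x, ...) {
  p <- x$points[order(1 - x$points$specificity, x$points$sensitivity), ]
  plot(1 - p$specificity, p$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("%s (%s axis), AUC = %.2f", x$intensity, x$axis, x$auc),
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::points(1 - x$optimal$specificity, x$optimal$sensitivity,
                   pch = 19, col = "red3")
  graphics::text(1 - x$optimal$specificity, x$optimal$sensitivity,
                 labels = format(x$optimal$threshold), pos = 4, cex = 0.8)
  invisible(x)
}
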