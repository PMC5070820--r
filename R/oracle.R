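#' Youden-optimal threshold for two discrete class distributions
#'
#' Exact optimum for known class-conditional probability mass functions
#' on a common ordered support: maximizes J(t) = sensitivity +
#' specificity - 1 over all thresholds.  When the maximum is attained on
#' a plateau (e.g. disjoint supports), the midpoint of the continuous
#' plateau is returned, so perfectly separated classes yield the gap
#' midpoint with J = 1.
#'
#' @param pmf_pos,pmf_neg numeric probability vectors over `values`.
#' @param direction `"positive-low"` (positive class classified by
#'   `x <= t`) or `"positive-high"` (`x >= t`).
#' @param values ordered numeric support (default `0:(K-1)` for integer
#'   counts).
#' @return list with `threshold`, `j` (the maximal Youden index), and
#'   `auc` (the analytic area under the ROC curve).
#' @export
optimal_threshold_pmf <- function(pmf_pos, pmf_neg,
                                  direction = c("positive-low", "positive-high"),
                                  values = seq_along(pmf_pos) - 1) {
  direction <- match.arg(direction)
  assert_that(length(pmf_pos) == length(pmf_neg) &&
                length(values) == length(pmf_pos),
              "pmf_pos, pmf_neg and values must have equal length")
  pmf_pos <- pmf_pos / sum(pmf_pos)
  pmf_neg <- pmf_neg / sum(pmf_neg)
  Fp <- cumsum(pmf_pos); Fn <- cumsum(pmf_neg)
  if (max(abs(Fp - Fn)) < 1e-12)
    stop_accelcal("no discriminating threshold: class distributions identical")
  n <- length(values)
  if (direction == "positive-low") {
    # threshold at values[i]: positive iff x <= values[i]
    J <- Fp - Fn
    auc <- sum(pmf_pos * (1 - Fn + pmf_neg / 2))
  } else {
    # threshold at values[i]: positive iff x >= values[i]
    J <- c(0, Fn[-n] - Fp[-n])
    auc <- sum(pmf_pos * (c(0, Fn[-n]) + pmf_neg / 2))
  }
  jmax <- max(J)
  run <- which(J > jmax - 1e-12)
  i1 <- min(run); i2 <- max(run)
  if (i1 == i2) {
    thr <- values[i1]
  } else if (direction == "positive-low") {
    # plateau extends continuously to just below values[i2 + 1]
    upper <- if (i2 < n) values[i2 + 1] else values[i2]
    thr <- (values[i1] + upper) / 2
  } else {
    lower <- if (i1 > 1) values[i1 - 1] else values[i1]
    thr <- (lower + values[i2]) / 2
  }
  list(threshold = thr, j = jmax, auc = auc)
}

# pmf of round(lognormal(meanlog, sdlog)) on 0..K
rounded_lnorm_pmf <- function(meanlog, sdlog, K) {
  if (!is.finite(meanlog)) {            # degenerate at zero
    p <- numeric(K + 1); p[1] <- 1; return(p)
  }
  k <- 0:K
  p <- stats::plnorm(k + 0.5, meanlog, sdlog) -
    stats::plnorm(pmax(k - 0.5, 0), meanlog, sdlog)
  p / sum(p)
}

# convolution of a pmf with itself (20-s sum of two independent 10-s epochs);
# FFT padded to a power of two, since an awkward (e.g. prime) transform
# length degrades R's mixed-radix FFT to quadratic time
self_convolve_pmf <- function(p) {
  n <- 2 * length(p) - 1
  N <- stats::nextn(n, 2)
  fp <- stats::fft(c(p, numeric(N - length(p))))
  q <- Re(stats::fft(fp * fp, inverse = TRUE)) / N
  q <- q[seq_len(n)]
  q[q < 0] <- 0
  q / sum(q)
}

# adjacent-category mislabelling kernel: K[c', c] = P(recorded c' | true c)
mislabel_kernel <- function(mislabel_prob) {
  K <- diag(5) * (1 - mislabel_prob)
  for (c in 1:5) {
    lo <- max(c - 1, 1); hi <- min(c + 1, 5)
    K[lo, c] <- K[lo, c] + mislabel_prob / 2
    K[hi, c] <- K[hi, c] + mislabel_prob / 2
  }
  K
}

#' Class-conditional 20-s count distributions implied by a configuration
#'
#' The positive/negative mixtures for one intensity under the binary
#' coding scheme, for recorded (possibly mislabelled) observation codes.
#' The per-participant activity multiplier is folded into the lognormal
#' analytically; the transition (higher-code) observation rule is not
#' modelled.
#'
#' @param config a [simulation_config()].
#' @param intensity one of `"sedentary"`, `"moderate"`, `"vigorous"`,
#'   `"mvpa"`.
#' @param scheme a [binary_coding_scheme()].
#' @return list with `pmf_pos`, `pmf_neg` over integer support `values`.
#' @keywords internal
#' @export
oracle_class_pmfs <- function(config, intensity, scheme = binary_coding_scheme()) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  pos_set <- scheme[[match.arg(intensity, names(scheme))]]
  ccp <- config$category_count_params
  psd <- config$participant_sd
  sg <- sqrt(ccp$sdlog^2 + psd^2)
  mu <- ccp$meanlog - psd^2 / 2        # multiplier has meanlog -psd^2/2
  fin <- is.finite(mu)
  K <- max(1, ceiling(max(stats::qlnorm(1 - 1e-7, mu[fin], sg[fin]))))
  pmf20 <- lapply(1:5, function(c) self_convolve_pmf(rounded_lnorm_pmf(mu[c], sg[c], K)))
  pi_cat <- marginal_category_mix(config)
  Kmis <- mislabel_kernel(config$mislabel_prob)
  p_rec_pos <- colSums(Kmis[pos_set, , drop = FALSE])   # P(recorded in pos | true c)
  w_pos <- pi_cat * p_rec_pos
  w_neg <- pi_cat * (1 - p_rec_pos)
  mix <- function(w) Reduce(`+`, Map(`*`, pmf20, w / sum(w)))
  list(pmf_pos = mix(w_pos), pmf_neg = mix(w_neg), values = 0:(2 * K))
}

#' Analytic Youden-optimal threshold for a simulation configuration
#'
#' Independent oracle for parameter-recovery tests: computes, from the
#' configuration's known mixtures (marginal category occupancy, the
#' mislabelling kernel, and the class-conditional 20-s count sum
#' distributions), the threshold that maximizes sensitivity +
#' specificity - 1 for the given intensity on the vertical axis, plus
#' the analytic Youden index and AUC at the distribution level.
#'
#' @inheritParams oracle_class_pmfs
#' @param axis only `"vertical"` is supported: the vector-magnitude
#'   factor enters after integer rounding, so its count distribution has
#'   no tractable closed form.
#' @return list with `threshold` (counts/20-s), `j`, `auc`.
#' @export
analytic_optimal_threshold <- function(config,
                                       intensity = c("sedentary", "moderate",
                                                     "vigorous", "mvpa"),
                                       scheme = binary_coding_scheme(),
                                       axis = "vertical") {
  intensity <- match.arg(intensity)
  assert_that(identical(axis, "vertical"),
              "analytic oracle is defined for the vertical axis only")
  pm <- oracle_class_pmfs(config, intensity, scheme)
  direction <- if (intensity == "sedentary") "positive-low" else "positive-high"
  optimal_threshold_pmf(pm$pmf_pos, pm$pmf_neg, direction, pm$values)
}
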