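#' Default activity-session phase plan
#'
#' Four phases of a semi-structured school physical-activity session
#' (warm-up, instruction games, obstacle games, team games) with target
#' mixes over the five SOFIT student-activity categories (1 = lying down,
#' 2 = sitting, 3 = standing, 4 = walking, 5 = very active).  Phase
#' durations are 10 + 10 + 10 + 15 minutes; the duration-weighted mix
#' reproduces typical observed session compositions (roughly 4% lying,
#' 21% sitting, 21% standing, 31% walking, 23% very active).
#'
#' @return A data frame with columns `phase`, `minutes`, and `p1`..`p5`
#'   (target category probabilities, each row summing to 1).
#' @export
default_phase_plan <- function() {
  data.frame(
    phase   = c("warm_up", "instruction_games", "obstacle_games", "team_games"),
    minutes = c(10, 10, 10, 15),
    p1 = c(0.05, 0.05, 0.03, 0.03),
    p2 = c(0.25, 0.20, 0.20, 0.20),
    p3 = c(0.30, 0.25, 0.17, 0.15),
    p4 = c(0.30, 0.35, 0.30, 0.30),
    p5 = c(0.10, 0.15, 0.30, 0.32),
    stringsAsFactors = FALSE
  )
}

#' Default class-conditional count-emission parameters
#'
#' Lognormal parameters for 10-s vertical-axis activity counts per SOFIT
#' category.  Medians (5, 55, 120, 250, 520 counts/10-s) place the
#' implied 20-s category medians either side of published
#' sedentary/moderate/vigorous boundaries for hip-worn devices in
#' children, and the common `sdlog` of 0.9 yields class overlap in the
#' discrimination range (AUC roughly .86-.94) reported by field
#' calibration studies.
#'
#' @return A data frame with columns `category`, `meanlog`, `sdlog`.
#' @export
default_count_params <- function() {
  data.frame(
    category = 1:5,
    meanlog  = log(c(5, 55, 120, 250, 520)),
    sdlog    = rep(0.9, 5)
  )
}

#' Build and validate a simulation configuration
#'
#' Defines the study conditions that the synthetic-session generator
#' emulates: the phase-structured session protocol, class-conditional
#' 10-s count distributions, the vector-magnitude/vertical count ratio,
#' behaviour bout dwell times, observer mislabelling, and out-of-hall
#' (invalid-interval) rates.
#'
#' @param n_sessions number of activity sessions.
#' @param participants_per_session participants per session; a scalar or a
#'   vector of length `n_sessions`.  The default (8, 8, 9, 7, 7, 5, 6)
#'   gives 50 children over seven sessions.
#' @param phase_plan data frame as produced by [default_phase_plan()].
#' @param category_count_params data frame as produced by
#'   [default_count_params()].
#' @param vm_ratio_params named numeric `c(meanlog=, sdlog=)` for the
#'   lognormal excess of the vector-magnitude/vertical factor; the factor
#'   applied is `1 + lognormal`, so it is at least 1 with probability 1.
#' @param dwell_mean_s mean behaviour bout duration in seconds
#'   (geometric dwell at 1-s resolution).
#' @param participant_sd `sdlog` of a per-participant lognormal activity
#'   multiplier with mean-log centred so the multiplier has median
#'   `exp(-participant_sd^2/2)` and mean 1 (between-child heterogeneity);
#'   0 disables it.
#' @param mislabel_prob probability that an observation code is replaced
#'   by an adjacent category (observer error).  The default 0.10
#'   corresponds to roughly 90% single-rater reliability.
#' @param out_of_hall_prob probability an observation interval is flagged
#'   invalid (child out of view of camera/observer).
#' @param seed integer RNG seed.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- simulation_config(n_sessions = 1, participants_per_session = 2,
#'                          seed = 7)
#' @export
simulation_config <- function(n_sessions = 7,
                              participants_per_session = c(8, 8, 9, 7, 7, 5, 6),
                              phase_plan = default_phase_plan(),
                              category_count_params = default_count_params(),
                              vm_ratio_params = c(meanlog = log(1.5), sdlog = 0.35),
                              dwell_mean_s = 15,
                              participant_sd = 0.15,
                              mislabel_prob = 0.10,
                              out_of_hall_prob = 0.02,
                              seed = 1L) {
  assert_that(is_count(n_sessions) && length(n_sessions) == 1 && n_sessions >= 1,
              "n_sessions must be a positive integer")
  if (length(participants_per_session) == 1)
    participants_per_session <- rep(participants_per_session, n_sessions)
  assert_that(is_count(participants_per_session) &&
                length(participants_per_session) == n_sessions,
              "participants_per_session must be a scalar or length n_sessions")
  assert_that(is.data.frame(phase_plan) && nrow(phase_plan) >= 1,
              "phase_plan must be a nonempty data frame")
  need <- c("phase", "minutes", paste0("p", 1:5))
  assert_that(all(need %in% names(phase_plan)),
              "phase_plan must have columns phase, minutes, p1..p5")
  assert_that(all(phase_plan$minutes > 0), "all phase durations must be > 0")
  mix <- as.matrix(phase_plan[, paste0("p", 1:5)])
  assert_that(all(mix >= 0) && all(abs(rowSums(mix) - 1) < 1e-8),
              "each phase mix must be a probability vector summing to 1")
  ccp <- category_count_params
  assert_that(is.data.frame(ccp) && identical(as.integer(ccp$category), 1:5),
              "category_count_params must cover categories 1..5 in order")
  # meanlog -Inf is allowed: a category degenerate at zero counts
  assert_that(all(!is.na(ccp$meanlog)) && all(ccp$meanlog < Inf) &&
                all(ccp$sdlog >= 0),
              "invalid count-emission parameters")
  mu <- exp(ccp$meanlog + ccp$sdlog^2 / 2)
  assert_that(mu[1] < mu[3] && mu[2] < mu[3] && mu[3] < mu[4] && mu[4] < mu[5],
              "category count means must increase from categories 1/2 through 5")
  assert_that(all(c("meanlog", "sdlog") %in% names(vm_ratio_params)),
              "vm_ratio_params needs meanlog and sdlog")
  assert_that(vm_ratio_params[["sdlog"]] >= 0, "vm_ratio sdlog must be >= 0")
  assert_that(length(dwell_mean_s) == 1 && dwell_mean_s > 0,
              "dwell_mean_s must be > 0")
  assert_that(length(participant_sd) == 1 && participant_sd >= 0,
              "participant_sd must be >= 0")
  assert_that(is_prob(mislabel_prob), "mislabel_prob must be in [0,1]")
  assert_that(is_prob(out_of_hall_prob), "out_of_hall_prob must be in [0,1]")
  assert_that(is.null(seed) || (is.numeric(seed) && length(seed) == 1),
              "seed must be a single number or NULL")

  structure(list(
    n_sessions = as.integer(n_sessions),
    participants_per_session = as.integer(participants_per_session),
    phase_plan = phase_plan,
    category_count_params = ccp,
    vm_ratio_params = vm_ratio_params,
    dwell_mean_s = dwell_mean_s,
    participant_sd = participant_sd,
    mislabel_prob = mislabel_prob,
    out_of_hall_prob = out_of_hall_prob,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' Session duration implied by a configuration's phase plan, in seconds
#' @param config a `sim_config`.
#' @return integer number of seconds.
#' @export
session_duration_s <- function(config) {
  as.integer(round(sum(config$phase_plan$minutes) * 60))
}

#' Duration-weighted marginal SOFIT category distribution
#'
#' The long-run fraction of session time spent in each category implied
#' by the phase plan (all categories share the same dwell distribution,
#' so occupancy converges to the target mix).
#'
#' @param config a `sim_config`.
#' @return numeric vector of length 5 summing to 1.
#' @export
marginal_category_mix <- function(config) {
  w <- config$phase_plan$minutes / sum(config$phase_plan$minutes)
  mix <- as.matrix(config$phase_plan[, paste0("p", 1:5)])
  as.numeric(crossprod(mix, w))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic activity-session configuration\n")
  cat(sprintf("  sessions: %d (participants per session: %s; total %d)\n",
              x$n_sessions, paste(x$participants_per_session, collapse = ", "),
              sum(x$participants_per_session)))
  cat(sprintf("  session duration: %d min in %d phases\n",
              as.integer(sum(x$phase_plan$minutes)), nrow(x$phase_plan)))
  cat(sprintf("  dwell mean %.0f s | mislabel %.2f | out-of-hall %.2f | participant sd %.2f\n",
              x$dwell_mean_s, x$mislabel_prob, x$out_of_hall_prob, x$participant_sd))
  cat(sprintf("  seed: %s\n", x$seed %||% "<none>"))
  invisible(x)
}
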