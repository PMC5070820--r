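# Shared simulation configurations for tests.

# Small default-condition study (2 sessions, 4 participants each).
small_config <- function(seed = 1, ...) {
  simulation_config(n_sessions = 2, participants_per_session = 4,
                    seed = seed, ...)
}

# Categories with essentially disjoint count supports and no observation
# error: a 5-phase plan with one pure category per phase, each phase a
# multiple of 20 s, so every interval is category-pure and calibration is
# a perfect-separation problem.
disjoint_config <- function(seed = 1, participants = 4, minutes = 2) {
  plan <- data.frame(phase = paste0("cat", 1:5), minutes = minutes,
                     p1 = as.numeric(1:5 == 1), p2 = as.numeric(1:5 == 2),
                     p3 = as.numeric(1:5 == 3), p4 = as.numeric(1:5 == 4),
                     p5 = as.numeric(1:5 == 5))
  simulation_config(
    n_sessions = 1, participants_per_session = participants,
    phase_plan = plan,
    category_count_params = data.frame(category = 1:5,
                                       meanlog = log(c(2, 10, 100, 1000, 10000)),
                                       sdlog = 0.1),
    dwell_mean_s = 1e6, participant_sd = 0, mislabel_prob = 0,
    out_of_hall_prob = 0, seed = seed)
}

# Parameter-recovery study conditions: one long session pool giving
# ~10,000 intervals of overlapping lognormal classes with 5% adjacent
# mislabelling; long (60-s) bouts keep observation intervals close to
# category-pure, matching the analytic oracle's mixture assumption.
recovery_config <- function(seed) {
  simulation_config(n_sessions = 1, participants_per_session = 75,
                    dwell_mean_s = 60, mislabel_prob = 0.05,
                    out_of_hall_prob = 0, seed = seed)
}

# gap between the distinct observed counts bracketing `at`
adjacent_count_spacing <- function(counts, at) {
  u <- sort(unique(counts))
  lo <- u[u <= at]; hi <- u[u > at]
  if (length(lo) == 0 || length(hi) == 0) return(Inf)
  max(hi[1] - lo[length(lo)], 1)
}
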