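#' Generate per-second behaviour traces for one session
#'
#' Simulates each participant's SOFIT category (1-5) at 1-s resolution
#' through the session's phases.  Within a phase, behaviour follows a
#' semi-Markov process: a category is drawn from the phase's target mix
#' and held for a geometric dwell time with mean `dwell_mean_s`, so the
#' occupancy of each category converges to the target mix as the phase
#' lengthens.
#'
#' @param config a [simulation_config()] object.
#' @param session_id integer session number (1-based).
#' @return A named list of integer vectors (one per participant, names
#'   `S<session>P<participant>`), each of length equal to the session
#'   duration in seconds.
#' @export
generate_behaviour_sequence <- function(config, session_id = 1L) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  assert_that(nrow(config$phase_plan) >= 1, "phase plan is empty")
  assert_that(session_id >= 1 && session_id <= config$n_sessions,
              "session_id out of range")
  n_part <- config$participants_per_session[session_id]
  ids <- sprintf("S%dP%02d", session_id, seq_len(n_part))
  with_seed(derive_seed(config$seed, session_id, 1L), {
    traces <- lapply(seq_len(n_part), function(i) sim_one_trace(config))
  })
  names(traces) <- ids
  traces
}

# one participant's per-second category trace across all phases
sim_one_trace <- function(config) {
  p_dwell <- min(1, 1 / config$dwell_mean_s)
  out <- vector("list", nrow(config$phase_plan))
  mix <- as.matrix(config$phase_plan[, paste0("p", 1:5)])
  for (ph in seq_len(nrow(config$phase_plan))) {
    dur <- as.integer(round(config$phase_plan$minutes[ph] * 60))
    sec <- integer(0)
    while (length(sec) < dur) {
      k <- max(8L, ceiling((dur - length(sec)) / config$dwell_mean_s * 1.5))
      cats <- sample.int(5L, k, replace = TRUE, prob = mix[ph, ])
      dwell <- 1L + stats::rgeom(k, p_dwell)
      sec <- c(sec, rep(cats, dwell))
    }
    out[[ph]] <- sec[seq_len(dur)]
  }
  unlist(out, use.names = FALSE)
}

#' Emit 10-s accelerometer count epochs from a behaviour trace
#'
#' Each 10-s window is assigned the category occupying the majority of
#' its seconds (ties broken in favour of the bout occurring later in the
#' window); a vertical-axis count is drawn from that category's
#' lognormal emission distribution, scaled by the participant's activity
#' multiplier and rounded to an integer.  The vector-magnitude count is
#' `round(vertical * factor)` with `factor = 1 + lognormal`, so vector
#' magnitude is never below the vertical count.  Trailing seconds that do
#' not fill a 10-s window are dropped.
#'
#' @param trace integer vector of per-second categories (one participant).
#' @param config a [simulation_config()].
#' @param multiplier positive scalar participant activity multiplier.
#' @param seed optional integer seed (`NULL` uses the current stream).
#' @return data frame with columns `offset_s`, `vertical_counts`,
#'   `vm_counts` (one row per 10-s epoch).
#' @export
emit_counts <- function(trace, config, multiplier = 1, seed = NULL) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  assert_that(all(trace %in% 1:5), "trace must contain categories 1..5")
  assert_that(multiplier > 0, "multiplier must be positive")
  n_epoch <- length(trace) %/% 10L
  assert_that(n_epoch >= 1, "trace shorter than one 10-s epoch")
  win <- matrix(trace[seq_len(10L * n_epoch)], nrow = 10L)
  cat10 <- apply(win, 2, majority_category)
  ccp <- config$category_count_params
  ml <- ccp$meanlog[cat10]; sl <- ccp$sdlog[cat10]
  with_seed(seed, {
    vertical <- numeric(n_epoch)
    fin <- is.finite(ml)              # meanlog -Inf: degenerate at zero
    vertical[fin] <- round(stats::rlnorm(sum(fin), ml[fin], sl[fin]) *
                             multiplier)
    factor <- 1 + stats::rlnorm(n_epoch, config$vm_ratio_params[["meanlog"]],
                                config$vm_ratio_params[["sdlog"]])
    vm <- round(vertical * factor)
  })
  data.frame(offset_s = 10L * (seq_len(n_epoch) - 1L),
             vertical_counts = as.integer(vertical),
             vm_counts = as.integer(vm))
}

# majority category of a 10-s window; ties go to the bout later in the window
majority_category <- function(x) {
  tab <- tabulate(x, 5L)
  top <- which(tab == max(tab))
  if (length(top) == 1L) return(top)
  last_pos <- vapply(top, function(c) max(which(x == c)), 0L)
  top[which.max(last_pos)]
}

#' Momentary time-sampled observation of a behaviour trace
#'
#' Emulates SOFIT coding with 10-s observe / 10-s record intervals: one
#' code per 20-s interval (3 observations per minute), taken at the final
#' second of the observe window.  If the behaviour changed at that
#' instant (a transition), the higher of the two codes is recorded.  With
#' probability `mislabel_prob` the recorded code is replaced by an
#' adjacent category (clamped to 1-5), and with probability
#' `out_of_hall_prob` the interval is flagged invalid.
#'
#' @param trace integer vector of per-second categories (>= 20 s).
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return data frame with columns `interval` (0-based), `category`
#'   (recorded code), `valid`, and `true_category` (the behaviour at the
#'   sampled instant, before the transition rule and mislabelling).
#' @export
observe_sofit <- function(trace, config, seed = NULL) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  assert_that(length(trace) >= 20, "trace must cover at least one 20-s interval")
  n_int <- length(trace) %/% 20L
  instant <- 20L * (seq_len(n_int) - 1L) + 10L
  true_cat <- trace[instant]
  prev_cat <- trace[instant - 1L]
  recorded <- pmax(true_cat, prev_cat)  # higher code on transition
  with_seed(seed, {
    mis <- stats::runif(n_int) < config$mislabel_prob
    step <- sample(c(-1L, 1L), n_int, replace = TRUE)
    recorded[mis] <- pmin(pmax(recorded[mis] + step[mis], 1L), 5L)
    valid <- stats::runif(n_int) >= config$out_of_hall_prob
  })
  data.frame(interval = seq_len(n_int) - 1L,
             category = as.integer(recorded),
             valid = valid,
             true_category = as.integer(true_cat))
}

#' Simulate a full calibration study
#'
#' Runs [generate_behaviour_sequence()], [emit_counts()] and
#' [observe_sofit()] for every participant in every session, drawing one
#' lognormal activity multiplier per participant (mean 1, `sdlog =
#' participant_sd`).  All randomness derives from `config$seed`, so the
#' same configuration always reproduces the same study byte for byte.
#'
#' @param config a [simulation_config()].
#' @return An object of class `sim_study`: a list with data frames
#'   `counts` (10-s epochs), `sofit` (recorded observations), `truth`
#'   (recorded vs true codes), and the `config`.
#' @export
simulate_study <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  counts_l <- list(); sofit_l <- list(); truth_l <- list()
  for (s in seq_len(config$n_sessions)) {
    traces <- generate_behaviour_sequence(config, s)
    with_seed(derive_seed(config$seed, s, 2L), {
      mult <- stats::rlnorm(length(traces), -config$participant_sd^2 / 2,
                            config$participant_sd)
      for (i in seq_along(traces)) {
        id <- names(traces)[i]
        cnt <- emit_counts(traces[[i]], config, multiplier = mult[i])
        obs <- observe_sofit(traces[[i]], config)
        counts_l[[id]] <- data.frame(participant = id, session = s, cnt)
        sofit_l[[id]] <- data.frame(participant = id, session = s,
                                    obs[c("interval", "category", "valid")])
        truth_l[[id]] <- data.frame(participant = id, session = s,
                                    interval = obs$interval,
                                    true_category = obs$true_category,
                                    recorded_category = obs$category,
                                    valid = obs$valid)
      }
    })
  }
  structure(list(counts = do.call(rbind, c(counts_l, make.row.names = FALSE)),
                 sofit = do.call(rbind, c(sofit_l, make.row.names = FALSE)),
                 truth = do.call(rbind, c(truth_l, make.row.names = FALSE)),
                 config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d sessions, %d participants, %d 10-s epochs, %d observations\n",
              x$config$n_sessions, length(unique(x$counts$participant)),
              nrow(x$counts), nrow(x$sofit)))
  invisible(x)
}

#' Write a simulated study in the package's delimited file formats
#'
#' Produces `counts.csv` and `sofit.csv` in exactly the layouts that
#' [read_count_epochs()] and [read_sofit_log()] read, plus a
#' `truth.csv` ground-truth sidecar for testing.
#'
#' @param sim a `sim_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulated_data <- function(sim, dir) {
  assert_that(inherits(sim, "sim_study"), "sim must be a sim_study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.csv", "sofit.csv", "truth.csv"))
  utils::write.csv(sim$counts, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$sofit, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
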