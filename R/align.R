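#' Sum consecutive 10-s count epochs into 20-s analysis epochs
#'
#' Pairs epochs (2k, 2k+1) within each participant into analysis
#' interval k, summing vertical and vector-magnitude counts, to match
#' the 20-s cadence of the observation criterion.  An unpaired trailing
#' 10-s epoch is dropped with a warning; a gap in the 10-s offset
#' sequence is an error, because pairing could then silently misalign.
#'
#' @param epochs data frame as returned by [read_count_epochs()].
#' @return data frame with columns `participant`, `session`, `interval`
#'   (0-based), `vertical_counts_20s`, `vm_counts_20s`.
#' @export
sum_to_20s <- function(epochs) {
  need <- c("participant", "session", "offset_s", "vertical_counts", "vm_counts")
  assert_that(all(need %in% names(epochs)), "epochs lacks required columns")
  if (nrow(epochs) == 0)
    return(data.frame(participant = character(), session = integer(),
                      interval = integer(), vertical_counts_20s = integer(),
                      vm_counts_20s = integer()))
  parts <- split(epochs, epochs$participant)
  dropped <- 0L
  out <- lapply(parts, function(d) {
    d <- d[order(d$offset_s), , drop = FALSE]
    gaps <- diff(d$offset_s)
    assert_that(all(gaps == 10L), "gap in 10-s offsets for participant ",
                d$participant[1], ": alignment cannot be guaranteed")
    n_int <- nrow(d) %/% 2L
    if (nrow(d) %% 2L == 1L) dropped <<- dropped + 1L
    if (n_int == 0L) return(NULL)
    i <- seq_len(n_int)
    data.frame(participant = d$participant[1], session = d$session[1],
               interval = i - 1L,
               vertical_counts_20s = d$vertical_counts[2 * i - 1] +
                 d$vertical_counts[2 * i],
               vm_counts_20s = d$vm_counts[2 * i - 1] + d$vm_counts[2 * i])
  })
  if (dropped > 0)
    warning("dropped an unpaired trailing 10-s epoch for ", dropped,
            " participant(s)", call. = FALSE)
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(res) <- NULL
  res
}

#' Time-match 20-s count epochs to observation records
#'
#' Inner join on (participant, interval) after shifting the observation
#' indexing by `start_offset_intervals`: count interval k is matched to
#' observation interval k + offset.  This makes the study's manual
#' video/accelerometer synchronisation an explicit, reproducible
#' parameter.  Intervals present in only one source are dropped and
#' tallied in the `dropped` attribute.
#'
#' @param counts20 data frame from [sum_to_20s()].
#' @param sofit data frame from [read_sofit_log()].
#' @param start_offset_intervals integer shift of observation indexing
#'   relative to count indexing (default 0).
#' @return data frame of aligned epochs with columns `participant`,
#'   `session`, `interval`, `vertical_counts_20s`, `vm_counts_20s`,
#'   `category`, `valid`, carrying attribute `dropped` (a named count of
#'   unmatched intervals per source).
#' @export
align_epochs <- function(counts20, sofit, start_offset_intervals = 0L) {
  assert_that(is_count(abs(start_offset_intervals)) ||
                start_offset_intervals == round(start_offset_intervals),
              "start_offset_intervals must be an integer")
  obs <- sofit
  obs$interval <- obs$interval - as.integer(start_offset_intervals)
  merged <- merge(counts20, obs[, c("participant", "interval", "category", "valid")],
                  by = c("participant", "interval"))
  assert_that(nrow(merged) > 0, "zero overlapping intervals between counts and observations")
  merged <- merged[order(merged$participant, merged$interval), , drop = FALSE]
  merged <- merged[, c("participant", "session", "interval",
                       "vertical_counts_20s", "vm_counts_20s", "category", "valid")]
  rownames(merged) <- NULL
  attr(merged, "dropped") <- c(counts_only = nrow(counts20) - nrow(merged),
                               observations_only = nrow(sofit) - nrow(merged))
  merged
}

#' Screening rules for aligned epochs
#'
#' @param max_vertical,max_vm maximum plausible 20-s count per axis;
#'   epochs above are excluded as spurious.  Defaults are `Inf` (no
#'   exclusion) because "spurious" has no universal definition; set them
#'   deliberately.
#' @param respect_validity drop epochs whose observation interval was
#'   flagged invalid (participant out of the hall).
#' @return a list of class `screen_rules`.
#' @export
screen_rules <- function(max_vertical = Inf, max_vm = Inf,
                         respect_validity = TRUE) {
  structure(list(max_vertical = max_vertical, max_vm = max_vm,
                 respect_validity = respect_validity),
            class = "screen_rules")
}

#' Screen aligned epochs for invalid intervals and spurious counts
#'
#' Removes epochs flagged invalid by the observer (out of hall) and
#' epochs whose counts exceed the configured per-axis plausibility
#' ceiling, and reports exclusions per rule per participant.  Retained
#' plus excluded always equals the input count.
#'
#' @param aligned data frame from [align_epochs()].
#' @param rules a [screen_rules()] object.
#' @return list with `retained` (data frame) and `report` (data frame
#'   with columns `participant`, `rule`, `n_excluded`).
#' @export
screen_epochs <- function(aligned, rules = screen_rules()) {
  assert_that(inherits(rules, "screen_rules"), "rules must be screen_rules")
  invalid <- if (rules$respect_validity) !aligned$valid else rep(FALSE, nrow(aligned))
  spurious <- !invalid & (aligned$vertical_counts_20s > rules$max_vertical |
                            aligned$vm_counts_20s > rules$max_vm)
  drop <- invalid | spurious
  tally <- function(flag, rule) {
    if (!any(flag)) return(NULL)
    agg <- stats::aggregate(list(n_excluded = flag),
                            by = list(participant = aligned$participant), sum)
    agg <- agg[agg$n_excluded > 0, , drop = FALSE]
    if (nrow(agg) == 0) return(NULL)
    data.frame(participant = agg$participant, rule = rule,
               n_excluded = as.integer(agg$n_excluded))
  }
  report <- rbind(tally(invalid, "out_of_hall"), tally(spurious, "spurious_count"))
  if (is.null(report))
    report <- data.frame(participant = character(), rule = character(),
                         n_excluded = integer())
  retained <- aligned[!drop, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, report = report)
}

#' Split aligned epochs into calibration and cross-validation groups
#'
#' Randomly selects `per_session` participants from each session for the
#' held-out cross-validation group; all of a participant's epochs move
#' together.  The draw is seeded and stratified by session, so the same
#' seed always reproduces the same split.
#'
#' @param aligned data frame of aligned (screened) epochs.
#' @param per_session number of validation participants per session.
#' @param seed integer seed for the random selection.
#' @return list with data frames `calibration` and `validation`, and
#'   `manifest` (seed, per-session validation participants).
#' @export
split_calibration_validation <- function(aligned, per_session = 2L, seed = 1L) {
  assert_that(is_count(per_session) && length(per_session) == 1,
              "per_session must be a nonnegative integer")
  by_sess <- split(unique(aligned[, c("participant", "session")]),
                   f = unique(aligned[, c("participant", "session")])$session)
  short <- vapply(by_sess, function(d) nrow(d) <= per_session, TRUE)
  assert_that(per_session == 0 || !any(short),
              "session(s) ", paste(names(by_sess)[short], collapse = ", "),
              " have too few participants for per_session = ", per_session)
  chosen <- with_seed(seed, {
    lapply(by_sess, function(d) sort(sample(d$participant, per_session)))
  })
  val_ids <- unlist(chosen, use.names = FALSE)
  validation <- aligned[aligned$participant %in% val_ids, , drop = FALSE]
  calibration <- aligned[!aligned$participant %in% val_ids, , drop = FALSE]
  rownames(validation) <- NULL; rownames(calibration) <- NULL
  list(calibration = calibration, validation = validation,
       manifest = list(seed = seed, per_session = per_session,
                       validation_participants = chosen))
}

#' Convert a counts/20-s threshold to counts per minute
#'
#' Three 20-s analysis epochs make one minute, so a boundary expressed
#' per 20-s epoch is multiplied by 3.
#'
#' @param threshold_counts_20s nonnegative numeric.
#' @return the threshold in counts per minute (cpm).
#' @examples
#' counts20_to_cpm(169)  # 507
#' counts20_to_cpm(1405) # 4215
#' @export
counts20_to_cpm <- function(threshold_counts_20s) {
  assert_that(all(is.finite(threshold_counts_20s)) &&
                all(threshold_counts_20s >= 0),
              "threshold must be nonnegative")
  threshold_counts_20s * 3
}
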