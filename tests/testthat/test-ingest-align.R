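write_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("three-axis files yield the rounded Euclidean norm as vector magnitude", {
  f <- write_lines(c("participant,session,offset_s,axis1,axis2,axis3",
                     "A,1,0,3,4,0",
                     "A,1,10,1,2,2"))
  ep <- read_count_epochs(f)
  expect_identical(ep$vm_counts, c(5L, 3L))   # 3-4-5 triangle; sqrt(9)=3
  expect_identical(ep$vertical_counts, c(3L, 1L))
})

test_that("reader validates columns, sign and order", {
  f <- write_lines(c("participant,session,offset_s,axis1", "A,1,0,10"))
  expect_error(read_count_epochs(f), "vector-magnitude")
  f2 <- write_lines(c("participant,session,offset_s,vertical_counts,vm_counts",
                      "A,1,0,-5,10"))
  expect_error(read_count_epochs(f2), "negative counts.*2")
  f3 <- write_lines("participant,session,offset_s,vertical_counts,vm_counts")
  expect_warning(ep <- read_count_epochs(f3), "empty")
  expect_equal(nrow(ep), 0)
  f4 <- write_lines(c("participant,session,offset_s,vertical_counts,vm_counts",
                      "A,1,10,20,25", "A,1,0,10,12"))
  expect_warning(ep4 <- read_count_epochs(f4), "out of time order")
  expect_identical(ep4$offset_s, c(0L, 10L))
  f5 <- write_lines(c("participant,session,offset_s,vertical_counts,vm_counts",
                      "A,1,0,10,12", "A,1,10,oops,13", "A,1,20,7,9"))
  expect_warning(ep5 <- read_count_epochs(f5), "malformed.*3")
  expect_equal(nrow(ep5), 2)
})

test_that("observation log reader enforces the category range and uniqueness", {
  f <- write_lines(c("participant,session,interval,category,valid",
                     "A,1,0,2,TRUE", "A,1,1,6,TRUE"))
  expect_error(read_sofit_log(f), "1\\.\\.5.*3")
  f2 <- write_lines(c("participant,session,interval,category",
                      "A,1,0,2", "A,1,1,3", "A,1,2,5"))
  log2 <- read_sofit_log(f2)
  expect_equal(nrow(log2), 3)
  expect_true(all(log2$valid))   # validity column absent: valid by default
  f3 <- write_lines(c("participant,session,interval,category",
                      "A,1,0,2", "A,1,0,3"))
  expect_error(read_sofit_log(f3), "duplicate.*3")
})

test_that("pairing 10-s epochs sums them and drops an odd trailing epoch", {
  ep <- data.frame(participant = "A", session = 1,
                   offset_s = seq(0, 40, 10),
                   vertical_counts = c(120L, 200L, 30L, 40L, 7L),
                   vm_counts = c(150L, 260L, 45L, 60L, 9L))
  expect_warning(p <- sum_to_20s(ep), "unpaired")
  expect_equal(nrow(p), 2)                     # floor(5/2)
  expect_identical(p$vertical_counts_20s, c(320L, 70L))
  expect_identical(p$vm_counts_20s, c(410L, 105L))
  expect_identical(p$interval, 0:1)
  gap <- ep[-2, ]
  expect_error(sum_to_20s(gap), "gap")
})

test_that("alignment inner-joins on interval with an explicit offset", {
  counts20 <- data.frame(participant = "A", session = 1, interval = 0:2,
                         vertical_counts_20s = c(10L, 20L, 30L),
                         vm_counts_20s = c(12L, 24L, 36L))
  sofit <- data.frame(participant = "A", session = 1, interval = 0:2,
                      category = c(1L, 3L, 5L), valid = TRUE)
  al <- align_epochs(counts20, sofit)
  expect_equal(nrow(al), 3)
  expect_identical(al$category, c(1L, 3L, 5L))
  al1 <- align_epochs(counts20, sofit, start_offset_intervals = 1)
  expect_equal(nrow(al1), 2)                   # index shift drops one
  expect_identical(al1$vertical_counts_20s, c(10L, 20L))
  expect_identical(al1$category, c(3L, 5L))
  sofit_b <- transform(sofit, participant = "B")
  expect_error(align_epochs(counts20, sofit_b), "zero overlapping")
  # aligning already-aligned data at offset 0 is the identity
  al_again <- align_epochs(
    al[, c("participant", "session", "interval",
           "vertical_counts_20s", "vm_counts_20s")],
    al[, c("participant", "session", "interval", "category", "valid")])
  expect_identical(as.data.frame(al_again), as.data.frame(al))
})

test_that("screening removes flagged and spurious epochs and conserves totals", {
  al <- data.frame(participant = rep(c("A", "B"), each = 3),
                   session = 1, interval = rep(0:2, 2),
                   vertical_counts_20s = c(10L, 5000L, 30L, 40L, 50L, 60L),
                   vm_counts_20s = c(12L, 6000L, 36L, 48L, 60L, 72L),
                   category = 3L,
                   valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  sc <- screen_epochs(al, screen_rules(max_vertical = 1000))
  expect_equal(nrow(sc$retained), 4)
  expect_equal(sum(sc$report$n_excluded), 2)
  expect_setequal(sc$report$rule, c("out_of_hall", "spurious_count"))
  expect_equal(nrow(sc$retained) + sum(sc$report$n_excluded), nrow(al))
  # no rules triggered: identity
  sc0 <- screen_epochs(al, screen_rules(respect_validity = FALSE))
  expect_identical(sc0$retained, al)
  expect_equal(nrow(sc0$report), 0)
})

test_that("the held-out split is stratified by session, exclusive and seeded", {
  cfg <- simulation_config(n_sessions = 7,
                           participants_per_session = c(8, 8, 9, 7, 7, 5, 6),
                           seed = 31)
  sim <- simulate_study(cfg)
  al <- align_epochs(sum_to_20s(sim$counts), sim$sofit)
  sp <- split_calibration_validation(al, per_session = 2, seed = 99)
  expect_equal(length(unique(sp$validation$participant)), 14)
  expect_equal(length(unique(sp$calibration$participant)), 36)
  expect_length(intersect(sp$validation$participant,
                          sp$calibration$participant), 0)
  expect_equal(nrow(sp$calibration) + nrow(sp$validation), nrow(al))
  # every session contributes exactly two validation participants
  vp <- unique(sp$validation[, c("participant", "session")])
  expect_true(all(table(vp$session) == 2))
  sp2 <- split_calibration_validation(al, per_session = 2, seed = 99)
  expect_identical(sp$validation$participant, sp2$validation$participant)
  sp0 <- split_calibration_validation(al, per_session = 0, seed = 1)
  expect_equal(nrow(sp0$validation), 0)
  expect_equal(nrow(sp0$calibration), nrow(al))
  tiny <- al[al$participant %in% c("S1P01", "S1P02"), ]
  expect_error(split_calibration_validation(tiny, per_session = 2, seed = 1),
               "too few participants")
})

test_that("simulated study files round-trip exactly through the readers", {
  cfg <- small_config(seed = 13)
  sim <- simulate_study(cfg)
  d <- withr::local_tempdir()
  write_simulated_data(sim, d)
  counts <- read_count_epochs(file.path(d, "counts.csv"))
  sofit <- read_sofit_log(file.path(d, "sofit.csv"))
  expect_identical(counts, sim$counts)
  expect_identical(sofit, sim$sofit)
})

test_that("cpm conversion triples 20-s thresholds and preserves order", {
  expect_equal(counts20_to_cpm(169), 507)
  expect_equal(counts20_to_cpm(1405), 4215)
  expect_equal(counts20_to_cpm(0), 0)
  expect_error(counts20_to_cpm(-3), "nonnegative")
  x <- sort(sample(0:3000, 50))
  expect_true(all(diff(counts20_to_cpm(x)) > 0))
})
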