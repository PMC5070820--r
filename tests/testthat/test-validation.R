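paper_vertical <- function() cutpoint_set("vertical", 169, 336, 767)

test_that("counts classify into exactly one of four intensity classes", {
  cp <- paper_vertical()
  expect_equal(classify_intensity(169, cp), "sedentary")
  expect_equal(classify_intensity(170, cp), "light")
  expect_equal(classify_intensity(200, cp), "light")
  expect_equal(classify_intensity(336, cp), "moderate")
  expect_equal(classify_intensity(766, cp), "moderate")
  expect_equal(classify_intensity(767, cp), "vigorous")
  counts <- 0:2000
  lab <- classify_intensity(counts, cp)
  expect_true(all(lab %in% c("sedentary", "light", "moderate", "vigorous")))
  # partition: class membership is consistent with the boundary definitions
  expect_equal(sum(lab == "sedentary"), 170)   # 0..169
  expect_equal(sum(lab == "light"), 336 - 170) # 170..335
  expect_equal(sum(lab == "moderate"), 767 - 336)
})

test_that("cpm-scale classification agrees except inside the -1 convention gap", {
  cp <- paper_vertical()
  counts <- 0:1200
  lab20 <- classify_intensity(counts, cp)
  cpm <- counts * 3
  lab_cpm <- ifelse(cpm <= cp$sedentary_upper_cpm, "sedentary",
                    ifelse(cpm < cp$moderate_lower_cpm, "light",
                           ifelse(cpm <= cp$moderate_upper_cpm, "moderate",
                                  ifelse(cpm >= cp$vigorous_lower_cpm,
                                         "vigorous", "gap"))))
  mismatch <- counts[lab20 != lab_cpm]
  expect_length(mismatch, 0)  # no integer 20-s count falls in the 1-cpm gap
})

test_that("confusion tallies match a hand enumeration", {
  cp <- paper_vertical()
  counts <- c(100, 180, 500, 800, 340, 50)
  cats <- c(1L, 3L, 4L, 5L, 2L, 2L)
  pred <- classify_intensity(counts, cp)
  # hand tally, sedentary: predictions S,L,M,V,M,S vs criterion +,-,-,-,+,+
  tab <- binary_confusion(pred, cats, "sedentary")
  expect_equal(unclass(tab)[c("tp", "fn", "fp", "tn")],
               list(tp = 2L, fn = 1L, fp = 0L, tn = 3L))
  tab_m <- binary_confusion(pred, cats, "moderate")
  expect_equal(unclass(tab_m)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 3L))
  tab_mv <- binary_confusion(pred, cats, "moderate",
                             moderate_includes_vigorous = TRUE)
  expect_equal(tab_mv$tp, 2L)
  tab_mvpa <- binary_confusion(pred, cats, "mvpa")
  expect_equal(unclass(tab_mvpa)[c("tp", "fn", "fp", "tn")],
               list(tp = 2L, fn = 0L, fp = 1L, tn = 3L))
  expect_error(binary_confusion(pred[-1], cats, "sedentary"), "length")
})

test_that("agreement statistics reproduce hand arithmetic and flag empty margins", {
  st <- agreement_stats(confusion_2x2(45, 5, 10, 40))
  expect_equal(st$sensitivity, 90)
  expect_equal(st$specificity, 80)
  expect_equal(st$total_agreement, 85)
  expect_length(st$flags, 0)
  perfect <- agreement_stats(confusion_2x2(30, 0, 0, 70))
  expect_equal(unlist(perfect[1:3]), c(sensitivity = 100, specificity = 100,
                                       total_agreement = 100))
  st0 <- agreement_stats(confusion_2x2(0, 0, 10, 40))
  expect_true(is.na(st0$sensitivity))
  expect_equal(st0$flags, "sensitivity_undefined")
})

test_that("Cohen's kappa matches hand arithmetic and an external oracle", {
  k <- cohen_kappa(confusion_2x2(45, 5, 10, 40))
  expect_equal(k$po, 0.85)
  expect_equal(k$pe, 0.50)
  expect_equal(k$kappa, 0.70)
  # SE frozen from statsmodels cohens_kappa (Fleiss-Cohen-Everitt variance)
  expect_equal(k$se, 0.0710563157, tolerance = 1e-9)
  k2 <- cohen_kappa(confusion_2x2(30, 10, 20, 40))
  expect_equal(k2$kappa, 0.40)
  expect_equal(k2$se, 0.0897997773, tolerance = 1e-9)
  k3 <- cohen_kappa(confusion_2x2(7, 2, 3, 8))
  expect_equal(k3$kappa, 0.50)
  expect_equal(k3$se, 0.1926784887, tolerance = 1e-9)
})

test_that("kappa is 1 for perfect mixed-margin agreement and 0 under independence", {
  expect_equal(cohen_kappa(confusion_2x2(30, 0, 0, 20))$kappa, 1)
  expect_equal(cohen_kappa(confusion_2x2(25, 25, 25, 25))$kappa, 0)
  expect_error(cohen_kappa(confusion_2x2(50, 0, 0, 0)), "kappa undefined")
})

test_that("kappa never exceeds the observed agreement proportion", {
  set.seed(55)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, 200, runif(4, 0.05, 1)))
    tab <- confusion_2x2(cells[1], cells[2], cells[3], cells[4])
    k <- tryCatch(cohen_kappa(tab), error = function(e) NULL)
    if (is.null(k)) next
    expect_lte(k$kappa, k$po + 1e-12)
    if (k$pe > 1e-12) expect_lt(k$kappa, k$po + 1e-12)
  }
})

test_that("kappa values map onto the agreement scale", {
  expect_equal(interpret_kappa(0.85), "almost perfect")
  expect_equal(interpret_kappa(0.51), "moderate")
  expect_equal(interpret_kappa(0.74), "substantial")
  expect_equal(interpret_kappa(0.20), "slight")
  expect_equal(interpret_kappa(0.21), "fair")
  expect_equal(interpret_kappa(-0.10), "less than chance")
  expect_error(interpret_kappa(1.2), "exceed")
})

test_that("cross-validation is perfect on disjoint error-free synthetic data", {
  cfg <- disjoint_config(seed = 5, participants = 4)
  sim <- simulate_study(cfg)
  al <- align_epochs(sum_to_20s(sim$counts), sim$sofit)
  cp <- calibrate_axis(al, "vertical")
  # with predicted-vigorous counted positive for the moderate row, every
  # per-intensity comparison is perfect on error-free disjoint data
  res <- cross_validate(al, cp, moderate_includes_vigorous = TRUE)
  expect_equal(nrow(res), 4)
  expect_equal(res$sensitivity, rep(100, 4))
  expect_equal(res$specificity, rep(100, 4))
  expect_equal(res$total_agreement, rep(100, 4))
  expect_equal(res$kappa, rep(1, 4))
  expect_equal(res$kappa_label, rep("almost perfect", 4))
  # under the default moderate-only pairing, criterion-positive epochs that
  # are truly vigorous count against moderate sensitivity by construction
  res0 <- cross_validate(al, cp)
  mod <- res0[res0$intensity == "moderate", ]
  n5 <- sum(al$category == 5); n4 <- sum(al$category == 4)
  expect_equal(mod$sensitivity, 100 * n4 / (n4 + n5))
  expect_equal(res0$sensitivity[res0$intensity != "moderate"], rep(100, 3))
  # determinism: same inputs, same results
  expect_identical(as.data.frame(res), as.data.frame(
    cross_validate(al, cp, moderate_includes_vigorous = TRUE)))
})

test_that("shuffling the criterion destroys agreement (kappa near zero)", {
  cfg <- recovery_config(seed = 17)
  cfg$participants_per_session <- 40L  # ~5,400 intervals is ample here
  sim <- simulate_study(cfg)
  al <- align_epochs(sum_to_20s(sim$counts), sim$sofit)
  cp <- calibrate_axis(al, "vertical")
  set.seed(3)
  al$category <- sample(al$category)
  res <- cross_validate(al, cp)
  expect_true(all(abs(res$kappa) < 0.05))
})

test_that("per-intensity binary predictions stay consistent with four-way labels", {
  cfg <- small_config(seed = 19)
  sim <- simulate_study(cfg)
  al <- align_epochs(sum_to_20s(sim$counts), sim$sofit)
  cp <- calibrate_axis(al, "vertical")
  pred <- classify_intensity(al$vertical_counts_20s, cp)
  for (int in c("sedentary", "vigorous", "mvpa")) {
    tab <- binary_confusion(pred, al$category, int)
    crit <- binarize(al$category, int)
    expect_equal(tab$tp + tab$fn, sum(crit == 1))
    expect_equal(tab$fp + tab$tn, sum(crit == 0))
    expect_equal(tab$tp + tab$fn + tab$fp + tab$tn, length(pred))
    st <- agreement_stats(tab)
    misclassified <- 100 * (tab$fn + tab$fp) / length(pred)
    expect_equal(st$total_agreement, 100 - misclassified)
  }
})
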