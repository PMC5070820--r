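# Independent brute-force oracles used to cross-check the ROC machinery.
# These deliberately share no code with the package implementation.

# AUC as the literal pairwise-comparison probability over all
# positive-negative pairs (ties counted one half).
brute_force_auc <- function(counts, labels, direction) {
  pos <- counts[labels == 1]
  neg <- counts[labels == 0]
  cmp <- outer(pos, neg, function(p, q) {
    if (direction == "positive-high") (p > q) + 0.5 * (p == q)
    else (p < q) + 0.5 * (p == q)
  })
  mean(cmp)
}

# Youden optimum by exhaustive confusion counts at every candidate
# threshold, applying the documented tie-break (higher sensitivity, then
# the more inclusive threshold) with independent scalar code.
brute_force_youden <- function(counts, labels, direction) {
  thr <- c(-Inf, sort(unique(counts)), Inf)
  best <- NULL
  for (t in thr) {
    pred <- if (direction == "positive-low") counts <= t else counts >= t
    tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
    fp <- sum(pred & labels == 0); tn <- sum(!pred & labels == 0)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    j <- sens + spec - 1
    better <- is.null(best) || j > best$j + 1e-12 ||
      (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && abs(sens - best$sens) <= 1e-12 &&
         ((direction == "positive-low" && t > best$t) ||
            (direction == "positive-high" && t < best$t)))
    if (better) best <- list(t = t, j = j, sens = sens, spec = spec)
  }
  best
}

# random small labelled instance with both classes present
random_instance <- function(n_max = 500) {
  n <- sample(4:n_max, 1)
  counts <- sample(0:200, n, replace = TRUE)
  repeat {
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (any(labels == 1) && any(labels == 0)) break
  }
  direction <- sample(c("positive-low", "positive-high"), 1)
  list(counts = counts, labels = labels, direction = direction)
}
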