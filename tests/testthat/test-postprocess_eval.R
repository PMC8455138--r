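test_that("threshold optimization separates a separable class and breaks ties low", {
  probs <- cbind(c(0.9, 0.8, 0.1, 0.2))
  labels <- cbind(c(1, 1, 0, 0))
  th <- optimize_thresholds(probs, labels)
  pred <- probs[, 1] > th$tau[1]
  expect_equal(th$f1[1], 1)
  expect_equal(as.numeric(pred), labels[, 1])
  # all-positive labels: any threshold below min(p) is perfect; smallest wins
  th2 <- optimize_thresholds(cbind(rep(0.6, 5)), cbind(rep(1, 5)))
  expect_equal(th2$tau[1], ethoflow:::threshold_grid()[1])
  # argmax dominance over the default threshold
  set.seed(5)
  p <- matrix(runif(400), 100)
  y <- matrix(rbinom(400, 1, 0.3), 100)
  th3 <- optimize_thresholds(p, y)
  for (k in 1:4) {
    f_at <- function(tau) {
      pr <- p[, k] > tau
      tp <- sum(pr & y[, k] == 1); fp <- sum(pr & y[, k] == 0)
      fn <- sum(!pr & y[, k] == 1)
      if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }
    expect_gte(f_at(th3$tau[k]), f_at(0.5))
  }
})

test_that("bout finding partitions the sequence with alternating polarity", {
  b <- find_bouts(c(0, 1, 1, 0, 1, 0))
  pos <- b[b$positive, ]
  expect_equal(pos$start, c(1, 4))
  expect_equal(pos$end, c(3, 5))
  expect_equal(pos$duration, c(2, 1))
  expect_equal(sum(b$duration), 6)
  expect_false(any(diff(as.integer(b$positive)) == 0))
  allz <- find_bouts(rep(0, 7))
  expect_equal(nrow(allz), 1)
  expect_equal(allz$duration, 7)
  expect_false(allz$positive)
})

test_that("bout-length cutoff is the interpolated first percentile", {
  m <- matrix(0L, sum(1:100) + 100, 1)
  at <- 1
  for (len in 1:100) {
    m[at:(at + len - 1), 1] <- 1L
    at <- at + len + 1
  }
  expect_equal(bout_length_cutoff(list(m)), 1.99)
  # degenerate distribution: all bouts the same length
  m5 <- matrix(rep(c(rep(1L, 5), 0L, 0L, 0L, 0L, 0L), 10), ncol = 1)
  expect_equal(bout_length_cutoff(list(m5)), 5)
  # strict "shorter than": bouts of exactly the cutoff length survive
  expect_equal(remove_short_bouts(m5[, 1], 5), m5[, 1])
  single <- matrix(c(0L, 1L, 1L, 1L, 0L), ncol = 1)
  expect_equal(bout_length_cutoff(list(single)), 3)
})

test_that("short-bout removal filters positives first, then interior negatives", {
  expect_equal(remove_short_bouts(c(0, 1, 0, 0, 1, 1, 1, 0), 2),
               c(0, 0, 0, 0, 1, 1, 1, 0))
  expect_equal(remove_short_bouts(c(1, 1, 0, 1, 1), 2), c(1, 1, 1, 1, 1))
  x <- c(0, 1, 1, 0, 1, 0, 0)
  expect_identical(remove_short_bouts(x, 0), x)
  # boundary negative bouts are exempt
  expect_equal(remove_short_bouts(c(0, 1, 1, 1, 0), 2), c(0, 1, 1, 1, 0))
})

test_that("background is the exact complement of the union of behaviors", {
  beh <- cbind(a = c(1L, 0L, 0L, 1L), b = c(0L, 0L, 1L, 1L))
  out <- set_background(beh)
  expect_equal(out[, "background"], c(0L, 1L, 0L, 0L))
  expect_true(all(rowSums(out) >= 1))
  ors <- apply(out, 1, max)
  expect_true(all(ors == 1))
})

test_that("metrics match hand counts and an independent reference", {
  # ConfusionCounts TP=3 TN=5 FP=1 FN=1 -> accuracy 0.8
  preds <- cbind(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  labs <- cbind(c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
  m <- eval_metrics(preds, labs)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$confusion$TP, 3)
  # precision 0.5, recall 1 -> F1 = 2/3
  preds2 <- cbind(c(1, 1, 1, 1))
  labs2 <- cbind(c(1, 1, 0, 0))
  m2 <- eval_metrics(preds2, labs2)
  expect_equal(m2$precision[1], 0.5)
  expect_equal(m2$recall[1], 1)
  expect_equal(m2$f1[1], 2 / 3)
  # random-input equivalence with a naive reference implementation
  set.seed(21)
  K <- 4; Tn <- 300
  p <- matrix(runif(Tn * K), Tn)
  pr <- (p > 0.5) + 0L
  y <- matrix(rbinom(Tn * K, 1, 0.4), Tn)
  m3 <- eval_metrics(pr, y, p)
  ref_acc <- mean(pr == y)
  expect_equal(m3$accuracy, ref_acc, tolerance = 1e-9)
  ref_f1 <- sapply(seq_len(K), function(k) {
    tp <- sum(pr[, k] == 1 & y[, k] == 1)
    prec <- tp / sum(pr[, k] == 1); rec <- tp / sum(y[, k] == 1)
    2 * prec * rec / (prec + rec)
  })
  expect_equal(m3$f1, ref_f1, tolerance = 1e-9)
  skip_if_not_installed("pROC")
  ref_auc <- sapply(seq_len(K), function(k)
    as.numeric(pROC::auc(pROC::roc(y[, k], p[, k], quiet = TRUE,
                                   direction = "<"))))
  expect_equal(m3$auroc, ref_auc, tolerance = 1e-9)
  # perfectly ranked probabilities give AUROC 1
  yy <- cbind(c(0, 0, 1, 1))
  pp <- cbind(c(0.1, 0.2, 0.8, 0.9))
  expect_equal(eval_metrics((pp > 0.5) + 0L, yy, pp)$auroc[1], 1)
})

test_that("bout statistics count time, bouts and durations", {
  eth <- cbind(x = c(0, 1, 1, 0, 1, 1, 1, 0, 0, 0))
  bs <- bout_statistics(eth, fps = 1)
  expect_equal(bs$time_percent, 50)
  expect_equal(bs$n_bouts, 2)
  expect_equal(bs$mean_bout_s, 2.5)
  bs0 <- bout_statistics(cbind(x = rep(0, 10)), fps = 30)
  expect_equal(bs0$time_percent, 0)
  expect_equal(bs0$n_bouts, 0)
  expect_equal(bs0$mean_bout_s, 0)
  expect_false(bs0$defined)
})

test_that("transition matrices are row-stochastic and count bout transitions", {
  # alternating A, B bouts
  eth <- cbind(background = rep(0L, 12),
               A = rep(c(1L, 1L, 0L, 0L), 3),
               B = rep(c(0L, 0L, 1L, 1L), 3))
  P <- transition_matrix(eth)
  expect_equal(P["A", "B"], 1)
  expect_equal(P["B", "A"], 1)
  expect_equal(unname(rowSums(P)), rep(1, 3))
  expect_true(all(P >= 0 & P <= 1))
  # single behavior: degenerate rows flagged
  eth1 <- cbind(background = rep(0L, 5), A = rep(1L, 5), B = rep(0L, 5))
  P1 <- transition_matrix(eth1)
  expect_true(length(attr(P1, "degenerate_rows")) >= 1)
})

test_that("circular shuffling preserves label counts and matches the analytic chance level", {
  set.seed(31)
  Tn <- 1e4
  q <- c(0.3, 0.1)  # label rates
  r <- c(0.5, 0.2)  # prediction rates
  y <- sapply(q, function(qq) rbinom(Tn, 1, qq))
  p <- sapply(r, function(rr) rbinom(Tn, 1, rr))
  res <- shuffle_chance(list(p), list(y), n_reps = 50, seed = 2)
  qhat <- colMeans(y); rhat <- colMeans(p)
  expected <- mean(qhat * rhat + (1 - qhat) * (1 - rhat))
  expect_lt(abs(res$mean_accuracy - expected), 0.02)
  # counts preserved under any shift
  off <- 1234
  shifted <- y[c((off + 1):Tn, 1:off), ]
  expect_equal(colSums(shifted), colSums(y))
  # a zero shift leaves metrics untouched
  m0 <- eval_metrics(p, y)
  expect_equal(m0$accuracy, mean(p == y))
})
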