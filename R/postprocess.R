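# Ethogram postprocessing: per-class probability thresholds maximizing F1,
# bout-length filtering, background complement; plus evaluation metrics,
# bout statistics, transition matrices and circular-shuffle chance levels.

threshold_grid <- function() seq_len(101) / 102

#' Pick per-class probability thresholds maximizing F1
#'
#' Thresholds are searched over a fixed grid of 101 evenly spaced values in
#' (0, 1); ties go to the smallest threshold. Thresholds are chosen on
#' training or validation data; test predictions must reuse the
#' validation-derived thresholds.
#'
#' @param probs T x K probability matrix (background column included but
#'   typically ignored downstream).
#' @param labels T x K binary matrix.
#' @return List with `tau` (length K) and `f1` (achieved F1 per class).
#' @export
optimize_thresholds <- function(probs, labels) {
  stopifnot(all(dim(probs) == dim(labels)))
  grid <- threshold_grid()
  K <- ncol(probs)
  tau <- numeric(K); f1 <- numeric(K)
  for (k in seq_len(K)) {
    y <- labels[, k]
    if (sum(y) == 0) {
      warning("class ", k, " has no positive labels; threshold defaults to 0.5")
      tau[k] <- 0.5; f1[k] <- 0
      next
    }
    best <- -1
    for (g in grid) {
      pred <- probs[, k] > g
      tp <- sum(pred & y == 1); fp <- sum(pred & y == 0); fn <- sum(!pred & y == 1)
      f <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      if (f > best + 1e-12) { best <- f; tau[k] <- g; f1[k] <- f }
    }
  }
  list(tau = tau, f1 = f1)
}

#' Find maximal runs (bouts) in a binary sequence
#'
#' @param x Binary vector.
#' @return Data frame with `start`, `end` (0-based, half-open), `duration`,
#'   `positive` (run of 1s or of 0s); rows alternate polarity and partition
#'   `[0, T)`.
#' @export
find_bouts <- function(x) {
  stopifnot(all(x %in% c(0, 1)))
  r <- rle(as.integer(x))
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(start = start, end = end, duration = r$lengths,
             positive = r$values == 1L)
}

#' Per-class bout-length cutoff from training labels
#'
#' First percentile (linear interpolation) of each class's positive-bout
#' length distribution in the training set; bouts strictly shorter than the
#' cutoff are removed at postprocessing time.
#'
#' @param labels_list List of T x K training label matrices (one per video).
#' @return Numeric vector of K cutoffs (0 disables the filter for a class
#'   with no training bouts).
#' @export
bout_length_cutoff <- function(labels_list) {
  if (is.matrix(labels_list)) labels_list <- list(labels_list)
  K <- ncol(labels_list[[1]])
  out <- numeric(K)
  for (k in seq_len(K)) {
    lens <- unlist(lapply(labels_list, function(m) {
      b <- find_bouts(m[, k])
      b$duration[b$positive]
    }))
    if (length(lens) == 0) {
      warning("no positive bouts for class ", k, "; bout filter disabled")
      out[k] <- 0
    } else {
      out[k] <- unname(stats::quantile(lens, 0.01, type = 7))
    }
  }
  out
}

#' Remove short bouts from a binary prediction sequence
#'
#' First removes positive bouts strictly shorter than `cutoff` (set to 0),
#' then re-finds bouts and removes interior negative bouts strictly shorter
#' than `cutoff` (set to 1). Negative bouts touching the sequence boundary
#' are exempt, so no behavior is fabricated at video edges.
#'
#' @param x Binary vector.
#' @param cutoff Minimum bout duration in frames (0 = no-op).
#' @return Filtered binary vector.
#' @export
remove_short_bouts <- function(x, cutoff) {
  stopifnot(cutoff >= 0)
  if (cutoff == 0) return(x)
  b <- find_bouts(x)
  for (i in seq_len(nrow(b)))
    if (b$positive[i] && b$duration[i] < cutoff) x[(b$start[i] + 1):b$end[i]] <- 0
  b <- find_bouts(x)
  n <- length(x)
  for (i in seq_len(nrow(b)))
    if (!b$positive[i] && b$duration[i] < cutoff &&
        b$start[i] > 0 && b$end[i] < n)
      x[(b$start[i] + 1):b$end[i]] <- 1
  x
}

#' Complete a prediction matrix with the background column
#'
#' Background is the logical NOT of the union of the behavior predictions;
#' the background column itself is never thresholded or bout-filtered.
#'
#' @param behavior_preds T x (K-1) binary matrix (behaviors only).
#' @return T x K binary matrix with the background column first.
#' @export
set_background <- function(behavior_preds) {
  bg <- as.integer(rowSums(behavior_preds) == 0)
  out <- cbind(background = bg, behavior_preds)
  out
}

#' Postprocess probabilities into a binary ethogram
#'
#' Thresholds each behavior (background column excluded), applies the
#' per-class bout-length filter, then recomputes background as the
#' complement.
#'
#' @param probs T x K probability matrix, background column first.
#' @param tau Length-K thresholds (background entry unused).
#' @param cutoffs Length-K bout cutoffs (background entry unused); `NULL`
#'   skips the filter.
#' @return T x K binary ethogram.
#' @export
postprocess_predictions <- function(probs, tau, cutoffs = NULL) {
  K <- ncol(probs)
  beh <- matrix(0L, nrow(probs), K - 1L)
  colnames(beh) <- colnames(probs)[-1]
  for (k in 2:K) {
    p <- as.integer(probs[, k] > tau[k])
    if (!is.null(cutoffs) && cutoffs[k] > 0) p <- remove_short_bouts(p, cutoffs[k])
    beh[, k - 1L] <- p
  }
  set_background(beh)
}

#' Classification metrics for multi-label ethograms
#'
#' Overall accuracy pooled over all T x K elements, per-class precision,
#' recall and F1 (macro-averaged), and macro AUROC from the probabilities.
#' A class absent from the labels gets F1 = 0 with a warning and is excluded
#' from the AUROC average.
#'
#' @param preds T x K binary predictions.
#' @param labels T x K binary labels.
#' @param probs Optional T x K probabilities for AUROC.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `macro_f1`,
#'   `auroc`, `macro_auroc`, `confusion` (per-class TP/TN/FP/FN).
#' @export
eval_metrics <- function(preds, labels, probs = NULL) {
  stopifnot(all(dim(preds) == dim(labels)))
  K <- ncol(labels)
  tp <- colSums(preds == 1 & labels == 1)
  tn <- colSums(preds == 0 & labels == 0)
  fp <- colSums(preds == 1 & labels == 0)
  fn <- colSums(preds == 0 & labels == 1)
  acc <- sum(tp + tn) / sum(tp + tn + fp + fn)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  absent <- colSums(labels) == 0
  if (any(absent)) {
    warning("class(es) absent from labels; F1 set to 0: ",
            paste(which(absent), collapse = ", "))
    f1[absent] <- 0
  }
  auroc <- rep(NA_real_, K)
  if (!is.null(probs)) {
    for (k in seq_len(K)) {
      y <- labels[, k]
      n1 <- sum(y == 1); n0 <- sum(y == 0)
      if (n1 == 0 || n0 == 0) next
      r <- rank(probs[, k])
      auroc[k] <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    if (anyNA(auroc)) warning("AUROC undefined for some classes; excluded from macro")
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       macro_f1 = mean(f1),
       auroc = auroc, macro_auroc = mean(auroc, na.rm = TRUE),
       confusion = data.frame(TP = tp, TN = tn, FP = fp, FN = fn))
}

#' Bout statistics of an ethogram
#'
#' @param ethogram T x K binary matrix.
#' @param fps Frames per second (> 0).
#' @return Data frame per class: `time_percent` (100 * positive frames / T),
#'   `n_bouts`, `mean_bout_s` (mean positive-bout duration in seconds; 0 with
#'   `defined = FALSE` when a class never occurs).
#' @export
bout_statistics <- function(ethogram, fps) {
  stopifnot(fps > 0)
  Tn <- nrow(ethogram)
  out <- lapply(seq_len(ncol(ethogram)), function(k) {
    b <- find_bouts(ethogram[, k])
    pos <- b[b$positive, , drop = FALSE]
    data.frame(class = colnames(ethogram)[k] %||% as.character(k),
               time_percent = 100 * sum(ethogram[, k]) / Tn,
               n_bouts = nrow(pos),
               mean_bout_s = if (nrow(pos)) mean(pos$duration) / fps else 0,
               defined = nrow(pos) > 0)
  })
  do.call(rbind, out)
}

#' Behavior-to-behavior transition matrix
#'
#' Frames are reduced to a single dominant non-background class (highest
#' probability among active classes; ties to the lowest index; background
#' where none is active), self-transitions within a bout are excluded, and
#' bout-to-bout transitions are counted. Rows with no outgoing transitions
#' become uniform and are flagged.
#'
#' @param ethogram T x K binary matrix, background first.
#' @param probs Optional T x K probabilities used to rank co-active classes.
#' @return K x K row-stochastic matrix with attribute `degenerate_rows`.
#' @export
transition_matrix <- function(ethogram, probs = NULL) {
  K <- ncol(ethogram)
  Tn <- nrow(ethogram)
  dom <- integer(Tn)
  for (t in seq_len(Tn)) {
    act <- which(ethogram[t, -1] == 1) + 1L
    dom[t] <- if (length(act) == 0) 1L
      else if (length(act) == 1L) act
      else if (is.null(probs)) min(act)
      else act[which.max(probs[t, act])]
  }
  r <- rle(dom)
  counts <- matrix(0, K, K, dimnames = list(colnames(ethogram), colnames(ethogram)))
  if (length(r$values) > 1)
    for (i in seq_len(length(r$values) - 1))
      counts[r$values[i], r$values[i + 1]] <- counts[r$values[i], r$values[i + 1]] + 1
  rs <- rowSums(counts)
  degenerate <- rs == 0
  P <- counts
  P[degenerate, ] <- 1 / K
  P[!degenerate, ] <- counts[!degenerate, , drop = FALSE] / rs[!degenerate]
  attr(P, "degenerate_rows") <- which(degenerate)
  P
}

#' Chance-level metrics by circular label shuffling
#'
#' Each repetition circularly shifts every video's label matrix by an
#' independent random offset (preserving per-class label counts exactly) and
#' recomputes the metrics; the mean over repetitions estimates chance
#' performance.
#'
#' @param preds_list List of T x K binary prediction matrices (one per video).
#' @param labels_list Matching list of label matrices.
#' @param n_reps Number of shuffle repetitions (default 100).
#' @param seed Integer seed.
#' @return List with `mean_accuracy`, `mean_macro_f1`, and the per-repetition
#'   vectors.
#' @export
shuffle_chance <- function(preds_list, labels_list, n_reps = 100L, seed = 1L) {
  set.seed(seed)
  accs <- numeric(n_reps); f1s <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    shifted <- lapply(labels_list, function(m) {
      off <- sample.int(nrow(m), 1L) - 1L
      if (off == 0) m else m[c((off + 1):nrow(m), 1:off), , drop = FALSE]
    })
    met <- eval_metrics(do.call(rbind, preds_list), do.call(rbind, shifted))
    accs[r] <- met$accuracy; f1s[r] <- met$macro_f1
  }
  list(mean_accuracy = mean(accs), mean_macro_f1 = mean(f1s),
       accuracy = accs, macro_f1 = f1s)
}
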