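# Project layout, video/label I/O, splits, channel statistics and
# stack-consistent augmentation.

write_labels_csv <- function(labels, path) {
  data.table::fwrite(data.table::as.data.table(labels), path)
}

#' Read a video from a project directory
#'
#' Videos are stored as lossless multi-page TIFF. Grayscale frames are
#' promoted to three identical channels so the input-channel contract of the
#' networks holds for any source.
#'
#' @param path Path to the video file.
#' @return A `video_clip` list: `frames` (H x W x 3 x T array of intensities
#'   in \[0, 1\]), `fps`, `path`.
#' @export
read_video <- function(path) {
  if (!file.exists(path)) stop("I/O error: video not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  H <- dim(pages[[1]])[1]; W <- dim(pages[[1]])[2]
  n <- length(pages)
  frames <- array(0, dim = c(H, W, 3, n))
  for (t in seq_len(n)) {
    p <- pages[[t]]
    if (length(dim(p)) == 2L) {
      frames[, , 1, t] <- p; frames[, , 2, t] <- p; frames[, , 3, t] <- p
    } else {
      nc <- dim(p)[3]
      for (c in 1:3) frames[, , c, t] <- p[, , min(c, nc)]
    }
  }
  meta <- file.path(dirname(path), "meta.yaml")
  fps <- if (file.exists(meta)) yaml::read_yaml(meta)$fps else NA_real_
  structure(list(frames = frames, fps = fps, path = path), class = "video_clip")
}

#' Read a per-frame multi-label CSV
#'
#' @param path Path to the label CSV (header of class names, background
#'   first; one 0/1 row per frame).
#' @param n_frames Optional frame count of the paired video; a mismatch is an
#'   alignment error naming both counts.
#' @return Integer T x K matrix with class-name columns.
#' @export
read_labels <- function(path, n_frames = NULL) {
  if (!file.exists(path)) stop("I/O error: labels not found: ", path)
  dt <- data.table::fread(path)
  m <- as.matrix(dt)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (ncol(m) < 2L) stop("labels need a background column plus >= 1 behavior")
  if (!is.null(n_frames) && nrow(m) != n_frames)
    stop(sprintf("alignment error: %d label rows but %d video frames",
                 nrow(m), n_frames))
  m
}

#' List video names in a project directory
#' @param project_dir Project root containing `DATA/`.
#' @return Character vector of video names.
#' @export
project_videos <- function(project_dir) {
  sort(basename(list.dirs(file.path(project_dir, "DATA"), recursive = FALSE)))
}

video_path <- function(project_dir, name)
  file.path(project_dir, "DATA", name, paste0(name, ".tiff"))
labels_path <- function(project_dir, name)
  file.path(project_dir, "DATA", name, "labels.csv")

#' Split videos into train/validation/test sets
#'
#' Picks 60/20/20 (by default) of videos per replicate, with validation and
#' test sizes floored and the remainder assigned to train, resampling until
#' every class has at least one positive frame in every subset.
#'
#' @param labels Named list of label matrices, one per video.
#' @param ratios Train/validation/test fractions summing to 1.
#' @param n_replicates Number of independent split replicates.
#' @param seed Integer seed.
#' @param max_attempts Resampling bound per replicate before an infeasibility
#'   error is raised.
#' @return List of split assignments; each has `train`, `validation`, `test`
#'   (character vectors of video names), `replicate`, `seed`.
#' @export
make_splits <- function(labels, ratios = c(0.6, 0.2, 0.2), n_replicates = 5,
                        seed = 1L, max_attempts = 1000L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8)
  nm <- names(labels)
  n <- length(nm)
  n_val <- max(1L, floor(ratios[2] * n))
  n_test <- max(1L, floor(ratios[3] * n))
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("infeasible: too few videos to split")
  # quick pigeonhole check: a class present in fewer videos than subsets
  # cannot cover all subsets
  present <- sapply(labels, function(m) colSums(m) > 0)  # K x n
  if (any(rowSums(present) < 3L))
    stop("infeasible: class '",
         rownames(present)[which(rowSums(present) < 3L)[1]],
         "' occurs in fewer than 3 videos; cannot cover all subsets")
  set.seed(seed)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      perm <- sample(nm)
      spl <- list(train = perm[seq_len(n_train)],
                  validation = perm[n_train + seq_len(n_val)],
                  test = perm[n_train + n_val + seq_len(n_test)])
      covered <- all(vapply(spl, function(vs) {
        all(Reduce(`+`, lapply(labels[vs], colSums)) > 0)
      }, logical(1)))
      if (covered) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible: could not satisfy class coverage in ",
                  max_attempts, " attempts")
    spl$replicate <- r
    spl$seed <- seed
    out[[r]] <- spl
  }
  out
}

#' Per-channel mean and standard deviation of training videos
#'
#' Computed over all pixels of the training subset only, on the 0-1 intensity
#' scale; the standard deviation is floored at 1e-4 to protect constant
#' (synthetic) videos.
#'
#' @param clips List of `video_clip` objects (the training subset).
#' @return List with `mean` and `sd`, each length 3.
#' @export
compute_channel_stats <- function(clips) {
  if (length(clips) == 0L) stop("empty training set")
  s <- n <- rep(0, 3); ss <- rep(0, 3)
  for (cl in clips) {
    f <- cl$frames
    for (c in 1:3) {
      v <- f[, , c, ]
      s[c] <- s[c] + sum(v)
      ss[c] <- ss[c] + sum(v^2)
      n[c] <- n[c] + length(v)
    }
  }
  mu <- s / n
  sd <- sqrt(pmax(ss / n - mu^2, 0))
  list(mean = mu, sd = pmax(sd, 1e-4))
}

#' Standardize frames channel-wise
#' @param frames H x W x 3 x T array on the 0-1 scale.
#' @param stats Output of [compute_channel_stats()].
#' @return Standardized array.
#' @export
standardize_frames <- function(frames, stats) {
  for (c in 1:3)
    frames[, , c, ] <- (frames[, , c, ] - stats$mean[c]) / stats$sd[c]
  frames
}

#' Extract the 11-frame input stack centered on a frame
#'
#' The stack for frame `t` is frames `t-5 .. t+5`; at video boundaries the
#' first/last frame is replicated, which avoids phantom motion at the edges.
#'
#' @param frames H x W x 3 x T array.
#' @param t Center frame (1-based).
#' @return H x W x 3 x 11 array.
#' @export
frame_stack <- function(frames, t) {
  T_ <- dim(frames)[4]
  idx <- pmin(pmax(seq(t - 5L, t + 5L), 1L), T_)
  frames[, , , idx, drop = FALSE]
}

#' Default augmentation policy
#'
#' @param brightness,contrast Maximum absolute jitter (fractional).
#' @param rotation Maximum rotation magnitude in degrees (capped at 10).
#' @param hflip,vflip Enable horizontal / vertical flips (probability 0.5).
#' @return Policy list.
#' @export
augment_policy <- function(brightness = 0.2, contrast = 0.2, rotation = 10,
                           hflip = FALSE, vflip = FALSE) {
  stopifnot(rotation <= 10)
  list(brightness = brightness, contrast = contrast, rotation = rotation,
       hflip = hflip, vflip = vflip)
}

#' Draw one set of augmentation parameters
#' @param policy An [augment_policy()].
#' @return List of drawn parameters (single draw for the whole stack).
#' @export
draw_augmentation <- function(policy) {
  list(brightness = stats::runif(1, -policy$brightness, policy$brightness),
       contrast = 1 + stats::runif(1, -policy$contrast, policy$contrast),
       angle = stats::runif(1, -policy$rotation, policy$rotation) * pi / 180,
       hflip = policy$hflip && stats::runif(1) < 0.5,
       vflip = policy$vflip && stats::runif(1) < 0.5)
}

rotation_flow <- function(H, W, angle) {
  # displacement field sampling the source image rotated by `angle` about the
  # center (bilinear, border replicate)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H), W), H, W) - cy
  sx <- cos(angle) * xs - sin(angle) * ys
  sy <- sin(angle) * xs + cos(angle) * ys
  fl <- array(0, dim = c(H, W, 2, 1))
  fl[, , 1, 1] <- sx - xs
  fl[, , 2, 1] <- sy - ys
  fl
}

apply_augmentation <- function(stack, par) {
  d <- dim(stack)
  if (isTRUE(par$hflip)) stack <- stack[, rev(seq_len(d[2])), , , drop = FALSE]
  if (isTRUE(par$vflip)) stack <- stack[rev(seq_len(d[1])), , , , drop = FALSE]
  if (abs(par$angle) > 1e-12) {
    fl <- rotation_flow(d[1], d[2], par$angle)
    flN <- array(rep(fl, d[4]), dim = c(d[1], d[2], 2, d[4]))
    x <- stack; dim(x) <- c(d[1], d[2], d[3], d[4])
    stack <- cpp_warp_fw(x, flN)
  }
  stack <- stack * par$contrast + par$brightness
  stack
}

#' Augment an 11-frame stack consistently
#'
#' One draw of brightness/contrast/rotation/flip parameters is applied
#' identically to every frame of the stack, so relative motion between frames
#' is untouched.
#'
#' @param stack H x W x C x 11 array.
#' @param policy An [augment_policy()]; pass
#'   `augment_policy(0, 0, 0)` for the identity.
#' @return Augmented stack (same shape), plus the drawn parameters as
#'   attribute `"draw"`.
#' @export
augment_stack <- function(stack, policy = augment_policy()) {
  par <- draw_augmentation(policy)
  out <- apply_augmentation(stack, par)
  attr(out, "draw") <- par
  out
}
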