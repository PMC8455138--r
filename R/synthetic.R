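#' Define a synthetic behavior
#'
#' A behavior specification controls both the label process (semi-Markov bout
#' structure) and the appearance of the rendered agent while the behavior is
#' active.
#'
#' Non-overlapping behaviors form a semi-Markov chain: bout lengths are
#' geometric (support >= 1 frame) with the configured mean, and on each bout
#' end the next state is drawn among the other states with probability
#' proportional to `prevalence_weight`. Overlapping behaviors toggle on/off
#' independently of the chain; for those, `prevalence_weight` is interpreted
#' as the stationary on-fraction and must lie in (0, 1).
#'
#' @param name Behavior name (unique).
#' @param render_mode One of `"still"`, `"locomote"`, `"spin"`, `"twitch"`,
#'   `"overlay_flash"`. Determines how the agent is drawn while active.
#' @param mean_bout_frames Mean bout duration in frames (>= 1).
#' @param prevalence_weight Positive weight controlling how often the behavior
#'   occurs (see Details).
#' @param overlapping Logical; may the behavior co-occur with a base behavior?
#' @param params Named list of render parameters overriding the mode defaults
#'   (`speed`, `spin_rate`, `twitch_amp`, `flash_amp`, ...).
#' @return A `behavior_spec` object.
#' @export
behavior_spec <- function(name,
                          render_mode = c("still", "locomote", "spin", "twitch",
                                          "overlay_flash"),
                          mean_bout_frames,
                          prevalence_weight = 1,
                          overlapping = FALSE,
                          params = list()) {
  render_mode <- match.arg(render_mode)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("behavior name must be a non-empty string")
  if (!is.numeric(mean_bout_frames) || mean_bout_frames < 1)
    stop("mean_bout_frames must be >= 1")
  if (prevalence_weight <= 0)
    stop("prevalence_weight must be positive")
  if (overlapping && prevalence_weight >= 1)
    stop("for overlapping behaviors prevalence_weight is the on-fraction and must be in (0,1)")
  structure(list(name = name, render_mode = render_mode,
                 mean_bout_frames = mean_bout_frames,
                 prevalence_weight = prevalence_weight,
                 overlapping = overlapping, params = params),
            class = "behavior_spec")
}

#' Desk-scale default behavior set
#'
#' Four behaviors plus background: `locomote` (translation), `spin` (rotating
#' elongated blob), `twitch` (rare, ~2% of frames: high-frequency positional
#' oscillation) and `flash` (overlapping global intensity increase).
#'
#' @return List of [behavior_spec()] objects.
#' @export
default_behavior_specs <- function() {
  list(
    behavior_spec("locomote", "locomote", mean_bout_frames = 30, prevalence_weight = 1),
    behavior_spec("spin", "spin", mean_bout_frames = 25, prevalence_weight = 1),
    behavior_spec("twitch", "twitch", mean_bout_frames = 7, prevalence_weight = 0.22),
    behavior_spec("flash", "overlay_flash", mean_bout_frames = 15,
                  prevalence_weight = 0.10, overlapping = TRUE)
  )
}

#' Default background bout parameters for the generating chain
#' @return List with `mean_bout_frames` and `prevalence_weight`.
#' @export
default_background <- function() list(mean_bout_frames = 35, prevalence_weight = 1)

validate_specs <- function(specs) {
  if (length(specs) == 0L) stop("invalid configuration: no behavior specs")
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("invalid configuration: duplicate behavior names")
  if (!any(!vapply(specs, function(s) s$overlapping, logical(1))))
    stop("invalid configuration: at least one non-overlapping spec required")
  nm
}

#' Stationary frame-occupancy distribution of the generating chain
#'
#' Closed-form stationary distribution over the non-overlapping states
#' (including background if supplied): solve the embedded jump chain
#' `P(i -> j) = w_j / sum_{k != i} w_k`, then weight by mean bout lengths.
#'
#' @param specs List of [behavior_spec()]; overlapping specs are ignored.
#' @param background `NULL`, or a list with `mean_bout_frames` and
#'   `prevalence_weight` for an explicit background state.
#' @return Named vector of stationary frame fractions.
#' @export
chain_stationary <- function(specs, background = NULL) {
  base <- Filter(function(s) !s$overlapping, specs)
  w <- vapply(base, function(s) s$prevalence_weight, numeric(1))
  m <- vapply(base, function(s) s$mean_bout_frames, numeric(1))
  nm <- vapply(base, function(s) s$name, character(1))
  if (!is.null(background)) {
    w <- c(background$prevalence_weight, w)
    m <- c(background$mean_bout_frames, m)
    nm <- c("background", nm)
  }
  k <- length(w)
  if (k == 1L) return(stats::setNames(1, nm))
  P <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j) P[i, j] <- w[j] / (sum(w) - w[i])
  e <- eigen(t(P))
  q <- Re(e$vectors[, which.min(abs(e$values - 1))])
  q <- q / sum(q)
  pi <- q * m
  stats::setNames(pi / sum(pi), nm)
}

# geometric bout length with support >= 1 and mean m
rboutlen <- function(m) {
  if (m <= 1) return(1L)
  stats::rgeom(1L, 1 / m) + 1L
}

#' Sample a per-frame behavior script
#'
#' Draws the semi-Markov state sequence over the non-overlapping behaviors
#' (plus an optional background state) and independent on/off sequences for
#' overlapping behaviors, and assembles the frame-by-frame multi-label matrix
#' with the background column first.
#'
#' @param specs List of [behavior_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; the script is reproducible given (specs, seed).
#' @param background Optional background state parameters
#'   (see [default_background()]); `NULL` omits the background state from the
#'   chain (background frames then never occur unless no spec is active).
#' @return List with `states` (character, per frame, `"background"` or a
#'   non-overlapping behavior name), `overlays` (T x n_overlap 0/1 matrix) and
#'   `labels` (T x K 0/1 matrix, background column first).
#' @export
sample_behavior_script <- function(specs, n_frames, seed = 1L,
                                   background = default_background()) {
  if (!is.numeric(n_frames) || n_frames < 1)
    stop("invalid configuration: n_frames must be >= 1")
  nm <- validate_specs(specs)
  n_frames <- as.integer(n_frames)
  set.seed(seed)
  base <- Filter(function(s) !s$overlapping, specs)
  over <- Filter(function(s) s$overlapping, specs)
  w <- vapply(base, function(s) s$prevalence_weight, numeric(1))
  m <- vapply(base, function(s) s$mean_bout_frames, numeric(1))
  base_nm <- vapply(base, function(s) s$name, character(1))
  if (!is.null(background)) {
    w <- c(background$prevalence_weight, w)
    m <- c(background$mean_bout_frames, m)
    base_nm <- c("background", base_nm)
  }
  k <- length(base_nm)
  pi <- chain_stationary(specs, background)
  states <- character(n_frames)
  cur <- sample.int(k, 1L, prob = pi)
  t <- 1L
  while (t <= n_frames) {
    len <- min(rboutlen(m[cur]), n_frames - t + 1L)
    states[t:(t + len - 1L)] <- base_nm[cur]
    t <- t + len
    if (k > 1L) {
      pnext <- w
      pnext[cur] <- 0
      cur <- sample.int(k, 1L, prob = pnext)
    }
  }
  # overlapping behaviors: independent alternating on/off renewal processes
  n_over <- length(over)
  overlays <- matrix(0L, n_frames, n_over)
  if (n_over > 0) colnames(overlays) <- vapply(over, function(s) s$name, character(1))
  for (i in seq_len(n_over)) {
    f <- over[[i]]$prevalence_weight           # stationary on-fraction
    m_on <- over[[i]]$mean_bout_frames
    m_off <- m_on * (1 - f) / f
    on <- stats::runif(1) < f
    t <- 1L
    while (t <= n_frames) {
      len <- min(rboutlen(if (on) m_on else m_off), n_frames - t + 1L)
      if (on) overlays[t:(t + len - 1L), i] <- 1L
      t <- t + len
      on <- !on
    }
  }
  class_names <- c("background", nm)
  lab <- matrix(0L, n_frames, length(class_names),
                dimnames = list(NULL, class_names))
  for (s in nm) {
    if (s %in% base_nm) lab[, s] <- as.integer(states == s)
    else lab[, s] <- overlays[, s]
  }
  lab[, "background"] <- as.integer(rowSums(lab[, nm, drop = FALSE]) == 0L)
  modes <- stats::setNames(vapply(specs, function(s) s$render_mode, character(1)), nm)
  list(states = states, overlays = overlays, labels = lab, modes = modes)
}

default_render_params <- function() {
  list(speed = 2, spin_rate = 0.35, twitch_amp = 1, flash_amp = 40,
       sigma = 5, sigma_major = 8, sigma_minor = 3.2,
       peak = 200, floor = 30, margin = 0.2)
}

#' Render one frame of the synthetic agent
#'
#' Draws a Gaussian blob whose shape and position encode the behavior state:
#' `locomote` translates the blob, `spin` uses a rotating elongated blob,
#' `twitch` adds a +/- `twitch_amp` pixel alternation, `overlay_flash` adds a
#' constant intensity offset to every pixel. Pixel values are rounded to
#' integers in \[0, 255\] so frames survive an 8-bit container round trip.
#'
#' @param state List with `pos` (x, y center in pixels), `angle` (radians),
#'   `mode` (render mode of the active base behavior) and `flash` (logical).
#' @param t Frame index (drives the twitch oscillation phase).
#' @param size Frame size `c(H, W)`, both >= 32.
#' @param noise_sd Standard deviation of additive pixel noise (intensity units).
#' @param params Render parameters (see `default_render_params`).
#' @return H x W numeric matrix of intensities in \[0, 255\].
#' @export
render_frame <- function(state, t, size = c(64, 64), noise_sd = 0,
                         params = default_render_params()) {
  if (any(size < 32)) stop("invalid configuration: frame size must be >= 32")
  H <- size[1]; W <- size[2]
  cx <- state$pos[1]; cy <- state$pos[2]
  if (identical(state$mode, "twitch"))
    cx <- cx + params$twitch_amp * (-1)^t
  xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H), W), H, W) - cy
  if (identical(state$mode, "spin")) {
    a <- state$angle
    u <- cos(a) * xs + sin(a) * ys
    v <- -sin(a) * xs + cos(a) * ys
    q <- (u / params$sigma_major)^2 + (v / params$sigma_minor)^2
  } else {
    q <- (xs^2 + ys^2) / params$sigma^2
  }
  img <- params$floor + params$peak * exp(-q / 2)
  if (isTRUE(state$flash)) img <- img + params$flash_amp
  if (noise_sd > 0) img <- img + stats::rnorm(H * W, sd = noise_sd)
  matrix(pmin(pmax(round(img), 0), 255), H, W)
}

#' Render a full synthetic video from a behavior script
#'
#' Integrates the agent's position/heading over frames (locomotion translates
#' with bout-persistent heading and bounces off a margin) and renders each
#' frame with [render_frame()].
#'
#' @param script Output of [sample_behavior_script()].
#' @param size Frame size `c(H, W)`.
#' @param noise_sd Additive pixel noise sd.
#' @param seed Integer seed for trajectory and noise draws.
#' @param params Render parameters.
#' @return H x W x T array of intensities in \[0, 255\].
#' @export
render_video <- function(script, size = c(64, 64), noise_sd = 3, seed = 1L,
                         params = default_render_params()) {
  set.seed(seed)
  H <- size[1]; W <- size[2]
  n <- length(script$states)
  out <- array(0, dim = c(H, W, n))
  pos <- c(W / 2 + stats::runif(1, -4, 4), H / 2 + stats::runif(1, -4, 4))
  angle <- stats::runif(1, 0, 2 * pi)
  heading <- stats::runif(1, 0, 2 * pi)
  lo <- params$margin * c(W, H); hi <- c(W, H) - lo
  has_flash <- ncol(script$overlays) > 0
  prev_state <- ""
  for (t in seq_len(n)) {
    st <- script$states[t]
    mode <- if (st == "background") "still" else script$modes[[st]]
    if (st != prev_state && st == "locomote")
      heading <- stats::runif(1, 0, 2 * pi)
    prev_state <- st
    if (mode == "locomote") {
      pos <- pos + params$speed * c(cos(heading), sin(heading))
      if (pos[1] < lo[1]) { pos[1] <- 2 * lo[1] - pos[1]; heading <- pi - heading }
      if (pos[1] > hi[1]) { pos[1] <- 2 * hi[1] - pos[1]; heading <- pi - heading }
      if (pos[2] < lo[2]) { pos[2] <- 2 * lo[2] - pos[2]; heading <- -heading }
      if (pos[2] > hi[2]) { pos[2] <- 2 * hi[2] - pos[2]; heading <- -heading }
    }
    if (mode == "spin") angle <- angle + params$spin_rate
    flash <- has_flash && any(script$overlays[t, ] == 1L)
    out[, , t] <- render_frame(list(pos = pos, angle = angle, mode = mode,
                                    flash = flash),
                               t, size, noise_sd, params)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_videos` lossless videos (multi-page 8-bit TIFF) plus matching
#' label CSVs in the project layout `<dir>/DATA/<name>/{<name>.tiff,
#' labels.csv, meta.yaml}`. Scripts are resampled (bounded attempts) until
#' every class has at least one positive frame in every video, so downstream
#' train/val/test splits can satisfy the class-coverage constraint.
#'
#' @param out_dir Project directory to create.
#' @param specs Behavior specs; default [default_behavior_specs()].
#' @param n_videos Number of videos (>= 1).
#' @param n_frames Frames per video.
#' @param size Frame size `c(H, W)`.
#' @param fps Frames per second recorded in the metadata.
#' @param noise_sd Additive pixel noise sd.
#' @param seed Integer seed; dataset is reproducible given the configuration.
#' @param background Background chain parameters (see [default_background()]).
#' @param max_attempts Resampling bound for the every-class-per-video rule.
#' @return Invisibly, a list with `dir`, `video_names`, `labels` (list of
#'   label matrices), `class_names`, `config`, `seed`.
#' @export
generate_dataset <- function(out_dir, specs = default_behavior_specs(),
                             n_videos = 6, n_frames = 600, size = c(64, 64),
                             fps = 30, noise_sd = 3, seed = 1L,
                             background = default_background(),
                             max_attempts = 100L) {
  if (n_videos < 1) stop("invalid configuration: n_videos must be >= 1")
  validate_specs(specs)
  dir.create(file.path(out_dir, "DATA"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "DATA"))) stop("cannot create output directory: ", out_dir)
  labels <- list()
  names_out <- character(n_videos)
  for (v in seq_len(n_videos)) {
    script <- NULL
    for (att in seq_len(max_attempts)) {
      cand <- sample_behavior_script(specs, n_frames,
                                     seed = seed * 10000L + v * 100L + att,
                                     background = background)
      if (all(colSums(cand$labels) > 0L)) { script <- cand; break }
    }
    if (is.null(script))
      stop("could not sample a script containing every class in video ", v)
    vid <- render_video(script, size = size, noise_sd = noise_sd,
                        seed = seed * 10000L + v)
    name <- sprintf("synthetic_%02d", v)
    vdir <- file.path(out_dir, "DATA", name)
    dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
    frames <- lapply(seq_len(dim(vid)[3]), function(t) vid[, , t] / 255)
    ok <- try(tiff::writeTIFF(frames, file.path(vdir, paste0(name, ".tiff")),
                              bits.per.sample = 8L, compression = "LZW"),
              silent = TRUE)
    if (inherits(ok, "try-error")) stop("I/O error writing video: ", vdir)
    write_labels_csv(script$labels, file.path(vdir, "labels.csv"))
    yaml::write_yaml(list(fps = fps, height = size[1], width = size[2],
                          n_frames = n_frames), file.path(vdir, "meta.yaml"))
    labels[[name]] <- script$labels
    names_out[v] <- name
  }
  invisible(list(dir = out_dir, video_names = names_out, labels = labels,
                 class_names = colnames(labels[[1]]),
                 config = list(specs = specs, n_frames = n_frames, size = size,
                               fps = fps, noise_sd = noise_sd,
                               background = background),
                 seed = seed))
}
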