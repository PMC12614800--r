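## Body-part roster of the pose model. Immobility detection uses the five
## trunk points (ear bases, upper/middle spine, tail base).
BODY_PARTS <- c("nose", "miniscope_base", "left_ear_base", "right_ear_base",
                "neck", "upper_spine", "middle_spine", "tail_base")
IMMOBILITY_POINTS <- c("left_ear_base", "right_ear_base", "upper_spine",
                       "middle_spine", "tail_base")

#' Generate a synthetic pose track with planted immobility bouts
#'
#' Simulates a two-state (mobile/immobile) semi-Markov path over the
#' session: immobile dwell times are `min_bout_s` plus an exponential tail,
#' mobile dwells are exponential. While mobile the animal translates at a
#' per-frame speed drawn from `mobile_speed` (pixels/frame); while immobile
#' all body parts jitter with `immobile_jitter_sd`. Each body part rides the
#' common trajectory with a fixed anatomical offset and small independent
#' jitter. A fraction `dropout_rate` of frames per body part receives a low
#' pose-estimation likelihood.
#'
#' @param config A `synth_config` (its `behaviour` list is used).
#' @param events `event_table` of the session (fixes the session duration;
#'   planted bouts may overlap CS windows, mirroring real behaviour).
#' @param seed Seed.
#' @return List with `pose` (a `pose_track`) and `bouts` (data frame
#'   `start_s`, `stop_s` of planted immobility intervals, all >=
#'   `min_bout_s` long, non-overlapping and sorted).
#' @export
generate_behaviour <- function(config, events, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  bh <- config$behaviour
  set.seed(seed)
  dur <- attr(events, "session_end_s")
  fps <- bh$frame_rate
  n_frames <- as.integer(round(dur * fps))

  ## state path: alternating mobile/immobile dwells
  starts <- numeric(0); stops <- numeric(0)
  if (bh$immobility_rate > 0) {
    mobile_mean <- 60 / bh$immobility_rate  # seconds of mobility per bout
    t <- stats::rexp(1, 1 / mobile_mean)
    while (t < dur - bh$min_bout_s) {
      d <- bh$min_bout_s + stats::rexp(1, 1 / (bh$immobile_mean_s -
                                                 bh$min_bout_s))
      d <- min(d, dur - t)
      if (d >= bh$min_bout_s) {
        starts <- c(starts, t); stops <- c(stops, t + d)
      }
      t <- t + d + stats::rexp(1, 1 / mobile_mean)
    }
  }
  bouts <- data.frame(start_s = starts, stop_s = stops)

  frame_t <- (seq_len(n_frames) - 1) / fps
  immobile <- rep(FALSE, n_frames)
  for (j in seq_len(nrow(bouts))) {
    immobile[frame_t >= bouts$start_s[j] & frame_t < bouts$stop_s[j]] <- TRUE
  }

  ## common trajectory: reflected random walk inside the arena
  speed <- stats::runif(n_frames, bh$mobile_speed[1], bh$mobile_speed[2])
  speed[immobile] <- 0
  heading <- cumsum(stats::rnorm(n_frames, 0, 0.3))
  step_x <- speed * cos(heading)
  step_y <- speed * sin(heading)
  base_x <- bh$arena_px / 2 + cumsum(step_x)
  base_y <- bh$arena_px / 2 + cumsum(step_y)
  reflect <- function(v, lim) {
    v <- v %% (2 * lim)
    ifelse(v > lim, 2 * lim - v, v)
  }
  base_x <- reflect(base_x, bh$arena_px)
  base_y <- reflect(base_y, bh$arena_px)

  offsets <- cbind(x = seq(-12, 16, length.out = length(BODY_PARTS)),
                   y = seq(8, -10, length.out = length(BODY_PARTS)))
  pose <- list()
  for (i in seq_along(BODY_PARTS)) {
    jit_sd <- ifelse(immobile, bh$immobile_jitter_sd, 0.5)
    x <- base_x + offsets[i, "x"] + stats::rnorm(n_frames, 0, jit_sd)
    y <- base_y + offsets[i, "y"] + stats::rnorm(n_frames, 0, jit_sd)
    drop <- stats::runif(n_frames) < bh$dropout_rate
    lik <- ifelse(drop, stats::runif(n_frames, 0, 0.5),
                  stats::runif(n_frames, 0.95, 1))
    pose[[BODY_PARTS[i]]] <- data.frame(x = x, y = y, likelihood = lik)
  }
  track <- structure(list(parts = pose, frame_rate = fps,
                          n_frames = n_frames),
                     class = "pose_track")
  list(pose = track, bouts = bouts)
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames at %g Hz, %d body parts\n",
              x$n_frames, x$frame_rate, length(x$parts)))
  invisible(x)
}

#' Write / read pose tracks as wide CSV
#'
#' Wide layout with two header rows (body part; then x/y/likelihood per
#' part), three columns per body part.
#'
#' @param pose A `pose_track`.
#' @param path File path.
#' @param frame_rate Frame rate used when reading (Hz).
#' @return `read_pose` returns a `pose_track`.
#' @export
write_pose <- function(pose, path) {
  parts <- names(pose$parts)
  h1 <- paste(rep(parts, each = 3), collapse = ",")
  h2 <- paste(rep(c("x", "y", "likelihood"), length(parts)), collapse = ",")
  m <- do.call(cbind, lapply(pose$parts, as.matrix))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(h1, h2), con)
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pose
#' @export
read_pose <- function(path, frame_rate = 20) {
  h1 <- strsplit(readLines(path, n = 1L), ",")[[1]]
  m <- as.matrix(utils::read.csv(path, skip = 2, header = FALSE))
  parts <- unique(h1)
  pose <- list()
  for (i in seq_along(parts)) {
    cols <- (i - 1L) * 3L + 1:3
    pose[[parts[i]]] <- data.frame(x = m[, cols[1]], y = m[, cols[2]],
                                   likelihood = m[, cols[3]])
  }
  structure(list(parts = pose, frame_rate = frame_rate, n_frames = nrow(m)),
            class = "pose_track")
}
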