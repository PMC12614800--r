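#' Filter low-likelihood pose estimates
#'
#' Frames whose pose-estimation likelihood falls below the threshold carry
#' forward the most recent confident coordinates; leading low-likelihood
#' frames are back-filled from the first confident frame.
#'
#' @param pose A `pose_track`.
#' @param likelihood_threshold Minimum accepted likelihood (default 0.9).
#' @return A cleaned `pose_track` (likelihood column preserved).
#' @export
filter_pose <- function(pose, likelihood_threshold = 0.9) {
  stopifnot(inherits(pose, "pose_track"))
  for (part in names(pose$parts)) {
    df <- pose$parts[[part]]
    ok <- df$likelihood >= likelihood_threshold
    if (!any(ok)) stop("body part '", part, "' has no confident frames")
    idx <- cumsum(ok)          # 0 before the first confident frame
    first_ok <- which(ok)[1]
    src <- which(ok)[pmax(idx, 1L)]
    src[idx == 0L] <- first_ok # back-fill the leading run
    df$x <- df$x[src]
    df$y <- df$y[src]
    pose$parts[[part]] <- df
  }
  pose
}

#' Frame-to-frame displacement of tracked points
#'
#' Euclidean displacement per frame (pixels/frame) for the requested body
#' parts; the first frame has displacement 0.
#'
#' @param pose A `pose_track` (run [filter_pose()] first).
#' @param points Body parts (default: the five trunk points used for
#'   immobility).
#' @return Matrix frames x points.
#' @export
displacement <- function(pose, points = IMMOBILITY_POINTS) {
  stopifnot(inherits(pose, "pose_track"))
  unknown <- setdiff(points, names(pose$parts))
  if (length(unknown)) {
    stop("unknown body part(s): ", paste(unknown, collapse = ", "))
  }
  out <- vapply(points, function(part) {
    df <- pose$parts[[part]]
    c(0, sqrt(diff(df$x)^2 + diff(df$y)^2))
  }, numeric(pose$n_frames))
  colnames(out) <- points
  out
}

#' Detect immobility bouts from point displacements
#'
#' Frames on which all tracked points fall below the displacement threshold
#' form candidate runs; runs of at least `min_duration` become immobility
#' bouts. Bouts intersecting any CS presentation are flagged `overlaps_CS`
#' (they are excluded from immobility-aligned neural analysis but kept in
#' the table). The threshold calibration range mirrors per-animal tuning;
#' values outside it draw a warning, not an error.
#'
#' @param displacements Matrix frames x points from [displacement()].
#' @param threshold Displacement threshold (px/frame; calibration range
#'   0.7-3.5, default 2).
#' @param min_duration Minimum bout duration in seconds (default 2).
#' @param events Optional `event_table` used for the CS-overlap flag.
#' @param frame_rate Frames per second (default 20).
#' @return An `immobility_bouts` data frame: `start_s`, `stop_s`,
#'   `duration_s`, `overlaps_CS`; sorted, non-overlapping.
#' @export
detect_immobility <- function(displacements, threshold = 2,
                              min_duration = 2, events = NULL,
                              frame_rate = 20) {
  if (threshold < 0.7 || threshold > 3.5) {
    warning("displacement threshold ", threshold,
            " outside the calibration range [0.7, 3.5]")
  }
  quiet <- rowSums(displacements >= threshold) == 0L
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration * frame_rate
  bouts <- data.frame(
    start_s = (starts[keep] - 1L) / frame_rate,
    stop_s = ends[keep] / frame_rate
  )
  bouts$duration_s <- bouts$stop_s - bouts$start_s
  bouts$overlaps_CS <- FALSE
  if (!is.null(events) && nrow(bouts)) {
    cs <- events[events$label %in% c("CS_PLUS", "CS_MINUS"), , drop = FALSE]
    for (j in seq_len(nrow(cs))) {
      hit <- bouts$start_s < cs$offset_s[j] & bouts$stop_s > cs$onset_s[j]
      bouts$overlaps_CS[hit] <- TRUE
    }
  }
  structure(bouts, threshold = threshold, min_duration = min_duration,
            class = c("immobility_bouts", "data.frame"))
}

#' Immobility-aligned neural activity
#'
#' Aligns binned traces to the onsets and offsets of usable (non-CS)
#' immobility bouts, baseline-corrects to the 2 s preceding each event,
#' pools the listed sessions, and integrates the pooled per-cell average
#' over the 2 s following onset/offset.
#'
#' @param pop A `trace_population`.
#' @param bouts Named list (by session) of `immobility_bouts`.
#' @param sessions Sessions to pool (default `c("test_ext1", "ext2")`).
#' @param pre_window,post_window,baseline_window Alignment windows (s).
#' @param auc_window AUC integration window (s, default 2).
#' @return List with `onset`/`offset`: each has `tensor` (cells x events x
#'   bins, pooled), `mean_trace` (cells x bins), `auc` (per-cell AUC of the
#'   pooled mean trace), and `per_session_auc` (cells x sessions).
#' @export
immobility_aligned_activity <- function(pop, bouts,
                                        sessions = c("test_ext1", "ext2"),
                                        pre_window = 2, post_window = 2,
                                        baseline_window = 2,
                                        auc_window = 2) {
  stopifnot(inherits(pop, "trace_population"))
  sessions <- intersect(sessions, names(pop$sessions))
  w <- pop$bin_width
  n_pre <- as.integer(round(pre_window / w))
  n_post <- as.integer(round(post_window / w))
  n_bins <- n_pre + n_post
  time <- (seq_len(n_bins) - 1L - n_pre) * w

  slice <- function(session, times) {
    m <- pop$sessions[[session]]
    out <- list()
    for (t0 in times) {
      b0 <- as.integer(round(t0 / w))
      if (b0 - n_pre < 0L || b0 + n_post > ncol(m)) next
      snip <- m[, (b0 - n_pre + 1L):(b0 + n_post), drop = FALSE]
      base <- rowMeans(snip[, seq_len(n_pre), drop = FALSE])
      out[[length(out) + 1L]] <- snip - base
    }
    out
  }
  one_side <- function(column) {
    per_session <- lapply(sessions, function(s) {
      b <- bouts[[s]]
      usable <- b[!b$overlaps_CS, , drop = FALSE]
      slice(s, usable[[column]])
    })
    names(per_session) <- sessions
    snips <- do.call(c, per_session)
    if (length(snips) == 0L) stop("no usable immobility bouts")
    tensor <- array(NA_real_, dim = c(nrow(snips[[1]]), length(snips),
                                      n_bins))
    for (j in seq_along(snips)) tensor[, j, ] <- snips[[j]]
    dimnames(tensor) <- list(pop$cell_ids, NULL, NULL)
    tensor <- structure(tensor, time = time, bin_width = w,
                        pre_window = pre_window, post_window = post_window,
                        baseline_window = baseline_window,
                        label = paste0("immobility_", column),
                        class = "aligned_tensor")
    mean_trace <- apply(tensor, c(1L, 3L), mean)
    keep <- time >= -1e-9 & time < auc_window - 1e-9
    auc <- rowSums(mean_trace[, keep, drop = FALSE]) * w
    per_session_auc <- vapply(sessions, function(s) {
      sn <- per_session[[s]]
      if (length(sn) == 0L) return(rep(NA_real_, length(pop$cell_ids)))
      mu <- Reduce(`+`, sn) / length(sn)
      rowSums(mu[, keep, drop = FALSE]) * w
    }, numeric(length(pop$cell_ids)))
    names(auc) <- pop$cell_ids
    list(tensor = tensor, mean_trace = mean_trace, auc = auc,
         per_session_auc = per_session_auc)
  }
  list(onset = one_side("start_s"), offset = one_side("stop_s"))
}

#' Across-session stability of immobility responses
#'
#' Spearman correlations of per-cell immobility onset/offset responses
#' between session pairs, per animal, tested across animals with one-sample
#' t-tests against 0.
#'
#' @param auc_by_animal Named list (animal) of named lists (session) of
#'   per-cell response vectors (e.g. per-session immobility AUCs).
#' @param min_cells Minimum cells per animal (default 3; smaller animals
#'   are excluded with a warning).
#' @return List with `per_animal` (data frame animal, session pair, rho)
#'   and `tests` (per session pair: mean rho, t, p across animals).
#' @export
stability_across_sessions <- function(auc_by_animal, min_cells = 3L) {
  rows <- list()
  for (animal in names(auc_by_animal)) {
    aucs <- auc_by_animal[[animal]]
    n <- length(aucs[[1]])
    if (n < min_cells) {
      warning("animal ", animal, " excluded (", n, " cells)")
      next
    }
    sess <- names(aucs)
    for (i in seq_along(sess)) {
      for (j in seq_along(sess)) {
        if (j <= i) next
        rho <- stats::cor(aucs[[i]], aucs[[j]], method = "spearman",
                          use = "complete.obs")
        rows[[length(rows) + 1L]] <- data.frame(
          animal = animal, pair = paste(sess[i], sess[j], sep = ":"),
          rho = rho, stringsAsFactors = FALSE)
      }
    }
  }
  per_animal <- do.call(rbind, rows)
  tests <- NULL
  if (!is.null(per_animal)) {
    tests <- do.call(rbind, lapply(split(per_animal, per_animal$pair),
                                   function(d) {
      tt <- tryCatch(stats::t.test(d$rho),
                     error = function(e) {
                       ## fewer than 2 animals, or constant rho
                       list(statistic = NA_real_, p.value = NA_real_)
                     })
      data.frame(pair = d$pair[1], mean_rho = mean(d$rho),
                 t = unname(tt$statistic), p = tt$p.value,
                 n_animals = nrow(d), stringsAsFactors = FALSE)
    }))
    rownames(tests) <- NULL
  }
  list(per_animal = per_animal, tests = tests)
}

#' Fraction of CS time spent immobile
#'
#' @param bouts `immobility_bouts` of the session (CS-overlapping bouts
#'   included: immobility during the tone is exactly what is scored here).
#' @param events Session `event_table`.
#' @param label CS label.
#' @param trials Trial subset (default: the balanced across-day set).
#' @return Fraction in `[0, 1]`.
#' @export
immobility_fraction <- function(bouts, events, label,
                                trials = NULL) {
  day <- unique(events$day_kind)[1]
  if (is.null(trials)) trials <- across_day_trial_sets(day, label, events)
  ev <- events[events$label == label & events$trial_index %in% trials, ,
               drop = FALSE]
  tot <- sum(ev$offset_s - ev$onset_s)
  imm <- 0
  for (j in seq_len(nrow(ev))) {
    ov <- pmin(bouts$stop_s, ev$offset_s[j]) -
      pmax(bouts$start_s, ev$onset_s[j])
    imm <- imm + sum(pmax(ov, 0))
  }
  imm / tot
}

#' Behavioural discrimination score
#'
#' `DS = (Imm_CS+ - Imm_CS-) / (Imm_CS+ + Imm_CS-)`, computed from CS+ and
#' CS- immobility during the first test/extinction session; in `[-1, 1]`,
#' positive when the animal freezes more to the CS+.
#'
#' @param imm_plus,imm_minus Non-negative immobility measures (fractions or
#'   durations; the score is scale-invariant).
#' @return Numeric DS; `NA` with a warning when both inputs are 0.
#' @export
discrimination_score <- function(imm_plus, imm_minus) {
  stopifnot(all(imm_plus >= 0), all(imm_minus >= 0))
  tot <- imm_plus + imm_minus
  out <- ifelse(tot > 0, (imm_plus - imm_minus) / tot, NA_real_)
  if (anyNA(out)) warning("DS undefined: both immobility measures are 0")
  out
}

#' Correlate per-animal cluster counts with behaviour
#'
#' Spearman correlation (with p-value) between the number of cells an
#' animal contributes to each cluster and its discrimination score.
#'
#' @param counts Data frame or matrix animals x clusters of cell counts.
#' @param ds Named numeric of discrimination scores (same animals).
#' @return Data frame `cluster`, `rho`, `p` (`NA` with a warning for
#'   constant counts); requires >= 4 animals.
#' @export
correlate_counts_with_behaviour <- function(counts, ds) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 4L) stop("need at least 4 animals")
  ds <- ds[rownames(counts)]
  rows <- lapply(colnames(counts), function(cl) {
    x <- counts[, cl]
    if (stats::sd(x) < 1e-12) {
      warning("constant counts for cluster ", cl, ": correlation undefined")
      return(data.frame(cluster = cl, rho = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, ds, method = "spearman", exact = FALSE))
    data.frame(cluster = cl, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
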