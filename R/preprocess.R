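#' Construct a cross-day registered trace population
#'
#' Takes raw fluorescence traces sampled at `sampling_rate_raw` Hz (one
#' matrix of cells x samples per session, identical cell set and ordering in
#' every session), z-scores each cell over the concatenated multi-session
#' recording and mean-bins the result. z-scoring over the concatenated trace
#' mirrors an acquisition pipeline in which all session movies are
#' concatenated before trace extraction; per-session z-scoring is available
#' via `per_session = TRUE`.
#'
#' @param raw Named list of numeric matrices (cells x samples), one per
#'   session, or a single matrix for a one-session recording.
#' @param bin_width Bin width in seconds; must be a positive multiple of the
#'   sample interval (default 0.25 s).
#' @param sampling_rate_raw Raw sampling rate in Hz (default 20).
#' @param animal_id Identifier stored with the population.
#' @param cell_ids Cell identifiers (default `cell_1 ...`).
#' @param centroids Optional cells x 2 matrix of ROI centroid pixel
#'   coordinates.
#' @param per_session If `TRUE`, z-score within each session instead of over
#'   the concatenated recording.
#' @return A `trace_population`: list with elements `animal_id`, `cell_ids`,
#'   `sessions` (named list of cells x bins matrices), `bin_width`,
#'   `sampling_rate_raw`, `centroids`.
#' @export
preprocess_traces <- function(raw, bin_width = 0.25, sampling_rate_raw = 20,
                              animal_id = "animal_1", cell_ids = NULL,
                              centroids = NULL, per_session = FALSE) {
  if (is.matrix(raw)) raw <- list(session_1 = raw)
  stopifnot(is.list(raw), length(raw) >= 1L)
  if (is.null(names(raw))) names(raw) <- paste0("session_", seq_along(raw))
  n_cells <- nrow(raw[[1]])
  if (n_cells < 1L) stop("need at least one cell")
  for (s in names(raw)) {
    if (nrow(raw[[s]]) != n_cells) {
      stop("inconsistent cell counts across sessions (session ", s, ")")
    }
    if (anyNA(raw[[s]])) stop("missing values in session ", s)
  }
  dt <- 1 / sampling_rate_raw
  ratio <- bin_width / dt
  if (bin_width <= 0 || abs(ratio - round(ratio)) > 1e-9) {
    stop("bin_width must be a positive multiple of the sample interval")
  }
  ratio <- as.integer(round(ratio))

  zscore_rows <- function(m) {
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    zero_var <- sd < 1e-12
    if (any(zero_var)) {
      warning(sum(zero_var), " constant trace(s): z-score set to zero")
      sd[zero_var] <- 1
    }
    (m - mu) / sd
  }
  if (per_session) {
    z <- lapply(raw, zscore_rows)
  } else {
    concat <- do.call(cbind, raw)
    zc <- zscore_rows(concat)
    lens <- vapply(raw, ncol, integer(1))
    ends <- cumsum(lens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    z <- Map(function(a, b) zc[, a:b, drop = FALSE], starts, ends)
    names(z) <- names(raw)
  }
  sessions <- lapply(z, function(m) bin_matrix(m, ratio))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n_cells))
  for (s in names(sessions)) rownames(sessions[[s]]) <- cell_ids
  structure(
    list(animal_id = animal_id, cell_ids = cell_ids, sessions = sessions,
         bin_width = bin_width, sampling_rate_raw = sampling_rate_raw,
         centroids = centroids),
    class = "trace_population"
  )
}

## Mean-bin the columns of a matrix in non-overlapping groups of `ratio`;
## a trailing partial bin is dropped (floor(samples / ratio) bins out).
bin_matrix <- function(m, ratio) {
  if (ratio == 1L) return(m)
  n_bins <- ncol(m) %/% ratio
  if (n_bins < 1L) stop("fewer samples than one bin")
  acc <- Reduce(`+`, lapply(0:(ratio - 1L), function(o) {
    m[, seq(1L + o, by = ratio, length.out = n_bins), drop = FALSE]
  }))
  acc / ratio
}

#' @export
print.trace_population <- function(x, ...) {
  cat(sprintf(
    "<trace_population> animal %s: %d cells, %d session(s), %.3g s bins\n",
    x$animal_id, length(x$cell_ids), length(x$sessions), x$bin_width))
  for (s in names(x$sessions)) {
    cat(sprintf("  %s: %d bins (%.1f s)\n", s, ncol(x$sessions[[s]]),
                ncol(x$sessions[[s]]) * x$bin_width))
  }
  invisible(x)
}

#' Align binned traces to stimulus events and baseline-correct
#'
#' Cuts per-trial snippets spanning `pre_window` s before to `post_window` s
#' after each event onset and subtracts, per cell and trial, the mean over
#' the `baseline_window` s immediately preceding onset. Time is half-open:
#' bin `b` covers `[b*w, (b+1)*w)` and the event onset is snapped to the
#' nearest bin edge. Trials whose window falls outside the recording are
#' dropped with a warning.
#'
#' @param pop A `trace_population`.
#' @param events An `event_table` for the session being aligned.
#' @param label Event label to align to (`"CS_PLUS"`, `"CS_MINUS"`, `"US"`).
#' @param session Name of the session in `pop$sessions` (defaults to the
#'   day kind of `events`).
#' @param pre_window,post_window Window extent in seconds around onset.
#' @param baseline_window Baseline extent in seconds (must be <=
#'   `pre_window`).
#' @param trials Optional 1-based trial subset (by `trial_index`).
#' @return An `aligned_tensor`: 3-D array cells x trials x bins with
#'   attributes `time` (bin start times relative to onset), `label`,
#'   `bin_width`, `pre_window`, `post_window`, `baseline_window`,
#'   `dropped_trials`.
#' @export
align_to_events <- function(pop, events, label, session = NULL,
                            pre_window = 30, post_window = 30,
                            baseline_window = pre_window, trials = NULL) {
  stopifnot(inherits(pop, "trace_population"))
  if (baseline_window > pre_window + 1e-9) {
    stop("baseline_window must be <= pre_window")
  }
  if (is.null(session)) session <- unique(events$day_kind)[1]
  if (!session %in% names(pop$sessions)) {
    stop("session '", session, "' not found in trace population")
  }
  m <- pop$sessions[[session]]
  w <- pop$bin_width
  ev <- events[events$label == label, , drop = FALSE]
  if (!is.null(trials)) ev <- ev[ev$trial_index %in% trials, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events with label ", label)

  n_pre <- as.integer(round(pre_window / w))
  n_post <- as.integer(round(post_window / w))
  n_base <- as.integer(round(baseline_window / w))
  if (n_base < 1L) stop("baseline_window shorter than one bin")
  onset_bin <- as.integer(round(ev$onset_s / w))  # 0-based bin of onset
  ok <- onset_bin - n_pre >= 0L & onset_bin + n_post <= ncol(m)
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) with out-of-range windows dropped")
    ev <- ev[ok, , drop = FALSE]
    onset_bin <- onset_bin[ok]
  }
  if (nrow(ev) == 0L) stop("no in-range events with label ", label)

  n_bins <- n_pre + n_post
  out <- array(NA_real_, dim = c(nrow(m), nrow(ev), n_bins))
  for (j in seq_len(nrow(ev))) {
    cols <- (onset_bin[j] - n_pre + 1L):(onset_bin[j] + n_post)
    snip <- m[, cols, drop = FALSE]
    base <- rowMeans(snip[, (n_pre - n_base + 1L):n_pre, drop = FALSE])
    out[, j, ] <- snip - base
  }
  dimnames(out) <- list(pop$cell_ids, NULL, NULL)
  structure(out,
            time = (seq_len(n_bins) - 1L - n_pre) * w,
            label = label, bin_width = w, pre_window = pre_window,
            post_window = post_window, baseline_window = baseline_window,
            trial_index = ev$trial_index,
            dropped_trials = sum(!ok),
            class = "aligned_tensor")
}

#' Area under the curve of aligned responses
#'
#' Integrates the baselined response of each cell and trial over
#' `[0, window)` s after event onset. Binned traces are step functions, so
#' the integral is the exact bin sum times the bin width; a unit-amplitude
#' rectangular response of duration `d` inside the window has AUC `d`.
#'
#' @param tensor An `aligned_tensor`.
#' @param window Integration window in seconds from event onset (CS: 30;
#'   US: 5; immobility: 2).
#' @return An `auc_table`: matrix cells x trials with attribute `window_s`.
#' @export
compute_auc <- function(tensor, window) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  time <- attr(tensor, "time")
  w <- attr(tensor, "bin_width")
  if (window > attr(tensor, "post_window") + 1e-9) {
    stop("window exceeds the post-event extent of the tensor")
  }
  keep <- time >= -1e-9 & time < window - 1e-9
  auc <- apply(tensor[, , keep, drop = FALSE], c(1L, 2L), sum) * w
  structure(auc, window_s = window, class = c("auc_table", class(auc)))
}

#' Mean trace with s.e.m. over cells and/or trials
#'
#' @param tensor An `aligned_tensor`.
#' @param over Axis collapsed: `"cells"`, `"trials"` or `"both"`.
#' @return List with `mean` and `sem` (s.e.m. uses the n-1 denominator;
#'   undefined for a single observation and returned as `NA` with a
#'   warning), plus the `time` axis.
#' @export
summarize_traces <- function(tensor, over = c("trials", "cells", "both")) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  over <- match.arg(over)
  d <- dim(tensor)
  if (any(d == 0L)) stop("empty tensor axis")
  margin <- switch(over, cells = c(2L, 3L), trials = c(1L, 3L), both = 3L)
  n <- switch(over, cells = d[1], trials = d[2], both = d[1] * d[2])
  mu <- apply(tensor, margin, mean)
  if (n < 2L) {
    warning("s.e.m. undefined for a single observation")
    sem <- array(NA_real_, dim = dim(as.array(mu)))
  } else {
    sem <- apply(tensor, margin, stats::sd) / sqrt(n)
  }
  list(mean = mu, sem = sem, time = attr(tensor, "time"), n = n)
}

## Re-bin an already binned cells x bins matrix to a coarser bin width.
rebin_matrix <- function(m, bin_width, new_width) {
  ratio <- new_width / bin_width
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("new_width must be a multiple of bin_width")
  }
  bin_matrix(m, as.integer(round(ratio)))
}
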