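#' Mean US reference population vector
#'
#' Per-cell mean of the baselined US response over `[0, window)` s,
#' averaged across US presentations; the reference point of all
#' population-vector-distance (PVD) computations.
#'
#' @param us_tensor An `aligned_tensor` of US responses.
#' @param window Averaging window in seconds (default 5).
#' @param cells Optional cell subset.
#' @return Named numeric vector of length n_cells.
#' @export
us_reference_vector <- function(us_tensor, window = 5, cells = NULL) {
  stopifnot(inherits(us_tensor, "aligned_tensor"))
  if (dim(us_tensor)[2] < 1L) stop("empty US tensor")
  time <- attr(us_tensor, "time")
  keep <- time >= -1e-9 & time < window - 1e-9
  v <- apply(us_tensor[, , keep, drop = FALSE], 1L, mean)
  names(v) <- dimnames(us_tensor)[[1]]
  if (!is.null(cells)) v <- v[cells]
  v
}

#' Population vector distance per CS presentation
#'
#' The CS response over `[0, 30)` s is read out at the analysis bin width;
#' for each bin the population vector (length n cells) is compared to the
#' mean US vector by Euclidean distance, and distances are averaged over
#' bins within each presentation. `mode = "mean_vector"` instead collapses
#' each presentation to a single 30 s mean vector before distancing.
#'
#' @param cs_tensor An `aligned_tensor` of CS responses.
#' @param us_vector Reference vector from [us_reference_vector()] (cell
#'   sets must match).
#' @param window CS readout window (s).
#' @param mode `"per_bin"` (default) or `"mean_vector"`.
#' @return Numeric vector of distances, one per CS presentation.
#' @export
pvd_per_presentation <- function(cs_tensor, us_vector, window = 30,
                                 mode = c("per_bin", "mean_vector")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cs_tensor, "aligned_tensor"))
  if (dim(cs_tensor)[1] != length(us_vector)) {
    stop("cell sets of CS tensor and US vector do not match")
  }
  ids <- dimnames(cs_tensor)[[1]]
  if (!is.null(ids) && !is.null(names(us_vector)) &&
      !identical(ids, names(us_vector))) {
    stop("cell ordering of CS tensor and US vector do not match")
  }
  time <- attr(cs_tensor, "time")
  keep <- which(time >= -1e-9 & time < window - 1e-9)
  vapply(seq_len(dim(cs_tensor)[2]), function(j) {
    snip <- matrix(cs_tensor[, j, keep], nrow = dim(cs_tensor)[1])
    if (mode == "mean_vector") {
      sqrt(sum((rowMeans(snip) - us_vector)^2))
    } else {
      mean(sqrt(colSums((snip - us_vector)^2)))
    }
  }, numeric(1))
}

#' PVD change across the conditioning session
#'
#' Distances per CS presentation are normalised to the first CS/US pairing:
#' change_t = 100 * (d_t - d_1) / d_1 percent, so negative values mean the
#' CS representation moved toward the US. Early is the mean over pairings
#' 1-2, late over pairings 4-5.
#'
#' @param cs_tensor,us_tensor `aligned_tensor`s from the conditioning
#'   session (5 CS presentations expected).
#' @param us_window,cs_window Readout windows (s).
#' @param mode Passed to [pvd_per_presentation()].
#' @param ablation Tag recorded with the result (default `"All cells"`).
#' @return A `pvd_result` data frame: `presentation`, `distance`,
#'   `change_pct`; attributes `early_change`, `late_change`,
#'   `early_late_diff`, `ablation`.
#' @export
pvd_conditioning <- function(cs_tensor, us_tensor, us_window = 5,
                             cs_window = 30, mode = "per_bin",
                             ablation = "All cells") {
  us_vec <- us_reference_vector(us_tensor, window = us_window)
  d <- pvd_per_presentation(cs_tensor, us_vec, window = cs_window,
                            mode = mode)
  if (d[1] < 1e-12) stop("degenerate reference: first-pairing PVD is 0")
  change <- 100 * (d - d[1]) / d[1]
  early <- mean(change[1:2])
  late <- mean(change[4:min(5, length(change))])
  out <- data.frame(presentation = seq_along(d), distance = d,
                    change_pct = change)
  structure(out, early_change = early, late_change = late,
            early_late_diff = late - early, ablation = ablation,
            class = c("pvd_result", "data.frame"))
}

#' PVD change under cluster-removal ablations
#'
#' Re-runs [pvd_conditioning()] on the complement of each removal set (plus
#' the untouched population, tagged `"All cells"`), reporting the early
#' (pairings 1-2) vs late (pairings 4-5) change per ablation.
#'
#' @param cs_tensor,us_tensor Conditioning tensors.
#' @param removals Named list of cell-id (or index) vectors to remove, e.g.
#'   cluster memberships.
#' @param ... Passed to [pvd_conditioning()].
#' @return Data frame `ablation`, `n_removed`, `n_kept`, `early_change`,
#'   `late_change`, `early_late_diff`.
#' @export
pvd_ablation <- function(cs_tensor, us_tensor, removals, ...) {
  ids <- dimnames(cs_tensor)[[1]]
  run_one <- function(keep_idx, tag, n_removed) {
    if (length(keep_idx) < 2L) {
      stop("ablation '", tag, "' leaves fewer than 2 cells")
    }
    cs <- cs_tensor[keep_idx, , , drop = FALSE]
    us <- us_tensor[keep_idx, , , drop = FALSE]
    for (a in c("time", "bin_width", "pre_window", "post_window",
                "baseline_window", "label")) {
      attr(cs, a) <- attr(cs_tensor, a)
      attr(us, a) <- attr(us_tensor, a)
    }
    class(cs) <- class(us) <- "aligned_tensor"
    res <- pvd_conditioning(cs, us, ablation = tag, ...)
    data.frame(ablation = tag, n_removed = n_removed,
               n_kept = length(keep_idx),
               early_change = attr(res, "early_change"),
               late_change = attr(res, "late_change"),
               early_late_diff = attr(res, "early_late_diff"),
               stringsAsFactors = FALSE)
  }
  all_idx <- seq_len(dim(cs_tensor)[1])
  rows <- list(run_one(all_idx, "All cells", 0L))
  for (tag in names(removals)) {
    rem <- removals[[tag]]
    rem_idx <- if (is.character(rem)) match(rem, ids) else rem
    if (anyNA(rem_idx) || !all(rem_idx %in% all_idx)) {
      stop("removal set '", tag, "' is not a subset of the cell set")
    }
    rows[[tag]] <- run_one(setdiff(all_idx, rem_idx), tag, length(rem_idx))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Across-day PVD normalised to habituation
#'
#' Per day, the mean distance of the first four CS presentations to the
#' conditioning-day US reference vector; changes are expressed relative to
#' the habituation-day distance.
#'
#' @param cs_tensors Named list of `aligned_tensor`s, one per day, each
#'   restricted to the presentations entering the comparison (typically the
#'   first four, see [across_day_trial_sets()]); must include
#'   `"habituation"`.
#' @param us_vector Conditioning-day US reference vector.
#' @param ... Passed to [pvd_per_presentation()].
#' @return Data frame `day`, `distance`, `change_pct` (0 for habituation).
#' @export
pvd_across_days <- function(cs_tensors, us_vector, ...) {
  if (!"habituation" %in% names(cs_tensors)) {
    stop("cs_tensors must include the habituation day")
  }
  d <- vapply(cs_tensors, function(tn) {
    mean(pvd_per_presentation(tn, us_vector, ...))
  }, numeric(1))
  if (d[["habituation"]] < 1e-12) stop("degenerate habituation distance 0")
  data.frame(day = names(cs_tensors), distance = unname(d),
             change_pct = unname(100 * (d - d[["habituation"]]) /
                                   d[["habituation"]]),
             stringsAsFactors = FALSE, row.names = NULL)
}
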