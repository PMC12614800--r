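#' Per-trial rank-sum test of evoked vs baseline activity
#'
#' For each cell and trial, compares the binned fluorescence during the
#' baseline window (bins before onset, up to `baseline_window`) against the
#' evoked window (`[0, evoked_window)` after onset) with the two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction; the
#' 120-bin CS windows make exact enumeration unnecessary). The response sign
#' is the sign of (mean evoked - mean baseline).
#'
#' @param tensor An `aligned_tensor` (baselined snippets).
#' @param evoked_window Evoked extent in seconds from onset (CS: 30, US: 2).
#' @param alpha Significance level recorded with the result (default 0.01).
#' @return List of matrices `p` and `sign` (cells x trials), plus `alpha`.
#' @export
trial_response_test <- function(tensor, evoked_window = 30, alpha = 0.01) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  time <- attr(tensor, "time")
  base_idx <- which(time < -1e-9 &
                      time >= -attr(tensor, "baseline_window") - 1e-9)
  ev_idx <- which(time >= -1e-9 & time < evoked_window - 1e-9)
  if (length(base_idx) < 2L || length(ev_idx) < 2L) {
    stop("need at least 2 bins in both baseline and evoked windows")
  }
  d <- dim(tensor)
  p <- sgn <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[2])) {
    e <- matrix(tensor[, j, ev_idx], nrow = d[1])
    b <- matrix(tensor[, j, base_idx], nrow = d[1])
    p[, j] <- ranksum_rows(e, b)
    sgn[, j] <- sign(rowMeans(e) - rowMeans(b))
  }
  rownames(p) <- rownames(sgn) <- dimnames(tensor)[[1]]
  list(p = p, sign = sgn, alpha = alpha)
}

## Row-wise two-sided Wilcoxon rank-sum p-values, normal approximation with
## tie and continuity corrections; numerically identical to
## stats::wilcox.test(x, y, exact = FALSE) but vectorised over cells, which
## matters when screening tens of thousands of cells.
ranksum_rows <- function(x, y) {
  nx <- ncol(x)
  ny <- ncol(y)
  n <- nx + ny
  comb <- cbind(x, y)
  vapply(seq_len(nrow(comb)), function(i) {
    rk <- rank(comb[i, ])
    stat <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
    tie_term <- 0
    if (anyDuplicated(rk)) {
      t_counts <- table(rk)
      tie_term <- sum(t_counts^3 - t_counts) / (n * (n - 1))
    }
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(1)
    z <- stat - nx * ny / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    min(1, 2 * stats::pnorm(-abs(z)))
  }, numeric(1))
}

#' Classify cells as responsive with a direction
#'
#' A cell is responsive to a stimulus when it shows significant per-trial
#' responses (p < `alpha`) on at least `min_significant` presentations. The
#' direction is the majority sign among the significant trials; an exact
#' tie is broken by the sign of the mean per-trial AUC (when supplied) and
#' logged with a message.
#'
#' @param test Result of [trial_response_test()] (or a list with `p`,
#'   `sign`).
#' @param alpha Per-trial significance level (default 0.01).
#' @param min_significant Minimum number of significant trials (default 3).
#' @param auc Optional `auc_table` used to break direction ties.
#' @return A `response_classification` data frame: one row per cell with
#'   `cell_id`, `n_significant`, `responsive`, `direction`
#'   (activated/inhibited/none), and attributes `alpha`, `min_significant`,
#'   `p` and `sign` matrices.
#' @export
classify_cells <- function(test, alpha = 0.01, min_significant = 3,
                           auc = NULL) {
  p <- test$p
  sgn <- test$sign
  if (min_significant > ncol(p)) {
    stop("min_significant exceeds the number of trials")
  }
  sig <- p < alpha
  n_sig <- rowSums(sig)
  responsive <- n_sig >= min_significant
  direction <- rep("none", nrow(p))
  ties <- 0L
  for (i in which(responsive)) {
    s <- sgn[i, sig[i, ]]
    bal <- sum(s > 0) - sum(s < 0)
    if (bal > 0) {
      direction[i] <- "activated"
    } else if (bal < 0) {
      direction[i] <- "inhibited"
    } else {
      ties <- ties + 1L
      tie_sign <- if (!is.null(auc)) sign(mean(auc[i, ])) else 1
      direction[i] <- if (tie_sign >= 0) "activated" else "inhibited"
    }
  }
  if (ties > 0L) message(ties, " direction tie(s) broken by mean AUC sign")
  cell_id <- rownames(p)
  if (is.null(cell_id)) cell_id <- paste0("cell_", seq_len(nrow(p)))
  out <- data.frame(cell_id = cell_id, n_significant = n_sig,
                    responsive = responsive, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, alpha = alpha, min_significant = min_significant,
            p = p, sign = sgn,
            class = c("response_classification", "data.frame"))
}

#' Fractions of responsive cells per stimulus
#'
#' @param classifications Named list of `response_classification` objects,
#'   one per stimulus (for `group_by = "animal"`, a list of such lists, one
#'   per animal).
#' @param group_by `"population"` (pooled) or `"animal"`.
#' @return Data frame with columns `group`, `stimulus`, `fraction_responsive`,
#'   `fraction_activated`, `fraction_inhibited`, `n_cells`.
#' @export
responsive_fractions <- function(classifications,
                                 group_by = c("population", "animal")) {
  group_by <- match.arg(group_by)
  one <- function(cls, group) {
    rows <- lapply(names(cls), function(stim) {
      cl <- cls[[stim]]
      if (nrow(cl) == 0L) stop("empty classification group")
      data.frame(group = group, stimulus = stim,
                 fraction_responsive = mean(cl$responsive),
                 fraction_activated = mean(cl$direction == "activated"),
                 fraction_inhibited = mean(cl$direction == "inhibited"),
                 n_cells = nrow(cl), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  if (group_by == "population") {
    one(classifications, "population")
  } else {
    do.call(rbind, Map(one, classifications, names(classifications)))
  }
}

## The seven responsiveness combinations of three stimuli.
OVERLAP_COMBOS <- c("CS+ only", "CS- only", "US only", "CS+/CS-", "CS+/US",
                    "CS-/US", "CS+/CS-/US")

#' Observed and chance overlap of stimulus responsiveness
#'
#' Observed fractions of cells in each combination of CS+/CS-/US
#' responsiveness. The chance level for a combination is the independence
#' product of the marginal responsive fractions (times the complement for
#' excluded stimuli), computed per animal.
#'
#' @param cs_plus,cs_minus,us `response_classification` objects on the same
#'   cell set.
#' @return Data frame with one row per combination: `combination`,
#'   `observed`, `chance`; attribute `fraction_nonresponsive`.
#' @export
overlap_with_chance <- function(cs_plus, cs_minus, us) {
  if (!(identical(cs_plus$cell_id, cs_minus$cell_id) &&
        identical(cs_plus$cell_id, us$cell_id))) {
    stop("classifications must cover the same cells in the same order")
  }
  r <- cbind(cs_plus$responsive, cs_minus$responsive, us$responsive)
  membership <- list(
    "CS+ only"   = c(TRUE, FALSE, FALSE),
    "CS- only"   = c(FALSE, TRUE, FALSE),
    "US only"    = c(FALSE, FALSE, TRUE),
    "CS+/CS-"    = c(TRUE, TRUE, FALSE),
    "CS+/US"     = c(TRUE, FALSE, TRUE),
    "CS-/US"     = c(FALSE, TRUE, TRUE),
    "CS+/CS-/US" = c(TRUE, TRUE, TRUE)
  )
  marg <- colMeans(r)
  rows <- lapply(OVERLAP_COMBOS, function(combo) {
    pat <- membership[[combo]]
    obs <- mean(apply(r, 1L, function(x) all(x == pat)))
    chance <- prod(ifelse(pat, marg, 1 - marg))
    data.frame(combination = combo, observed = obs, chance = chance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out,
            fraction_nonresponsive = mean(rowSums(r) == 0),
            class = c("overlap_summary", "data.frame"))
}

#' Within-group spatial distance distribution of responsive cells
#'
#' For each cell of a group, the mean Euclidean pixel distance to all other
#' cells of the same group, plus the empirical CDF per group. Singleton
#' groups are excluded with a warning.
#'
#' @param centroids Cells x 2 matrix of ROI centroids (pixels), with cell
#'   ids as row names where available.
#' @param groups Character/factor of group labels per cell (`NA` = not in
#'   any group).
#' @return Data frame `cell`, `group`, `mean_distance`, with attribute
#'   `ecdf`: named list of [stats::ecdf()] functions per group.
#' @export
spatial_distance_distribution <- function(centroids, groups) {
  stopifnot(nrow(centroids) == length(groups))
  groups <- as.character(groups)
  keep_groups <- names(which(table(groups[!is.na(groups)]) >= 2))
  dropped <- setdiff(unique(groups[!is.na(groups)]), keep_groups)
  if (length(dropped)) {
    warning("singleton group(s) excluded: ", paste(dropped, collapse = ", "))
  }
  rows <- list()
  for (g in keep_groups) {
    idx <- which(groups == g)
    d <- as.matrix(stats::dist(centroids[idx, , drop = FALSE]))
    mean_d <- rowSums(d) / (length(idx) - 1L)
    cell <- rownames(centroids)[idx]
    if (is.null(cell)) cell <- as.character(idx)
    rows[[g]] <- data.frame(cell = cell, group = g, mean_distance = mean_d,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ecdf") <- lapply(split(out$mean_distance, out$group), stats::ecdf)
  out
}

#' Export a response classification as TSV
#'
#' One row per cell: `cell_id`, per-trial p-values `p1..pn`, `responsive`,
#' `direction`.
#'
#' @param classification A `response_classification`.
#' @param path Output path.
#' @param stimulus Stimulus label stored in the file.
#' @export
write_classification <- function(classification, path, stimulus = "CS_PLUS") {
  p <- attr(classification, "p")
  colnames(p) <- paste0("p", seq_len(ncol(p)))
  out <- cbind(data.frame(cell_id = classification$cell_id,
                          stimulus = stimulus, stringsAsFactors = FALSE),
               as.data.frame(round(p, 10)),
               classification[c("responsive", "direction")])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
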