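DECODER_CLASSES <- c("BASELINE", "CS_PLUS", "CS_MINUS")

#' Build a class-balanced decoder dataset from one session
#'
#' One sample per 1 s bin of a 30 s window; features are a random subsample
#' of `n_cells` cells (37 by default, the minimum population size across
#' animals in the emulated study). Each CS presentation contributes a
#' 30-sample block; BASELINE blocks are the 30 s windows immediately
#' preceding CS onsets, drawn (without replacement) to match the per-class
#' block count so class counts are exactly equal.
#'
#' @param pop A `trace_population`.
#' @param events `event_table` of the session.
#' @param session Session name in `pop$sessions` (default: day kind).
#' @param classes Classes to include (subset of BASELINE/CS_PLUS/CS_MINUS).
#' @param n_cells Cell subsample size (default 37); `NULL` uses all cells.
#' @param cells Explicit cell subset (overrides the random subsample).
#' @param cs_trials Named list of trial subsets per CS label (default: the
#'   balanced across-day sets on test/extinction days, all trials
#'   otherwise).
#' @param sample_bin 1 s decoding bin width.
#' @param window_s Block window length (30 s).
#' @param seed Seed for the cell subsample and baseline block draw.
#' @return A `decoder_dataset`: list with `x` (samples x cells), `y`
#'   (factor), `block` (block id per sample), `cells`, `animal_id`, `day`,
#'   `seed`.
#' @export
build_dataset <- function(pop, events, session = NULL,
                          classes = DECODER_CLASSES, n_cells = 37L,
                          cells = NULL, cs_trials = NULL, sample_bin = 1,
                          window_s = 30, seed = 1L) {
  stopifnot(inherits(pop, "trace_population"))
  classes <- match.arg(classes, DECODER_CLASSES, several.ok = TRUE)
  day <- unique(events$day_kind)[1]
  if (is.null(session)) session <- day
  m <- pop$sessions[[session]]
  if (is.null(m)) stop("session '", session, "' not found")
  m1 <- rebin_matrix(m, pop$bin_width, sample_bin)

  set.seed(seed)
  if (is.null(cells)) {
    if (is.null(n_cells)) {
      cells <- seq_len(nrow(m1))
    } else {
      if (nrow(m1) < n_cells) {
        stop("animal ", pop$animal_id, " has only ", nrow(m1),
             " cells; need ", n_cells)
      }
      cells <- sort(sample(seq_len(nrow(m1)), n_cells))
    }
  } else if (is.character(cells)) {
    cells <- match(cells, pop$cell_ids)
    if (anyNA(cells)) stop("unknown cell ids for animal ", pop$animal_id)
  }

  n_win <- as.integer(window_s / sample_bin)
  block_of <- function(onset_s) {
    b0 <- as.integer(round(onset_s / sample_bin))
    if (b0 < 0L || b0 + n_win > ncol(m1)) return(NULL)
    t(m1[cells, (b0 + 1L):(b0 + n_win), drop = FALSE])
  }

  cs_labels <- intersect(classes, c("CS_PLUS", "CS_MINUS"))
  if (is.null(cs_trials)) {
    cs_trials <- lapply(stats::setNames(nm = cs_labels), function(lab) {
      if (day %in% c("test_ext1", "ext2")) {
        across_day_trial_sets(day, lab, events)
      } else {
        sort(events$trial_index[events$label == lab])
      }
    })
  }
  xs <- list(); ys <- character(0); blocks <- integer(0); bid <- 0L
  n_blocks_cs <- integer(0)
  for (lab in cs_labels) {
    ev <- events[events$label == lab &
                   events$trial_index %in% cs_trials[[lab]], , drop = FALSE]
    n_blocks_cs[lab] <- nrow(ev)
    for (j in seq_len(nrow(ev))) {
      blk <- block_of(ev$onset_s[j])
      if (is.null(blk)) stop("CS window out of session range")
      bid <- bid + 1L
      xs[[bid]] <- blk
      ys <- c(ys, rep(lab, n_win))
      blocks <- c(blocks, rep(bid, n_win))
    }
  }
  if ("BASELINE" %in% classes) {
    need <- if (length(n_blocks_cs)) max(n_blocks_cs) else 1L
    cs_all <- events[events$label %in% c("CS_PLUS", "CS_MINUS"), ,
                     drop = FALSE]
    cand <- cs_all$onset_s - window_s
    cand <- cand[cand >= 0]
    if (length(cand) < need) stop("not enough pre-CS baseline epochs")
    use <- sort(sample(seq_along(cand), need))
    for (onset in cand[use]) {
      blk <- block_of(onset)
      bid <- bid + 1L
      xs[[bid]] <- blk
      ys <- c(ys, rep("BASELINE", n_win))
      blocks <- c(blocks, rep(bid, n_win))
    }
  }
  x <- do.call(rbind, xs)
  colnames(x) <- pop$cell_ids[cells]
  structure(list(x = x, y = factor(ys, levels = classes), block = blocks,
                 cells = pop$cell_ids[cells], animal_id = pop$animal_id,
                 day = day, seed = seed),
            class = "decoder_dataset")
}

#' Confusion-matrix metrics
#'
#' Accuracy (trace over total), and per-class precision, recall and F1
#' (`2 * precision * recall / (precision + recall)`).
#'
#' @param confusion Square confusion matrix (rows = truth, columns =
#'   prediction).
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `confusion`.
#' @export
decoder_metrics <- function(confusion) {
  stopifnot(nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  precision <- tp / pmax(colSums(confusion), 1e-300)
  recall <- tp / pmax(rowSums(confusion), 1e-300)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = sum(tp) / sum(confusion), precision = precision,
       recall = recall, f1 = f1, confusion = confusion)
}

## Stratified fold assignment: within each class, samples are dealt around
## the folds so every fold sees every class.
stratified_folds <- function(y, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds) stop("fewer than ", folds,
                                  " samples in class ", cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Cross-validated multiclass linear-SVM decoding
#'
#' One-vs-one linear SVMs with majority vote (regularisation C = 1, no
#' additional feature rescaling: traces are already z-scored), validated by
#' stratified k-fold cross-validation; held-out predictions are pooled into
#' a single confusion matrix.
#'
#' @param dataset A `decoder_dataset`.
#' @param folds Number of CV folds (default 10).
#' @param cost SVM regularisation parameter.
#' @param seed Seed for the fold assignment.
#' @return A `decoder_result`: [decoder_metrics()] list plus `folds` and
#'   `n_samples`.
#' @export
crossval_multiclass <- function(dataset, folds = 10L, cost = 1, seed = 1L) {
  y <- droplevels(dataset$y)
  if (nlevels(y) < 2L) stop("dataset has a single class")
  x <- dataset$x
  fold <- stratified_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    test <- fold == f
    fit <- e1071::svm(x[!test, , drop = FALSE], y[!test],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred[test] <- stats::predict(fit, x[test, , drop = FALSE])
  }
  confusion <- table(truth = y, prediction = pred)
  out <- decoder_metrics(unclass(confusion))
  out$folds <- folds
  out$n_samples <- length(y)
  class(out) <- "decoder_result"
  out
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result> accuracy %.3f over %d samples\n",
              x$accuracy, sum(x$confusion)))
  invisible(x)
}

#' Shuffled-label chance control
#'
#' Repeats the cross-validated decoding with labels randomly permuted
#' across samples (class balance preserved by construction).
#'
#' @param dataset A `decoder_dataset`.
#' @param n_shuffles Number of shuffles (>= 1).
#' @param folds,cost As in [crossval_multiclass()].
#' @param seed Seed.
#' @return Numeric vector of shuffled CV accuracies.
#' @export
shuffled_label_control <- function(dataset, n_shuffles = 100L, folds = 10L,
                                   cost = 1, seed = 1L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  set.seed(seed)
  vapply(seq_len(n_shuffles), function(i) {
    ds <- dataset
    ds$y <- sample(ds$y)
    crossval_multiclass(ds, folds = folds, cost = cost,
                        seed = seed + i)$accuracy
  }, numeric(1))
}

#' Cell subsets for decoder controls
#'
#' `responsive_only` / `nonresponsive_only` restrict to cells classified as
#' CS-responsive (to either CS) or not; `random_size_matched` draws a
#' random subset of all cells matching the non-responsive count, the
#' control for cell-number effects.
#'
#' @param classifications Named list with `response_classification`s for
#'   `CS_PLUS` and `CS_MINUS` (same cells).
#' @param mode Subset rule.
#' @param seed Seed for the size-matched draw.
#' @return Character vector of cell ids.
#' @export
subset_cells <- function(classifications,
                         mode = c("responsive_only", "nonresponsive_only",
                                  "random_size_matched"),
                         seed = 1L) {
  mode <- match.arg(mode)
  resp <- classifications$CS_PLUS$responsive |
    classifications$CS_MINUS$responsive
  ids <- classifications$CS_PLUS$cell_id
  out <- switch(mode,
    responsive_only = ids[resp],
    nonresponsive_only = ids[!resp],
    random_size_matched = {
      set.seed(seed)
      sample(ids, sum(!resp))
    }
  )
  if (length(out) < 2L) stop("cell subset '", mode, "' has fewer than 2 cells")
  out
}

#' Train a two-way linear SVM and extract per-cell weights
#'
#' Fits a linear SVM on all samples of a two-class dataset (e.g. baseline
#' vs CS+) and exposes the primal weight vector `w = t(coefs) %*% SV`;
#' absolute weights index each cell's contribution to the decision.
#'
#' @param dataset A `decoder_dataset` restricted to exactly two classes.
#' @param cost SVM regularisation parameter.
#' @return A `twoway_decoder`: list with `model`, `weights` (signed, named
#'   by cell), `abs_weights`, `classes`, `cells`.
#' @export
train_twoway <- function(dataset, cost = 1) {
  y <- droplevels(dataset$y)
  if (nlevels(y) != 2L) stop("two-way decoder requires exactly 2 classes")
  fit <- e1071::svm(dataset$x, y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  names(w) <- colnames(dataset$x)
  structure(list(model = fit, weights = w, abs_weights = abs(w),
                 classes = levels(y), cells = dataset$cells),
            class = "twoway_decoder")
}

#' Evaluate a trained decoder on another day's dataset
#'
#' Applies a fitted two-way (or multiclass) model to a dataset from a
#' different session without retraining; the feature cell subsample must be
#' identical (guaranteed by cross-day registration).
#'
#' @param decoder A `twoway_decoder` (or anything with `$model`, `$cells`).
#' @param dataset Target `decoder_dataset`.
#' @return A `decoder_result` on the target samples.
#' @export
cross_day_evaluate <- function(decoder, dataset) {
  if (!identical(decoder$cells, dataset$cells)) {
    stop("feature cells of model and dataset do not match")
  }
  y <- droplevels(dataset$y)
  pred <- stats::predict(decoder$model, dataset$x)
  pred <- factor(as.character(pred), levels = levels(y))
  confusion <- table(truth = y, prediction = pred)
  out <- decoder_metrics(unclass(confusion))
  out$folds <- NA_integer_
  out$n_samples <- length(y)
  class(out) <- "decoder_result"
  out
}

#' Correlation of absolute CS+ and CS- decoding weights
#'
#' Per iteration, draws a fresh cell subsample, trains baseline-vs-CS+ and
#' baseline-vs-CS- two-way decoders, and correlates the absolute weights;
#' negative correlations indicate stimulus-selective cells, near-zero
#' broad tuning.
#'
#' @param pop A `trace_population`.
#' @param events Session `event_table`.
#' @param session Session name (default: day kind of `events`).
#' @param n_iterations Number of subsample iterations (default 100).
#' @param n_cells Cell subsample size.
#' @param method Correlation type (`"pearson"` default; `"spearman"`
#'   available).
#' @param seed Seed; per-iteration seeds are spawned from it.
#' @return List with `correlations` (per iteration), `mean_correlation`,
#'   `animal_id`.
#' @export
weight_selectivity <- function(pop, events, session = NULL,
                               n_iterations = 100L, n_cells = 37L,
                               method = c("pearson", "spearman"),
                               seed = 1L) {
  method <- match.arg(method)
  cors <- vapply(seq_len(n_iterations), function(i) {
    it_seed <- seed + i
    dsp <- build_dataset(pop, events, session = session,
                         classes = c("BASELINE", "CS_PLUS"),
                         n_cells = n_cells, seed = it_seed)
    dsm <- build_dataset(pop, events, session = session,
                         classes = c("BASELINE", "CS_MINUS"),
                         n_cells = n_cells, seed = it_seed)
    wp <- train_twoway(dsp)$abs_weights
    wm <- train_twoway(dsm)$abs_weights
    if (stats::sd(wp) < 1e-12 || stats::sd(wm) < 1e-12) {
      warning("constant weight vector: correlation undefined")
      return(NA_real_)
    }
    stats::cor(wp, wm, method = method)
  }, numeric(1))
  list(correlations = cors, mean_correlation = mean(cors, na.rm = TRUE),
       animal_id = pop$animal_id)
}

#' Stability control: correlation of CS+ weights across refits
#'
#' Trains `n_correlations + 1` CS+ decoders on random 90% partitions of the
#' data (all cells) and correlates the absolute weights of successive
#' iterations.
#'
#' @param pop,events,session As in [weight_selectivity()].
#' @param n_correlations Number of successive-iteration correlations
#'   (default 100, i.e. 101 refits).
#' @param train_fraction Fraction of samples per refit (default 0.9).
#' @param method Correlation type.
#' @param seed Seed.
#' @return List with `correlations` and `mean_correlation`.
#' @export
weight_stability <- function(pop, events, session = NULL,
                             n_correlations = 100L, train_fraction = 0.9,
                             method = c("pearson", "spearman"), seed = 1L) {
  method <- match.arg(method)
  ds <- build_dataset(pop, events, session = session,
                      classes = c("BASELINE", "CS_PLUS"), n_cells = NULL,
                      seed = seed)
  set.seed(seed)
  refit <- function() {
    idx <- sort(sample(nrow(ds$x), round(train_fraction * nrow(ds$x))))
    sub <- ds
    sub$x <- ds$x[idx, , drop = FALSE]
    sub$y <- ds$y[idx]
    train_twoway(sub)$abs_weights
  }
  w_prev <- refit()
  cors <- numeric(n_correlations)
  for (i in seq_len(n_correlations)) {
    w_next <- refit()
    cors[i] <- stats::cor(w_prev, w_next, method = method)
    w_prev <- w_next
  }
  list(correlations = cors, mean_correlation = mean(cors))
}
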