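#' Build a cells x features matrix from aligned tensors
#'
#' Concatenates, per cell, baselined response snippets from one or more
#' aligned tensors. Layouts: `"per_trial"` concatenates every trial's
#' snippet (optionally restricted to `trials`); `"trial_average"`
#' concatenates the trial-averaged snippet; `"blocks"` averages the trial
#' blocks given in `blocks` (a list of trial-index vectors, e.g. the first,
#' middle and last blocks of four extinction trials) and concatenates the
#' block averages. Multiple tensors (e.g. the two extinction sessions, or
#' one per day) are concatenated left to right.
#'
#' @param tensors List of `aligned_tensor`s over a common cell set.
#' @param layout `"per_trial"`, `"trial_average"` or `"blocks"`.
#' @param trials Optional trial subset (per-trial layout).
#' @param blocks List of trial-index vectors (blocks layout).
#' @param cells Optional cell subset (indices or names), e.g. responsive
#'   cells only.
#' @return Numeric matrix cells x features.
#' @export
feature_matrix <- function(tensors, layout = c("per_trial", "trial_average",
                                               "blocks"),
                           trials = NULL, blocks = NULL, cells = NULL) {
  layout <- match.arg(layout)
  if (inherits(tensors, "aligned_tensor")) tensors <- list(tensors)
  stopifnot(length(tensors) >= 1L)
  n_cells <- dim(tensors[[1]])[1]
  ids <- dimnames(tensors[[1]])[[1]]
  for (tn in tensors) {
    if (dim(tn)[1] != n_cells) stop("tensors must share the cell set")
  }
  pieces <- lapply(tensors, function(tn) {
    if (layout == "per_trial") {
      tr <- if (is.null(trials)) seq_len(dim(tn)[2]) else trials
      do.call(cbind, lapply(tr, function(j) {
        m <- tn[, j, , drop = FALSE]
        dim(m) <- dim(m)[c(1L, 3L)]
        m
      }))
    } else if (layout == "trial_average") {
      apply(tn, c(1L, 3L), mean)
    } else {
      if (is.null(blocks)) stop("blocks layout requires `blocks`")
      do.call(cbind, lapply(blocks, function(b) {
        apply(tn[, b, , drop = FALSE], c(1L, 3L), mean)
      }))
    }
  })
  out <- do.call(cbind, pieces)
  rownames(out) <- ids
  if (!is.null(cells)) out <- out[cells, , drop = FALSE]
  if (nrow(out) == 0L) stop("empty cell set")
  out
}

## PCA retaining the smallest number of components whose cumulative
## explained variance reaches the threshold.
pca_to_threshold <- function(x, variance_threshold = 0.8) {
  if (all(apply(x, 2L, stats::sd) < 1e-12)) {
    stop("degenerate feature matrix: zero variance")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  n_comp <- which(cumsum(ev) >= variance_threshold - 1e-12)[1]
  list(scores = pc$x[, seq_len(n_comp), drop = FALSE],
       rotation = pc$rotation[, seq_len(n_comp), drop = FALSE],
       center = pc$center, explained_variance = ev, n_components = n_comp)
}

#' Fit a PCA + K-means response-archetype model
#'
#' Projects the feature matrix onto the smallest principal subspace with at
#' least `variance_threshold` explained variance and partitions the scores
#' with seeded K-means (50 restarts, consistent with a stable partition
#' being required downstream).
#'
#' @param x Cells x features matrix (see [feature_matrix()]).
#' @param k Number of clusters, `2 <= k <=` number of cells.
#' @param variance_threshold PCA explained-variance threshold (default 0.8).
#' @param seed Seed for the K-means restarts.
#' @param nstart Number of K-means restarts (default 50).
#' @return A `cluster_model`: list with `assignment` (named integer),
#'   `centers` (in PCA space), `pca`, `k`, `silhouette` (mean silhouette on
#'   the PCA scores), `features` (the input matrix), `seed`.
#' @export
fit_cluster_model <- function(x, k, variance_threshold = 0.8, seed = 1L,
                              nstart = 50L) {
  if (k < 2 || k > nrow(x)) stop("require 2 <= k <= number of cells")
  pca <- pca_to_threshold(x, variance_threshold)
  set.seed(seed)
  km <- stats::kmeans(pca$scores, centers = k, nstart = nstart,
                      iter.max = 100L)
  sil <- cluster::silhouette(km$cluster, stats::dist(pca$scores))
  assignment <- km$cluster
  names(assignment) <- rownames(x)
  structure(
    list(assignment = assignment, centers = km$centers, pca = pca, k = k,
         silhouette = mean(sil[, "sil_width"]), features = x, seed = seed),
    class = "cluster_model"
  )
}

#' Mean silhouette across a range of cluster counts
#'
#' Runs [fit_cluster_model()] for each k and reports the mean silhouette
#' coefficient (Euclidean, on the PCA scores used for clustering). Values
#' of k exceeding the number of cells are skipped with a warning.
#'
#' @param x Cells x features matrix.
#' @param k_range Candidate cluster counts (default 2:20).
#' @param variance_threshold PCA explained-variance threshold.
#' @param seed Seed.
#' @return Data frame `k`, `mean_silhouette`, with attribute `best_k`.
#' @export
silhouette_scan <- function(x, k_range = 2:20, variance_threshold = 0.8,
                            seed = 1L) {
  ok <- k_range <= nrow(x) - 1L
  if (any(!ok)) warning("skipping k > n_cells - 1")
  k_range <- k_range[ok]
  sil <- vapply(k_range, function(k) {
    fit_cluster_model(x, k, variance_threshold, seed)$silhouette
  }, numeric(1))
  out <- data.frame(k = k_range, mean_silhouette = sil)
  attr(out, "best_k") <- k_range[which.max(sil)]
  out
}

#' Merge raw clusters and attach semantic archetype labels
#'
#' Applies an explicit raw-to-merged map (the reproducible analogue of
#' manual inspection-and-merge), then labels each merged cluster by the
#' maximal Pearson correlation of its mean feature vector with a library of
#' named templates (see [archetype_feature_templates()]).
#'
#' @param model A `cluster_model`.
#' @param merge_map Integer vector of length `k` mapping each raw cluster
#'   to a merged group id, or `NULL` for the identity map.
#' @param templates Matrix templates x features with archetype row names,
#'   in the same feature layout as `model$features`.
#' @return List with `labels` (semantic label per cell), `merged`
#'   (merged group id per cell), `label_map` (per merged group: label and
#'   template correlation), `correlations` (groups x templates matrix).
#' @export
merge_and_label <- function(model, merge_map = NULL, templates) {
  k <- model$k
  if (is.null(merge_map)) merge_map <- seq_len(k)
  if (length(merge_map) != k || anyNA(merge_map)) {
    stop("merge_map must cover all ", k, " raw clusters")
  }
  if (ncol(templates) != ncol(model$features)) {
    stop("templates and features disagree in layout (",
         ncol(templates), " vs ", ncol(model$features), " columns)")
  }
  merged <- merge_map[model$assignment]
  names(merged) <- names(model$assignment)
  groups <- sort(unique(merge_map))
  cors <- matrix(NA_real_, length(groups), nrow(templates),
                 dimnames = list(as.character(groups), rownames(templates)))
  for (gi in seq_along(groups)) {
    mu <- colMeans(model$features[merged == groups[gi], , drop = FALSE])
    cors[gi, ] <- apply(templates, 1L, function(tp) stats::cor(mu, tp))
  }
  best <- apply(cors, 1L, which.max)
  label_map <- data.frame(
    group = groups, label = rownames(templates)[best],
    correlation = cors[cbind(seq_along(groups), best)],
    stringsAsFactors = FALSE
  )
  labels <- label_map$label[match(merged, label_map$group)]
  names(labels) <- names(merged)
  list(labels = labels, merged = merged, label_map = label_map,
       correlations = cors)
}

#' Cross-labelling flow (Sankey) counts
#'
#' Count matrix of cells moving between two labellings on their common cell
#' set, with a display mask for flows below `min_flow` (default 5).
#'
#' @param labels_a,labels_b Named label vectors.
#' @param min_flow Minimum displayed flow (counts below are masked, not
#'   dropped).
#' @return A `cluster_flow`: list with `counts`, `display` (counts with
#'   sub-threshold flows set to 0), `min_flow`, `n_common`.
#' @export
cluster_flow <- function(labels_a, labels_b, min_flow = 5L) {
  common <- intersect(names(labels_a), names(labels_b))
  if (length(common) == 0L) stop("label vectors share no cells")
  counts <- table(source = labels_a[common], target = labels_b[common])
  display <- counts
  display[display < min_flow] <- 0L
  structure(list(counts = counts, display = display, min_flow = min_flow,
                 n_common = length(common)),
            class = "cluster_flow")
}

#' Per-animal cluster membership fractions
#'
#' @param labels Named label vector over responsive cells.
#' @param animals Named character vector mapping the same cells to animal
#'   ids.
#' @return Data frame animals x clusters of fractions (rows sum to 1);
#'   animals with zero labelled cells are excluded with a warning.
#' @export
cluster_fractions_per_animal <- function(labels, animals) {
  stopifnot(!is.null(names(labels)), !is.null(names(animals)))
  common <- intersect(names(labels), names(animals))
  tab <- table(animal = animals[common], cluster = labels[common])
  empty <- rownames(tab)[rowSums(tab) == 0]
  all_animals <- unique(animals)
  missing <- setdiff(all_animals, rownames(tab))
  if (length(empty) || length(missing)) {
    warning("animal(s) without labelled cells excluded: ",
            paste(c(empty, missing), collapse = ", "))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  }
  frac <- sweep(tab, 1L, rowSums(tab), "/")
  as.data.frame.matrix(frac)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < 1e-12) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
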