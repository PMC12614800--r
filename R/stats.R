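## Dunn's multiple-comparison z-tests on the pooled ranks after a
## significant Friedman/Kruskal-style omnibus, with tie correction. No
## installed package provides this post hoc, so it is computed from the
## standard formula.
dunn_posthoc <- function(values, groups, blocks = NULL,
                         p_adjust = "bonferroni") {
  groups <- as.factor(groups)
  if (!is.null(blocks)) {
    ## Friedman design: rank within blocks, compare rank sums
    blocks <- as.factor(blocks)
    k <- nlevels(groups)
    n <- nlevels(blocks)
    rk <- unlist(lapply(split(values, blocks), rank))
    grp <- unlist(lapply(split(groups, blocks), identity))
    rank_sums <- tapply(rk, grp, sum)
    se <- sqrt(n * k * (k + 1) / 6)
    pairs <- utils::combn(levels(groups), 2)
    z <- apply(pairs, 2L, function(pr) {
      abs(rank_sums[pr[1]] - rank_sums[pr[2]]) / se
    })
  } else {
    ## Kruskal-Wallis design: pooled ranks with tie correction
    rk <- rank(values)
    n <- length(values)
    ties <- table(rk)
    tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    mean_rank <- tapply(rk, groups, mean)
    n_g <- tapply(rk, groups, length)
    pairs <- utils::combn(levels(groups), 2)
    z <- apply(pairs, 2L, function(pr) {
      se <- sqrt(tie_corr * n * (n + 1) / 12 *
                   (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
      abs(mean_rank[pr[1]] - mean_rank[pr[2]]) / se
    })
  }
  p <- stats::p.adjust(2 * stats::pnorm(-z), method = p_adjust)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = unname(z),
             p_adjusted = pmin(unname(p), 1), stringsAsFactors = FALSE)
}

#' Standard nonparametric group comparison with screening
#'
#' The reporting pattern used throughout the pipeline: repeated-measures
#' designs use a Friedman test followed by Dunn's multiple comparisons;
#' independent groups use pairwise Mann-Whitney tests, paired designs
#' pairwise Wilcoxon signed-rank tests (both Bonferroni-adjusted);
#' proportion tables use an omnibus chi-square followed by pairwise
#' comparisons with Yates continuity correction when any expected count is
#' below 5. Normality (Shapiro-Wilk) and homoscedasticity (Levene) are
#' screened and reported, but the nonparametric path is always taken.
#'
#' @param values Numeric values, or for `design = "proportions"` a matrix
#'   of successes/failures (groups x 2) or counts (groups x categories).
#' @param groups Group labels (ignored for proportions).
#' @param blocks Block/subject labels for `design = "repeated"`.
#' @param design `"repeated"`, `"independent"`, `"paired"` or
#'   `"proportions"`.
#' @return A list of class `group_comparison`: `omnibus` (htest),
#'   `pairwise` (data frame with adjusted p-values), `screening`
#'   (Shapiro-Wilk and Levene p-values, where applicable).
#' @export
group_comparison <- function(values, groups = NULL, blocks = NULL,
                             design = c("repeated", "independent", "paired",
                                        "proportions")) {
  design <- match.arg(design)
  if (design == "proportions") {
    counts <- as.matrix(values)
    if (nrow(counts) < 2L) stop("need at least 2 groups")
    omnibus <- suppressWarnings(stats::chisq.test(counts))
    pairs <- utils::combn(seq_len(nrow(counts)), 2)
    pw <- apply(pairs, 2L, function(pr) {
      sub <- counts[pr, , drop = FALSE]
      expected <- outer(rowSums(sub), colSums(sub)) / sum(sub)
      correct <- any(expected < 5)
      pt <- suppressWarnings(stats::prop.test(sub, correct = correct))
      pt$p.value
    })
    pairwise <- data.frame(
      group1 = rownames(counts)[pairs[1, ]],
      group2 = rownames(counts)[pairs[2, ]],
      p_adjusted = pmin(stats::p.adjust(pw, "bonferroni"), 1),
      stringsAsFactors = FALSE)
    return(structure(list(omnibus = omnibus, pairwise = pairwise,
                          screening = NULL, design = design),
                     class = "group_comparison"))
  }

  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  screening <- list(
    shapiro_p = tryCatch(stats::shapiro.test(
      stats::residuals(stats::lm(values ~ groups)))$p.value,
      error = function(e) NA_real_),
    levene_p = tryCatch(
      suppressWarnings(car::leveneTest(values, groups)[1, "Pr(>F)"]),
      error = function(e) NA_real_)
  )
  if (design == "repeated") {
    if (is.null(blocks)) stop("repeated design requires blocks")
    omnibus <- stats::friedman.test(values, groups, as.factor(blocks))
    pairwise <- dunn_posthoc(values, groups, blocks)
  } else {
    pairs <- utils::combn(levels(groups), 2)
    pw <- apply(pairs, 2L, function(pr) {
      x <- values[groups == pr[1]]
      y <- values[groups == pr[2]]
      suppressWarnings(stats::wilcox.test(
        x, y, paired = (design == "paired"), exact = FALSE)$p.value)
    })
    omnibus <- if (nlevels(groups) > 2L) {
      stats::kruskal.test(values, groups)
    } else {
      suppressWarnings(stats::wilcox.test(
        values[groups == levels(groups)[1]],
        values[groups == levels(groups)[2]],
        paired = (design == "paired"), exact = FALSE))
    }
    pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           p_adjusted = pmin(stats::p.adjust(pw,
                                                             "bonferroni"),
                                             1),
                           stringsAsFactors = FALSE)
  }
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 screening = screening, design = design),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> design:", x$design, "\n")
  cat(sprintf("omnibus: %s, p = %.4g\n", x$omnibus$method,
              x$omnibus$p.value))
  print(x$pairwise)
  invisible(x)
}
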