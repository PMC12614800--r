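test_that("vectorised rank-sum matches wilcox.test exactly", {
  set.seed(2)
  for (i in 1:60) {
    nx <- sample(5:40, 1)
    ny <- sample(5:40, 1)
    digits <- sample(0:3, 1)  # coarse rounding induces heavy ties
    x <- round(rnorm(nx), digits)
    y <- round(rnorm(ny), digits)
    p_fast <- fearca:::ranksum_rows(matrix(x, 1), matrix(y, 1))
    p_ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    expect_equal(p_fast, p_ref, tolerance = 1e-12)
  }
})

test_that("per-trial tests behave at the distributional extremes", {
  ## identical samples: p = 1 under tie handling
  arr <- array(1, dim = c(1, 1, 240))
  tens <- make_tensor(arr, pre_window = 30, baseline_window = 30)
  tens[1, 1, ] <- rep(c(2, 3), 120)  # identical distributions in both halves
  res <- trial_response_test(tens, evoked_window = 30)
  expect_equal(res$p[1, 1], 1)
  ## strong shift: baseline 0, evoked +5, 120 vs 120 bins
  arr2 <- array(0, dim = c(1, 1, 240))
  arr2[1, 1, 121:240] <- 5
  tens2 <- make_tensor(arr2, pre_window = 30, baseline_window = 30)
  res2 <- trial_response_test(tens2, evoked_window = 30)
  expect_lt(res2$p[1, 1], 1e-10)
  expect_equal(res2$sign[1, 1], 1)
  ## negation flips the sign but not the p-value
  tens3 <- make_tensor(-arr2, pre_window = 30, baseline_window = 30)
  res3 <- trial_response_test(tens3, evoked_window = 30)
  expect_equal(res3$p[1, 1], res2$p[1, 1])
  expect_equal(res3$sign[1, 1], -1)
  ## too few bins
  tiny <- make_tensor(array(0, c(1, 1, 2)), pre_window = 0.25,
                      baseline_window = 0.25)
  expect_error(trial_response_test(tiny, evoked_window = 0.25), "2 bins")
})

test_that("the >=3-significant rule drives the responsive flag", {
  mk <- function(p, s) list(p = matrix(p, 1), sign = matrix(s, 1))
  c1 <- classify_cells(mk(c(.005, .2, .009, .003, .5), rep(1, 5)))
  expect_true(c1$responsive)
  expect_equal(c1$direction, "activated")
  c2 <- classify_cells(mk(c(.005, .2, .009, .2, .5), rep(1, 5)))
  expect_false(c2$responsive)
  expect_equal(c2$direction, "none")
  ## majority sign among significant trials
  c3 <- classify_cells(mk(c(.001, .001, .001, .9, .9), c(1, 1, -1, 1, -1)))
  expect_equal(c3$direction, "activated")
  ## exact tie: broken by mean AUC sign, with a message
  expect_message(
    c4 <- classify_cells(mk(c(.001, .001, .001, .001, .9),
                            c(1, 1, -1, -1, 1)),
                         auc = matrix(rep(-2, 5), 1)),
    "tie")
  expect_equal(c4$direction, "inhibited")
  expect_error(classify_cells(mk(rep(.001, 2), rep(1, 2)),
                              min_significant = 3), "exceeds")
})

test_that("responsive fractions aggregate per animal and pooled", {
  cls <- list(CS_PLUS = make_classification(c(TRUE, TRUE, FALSE, FALSE)),
              CS_MINUS = make_classification(rep(FALSE, 4)))
  fr <- responsive_fractions(cls, group_by = "population")
  expect_equal(fr$fraction_responsive[fr$stimulus == "CS_PLUS"], 0.5)
  expect_equal(fr$fraction_responsive[fr$stimulus == "CS_MINUS"], 0)
  ## per-animal mean equals pooled value with equal n per animal
  by_animal <- list(a1 = cls, a2 = cls)
  fa <- responsive_fractions(by_animal, group_by = "animal")
  expect_equal(mean(fa$fraction_responsive[fa$stimulus == "CS_PLUS"]), 0.5)
})

test_that("overlap combinations match the independence chance model", {
  ## marginals (0.5, 0.5, 0.5): chance triple overlap is 0.125
  resp <- rep(c(TRUE, FALSE), each = 4)
  ov <- overlap_with_chance(make_classification(resp),
                            make_classification(resp),
                            make_classification(resp))
  expect_equal(ov$chance[ov$combination == "CS+/CS-/US"], 0.125)
  expect_equal(ov$observed[ov$combination == "CS+/CS-/US"], 0.5)
  ## disjoint responders: observed triple overlap 0
  ov2 <- overlap_with_chance(
    make_classification(c(TRUE, FALSE, FALSE, FALSE)),
    make_classification(c(FALSE, TRUE, FALSE, FALSE)),
    make_classification(c(FALSE, FALSE, TRUE, FALSE)))
  expect_equal(ov2$observed[ov2$combination == "CS+/CS-/US"], 0)
  ## combination fractions plus non-responsive sum to 1
  expect_equal(sum(ov2$observed) + attr(ov2, "fraction_nonresponsive"), 1,
               tolerance = 1e-9)
  ## invariant to cell ordering
  perm <- c(3, 1, 4, 2)
  ov3 <- overlap_with_chance(
    make_classification(c(TRUE, FALSE, FALSE, FALSE)[perm]),
    make_classification(c(FALSE, TRUE, FALSE, FALSE)[perm]),
    make_classification(c(FALSE, FALSE, TRUE, FALSE)[perm]))
  expect_equal(ov3$observed, ov2$observed)
  ## mismatched cell sets rejected
  expect_error(overlap_with_chance(
    make_classification(c(TRUE, FALSE)),
    make_classification(c(TRUE, FALSE), cell_id = c("x", "y")),
    make_classification(c(TRUE, FALSE))), "same cells")
})

test_that("planted independent responders sit at chance overlap", {
  set.seed(7)
  n <- 4000
  marg <- c(0.6, 0.5, 0.7)
  r <- lapply(marg, function(m) runif(n) < m)
  ov <- overlap_with_chance(make_classification(r[[1]]),
                            make_classification(r[[2]]),
                            make_classification(r[[3]]))
  ## binomial CI on each combination
  for (i in seq_len(nrow(ov))) {
    se <- sqrt(ov$chance[i] * (1 - ov$chance[i]) / n)
    expect_lt(abs(ov$observed[i] - ov$chance[i]), 4 * se)
  }
})

test_that("within-group spatial distances follow the geometry", {
  cent <- rbind(c(0, 0), c(3, 4))
  d <- spatial_distance_distribution(cent, c("US", "US"))
  expect_equal(d$mean_distance, c(5, 5))
  ## co-located cells
  d2 <- spatial_distance_distribution(rbind(c(1, 1), c(1, 1)),
                                      c("a", "a"))
  expect_equal(d2$mean_distance, c(0, 0))
  expect_warning(
    spatial_distance_distribution(rbind(c(0, 0), c(1, 1), c(2, 2)),
                                  c("a", "a", "b")), "singleton")
  ## uniformly scattered groups show no spatial clustering: a label-
  ## permutation test of the mean within-group distance stays null
  set.seed(11)
  n_pass <- 0
  for (i in 1:20) {
    cent <- cbind(runif(60, 0, 500), runif(60, 0, 500))
    g <- rep(c("x", "y"), each = 30)
    stat <- function(gg) {
      dd <- spatial_distance_distribution(cent, gg)
      abs(diff(tapply(dd$mean_distance, dd$group, mean)))
    }
    obs <- stat(g)
    null <- replicate(99, stat(sample(g)))
    p <- (1 + sum(null >= obs)) / 100
    if (p > 0.05) n_pass <- n_pass + 1
  }
  expect_gte(n_pass, 18)
})

test_that("classification export writes per-trial p-values", {
  mk <- list(p = matrix(runif(10), 2, dimnames = list(c("c1", "c2"))),
             sign = matrix(1, 2, 5))
  cl <- classify_cells(mk)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification(cl, path, stimulus = "US")
  back <- read.delim(path)
  expect_equal(names(back),
               c("cell_id", "stimulus", paste0("p", 1:5), "responsive",
                 "direction"))
  expect_equal(back$cell_id, c("c1", "c2"))
})
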