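## helper for the subset test: classify one stimulus on the fixture
classify_stim_helper <- function(fx, label) {
  tens <- align_to_events(fx$pop, fx$events, label, pre_window = 30,
                          post_window = 30)
  classify_cells(trial_response_test(tens, evoked_window = 30))
}

## One shared separable population: distinct cells carry CS+ and CS- drive.
separable_pop <- function() {
  fixture("separable_pop", function() {
    ev <- cond_protocol()
    cfg <- null_config(n_cells = 58, seed = 5)
    truth <- data.frame(
      animal = "animal_1", cell_id = paste0("cell_", 1:58),
      us = "Null",
      cs_plus = c(rep("Stable activated", 20), rep("Null", 38)),
      cs_minus = c(rep("Null", 38), rep("Stable activated", 20)),
      across_day = "Null", stringsAsFactors = FALSE)
    gen <- generate_population(cfg, list(conditioning = ev), truth = truth)
    list(pop = gen$populations[[1]], events = ev, truth = truth)
  })
}

test_that("decoder datasets are balanced and reproducible", {
  fx <- separable_pop()
  ds <- build_dataset(fx$pop, fx$events, n_cells = 37, seed = 2)
  expect_equal(dim(ds$x), c(450L, 37L))  # 3 classes x 5 blocks x 30 bins
  expect_equal(unname(table(ds$y)), rep(150L, 3), ignore_attr = TRUE)
  ds2 <- build_dataset(fx$pop, fx$events, n_cells = 37, seed = 2)
  expect_identical(ds$x, ds2$x)
  expect_identical(ds$cells, ds2$cells)
  expect_error(build_dataset(fx$pop, fx$events, n_cells = 100, seed = 1),
               "animal_1")
})

test_that("confusion-matrix metric identities hold exactly", {
  ## hand-checked 2x2
  m <- decoder_metrics(matrix(c(10, 0, 0, 10), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$f1), c(1, 1))
  ## random confusion matrices vs an independent recomputation
  set.seed(3)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    conf <- matrix(rpois(k * k, 8), k)
    m <- decoder_metrics(conf)
    expect_equal(m$accuracy, sum(diag(conf)) / sum(conf),
                 tolerance = 1e-12)
    for (j in seq_len(k)) {
      prec <- conf[j, j] / sum(conf[, j])
      rec <- conf[j, j] / sum(conf[j, ])
      expect_equal(m$precision[j], prec, tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(m$recall[j], rec, tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(m$f1[j], 2 * prec * rec / (prec + rec),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("separable classes decode near perfectly, shuffles at chance", {
  fx <- separable_pop()
  ds <- build_dataset(fx$pop, fx$events, n_cells = 37, seed = 2)
  res <- crossval_multiclass(ds, folds = 10, seed = 1)
  expect_gte(res$accuracy, 0.99)
  sh <- shuffled_label_control(ds, n_shuffles = 20, folds = 10, seed = 7)
  expect_lt(abs(mean(sh) - 1 / 3), 0.08)
  expect_gt(res$accuracy, quantile(sh, 0.95))
  expect_error(shuffled_label_control(ds, n_shuffles = 0), ">= 1")
  ds1 <- ds
  ds1$y <- factor(rep("BASELINE", length(ds$y)))
  expect_error(crossval_multiclass(ds1), "single class")
})

test_that("decoder cell subsets reflect CS responsiveness", {
  fx <- separable_pop()
  cs_p <- classify_stim_helper(fx, "CS_PLUS")
  cs_m <- classify_stim_helper(fx, "CS_MINUS")
  cls <- list(CS_PLUS = cs_p, CS_MINUS = cs_m)
  resp <- subset_cells(cls, "responsive_only")
  nonresp <- subset_cells(cls, "nonresponsive_only")
  expect_length(intersect(resp, nonresp), 0)
  ## signal-carrying cells are (mostly) in the responsive subset
  expect_gte(length(intersect(resp, paste0("cell_", c(1:20, 39:58)))) /
               40, 0.9)
  matched <- subset_cells(cls, "random_size_matched", seed = 4)
  expect_length(matched, length(nonresp))
  ## decoding: responsive cells carry the signal, non-responders don't
  ds_resp <- build_dataset(fx$pop, fx$events, cells = resp, seed = 3)
  ds_non <- build_dataset(fx$pop, fx$events, cells = nonresp, seed = 3)
  acc_resp <- crossval_multiclass(ds_resp, seed = 1)$accuracy
  acc_non <- crossval_multiclass(ds_non, seed = 1)$accuracy
  expect_gte(acc_resp, 0.95)
  expect_lt(acc_non, 0.6)
})

test_that("two-way decoders expose informative weights", {
  fx <- separable_pop()
  ds <- build_dataset(fx$pop, fx$events, classes = c("BASELINE", "CS_PLUS"),
                      n_cells = NULL, seed = 2)
  tw <- train_twoway(ds)
  expect_length(tw$weights, 58L)
  ## CS+ coding cells dominate the absolute weights
  top <- names(sort(tw$abs_weights, decreasing = TRUE))[1:10]
  expect_gte(length(intersect(top, paste0("cell_", 1:20))), 6)
  ## a perfectly discriminative feature takes the maximal |weight|
  dsp <- ds
  dsp$x <- cbind(dsp$x, oracle = ifelse(dsp$y == "CS_PLUS", 1, -1))
  dsp$cells <- c(dsp$cells, "oracle")
  twp <- train_twoway(dsp)
  expect_equal(names(which.max(twp$abs_weights)), "oracle")
  ## a zero-variance feature gets (near) zero weight
  ds0 <- ds
  ds0$x <- cbind(ds0$x, dead = 0)
  ds0$cells <- c(ds0$cells, "dead")
  tw0 <- train_twoway(ds0)
  expect_lt(abs(tw0$weights["dead"]), 1e-8)
  ## more than two classes rejected
  ds3 <- build_dataset(fx$pop, fx$events, n_cells = 37, seed = 2)
  expect_error(train_twoway(ds3), "exactly 2")
})

test_that("evaluating on the training day reproduces training accuracy", {
  fx <- separable_pop()
  ds <- build_dataset(fx$pop, fx$events, classes = c("BASELINE", "CS_PLUS"),
                      n_cells = 37, seed = 2)
  tw <- train_twoway(ds)
  self_eval <- cross_day_evaluate(tw, ds)
  train_acc <- mean(predict(tw$model, ds$x) == ds$y)
  expect_equal(self_eval$accuracy, train_acc, tolerance = 1e-12)
  ds_bad <- ds
  ds_bad$cells <- rev(ds_bad$cells)
  expect_error(cross_day_evaluate(tw, ds_bad), "do not match")
})

test_that("weight correlations separate broad from selective coding", {
  fx <- separable_pop()
  ## disjoint CS+/CS- coding populations: negative |w| correlation
  ws <- weight_selectivity(fx$pop, fx$events, n_iterations = 5,
                           n_cells = 37, seed = 11)
  expect_lt(ws$mean_correlation, -0.2)
  ## identical weights correlate at 1 by construction
  expect_equal(cor(abs(ws$correlations), abs(ws$correlations)), 1)
  ## stability control: CS+ weights correlate across 90% refits
  st <- weight_stability(fx$pop, fx$events, n_correlations = 4, seed = 12)
  expect_gt(st$mean_correlation, 0.6)
})

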