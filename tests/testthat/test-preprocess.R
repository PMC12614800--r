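test_that("z-scoring standardises each cell over the concatenated trace", {
  set.seed(1)
  raw <- matrix(rnorm(2 * 400, mean = 5, sd = 2), nrow = 2)
  pop <- preprocess_traces(raw, bin_width = 0.05)  # bin = sample: no binning
  z <- pop$sessions[[1]]
  expect_equal(rowMeans(z), c(0, 0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(apply(z, 1, sd), c(1, 1), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("constant traces z-score to zero with a warning", {
  raw <- rbind(rep(3, 100), rnorm(100))
  expect_warning(pop <- preprocess_traces(raw, bin_width = 0.05),
                 "constant")
  expect_equal(unname(pop$sessions[[1]][1, ]), rep(0, 100))
})

test_that("binning averages the expected number of samples", {
  raw <- matrix(rep(1:20, each = 5), nrow = 1, byrow = FALSE)
  raw <- rbind(as.numeric(raw))  # 100 samples: 20 bins of 5 at 250 ms
  pop <- preprocess_traces(raw, bin_width = 0.25)
  expect_equal(ncol(pop$sessions[[1]]), 20L)
  ## z-score first, then mean of 5 identical samples per bin: sd over bins
  ## stays 1 since within-bin values are constant
  expect_equal(sd(pop$sessions[[1]][1, ]), 1, tolerance = 0.03)
  ## bin count is floor(samples * dt / bin_width)
  pop2 <- preprocess_traces(matrix(rnorm(103), 1), bin_width = 0.25)
  expect_equal(ncol(pop2$sessions[[1]]), 20L)
})

test_that("preprocessing rejects invalid input", {
  expect_error(preprocess_traces(matrix(c(1, NA, 3, 4), 1)), "missing")
  expect_error(preprocess_traces(matrix(rnorm(100), 1), bin_width = 0.13),
               "multiple")
  expect_error(preprocess_traces(list(a = matrix(rnorm(40), 2),
                                      b = matrix(rnorm(60), 3))),
               "inconsistent cell counts")
})

test_that("preprocessing is idempotent on z-scored, binned input", {
  set.seed(2)
  raw <- matrix(rnorm(3 * 1000), nrow = 3)
  binned <- preprocess_traces(raw, bin_width = 0.25)$sessions[[1]]
  ## standardise at bin resolution: already z-scored, already binned input
  x <- t(scale(t(binned)))
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  pop2 <- preprocess_traces(x, bin_width = 0.25, sampling_rate_raw = 4)
  expect_equal(unname(pop2$sessions[[1]]), unname(x), tolerance = 1e-9)
})

test_that("alignment removes constant offsets and respects cardinality", {
  ev <- cond_protocol()
  n_bins <- ceiling(attr(ev, "session_end_s") / 0.25)
  m <- matrix(7, nrow = 2, ncol = n_bins)  # constant-offset traces
  pop <- structure(list(animal_id = "a", cell_ids = c("c1", "c2"),
                        sessions = list(conditioning = m), bin_width = 0.25,
                        sampling_rate_raw = 20, centroids = NULL),
                   class = "trace_population")
  tens <- align_to_events(pop, ev, "CS_PLUS", pre_window = 30,
                          post_window = 30)
  expect_equal(dim(tens), c(2L, 5L, 240L))
  expect_true(all(abs(tens) < 1e-12))
  ## per cell-trial baseline mean is zero
  time <- attr(tens, "time")
  base <- time < 0
  expect_true(all(abs(apply(tens[, , base], c(1, 2), mean)) < 1e-9))
  ## US alignment uses a 5 s baseline
  us <- align_to_events(pop, ev, "US", pre_window = 5, post_window = 5,
                        baseline_window = 5)
  expect_equal(attr(us, "baseline_window"), 5)
  expect_error(align_to_events(pop, ev, "CS_PLUS", pre_window = 30,
                               post_window = 30, baseline_window = 40),
               "baseline_window")
})

test_that("out-of-range trials are dropped with a warning", {
  ev <- cond_protocol()
  m <- matrix(rnorm(2 * 600), nrow = 2)  # 150 s session only
  pop <- structure(list(animal_id = "a", cell_ids = c("c1", "c2"),
                        sessions = list(conditioning = m), bin_width = 0.25,
                        sampling_rate_raw = 20, centroids = NULL),
                   class = "trace_population")
  expect_warning(tens <- align_to_events(pop, ev, "CS_PLUS",
                                         pre_window = 30, post_window = 30),
                 "dropped")
  expect_lt(dim(tens)[2], 5L)
})

test_that("AUC is the exact integral of the binned step response", {
  ## unit-amplitude rectangle of 10 s inside a 30 s window
  arr <- array(0, dim = c(1, 1, 120))
  arr[1, 1, 1:40] <- 1
  tens <- make_tensor(arr)
  expect_equal(as.numeric(compute_auc(tens, 30)), 10)
  ## all-zero tensor
  expect_equal(as.numeric(compute_auc(make_tensor(array(0, c(2, 3, 120))),
                                      30)),
               rep(0, 6))
  ## exact linearity and additivity over disjoint windows
  set.seed(3)
  arr <- array(rnorm(4 * 5 * 120), dim = c(4, 5, 120))
  tens <- make_tensor(arr)
  expect_equal(unclass(compute_auc(tens, 30)),
               unclass(compute_auc(tens, 10)) +
                 apply(arr[, , 41:120], c(1, 2), sum) * 0.25,
               ignore_attr = TRUE)
  tens2 <- make_tensor(2 * arr)
  expect_equal(unclass(compute_auc(tens2, 30)),
               2 * unclass(compute_auc(tens, 30)), ignore_attr = TRUE)
  expect_error(compute_auc(tens, 31), "exceeds")
})

test_that("trace summaries compute mean and s.e.m. correctly", {
  arr <- array(0, dim = c(1, 2, 4))
  arr[1, 1, ] <- 0
  arr[1, 2, ] <- 2
  s <- summarize_traces(make_tensor(arr), over = "trials")
  expect_equal(unname(s$mean[1, ]), rep(1, 4))
  expect_equal(unname(s$sem[1, ]), rep(1, 4))  # sd(c(0,2))/sqrt(2) = 1
  ## identical trials: s.e.m. 0
  arr[1, 2, ] <- 0
  s2 <- summarize_traces(make_tensor(arr), over = "trials")
  expect_equal(unname(s2$sem[1, ]), rep(0, 4))
  ## single observation: flagged undefined
  expect_warning(s3 <- summarize_traces(make_tensor(array(1, c(1, 1, 4))),
                                        over = "both"))
  expect_true(all(is.na(s3$sem)))
  expect_equal(unname(s3$mean), rep(1, 4))
})

test_that("alignment recovers a planted event-locked template", {
  ev <- cond_protocol()
  fs <- 20
  n <- round(attr(ev, "session_end_s") * fs)
  template <- c(rep(1.5, 100), rep(0.5, 100))  # 10 s two-step template
  sig <- numeric(n)
  for (on in ev$onset_s[ev$label == "CS_PLUS"]) {
    idx <- round(on * fs) + seq_along(template)
    sig[idx] <- sig[idx] + template
  }
  set.seed(4)
  noise_sd <- 0.3
  raw <- rbind(sig + rnorm(n, 0, noise_sd))
  pop <- preprocess_traces(list(conditioning = raw), bin_width = 0.25)
  tens <- align_to_events(pop, ev, "CS_PLUS", pre_window = 10,
                          post_window = 10)
  avg <- apply(tens, 3, mean)  # mean over the 5 trials
  time <- attr(tens, "time")
  ## rescale the planted template into the z-scored units of the trace
  scale_z <- sd(raw[1, ])
  expected <- ifelse(time < 0, 0,
                     ifelse(time < 5, 1.5, 0.5) / scale_z)
  expected <- expected - mean(expected[time < 0])
  se <- noise_sd / scale_z / sqrt(5 * 5)  # 5 trials x 5 samples per bin
  ## onset snapping smears the bins at the template steps; exclude them
  at_step <- vapply(time, function(t) {
    any(abs(t - c(0, 5, 10)) <= 0.3)
  }, TRUE)
  expect_lt(max(abs(avg - expected)[!at_step]), 3.5 * se + 0.02)
})
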