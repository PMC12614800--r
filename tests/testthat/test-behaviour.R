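## Minimal hand-built pose track.
make_pose <- function(xy_list, likelihood = NULL, frame_rate = 20) {
  n <- nrow(xy_list[[1]])
  parts <- lapply(xy_list, function(m) {
    lk <- if (is.null(likelihood)) rep(1, n) else likelihood
    data.frame(x = m[, 1], y = m[, 2], likelihood = lk)
  })
  structure(list(parts = parts, frame_rate = frame_rate, n_frames = n),
            class = "pose_track")
}

five_points <- function(m, likelihood = NULL) {
  make_pose(setNames(rep(list(m), 5),
                     c("left_ear_base", "right_ear_base", "upper_spine",
                       "middle_spine", "tail_base")), likelihood)
}

test_that("pose filtering holds the last confident position", {
  m <- cbind(1:5, 1:5)
  ## all confident: unchanged
  p <- five_points(m)
  expect_equal(filter_pose(p, 0.9)$parts[[1]]$x, 1:5)
  ## single dropout carries the previous frame forward
  p2 <- five_points(m, likelihood = c(1, 1, 0.2, 1, 1))
  f2 <- filter_pose(p2, 0.9)
  expect_equal(f2$parts[[1]]$x, c(1, 2, 2, 4, 5))
  ## leading dropouts are back-filled from the first confident frame
  p3 <- five_points(m, likelihood = c(0.1, 0.1, 1, 1, 1))
  f3 <- filter_pose(p3, 0.9)
  expect_equal(f3$parts[[1]]$x, c(3, 3, 3, 4, 5))
  ## a part that is never confident is rejected by name
  p4 <- five_points(m, likelihood = rep(0.1, 5))
  expect_error(filter_pose(p4, 0.9), "left_ear_base")
})

test_that("displacements are Euclidean and offset-invariant", {
  m <- rbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4))
  d <- displacement(five_points(m))
  expect_equal(unname(d[, 1]), c(0, 0, 5, 0))
  ## static pose
  expect_true(all(displacement(five_points(matrix(2, 10, 2))) == 0))
  ## global offset changes nothing
  d2 <- displacement(five_points(m + 100))
  expect_equal(d, d2)
  expect_error(displacement(five_points(m), points = "tail_tip"),
               "unknown")
})

test_that("immobility detection respects duration and CS overlap", {
  fr <- 20
  n <- 120 * fr  # 120 s
  disp <- matrix(5, n, 5)
  disp[(10 * fr + 1):(20 * fr), ] <- 0    # 10 s quiet at 10 s
  disp[(30 * fr + 1):(31.5 * fr), ] <- 0  # 1.5 s: too short
  disp[(50 * fr + 1):(56 * fr), ] <- 0    # 6 s inside a fake CS
  ev <- data.frame(session_id = "s", day_kind = "custom",
                   label = "CS_PLUS", onset_s = 45, offset_s = 75,
                   trial_index = 1)
  bouts <- detect_immobility(disp, threshold = 2, events = ev,
                             frame_rate = fr)
  expect_equal(nrow(bouts), 2L)
  expect_equal(bouts$start_s[1], 10, tolerance = 0.05)
  expect_equal(bouts$duration_s[1], 10, tolerance = 0.1)
  expect_false(bouts$overlaps_CS[1])
  expect_true(bouts$overlaps_CS[2])
  ## no bout shorter than the minimum, none overlapping
  expect_true(all(bouts$duration_s >= 2))
  expect_true(all(diff(bouts$start_s) >= 0))
  expect_warning(detect_immobility(disp, threshold = 5, frame_rate = fr),
                 "calibration")
})

test_that("bout detection recovers planted bouts on synthetic pose", {
  cfg <- null_config(n_cells = 2, seed = 3)
  ev <- build_protocol("test_ext1", seed = 4)
  beh <- generate_behaviour(cfg, ev, seed = 6)
  pose <- filter_pose(beh$pose, 0.9)
  disp <- displacement(pose)
  bouts <- detect_immobility(disp, threshold = 2, events = ev,
                             frame_rate = 20)
  match_rate <- function(a, b) {
    mean(vapply(seq_len(nrow(a)), function(i) {
      ov <- pmin(a$stop_s[i], b$stop_s) - pmax(a$start_s[i], b$start_s)
      un <- pmax(a$stop_s[i], b$stop_s) - pmin(a$start_s[i], b$start_s)
      any(ov / un > 0.8)
    }, TRUE))
  }
  expect_gte(nrow(beh$bouts), 20)
  expect_gte(match_rate(beh$bouts, bouts), 0.95)  # recall
  expect_gte(match_rate(bouts, beh$bouts), 0.95)  # precision
})

test_that("state-modulated cells show signed immobility responses", {
  ev1 <- build_protocol("test_ext1", seed = 4)
  ev2 <- build_protocol("ext2", seed = 5)
  prot <- list(test_ext1 = ev1, ext2 = ev2)
  cfg <- null_config(n_cells = 30, seed = 7)
  cfg$across_day_props <- c("Fear inhibited" = 0.5, "Null" = 0.5)
  beh <- lapply(prot, function(ev) generate_behaviour(cfg, ev,
                                                      seed = ev$onset_s[1]))
  bouts <- lapply(beh, `[[`, "bouts")
  gen <- generate_population(cfg, prot, bouts = bouts)
  pop <- gen$populations[[1]]
  detected <- lapply(names(prot), function(day) {
    disp <- displacement(filter_pose(beh[[day]]$pose, 0.9))
    detect_immobility(disp, threshold = 2, events = prot[[day]],
                      frame_rate = 20)
  })
  names(detected) <- names(prot)
  act <- immobility_aligned_activity(pop, detected)
  state <- gen$ground_truth$state_sign == -1
  ## suppressed during immobility: negative onset AUC, positive offset AUC
  expect_lt(mean(act$onset$auc[state]), -0.5)
  expect_gt(mean(act$offset$auc[state]), 0.5)
  ## state-independent cells hover near zero
  expect_lt(abs(mean(act$onset$auc[!state])), 0.4)
  ## pooling two identical sessions equals either session's average
  same <- list(test_ext1 = detected$test_ext1,
               ext2 = detected$test_ext1)
  pop_same <- pop
  pop_same$sessions$ext2 <- pop$sessions$test_ext1
  act2 <- immobility_aligned_activity(pop_same, same)
  one <- immobility_aligned_activity(pop_same, same,
                                     sessions = "test_ext1")
  expect_equal(act2$onset$auc, one$onset$auc, tolerance = 1e-12)
})

test_that("across-session stability uses rank correlations", {
  aucs <- list(m1 = list(s1 = 1:10, s2 = (1:10)^3),  # monotone transform
               m2 = list(s1 = 1:10, s2 = exp(1:10)))
  st <- stability_across_sessions(aucs)
  expect_equal(st$per_animal$rho, c(1, 1))
  expect_equal(st$tests$mean_rho, 1)
  ## independent responses: mean rho near zero across simulated animals
  set.seed(8)
  indep <- lapply(1:8, function(i) list(s1 = rnorm(40), s2 = rnorm(40)))
  names(indep) <- paste0("m", 1:8)
  st2 <- stability_across_sessions(indep)
  expect_lt(abs(st2$tests$mean_rho), 0.2)
  expect_warning(stability_across_sessions(
    list(tiny = list(s1 = 1:2, s2 = 2:1))), "excluded")
})

test_that("the discrimination score follows its closed form", {
  expect_equal(discrimination_score(60, 20), 0.5)
  expect_equal(discrimination_score(7, 7), 0)
  expect_equal(discrimination_score(50, 0), 1)
  expect_equal(discrimination_score(0, 50), -1)
  ## scale invariance
  expect_equal(discrimination_score(3 * 60, 3 * 20),
               discrimination_score(60, 20))
  expect_warning(ds <- discrimination_score(0, 0))
  expect_true(is.na(ds))
  expect_error(discrimination_score(-1, 2))
})

test_that("immobility fractions integrate bout-CS overlap", {
  ev <- data.frame(session_id = "s", day_kind = "test_ext1",
                   label = rep(c("CS_MINUS", "CS_PLUS"), c(4, 12)),
                   onset_s = seq(100, 1600, by = 100)[1:16],
                   offset_s = seq(100, 1600, by = 100)[1:16] + 30,
                   trial_index = c(1:4, 1:12))
  class(ev) <- c("event_table", "data.frame")
  ## immobile during exactly half of each of the first four CS+ windows
  plus <- ev[ev$label == "CS_PLUS", ][1:4, ]
  bouts <- data.frame(start_s = plus$onset_s, stop_s = plus$onset_s + 15)
  expect_equal(immobility_fraction(bouts, ev, "CS_PLUS"), 0.5)
  expect_equal(immobility_fraction(bouts, ev, "CS_MINUS"), 0)
})

test_that("cluster counts correlate with behaviour as planted", {
  ds <- setNames(c(0.9, 0.5, 0.1, -0.3, -0.7), paste0("m", 1:5))
  counts <- cbind(fear_inhibited = rank(ds), flat = rep(3, 5))
  rownames(counts) <- names(ds)
  expect_warning(res <- correlate_counts_with_behaviour(counts, ds),
                 "constant")
  expect_equal(res$rho[res$cluster == "fear_inhibited"], 1)
  expect_true(is.na(res$rho[res$cluster == "flat"]))
  ## sign flip of DS flips rho
  res2 <- suppressWarnings(correlate_counts_with_behaviour(counts, -ds))
  expect_equal(res2$rho[res2$cluster == "fear_inhibited"], -1)
  expect_error(correlate_counts_with_behaviour(counts[1:3, ], ds[1:3]),
               "4 animals")
})

test_that("pose tracks round-trip through wide CSV", {
  cfg <- null_config(n_cells = 2, seed = 9)
  ev <- cond_protocol()
  beh <- generate_behaviour(cfg, ev, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose(beh$pose, path)
  back <- read_pose(path, frame_rate = 20)
  expect_equal(names(back$parts), names(beh$pose$parts))
  expect_equal(back$parts[[3]]$x, beh$pose$parts[[3]]$x, tolerance = 1e-6)
  expect_equal(back$parts[[8]]$likelihood, beh$pose$parts[[8]]$likelihood,
               tolerance = 1e-6)
})
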