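## Response-archetype vocabularies. US and CS archetypes describe trial-by-
## trial modulation within the conditioning session; across-day archetypes
## gate CS responses by day (habituation / test-extinction 1 / extinction 2).
US_ARCHETYPES <- c("Activated stable", "Activated down", "Activated up",
                   "Inhibited stable", "Inhibited up", "US off", "Null")
CS_ARCHETYPES <- c("Up", "Down inhibited", "Stable activated",
                   "First activated", "First inhibited", "Down activated",
                   "Null")
ACROSS_DAY_ARCHETYPES <- c("Tone activated", "Tone inhibited", "Fear",
                           "Fear inhibited", "Extinction",
                           "Extinction inhibited", "Stable activated",
                           "Stable inhibited", "Null")

#' Configuration of the synthetic multi-day recording generator
#'
#' Defaults emulate the recorded study conditions: 9 animals with 58
#' registered interneurons each, archetype mixtures matching the reported
#' cluster proportions (fractions of 519 recorded cells), GCaMP6f-like
#' transient kernel (0.1 s rise, 0.6 s decay), tones built from 200 ms pips
#' at 0.9 Hz, and unit-variance noise dominated by temporally white
#' photon-shot noise with a small slow AR(1) component capturing residual
#' calcium-like autocorrelation.
#'
#' @param n_animals,cells_per_animal Population size.
#' @param us_props,cs_plus_props,cs_minus_props,across_day_props Named
#'   archetype mixture proportions; each family must sum to 1.
#' @param amplitude Evoked amplitude in units of the noise s.d.
#' @param ramp Per-trial geometric decay factor of "Activated down".
#' @param noise List: `ar_coef`, `ar_sd` (marginal s.d. of the AR(1)
#'   component), `white_sd`; defaults give total variance 1.
#' @param kernel List: `rise_tau`, `decay_tau` in seconds.
#' @param sampling_rate Raw sampling rate (Hz).
#' @param bin_width Analysis bin width (s).
#' @param pip_rate,pip_duration Tone pip structure (Hz, s).
#' @param state_modulation Named numeric over across-day archetypes: sign of
#'   activity modulation during immobility (-1 = suppressed while immobile).
#' @param state_amplitude Magnitude of the immobility-state drive (noise-s.d.
#'   units).
#' @param behaviour List of pose-simulation parameters: `frame_rate`,
#'   `immobility_rate` (expected bouts per minute of inter-trial time),
#'   `immobile_mean_s`, `min_bout_s`, `mobile_speed` (px/frame range),
#'   `immobile_jitter_sd`, `dropout_rate`, `arena_px`.
#' @param seed Integer seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_animals = 9, cells_per_animal = 58,
                         us_props = c("Activated stable" = 70,
                                      "Activated down" = 112,
                                      "Activated up" = 36,
                                      "Inhibited stable" = 63,
                                      "Inhibited up" = 73,
                                      "US off" = 28, "Null" = 137) / 519,
                         cs_plus_props = c("Up" = 63, "Down inhibited" = 38,
                                           "Stable activated" = 72,
                                           "First activated" = 49,
                                           "First inhibited" = 44,
                                           "Down activated" = 0,
                                           "Null" = 253) / 519,
                         cs_minus_props = c("Up" = 88, "Down inhibited" = 61,
                                            "Stable activated" = 0,
                                            "First activated" = 39,
                                            "First inhibited" = 40,
                                            "Down activated" = 27,
                                            "Null" = 264) / 519,
                         across_day_props = c("Tone activated" = 65,
                                              "Tone inhibited" = 40,
                                              "Fear" = 66,
                                              "Fear inhibited" = 48,
                                              "Extinction" = 63,
                                              "Extinction inhibited" = 33,
                                              "Stable activated" = 0,
                                              "Stable inhibited" = 50,
                                              "Null" = 154) / 519,
                         amplitude = 3, ramp = 0.5,
                         noise = list(ar_coef = 0.9, ar_sd = 0.15,
                                      white_sd = sqrt(1 - 0.15^2)),
                         kernel = list(rise_tau = 0.1, decay_tau = 0.6),
                         sampling_rate = 20, bin_width = 0.25,
                         pip_rate = 0.9, pip_duration = 0.2,
                         state_modulation = c("Fear inhibited" = -1,
                                              "Extinction" = -1),
                         state_amplitude = 1.5,
                         behaviour = list(frame_rate = 20,
                                          immobility_rate = 1.5,
                                          immobile_mean_s = 3,
                                          min_bout_s = 2,
                                          mobile_speed = c(3, 8),
                                          immobile_jitter_sd = 0.15,
                                          dropout_rate = 0.02,
                                          arena_px = 400),
                         seed = 1L) {
  cfg <- list(n_animals = n_animals, cells_per_animal = cells_per_animal,
              us_props = us_props, cs_plus_props = cs_plus_props,
              cs_minus_props = cs_minus_props,
              across_day_props = across_day_props,
              amplitude = amplitude, ramp = ramp, noise = noise,
              kernel = kernel, sampling_rate = sampling_rate,
              bin_width = bin_width, pip_rate = pip_rate,
              pip_duration = pip_duration,
              state_modulation = state_modulation,
              state_amplitude = state_amplitude, behaviour = behaviour,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  check_props <- function(p, names_ok, family) {
    if (!all(names(p) %in% names_ok) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("invalid ", family, " archetype proportions (must be named, ",
           "non-negative and sum to 1)")
    }
  }
  check_props(cfg$us_props, US_ARCHETYPES, "US")
  check_props(cfg$cs_plus_props, CS_ARCHETYPES, "CS+")
  check_props(cfg$cs_minus_props, CS_ARCHETYPES, "CS-")
  check_props(cfg$across_day_props, ACROSS_DAY_ARCHETYPES, "across-day")
  with(cfg$kernel, {
    if (!(decay_tau > rise_tau && rise_tau > 0)) {
      stop("kernel requires decay_tau > rise_tau > 0")
    }
  })
  if (!is.finite(cfg$amplitude)) stop("amplitude must be finite")
  invisible(cfg)
}

#' Calcium indicator impulse response
#'
#' Difference-of-exponentials transient, peak-normalised to 1. The kernel
#' is truncated after at least five decay time constants, extended where
#' needed until the peak-normalised tail falls below 0.005 (peak
#' normalisation raises the raw tail, so a fixed five-tau cut can leave a
#' visible step). Defaults are GCaMP6f-like (0.1 s rise, 0.6 s decay);
#' slower indicators are obtained by raising `decay_tau`.
#'
#' @param rise_tau,decay_tau Rise and decay time constants (s);
#'   `decay_tau > rise_tau > 0`.
#' @param dt Sample interval (s).
#' @return Numeric kernel sampled at `dt`, starting at lag 0.
#' @export
calcium_kernel <- function(rise_tau = 0.1, decay_tau = 0.6, dt = 0.05) {
  if (!(decay_tau > rise_tau && rise_tau > 0)) {
    stop("require decay_tau > rise_tau > 0")
  }
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  t_end <- decay_tau * max(5, -log(0.005 * peak))
  t <- seq(0, t_end, by = dt)
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  k / max(k)
}

#' Per-trial amplitude schedule of a planted response archetype
#'
#' Encodes the trial-by-trial semantics of the archetype families:
#' "Activated stable" is constant, "Activated down" decays geometrically,
#' "Activated up" / "Inhibited up" ramp in magnitude, "First
#' activated"/"First inhibited" respond only on trial 1, "Down activated"
#' is positive then silent after trial 2, "Up"/"Down inhibited" ramp from
#' zero, inhibited archetypes carry negative sign, and "Null" is silent.
#' "US off" keeps a constant (positive) schedule; its response is placed
#' after stimulus offset by the generator.
#'
#' @param archetype One of the US or CS archetype names.
#' @param n_trials Number of trials (>= 1).
#' @param base_amp Base amplitude.
#' @param ramp Geometric factor for "Activated down" (< 1).
#' @return Numeric vector of per-trial amplitudes.
#' @export
archetype_amplitude_schedule <- function(archetype, n_trials, base_amp = 1,
                                         ramp = 0.5) {
  stopifnot(n_trials >= 1)
  n <- n_trials
  a <- base_amp
  switch(archetype,
    "Activated stable" = rep(a, n),
    "Activated down"   = a * ramp^(seq_len(n) - 1),
    "Activated up"     = a * seq_len(n) / n,
    "Inhibited stable" = rep(-a, n),
    "Inhibited up"     = -a * seq_len(n) / n,
    "US off"           = rep(a, n),
    "Up"               = if (n == 1) a else a * (seq_len(n) - 1) / (n - 1),
    "Down inhibited"   = if (n == 1) -a else -a * (seq_len(n) - 1) / (n - 1),
    "Stable activated" = rep(a, n),
    "First activated"  = c(a, rep(0, n - 1)),
    "First inhibited"  = c(-a, rep(0, n - 1)),
    "Down activated"   = c(rep(a, min(2, n)), rep(0, max(0, n - 2))),
    "Null"             = rep(0, n),
    stop("unknown archetype: ", archetype)
  )
}

## Day gate of an across-day archetype: signed multiplier of the CS response
## on non-conditioning days.
across_day_gate <- function(archetype, day_kind) {
  if (day_kind == "conditioning") return(0)
  on <- switch(archetype,
    "Tone activated"       = c(habituation = 1),
    "Tone inhibited"       = c(habituation = -1),
    "Fear"                 = c(test_ext1 = 1),
    "Fear inhibited"       = c(test_ext1 = -1),
    "Extinction"           = c(ext2 = 1),
    "Extinction inhibited" = c(ext2 = -1),
    "Stable activated"     = c(habituation = 1, test_ext1 = 1, ext2 = 1),
    "Stable inhibited"     = c(habituation = -1, test_ext1 = -1, ext2 = -1),
    "Null"                 = numeric(0),
    stop("unknown across-day archetype: ", archetype)
  )
  if (day_kind %in% names(on)) unname(on[day_kind]) else 0
}

## Add a pip-structured tone drive (200 ms pulses at pip_rate Hz for the
## 30 s tone) to a drive vector, scaled so the pip-train time average over
## the tone equals `amp`.
add_cs_drive <- function(drive, onset_s, amp, fs, pip_rate, pip_duration,
                         cs_duration = 30) {
  if (amp == 0) return(drive)
  duty <- pip_rate * pip_duration
  height <- amp / duty
  pip_starts <- seq(0, cs_duration - pip_duration, by = 1 / pip_rate)
  for (p in pip_starts) {
    i0 <- floor((onset_s + p) * fs) + 1L
    i1 <- ceiling((onset_s + p + pip_duration) * fs)
    idx <- i0:min(i1, length(drive))
    drive[idx] <- drive[idx] + height
  }
  drive
}

add_boxcar_drive <- function(drive, onset_s, offset_s, amp, fs) {
  if (amp == 0) return(drive)
  i0 <- floor(onset_s * fs) + 1L
  i1 <- ceiling(offset_s * fs)
  idx <- i0:min(i1, length(drive))
  drive[idx] <- drive[idx] + amp
  drive
}

## Build the noiseless 20 Hz drive of one archetype profile for one session.
## profile: list(cs_plus, cs_minus, us, across_day) archetype names.
session_drive <- function(profile, events, n_samples, cfg) {
  fs <- cfg$sampling_rate
  day <- unique(events$day_kind)[1]
  drive <- numeric(n_samples)
  for (lab in c("CS_PLUS", "CS_MINUS")) {
    ev <- events[events$label == lab, , drop = FALSE]
    if (nrow(ev) == 0L) next
    if (day == "conditioning") {
      arch <- if (lab == "CS_PLUS") profile$cs_plus else profile$cs_minus
      amps <- archetype_amplitude_schedule(arch, nrow(ev), cfg$amplitude,
                                           cfg$ramp)
    } else {
      gate <- across_day_gate(profile$across_day, day)
      amps <- rep(gate * cfg$amplitude, nrow(ev))
    }
    for (j in seq_len(nrow(ev))) {
      drive <- add_cs_drive(drive, ev$onset_s[j], amps[j], fs,
                            cfg$pip_rate, cfg$pip_duration)
    }
  }
  ev <- events[events$label == "US", , drop = FALSE]
  if (nrow(ev) > 0L && profile$us != "Null") {
    amps <- archetype_amplitude_schedule(profile$us, nrow(ev),
                                         cfg$amplitude, cfg$ramp)
    post_offset <- identical(profile$us, "US off")
    for (j in seq_len(nrow(ev))) {
      if (post_offset) {
        drive <- add_boxcar_drive(drive, ev$offset_s[j], ev$offset_s[j] + 2,
                                  amps[j], fs)
      } else {
        drive <- add_boxcar_drive(drive, ev$onset_s[j], ev$offset_s[j],
                                  amps[j], fs)
      }
    }
  }
  drive
}

## Convolve a drive (rate) with the calcium kernel normalised to unit area,
## so a sustained drive of height a produces a plateau of height a.
convolve_kernel <- function(drive, cfg) {
  dt <- 1 / cfg$sampling_rate
  k <- calcium_kernel(cfg$kernel$rise_tau, cfg$kernel$decay_tau, dt)
  k <- k / sum(k)
  out <- stats::filter(drive, k, method = "convolution", sides = 1)
  out <- as.numeric(out)
  out[is.na(out)] <- 0
  out
}

#' Generate a synthetic multi-day trace population with ground truth
#'
#' Per cell, an event-locked rate drive is assembled from the planted
#' archetypes (pip-structured for tones, boxcar for the US, across-day gated
#' on non-conditioning days), convolved with the calcium kernel, summed with
#' unit-variance noise (white + small AR(1)), optionally modulated during
#' planted immobility bouts, and passed through [preprocess_traces()].
#'
#' @param config A `synth_config`.
#' @param protocols Named list of `event_table`s keyed by day kind (any
#'   subset of the 4 days).
#' @param bouts Optional named list (by day kind) of data frames with
#'   `start_s`, `stop_s`: planted immobility intervals used to modulate
#'   state-sensitive cells.
#' @param truth Optional pre-specified archetype assignment: data frame with
#'   columns `animal`, `cell_id`, `us`, `cs_plus`, `cs_minus`, `across_day`
#'   (one row per cell). When omitted, archetypes are drawn from the
#'   configured proportions.
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `populations` (one [preprocess_traces()] result per
#'   animal), `ground_truth` (data frame incl. `state_sign`), and `bouts`.
#' @export
generate_population <- function(config, protocols, bouts = NULL,
                                truth = NULL, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  bad <- setdiff(names(protocols), DAY_KINDS)
  if (length(bad)) stop("unknown day kinds in protocols: ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  fs <- config$sampling_rate
  n_samples <- vapply(protocols, function(ev) {
    as.integer(round(attr(ev, "session_end_s") * fs))
  }, integer(1))

  if (is.null(truth)) {
    n_total <- config$n_animals * config$cells_per_animal
    draw <- function(p) sample(names(p), n_total, replace = TRUE, prob = p)
    truth <- data.frame(
      animal = rep(paste0("animal_", seq_len(config$n_animals)),
                   each = config$cells_per_animal),
      cell_id = paste0("cell_", rep(seq_len(config$cells_per_animal),
                                    config$n_animals)),
      us = draw(config$us_props),
      cs_plus = draw(config$cs_plus_props),
      cs_minus = draw(config$cs_minus_props),
      across_day = draw(config$across_day_props),
      stringsAsFactors = FALSE
    )
  }
  sm <- config$state_modulation
  truth$state_sign <- unname(ifelse(truth$across_day %in% names(sm),
                                    sm[truth$across_day], 0))

  ## one drive per unique archetype profile, shared by all cells carrying it
  prof_key <- with(truth, paste(us, cs_plus, cs_minus, across_day, sep = "|"))
  uniq <- !duplicated(prof_key)
  drives <- list()
  for (i in which(uniq)) {
    key <- prof_key[i]
    profile <- list(us = truth$us[i], cs_plus = truth$cs_plus[i],
                    cs_minus = truth$cs_minus[i],
                    across_day = truth$across_day[i])
    drives[[key]] <- lapply(names(protocols), function(day) {
      d <- session_drive(profile, protocols[[day]], n_samples[[day]], config)
      if (all(d == 0)) return(NULL)           # flat drive: skip convolution
      convolve_kernel(d, config)
    })
    names(drives[[key]]) <- names(protocols)
  }
  ## immobility-state drive (shared across cells; sign applied per cell)
  state_drive <- lapply(names(protocols), function(day) {
    b <- bouts[[day]]
    if (is.null(b) || nrow(b) == 0L) return(NULL)
    d <- numeric(n_samples[[day]])
    for (j in seq_len(nrow(b))) {
      d <- add_boxcar_drive(d, b$start_s[j], b$stop_s[j],
                            config$state_amplitude, fs)
    }
    convolve_kernel(d, config)
  })
  names(state_drive) <- names(protocols)

  phi <- config$noise$ar_coef
  inn_sd <- config$noise$ar_sd * sqrt(1 - phi^2)
  populations <- vector("list", config$n_animals)
  for (a in seq_len(config$n_animals)) {
    animal <- paste0("animal_", a)
    rows <- which(truth$animal == animal)
    raw <- lapply(names(protocols), function(day) {
      ns <- n_samples[[day]]
      noise <- matrix(stats::rnorm(ns * length(rows), 0,
                                   config$noise$white_sd), ns, length(rows))
      if (config$noise$ar_sd > 0) {
        ar <- stats::filter(
          matrix(stats::rnorm(ns * length(rows), 0, inn_sd), ns,
                 length(rows)), phi, method = "recursive")
        noise <- noise + matrix(as.numeric(ar), ns, length(rows))
      }
      for (jj in seq_along(rows)) {
        i <- rows[jj]
        sig <- drives[[prof_key[i]]][[day]]
        if (!is.null(sig)) noise[, jj] <- noise[, jj] + sig
        if (truth$state_sign[i] != 0 && !is.null(state_drive[[day]])) {
          noise[, jj] <- noise[, jj] +
            truth$state_sign[i] * state_drive[[day]]
        }
      }
      t(noise)
    })
    names(raw) <- names(protocols)
    centroids <- cbind(x = stats::runif(length(rows), 0, 500),
                       y = stats::runif(length(rows), 0, 500))
    populations[[a]] <- preprocess_traces(
      raw, bin_width = config$bin_width, sampling_rate_raw = fs,
      animal_id = animal, cell_ids = truth$cell_id[rows],
      centroids = centroids)
  }
  names(populations) <- paste0("animal_", seq_len(config$n_animals))
  list(populations = populations, ground_truth = truth, bouts = bouts)
}

#' Noiseless archetype templates in a given feature layout
#'
#' Simulates one noise-free cell per archetype through the identical
#' generation, preprocessing and alignment path used for the data, and
#' returns per-trial concatenated feature rows suitable for
#' [merge_and_label()].
#'
#' @param config A `synth_config` (its noise is zeroed internally).
#' @param protocols Named list of `event_table`s.
#' @param family `"us"`, `"cs_plus"` or `"cs_minus"`: which archetype family
#'   to instantiate (conditioning-day templates).
#' @param archetypes Archetype names (default: the non-Null members of the
#'   family).
#' @param align_args List of arguments forwarded to [align_to_events()]
#'   (label, session, windows).
#' @param trials Trial subset for the feature rows.
#' @return Matrix archetypes x features with archetype row names.
#' @export
archetype_feature_templates <- function(config, protocols,
                                        family = c("us", "cs_plus",
                                                   "cs_minus"),
                                        archetypes = NULL,
                                        align_args = list(), trials = NULL) {
  family <- match.arg(family)
  pool <- if (family == "us") US_ARCHETYPES else CS_ARCHETYPES
  if (is.null(archetypes)) archetypes <- setdiff(pool, "Null")
  cfg <- config
  cfg$noise <- list(ar_coef = 0, ar_sd = 0, white_sd = 0)
  cfg$n_animals <- 1L
  cfg$cells_per_animal <- length(archetypes)
  truth <- data.frame(
    animal = "animal_1", cell_id = paste0("cell_", seq_along(archetypes)),
    us = "Null", cs_plus = "Null", cs_minus = "Null", across_day = "Null",
    stringsAsFactors = FALSE
  )
  truth[[family]] <- archetypes
  gen <- suppressWarnings(
    generate_population(cfg, protocols, truth = truth, seed = cfg$seed))
  pop <- gen$populations[[1]]
  defaults <- if (family == "us") {
    list(label = "US", pre_window = 5, post_window = 7, baseline_window = 5)
  } else {
    list(label = if (family == "cs_plus") "CS_PLUS" else "CS_MINUS",
         pre_window = 30, post_window = 30, baseline_window = 30)
  }
  align_args <- utils::modifyList(defaults, align_args)
  tensor <- do.call(align_to_events,
                    c(list(pop = pop, events = protocols$conditioning,
                           session = "conditioning"), align_args))
  feats <- feature_matrix(list(tensor), layout = "per_trial", trials = trials)
  rownames(feats) <- archetypes
  feats
}

#' Construct CS/US tensors with a planted representational morph
#'
#' Builds population response tensors in which the CS population vector
#' moves linearly toward the US vector across presentations: the planted
#' morph levels are `0, (1-r)/3, 2(1-r)/3, 1-r, 1-r`, so the expected
#' normalised population-vector-distance change at pairings 4-5 is
#' `-100 * (1 - r)` percent. Variability is planted as per-bin jitter of
#' the morph coefficient (a noisy morph rate along the CS-US line), which
#' keeps the Euclidean distance exactly linear in the noise and hence the
#' recovery unbiased; isotropic off-line noise would inflate every
#' distance (`E||v + eps|| > ||v||`) and bias the change towards zero.
#'
#' @param n_cells Population size.
#' @param r Residual distance fraction at late conditioning (0 < r <= 1).
#' @param n_trials Number of CS presentations (default 5).
#' @param morph_jitter S.d. of the per-bin jitter of the morph coefficient.
#' @param us_noise_sd Isotropic noise on the US tensor (averaged out by the
#'   reference-vector mean).
#' @param bin_width Bin width (s); the CS window is 30 s, the US window 5 s.
#' @param seed Seed.
#' @return List with `cs_tensor`, `us_tensor` (classed `aligned_tensor`) and
#'   `expected_late_change` (percent).
#' @export
simulate_cs_us_morph <- function(n_cells = 50, r = 0.5, n_trials = 5,
                                 morph_jitter = 0.05, us_noise_sd = 0.1,
                                 bin_width = 0.25, seed = 1L) {
  stopifnot(r > 0, r <= 1)
  set.seed(seed)
  v_cs <- stats::rnorm(n_cells, 0, 1.5)
  v_us <- stats::rnorm(n_cells, 0, 1.5)
  morph <- c(0, (1 - r) / 3, 2 * (1 - r) / 3, 1 - r, 1 - r)[seq_len(n_trials)]
  n_cs_bins <- as.integer(30 / bin_width)
  n_us_bins <- as.integer(5 / bin_width)
  cs <- array(NA_real_, dim = c(n_cells, n_trials, n_cs_bins))
  for (j in seq_len(n_trials)) {
    m_bin <- morph[j] + stats::rnorm(n_cs_bins, 0, morph_jitter)
    cs[, j, ] <- outer(v_cs, 1 - m_bin) + outer(v_us, m_bin)
  }
  us <- array(stats::rnorm(n_cells * n_trials * n_us_bins, 0, us_noise_sd),
              dim = c(n_cells, n_trials, n_us_bins)) + as.vector(v_us)
  as_tensor <- function(arr, post) {
    n_bins <- dim(arr)[3]
    structure(arr, time = (seq_len(n_bins) - 1L) * bin_width,
              bin_width = bin_width, pre_window = 0, post_window = post,
              baseline_window = 0, label = "synthetic",
              class = "aligned_tensor")
  }
  list(cs_tensor = as_tensor(cs, 30), us_tensor = as_tensor(us, 5),
       expected_late_change = -100 * (1 - r))
}
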