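#' @keywords internal
"_PACKAGE"

## Canonical stimulus labels and day kinds used throughout the pipeline.
EVENT_LABELS <- c("CS_PLUS", "CS_MINUS", "US")
DAY_KINDS <- c("habituation", "conditioning", "test_ext1", "ext2")

#' Trial counts per stimulus for each day of the 4-day paradigm
#'
#' Habituation: 5 CS+ and 5 CS- tones, alternated. Conditioning: 5 CS+ each
#' followed by a US foot shock, interleaved with 5 CS-. Test/extinction days:
#' 4 CS- followed by 12 CS+.
#'
#' @param day_kind One of `"habituation"`, `"conditioning"`, `"test_ext1"`,
#'   `"ext2"`.
#' @return Named integer vector with elements `CS_PLUS`, `CS_MINUS`, `US`.
#' @export
day_trial_counts <- function(day_kind) {
  day_kind <- match.arg(day_kind, DAY_KINDS)
  switch(day_kind,
    habituation  = c(CS_PLUS = 5L,  CS_MINUS = 5L, US = 0L),
    conditioning = c(CS_PLUS = 5L,  CS_MINUS = 5L, US = 5L),
    test_ext1    = c(CS_PLUS = 12L, CS_MINUS = 4L, US = 0L),
    ext2         = c(CS_PLUS = 12L, CS_MINUS = 4L, US = 0L)
  )
}

#' Build the stimulus timeline for one session of the paradigm
#'
#' Lays out conditioned-stimulus (CS) tones of 30 s and, on the conditioning
#' day, 2 s unconditioned stimuli (US) that follow each CS+ offset at the
#' time of the next expected pip (one pip period, 1/0.9 s, later). Inter-trial
#' intervals are drawn uniformly from `iti_range`, after a 2 min baseline
#' before the first tone. Habituation alternates CS+/CS- starting with the
#' CS+; conditioning alternates starting with the CS+; test/extinction days
#' present 4 CS- followed by 12 CS+. The 200 ms / 0.9 Hz pip substructure of
#' the tones is a concern of the synthetic generator; each tone is recorded
#' here as a single 30 s event.
#'
#' @param day_kind One of `"habituation"`, `"conditioning"`, `"test_ext1"`,
#'   `"ext2"`.
#' @param iti_range Length-2 numeric, inter-trial interval range in seconds
#'   (default `c(60, 90)`).
#' @param seed Integer seed for the ITI draws.
#' @param session_id Session identifier stored in the table (defaults to
#'   `day_kind`).
#' @param baseline_s Baseline period before the first tone (s).
#' @param cs_duration_s,us_duration_s,us_lag_s Stimulus timing constants (s).
#' @return An `event_table`: data frame with columns `session_id`,
#'   `day_kind`, `label`, `onset_s`, `offset_s`, `trial_index`, sorted by
#'   onset, with attribute `session_end_s`.
#' @export
build_protocol <- function(day_kind, iti_range = c(60, 90), seed = NULL,
                           session_id = day_kind, baseline_s = 120,
                           cs_duration_s = 30, us_duration_s = 2,
                           us_lag_s = 1 / 0.9) {
  if (!is.character(day_kind) || length(day_kind) != 1L ||
      !day_kind %in% DAY_KINDS) {
    stop("unknown day_kind: must be one of ",
         paste(DAY_KINDS, collapse = ", "))
  }
  stopifnot(length(iti_range) == 2L, all(iti_range > 0),
            iti_range[1] <= iti_range[2])
  if (!is.null(seed)) set.seed(seed)

  cs_seq <- switch(day_kind,
    habituation  = rep(c("CS_PLUS", "CS_MINUS"), 5L),
    conditioning = rep(c("CS_PLUS", "CS_MINUS"), 5L),
    test_ext1    = c(rep("CS_MINUS", 4L), rep("CS_PLUS", 12L)),
    ext2         = c(rep("CS_MINUS", 4L), rep("CS_PLUS", 12L))
  )
  n_cs <- length(cs_seq)
  itis <- stats::runif(n_cs - 1L, iti_range[1], iti_range[2])
  onsets <- baseline_s + c(0, cumsum(cs_duration_s + itis))
  tab <- data.frame(
    session_id = session_id, day_kind = day_kind, label = cs_seq,
    onset_s = onsets, offset_s = onsets + cs_duration_s,
    trial_index = stats::ave(seq_len(n_cs), cs_seq, FUN = seq_along),
    stringsAsFactors = FALSE
  )
  if (day_kind == "conditioning") {
    plus <- tab[tab$label == "CS_PLUS", ]
    us <- data.frame(
      session_id = session_id, day_kind = day_kind, label = "US",
      onset_s = plus$offset_s + us_lag_s,
      offset_s = plus$offset_s + us_lag_s + us_duration_s,
      trial_index = plus$trial_index, stringsAsFactors = FALSE
    )
    tab <- rbind(tab, us)
  }
  tab <- tab[order(tab$onset_s), ]
  rownames(tab) <- NULL
  attr(tab, "session_end_s") <- max(tab$offset_s) + 60
  class(tab) <- c("event_table", "data.frame")
  validate_event_table(tab)
  tab
}

#' Validate an event table against the paradigm invariants
#'
#' Checks onset/offset ordering, stimulus durations (30 s CS, 2 s US),
#' CS+ -> US pairing on the conditioning day, and per-day trial counts.
#'
#' @param events An `event_table`.
#' @return The table, invisibly; errors describe the first violation.
#' @export
validate_event_table <- function(events) {
  required <- c("session_id", "day_kind", "label", "onset_s", "offset_s",
                "trial_index")
  missing <- setdiff(required, names(events))
  if (length(missing)) {
    stop("event table missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(events$label %in% EVENT_LABELS)) {
    stop("event table has unknown labels: ",
         paste(setdiff(events$label, EVENT_LABELS), collapse = ", "))
  }
  if (any(events$onset_s >= events$offset_s)) stop("onset_s must be < offset_s")
  if (is.unsorted(events$onset_s)) stop("event rows must be sorted by onset")
  dur <- events$offset_s - events$onset_s
  if (any(abs(dur[events$label != "US"] - 30) > 1e-9)) {
    stop("CS events must last 30 s")
  }
  if (any(abs(dur[events$label == "US"] - 2) > 1e-9)) {
    stop("US events must last 2 s")
  }
  day_kind <- unique(events$day_kind)
  if (length(day_kind) == 1L && day_kind %in% DAY_KINDS) {
    want <- day_trial_counts(day_kind)
    got <- vapply(names(want), function(l) sum(events$label == l), integer(1))
    if (!identical(unname(got), unname(want))) {
      stop(sprintf("trial counts %s do not match day_kind '%s'",
                   paste(got, collapse = "/"), day_kind))
    }
    if (day_kind == "conditioning") {
      plus_off <- events$offset_s[events$label == "CS_PLUS"]
      us_on <- events$onset_s[events$label == "US"]
      if (any(us_on <= plus_off - 1e-9)) {
        stop("each US onset must follow its paired CS_PLUS offset")
      }
    }
  }
  invisible(events)
}

#' Write / read event tables as TSV
#'
#' Columns `session_id`, `day_kind`, `label`, `onset_s`, `offset_s`,
#' `trial_index`; the session end time travels in a `# session_end_s:`
#' comment line.
#'
#' @param events An `event_table`.
#' @param path File path.
#' @return `read_event_table` returns an `event_table`.
#' @export
write_event_table <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# session_end_s: %.10g", attr(events, "session_end_s")),
             con)
  utils::write.table(as.data.frame(events), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  first <- readLines(path, n = 1L)
  end_s <- NA_real_
  if (startsWith(first, "# session_end_s:")) {
    end_s <- as.numeric(sub("# session_end_s:", "", first))
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab <- tab[order(tab$onset_s), ]
  rownames(tab) <- NULL
  if (is.na(end_s)) end_s <- max(tab$offset_s) + 60
  attr(tab, "session_end_s") <- end_s
  class(tab) <- c("event_table", "data.frame")
  validate_event_table(tab)
  tab
}

## Trial subsets used for balanced across-day comparisons: habituation uses
## the first four presentations of each CS, test/extinction 1 the first four
## CS+ (and the four CS-), extinction 2 the last four CS+.

#' Trial subset entering across-day comparisons
#'
#' @param day_kind Day of the paradigm.
#' @param stimulus `"CS_PLUS"` or `"CS_MINUS"`.
#' @param events Optional `event_table` used to check trial availability.
#' @return Integer vector of 1-based trial indices.
#' @export
across_day_trial_sets <- function(day_kind, stimulus = c("CS_PLUS", "CS_MINUS"),
                                  events = NULL) {
  day_kind <- match.arg(day_kind, DAY_KINDS)
  stimulus <- match.arg(stimulus)
  n_avail <- if (!is.null(events)) {
    sum(events$label == stimulus)
  } else {
    day_trial_counts(day_kind)[[stimulus]]
  }
  idx <- if (stimulus == "CS_MINUS") {
    1:4
  } else {
    switch(day_kind,
      habituation = 1:4,
      conditioning = 1:4,
      test_ext1 = 1:4,
      ext2 = 9:12
    )
  }
  if (n_avail < max(idx)) {
    stop(sprintf("day '%s' has only %d %s trials; need trial %d",
                 day_kind, n_avail, stimulus, max(idx)))
  }
  idx
}
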