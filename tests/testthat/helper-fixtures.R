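## Shared fixtures, built in code. Heavy objects are memoised per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

cond_protocol <- function() {
  fixture("cond_protocol", function() build_protocol("conditioning",
                                                     seed = 3))
}

## A tiny archetype-free config: all families Null unless overridden.
null_config <- function(n_cells = 20, seed = 1, ...) {
  synth_config(n_animals = 1, cells_per_animal = n_cells,
               us_props = c(Null = 1), cs_plus_props = c(Null = 1),
               cs_minus_props = c(Null = 1),
               across_day_props = c(Null = 1), seed = seed, ...)
}

## Hand-built aligned tensor with full control over values.
make_tensor <- function(arr, bin_width = 0.25, pre_window = 0,
                        baseline_window = 0, label = "test") {
  n_bins <- dim(arr)[3]
  n_pre <- as.integer(round(pre_window / bin_width))
  structure(arr,
            time = (seq_len(n_bins) - 1L - n_pre) * bin_width,
            bin_width = bin_width, pre_window = pre_window,
            post_window = (n_bins - n_pre) * bin_width,
            baseline_window = baseline_window, label = label,
            class = "aligned_tensor")
}

## Minimal classification object for overlap / subset tests.
make_classification <- function(responsive, direction = NULL,
                                cell_id = NULL) {
  n <- length(responsive)
  if (is.null(direction)) {
    direction <- ifelse(responsive, "activated", "none")
  }
  if (is.null(cell_id)) cell_id <- paste0("cell_", seq_len(n))
  structure(
    data.frame(cell_id = cell_id, n_significant = ifelse(responsive, 3L, 0L),
               responsive = responsive, direction = direction,
               stringsAsFactors = FALSE),
    class = c("response_classification", "data.frame"))
}
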