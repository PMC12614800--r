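#' Full pipeline configuration
#'
#' Collects every tunable parameter of the analysis with its default:
#' responsiveness (`alpha` 0.01, `min_significant` 3 presentations),
#' clustering (PCA `variance_threshold` 0.8; K-means k of 16 for US
#' patterns, 8 for conditioning CS patterns, 10 for across-day patterns, 5
#' for extinction dynamics), decoding (37-cell subsamples, 100 iterations,
#' 10-fold CV, 1 s decoding bins over 30 s windows), analysis windows
#' (0.25 s bins; 30 s CS, 5 s US, 2 s immobility AUC windows), and
#' behaviour (0.9 likelihood threshold, displacement threshold 2 px/frame
#' within the 0.7-3.5 calibration range, 2 s minimum bout). A config plus
#' seed fully serialises a run.
#'
#' @param seed Global seed.
#' @param synth A [synth_config()] describing the synthetic inputs.
#' @param stages Stages to run (subset of simulate, responsiveness,
#'   clustering, pvd, decoding, behaviour).
#' @param ... Overrides of the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, synth = synth_config(seed = seed),
                            stages = c("simulate", "responsiveness",
                                       "clustering", "pvd", "decoding",
                                       "behaviour"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed), synth = synth, stages = stages,
    alpha = 0.01, min_significant = 3L,
    variance_threshold = 0.8,
    k_us = 16L, k_cs = 8L, k_across_day = 10L, k_extinction = 5L,
    min_flow = 5L,
    n_cells = 37L, n_iterations = 100L, folds = 10L,
    bin_width = 0.25, decode_bin = 1,
    cs_window = 30, us_window = 5, imm_window = 2,
    cs_baseline = 30, us_baseline = 5,
    likelihood_threshold = 0.9, displacement_threshold = 2,
    min_bout_s = 2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load or simulate pipeline inputs
#'
#' In synthetic mode (the default), builds the 4-day protocol, behaviour
#' and trace populations from the config with ground truth attached. In
#' file mode, reads event tables, per-session trace CSVs and pose CSVs
#' from `paths` and validates them.
#'
#' @param config A `pipeline_config`.
#' @param paths Optional list for file mode: `events` (named by day),
#'   `traces` (list per animal: named by day), `pose` (named by day).
#' @return List with `protocols`, `behaviour` (pose + planted bouts per
#'   day), `populations`, `ground_truth` (synthetic mode only).
#' @export
load_inputs <- function(config, paths = NULL) {
  if (is.null(paths)) {
    protocols <- lapply(stats::setNames(nm = DAY_KINDS), function(day) {
      build_protocol(day, seed = config$seed + match(day, DAY_KINDS))
    })
    behaviour <- lapply(stats::setNames(nm = DAY_KINDS), function(day) {
      generate_behaviour(config$synth, protocols[[day]],
                         seed = config$seed + 100L + match(day, DAY_KINDS))
    })
    bouts <- lapply(behaviour, `[[`, "bouts")
    gen <- generate_population(config$synth, protocols, bouts = bouts,
                               seed = config$seed + 200L)
    list(protocols = protocols, behaviour = behaviour,
         populations = gen$populations, ground_truth = gen$ground_truth)
  } else {
    protocols <- lapply(paths$events, read_event_table)
    populations <- lapply(paths$traces, function(sess_files) {
      read_trace_population(sess_files, bin_width = config$bin_width)
    })
    behaviour <- if (!is.null(paths$pose)) {
      lapply(paths$pose, function(p) list(pose = read_pose(p), bouts = NULL))
    }
    list(protocols = protocols, behaviour = behaviour,
         populations = populations, ground_truth = NULL)
  }
}

#' Write / read a trace population as per-session CSV
#'
#' One CSV per session (rows = cells, first column `cell_id`), plus a
#' `centroids.csv` when centroids are present.
#'
#' @param pop A `trace_population`.
#' @param dir Output directory (created if needed).
#' @param files Named character vector/list: session name -> CSV path.
#' @param bin_width,sampling_rate_raw,animal_id Metadata for reading.
#' @return `read_trace_population` returns a `trace_population`.
#' @export
write_trace_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(pop$sessions)) {
    df <- data.frame(cell_id = pop$cell_ids,
                     round(pop$sessions[[s]], 8), check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0(s, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(pop$centroids)) {
    utils::write.csv(data.frame(cell_id = pop$cell_ids, pop$centroids),
                     file.path(dir, "centroids.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_trace_population
#' @export
read_trace_population <- function(files, bin_width = 0.25,
                                  sampling_rate_raw = 20,
                                  animal_id = "animal_1") {
  sessions <- list()
  cell_ids <- NULL
  for (s in names(files)) {
    df <- utils::read.csv(files[[s]], check.names = FALSE)
    if (!"cell_id" %in% names(df)) {
      stop("trace CSV ", files[[s]], " lacks a cell_id column")
    }
    ids <- as.character(df$cell_id)
    if (is.null(cell_ids)) {
      cell_ids <- ids
    } else if (!identical(ids, cell_ids)) {
      bad <- c(setdiff(cell_ids, ids), setdiff(ids, cell_ids))
      stop("session ", s, " disagrees on cells: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    m <- as.matrix(df[, setdiff(names(df), "cell_id"), drop = FALSE])
    rownames(m) <- ids
    sessions[[s]] <- m
  }
  structure(list(animal_id = animal_id, cell_ids = cell_ids,
                 sessions = sessions, bin_width = bin_width,
                 sampling_rate_raw = sampling_rate_raw, centroids = NULL),
            class = "trace_population")
}

## Classify one animal's cells for one stimulus on one day.
classify_stimulus <- function(pop, events, label, day, config,
                              trials = NULL) {
  is_us <- label == "US"
  tensor <- align_to_events(
    pop, events, label, session = day,
    pre_window = if (is_us) config$us_baseline else config$cs_baseline,
    post_window = if (is_us) config$us_window + 2 else config$cs_window,
    baseline_window = if (is_us) config$us_baseline else config$cs_baseline,
    trials = trials)
  test <- trial_response_test(
    tensor, evoked_window = if (is_us) 2 else config$cs_window,
    alpha = config$alpha)
  auc <- compute_auc(tensor, if (is_us) config$us_window else
    config$cs_window)
  list(tensor = tensor,
       classification = classify_cells(test, alpha = config$alpha,
                                       min_significant =
                                         config$min_significant,
                                       auc = auc),
       auc = auc)
}

#' Run the full analysis pipeline
#'
#' Executes the stages enabled in the config in dependency order on
#' synthetic (or loaded) inputs: simulate -> responsiveness (conditioning
#' CS+/CS-/US, overlap vs chance, spatial distances) -> clustering (US
#' response archetypes with template labels, per-animal fractions, flows)
#' -> PVD (conditioning change, ablations by US archetype, across days) ->
#' decoding (intra-day multiclass with subsample iterations, shuffled
#' controls, cross-day two-way transfer, weight selectivity) -> behaviour
#' (immobility detection, DS, immobility-aligned activity, across-session
#' stability, cluster-count/DS correlations). Stages whose prerequisites
#' were toggled off are skipped with a warning.
#'
#' @param config A `pipeline_config`.
#' @param inputs Optional pre-built [load_inputs()] result.
#' @param out_dir Optional directory: stage tables are written as TSV/JSON.
#' @return A `results_bundle`: list of stage outputs plus `provenance`
#'   (config hash, seed, package version) and `log` (per-stage timing).
#' @export
run_pipeline <- function(config, inputs = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- list()
  log <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    log[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  has <- function(s) s %in% config$stages

  if (is.null(inputs)) {
    if (!has("simulate")) stop("no inputs and 'simulate' stage disabled")
    inputs <- tick("simulate", load_inputs(config))
  }
  bundle$inputs <- inputs
  pops <- inputs$populations
  protocols <- inputs$protocols
  cond <- protocols$conditioning

  if (has("responsiveness")) {
    bundle$responsiveness <- tick("responsiveness", {
      per_animal <- lapply(pops, function(pop) {
        lapply(stats::setNames(nm = c("CS_PLUS", "CS_MINUS", "US")),
               function(lab) {
                 classify_stimulus(pop, cond, lab, "conditioning", config)
               })
      })
      cls <- lapply(per_animal, function(a) {
        lapply(a, `[[`, "classification")
      })
      overlap <- lapply(cls, function(a) {
        overlap_with_chance(a$CS_PLUS, a$CS_MINUS, a$US)
      })
      fractions <- responsive_fractions(cls, group_by = "animal")
      spatial <- lapply(names(pops), function(an) {
        groups <- ifelse(cls[[an]]$US$responsive, "US", NA)
        groups[cls[[an]]$CS_PLUS$responsive] <- "CS+"
        groups[cls[[an]]$CS_MINUS$responsive] <- "CS-"
        tryCatch(
          spatial_distance_distribution(pops[[an]]$centroids, groups),
          error = function(e) NULL)
      })
      stat <- tryCatch(group_comparison(
        fractions$fraction_responsive, fractions$stimulus,
        blocks = fractions$group, design = "repeated"),
        error = function(e) NULL)
      list(per_animal = per_animal, fractions = fractions,
           overlap = overlap, spatial = spatial,
           fraction_test = stat)
    })
  }

  if (has("clustering")) {
    if (is.null(bundle$responsiveness)) {
      warning("clustering skipped: responsiveness stage disabled")
    } else {
      bundle$clustering <- tick("clustering", {
        ra <- bundle$responsiveness$per_animal
        feats <- list(); animals <- character(0)
        for (an in names(pops)) {
          us <- ra[[an]]$US
          resp <- us$classification$responsive
          if (!any(resp)) next
          tensor <- align_to_events(pops[[an]], cond, "US",
                                    session = "conditioning",
                                    pre_window = config$us_baseline,
                                    post_window = config$us_window + 2,
                                    baseline_window = config$us_baseline)
          fm <- feature_matrix(list(tensor), layout = "per_trial")
          rownames(fm) <- paste(an, rownames(fm), sep = ".")
          feats[[an]] <- fm[resp, , drop = FALSE]
          animals <- c(animals,
                       stats::setNames(rep(an, sum(resp)),
                                       rownames(fm)[resp]))
        }
        x <- do.call(rbind, feats)
        k <- min(config$k_us, nrow(x) - 1L)
        model <- fit_cluster_model(x, k = k,
                                   variance_threshold =
                                     config$variance_threshold,
                                   seed = config$seed)
        templates <- archetype_feature_templates(
          config$synth, protocols, family = "us",
          align_args = list(pre_window = config$us_baseline,
                            post_window = config$us_window + 2,
                            baseline_window = config$us_baseline))
        labelled <- merge_and_label(model, templates = templates)
        fractions <- cluster_fractions_per_animal(labelled$labels, animals)
        list(model = model, labelled = labelled, animals = animals,
             fractions = fractions)
      })
    }
  }

  if (has("pvd")) {
    bundle$pvd <- tick("pvd", {
      per_animal <- lapply(names(pops), function(an) {
        pop <- pops[[an]]
        cs <- align_to_events(pop, cond, "CS_PLUS", session = "conditioning",
                              pre_window = config$cs_baseline,
                              post_window = config$cs_window,
                              baseline_window = config$cs_baseline)
        us <- align_to_events(pop, cond, "US", session = "conditioning",
                              pre_window = config$us_baseline,
                              post_window = config$us_window,
                              baseline_window = config$us_baseline)
        res <- pvd_conditioning(cs, us, us_window = config$us_window,
                                cs_window = config$cs_window)
        removals <- NULL
        if (!is.null(bundle$clustering)) {
          labs <- bundle$clustering$labelled$labels
          mine <- labs[startsWith(names(labs), paste0(an, "."))]
          names(mine) <- sub(paste0("^", an, "\\."), "", names(mine))
          removals <- split(names(mine), mine)
          removals <- removals[vapply(removals, length, 1L) <
                                 dim(cs)[1] - 1L]
        }
        ablation <- if (length(removals)) {
          pvd_ablation(cs, us, removals, us_window = config$us_window,
                       cs_window = config$cs_window)
        }
        us_vec <- us_reference_vector(us, window = config$us_window)
        day_tensors <- lapply(
          stats::setNames(nm = intersect(names(protocols),
                                         c("habituation", "test_ext1",
                                           "ext2"))),
          function(day) {
            align_to_events(pop, protocols[[day]], "CS_PLUS", session = day,
                            pre_window = config$cs_baseline,
                            post_window = config$cs_window,
                            baseline_window = config$cs_baseline,
                            trials = across_day_trial_sets(day, "CS_PLUS"))
          })
        across <- pvd_across_days(day_tensors, us_vec)
        list(conditioning = res, ablation = ablation, across_days = across)
      })
      names(per_animal) <- names(pops)
      per_animal
    })
  }

  if (has("decoding")) {
    bundle$decoding <- tick("decoding", {
      per_animal <- lapply(names(pops), function(an) {
        pop <- pops[[an]]
        n_cells <- min(config$n_cells, length(pop$cell_ids))
        accs <- matrix(NA_real_, config$n_iterations, 2,
                       dimnames = list(NULL, c("intraday", "shuffled")))
        for (i in seq_len(config$n_iterations)) {
          ds <- build_dataset(pop, cond, session = "conditioning",
                              n_cells = n_cells,
                              seed = config$seed + 1000L * i)
          accs[i, "intraday"] <- crossval_multiclass(
            ds, folds = config$folds, seed = config$seed + i)$accuracy
          accs[i, "shuffled"] <- shuffled_label_control(
            ds, n_shuffles = 1L, folds = config$folds,
            seed = config$seed + i)[1]
        }
        cross <- NULL
        if (all(c("test_ext1", "ext2") %in% names(protocols))) {
          ds_a <- build_dataset(pop, protocols$test_ext1,
                                session = "test_ext1",
                                classes = c("BASELINE", "CS_PLUS"),
                                n_cells = n_cells, seed = config$seed)
          ds_b <- build_dataset(pop, protocols$ext2, session = "ext2",
                                classes = c("BASELINE", "CS_PLUS"),
                                cells = ds_a$cells, seed = config$seed)
          tw <- train_twoway(ds_a)
          cross <- list(
            intraday = crossval_multiclass(ds_a, folds = config$folds,
                                           seed = config$seed),
            transfer = cross_day_evaluate(tw, ds_b))
        }
        selectivity <- weight_selectivity(
          pop, cond, session = "conditioning",
          n_iterations = min(config$n_iterations, 20L),
          n_cells = n_cells, seed = config$seed)
        list(accuracy = accs, cross_day = cross,
             selectivity = selectivity)
      })
      names(per_animal) <- names(pops)
      per_animal
    })
  }

  if (has("behaviour")) {
    bundle$behaviour <- tick("behaviour", {
      days <- intersect(names(protocols), c("habituation", "test_ext1",
                                            "ext2"))
      detected <- lapply(stats::setNames(nm = days), function(day) {
        bh <- inputs$behaviour[[day]]
        if (is.null(bh)) return(NULL)
        pose <- filter_pose(bh$pose, config$likelihood_threshold)
        disp <- displacement(pose)
        detect_immobility(disp, threshold = config$displacement_threshold,
                          min_duration = config$min_bout_s,
                          events = protocols[[day]],
                          frame_rate = bh$pose$frame_rate)
      })
      ds <- NULL
      if (!is.null(detected$test_ext1)) {
        imm_p <- immobility_fraction(detected$test_ext1,
                                     protocols$test_ext1, "CS_PLUS")
        imm_m <- immobility_fraction(detected$test_ext1,
                                     protocols$test_ext1, "CS_MINUS")
        ds <- discrimination_score(imm_p, imm_m)
      }
      aligned <- lapply(pops, function(pop) {
        tryCatch(immobility_aligned_activity(
          pop, detected, sessions = intersect(c("test_ext1", "ext2"),
                                              names(detected))),
          error = function(e) NULL)
      })
      stability <- NULL
      aucs <- lapply(names(pops), function(an) {
        al <- aligned[[an]]
        if (is.null(al)) return(NULL)
        ons <- al$onset$per_session_auc
        lapply(stats::setNames(nm = colnames(ons)), function(s) ons[, s])
      })
      names(aucs) <- names(pops)
      aucs <- Filter(Negate(is.null), aucs)
      if (length(aucs)) {
        stability <- tryCatch(stability_across_sessions(aucs),
                              error = function(e) NULL)
      }
      list(bouts = detected, discrimination_score = ds,
           aligned = aligned, stability = stability)
    })
  }

  bundle$provenance <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("fearca")))
  bundle$log <- log
  class(bundle) <- "results_bundle"
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

## Deterministic hash of a config: serialize to canonical JSON, md5 the file.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    unclass(x)
  }
}

#' Write the headline tables of a results bundle to disk
#'
#' Deterministic TSV/JSON exports: responsive fractions, overlap, cluster
#' assignments and fractions, PVD tables, decoder accuracies, immobility
#' bouts and DS, plus provenance JSON.
#'
#' @param bundle A `results_bundle`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(bundle$responsiveness)) {
    tsv(bundle$responsiveness$fractions, "responsive_fractions.tsv")
    ov <- do.call(rbind, Map(function(o, an) {
      data.frame(animal = an, as.data.frame(o))
    }, bundle$responsiveness$overlap,
    names(bundle$responsiveness$overlap)))
    tsv(ov, "overlap.tsv")
  }
  if (!is.null(bundle$clustering)) {
    lab <- bundle$clustering$labelled
    tsv(data.frame(cell_id = names(lab$labels),
                   raw_cluster = bundle$clustering$model$assignment,
                   final_label = lab$labels), "cluster_assignments.tsv")
    tsv(data.frame(animal = rownames(bundle$clustering$fractions),
                   bundle$clustering$fractions, check.names = FALSE),
        "cluster_fractions.tsv")
  }
  if (!is.null(bundle$pvd)) {
    pv <- do.call(rbind, Map(function(p, an) {
      data.frame(animal = an, as.data.frame(p$conditioning))
    }, bundle$pvd, names(bundle$pvd)))
    tsv(pv, "pvd_conditioning.tsv")
    across <- do.call(rbind, Map(function(p, an) {
      data.frame(animal = an, p$across_days)
    }, bundle$pvd, names(bundle$pvd)))
    tsv(across, "pvd_across_days.tsv")
  }
  if (!is.null(bundle$decoding)) {
    acc <- do.call(rbind, Map(function(d, an) {
      data.frame(animal = an,
                 mean_intraday = mean(d$accuracy[, "intraday"]),
                 mean_shuffled = mean(d$accuracy[, "shuffled"]),
                 selectivity = d$selectivity$mean_correlation)
    }, bundle$decoding, names(bundle$decoding)))
    tsv(acc, "decoder_accuracy.tsv")
  }
  if (!is.null(bundle$behaviour)) {
    for (day in names(bundle$behaviour$bouts)) {
      b <- bundle$behaviour$bouts[[day]]
      if (!is.null(b)) tsv(as.data.frame(b), paste0("bouts_", day, ".tsv"))
    }
    jsonlite::write_json(
      list(discrimination_score = bundle$behaviour$discrimination_score),
      file.path(out_dir, "behaviour.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.results_bundle <- function(x, ...) {
  stages <- setdiff(names(x), c("inputs", "provenance", "log"))
  cat("<results_bundle> stages:", paste(stages, collapse = ", "), "\n")
  cat("seed:", x$provenance$seed, " config:", x$provenance$config_hash, "\n")
  invisible(x)
}
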