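#' Default run configuration
#'
#' A run configuration drives the end-to-end pipeline: generator,
#' pattern, spike-inference, ISI-statistics, engram-classifier and
#' population sections plus a global seed. Stored as JSON
#' ([read_run_config()] / [write_run_config()]); unknown keys are
#' rejected before any computation.
#'
#' @param seed Global seed.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    generator = list(n_cells = 200, background_rate = 0.2,
                     test_pulse_rate = 0.5,
                     epoch_durations = c(test1 = 20, prestim = 60,
                                         stim = 10, poststim = 60,
                                         test2 = 20),
                     reverb_fraction = 0.3, reverb_duration = 20,
                     reverb_jitter_sd = 0.01,
                     component_assignment = "whole_pattern",
                     ei_fraction = 0.8, inhibitory_reverb_odds = 1,
                     stim_response_prob = 0.9, exposure = 0.02),
    pattern = list(kind = "single", frequency = 8, doublet_isi = NULL,
                   pattern_period = NULL, duration = 10),
    spikes = list(use_traces = FALSE, decay_tau = 0.5, threshold_sd = 4,
                  noise_sd = 0.1, rise_time_threshold = 1.0),
    paradigm = list(min_response_frac = 0.5, response_window = 0.1),
    isistats = list(min_matches = 2),
    engramnet = list(enabled = FALSE, null_kind = "isi_shuffle",
                     hidden = 64, max_epochs = 60, batch_size = 100,
                     learning_rate = 0.005, window_step = 0.02,
                     threshold = 0.5),
    population = list(overlap_measure = "jaccard")),
    class = "run_config")
}

#' @rdname default_run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- unclass(default_run_config())
  bad <- setdiff(names(raw), names(base))
  if (length(bad))
    stopf("unknown config section(s): %s", paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    if (is.list(base[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(base[[sec]]))
      if (length(bad))
        stopf("unknown key(s) in section '%s': %s", sec,
              paste(bad, collapse = ", "))
      for (k in names(raw[[sec]])) base[[sec]][[k]] <- raw[[sec]][[k]]
    } else base[[sec]] <- raw[[sec]]
  }
  ed <- base$generator$epoch_durations
  if (!is.null(names(ed))) base$generator$epoch_durations <- unlist(ed)
  structure(base, class = "run_config")
}

#' @rdname default_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  # named vectors would serialize as unnamed arrays; keep the names
  x$generator$epoch_durations <- as.list(x$generator$epoch_durations)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

config_pattern <- function(config) {
  p <- config$pattern
  stim_pattern(p$kind, frequency = p$frequency,
               doublet_isi = p$doublet_isi,
               pattern_period = p$pattern_period,
               duration = p$duration %||% 10)
}

config_generator <- function(config) {
  g <- config$generator
  generator_config(
    n_cells = g$n_cells, background_rate = g$background_rate,
    test_pulse_rate = g$test_pulse_rate,
    epoch_durations = g$epoch_durations,
    reverb_fraction = g$reverb_fraction,
    reverb_duration = g$reverb_duration,
    reverb_jitter_sd = g$reverb_jitter_sd,
    component_assignment = g$component_assignment,
    ei_fraction = g$ei_fraction,
    inhibitory_reverb_odds = g$inhibitory_reverb_odds,
    stim_response_prob = g$stim_response_prob, exposure = g$exposure,
    seed = config$seed)
}

#' Run the full analysis pipeline
#'
#' Executes generate (or ingest) -> (optionally render + infer) ->
#' segment -> ISI statistics -> (optionally train + scan) -> population
#' statistics, writing all result tables as CSV, reports as JSON and a
#' run manifest (seed, config, file checksums) into `out_dir`. Any stage
#' failure aborts with a stage-tagged message; outputs of completed
#' stages are preserved.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @param raster Optional externally supplied [spike_raster()]; when
#'   given, the generator stage is skipped and ground-truth-dependent
#'   outputs are omitted.
#' @param figures Also render figures via [make_figures()].
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir, raster = NULL, figures = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[stage %s] %s", name, conditionMessage(e)))
  }
  pattern <- stage("config", config_pattern(config))
  gen <- stage("config", config_generator(config))

  truth <- NULL
  if (is.null(raster)) {
    out <- stage("generate", generate_raster(gen, pattern))
    raster <- out$raster
    timeline <- out$timeline
    truth <- out$truth
  } else {
    timeline <- stage("generate", build_timeline(gen, pattern))
  }
  stage("generate", write_raster_csv(raster, file.path(out_dir,
                                                       "raster.csv")))

  if (isTRUE(config$spikes$use_traces)) {
    traces <- stage("render", render_calcium(
      raster, calcium_model(kernel_decay_tau = config$spikes$decay_tau,
                            noise_sd = config$spikes$noise_sd),
      seed = derive_seed(config$seed, 11L)))
    mask <- stage("infer", exclude_slow_waves(
      traces, config$spikes$rise_time_threshold))
    raster <- stage("infer", infer_spikes(
      traces, config$spikes$decay_tau, config$spikes$threshold_sd,
      mask = mask$keep_mask))
  }

  views <- stage("segment", segment(raster, timeline))
  active <- stage("segment", select_active(
    raster, timeline, config$paradigm$min_response_frac,
    config$paradigm$response_window))
  utils::write.csv(
    data.frame(cell_id = active$cells),
    file.path(out_dir, "active_cells.csv"), row.names = FALSE)

  bw <- raster$exposure
  mm <- config$isistats$min_matches
  periods <- if (pattern$kind == "single") {
    c(period = 1 / pattern$frequency)
  } else {
    c(d = pattern$doublet_isi,
      P = pattern$pattern_period)
  }
  act_isis <- function(v) compute_isis(v)[as.character(active$cells)]
  isi_rows <- list()
  reports <- list()
  stage("isistats", for (pn in names(periods)) {
    m <- lapply(views[c("prestim", "stim", "poststim")], function(v)
      match_cells_at_period(act_isis(v), periods[[pn]], bw, mm))
    rep <- reverberation_stats(
      m$prestim, m$stim, m$poststim, n_active = length(active$cells),
      durations = c(pre = diff(epoch_window(timeline, "prestim")),
                    stim = diff(epoch_window(timeline, "stim")),
                    post = diff(epoch_window(timeline, "poststim"))),
      frequency = 1 / periods[[pn]])
    reports[[pn]] <- rep
    for (ep in c("prestim", "stim", "poststim"))
      isi_rows[[length(isi_rows) + 1L]] <- data.frame(
        epoch = ep, component = pn, period_s = periods[[pn]],
        frequency_hz = 1 / periods[[pn]],
        n_isis_matched = m[[ep]]$n_isis, n_cells_matched = m[[ep]]$n_cells,
        pct_increase_total = rep$pct_increase_total,
        pct_cells_increase = rep$pct_cells_increase)
  })
  isi_tab <- do.call(rbind, isi_rows)
  utils::write.csv(isi_tab, file.path(out_dir, "isi_stats.csv"),
                   row.names = FALSE)

  detection <- NULL
  classifier <- NULL
  if (isTRUE(config$engramnet$enabled)) {
    en <- config$engramnet
    ts <- stage("train", build_training_set(
      raster, timeline, pattern, null_kind = en$null_kind,
      cells = active$cells, seed = derive_seed(config$seed, 23L)))
    classifier <- stage("train", train_engram_classifier(
      ts, classifier_spec(hidden = en$hidden, max_epochs = en$max_epochs,
                          batch_size = en$batch_size,
                          learning_rate = en$learning_rate,
                          seed = derive_seed(config$seed, 29L))))
    detection <- stage("scan", scan_raster(
      raster, classifier, window_step = en$window_step,
      threshold = en$threshold, cells = active$cells,
      timeline = timeline))
    utils::write.csv(detection$events,
                     file.path(out_dir, "engram_events.csv"),
                     row.names = FALSE)
    inc <- engram_increase(detection, timeline)
    jsonlite::write_json(inc, file.path(out_dir, "engram_increase.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  population <- NULL
  if (!is.null(truth)) {
    ann <- cell_annotations(raster$cell_ids, truth$cell_type)
    ei <- stage("population", lapply(
      views[c("prestim", "stim", "poststim")], function(v) {
        m <- match_cells_at_period(act_isis(v), periods[[1]], bw, mm)
        ei_ratio(m$cells, ann)
      }))
    population <- list(ei = ei)
    if (pattern$kind == "doublet")
      population$overlap <- stage("population", lapply(
        views[c("prestim", "stim", "poststim")], function(v)
          component_overlap(v, pattern, bw, mm,
                            measure = config$population$overlap_measure)))
    jsonlite::write_json(
      list(ei = ei,
           overlap = lapply(population$overlap, function(o)
             if (is.null(o)) NULL else o$overlap_pct)),
      file.path(out_dir, "population.json"), auto_unbox = TRUE,
      digits = NA)
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest <- list(
    package = "engramr",
    version = as.character(utils::packageVersion("engramr")),
    seed = config$seed,
    config = unclass(config),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  res <- list(raster = raster, timeline = timeline, truth = truth,
              active = active, isi_table = isi_tab, reports = reports,
              classifier = classifier, detection = detection,
              population = population, out_dir = out_dir)
  if (figures) make_figures(res, out_dir)
  invisible(res)
}

#' Render standard figures from a pipeline result
#'
#' Produces a raster plot with epoch shading, per-epoch ISI histograms
#' and (when a scan was run) a detection-confidence heatmap as PNG
#' files. Missing inputs are skipped with a warning; no statistics are
#' derived from figures.
#'
#' @param results List returned by [run_pipeline()].
#' @param out_dir Output directory (default: the run's).
#' @return Invisibly, the written file paths.
#' @export
make_figures <- function(results, out_dir = results$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  raster <- results$raster
  timeline <- results$timeline

  f <- file.path(out_dir, "raster.png")
  grDevices::png(f, width = 900, height = 600)
  graphics::plot(NULL, xlim = c(0, raster$duration),
                 ylim = c(0, raster$n_cells + 1), xlab = "time (s)",
                 ylab = "cell", main = "spike raster")
  if (!is.null(timeline)) {
    w <- epoch_window(timeline, "stim")
    graphics::rect(w[1], 0, w[2], raster$n_cells + 1,
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  for (i in seq_len(raster$n_cells)) {
    t <- raster$spikes[[i]]
    if (length(t))
      graphics::points(t, rep(i, length(t)), pch = "|", cex = 0.4)
  }
  grDevices::dev.off()
  written <- c(written, f)

  if (!is.null(timeline)) {
    views <- segment(raster, timeline)
    f <- file.path(out_dir, "isi_histograms.png")
    grDevices::png(f, width = 900, height = 350)
    graphics::par(mfrow = c(1, 3))
    for (ep in c("prestim", "stim", "poststim")) {
      h <- build_histogram(compute_isis(views[[ep]]), raster$exposure,
                           epoch = ep)
      keep <- h$mids <= 1.5
      graphics::barplot(h$counts[keep], names.arg = round(h$mids[keep], 2),
                        main = sprintf("ISI histogram (%s)", ep),
                        xlab = "ISI (s)", ylab = "count", border = NA)
    }
    grDevices::dev.off()
    written <- c(written, f)
  }

  if (!is.null(results$detection)) {
    dm <- results$detection
    f <- file.path(out_dir, "detection_map.png")
    grDevices::png(f, width = 900, height = 600)
    graphics::image(dm$window_starts, seq_len(nrow(dm$confidence)),
                    t(dm$confidence), col = grDevices::gray.colors(
                      64, start = 0, end = 1, rev = TRUE),
                    xlab = "time (s)", ylab = "cell",
                    main = "pattern-match confidence")
    grDevices::dev.off()
    written <- c(written, f)
  } else {
    warning("no detection map available; heatmap skipped", call. = FALSE)
  }
  invisible(written)
}
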