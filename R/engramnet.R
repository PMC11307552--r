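#' Build a classifier training set from the stimulation epoch
#'
#' Positive samples are the firing pattern of one cell for one cycle of
#' the stimulation pattern: the stim epoch is cut at pattern-cycle
#' boundaries into windows of one cycle length and binarized at
#' `bin_width` (0/1 per bin). One negative is generated per positive,
#' according to `null_kind`:
#'
#' * `isi_shuffle` -- the positive's ISIs (in bins) are permuted
#'   uniformly at random, preserving the ISI multiset and the first-spike
#'   offset. When no distinct permutation exists (fewer than two ISIs, or
#'   all ISIs equal -- e.g. a clean doublet cycle has a single ISI), the
#'   ISIs are instead re-drawn at random with the spike count and
#'   first-spike offset preserved, re-drawn until the binarized sequence
#'   differs from its source; sequences with fewer than two spikes fall
#'   back to uniform random placement. Without this fallback the null
#'   would reproduce sparse patterns verbatim and the two classes would
#'   be inseparable.
#' * `uniform_noise` -- spikes placed uniformly at random, preserving the
#'   spike count.
#' * `prestim_slices` -- windows cut at random from the prestimulation
#'   epoch of the same cell.
#'
#' Duplicate positives (e.g. from a jitter-free generator) are kept:
#' deduplication is disabled by default and no option is offered.
#'
#' @param raster A [spike_raster()].
#' @param timeline A [paradigm_timeline()].
#' @param pattern A [stim_pattern()] (defaults to the timeline's).
#' @param null_kind Negative-sample construction, see above.
#' @param cells Cell ids to use (default: all; normally the
#'   [select_active()] set).
#' @param bin_width Bin width in seconds (default: the raster exposure).
#' @param sequence_cap Maximum sequence length in bins (default 100); a
#'   pattern cycle exceeding `sequence_cap * bin_width` is rejected.
#' @param seed Integer seed for the null randomization.
#' @return An object of class `training_set`: `X` (0/1 matrix, samples x
#'   bins), `y` (factor `null`/`pattern`), `meta` (cell/cycle of each
#'   positive), `n_bins`, `bin_width`, `n_duplicate_negatives` (negatives
#'   identical to their source positive; only possible for empty cycles).
#' @export
build_training_set <- function(raster, timeline, pattern = timeline$pattern,
                               null_kind = c("isi_shuffle", "uniform_noise",
                                             "prestim_slices"),
                               cells = NULL, bin_width = raster$exposure,
                               sequence_cap = 100, seed = 1L) {
  null_kind <- match.arg(null_kind)
  stopifnot(inherits(raster, "spike_raster"),
            inherits(timeline, "paradigm_timeline"))
  cyc <- cycle_period(pattern)
  n_bins <- round(cyc / bin_width)
  if (n_bins > sequence_cap)
    stopf(paste0("pattern cycle (%g s) exceeds the sequence cap: %d bins",
                 " needed, cap is %d; increase bin_width or the cap"),
          cyc, n_bins, sequence_cap)
  if (n_bins < 2) stopf("pattern cycle must span at least 2 bins")
  sw <- epoch_window(timeline, "stim")
  n_cycles <- floor((sw[2] - sw[1]) / cyc + 1e-9)
  if (n_cycles < 1) stopf("stimulation epoch contains no complete cycle")
  ids <- cells %||% raster$cell_ids
  ids <- intersect(ids, raster$cell_ids)
  if (length(ids) == 0) stopf("no cells selected")
  if (pattern$kind == "single")
    warning(paste("single-frequency cycles carry one spike at a fixed",
                  "offset; the shuffle null is weakly informative for",
                  "them (intended use is doublet patterns)"), call. = FALSE)

  binarize <- function(t, start) binarize_window(t, start, n_bins, bin_width)
  pos <- matrix(0L, length(ids) * n_cycles, n_bins)
  meta <- data.frame(cell_id = rep(ids, each = n_cycles),
                     cycle = rep(seq_len(n_cycles), length(ids)))
  r <- 0L
  for (i in ids) {
    t <- raster$spikes[[as.character(i)]]
    for (k in seq_len(n_cycles)) {
      r <- r + 1L
      pos[r, ] <- binarize(t, sw[1] + (k - 1) * cyc)
    }
  }

  pw <- epoch_window(timeline, "prestim")
  neg <- matrix(0L, nrow(pos), n_bins)
  n_dup <- 0L
  with_seed_(seed, {
    for (r in seq_len(nrow(pos))) {
      neg[r, ] <- switch(null_kind,
        isi_shuffle = shuffle_sequence(pos[r, ]),
        uniform_noise = {
          v <- integer(n_bins)
          k <- sum(pos[r, ])
          if (k > 0) v[sample.int(n_bins, k)] <- 1L
          v
        },
        prestim_slices = {
          i <- meta$cell_id[r]
          start <- stats::runif(1, pw[1], pw[2] - n_bins * bin_width)
          binarize(raster$spikes[[as.character(i)]], start)
        })
      if (identical(neg[r, ], pos[r, ])) n_dup <- n_dup + 1L
    }
  })
  structure(list(X = rbind(pos, neg),
                 y = factor(rep(c("pattern", "null"), each = nrow(pos)),
                            levels = c("null", "pattern")),
                 meta = meta, n_bins = n_bins, bin_width = bin_width,
                 null_kind = null_kind, pattern = pattern,
                 n_duplicate_negatives = n_dup),
            class = "training_set")
}

# Binarize spikes into one classifier window. Bins are centered on the
# window grid (spikes collected from [start - bw/2, start + nb*bw - bw/2),
# bin = round(rel/bw) + 1): pattern-locked spikes sit by construction on
# bin-edge times, and centering makes their bin assignment robust to
# sub-bin jitter instead of knife-edged.
binarize_window <- function(t, start, n_bins, bin_width) {
  rel <- t - start
  rel <- rel[rel >= -bin_width / 2 & rel < n_bins * bin_width - bin_width / 2]
  v <- integer(n_bins)
  if (length(rel))
    v[unique(pmin(pmax(as.integer(round(rel / bin_width)) + 1L, 1L),
                  n_bins))] <- 1L
  v
}

# ISI shuffle of one binarized sequence (0/1 vector). Permutes inter-spike
# gaps when a distinct permutation exists; otherwise re-draws the gaps at
# random (count and first-spike offset preserved), avoiding the original
# arrangement.
shuffle_sequence <- function(v) {
  n <- length(v)
  s <- which(v == 1L)
  k <- length(s)
  out <- integer(n)
  if (k == 0) return(out)
  if (k >= 2 && length(unique(diff(s))) > 1) {
    gaps <- sample(diff(s))
    idx <- s[1] + cumsum(c(0L, gaps))
  } else if (k >= 2) {
    # all gaps equal: permutation degenerate; re-draw spike positions
    # after the (preserved) first spike
    for (try in 1:20) {
      idx <- c(s[1], sort(sample((s[1] + 1L):n, k - 1L)))
      if (!identical(idx, s)) break
    }
  } else {
    # single spike: uniform random position
    for (try in 1:20) {
      idx <- sample.int(n, 1L)
      if (!identical(idx, s)) break
    }
  }
  out[idx] <- 1L
  out
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf(
    "<training_set> %d samples (%d positive) x %d bins of %g s, null = %s\n",
    nrow(x$X), sum(x$y == "pattern"), x$n_bins, x$bin_width, x$null_kind))
  invisible(x)
}

#' Train the engram classifier
#'
#' Trains the bidirectional recurrent sequence classifier on a
#' [build_training_set()] and reports per-epoch loss and accuracy.
#' Training is considered successful when held-out accuracy on
#' target-pattern sequences reaches at least 99% (and, typically,
#' prediction on the training patterns is 100% accurate). If the epoch
#' ceiling is reached without convergence the final weights are kept and
#' the report flags the failure.
#'
#' @param ts A [build_training_set()] result.
#' @param spec A [classifier_spec()].
#' @param validation Optional second `training_set` (same binning) used
#'   for held-out evaluation after training.
#' @param verbose Print per-epoch progress.
#' @return An object of class `engram_classifier`: `params` (weights),
#'   `history`, `converged`, `train_accuracy`, `pattern_accuracy`
#'   (accuracy on the positive training patterns alone), optional
#'   `validation_accuracy`, plus the binning metadata needed by
#'   [scan_raster()].
#' @export
train_engram_classifier <- function(ts, spec = classifier_spec(),
                                    validation = NULL, verbose = FALSE) {
  stopifnot(inherits(ts, "training_set"), inherits(spec, "classifier_spec"))
  y <- as.integer(ts$y == "pattern")
  fit <- rnn_train(ts$X, y, spec, verbose = verbose)
  pr <- rnn_predict_probs(fit$params, ts$X)
  pred <- as.integer(pr[, 2] >= 0.5)
  train_acc <- mean(pred == y)
  pattern_acc <- mean(pred[y == 1] == 1)
  val_acc <- NA_real_
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "training_set"),
              validation$n_bins == ts$n_bins)
    yv <- as.integer(validation$y == "pattern")
    prv <- rnn_predict_probs(fit$params, validation$X)
    val_acc <- mean((prv[, 2] >= 0.5) == (yv == 1))
  }
  structure(list(params = fit$params, spec = spec, history = fit$history,
                 converged = fit$converged, train_accuracy = train_acc,
                 pattern_accuracy = pattern_acc,
                 validation_accuracy = val_acc,
                 n_bins = ts$n_bins, bin_width = ts$bin_width,
                 pattern = ts$pattern),
            class = "engram_classifier")
}

#' @export
print.engram_classifier <- function(x, ...) {
  cat(sprintf(
    "<engram_classifier> %d bins of %g s; %d epochs, train acc %.1f%%, pattern acc %.1f%%%s\n",
    x$n_bins, x$bin_width, nrow(x$history), 100 * x$train_accuracy,
    100 * x$pattern_accuracy,
    if (!is.na(x$validation_accuracy))
      sprintf(", held-out acc %.1f%%", 100 * x$validation_accuracy) else ""))
  invisible(x)
}

#' Classify sequences with a trained engram classifier
#'
#' @param object An `engram_classifier`.
#' @param X 0/1 matrix, samples x `n_bins`.
#' @param ... Unused.
#' @return Numeric vector of P(pattern) per row.
#' @export
predict.engram_classifier <- function(object, X, ...) {
  stopifnot(is.matrix(X), ncol(X) == object$n_bins)
  rnn_predict_probs(object$params, X)[, 2]
}

#' Sliding-window engram scan of a recording
#'
#' Each cell's spike sequence is swept with a window of one pattern
#' length, advanced in steps of `window_step` (10--50 ms), and each
#' window is scored by the classifier; contiguous (time-overlapping or
#' touching) suprathreshold windows on the same cell are merged into one
#' engram event with an interval, a peak confidence, and the epoch
#' containing its peak-confidence window. Two kinds of window are
#' assigned confidence 0 without being scored: windows with fewer than
#' `min_spikes` spikes (they cannot contain the pattern), and windows
#' whose first spike does not fall in the first bin -- every training
#' sequence starts with the pattern's first spike, so only spike-aligned
#' windows are in-distribution for the classifier, and the sliding grid
#' guarantees an aligned window exists for every candidate event.
#'
#' @param raster A [spike_raster()].
#' @param classifier A trained [train_engram_classifier()].
#' @param window_step Step between window starts, seconds (default 0.02).
#' @param threshold Detection probability threshold (default 0.5).
#' @param cells Cell ids to scan (default all).
#' @param timeline Optional [paradigm_timeline()] used to label events
#'   with their epoch.
#' @param min_spikes Minimum spikes per scored window (default 2).
#' @param chunk Prediction batch size.
#' @return An object of class `detection_map`: `confidence` (cells x
#'   windows), `window_starts`, `window_length`, `step`, `threshold` and
#'   `events` (data frame `cell_id`, `start_s`, `end_s`, `peak_conf`,
#'   `peak_s`, `epoch`).
#' @export
scan_raster <- function(raster, classifier, window_step = 0.02,
                        threshold = 0.5, cells = NULL, timeline = NULL,
                        min_spikes = 2, chunk = 4096L) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(classifier, "engram_classifier"))
  assert_scalar_num(window_step, "window_step", 0, strict_lower = TRUE)
  assert_prob(threshold, "threshold")
  bw <- classifier$bin_width
  nb <- classifier$n_bins
  win <- nb * bw
  ids <- cells %||% raster$cell_ids
  starts <- seq(0, raster$duration - win, by = window_step)
  conf <- matrix(0, length(ids), length(starts))
  rownames(conf) <- as.character(ids)

  # collect aligned windows holding >= min_spikes spikes, batch-predict
  rows <- list()
  where <- list()
  for (ci in seq_along(ids)) {
    t <- raster$spikes[[as.character(ids[ci])]]
    if (length(t) < min_spikes) next
    # spike count per window over [s - bw/2, s + win - bw/2)
    lo <- findInterval(starts - bw / 2 - 1e-12, t)
    hi <- findInterval(starts + win - bw / 2 - 1e-12, t)
    # aligned: some spike in the first (centered) bin [s - bw/2, s + bw/2)
    first <- findInterval(starts + bw / 2 - 1e-12, t)
    sel <- which(hi - lo >= min_spikes & first > lo)
    for (w in sel) {
      rows[[length(rows) + 1L]] <- binarize_window(t, starts[w], nb, bw)
      where[[length(where) + 1L]] <- c(ci, w)
    }
  }
  if (length(rows)) {
    X <- do.call(rbind, rows)
    p <- rnn_predict_probs(classifier$params, X, chunk = chunk)[, 2]
    for (j in seq_along(where))
      conf[where[[j]][1], where[[j]][2]] <- p[j]
  }

  ev <- list()
  for (ci in seq_along(ids)) {
    hot <- which(conf[ci, ] >= threshold)
    if (length(hot) == 0) next
    # merge windows whose intervals overlap or touch
    brk <- c(0, which(diff(starts[hot]) > win + 1e-9), length(hot))
    for (k in seq_len(length(brk) - 1)) {
      grp <- hot[(brk[k] + 1):brk[k + 1]]
      pk <- grp[which.max(conf[ci, grp])]
      ev[[length(ev) + 1L]] <- data.frame(
        cell_id = ids[ci], start_s = starts[grp[1]],
        end_s = starts[grp[length(grp)]] + win,
        peak_conf = conf[ci, pk], peak_s = starts[pk])
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cell_id = integer(0), start_s = numeric(0),
               end_s = numeric(0), peak_conf = numeric(0),
               peak_s = numeric(0))
  events$epoch <- rep(NA_character_, nrow(events))
  if (!is.null(timeline) && nrow(events) > 0) {
    # label each event by the epoch of its peak-confidence window
    for (i in seq_len(nrow(events))) {
      e <- timeline$epochs
      hit <- which(events$peak_s[i] >= e$start_s & events$peak_s[i] < e$end_s)
      if (length(hit)) events$epoch[i] <- e$epoch[hit[1]]
    }
  }
  structure(list(confidence = conf, window_starts = starts,
                 window_length = win, step = window_step,
                 threshold = threshold, events = events, cell_ids = ids),
            class = "detection_map")
}

#' @export
print.detection_map <- function(x, ...) {
  cat(sprintf(
    "<detection_map> %d cells x %d windows (%.0f ms step), %d events at threshold %.2f\n",
    nrow(x$confidence), ncol(x$confidence), 1000 * x$step,
    nrow(x$events), x$threshold))
  invisible(x)
}

#' Percent increase in engram events, poststimulation vs prestimulation
#'
#' Event counts from epochs of unequal duration are rate-normalised to a
#' common 60 s. Two denominators are offered because the normalisation
#' behind the headline percent-increase is not uniquely determined:
#' `"prestim"` (default) divides by `max(n_pre, 1)`; `"stim"` mirrors
#' the ISI-statistic formula and divides by the stimulation-epoch event
#' count.
#'
#' @param events Event data frame from [scan_raster()] (with `epoch`),
#'   or a `detection_map`.
#' @param timeline A [paradigm_timeline()].
#' @param denominator `"prestim"` or `"stim"`.
#' @return List with `pct_increase`, `n_pre`, `n_post`, `n_stim` (raw
#'   counts) and `denominator`.
#' @export
engram_increase <- function(events, timeline,
                            denominator = c("prestim", "stim")) {
  denominator <- match.arg(denominator)
  if (inherits(events, "detection_map")) events <- events$events
  stopifnot(is.data.frame(events), inherits(timeline, "paradigm_timeline"))
  dur <- function(ep) diff(epoch_window(timeline, ep))
  cnt <- function(ep) sum(events$epoch == ep, na.rm = TRUE)
  n_pre <- cnt("prestim"); n_post <- cnt("poststim"); n_stim <- cnt("stim")
  r_pre <- n_pre * 60 / dur("prestim")
  r_post <- n_post * 60 / dur("poststim")
  pct <- switch(denominator,
    prestim = 100 * (r_post - r_pre) / max(r_pre, 1),
    stim = if (n_stim > 0) 100 * (r_post - r_pre) / n_stim else NA_real_)
  list(pct_increase = pct, n_pre = n_pre, n_post = n_post,
       n_stim = n_stim, denominator = denominator)
}
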