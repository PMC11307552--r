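#' Per-cell inter-spike intervals
#'
#' ISIs are successive differences of the sorted spike times of each cell
#' within an epoch; cells with fewer than two spikes yield empty lists.
#'
#' @param x A [spike_raster()] or epoch view from [segment()].
#' @return Named list (by cell id) of numeric ISI vectors, seconds.
#' @examples
#' r <- spike_raster(list(c(0, 0.33, 0.66)), duration = 1)
#' compute_isis(r)
#' @export
compute_isis <- function(x) {
  stopifnot(inherits(x, "spike_raster"))
  lapply(x$spikes, function(t) if (length(t) < 2) numeric(0) else diff(t))
}

#' Build an ISI histogram
#'
#' Uniform bins of width `bin_width` starting at zero, half-open
#' `[edge, edge + bin_width)`. By convention the bin width matches the
#' frame exposure of the recording (~0.02 s). Raw ISIs are retained so
#' that peak locations can be reported free of half-bin quantization (see
#' [isi_peaks()]).
#'
#' @param isis Numeric vector of ISIs, or a per-cell list as returned by
#'   [compute_isis()] (pooled).
#' @param bin_width Bin width in seconds.
#' @param epoch Optional epoch label carried in the result.
#' @return An object of class `isi_histogram` with fields `bin_width`,
#'   `edges`, `mids`, `counts`, `n_isis`, `epoch`, `isis`.
#' @export
build_histogram <- function(isis, bin_width, epoch = NA_character_) {
  assert_scalar_num(bin_width, "bin_width", 0, strict_lower = TRUE)
  isis <- unlist(isis, use.names = FALSE)
  isis <- isis[is.finite(isis) & isis >= 0]
  if (length(isis) == 0) {
    return(structure(list(bin_width = bin_width, edges = c(0, bin_width),
                          mids = bin_width / 2, counts = 0L, n_isis = 0L,
                          epoch = epoch, isis = numeric(0)),
                     class = "isi_histogram"))
  }
  n_bins <- max(1L, ceiling(max(isis) / bin_width + 1e-9))
  edges <- (0:n_bins) * bin_width
  idx <- pmin(pmax(findInterval(isis, edges, rightmost.closed = FALSE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_width = bin_width, edges = edges,
                 mids = edges[-1] - bin_width / 2, counts = counts,
                 n_isis = length(isis), epoch = epoch, isis = isis),
            class = "isi_histogram")
}

#' @export
print.isi_histogram <- function(x, ...) {
  cat(sprintf("<isi_histogram> %d ISIs, %d bins of %g s", x$n_isis,
              length(x$counts), x$bin_width))
  if (!is.na(x$epoch)) cat(sprintf(" (epoch %s)", x$epoch))
  cat("\n")
  if (x$n_isis > 0)
    cat(sprintf("  modal bin: [%g, %g) s, %d ISIs\n",
                x$edges[modal_bin(x)], x$edges[modal_bin(x) + 1],
                max(x$counts)))
  invisible(x)
}

#' Modal bin of an ISI histogram
#'
#' Ties are broken toward the lower bin index.
#'
#' @param h An [build_histogram()] result.
#' @return Integer bin index (1-based), or `NA` for an empty histogram.
#' @export
modal_bin <- function(h) {
  stopifnot(inherits(h, "isi_histogram"))
  if (h$n_isis == 0) return(NA_integer_)
  which.max(h$counts)
}

#' Histogram peaks and their locations
#'
#' Local maxima of the bin counts (ties toward the lower bin; no
#' smoothing, the bin width is already coarse), filtered to peaks holding
#' at least `min_peak_frac` of the modal count. The reported `location`
#' of a peak is the mean of the ISIs inside its bin, which is free of the
#' half-bin bias a bin-center convention would impose on period-locked
#' trains whose ISIs fall exactly on bin edges.
#'
#' @param h An `isi_histogram`.
#' @param min_peak_frac Minimum count relative to the modal bin for a
#'   local maximum to be reported (default 0.05).
#' @return Data frame with `bin`, `center`, `location`, `count`, ordered
#'   by increasing interval.
#' @export
isi_peaks <- function(h, min_peak_frac = 0.05) {
  stopifnot(inherits(h, "isi_histogram"))
  n <- length(h$counts)
  if (h$n_isis == 0)
    return(data.frame(bin = integer(0), center = numeric(0),
                      location = numeric(0), count = integer(0)))
  c0 <- h$counts
  left <- c(-1, c0[-n])
  right <- c(c0[-1], -1)
  is_peak <- c0 > left & c0 >= right & c0 >= min_peak_frac * max(c0) &
    c0 > 0
  bins <- which(is_peak)
  data.frame(
    bin = bins,
    center = h$mids[bins],
    location = vapply(bins, function(b) {
      inb <- h$isis >= h$edges[b] & h$isis < h$edges[b + 1]
      mean(h$isis[inb])
    }, numeric(1)),
    count = c0[bins])
}

#' Match cells and ISIs at a target period
#'
#' An ISI matches the target period iff `|ISI - period| <= bin_width`
#' (the "+/- 1 bin" rule, alignment-free and symmetric); a cell matches
#' iff it has at least `min_matches` matching ISIs (default 2 -- a single
#' chance interval under Poisson background should not call a cell).
#'
#' @param x A [spike_raster()] / epoch view, or a per-cell ISI list.
#' @param period Target period in seconds (e.g. `1/frequency`).
#' @param bin_width Histogram bin width in seconds.
#' @param min_matches Minimum matching ISIs per matched cell.
#' @return An object of class `period_match`: `n_isis` (total matching
#'   ISIs), `n_cells` (matched cells), `cells` (their ids), `per_cell`
#'   (matching-ISI count per cell), plus the query parameters.
#' @export
match_cells_at_period <- function(x, period, bin_width, min_matches = 2) {
  assert_scalar_num(period, "period", 0, strict_lower = TRUE)
  assert_scalar_num(bin_width, "bin_width", 0, strict_lower = TRUE)
  isis <- if (inherits(x, "spike_raster")) compute_isis(x) else x
  stopifnot(is.list(isis))
  ids <- names(isis) %||% as.character(seq_along(isis))
  per_cell <- vapply(isis, function(v)
    sum(abs(v - period) <= bin_width + 1e-12), integer(1))
  names(per_cell) <- ids
  matched <- per_cell >= min_matches
  structure(list(n_isis = sum(per_cell), n_cells = sum(matched),
                 cells = ids[matched], per_cell = per_cell,
                 period = period, bin_width = bin_width,
                 min_matches = min_matches),
            class = "period_match")
}

#' @export
print.period_match <- function(x, ...) {
  cat(sprintf(
    "<period_match> period %g s: %d matching ISIs, %d matched cells\n",
    x$period, x$n_isis, x$n_cells))
  invisible(x)
}

#' Reverberation statistics across paradigm epochs
#'
#' Quantifies the increase in stimulation-frequency firing after the
#' stimulus. The headline statistic divides the difference between
#' poststimulation and prestimulation matched counts by the count during
#' stimulation:
#' `pct_increase_total = 100 * (n_post - n_pre) / n_stim`,
#' normalising for how much of the network the stimulus actually drove.
#' The companion recruitment statistic normalises matched-cell gain by
#' the number of viable cells:
#' `pct_cells_increase = 100 * (cells_post - cells_pre) / n_active`.
#' Both are reported because "increase in ISIs normalised by active
#' cells" is ambiguous between them. Pre/post ISI counts from epochs of
#' unequal duration are rate-normalised to a common 60 s before
#' comparison; cell counts are not (a cell either recruits or not), so
#' unequal pre/post durations are flagged.
#'
#' @param pre,stim,post [match_cells_at_period()] results for the
#'   prestim, stim and poststim epochs.
#' @param n_active Number of viable cells (from [select_active()]).
#' @param durations Named epoch durations in seconds,
#'   `c(pre=, stim=, post=)` (default 60/10/60).
#' @param frequency Optional frequency label (Hz) carried in the report.
#' @return An object of class `reverberation_report`.
#' @examples
#' mk <- function(n_isis, n_cells) structure(list(n_isis = n_isis,
#'   n_cells = n_cells, per_cell = integer(0), cells = character(0)),
#'   class = "period_match")
#' reverberation_stats(mk(5, 3), mk(50, 40), mk(30, 12), n_active = 50)
#' @export
reverberation_stats <- function(pre, stim, post, n_active,
                                durations = c(pre = 60, stim = 10,
                                              post = 60),
                                frequency = NA_real_) {
  stopifnot(inherits(pre, "period_match"), inherits(stim, "period_match"),
            inherits(post, "period_match"))
  assert_scalar_num(n_active, "n_active", 0)
  n_pre <- pre$n_isis * 60 / durations[["pre"]]
  n_post <- post$n_isis * 60 / durations[["post"]]
  n_stim <- stim$n_isis
  pct_total <- if (n_stim > 0) 100 * (n_post - n_pre) / n_stim else NA_real_
  cells_pre <- pre$n_cells
  cells_post <- post$n_cells
  pct_cells <- if (n_active > 0)
    100 * (cells_post - cells_pre) / n_active else NA_real_
  structure(list(
    frequency = frequency,
    n_pre = n_pre, n_stim = n_stim, n_post = n_post,
    cells_pre = cells_pre, cells_stim = stim$n_cells,
    cells_post = cells_post, n_active = n_active,
    pct_increase_total = pct_total,
    pct_cells_increase = pct_cells,
    note = if (n_stim == 0)
      "no matched ISIs during stimulation: pct_increase_total undefined"
      else NA_character_,
    unequal_pre_post = durations[["pre"]] != durations[["post"]],
    per_cell_flags = list(pre = pre$cells, stim = stim$cells,
                          post = post$cells)),
    class = "reverberation_report")
}

#' @export
print.reverberation_report <- function(x, ...) {
  cat("<reverberation_report>")
  if (!is.na(x$frequency)) cat(sprintf(" %g Hz", x$frequency))
  cat(sprintf("\n  matched ISIs  pre/stim/post: %.1f / %d / %.1f\n",
              x$n_pre, x$n_stim, x$n_post))
  cat(sprintf("  matched cells pre/stim/post: %d / %d / %d (of %d active)\n",
              x$cells_pre, x$cells_stim, x$cells_post, x$n_active))
  cat(sprintf("  pct_increase_total: %s\n",
              if (is.na(x$pct_increase_total)) paste0("NA (", x$note, ")")
              else sprintf("%.1f%%", x$pct_increase_total)))
  cat(sprintf("  pct_cells_increase: %.1f%%\n", x$pct_cells_increase))
  invisible(x)
}

#' Decompose a doublet-pattern ISI histogram into its component peaks
#'
#' A doublet pattern with within-doublet interval `d` and period `P`
#' produces ISI peaks at `d` (the high-frequency component), `P - d`
#' (end of one doublet to start of the next) and -- when individual
#' spikes fail -- `P` (one pattern repeat to the next). For each target
#' the histogram mass within +/- 1 bin is reported together with whether
#' the target sits on a local maximum and its rank among local maxima.
#'
#' @param h An `isi_histogram`.
#' @param pattern A [stim_pattern()]. For a single-frequency pattern only
#'   the single period `1/frequency` is reported.
#' @return Data frame with `component`, `period_s`, `mass`, `is_peak`,
#'   `rank` (rank among local maxima by count; `NA` if not a peak).
#' @export
decompose_components <- function(h, pattern) {
  stopifnot(inherits(h, "isi_histogram"), inherits(pattern, "stim_pattern"))
  targets <- if (pattern$kind == "doublet") {
    c(d = pattern$doublet_isi,
      `P-d` = pattern$pattern_period - pattern$doublet_isi,
      P = pattern$pattern_period)
  } else c(period = 1 / pattern$frequency)
  peaks <- isi_peaks(h, min_peak_frac = 0)
  peaks <- peaks[order(-peaks$count), , drop = FALSE]
  bw <- h$bin_width
  rows <- lapply(seq_along(targets), function(j) {
    tg <- targets[j]
    mass <- sum(h$counts[h$mids > tg - bw - bw / 2 &
                           h$mids < tg + bw + bw / 2])
    hit <- which(abs(peaks$location - tg) <= bw + 1e-12)
    data.frame(component = names(targets)[j], period_s = unname(tg),
               mass = mass, is_peak = length(hit) > 0,
               rank = if (length(hit)) min(hit) else NA_integer_)
  })
  do.call(rbind, rows)
}

#' Brute-force oracle for period matching
#'
#' Independent reference for [match_cells_at_period()]: an explicit
#' double loop over consecutive spike pairs. Quadratic bookkeeping, for
#' verification on small rasters only.
#'
#' @inheritParams match_cells_at_period
#' @return Same structure as [match_cells_at_period()].
#' @export
match_cells_bruteforce <- function(x, period, bin_width, min_matches = 2) {
  isis_per_cell <- if (inherits(x, "spike_raster")) {
    lapply(x$spikes, function(t) {
      if (length(t) < 2) return(numeric(0))
      t <- sort(t)
      out <- numeric(0)
      for (k in 2:length(t)) out <- c(out, t[k] - t[k - 1])
      out
    })
  } else x
  n_isis <- 0L
  matched <- character(0)
  per_cell <- integer(length(isis_per_cell))
  ids <- names(isis_per_cell) %||% as.character(seq_along(isis_per_cell))
  for (i in seq_along(isis_per_cell)) {
    m <- 0L
    for (v in isis_per_cell[[i]])
      if (abs(v - period) <= bin_width + 1e-12) m <- m + 1L
    per_cell[i] <- m
    n_isis <- n_isis + m
    if (m >= min_matches) matched <- c(matched, ids[i])
  }
  names(per_cell) <- ids
  structure(list(n_isis = n_isis, n_cells = length(matched),
                 cells = matched, per_cell = per_cell, period = period,
                 bin_width = bin_width, min_matches = min_matches),
            class = "period_match")
}
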