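#' Construct a spike raster
#'
#' A spike raster holds per-cell sorted spike times (seconds) over a
#' recording of known duration, together with the frame exposure of the
#' underlying imaging.
#'
#' @param spikes List of numeric vectors, one per cell, of spike times in
#'   seconds. Times must lie in `[0, duration]` and be strictly increasing
#'   within a cell.
#' @param duration Recording duration in seconds.
#' @param exposure Frame exposure in seconds (default 0.02, i.e. 50 fps).
#' @param cell_ids Optional integer cell identifiers (default `1:n`).
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, duration, exposure = 0.02, cell_ids = NULL) {
  stopifnot(is.list(spikes))
  assert_scalar_num(duration, "duration", 0, strict_lower = TRUE)
  assert_scalar_num(exposure, "exposure", 0, strict_lower = TRUE)
  spikes <- lapply(spikes, function(t) sort(as.numeric(t)))
  for (t in spikes) {
    if (length(t) && (min(t) < 0 || max(t) > duration + 1e-9))
      stopf("spike times must lie within [0, duration]")
    if (anyDuplicated(t))
      stopf("spike times must be strictly increasing per cell")
  }
  ids <- as.integer(cell_ids %||% seq_along(spikes))
  stopifnot(length(ids) == length(spikes))
  names(spikes) <- as.character(ids)
  structure(list(spikes = spikes, n_cells = length(spikes),
                 duration = duration, exposure = exposure,
                 cell_ids = ids),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  n <- sum(lengths(x$spikes))
  cat(sprintf("<spike_raster> %d cells, %d spikes, %.1f s at %.0f fps\n",
              x$n_cells, n, x$duration, 1 / x$exposure))
  invisible(x)
}

#' Total spike count of a raster
#' @param raster A [spike_raster()].
#' @return Integer spike count over all cells.
#' @export
n_spikes <- function(raster) sum(lengths(raster$spikes))

#' Write / read a spike raster as CSV
#'
#' The interchange format is a two-column CSV with header
#' `cell_id,spike_time_s`, one row per spike.
#'
#' @param raster A [spike_raster()].
#' @param path Output file path.
#' @return `write_raster_csv` returns `path` invisibly; `read_raster_csv`
#'   returns a [spike_raster()].
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  df <- data.frame(
    cell_id = rep(raster$cell_ids, lengths(raster$spikes)),
    spike_time_s = unlist(raster$spikes, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @param duration,exposure Recording metadata; `duration` defaults to the
#'   last spike time rounded up to the next frame.
#' @export
read_raster_csv <- function(path, duration = NULL, exposure = 0.02) {
  df <- utils::read.csv(path)
  if (!all(c("cell_id", "spike_time_s") %in% names(df)))
    stopf("raster CSV must have columns cell_id, spike_time_s")
  ids <- sort(unique(as.integer(df$cell_id)))
  spikes <- split(df$spike_time_s, factor(df$cell_id, levels = ids))
  if (is.null(duration))
    duration <- ceiling(max(df$spike_time_s, 0) / exposure) * exposure
  spike_raster(spikes, duration = duration, exposure = exposure,
               cell_ids = ids)
}

# Drop spikes closer than `refractory` to the previous retained spike of
# the same cell (physiological floor; prevents degenerate zero ISIs).
enforce_refractory <- function(times, refractory = 0.005) {
  if (length(times) < 2) return(times)
  times <- sort(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}
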