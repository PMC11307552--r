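#' Cell-type annotations
#'
#' @param cell_id Integer cell ids.
#' @param type Character vector: `"excitatory"`, `"inhibitory"` or
#'   `"unknown"`.
#' @param source `"synthetic"` (generator ground truth) or `"imported"`.
#' @return Data frame of class `cell_annotations` with one row per cell.
#' @export
cell_annotations <- function(cell_id, type,
                             source = c("synthetic", "imported")) {
  source <- match.arg(source)
  stopifnot(length(cell_id) == length(type))
  if (anyDuplicated(cell_id)) stopf("one annotation per cell required")
  ok <- c("excitatory", "inhibitory", "unknown")
  if (!all(type %in% ok))
    stopf("type must be one of: %s", paste(ok, collapse = ", "))
  structure(data.frame(cell_id = as.integer(cell_id), type = type,
                       source = source),
            class = c("cell_annotations", "data.frame"))
}

#' Import annotations from a CSV (`cell_id,type`)
#' @param path CSV path.
#' @return A [cell_annotations()] object.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("cell_id", "type") %in% names(df)))
    stopf("annotation CSV must have columns cell_id, type")
  cell_annotations(df$cell_id, df$type, source = "imported")
}

#' Excitatory percentage of a matched cell set
#'
#' Computes `100 * |excitatory matched| / |typed matched|`; cells of
#' unknown type are excluded from the denominator and reported
#' separately.
#'
#' @param matched_cells Cell ids (integer or character) of the matched
#'   population, e.g. `match_cells_at_period(...)$cells`.
#' @param annotations A [cell_annotations()] object covering the cells.
#' @return List with `pct_excitatory` (`NA` when no matched cell is
#'   typed), `n_excitatory`, `n_inhibitory`, `n_unknown`.
#' @examples
#' ann <- cell_annotations(1:10, rep(c("excitatory", "inhibitory"),
#'                                   c(8, 2)))
#' ei_ratio(1:10, ann)
#' @export
ei_ratio <- function(matched_cells, annotations) {
  stopifnot(inherits(annotations, "cell_annotations"))
  ids <- as.integer(matched_cells)
  ty <- annotations$type[match(ids, annotations$cell_id)]
  ty[is.na(ty)] <- "unknown"
  ne <- sum(ty == "excitatory")
  ni <- sum(ty == "inhibitory")
  nu <- sum(ty == "unknown")
  list(pct_excitatory = if (ne + ni > 0) 100 * ne / (ne + ni) else NA_real_,
       n_excitatory = ne, n_inhibitory = ni, n_unknown = nu)
}

#' Overlap between high- and low-frequency component populations
#'
#' For a doublet pattern, identifies within one epoch the cells firing at
#' the high-frequency component (ISIs matching `doublet_isi`) and at the
#' low-frequency component (ISIs matching `pattern_period`), and computes
#' the percentage overlap between the two populations. Because the
#' overlap statistic is not algebraically pinned down by its typical
#' reported values, three measures are provided; Jaccard
#' (`100 * |A ∩ B| / |A ∪ B|`) is the symmetric default, with
#' `min_denominator` (`/ min(|A|, |B|)`) and `mean_denominator`
#' (`/ mean(|A|, |B|)`) as alternatives.
#'
#' @param x Epoch view ([segment()]) or [spike_raster()].
#' @param pattern A doublet [stim_pattern()].
#' @param bin_width Histogram bin width in seconds.
#' @param min_matches Minimum matching ISIs per cell (default 2).
#' @param measure Overlap measure (default `"jaccard"`).
#' @return An object of class `overlap_report`: `set_high`, `set_low`,
#'   `overlap_pct` (`NA` when both sets are empty), `measure`.
#' @export
component_overlap <- function(x, pattern, bin_width, min_matches = 2,
                              measure = c("jaccard", "min_denominator",
                                          "mean_denominator")) {
  measure <- match.arg(measure)
  stopifnot(inherits(pattern, "stim_pattern"))
  if (pattern$kind != "doublet")
    stopf("component_overlap requires a doublet pattern")
  hi <- match_cells_at_period(x, pattern$doublet_isi, bin_width,
                              min_matches)
  lo <- match_cells_at_period(x, pattern$pattern_period, bin_width,
                              min_matches)
  structure(list(set_high = hi$cells, set_low = lo$cells,
                 overlap_pct = overlap_measure(hi$cells, lo$cells, measure),
                 measure = measure),
            class = "overlap_report")
}

# Overlap of two id sets under the chosen measure; NA when both empty.
overlap_measure <- function(a, b, measure) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  inter <- length(intersect(a, b))
  den <- switch(measure,
    jaccard = length(union(a, b)),
    min_denominator = min(length(a), length(b)),
    mean_denominator = mean(c(length(a), length(b))))
  if (den == 0) return(0)
  100 * inter / den
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> |high| = %d, |low| = %d, overlap = %s (%s)\n",
    length(x$set_high), length(x$set_low),
    if (is.na(x$overlap_pct)) "NA" else sprintf("%.1f%%", x$overlap_pct),
    x$measure))
  invisible(x)
}
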