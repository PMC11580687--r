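#' Per-window numeric track on a genomic grid
#'
#' Holds one numeric value per window on a regular grid of 0-based half-open
#' intervals `[start, start + window_bp)`. Windows may overlap when
#' `step_bp < window_bp` (as in the 100-kb / 10-kb FST scan); the last window
#' may be truncated at `chrom_length` and is flagged.
#'
#' @param chrom Chromosome name (single string).
#' @param starts Integer vector of 0-based window starts, strictly increasing
#'   multiples of `step_bp`.
#' @param values Numeric vector, one value per window (`NaN`/`NA` allowed
#'   where a window is empty or a denominator was zero).
#' @param window_bp Window size in bp.
#' @param step_bp Step between window starts in bp (defaults to `window_bp`,
#'   i.e. non-overlapping windows).
#' @param n_items Optional per-window item count (SNPs, reads, features).
#' @param chrom_length Optional chromosome length used to flag a truncated
#'   terminal window.
#'
#' @return An object of class `window_track`.
#' @export
window_track <- function(chrom, starts, values, window_bp,
                         step_bp = window_bp, n_items = NULL,
                         chrom_length = NA_real_) {
  starts <- as.numeric(starts)
  if (length(starts) && any(diff(starts) <= 0))
    stop("window starts must be strictly increasing")
  if (length(starts) && any(starts %% step_bp != 0))
    stop("window starts must be multiples of step_bp")
  if (length(values) != length(starts))
    stop("values length != starts length")
  if (!is.null(n_items) && length(n_items) != length(starts))
    stop("n_items length != starts length")
  structure(
    list(chrom = as.character(chrom), starts = starts,
         values = as.numeric(values), window_bp = as.numeric(window_bp),
         step_bp = as.numeric(step_bp), n_items = n_items,
         chrom_length = as.numeric(chrom_length)),
    class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat("<window_track> ", x$chrom, ": ", length(x$starts), " windows of ",
      x$window_bp, " bp (step ", x$step_bp, " bp)\n", sep = "")
  invisible(x)
}

#' @export
length.window_track <- function(x) length(x$starts)

#' Window end coordinates (0-based half-open, truncated at chrom_length)
#' @param track A [window_track()].
#' @return Numeric vector of window ends.
#' @export
window_ends <- function(track) {
  ends <- track$starts + track$window_bp
  if (!is.na(track$chrom_length)) ends <- pmin(ends, track$chrom_length)
  ends
}

#' Window center coordinates
#'
#' The representative coordinate of each window, `start + window_bp / 2`.
#' Boundary calling reports SLR limits at window centers, which undoes the
#' smearing that overlapping windows introduce at sharp transitions.
#'
#' @param track A [window_track()].
#' @return Numeric vector of window centers in bp.
#' @export
window_centers <- function(track) track$starts + track$window_bp / 2

# TRUE for windows truncated by the chromosome end.
window_is_partial <- function(track) {
  if (is.na(track$chrom_length)) rep(FALSE, length(track$starts))
  else track$starts + track$window_bp > track$chrom_length
}

check_same_grid <- function(a, b) {
  if (!identical(a$chrom, b$chrom) || length(a$starts) != length(b$starts) ||
      any(a$starts != b$starts) || a$window_bp != b$window_bp)
    stop("window tracks are not on the same grid")
  invisible(TRUE)
}
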