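#' Bin item positions or per-base weights into windows
#'
#' Counts items (reads, SNPs, features) falling in consecutive non-overlapping
#' windows of `window_bp`. The terminal partial window is kept (and flagged
#' through the track's `chrom_length`), so the window sums always add up to
#' the total input count.
#'
#' @param positions Numeric vector of 0-based item positions in
#'   `[0, chrom_length)`.
#' @param chrom_length Chromosome length in bp.
#' @param window_bp Window size in bp (> 0).
#' @param weights Optional per-item weights (default 1 per item).
#' @param chrom Chromosome name for the returned track.
#' @return A [window_track()] of per-window counts (or weight sums).
#' @export
bin_counts <- function(positions, chrom_length, window_bp, weights = NULL,
                       chrom = "chr") {
  stopifnot(window_bp > 0, chrom_length > 0)
  if (length(positions) && (any(positions < 0) ||
                            any(positions >= chrom_length)))
    stop("positions must lie in [0, chrom_length)")
  n_win <- ceiling(chrom_length / window_bp)
  starts <- (seq_len(n_win) - 1) * window_bp
  idx <- floor(positions / window_bp) + 1L
  if (is.null(weights)) {
    counts <- tabulate(idx, nbins = n_win)
  } else {
    stopifnot(length(weights) == length(positions))
    counts <- as.numeric(tapply(weights, factor(idx, levels = seq_len(n_win)),
                                sum, default = 0))
  }
  window_track(chrom, starts, counts, window_bp,
               n_items = tabulate(idx, nbins = n_win),
               chrom_length = chrom_length)
}

#' Chromosome quotient (CQ) from female and male coverage tracks
#'
#' The CQ of a window is the female:male coverage ratio, optionally
#' normalised by the total mapped counts of each sex so that differences in
#' sequencing effort between the sex pools cancel:
#' `CQ_w = (F_w / sum(F)) / (M_w / sum(M))`. With reads mapped to the X
#' haplotype, CQ is expected near 2 in X-linked windows, near 1 in autosomal
#' (and pseudo-autosomal) windows, and near 0 in Y-specific windows.
#' `M_w = 0` with `F_w > 0` yields `Inf`; `0/0` yields `NaN`.
#'
#' @param female,male [window_track()]s of per-window read counts on the same
#'   grid.
#' @param normalize Normalise each sex by its total count (default `TRUE`).
#' @return An object of class `cq_profile`: list with the CQ `track`, the
#'   normalisation totals and a `labels` slot (filled by
#'   [classify_cq_windows()]).
#' @export
chromosome_quotient <- function(female, male, normalize = TRUE) {
  stopifnot(inherits(female, "window_track"), inherits(male, "window_track"))
  check_same_grid(female, male)
  f_tot <- sum(female$values); m_tot <- sum(male$values)
  scale <- if (normalize) {
    if (f_tot <= 0 || m_tot <= 0)
      stop("cannot normalize: a sex has zero total coverage")
    m_tot / f_tot
  } else 1
  cq <- scale * female$values / male$values
  cq[female$values == 0 & male$values == 0] <- NaN
  track <- window_track(female$chrom, female$starts, cq, female$window_bp,
                        step_bp = female$step_bp,
                        chrom_length = female$chrom_length)
  structure(list(track = track, female_total = f_tot, male_total = m_tot,
                 normalized = normalize, labels = NULL),
            class = "cq_profile")
}

#' @export
print.cq_profile <- function(x, ...) {
  cat("<cq_profile> ", length(x$track$starts), " windows; mean CQ = ",
      signif(mean(x$track$values[is.finite(x$track$values)]), 4), "\n",
      sep = "")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Classify CQ windows as X-like, autosomal-like, Y-specific or ambiguous
#'
#' Operationalises the 2 / 1 / 0 coverage-dose expectations: windows with
#' `CQ <= low` are called `Y_specific`, `CQ >= high` are `X_like`, windows in
#' `auto_band` are `autosomal_like`, everything else (including `NaN`) is
#' `ambiguous`.
#'
#' @param profile A `cq_profile` from [chromosome_quotient()].
#' @param low,high Lower/upper thresholds (defaults 0.3 and 1.6; require
#'   `0 < low < 1 < high`).
#' @param auto_band Length-2 numeric band around 1 for the autosomal call.
#' @return The profile with its `labels` slot filled (factor per window).
#' @export
classify_cq_windows <- function(profile, low = 0.3, high = 1.6,
                                auto_band = c(0.7, 1.3)) {
  stopifnot(inherits(profile, "cq_profile"), low > 0, low < 1, high > 1,
            auto_band[1] < 1, auto_band[2] > 1)
  cq <- profile$track$values
  lab <- rep("ambiguous", length(cq))
  lab[!is.nan(cq) & cq <= low] <- "Y_specific"
  lab[!is.nan(cq) & cq >= high] <- "X_like"
  lab[!is.nan(cq) & cq >= auto_band[1] & cq <= auto_band[2]] <-
    "autosomal_like"
  profile$labels <- factor(lab, levels = c("X_like", "autosomal_like",
                                           "Y_specific", "ambiguous"))
  profile
}

#' Fraction of each window covered by features
#'
#' Computes, per window, the fraction of bases covered by features of the
#' requested kinds; overlapping features are merged before counting, and a
#' feature spanning a window boundary contributes proportionally to both
#' windows. Used for the TE-density / gene-density tracks that support
#' pericentromere inference.
#'
#' @param features Feature data frame as returned by [read_features()].
#' @param chrom_length Chromosome length in bp.
#' @param window_bp Window size in bp.
#' @param kinds Optional character vector restricting the feature kinds used.
#' @param chrom Chromosome to compute on (defaults to the first in
#'   `features`).
#' @return A [window_track()] of densities in `[0, 1]`.
#' @export
feature_density <- function(features, chrom_length, window_bp, kinds = NULL,
                            chrom = NULL) {
  if (is.null(chrom))
    chrom <- if (nrow(features)) features$chrom[1L] else "chr"
  keep <- features$chrom == chrom
  if (!is.null(kinds)) keep <- keep & features$kind %in% kinds
  feats <- features[keep, , drop = FALSE]
  n_win <- ceiling(chrom_length / window_bp)
  starts <- (seq_len(n_win) - 1) * window_bp
  ends <- pmin(starts + window_bp, chrom_length)
  if (nrow(feats) == 0)
    return(window_track(chrom, starts, rep(0, n_win), window_bp,
                        n_items = rep(0L, n_win),
                        chrom_length = chrom_length))
  # merge overlaps, then intersect merged pieces with the window grid
  fir <- IRanges::reduce(IRanges::IRanges(start = feats$start + 1,
                                          end = pmin(feats$end, chrom_length)))
  wir <- IRanges::IRanges(start = starts + 1, end = ends)
  ov <- IRanges::findOverlaps(wir, fir)
  inter <- IRanges::pintersect(wir[S4Vectors::queryHits(ov)],
                               fir[S4Vectors::subjectHits(ov)])
  covered <- rep(0, n_win)
  bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
  covered[as.integer(names(bp))] <- bp
  window_track(chrom, starts, covered / (ends - starts), window_bp,
               n_items = tabulate(S4Vectors::queryHits(ov), nbins = n_win),
               chrom_length = chrom_length)
}
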