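#' Mean-shift changepoint segmentation by PELT
#'
#' Exact penalised segmentation of a numeric series under a Gaussian
#' mean-shift model with common variance, solved with the PELT dynamic
#' program (pruned exact linear time). The segment cost is the residual sum
#' of squares; the default penalty is BIC-style,
#' `beta = 2 * sigma^2 * indep_spacing * log(n)`, with `sigma^2` the
#' variance of the whole series - the convention of standard mean-shift
#' changepoint tools, deliberately conservative in the presence of signal so
#' that smooth within-segment structure is not chased as spurious segments.
#' The optimum is exact for the given penalty and the result is
#' deterministic. A binary-segmentation mode is provided as a cross-check;
#' it is greedy and not guaranteed optimal.
#'
#' When consecutive windows overlap (step < window, as in the 100-kb/10-kb
#' FST scan) neighbouring values share most of their SNPs and the series
#' noise is strongly autocorrelated; `indep_spacing` (the window/step
#' ratio) makes the noise scale be estimated from differences at that lag
#' and inflates the penalty by the same factor, so that a noise excursion -
#' which persists for about one window width - is not fitted as a segment.
#'
#' @param series Numeric vector without `NA` (drop `NA` windows first and
#'   keep an index map; see [detect_slr()]), length >= 3.
#' @param penalty Either the string `"bic"` (default) or a non-negative
#'   number used directly as the penalty on the RSS scale.
#' @param method `"pelt"` (exact) or `"binseg"` (greedy cross-check).
#' @param indep_spacing Lag (in windows) at which series values are
#'   approximately independent; 1 for non-overlapping windows,
#'   `window_bp / step_bp` for overlapping scans.
#' @return An object of class `segmentation`: list with `breakpoints`
#'   (indices of the last element of each segment except the final one, in
#'   increasing order), `segment_means`, `penalty` and `cost` (total
#'   penalised cost).
#' @export
segment_mean_shift <- function(series, penalty = "bic",
                               method = c("pelt", "binseg"),
                               indep_spacing = 1L) {
  method <- match.arg(method)
  x <- as.numeric(series)
  if (anyNA(x))
    stop("series contains NA; remove NA windows before segmentation")
  n <- length(x)
  if (n < 3) stop("series must have length >= 3")
  m <- max(1L, as.integer(indep_spacing))
  if (identical(penalty, "bic")) {
    # variance of the whole series, the convention of mean-shift changepoint
    # tools: conservative in the presence of signal, which keeps smooth
    # within-plateau structure from being chased as spurious segments
    sigma2 <- stats::var(x)
    if (is.na(sigma2) || sigma2 == 0) {
      # constant series: single segment
      return(structure(list(breakpoints = integer(0),
                            segment_means = mean(x), penalty = 0,
                            cost = 0), class = "segmentation"))
    }
    beta <- 2 * sigma2 * m * log(n)
  } else {
    beta <- as.numeric(penalty)
    if (is.na(beta) || beta < 0) stop("penalty must be 'bic' or >= 0")
  }
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  segcost <- function(i, j) {     # RSS of x[i..j], 1-based inclusive
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  bp <- if (method == "pelt") pelt_rss(x, beta, cs, cs2)
        else binseg_rss(x, beta, segcost)
  bounds <- c(0L, bp, n)
  means <- vapply(seq_len(length(bounds) - 1L), function(k)
    mean(x[(bounds[k] + 1L):bounds[k + 1L]]), numeric(1))
  cost <- sum(vapply(seq_len(length(bounds) - 1L), function(k)
    segcost(bounds[k] + 1L, bounds[k + 1L]), numeric(1))) +
    (if (length(bp)) beta * length(bp) else 0)
  structure(list(breakpoints = bp, segment_means = means, penalty = beta,
                 cost = cost), class = "segmentation")
}

# PELT dynamic program over RSS cost with penalty beta.
pelt_rss <- function(x, beta, cs, cs2) {
  n <- length(x)
  if (!is.finite(beta))
    return(integer(0))                    # infinite penalty: no breakpoints
  Fv <- c(-beta, rep(Inf, n))             # F[0..n], shifted by 1
  last <- integer(n + 1L)
  cand <- 0L                              # candidate previous changepoints
  for (t in seq_len(n)) {
    len <- t - cand
    s <- cs[t + 1] - cs[cand + 1]
    cost <- (cs2[t + 1] - cs2[cand + 1]) - s^2 / len
    tot <- Fv[cand + 1L] + cost + beta
    k <- which.min(tot)
    Fv[t + 1L] <- tot[k]
    last[t + 1L] <- cand[k]
    keep <- Fv[cand + 1L] + cost <= Fv[t + 1L]
    cand <- c(cand[keep], t)
  }
  bp <- integer(0)
  t <- n
  while (last[t + 1L] > 0L) {
    bp <- c(last[t + 1L], bp)
    t <- last[t + 1L]
  }
  bp
}

# Greedy binary segmentation (cross-check mode).
binseg_rss <- function(x, beta, segcost) {
  n <- length(x)
  split1 <- function(i, j) {
    if (j - i < 1L) return(NULL)
    ks <- i:(j - 1L)
    gain <- segcost(i, j) -
      vapply(ks, function(k) segcost(i, k) + segcost(k + 1L, j), numeric(1))
    k <- ks[which.max(gain)]
    list(k = k, gain = max(gain))
  }
  bps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue)) {
    seg <- queue[[1L]]; queue <- queue[-1L]
    s <- split1(seg[1L], seg[2L])
    if (!is.null(s) && s$gain > beta) {
      bps <- c(bps, s$k)
      queue <- c(queue, list(c(seg[1L], s$k)), list(c(s$k + 1L, seg[2L])))
    }
  }
  sort(bps)
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation> ", length(x$segment_means), " segments; breakpoints: ",
      if (length(x$breakpoints)) paste(x$breakpoints, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Construct an SLR call
#'
#' A single sex-linked-region call on 0-based half-open coordinates; the span
#' is `end - start` exactly, and `span_mb` rounds to the two decimals used
#' when reporting SLR sizes in Mb (e.g. boundaries at 5.40 and 13.94 Mb give
#' a span of 8.54 Mb).
#'
#' @param chrom Chromosome name.
#' @param start,end Boundaries in bp, `start < end`.
#' @param mean_theta Mean windowed FST of the called region (optional).
#' @param role One of `"X_SLR", "Y_SLR", "Z_SLR", "W_SLR", "unknown"`.
#' @return A one-row data frame of class `slr_call` with columns `chrom,
#'   start, end, span_bp, span_mb, mean_theta, role`.
#' @export
slr_call <- function(chrom, start, end, mean_theta = NA_real_,
                     role = c("unknown", "X_SLR", "Y_SLR", "Z_SLR",
                              "W_SLR")) {
  role <- match.arg(role)
  stopifnot(start < end, start >= 0)
  out <- data.frame(chrom = chrom, start = start, end = end,
                    span_bp = end - start,
                    span_mb = round((end - start) / 1e6, 2),
                    mean_theta = mean_theta, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("slr_call", class(out))
  out
}

#' Convert a segmentation of an FST profile into SLR calls
#'
#' Segments whose mean exceeds the calling threshold (default
#' `max(0.1, 3 * median(segment_means))`) are merged when adjacent and
#' converted to bp intervals. Boundaries are reported at window centers and,
#' when `refine = TRUE`, refined to the half-amplitude crossing of the
#' series: the boundary is the center of the first/last window whose value
#' exceeds the midpoint between the high-segment mean and the neighbouring
#' background mean, searched within one window width of the segment edge.
#' This undoes the boundary smearing produced by overlapping windows.
#'
#' @param seg A [segment_mean_shift()] result computed on `series`.
#' @param track The [window_track()] the series came from (its window grid
#'   supplies coordinates).
#' @param series The series that was segmented (defaults to `track$values`);
#'   pass the NA-stripped series together with `index_map` when NA windows
#'   were removed.
#' @param index_map Integer map from series index to window index in `track`
#'   (defaults to the identity).
#' @param threshold Calling threshold on segment means, or `NULL` for the
#'   default rule.
#' @param refine Apply half-amplitude boundary refinement (default `TRUE`).
#' @param role Haplotype role recorded in the calls.
#' @return A data frame of SLR calls (zero rows when no segment qualifies).
#' @export
call_slr <- function(seg, track, series = track$values,
                     index_map = seq_along(series), threshold = NULL,
                     refine = TRUE, role = "unknown") {
  stopifnot(inherits(seg, "segmentation"), inherits(track, "window_track"))
  means <- seg$segment_means
  if (is.null(threshold)) threshold <- max(0.1, 3 * stats::median(means))
  qual <- means > threshold
  if (!any(qual)) {
    out <- slr_call("none", 0, 1)[0, ]
    return(out)
  }
  centers <- window_centers(track)
  bounds <- c(0L, seg$breakpoints, length(series))
  runs <- rle(qual)
  seg_idx <- cumsum(runs$lengths)
  out <- list()
  first_seg <- c(1L, utils::head(cumsum(runs$lengths), -1L) + 1L)
  for (r in which(runs$values)) {
    s1 <- first_seg[r]; s2 <- seg_idx[r]
    i1 <- bounds[s1] + 1L; i2 <- bounds[s2 + 1L]       # series indices
    hi_mean <- mean(series[i1:i2])
    start <- centers[index_map[i1]]
    end <- centers[index_map[i2]]
    if (refine) {
      ww <- max(1L, round(track$window_bp / track$step_bp))
      lo_left <- if (s1 > 1L) means[s1 - 1L] else 0
      lo_right <- if (s2 < length(means)) means[s2 + 1L] else 0
      start <- fit_boundary_ramp(series, centers[index_map], i1, "left",
                                 lo_left, i2, track$window_bp,
                                 track$step_bp)
      end <- fit_boundary_ramp(series, centers[index_map], i2, "right",
                               lo_right, i1, track$window_bp,
                               track$step_bp)
    }
    if (end <= start) next
    out[[length(out) + 1L]] <-
      slr_call(track$chrom, start, end, mean_theta = hi_mean, role = role)
  }
  if (!length(out)) return(slr_call("none", 0, 1)[0, ])
  do.call(rbind, out)
}

# Least-squares boundary refinement. Near a sharp transition the expected
# windowed value is a linear ramp of width one window (the overlap fraction
# of each window with the high region); fitting the ramp's offset over the
# ~2 window-widths around the segmentation edge averages noise across many
# windows instead of relying on a single threshold crossing. Returns the
# refined boundary in bp (window-center coordinates, step resolution).
fit_boundary_ramp <- function(series, centers, i_edge, side, lo, i_other,
                              window_bp, step_bp) {
  m <- max(1L, round(window_bp / step_bp))
  n <- length(series)
  if (side == "left") {
    idx <- max(1L, i_edge - 2L * m):min(i_other, i_edge + 2L * m)
    hi_idx <- (i_edge + m):min(i_other, i_edge + 3L * m)
  } else {
    idx <- max(i_other, i_edge - 2L * m):min(n, i_edge + 2L * m)
    hi_idx <- max(i_other, i_edge - 3L * m):(i_edge - m)
  }
  hi_idx <- hi_idx[hi_idx >= 1L & hi_idx <= n]
  hi <- if (length(hi_idx)) mean(series[hi_idx])
        else mean(series[min(i_edge, i_other):max(i_edge, i_other)])
  tau_grid <- centers[i_edge] + step_bp * (-m:m)
  cv <- centers[idx]
  sse <- vapply(tau_grid, function(tau) {
    f <- if (side == "left") (cv + window_bp / 2 - tau) / window_bp
         else (tau + window_bp / 2 - cv) / window_bp
    pred <- lo + (hi - lo) * pmin(1, pmax(0, f))
    sum((series[idx] - pred)^2)
  }, numeric(1))
  tau_grid[which.min(sse)]
}

# Site-level boundary refinement. Windowed FST smears a sharp SLR boundary
# over one window width, but individual XY-diagnostic sites carry per-site
# theta = 0.5 (far above the background tail at moderate sample sizes), so
# the boundary is localised by a two-rate Bernoulli changepoint on the
# indicator theta >= thr over the sites within one window of the coarse
# boundary. Robust to isolated outlier sites, unlike "first high site".
refine_boundary_sites <- function(components, tau0, side, window_bp,
                                  thr = 0.35) {
  pos0 <- components$pos - 1
  sel <- which(pos0 >= tau0 - window_bp & pos0 <= tau0 + window_bp &
                 !is.na(components$theta))
  if (length(sel) < 4L) return(tau0)
  sel <- sel[order(pos0[sel])]
  z <- as.integer(components$theta[sel] >= thr)
  p <- pos0[sel]
  n <- length(z)
  cz <- c(0, cumsum(z))
  ent <- function(k, s) {           # k trials, s successes: max log-lik
    if (k == 0) return(0)
    r <- s / k
    s * log(max(r, 1e-300)) + (k - s) * log(max(1 - r, 1e-300))
  }
  ll <- vapply(0:n, function(k)
    ent(k, cz[k + 1]) + ent(n - k, cz[n + 1] - cz[k + 1]), numeric(1))
  # enforce the expected direction: low->high for a left boundary
  dirok <- vapply(0:n, function(k) {
    rl <- if (k > 0) cz[k + 1] / k else 0
    rr <- if (k < n) (cz[n + 1] - cz[k + 1]) / (n - k) else 0
    if (side == "left") rr > rl else rl > rr
  }, logical(1))
  if (!any(dirok)) return(tau0)
  k <- (0:n)[dirok][which.max(ll[dirok])]
  if (k == 0) p[1] else if (k == n) p[n] else (p[k] + p[k + 1]) / 2
}

#' End-to-end SLR detection on an FST profile
#'
#' Removes `NA` windows (keeping the index bookkeeping), runs PELT
#' segmentation with the overlap-corrected penalty and converts qualifying
#' segments to SLR calls. When the per-site Weir-Cockerham components are
#' supplied, call boundaries are additionally refined at the SNP level (see
#' the vignette) and snapped to the step grid, which recovers sharp
#' boundaries to about one step.
#'
#' @param profile An `fst_profile` from [fst_windows()] (or a bare
#'   [window_track()]).
#' @param penalty,threshold,refine,role Passed to [segment_mean_shift()] and
#'   [call_slr()].
#' @param components Optional site components data frame from
#'   [wc_site_components()] for site-level boundary refinement.
#' @return List with elements `segmentation`, `calls` and `index_map`.
#' @export
detect_slr <- function(profile, penalty = "bic", threshold = NULL,
                       refine = TRUE, role = "unknown", components = NULL) {
  track <- if (inherits(profile, "fst_profile")) profile$track else profile
  keep <- which(!is.na(track$values))
  if (length(keep) < 3) stop("fewer than 3 usable windows")
  series <- track$values[keep]
  seg <- segment_mean_shift(series, penalty = penalty,
                            indep_spacing = round(track$window_bp /
                                                    track$step_bp))
  calls <- call_slr(seg, track, series = series, index_map = keep,
                    threshold = threshold, refine = refine, role = role)
  if (!is.null(components) && nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      s <- refine_boundary_sites(components, calls$start[i], "left",
                                 track$window_bp)
      e <- refine_boundary_sites(components, calls$end[i], "right",
                                 track$window_bp)
      s <- round(s / track$step_bp) * track$step_bp
      e <- round(e / track$step_bp) * track$step_bp
      if (e > s) {
        calls$start[i] <- s; calls$end[i] <- e
        calls$span_bp[i] <- e - s
        calls$span_mb[i] <- round((e - s) / 1e6, 2)
      }
    }
  }
  list(segmentation = seg, calls = calls, index_map = keep)
}
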