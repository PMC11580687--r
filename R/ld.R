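#' Genotype (composite) r-squared between two sites
#'
#' Squared Pearson correlation of the 0/1/2 allele-count vectors over
#' pairwise-complete samples. This is the genotype-based LD measure used on
#' unphased data; it is symmetric in its arguments and invariant to allele
#' relabelling (0 <-> 2 flips). Returns `NaN` (with a message) when either
#' site is monomorphic among the pairwise-complete samples or fewer than two
#' such samples exist.
#'
#' @param g_i,g_j Integer vectors of genotype codes (`NA` = missing).
#' @return The r-squared value in `[0, 1]`, or `NaN`.
#' @export
genotype_r2 <- function(g_i, g_j) {
  stopifnot(length(g_i) == length(g_j))
  ok <- !is.na(g_i) & !is.na(g_j)
  if (sum(ok) < 2L || stats::var(g_i[ok]) == 0 || stats::var(g_j[ok]) == 0) {
    message("monomorphic or under-sampled site pair; r2 undefined")
    return(NaN)
  }
  stats::cor(g_i[ok], g_j[ok])^2
}

# Pairwise r2 for all site pairs within max_dist inside a region.
# Returns a data.frame(distance, r2). Sites are capped (seeded subsample via
# the caller's RNG) to keep the pair count tractable.
region_pairs_r2 <- function(gm, region, max_dist = Inf, max_sites = 2000L) {
  pos0 <- gm$pos - 1
  idx <- which(pos0 >= region[1] & pos0 < region[2])
  # drop monomorphic sites up front
  if (length(idx)) {
    v <- apply(gm$geno[, idx, drop = FALSE], 2L,
               function(g) stats::var(g, na.rm = TRUE))
    idx <- idx[!is.na(v) & v > 0]
  }
  if (length(idx) < 2L)
    return(data.frame(distance = numeric(0), r2 = numeric(0)))
  if (length(idx) > max_sites)
    idx <- sort(sample(idx, max_sites))
  r2 <- suppressWarnings(
    stats::cor(gm$geno[, idx, drop = FALSE],
               use = "pairwise.complete.obs")^2)
  d <- abs(outer(pos0[idx], pos0[idx], "-"))
  ut <- upper.tri(d)
  keep <- ut & d <= max_dist & !is.na(r2)
  data.frame(distance = d[keep], r2 = r2[keep])
}

#' LD decay curve within a region
#'
#' Computes genotype r-squared for all within-region site pairs separated by
#' at most `max_dist`, bins the pairs by distance and reports per-bin mean
#' r-squared and pair counts. Pairs per bin are capped with a subsample drawn
#' from the current RNG stream for tractability.
#'
#' @param gm A [genotype_matrix()].
#' @param region Length-2 numeric, 0-based half-open interval in bp.
#' @param max_dist Maximum pair separation in bp (default 50000, which
#'   comfortably covers the ~25-kb scale at which autosomal LD has decayed
#'   while fully sex-linked LD has not).
#' @param bin_bp Distance bin width in bp (default 2500).
#' @param max_pairs_per_bin Cap on pairs per bin (default 50000).
#' @param region_class Label attached to the curve (e.g. `"autosome_PAR"`,
#'   `"X_SLR"`, `"Y_SLR"`).
#' @param max_sites Cap on polymorphic sites considered (default 2000).
#' @return A data frame of class `decay_curve`: `bin_lo, bin_hi, mean_r2,
#'   n_pairs, region_class`.
#' @export
ld_decay <- function(gm, region, max_dist = 50000, bin_bp = 2500,
                     max_pairs_per_bin = 50000,
                     region_class = "autosome_PAR", max_sites = 2000L) {
  stopifnot(inherits(gm, "genotype_matrix"), length(region) == 2)
  pr <- region_pairs_r2(gm, region, max_dist, max_sites)
  edges <- seq(0, max_dist, by = bin_bp)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  if (nrow(pr) == 0) {
    out <- data.frame(bin_lo = utils::head(edges, -1L),
                      bin_hi = edges[-1L], mean_r2 = NaN, n_pairs = 0L,
                      region_class = region_class)
    class(out) <- c("decay_curve", class(out))
    return(out)
  }
  bin <- cut(pr$distance, breaks = edges, include.lowest = FALSE,
             right = TRUE)
  mean_r2 <- rep(NaN, length(edges) - 1L)
  n_pairs <- integer(length(edges) - 1L)
  for (k in seq_along(mean_r2)) {
    r <- pr$r2[!is.na(bin) & as.integer(bin) == k]
    if (length(r) > max_pairs_per_bin) r <- sample(r, max_pairs_per_bin)
    n_pairs[k] <- length(r)
    if (length(r)) mean_r2[k] <- mean(r)
  }
  out <- data.frame(bin_lo = utils::head(edges, -1L), bin_hi = edges[-1L],
                    mean_r2 = mean_r2, n_pairs = n_pairs,
                    region_class = region_class)
  class(out) <- c("decay_curve", class(out))
  out
}

#' Regional LD summary table
#'
#' One row per (non-overlapping) labeled region with the mean and median
#' pairwise genotype r-squared and the number of pairs used. Deterministic
#' given the input (sites are capped deterministically by taking the first
#' `max_sites` polymorphic sites).
#'
#' @param gm A [genotype_matrix()].
#' @param regions Data frame with columns `start, end, region_class`
#'   (0-based half-open bp intervals; must not overlap).
#' @param max_dist Maximum pair separation considered (default `Inf`).
#' @param max_sites Cap on sites per region (default 1500).
#' @return Data frame `region_class, mean_r2, median_r2, n_pairs`.
#' @export
region_ld_summary <- function(gm, regions, max_dist = Inf,
                              max_sites = 1500L) {
  stopifnot(all(c("start", "end", "region_class") %in% names(regions)))
  o <- order(regions$start)
  if (any(regions$start[o][-1] < regions$end[o][-nrow(regions)]))
    stop("regions must not overlap")
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    pos0 <- gm$pos - 1
    idx <- which(pos0 >= regions$start[i] & pos0 < regions$end[i])
    if (length(idx) > max_sites) idx <- idx[seq_len(max_sites)]
    sub <- gm
    pr <- if (length(idx) >= 2L)
      region_pairs_r2(subset_sites(sub, idx),
                      c(regions$start[i], regions$end[i]), max_dist,
                      max_sites)
    else data.frame(distance = numeric(0), r2 = numeric(0))
    data.frame(region_class = regions$region_class[i],
               mean_r2 = if (nrow(pr)) mean(pr$r2) else NaN,
               median_r2 = if (nrow(pr)) stats::median(pr$r2) else NaN,
               n_pairs = nrow(pr))
  })
  do.call(rbind, rows)
}
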