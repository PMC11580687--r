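#' Filter SNPs for the between-sex FST scan
#'
#' Applies three exclusion rules in order: (i) sites whose mean depth across
#' all samples exceeds `max_depth_ratio` times the genome-wide mean depth at
#' variant sites; (ii) non-biallelic sites; (iii) sites with more than
#' `max_missing` missing genotypes and/or minor allele frequency below
#' `min_maf` (a MAF exactly at `min_maf` is retained). Rule (i) is skipped
#' with a warning when no depth is available.
#'
#' @param gm A [genotype_matrix()].
#' @param max_depth_ratio Depth cutoff as a multiple of the mean (default 2).
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @return The filtered `genotype_matrix`, with an attribute
#'   `"filter_tally"` giving the number of sites removed by each rule (a site
#'   may be counted under several rules) and the number surviving.
#' @export
filter_snps <- function(gm, max_depth_ratio = 2, max_missing = 0.10,
                        min_maf = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_sites <- length(gm$pos)
  if (n_sites == 0) {
    warning("empty genotype matrix; nothing to filter")
    attr(gm, "filter_tally") <- c(depth = 0L, nonbiallelic = 0L,
                                  missing_or_maf = 0L, kept = 0L)
    return(gm)
  }
  if (!is.null(gm$depth)) {
    site_depth <- colMeans(gm$depth, na.rm = TRUE)
    grand_mean <- mean(site_depth, na.rm = TRUE)
    rule_depth <- !is.na(site_depth) & site_depth > max_depth_ratio * grand_mean
  } else {
    warning("no depth available; depth filter (rule i) skipped")
    rule_depth <- rep(FALSE, n_sites)
  }
  rule_biall <- gm$n_alleles != 2L

  miss <- colMeans(is.na(gm$geno))
  p <- colMeans(gm$geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  rule_mm <- miss > max_missing | (!is.na(maf) & maf < min_maf) | is.na(maf)

  keep <- !(rule_depth | rule_biall | rule_mm)
  out <- subset_sites(gm, keep)
  attr(out, "filter_tally") <- c(depth = sum(rule_depth),
                                 nonbiallelic = sum(rule_biall),
                                 missing_or_maf = sum(rule_mm),
                                 kept = sum(keep))
  out
}

#' Weir-Cockerham variance components at each site, between the sexes
#'
#' Computes the two-population (females vs males, r = 2) diploid
#' Weir-Cockerham variance components at every site:
#' \deqn{\bar n = (n_f + n_m)/2, \quad
#'       n_c = 2\bar n - (n_f^2 + n_m^2)/(2\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[S^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{S^2}{2} -
#'       \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'       \frac{S^2}{2} - \frac{2\bar n - 1}{4\bar n}\bar h\right], \quad
#'       c = \bar h / 2}
#' with \eqn{\bar p} the sample-size-weighted mean alternate-allele
#' frequency, \eqn{S^2 = \sum_i n_i (p_i - \bar p)^2 / \bar n} the
#' between-sex frequency variance and \eqn{\bar h} the weighted mean observed
#' heterozygosity. Only non-missing genotypes contribute. Components are `NA`
#' at sites monomorphic across both sexes or genotyped in only one sex
#' (skipped sites are reported via the `skipped` attribute).
#'
#' At an XY-diagnostic site (all females homozygous reference, all males
#' heterozygous, equal sample sizes) the components collapse to a = 1/8,
#' b = -1/8, c = 1/4, so the per-site theta is exactly 0.5 for any n.
#'
#' @param gm A [genotype_matrix()] with at least one female and one male.
#' @param sites Optional site index; defaults to all sites.
#' @return A data frame with one row per requested site: `chrom, pos, n_f,
#'   n_m, p_f, p_m, h_f, h_m, a, b, c, theta` (`theta = a/(a+b+c)` where the
#'   denominator is positive).
#' @export
wc_site_components <- function(gm, sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_both_sexes(gm)
  if (is.null(sites)) sites <- seq_along(gm$pos)
  gf <- gm$geno[gm$sex == "female", sites, drop = FALSE]
  gmat <- gm$geno[gm$sex == "male", sites, drop = FALSE]

  n_f <- colSums(!is.na(gf)); n_m <- colSums(!is.na(gmat))
  p_f <- colMeans(gf, na.rm = TRUE) / 2
  p_m <- colMeans(gmat, na.rm = TRUE) / 2
  h_f <- colMeans(gf == 1L, na.rm = TRUE)
  h_m <- colMeans(gmat == 1L, na.rm = TRUE)

  nbar <- (n_f + n_m) / 2
  nc <- 2 * nbar - (n_f^2 + n_m^2) / (2 * nbar)
  pbar <- (n_f * p_f + n_m * p_m) / (2 * nbar)
  s2 <- (n_f * (p_f - pbar)^2 + n_m * (p_m - pbar)^2) / nbar
  hbar <- (n_f * h_f + n_m * h_m) / (2 * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  skipped <- n_f == 0L | n_m == 0L
  mono <- !skipped & (pbar <= 0 | pbar >= 1)
  drop <- skipped | mono
  a[drop] <- NA_real_; b[drop] <- NA_real_; cc[drop] <- NA_real_
  if (any(skipped))
    message(sum(skipped), " site(s) skipped: no genotyped individuals in ",
            "one sex")
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom > 0, a / denom, NA_real_)
  out <- data.frame(chrom = gm$chrom[sites], pos = gm$pos[sites],
                    n_f = n_f, n_m = n_m, p_f = p_f, p_m = p_m,
                    h_f = h_f, h_m = h_m, a = a, b = b, c = cc,
                    theta = theta)
  attr(out, "skipped") <- sum(skipped)
  out
}

#' Windowed weighted FST between the sexes
#'
#' Aggregates Weir-Cockerham site components into overlapping windows as the
#' ratio of sums `theta_w = sum(a) / sum(a + b + c)` (the weighted
#' estimator), not the mean of per-site ratios. Default geometry follows the
#' 100-kb windows with 10-kb steps used for SLR scans. Windows with fewer
#' than `min_snps` usable sites carry `NA`.
#'
#' @param components Data frame from [wc_site_components()].
#' @param window_bp Window size in bp (default 100000).
#' @param step_bp Step between window starts (default 10000; must not exceed
#'   `window_bp`).
#' @param min_snps Minimum usable SNPs per window (default 1).
#' @param chrom_length Optional chromosome length (defaults to the last SNP
#'   position).
#' @return An object of class `fst_profile`: list with the theta
#'   [window_track()] (`n_items` = SNPs per window) and the scan parameters.
#' @export
fst_windows <- function(components, window_bp = 100000, step_bp = 10000,
                        min_snps = 1, chrom_length = NULL) {
  if (window_bp < step_bp) stop("window_bp must be >= step_bp")
  comp <- components[!is.na(components$a), , drop = FALSE]
  chrom <- if (nrow(components)) components$chrom[1L] else "chr"
  if (is.null(chrom_length))
    chrom_length <- if (nrow(components)) max(components$pos) else window_bp
  pos0 <- comp$pos - 1                      # 0-based
  ord <- order(pos0)
  pos0 <- pos0[ord]
  ca <- cumsum(comp$a[ord])
  cd <- cumsum((comp$a + comp$b + comp$c)[ord])
  starts <- seq(0, max(0, chrom_length - 1), by = step_bp)
  lo <- findInterval(starts - 0.5, pos0)    # sites strictly before window
  hi <- findInterval(starts + window_bp - 0.5, pos0)
  n_snps <- hi - lo
  sum_a <- c(0, ca)[hi + 1] - c(0, ca)[lo + 1]
  sum_d <- c(0, cd)[hi + 1] - c(0, cd)[lo + 1]
  theta <- ifelse(n_snps >= min_snps & sum_d != 0, sum_a / sum_d, NA_real_)
  theta <- pmax(theta, -1)                  # clip -Inf artifacts
  track <- window_track(chrom, starts, theta, window_bp, step_bp = step_bp,
                        n_items = n_snps, chrom_length = chrom_length)
  structure(list(track = track, window_bp = window_bp, step_bp = step_bp,
                 min_snps = min_snps),
            class = "fst_profile")
}

#' @export
print.fst_profile <- function(x, ...) {
  v <- x$track$values
  cat("<fst_profile> ", length(v), " windows (", x$window_bp, "/",
      x$step_bp, " bp); mean theta = ", signif(mean(v, na.rm = TRUE), 4),
      "; ", sum(is.na(v)), " NA window(s)\n", sep = "")
  invisible(x)
}
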