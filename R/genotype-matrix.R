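#' Genotype matrix with sample sex labels
#'
#' The central container for between-sex analyses: a samples x sites matrix of
#' diploid genotype codes (0/1/2 alternate-allele counts, `NA` for missing)
#' together with per-sample sex labels and per-site positional metadata.
#' Positions are stored 1-based as read from VCF; windowing functions convert
#' to 0-based half-open coordinates internally.
#'
#' @param sample_ids Character vector of sample names.
#' @param sex Character vector, one of `"female"`, `"male"`, `"unknown"` per
#'   sample.
#' @param chrom Character vector, chromosome per site.
#' @param pos Integer vector, 1-based position per site.
#' @param ref,alt Character vectors of reference and alternate alleles per
#'   site; multiallelic sites carry a comma-separated `alt`.
#' @param geno Integer matrix (`n_samples` x `n_sites`) of codes in
#'   `{0, 1, 2, NA}`.
#' @param depth Optional numeric matrix of per-sample per-site read depth,
#'   same dimensions as `geno`, or `NULL`.
#' @param n_alleles Optional integer vector of allele counts per site
#'   (default derived from `alt`).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, sex, chrom, pos, ref, alt, geno,
                            depth = NULL, n_alleles = NULL) {
  sex <- match.arg(as.character(sex), c("female", "male", "unknown"),
                   several.ok = TRUE)
  if (length(sex) != length(sample_ids))
    stop("`sex` must have one label per sample")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(sample_ids))
    stop("geno rows (", nrow(geno), ") != number of samples (",
         length(sample_ids), ")")
  n_sites <- length(pos)
  if (ncol(geno) != n_sites)
    stop("geno columns (", ncol(geno), ") != number of sites (", n_sites, ")")
  stopifnot(length(chrom) == n_sites, length(ref) == n_sites,
            length(alt) == n_sites)
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(n_alleles)) {
    n_alleles <- 1L + lengths(strsplit(as.character(alt), ",", fixed = TRUE))
    n_alleles[is.na(alt) | alt == "."] <- 1L
  }
  ord <- order(chrom, pos)
  if (is.unsorted(ord)) {
    chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
    n_alleles <- n_alleles[ord]
    geno <- geno[, ord, drop = FALSE]
    if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(geno)))
      stop("depth must have the same dimensions as geno")
    if (any(depth[!is.na(depth)] < 0)) stop("depth must be non-negative")
  }
  structure(
    list(sample_ids = as.character(sample_ids), sex = sex,
         chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         n_alleles = as.integer(n_alleles), geno = geno, depth = depth),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$sample_ids), " samples (",
      sum(x$sex == "female"), " F / ", sum(x$sex == "male"), " M / ",
      sum(x$sex == "unknown"), " ?) x ", length(x$pos), " sites on ",
      length(unique(x$chrom)), " chromosome(s)",
      if (!is.null(x$depth)) "; depth available", "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by site index
#'
#' @param gm A [genotype_matrix()].
#' @param sites Integer or logical index over sites.
#' @return A `genotype_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(gm, sites) {
  stopifnot(inherits(gm, "genotype_matrix"))
  genotype_matrix(gm$sample_ids, gm$sex,
                  gm$chrom[sites], gm$pos[sites], gm$ref[sites],
                  gm$alt[sites], gm$geno[, sites, drop = FALSE],
                  depth = if (!is.null(gm$depth)) gm$depth[, sites, drop = FALSE],
                  n_alleles = gm$n_alleles[sites])
}

# Require at least one genotyped individual of each sex before a between-sex
# statistic is computed.
check_both_sexes <- function(gm) {
  if (sum(gm$sex == "female") < 1L || sum(gm$sex == "male") < 1L)
    stop("between-sex statistics need at least one female and one male sample")
  invisible(TRUE)
}
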