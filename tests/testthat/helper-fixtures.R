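# Shared fixtures and independent oracles, built in code at test time.

# Write a small literal VCF; `body` is a character vector of record lines.
write_toy_vcf <- function(path, samples, body, format = "GT") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (grepl("DP", format))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, gts, format = "GT") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", format, gts),
        collapse = "\t")
}

# A small genotype matrix from an explicit genotype matrix (samples x sites).
toy_gm <- function(geno, sex, pos = seq_len(ncol(geno)) * 1000L,
                   chrom = "chr7", depth = NULL, n_alleles = NULL) {
  genotype_matrix(
    sample_ids = sprintf("S%02d", seq_len(nrow(geno))), sex = sex,
    chrom = rep(chrom, ncol(geno)), pos = pos,
    ref = rep("A", ncol(geno)), alt = rep("T", ncol(geno)),
    geno = geno, depth = depth, n_alleles = n_alleles)
}

# Independent oracle: exhaustive optimal segmentation with at most two
# breakpoints under penalised RSS.
brute_segment <- function(x, beta) {
  n <- length(x)
  rss <- function(i, j) { s <- x[i:j]; sum((s - mean(s))^2) }
  best <- list(cost = rss(1, n), bp = integer(0))
  for (k in 1:(n - 1)) {
    cost <- rss(1, k) + rss(k + 1, n) + beta
    if (cost < best$cost - 1e-12) best <- list(cost = cost, bp = k)
  }
  if (n >= 3) {
    for (k1 in 1:(n - 2)) for (k2 in (k1 + 1):(n - 1)) {
      cost <- rss(1, k1) + rss(k1 + 1, k2) + rss(k2 + 1, n) + 2 * beta
      if (cost < best$cost - 1e-12)
        best <- list(cost = cost, bp = c(k1, k2))
    }
  }
  best
}

# Independent oracle: two-sided Fisher p by direct hypergeometric
# enumeration of all tables with the observed margins.
fisher_enum <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  pobs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Independent oracle: windowed weighted FST by direct summation.
ratio_of_sums <- function(a, d) sum(a) / sum(d)
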