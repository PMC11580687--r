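#' Simulation configuration for a sex-chromosome population sample
#'
#' Defines the study conditions for the synthetic genotype/coverage data: a
#' single chromosome with a PAR-SLR-PAR structure, X/Y (or Z/W) haplotypes
#' carrying fixed differences inside the SLR, and female/male sampling.
#' Defaults describe a 10-Mb chromosome with a pericentromeric SLR at
#' 4-6 Mb, 20 females + 20 males, one SNP per kb, 40% of SLR sites fixed
#' between the gametologs, haploid sequencing depth 50x with 150-bp reads,
#' 50-kb coverage windows and 2% missing genotypes. The diagnostic-site
#' fraction sets the boundary information content: the spacing of fixed
#' differences (1 / (site_density * diag_site_fraction), 2.5 kb at the
#' defaults) is the localisation limit for SLR boundary calls.
#'
#' @param system `"XY"` (male heterogamety) or `"ZW"` (female heterogamety).
#' @param chrom_length Chromosome length in bp.
#' @param slr_interval Length-2 numeric, 0-based half-open SLR interval in
#'   bp; `c(0, 0)` means no SLR (a pure autosome).
#' @param n_females,n_males Sample counts (>= 2 each).
#' @param site_density Expected SNPs per bp.
#' @param diag_site_fraction Fraction of SLR sites that are fixed X/Y
#'   (diagnostic) differences.
#' @param mean_depth Haploid per-base sequencing depth: a window's expected
#'   read count is `mean_depth * dose * window_bp / read_length`.
#' @param read_length Read length in bp used to convert depth to per-window
#'   read counts (default 150, short-read resequencing).
#' @param window_bp Coverage window size in bp.
#' @param missing_rate Genotype missingness rate in `[0, 1)`.
#' @param maf_floor Minimum minor allele frequency of background SNPs.
#' @param mutation_scale Substitutions/site scale for gametolog sequence
#'   evolution.
#' @param seed RNG seed applied at the start of each `simulate_*` call
#'   (`NULL` = use the current RNG state).
#' @param chrom Chromosome name.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(system = c("XY", "ZW"), chrom_length = 1e7,
                       slr_interval = c(4e6, 6e6), n_females = 20,
                       n_males = 20, site_density = 1e-3,
                       diag_site_fraction = 0.4, mean_depth = 50,
                       read_length = 150, window_bp = 50000,
                       missing_rate = 0.02, maf_floor = 0.05,
                       mutation_scale = 0.05, seed = NULL,
                       chrom = "chr7") {
  system <- match.arg(system)
  stopifnot(chrom_length > 0,
            length(slr_interval) == 2,
            slr_interval[1] >= 0, slr_interval[1] <= slr_interval[2],
            slr_interval[2] <= chrom_length,
            n_females >= 2, n_males >= 2,
            site_density > 0, diag_site_fraction >= 0,
            diag_site_fraction <= 1, mean_depth > 0, window_bp > 0,
            read_length > 0, missing_rate >= 0, missing_rate < 1,
            maf_floor > 0, maf_floor < 0.5, mutation_scale >= 0)
  if (diag_site_fraction > 0 && slr_interval[1] == slr_interval[2])
    stop("diag_site_fraction > 0 requires a non-empty slr_interval")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$system, " system; chrom ", x$chrom, " ",
      x$chrom_length / 1e6, " Mb; SLR ", x$slr_interval[1] / 1e6, "-",
      x$slr_interval[2] / 1e6, " Mb; ", x$n_females, "F + ", x$n_males,
      "M\n", sep = "")
  invisible(x)
}

maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  invisible(NULL)
}

#' Simulate a sexed population genotype sample with a known SLR
#'
#' Background SNPs get an allele frequency drawn uniformly on
#' `[maf_floor, 0.5]`, identical in both sexes, with Hardy-Weinberg binomial
#' genotypes. Diagnostic SLR sites carry a fixed X/Y difference: under XY the
#' alternate allele is Y-linked, so every female is homozygous reference and
#' every male heterozygous; under ZW the sexes are mirrored. Missingness is
#' applied uniformly at `missing_rate`. Per-site depths are Poisson around
#' `mean_depth` (per site, all samples) so the depth filter is exercised.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth` (list
#'   with the SLR interval, per-site class in
#'   `{PAR_background, SLR_background, SLR_diagnostic}` and the config).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(config)
  L <- config$chrom_length
  n_sites <- round(config$site_density * L)
  pos <- sort(sample.int(L, n_sites))             # 1-based positions
  pos0 <- pos - 1
  in_slr <- pos0 >= config$slr_interval[1] & pos0 < config$slr_interval[2]
  site_class <- ifelse(in_slr, "SLR_background", "PAR_background")
  idx_slr <- which(in_slr)
  n_diag <- round(config$diag_site_fraction * length(idx_slr))
  if (n_diag > 0)
    site_class[sample(idx_slr, n_diag)] <- "SLR_diagnostic"
  diag <- site_class == "SLR_diagnostic"

  n_f <- config$n_females; n_m <- config$n_males
  n <- n_f + n_m
  p <- stats::runif(n_sites, config$maf_floor, 0.5)
  geno <- matrix(stats::rbinom(n * n_sites, 2L, rep(p, each = n)),
                 nrow = n, ncol = n_sites)
  sex <- c(rep("female", n_f), rep("male", n_m))
  het_sex <- if (config$system == "XY") "male" else "female"
  if (any(diag)) {
    geno[sex != het_sex, diag] <- 0L               # homogametic: hom ref
    geno[sex == het_sex, diag] <- 1L               # heterogametic: het
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }
  depth <- matrix(stats::rpois(length(geno), config$mean_depth),
                  nrow = n, ncol = n_sites)
  gm <- genotype_matrix(
    sample_ids = sprintf("S%03d", seq_len(n)), sex = sex,
    chrom = rep(config$chrom, n_sites), pos = pos,
    ref = rep("A", n_sites), alt = rep("T", n_sites),
    geno = geno, depth = depth)
  list(genotypes = gm,
       truth = list(slr_interval = config$slr_interval,
                    site_class = site_class, pos = pos, config = config))
}

#' Simulate female and male coverage tracks with known window doses
#'
#' Window read counts are Poisson with mean proportional to
#' `mean_depth * dose` (scaled by `window_bp / read_length`, the number of
#' reads a window holds at unit depth). Doses
#' follow the reference haplotype: mapping to the X haplotype gives female
#' dose 2 / male dose 1 in SLR windows and 2/2 in the PARs; mapping to the Y
#' haplotype gives female dose 0 (counts exactly zero) / male dose 1 in the
#' SLR. Under a ZW system the sexes are mirrored. A window is treated as SLR
#' when its midpoint falls inside `slr_interval`.
#'
#' @param config A [sim_config()].
#' @param haplotype Reference haplotype, `"X"` or `"Y"` (`"Z"`/`"W"`
#'   equivalents under ZW).
#' @return List with `female` and `male` [window_track()]s and `truth`
#'   (per-window doses and classes).
#' @export
simulate_coverage <- function(config, haplotype = c("X", "Y")) {
  stopifnot(inherits(config, "sim_config"))
  haplotype <- match.arg(haplotype)
  maybe_seed(config)
  L <- config$chrom_length
  W <- config$window_bp
  n_win <- ceiling(L / W)
  starts <- (seq_len(n_win) - 1) * W
  mid <- pmin(starts + W / 2, L)
  in_slr <- mid >= config$slr_interval[1] & mid < config$slr_interval[2]
  dose_het <- ifelse(in_slr, 1, 2)               # heterogametic sex: one X
  dose_hom <- if (haplotype == "X") rep(2, n_win)
              else ifelse(in_slr, 0, 2)          # Y reference: no female copy
  if (config$system == "XY") {
    dose_f <- dose_hom; dose_m <- dose_het
  } else {
    dose_f <- dose_het; dose_m <- dose_hom
  }
  reads_per_dose <- config$mean_depth * W / config$read_length
  counts_f <- stats::rpois(n_win, reads_per_dose * dose_f)
  counts_m <- stats::rpois(n_win, reads_per_dose * dose_m)
  cls <- ifelse(!in_slr, "PAR",
                ifelse(haplotype == "Y", "SEX_SPECIFIC", "SLR"))
  list(female = window_track(config$chrom, starts, counts_f, W,
                             chrom_length = L),
       male = window_track(config$chrom, starts, counts_m, W,
                           chrom_length = L),
       truth = list(dose_female = dose_f, dose_male = dose_m,
                    mu_female = reads_per_dose * dose_f,
                    mu_male = reads_per_dose * dose_m,
                    window_class = cls, slr_interval = config$slr_interval,
                    config = config))
}

# Ladder (caterpillar) newick subtree over tips, fixed edge length.
ladder_newick <- function(tips, edge) {
  if (length(tips) == 1L) return(sprintf("%s:%g", tips, edge))
  out <- sprintf("(%s:%g,%s:%g)", tips[1], edge, tips[2], edge)
  for (t in tips[-(1:2)])
    out <- sprintf("(%s:%g,%s:%g)", out, edge, t, edge)
  out
}

#' Simulate gametolog alignments under a turnover scenario
#'
#' Builds the true gametolog tree implied by the scenario and evolves
#' sequences along it under Jukes-Cantor (via \pkg{phangorn}). Scenarios:
#' `GAMETOLOG_CLUSTERING` (recombination suppression predates the species
#' splits: an X/W clade and a Y/Z clade, each containing all species),
#' `SPECIES_CLUSTERING` (suppression after the splits: X-Y sister within
#' each species) and `NEO_FROM_X` (the focal species' Y branches first and
#' the remaining species' X and Y cluster with the focal X - the signature
#' of a neo-Y derived from the ancestral X). Branch lengths put the species
#' divergence at `mutation_scale` and the gametolog divergence at twice
#' that, deep enough for NJ to resolve the topology at alignment lengths of
#' a couple of kb.
#'
#' @param scenario One of the three scenario labels above.
#' @param species Character vector of ingroup species names (>= 2; >= 3 for
#'   `NEO_FROM_X`).
#' @param mutation_scale Substitutions/site for the species divergence.
#' @param seq_length Alignment length in bp (default 2000).
#' @param outgroup Outgroup species name (leaf `<outgroup>_A`).
#' @param focal Focal species for `NEO_FROM_X` (default the first species).
#' @param seed Optional RNG seed.
#' @return List with `alignment` (a `DNAbin` matrix, rows named
#'   `"<species>_<X|Y>"` and `"<outgroup>_A"`), `tree` (the generating
#'   `phylo`), `scenario` and `focal`.
#' @export
simulate_gametolog_sequences <- function(scenario = c("GAMETOLOG_CLUSTERING",
                                                      "SPECIES_CLUSTERING",
                                                      "NEO_FROM_X"),
                                         species, mutation_scale = 0.05,
                                         seq_length = 2000,
                                         outgroup = "Ipoly", focal = NULL,
                                         seed = NULL) {
  scenario <- match.arg(scenario)
  if (length(species) < 2) stop("need at least 2 ingroup species")
  if (!is.null(seed)) set.seed(seed)
  u <- mutation_scale
  x_tips <- paste0(species, "_X")
  y_tips <- paste0(species, "_Y")
  out_tip <- paste0(outgroup, "_A")
  nwk <- switch(scenario,
    GAMETOLOG_CLUSTERING = sprintf("(%s:%g,(%s:%g,%s:%g):%g);",
      out_tip, 2 * u, ladder_newick(x_tips, u / 2),
      u, ladder_newick(y_tips, u / 2), u, u),
    SPECIES_CLUSTERING = {
      cherries <- sprintf("(%s:%g,%s:%g)", x_tips, u / 4, y_tips, u / 4)
      sprintf("(%s:%g,%s:%g);", out_tip, 2 * u,
              ladder_newick(cherries, u / 2), u)
    },
    NEO_FROM_X = {
      if (length(species) < 3)
        stop("NEO_FROM_X needs at least 3 ingroup species")
      if (is.null(focal)) focal <- species[1]
      if (!focal %in% species) stop("focal species not in species list")
      others <- setdiff(species, focal)
      sprintf("(%s:%g,(%s_Y:%g,(%s_X:%g,(%s:%g,%s:%g):%g):%g):%g);",
              out_tip, 2 * u,                  # outgroup branch
              focal, u,                        # focal Y, basal ingroup
              focal, u / 2,                    # focal X
              ladder_newick(paste0(others, "_X"), u / 4), u / 4,
              ladder_newick(paste0(others, "_Y"), u / 4), u / 4,
              u / 4,                           # (others X, others Y) clade
              u / 2,                           # (focal X, others) clade
              u / 2)                           # ingroup clade
    })
  tree <- ape::read.tree(text = nwk)
  sim <- phangorn::simSeq(tree, l = seq_length, type = "DNA")
  aln <- ape::as.DNAbin(sim)
  list(alignment = as.matrix(aln), tree = tree, scenario = scenario,
       focal = if (scenario == "NEO_FROM_X") focal else NA_character_)
}

#' Simulate an inversion comparison table
#'
#' One Bernoulli inversion indicator per pairwise synteny comparison, with
#' separate rates for autosome-autosome comparisons and comparisons
#' involving a sex-linked region.
#'
#' @param n_auto_pairs,n_sex_pairs Numbers of comparisons per class.
#' @param p_inv_auto,p_inv_sex Inversion probabilities per class.
#' @param seed Optional RNG seed.
#' @return Data frame `comparison_id, class, inversion_present`.
#' @export
simulate_comparison_table <- function(n_auto_pairs, n_sex_pairs,
                                      p_inv_auto, p_inv_sex, seed = NULL) {
  stopifnot(p_inv_auto >= 0, p_inv_auto <= 1, p_inv_sex >= 0,
            p_inv_sex <= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    comparison_id = sprintf("cmp%03d", seq_len(n_auto_pairs + n_sex_pairs)),
    class = c(rep("autosome_pair", n_auto_pairs),
              rep("sex_involved", n_sex_pairs)),
    inversion_present = c(stats::runif(n_auto_pairs) < p_inv_auto,
                          stats::runif(n_sex_pairs) < p_inv_sex),
    stringsAsFactors = FALSE)
}
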