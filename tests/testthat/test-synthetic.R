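test_that("diagnostic sites have the sex-linked genotype structure", {
  cfg <- sim_config(seed = 11, missing_rate = 0)
  pop <- simulate_population(cfg)
  gm <- pop$genotypes
  diag <- which(pop$truth$site_class == "SLR_diagnostic")
  expect_gt(length(diag), 0)
  f <- gm$sex == "female"
  # XY: females homozygous X allele (alt freq 0), males heterozygous (0.5)
  expect_true(all(gm$geno[f, diag] == 0L))
  expect_true(all(gm$geno[!f, diag] == 1L))
  expect_true(all(pop$truth$pos[diag] - 1 >= cfg$slr_interval[1] &
                    pop$truth$pos[diag] - 1 < cfg$slr_interval[2]))
})

test_that("background sites have equal expected frequency in both sexes", {
  cfg <- sim_config(seed = 12, diag_site_fraction = 0, missing_rate = 0,
                    chrom_length = 2e6, slr_interval = c(8e5, 1.2e6))
  pop <- simulate_population(cfg)
  gm <- pop$genotypes
  f <- gm$sex == "female"
  dp <- colMeans(gm$geno[f, , drop = FALSE]) / 2 -
    colMeans(gm$geno[!f, , drop = FALSE]) / 2
  expect_lt(abs(mean(dp)), 0.01)  # mean over 2000 sites, expectation 0
  expect_true(all(pop$truth$site_class %in%
                    c("PAR_background", "SLR_background")))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 13)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$truth$site_class, b$truth$site_class)

  s1 <- simulate_gametolog_sequences("SPECIES_CLUSTERING",
                                     c("Sdun", "Scha"), seed = 5)
  s2 <- simulate_gametolog_sequences("SPECIES_CLUSTERING",
                                     c("Sdun", "Scha"), seed = 5)
  expect_identical(as.character(s1$alignment), as.character(s2$alignment))

  t1 <- simulate_comparison_table(10, 10, 0.3, 0.8, seed = 3)
  t2 <- simulate_comparison_table(10, 10, 0.3, 0.8, seed = 3)
  expect_identical(t1, t2)
})

test_that("ZW simulation is the exact sex-mirror of XY", {
  xy <- simulate_population(sim_config(system = "XY", seed = 14,
                                       missing_rate = 0))
  zw <- simulate_population(sim_config(system = "ZW", seed = 14,
                                       missing_rate = 0))
  f <- xy$genotypes$sex == "female"
  # same RNG stream, mirrored sex roles: swapping labels maps one to the
  # other at diagnostic sites
  diag <- which(xy$truth$site_class == "SLR_diagnostic")
  expect_identical(zw$truth$site_class, xy$truth$site_class)
  expect_true(all(zw$genotypes$geno[f, diag] == 1L))
  expect_true(all(zw$genotypes$geno[!f, diag] == 0L))
})

test_that("coverage doses follow the reference haplotype", {
  cfg <- sim_config(seed = 15)
  cx <- simulate_coverage(cfg, haplotype = "X")
  par <- cx$truth$window_class == "PAR"
  slr <- cx$truth$window_class == "SLR"
  rpd <- cfg$mean_depth * cfg$window_bp / cfg$read_length
  # PAR windows: E[female] = E[male] = 2 doses; SLR male windows 1 dose
  expect_lt(abs(mean(cx$female$values[par]) / (2 * rpd) - 1), 0.01)
  expect_lt(abs(mean(cx$male$values[par]) / (2 * rpd) - 1), 0.01)
  expect_lt(abs(mean(cx$male$values[slr]) / rpd - 1), 0.01)
  expect_equal(cx$truth$mu_female[par], rep(2 * rpd, sum(par)))

  cy <- simulate_coverage(cfg, haplotype = "Y")
  ysp <- cy$truth$window_class == "SEX_SPECIFIC"
  expect_true(any(ysp))
  expect_true(all(cy$female$values[ysp] == 0))   # dose 0 exactly
})

test_that("X-linked windows give mean raw CQ within 10% of the dose ratio", {
  cfg <- sim_config(seed = 16, chrom_length = 1e7, slr_interval = c(0, 5e6),
                    window_bp = 50000)
  cov <- simulate_coverage(cfg, haplotype = "X")
  cq <- chromosome_quotient(cov$female, cov$male, normalize = FALSE)
  xl <- cov$truth$window_class == "SLR"
  expect_gte(sum(xl), 100)
  expect_lt(abs(mean(cq$track$values[xl]) - 2), 0.2)
})

test_that("comparison tables reproduce extreme and null rates", {
  ext <- simulate_comparison_table(7, 9, 0, 1, seed = 17)
  tab <- tabulate_inversions(ext)
  expect_equal(unname(tab), matrix(c(0L, 9L, 7L, 0L), 2))

  # equal rates: Fisher P roughly uniform; median over 200 replicates > 0.1
  set.seed(18)
  ps <- replicate(200, {
    rec <- simulate_comparison_table(15, 15, 0.5, 0.5)
    fisher_exact(tabulate_inversions(rec))$p_two_sided
  })
  expect_gt(median(ps), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(slr_interval = c(6e6, 4e6)))
  expect_error(sim_config(slr_interval = c(0, 0), diag_site_fraction = 0.2),
               "slr_interval")
  expect_error(sim_config(n_females = 1))
  expect_silent(sim_config(slr_interval = c(0, 0), diag_site_fraction = 0))
})
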