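test_that("the three SNP filter rules act as specified on a toy panel", {
  # 6 sites: clean, triallelic, high-depth, MAF below floor, high-missing,
  # clean
  geno <- rbind(c(0L, 1L, 1L, 0L, NA, 1L),
                c(1L, 1L, 0L, 0L, 0L, 0L),
                c(1L, 0L, 1L, 0L, NA, 1L),
                c(0L, 0L, 0L, 0L, 0L, 2L),
                c(2L, 1L, 1L, 0L, 0L, 0L),
                c(1L, 0L, 0L, 0L, 0L, 1L),
                c(0L, 1L, 1L, 0L, 0L, 0L),
                c(1L, 0L, 0L, 0L, 0L, 1L),
                c(0L, 1L, 1L, 0L, 0L, 0L),
                c(1L, 0L, 0L, 0L, 0L, 1L))
  depth <- matrix(10, 10, 6); depth[, 3] <- 60   # site 3 at 2.5x the mean
  gm <- toy_gm(geno, rep(c("female", "male"), 5), depth = depth,
               n_alleles = c(2L, 3L, 2L, 2L, 2L, 2L))
  out <- filter_snps(gm)
  tally <- attr(out, "filter_tally")
  expect_equal(out$pos, c(1000L, 6000L))         # only the clean pair left
  expect_equal(unname(tally["kept"]), 2L)
  expect_equal(unname(tally["nonbiallelic"]), 1L)
  expect_gte(unname(tally["depth"]), 1L)

  # all sites clean -> identity
  clean <- toy_gm(geno[, c(1, 6)], rep(c("female", "male"), 5))
  expect_equal(suppressWarnings(filter_snps(clean))$pos, clean$pos)

  # MAF exactly at the floor is retained (rule is strictly "< 5%")
  g <- matrix(0L, 10, 1); g[1, 1] <- 1L          # MAF 1/20 = 0.05
  gmaf <- toy_gm(g, rep(c("female", "male"), 5))
  expect_equal(length(suppressWarnings(filter_snps(gmaf))$pos), 1L)
  g2 <- matrix(0L, 11, 1); g2[1, 1] <- 1L        # MAF 1/22 < 0.05
  gmaf2 <- toy_gm(g2, c(rep(c("female", "male"), 5), "male"))
  expect_equal(length(suppressWarnings(filter_snps(gmaf2))$pos), 0L)

  empty <- subset_sites(gm, integer(0))
  expect_warning(filter_snps(empty), "empty")
})

test_that("Weir-Cockerham identities hold at archetypal sites", {
  for (n in c(2L, 5L, 20L, 33L)) {
    # XY-diagnostic: females all 0/0, males all 0/1 -> theta = 1/2 exactly
    geno <- cbind(c(rep(0L, n), rep(1L, n)),
                  c(rep(0L, n), rep(2L, n)),    # fixed difference
                  rep(c(0L, 1L, 2L, 1L), length.out = 2 * n))
    gm <- toy_gm(geno, c(rep("female", n), rep("male", n)))
    comp <- wc_site_components(gm)
    expect_equal(comp$a[1], 1 / 8)
    expect_equal(comp$b[1], -1 / 8)
    expect_equal(comp$c[1], 1 / 4)
    expect_equal(comp$theta[1], 0.5)
    expect_equal(comp$theta[2], 1)              # maximal differentiation
  }
  # equal frequencies and heterozygosities: a = 0 numerator at most
  geno <- cbind(rep(c(0L, 1L, 2L, 1L), 5))
  gm <- toy_gm(geno, rep(c("female", "male"), 10))
  comp <- wc_site_components(gm)
  expect_lte(comp$a[1], 1e-12)

  # monomorphic site -> NA components
  gmono <- toy_gm(matrix(0L, 4, 1), c("female", "female", "male", "male"))
  expect_true(is.na(wc_site_components(gmono)$a[1]))
})

test_that("theta is invariant to swapping the sex labels", {
  set.seed(31)
  geno <- matrix(rbinom(40 * 50, 2, runif(50, 0.1, 0.9)[rep(1:50, each = 40)]),
                 40, 50)
  sex <- rep(c("female", "male"), 20)
  a <- wc_site_components(toy_gm(geno, sex))
  b <- wc_site_components(toy_gm(geno, ifelse(sex == "female", "male",
                                              "female")))
  expect_equal(a$theta, b$theta, tolerance = 1e-12)
})

test_that("windowed theta is the ratio of sums, matching direct summation", {
  set.seed(32)
  n_sites <- 1000
  geno <- matrix(rbinom(40 * n_sites, 2,
                        rep(runif(n_sites, 0.05, 0.95), each = 40)),
                 40, n_sites)
  gm <- toy_gm(geno, rep(c("female", "male"), 20),
               pos = sort(sample.int(99000, n_sites)))
  comp <- wc_site_components(gm)
  ok <- !is.na(comp$a)
  prof <- fst_windows(comp, window_bp = 100000, step_bp = 100000,
                      chrom_length = 100000)
  expect_equal(prof$track$values[1],
               ratio_of_sums(comp$a[ok],
                             (comp$a + comp$b + comp$c)[ok]),
               tolerance = 1e-12)
  # ratio of sums differs from mean of ratios on heterogeneous windows
  expect_false(isTRUE(all.equal(prof$track$values[1],
                                mean(comp$theta, na.rm = TRUE))))

  # one site per window: window theta equals site theta
  g1 <- toy_gm(geno[, 1:3], rep(c("female", "male"), 20),
               pos = c(5000L, 15000L, 25000L))
  c1 <- wc_site_components(g1)
  p1 <- fst_windows(c1, window_bp = 10000, step_bp = 10000,
                    chrom_length = 30000)
  expect_equal(p1$track$values, c1$theta, tolerance = 1e-12)

  expect_error(fst_windows(comp, window_bp = 1000, step_bp = 10000),
               "window_bp")
})

test_that("mixed windows fall between diagnostic and background theta", {
  n <- 20
  diag_block <- cbind(matrix(rep(c(rep(0L, n), rep(1L, n)), 10), ncol = 10))
  set.seed(33)
  bg_block <- matrix(rbinom(2 * n * 10, 2, 0.3), ncol = 10)
  gm <- toy_gm(cbind(diag_block, bg_block),
               c(rep("female", n), rep("male", n)),
               pos = seq(1000L, 20000L, 1000L))
  comp <- wc_site_components(gm)
  prof <- fst_windows(comp, window_bp = 20000, step_bp = 20000,
                      chrom_length = 20000)
  w <- prof$track$values[1]
  expect_gt(w, 0)
  expect_lt(w, 0.5)
  expect_equal(w, sum(comp$a, na.rm = TRUE) /
                 sum(comp$a + comp$b + comp$c, na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("SLR windows dominate PAR windows on default simulations", {
  cfg <- sim_config(seed = 34)
  pop <- simulate_population(cfg)
  gm <- filter_snps(pop$genotypes)
  comp <- wc_site_components(gm)
  prof <- fst_windows(comp, chrom_length = cfg$chrom_length)
  centers <- window_centers(prof$track)
  in_slr <- centers > cfg$slr_interval[1] + 1e5 &
    centers < cfg$slr_interval[2] - 1e5
  in_par <- centers < cfg$slr_interval[1] - 1e5 |
    centers > cfg$slr_interval[2] + 1e5
  mean_slr <- mean(prof$track$values[in_slr], na.rm = TRUE)
  mean_par <- mean(abs(prof$track$values[in_par]), na.rm = TRUE)
  expect_gte(mean_slr, 10 * mean_par)
})
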