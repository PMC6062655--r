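test_that("sim_config validates its invariants", {
  expect_error(sim_config(chrom_lengths = c(1e5)), "named")
  expect_error(sim_config(snp_density = 0), "snp_density")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(
    sim_config(sweeps = tibble::tibble(chrom = "chr1", start = 4.9e6,
                                       end = 5.1e6, maf_ceiling = 0.01)),
    "within its chromosome")
  # a sweep ceiling at/above the background support cannot depress Hp
  expect_error(
    sim_config(sweeps = tibble::tibble(chrom = "chr1", start = 1e5,
                                       end = 2e5, maf_ceiling = 0.1)),
    "maf_ceiling")
  expect_error(
    sim_config(sweeps = tibble::tibble(chrom = "chrX", start = 1, end = 10,
                                       maf_ceiling = 0.01)),
    "unknown chromosome")
})

test_that("simulate_sites is deterministic, sorted, and respects sweeps", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e5, chr2 = 3e5),
                    snp_density = 10,
                    sweeps = tibble::tibble(chrom = "chr1", start = 100001,
                                            end = 200000, maf_ceiling = 0.02),
                    seed = 42)
  s1 <- simulate_sites(cfg)
  s2 <- simulate_sites(cfg)
  expect_identical(s1, s2)
  for (ch in unique(s1$chrom)) {
    expect_true(all(diff(s1$pos[s1$chrom == ch]) > 0))
  }
  # realized site counts close to Poisson expectation (5 sigma)
  n1 <- sum(s1$chrom == "chr1"); lam1 <- 10 * 500
  expect_lt(abs(n1 - lam1), 5 * sqrt(lam1))
  # in-sweep sites flagged and folded below the ceiling
  insw <- s1$chrom == "chr1" & s1$pos >= 100001 & s1$pos <= 200000
  expect_identical(s1$in_sweep, insw)
  maf <- pmin(s1$freq_alt[insw], 1 - s1$freq_alt[insw])
  expect_true(all(maf <= 0.02))
  # alleles are single distinct bases
  expect_true(all(s1$ref %in% c("A", "C", "G", "T")))
  expect_true(all(s1$alt %in% c("A", "C", "G", "T")))
  expect_true(all(s1$ref != s1$alt))
})

test_that("a zero-MAF sweep yields monomorphic in-sweep sites", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e5), snp_density = 10,
                    sweeps = tibble::tibble(chrom = "chr1", start = 50001,
                                            end = 150000, maf_ceiling = 0),
                    seed = 3)
  s <- simulate_sites(cfg)
  insw <- s$pos >= 50001 & s$pos <= 150000
  expect_true(all(s$freq_alt[insw] %in% c(0, 1)))
})

test_that("overlapping sweeps on one chromosome are rejected", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6),
                    sweeps = tibble::tibble(chrom = "chr1",
                                            start = c(1e5, 1.5e5),
                                            end = c(2e5, 2.5e5),
                                            maf_ceiling = 0.02),
                    seed = 1)
  expect_error(simulate_sites(cfg), "Overlapping sweep")
})

test_that("background expected heterozygosity matches the analytic mean", {
  # independent oracle: numerically integrate 2f(1-f) over Uniform(0.05, 0.5)
  analytic <- integrate(function(f) 2 * f * (1 - f) * dunif(f, 0.05, 0.5),
                        0.05, 0.5)$value
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), snp_density = 14,
                    sweeps = NULL, seed = 11)
  s <- simulate_sites(cfg)
  f <- s$freq_alt
  expect_gt(nrow(s), 20000)
  expect_lt(abs(mean(2 * f * (1 - f)) - analytic), 0.005)
})

test_that("genotype draws follow the site frequency and missing rules", {
  sites <- tibble::tibble(chrom = "chr1", pos = 1:3, ref = "A", alt = "C",
                          freq_alt = c(1, 0, 0.5))
  g <- genotype_samples(sites, 4, missing_rate = 0, seed = 1)
  expect_true(all(g[1, ] == 2L))
  expect_true(all(g[2, ] == 0L))
  # frequency 0.5 with many samples: alt fraction within 3 binomial SEs
  big <- tibble::tibble(chrom = "chr1", pos = 1, ref = "A", alt = "C",
                        freq_alt = 0.5)
  gb <- genotype_samples(big, 10000, missing_rate = 0, seed = 5)
  frac <- sum(gb) / (2 * 10000)
  se <- sqrt(0.5 * 0.5 / (2 * 10000))
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_error(genotype_samples(sites, 0), "n_samples")
  expect_error(genotype_samples(sites, 4, missing_rate = 1), "missing_rate")
  gm <- genotype_samples(sites, 100, missing_rate = 0.3, seed = 2)
  miss <- mean(is.na(gm))
  expect_lt(abs(miss - 0.3), 0.1)
})

test_that("VCF output round-trips losslessly through the ingest path", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e5, chr2 = 5e4),
                    snp_density = 8, sweeps = NULL, missing_rate = 0.05,
                    populations = "pp", seed = 21)
  sim <- simulate_population(cfg, "pp", out_dir = tempfile())
  snps <- suppressMessages(read_biallelic_snps(sim$vcf))
  expect_equal(snps$sites$pos, sim$sites$pos)
  expect_identical(snps$sites$ref, sim$sites$ref)
  # pooled counts via VCF equal counts straight from the dosage matrix
  from_vcf <- suppressMessages(pool_allele_counts(snps))
  direct <- suppressMessages(
    pool_allele_counts(list(sites = sim$sites, gt = sim$genotypes)))
  expect_equal(from_vcf$n_major, direct$n_major)
  expect_equal(from_vcf$n_minor, direct$n_minor)
  # missing genotypes written as ./.
  lines <- readLines(sim$vcf)
  expect_true(any(grepl("\\./\\.", lines)))
})

test_that("zero sites give a header-only VCF and unsorted input errors", {
  p <- tempfile(fileext = ".vcf")
  empty <- tibble::tibble(chrom = character(), pos = numeric(),
                          ref = character(), alt = character())
  write_vcf(empty, matrix(integer(), 0, 2), p, c(chr1 = 1000),
            sample_names = c("a", "b"))
  lines <- readLines(p)
  expect_true(all(startsWith(lines, "#")))
  bad <- tibble::tibble(chrom = "chr1", pos = c(10, 5), ref = "A", alt = "C")
  expect_error(write_vcf(bad, matrix(0L, 2, 1), p, c(chr1 = 1000)), "sorted")
})

test_that("truth BED uses 0-based half-open coordinates and sorts", {
  p <- tempfile(fileext = ".bed")
  write_truth(tibble::tibble(chrom = "chr1", start = 100000, end = 200000,
                             maf_ceiling = 0.02), p)
  expect_equal(readLines(p), "chr1\t99999\t200000\t0.02")
  write_truth(tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric(), maf_ceiling = numeric()), p)
  expect_length(readLines(p), 0)
  two <- tibble::tibble(chrom = c("chr2", "chr1"), start = c(11, 21),
                        end = c(30, 40), maf_ceiling = 0.01)
  write_truth(two, p)
  lines <- readLines(p)
  expect_length(lines, 2)
  expect_match(lines[1], "^chr1\t20\t40")
  rt <- read_truth(p)
  expect_equal(rt$start, c(21, 11))
  expect_equal(rt$end, c(40, 30))
})

test_that("identical config and seed reproduce byte-identical VCFs", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e5), snp_density = 5,
                    sweeps = NULL, populations = "q", seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_population(cfg, "q", d1)
  simulate_population(cfg, "q", d2)
  expect_identical(readLines(file.path(d1, "q.vcf")),
                   readLines(file.path(d2, "q.vcf")))
})

test_that("adding a population leaves existing streams untouched", {
  cfg1 <- sim_config(chrom_lengths = c(chr1 = 1e5), snp_density = 5,
                     sweeps = NULL, populations = c("a", "b"), seed = 13)
  cfg2 <- sim_config(chrom_lengths = c(chr1 = 1e5), snp_density = 5,
                     sweeps = NULL, populations = c("a", "b", "c"), seed = 13)
  expect_identical(simulate_sites(cfg1, "a"), simulate_sites(cfg2, "a"))
  expect_identical(simulate_sites(cfg1, "b"), simulate_sites(cfg2, "b"))
  expect_false(identical(simulate_sites(cfg2, "b"), simulate_sites(cfg2, "c")))
})

test_that("default generator calibrates to the intended Hp band", {
  # >= 1,000 windows; genome-mean window Hp within [0.25, 0.40]
  cfg <- sim_config(chrom_lengths = c(chr1 = 5.05e6, chr2 = 5.05e6),
                    populations = "calib", seed = 101)
  sim <- simulate_population(cfg, "calib")
  counts <- suppressMessages(
    pool_allele_counts(list(sites = sim$sites, gt = sim$genotypes)))
  scan <- hp_scan(counts, cfg$chrom_lengths, population = "calib")
  expect_gte(scan$summary$n_analyzed, 1000)
  expect_gt(scan$summary$mean_hp, 0.25)
  expect_lt(scan$summary$mean_hp, 0.40)
  # sweep contrast: windows fully inside planted sweeps sit far below background
  w <- scan$windows[scan$windows$passes_filter, ]
  sw <- cfg$sweeps
  in_sweep <- rep(FALSE, nrow(w))
  for (k in seq_len(nrow(sw))) {
    in_sweep <- in_sweep | (w$chrom == sw$chrom[k] & w$start >= sw$start[k] &
                              w$end <= sw$end[k])
  }
  bg_mean <- mean(w$hp[!in_sweep]); bg_sd <- sd(w$hp[!in_sweep])
  expect_lt(mean(w$hp[in_sweep]), bg_mean - 4 * bg_sd)
})
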