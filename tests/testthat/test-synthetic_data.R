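test_that("zero switch probability copies whole founder haplotypes", {
  cfg <- sim_config(n_individuals = 10, n_snps = 500,
                    recombination_switch_prob = 0, seed = 5)
  sim <- simulate_neutral(cfg)
  for (i in seq_len(nrow(sim$haplotypes$alleles))) {
    seg <- sim$truth$founder_segments[[i]]
    expect_identical(nrow(seg), 1L)
  }
})

test_that("switch probability one with two founders redraws i.i.d. per SNP", {
  cfg <- sim_config(n_individuals = 1, n_snps = 10000,
                    n_founder_haplotypes = 2,
                    recombination_switch_prob = 1, seed = 6)
  sim <- simulate_neutral(cfg)
  seg <- sim$truth$founder_segments[[1]]
  fid <- rep(seg$founder, seg$end_snp - seg$start_snp + 1L)
  agree <- mean(fid[-1] == fid[-length(fid)])
  se <- sqrt(0.25 / (length(fid) - 1))
  expect_lt(abs(agree - 0.5), 3 * se)
})

test_that("the simulator is bit-identical under a fixed seed", {
  cfg <- sim_config(n_individuals = 20, n_snps = 800, seed = 99,
                    sweep = list(enabled = TRUE))
  run <- function() {
    nt <- simulate_neutral(cfg)
    sw <- overlay_sweep(nt$haplotypes, cfg)
    pa <- pair_with_autozygosity(sw$haplotypes, cfg)
    nz <- inject_noise(pa$genotypes, cfg)
    list(nt$haplotypes$alleles, sw$haplotypes$alleles,
         pa$genotypes$dosages, nz$genotypes$dosages,
         pa$truth$tracts, sw$truth$focal_pos)
  }
  expect_identical(run(), run())
})

test_that("the sweep overlay forces a shared carrier haplotype over the halo", {
  cfg <- sim_config(n_individuals = 200, n_snps = 4000, seed = 12,
                    sweep = list(enabled = TRUE, carrier_fraction = 0.5,
                                 halo_bp = 2e6))
  nt <- simulate_neutral(cfg)
  sw <- overlay_sweep(nt$haplotypes, cfg)
  tr <- sw$truth
  expect_identical(length(tr$carriers), 200L)  # 0.5 of 400, deterministic
  halo <- which(sw$haplotypes$variants$pos >= tr$sweep_interval$start &
                  sw$haplotypes$variants$pos <= tr$sweep_interval$end)
  carrier_haps <- sw$haplotypes$alleles[tr$carriers, halo, drop = FALSE]
  expect_true(all(apply(carrier_haps, 2, function(col)
    length(unique(col)) == 1L)))
  expect_true(all(sw$haplotypes$alleles[tr$carriers, tr$focal_index] == 1L))
  # non-carriers untouched
  others <- setdiff(seq_len(400), tr$carriers)
  expect_identical(sw$haplotypes$alleles[others, ],
                   nt$haplotypes$alleles[others, ])
})

test_that("a disabled sweep returns the input bit-for-bit", {
  cfg <- sim_config(n_individuals = 15, n_snps = 300, seed = 2)
  nt <- simulate_neutral(cfg)
  sw <- overlay_sweep(nt$haplotypes, cfg)
  expect_identical(sw$haplotypes, nt$haplotypes)
  expect_null(sw$truth$sweep_interval)
})

test_that("without tracts, heterozygosity matches the founder-pool expectation", {
  cfg <- sim_config(n_individuals = 150, n_snps = 3000, seed = 8,
                    autozygosity = list(tract_rate_per_bp = 0))
  nt <- simulate_neutral(cfg)
  pa <- pair_with_autozygosity(nt$haplotypes, cfg)
  expect_identical(nrow(pa$truth$tracts), 0L)
  # expected per-SNP het rate: two independently drawn founder alleles
  # differ with prob 2 f (1 - f), f the founder-pool allele frequency
  founders_f <- colMeans(nt$haplotypes$alleles)  # close proxy at 300 haps
  het_obs <- mean(pa$genotypes$dosages == 1L)
  het_exp <- mean(2 * founders_f * (1 - founders_f))
  expect_lt(abs(het_obs - het_exp), 0.02)
})

test_that("dosages inside forced tracts are strictly homozygous", {
  cfg <- sim_config(n_individuals = 50, n_snps = 2000, seed = 14,
                    autozygosity = list(tract_rate_per_bp = 5e-8,
                                        mean_tract_length_bp = 3e6))
  nt <- simulate_neutral(cfg)
  pa <- pair_with_autozygosity(nt$haplotypes, cfg)
  tr <- pa$truth$tracts
  expect_gt(nrow(tr), 0)
  pos <- pa$genotypes$variants$pos
  for (k in seq_len(nrow(tr))) {
    row <- match(tr$sample_id[k], pa$genotypes$sample_ids)
    d <- pa$genotypes$dosages[row, pos >= tr$start[k] & pos <= tr$end[k]]
    expect_true(all(d %in% c(0L, 2L)))
  }
})

test_that("tract lengths are exponential with the configured mean", {
  cfg <- sim_config(n_individuals = 150, n_snps = 200, seed = 21,
                    autozygosity = list(tract_rate_per_bp = 6.7e-8,
                                        mean_tract_length_bp = 2e6))
  nt <- simulate_neutral(cfg)
  pa <- pair_with_autozygosity(nt$haplotypes, cfg)
  len <- pa$truth$tracts$end - pa$truth$tracts$start
  expect_gt(length(len), 800)
  se <- 2e6 / sqrt(length(len))
  expect_lt(abs(mean(len) - 2e6), 3 * se)
})

test_that("noise injection matches its configured rates", {
  cfg0 <- sim_config(n_individuals = 10, n_snps = 200, seed = 1,
                     error_rate = 0, missing_rate = 0)
  nt <- simulate_neutral(cfg0)
  g <- pair_with_autozygosity(nt$haplotypes, cfg0)$genotypes
  nz <- inject_noise(g, cfg0)
  expect_identical(nz$genotypes$dosages, g$dosages)

  cfg1 <- sim_config(n_individuals = 10, n_snps = 200, seed = 1,
                     missing_rate = 1)
  nz1 <- inject_noise(g, cfg1)
  expect_true(all(is.na(nz1$genotypes$dosages)))

  # binomial count on 10^6 cells at rate 0.01
  set.seed(33)
  big <- genotype_set(matrix(0L, 100, 10000), sprintf("s%d", 1:100),
                      variant_table(rep("1", 10000),
                                    sort(sample.int(2e8, 10000))))
  cfg2 <- sim_config(n_individuals = 100, n_snps = 10000, seed = 33,
                     error_rate = 0.01, missing_rate = 0)
  nz2 <- inject_noise(big, cfg2)
  n_pert <- sum(nz2$error_mask)
  expect_lt(abs(n_pert - 10000), 3 * sqrt(1e6 * 0.01 * 0.99))
  # every flagged cell really changed
  expect_true(all(nz2$genotypes$dosages[nz2$error_mask] !=
                    big$dosages[nz2$error_mask]))
})
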