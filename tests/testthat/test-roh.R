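make_geno <- function(dos, pos, chrom = "1") {
  genotype_set(matrix(dos, nrow = 1), "ind1",
               variant_table(rep(chrom, length(pos)), pos))
}

test_that("an unbroken homozygous stretch is called as one segment", {
  pos <- seq(1e6, 2.5e6, length.out = 200)
  g <- make_geno(rep(0L, 200), round(pos))
  segs <- detect_roh(g)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_snps, 200L)
  expect_equal(segs$length_bp, 1.5e6)
  expect_equal(segs$start_bp, 1e6)
  expect_equal(segs$end_bp, 2.5e6)
})

test_that("one heterozygous call inside a run is tolerated", {
  pos <- round(seq(1e6, 2.5e6, length.out = 200))
  dos <- rep(2L, 200)
  dos[100] <- 1L
  segs <- detect_roh(make_geno(dos, pos))
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_snps, 200L)
})

test_that("a gap over 100 kb splits the run and short halves are discarded", {
  # two homozygous halves of ~0.9 Mb separated by a 150-kb gap
  pos <- c(round(seq(1e6, 1.9e6, length.out = 100)),
           round(seq(2.05e6, 2.95e6, length.out = 100)))
  segs <- detect_roh(make_geno(rep(0L, 200), pos))
  expect_identical(nrow(segs), 0L)
})

test_that("chromosomes with fewer SNPs than the window are skipped with a warning", {
  g <- make_geno(rep(0L, 50), seq(1e6, 2e6, length.out = 50))
  expect_warning(segs <- detect_roh(g), "fewer than")
  expect_identical(nrow(segs), 0L)
  g2 <- genotype_set(matrix(0L, 1, 3), "a",
                     variant_table(rep("1", 3), c(1, 2, 3)))
  g2$variants$pos <- c(3L, 2L, 1L)
  expect_error(detect_roh(g2), "sorted")
})

test_that("detect_roh matches the exhaustive reference on random panels", {
  set.seed(55)
  params <- roh_params(window_snps = 20, min_snps_per_segment = 20,
                       min_length_bp = 2e5)
  for (r in 1:200) {
    g <- random_roh_panel(m = sample(100:300, 1),
                          het_rate = runif(1, 0, 0.08),
                          miss_rate = runif(1, 0, 0.06),
                          spacing_bp = sample(c(4000, 8000, 15000), 1))
    got <- detect_roh(g, params)
    ref <- oracle_roh(g$dosages[1, ], g$variants$pos, params)
    expect_identical(nrow(got), nrow(ref))
    if (nrow(ref)) {
      got <- got[order(got$start_bp), ]
      expect_equal(got$start_bp, ref$start_bp)
      expect_equal(got$end_bp, ref$end_bp)
      expect_identical(got$n_snps, ref$n_snps)
    }
  }
})

test_that("length classes are left-closed and summaries add up", {
  segs <- data.frame(
    sample_id = "a", chrom = "1",
    start_bp = 0, end_bp = 1,
    n_snps = 100L,
    length_bp = c(1.2e6, 1.9e6, 2e6, 3.5e6, 5e6, 9e6))
  class(segs) <- c("roh_segments", "data.frame")
  s <- classify_and_summarize(segs, genome_length_bp = 100e6,
                              n_individuals = 2)
  expect_identical(s$n[s$class == "1-2Mb"], 2L)
  expect_identical(s$n[s$class == "2-4Mb"], 2L)   # exactly 2 Mb falls here
  expect_identical(s$n[s$class == "4-8Mb"], 1L)
  expect_identical(s$n[s$class == ">8Mb"], 1L)
  expect_identical(s$n[s$class == "total"], 6L)
  expect_equal(sum(s$n[s$class != "total"]), s$n[s$class == "total"])
  expect_equal(sum(s$coverage_pct[s$class != "total"]),
               s$coverage_pct[s$class == "total"])
  expect_equal(s$coverage_pct[s$class == "total"],
               sum(segs$length_bp) / (100e6 * 2) * 100)
})

test_that("class-level totals reproduce printed-table arithmetic", {
  tot <- roh_class_totals(counts = c(10, 30, 5, 5),
                          mean_lengths_mb = c(1.5, 3, 5, 10),
                          coverage_pct = c(0.5, 1.5, 0.7, 0.3))
  expect_identical(tot$total_n, 50)
  expect_equal(tot$percent, c(20, 60, 10, 10))
  expect_equal(tot$weighted_mean_mb, round((15 + 90 + 25 + 50) / 50, 2))
  expect_equal(tot$total_coverage_pct, 3.0)
})

test_that("per-chromosome summary averages coverage over all individuals", {
  segs <- data.frame(sample_id = c("a", "a", "b", "a"),
                     chrom = c("1", "2", "2", "2"),
                     start_bp = c(10e6, 1e6, 2e6, 30e6),
                     end_bp = c(20e6, 2e6, 3e6, 31e6),
                     n_snps = 100L,
                     length_bp = c(10e6, 1e6, 1e6, 1e6))
  class(segs) <- c("roh_segments", "data.frame")
  s <- per_chromosome_summary(segs, c("1" = 100e6, "2" = 50e6),
                              n_individuals = 2)
  # chr1: one 10-Mb ROH in one of two individuals -> mean coverage 5%
  expect_equal(s$mean_coverage_pct[s$chrom == "1"], 5)
  expect_identical(s$n_segments[s$chrom == "2"], 3L)
  expect_equal(s$mean_coverage_pct[s$chrom == "2"],
               (2e6 / 50e6 + 1e6 / 50e6) / 2 * 100)
  expect_error(per_chromosome_summary(segs, c("1" = 15e6, "2" = 50e6), 2),
               "beyond")
})

test_that("forced autozygosity tracts are recovered by the detector", {
  cfg <- sim_config(n_individuals = 40, n_snps = 10000, seed = 77,
                    autozygosity = list(tract_rate_per_bp = 2e-8,
                                        mean_tract_length_bp = 3e6),
                    error_rate = 0.001, missing_rate = 0.01)
  nt <- simulate_neutral(cfg)
  pa <- pair_with_autozygosity(nt$haplotypes, cfg)
  nz <- inject_noise(pa$genotypes, cfg)
  segs <- detect_roh(nz$genotypes)
  tr <- pa$truth$tracts
  tr$len <- tr$end - tr$start
  big <- tr[tr$len >= 1.5e6, ]
  expect_gt(nrow(big), 10)
  cov <- 0
  for (k in seq_len(nrow(big))) {
    s <- segs[segs$sample_id == big$sample_id[k], ]
    if (nrow(s)) {
      cov <- cov + sum(pmax(pmin(s$end_bp, big$end[k]) -
                              pmax(s$start_bp, big$start[k]), 0))
    }
  }
  expect_gt(cov / sum(big$len), 0.85)
})
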