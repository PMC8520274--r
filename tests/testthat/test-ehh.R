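test_that("EHH is 1 at the core and follows the pairwise-identity definition", {
  # 4 carriers of allele 1 at the core (SNP 2); at SNP 3 they split {2,1,1}
  hap <- rbind(c(0L, 1L, 0L, 0L),
               c(0L, 1L, 0L, 1L),
               c(1L, 1L, 1L, 0L),
               c(0L, 1L, 1L, 1L),
               c(0L, 0L, 0L, 0L),
               c(1L, 0L, 1L, 0L))
  # at SNP 3 carriers have alleles 0,0,1,1 -> split {2,2}; redo to {2,1,1}:
  hap[4, 3] <- 0L  # alleles now 0,0,1,0 -> groups {1,2,4},{3}? recompute below
  # carriers 1,2,3,4; SNP3 alleles 0,0,1,0 -> {1,2,4} and {3}: EHH = 3/6
  h <- haplotype_set(hap, c("a", "b", "c"),
                     variant_table(rep("1", 4), c(100, 200, 300, 400)))
  dec <- compute_ehh(h, core_index = 2, allele = 1)
  expect_equal(dec$grid$ehh[dec$grid$index == 2], 1)
  expect_equal(dec$grid$ehh[dec$grid$index == 3], 3 / 6)
  # at SNP 4 the {1,2,4} group splits on alleles 0,1,1 -> {2,4} only: 1/6
  expect_equal(dec$grid$ehh[dec$grid$index == 4], 1 / 6)
})

test_that("a four-carrier panel with one dropped haplotype gives EHH 1/6", {
  # carriers {1,2,3,4} at SNP 1; haplotype 4 is missing at SNP 2 and is
  # dropped there; remaining alleles 0,0,1 partition {2},{1} -> 1 pair of 6
  hap <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, NA))
  h <- haplotype_set(hap, c("a", "b"), variant_table(rep("1", 2), c(10, 2000)))
  dec <- compute_ehh(h, 1, 1)
  expect_equal(dec$grid$ehh[dec$grid$index == 2], 1 / 6)
})

test_that("EHH stays 1 when all carriers share one extended haplotype", {
  core_hap <- c(1L, 0L, 1L, 1L, 0L)
  other <- c(0L, 1L, 0L, 0L, 1L)
  hap <- rbind(core_hap, core_hap, core_hap, core_hap, other, other)
  h <- haplotype_set(hap, c("a", "b", "c"),
                     variant_table(rep("1", 5), c(1, 50, 100, 150, 200) * 1000))
  dec <- compute_ehh(h, 3, 1)
  expect_equal(dec$grid$ehh, rep(1, 5))
})

test_that("EHH errors with fewer than two carriers", {
  hap <- rbind(c(1L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 0L))
  h <- haplotype_set(hap, c("a", "b"), variant_table(rep("1", 2), c(10, 20)))
  expect_error(compute_ehh(h, 1, 1), "fewer than 2")
})

test_that("compute_ehh matches the brute-force pairwise oracle exactly", {
  set.seed(90)
  for (r in 1:30) {
    h <- random_panel(n_hap = sample(6:20, 1), m = sample(8:15, 1),
                      miss_rate = 0.08)
    m <- ncol(h$alleles)
    core <- sample(seq_len(m), 1)
    for (allele in 0:1) {
      carriers <- sum(!is.na(h$alleles[, core]) & h$alleles[, core] == allele)
      if (carriers < 2) next
      dec <- compute_ehh(h, core, allele)
      for (x in seq_len(m)) {
        expect_equal(dec$grid$ehh[dec$grid$index == x],
                     oracle_ehh(h$alleles, core, allele, x),
                     info = sprintf("rep %d core %d allele %d marker %d",
                                    r, core, allele, x))
      }
    }
  }
})

test_that("EHH decays monotonically away from the core", {
  set.seed(4)
  for (r in 1:15) {
    h <- random_panel(n_hap = 16, m = 20, miss_rate = 0.05)
    core <- sample(2:19, 1)
    for (allele in 0:1) {
      n_car <- sum(!is.na(h$alleles[, core]) & h$alleles[, core] == allele)
      if (n_car < 2) next
      dec <- compute_ehh(h, core, allele)
      g <- dec$grid
      right <- g$ehh[g$pos >= dec$core_pos]
      left <- rev(g$ehh[g$pos <= dec$core_pos])
      expect_true(all(diff(right) <= 1e-12))
      expect_true(all(diff(left) <= 1e-12))
    }
  }
})

test_that("iHH trapezoid truncates at the EHH cutoff and at large gaps", {
  mk_decay <- function(pos, ehh, core_pos) {
    structure(list(core_index = 1L, allele = 1L, core_pos = core_pos,
                   grid = data.frame(index = seq_along(pos), pos = pos,
                                     ehh = ehh)),
              class = "ehh_decay")
  }
  # one-sided grid (0, 1.0), (1000, 0.5), (2000, 0.04), cutoff 0.05:
  # only the first trapezoid (1.0 + 0.5)/2 * 1000 = 750 integrates
  d <- mk_decay(c(0, 1000, 2000), c(1, 0.5, 0.04), core_pos = 0)
  expect_equal(as.numeric(compute_ihh(d, ehh_cutoff = 0.05,
                                      max_gap_bp = 2e5)), 750)

  # flat decay of 1 over [-L, +L] integrates to the rectangle 2L
  L <- 5000
  d2 <- mk_decay(seq(-L, L, by = 1000), rep(1, 11), core_pos = 0)
  expect_equal(as.numeric(compute_ihh(d2)), 2 * L)

  # a single-marker side contributes zero and flags untruncatable
  d3 <- mk_decay(0, 1, core_pos = 0)
  v <- compute_ihh(d3)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "untruncatable"))

  # gap over max_gap truncates at the near edge
  d4 <- mk_decay(c(0, 1000, 300000), c(1, 0.8, 0.8), core_pos = 0)
  expect_equal(as.numeric(compute_ihh(d4, max_gap_bp = 2e5)),
               0.5 * (1 + 0.8) * 1000)
})

test_that("per-SNP iHH from the scan equals compute_ehh plus compute_ihh", {
  set.seed(31)
  h <- assign_ancestral(random_panel(n_hap = 18, m = 15, miss_rate = 0))
  ihs <- compute_ihs(h, maf_min = 0.05, min_bin_n = 1)
  for (s in which(!is.na(ihs$ihh_a))[1:5]) {
    anc <- h$ancestral$ancestral_allele[s]
    ia <- compute_ihh(compute_ehh(h, s, anc))
    id <- compute_ihh(compute_ehh(h, s, 1L - anc))
    expect_equal(ihs$ihh_a[s], as.numeric(ia))
    expect_equal(ihs$ihh_d[s], as.numeric(id))
  }
})
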