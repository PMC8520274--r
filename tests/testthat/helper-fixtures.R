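# In-code fixtures shared across test files.

# A small phased VCF on disk: 3 samples x 5 autosomal SNPs plus one record
# on the X chromosome and one fully missing genotype.
write_tiny_vcf <- function(path, with_x = TRUE, unphased = FALSE) {
  sep <- if (unphased) "/" else "|"
  gt <- function(a, b) paste0(a, sep, b)
  rows <- c(
    paste("1", "1000", "s1", "A", "G", ".", "PASS", ".", "GT",
          gt(0, 1), gt(1, 1), gt(0, 0), sep = "\t"),
    paste("1", "2000", "s2", "C", "T", ".", "PASS", ".", "GT",
          gt(0, 0), "./.", gt(0, 1), sep = "\t"),
    paste("1", "3000", "s3", "G", "A", ".", "PASS", ".", "GT",
          gt(1, 0), gt(0, 0), gt(1, 1), sep = "\t"),
    paste("2", "1500", "s4", "T", "C", ".", "PASS", ".", "GT",
          gt(0, 1), gt(0, 1), gt(0, 0), sep = "\t"),
    paste("2", "2500", "s5", "A", "C", ".", "PASS", ".", "GT",
          gt(1, 1), gt(0, 0), gt(0, 1), sep = "\t"))
  if (with_x) {
    rows <- c(rows,
              paste("X", "500", "sx", "A", "G", ".", "PASS", ".", "GT",
                    gt(0, 1), gt(0, 0), gt(1, 1), sep = "\t"))
  }
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "cowA", "cowB", "cowC", sep = "\t"),
               rows), path)
  path
}

# Random small haplotype panel for oracle comparisons.
random_panel <- function(n_hap = 12, m = 15, miss_rate = 0.05) {
  if (n_hap %% 2L != 0L) n_hap <- n_hap + 1L
  hap <- matrix(rbinom(n_hap * m, 1L, runif(m, 0.2, 0.8)[rep(1:m, each = n_hap)]),
                nrow = n_hap)
  hap[runif(n_hap * m) < miss_rate] <- NA_integer_
  pos <- sort(sample.int(1e6, m))
  haplotype_set(hap, sprintf("s%02d", seq_len(n_hap / 2)),
                variant_table(rep("1", m), pos))
}

# Genotype panel with mostly homozygous calls and irregular spacing, for
# the ROH oracle comparisons.
random_roh_panel <- function(m = 250, het_rate = 0.02, miss_rate = 0.02,
                             spacing_bp = 12000) {
  dos <- sample(c(0L, 2L), m, replace = TRUE)
  r <- runif(m)
  dos[r < het_rate] <- 1L
  dos[r > 1 - miss_rate] <- NA_integer_
  pos <- cumsum(pmax(1, round(rexp(m, 1 / spacing_bp))))
  genotype_set(matrix(dos, nrow = 1), "ind1",
               variant_table(rep("1", m), pos))
}

# Build an ihs_result carrier by hand for window-scan unit tests.
fake_ihs <- function(chrom, pos, std) {
  out <- data.frame(chrom = as.character(chrom), pos = pos,
                    derived_freq = 0.5, ihh_a = 1, ihh_d = 1,
                    raw_ihs = std, std_ihs = std, bin_id = 1L, flag = "")
  class(out) <- c("ihs_result", "data.frame")
  out
}

# Incidence track builder for island unit tests.
fake_track <- function(chrom, pos, incidence) {
  out <- data.frame(chrom = as.character(chrom), pos = pos,
                    incidence = incidence)
  class(out) <- c("incidence_track", "data.frame")
  out
}

# First 3-Mb window of the map whose internal gaps stay under the ROH
# max-gap limit and which carries enough SNPs for segment calling; a forced
# tract placed there is detectable by construction.
pick_clean_window <- function(pos, width = 3e6, max_gap = 1e5,
                              min_snps = 150) {
  for (lo in seq(10e6, max(pos) - width, by = 1e6)) {
    idx <- which(pos >= lo & pos < lo + width)
    if (length(idx) >= min_snps && all(diff(pos[idx]) <= max_gap)) {
      return(c(lo, lo + width))
    }
  }
  stop("no clean window in this position draw")
}

# Haplotype set with i.i.d. Bernoulli alleles (no LD), handy when a test
# needs a Hardy-Weinberg background with no founder sharing.
iid_haplotypes <- function(n_ind, m, L = 150e6, p = NULL) {
  if (is.null(p)) p <- runif(m, 0.05, 0.5)
  hap <- matrix(rbinom(2 * n_ind * m, 1L, rep(p, each = 2 * n_ind)),
                nrow = 2 * n_ind)
  pos <- sort(sample.int(L, m))
  haplotype_set(hap, sprintf("ind%04d", seq_len(n_ind)),
                variant_table(rep("1", m), pos))
}
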