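#' Read phased genotypes from a VCF file
#'
#' Parses a VCF 4.x file with a GT field into a [haplotype_set()]. Only
#' biallelic records on the declared autosomes are retained; records are
#' sorted by chromosome and position. Missing calls (`./.` or `.`) become
#' missing on both haplotypes. Unphased diploid records (`/` separator) are
#' counted and reported via the `n_unphased` attribute with a warning; mixed
#' ploidy is rejected.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param autosomes character vector of chromosome labels to keep.
#' @return A `haplotype_set`; attribute `n_unphased` carries the number of
#'   unphased genotype calls encountered.
#' @export
read_phased_vcf <- function(path, autosomes = as.character(1:29)) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(v@gt)[-1]
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])

  keep <- chrom %in% as.character(autosomes)
  if (!any(keep)) stop("no variants on the declared autosomes")
  chrom <- chrom[keep]; pos <- pos[keep]
  ref <- as.character(fix[keep, "REF"]); alt <- as.character(fix[keep, "ALT"])
  gt <- gt[keep, , drop = FALSE]

  ord <- order(match(chrom, unique(chrom)), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
  gt <- gt[ord, , drop = FALSE]

  gt[is.na(gt)] <- "."
  bad <- !grepl("^(\\.|[01.][/|][01.])$", gt)
  if (any(bad)) {
    i <- which(bad)[1]
    val <- gt[i]
    rec <- (i - 1L) %% nrow(gt) + 1L
    if (grepl("^[01]$", val) || grepl("[/|].+[/|]", val)) {
      stop("mixed or non-diploid ploidy in GT '", val, "' at record ", rec)
    }
    stop("cannot parse GT '", val, "' at record ", rec,
         " (only biallelic 0/1 diploid calls supported)")
  }
  n_unphased <- sum(grepl("^[01]/[01]$", gt))
  if (n_unphased > 0) {
    warning(n_unphased, " unphased genotype call(s); alleles taken in file order")
  }

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  a2[gt == "."] <- "."
  to_int <- function(a) { z <- suppressWarnings(as.integer(a)); z }
  m <- nrow(gt); n <- length(samples)
  hap <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  hap[seq(1L, 2L * n, 2L), ] <- t(matrix(to_int(a1), nrow = m))
  hap[seq(2L, 2L * n, 2L), ] <- t(matrix(to_int(a2), nrow = m))

  vt <- variant_table(chrom, pos, ref, alt, autosomes = autosomes)
  h <- haplotype_set(hap, samples, vt)
  attr(h, "n_unphased") <- n_unphased
  h
}

#' Write a haplotype set as a phased VCF
#'
#' Emits a minimal plain-text VCF 4.2 with phased GT calls; the exact inverse
#' of [read_phased_vcf()] for data produced by this package.
#'
#' @param h a `haplotype_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(h, path) {
  stopifnot(inherits(h, "haplotype_set"))
  n <- length(h$sample_ids)
  i1 <- seq(1L, 2L * n, 2L); i2 <- i1 + 1L
  code <- function(x) { y <- as.character(x); y[is.na(x)] <- "."; y }
  m <- ncol(h$alleles)
  gt_cols <- vapply(seq_len(n), function(s) {
    paste0(code(h$alleles[i1[s], ]), "|", code(h$alleles[i2[s], ]))
  }, character(m))
  if (m == 1L) gt_cols <- matrix(gt_cols, nrow = 1L)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", h$sample_ids), collapse = "\t"))
  body <- paste(h$variants$chrom, h$variants$pos,
                paste0("snp", seq_len(m)), h$variants$ref, h$variants$alt,
                ".", "PASS", ".", "GT",
                apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Variant quality-control filter
#'
#' Retains variants with minor-allele frequency at or above `maf_min`
#' (inclusive) and call rate strictly above `call_rate_min`. A filter report
#' counting removals per rule is attached as attribute `qc_report`.
#' Applying the filter twice is equivalent to applying it once.
#'
#' @param x a `genotype_set` or `haplotype_set`.
#' @param maf_min minimum minor-allele frequency (kept when `maf >= maf_min`).
#' @param call_rate_min call-rate floor (kept when `call_rate > call_rate_min`).
#' @return The filtered object, with attribute `qc_report`.
#' @export
apply_qc <- function(x, maf_min = 0.05, call_rate_min = 0.30) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0, call_rate_min <= 1)
  UseMethod("apply_qc")
}

qc_core <- function(x, maf, call_rate, maf_min, call_rate_min) {
  pass_maf <- !is.na(maf) & maf >= maf_min
  pass_cr <- call_rate > call_rate_min
  keep <- pass_maf & pass_cr
  if (!any(keep)) stop("QC removed every variant: empty panel")
  out <- subset_variants(x, which(keep))
  attr(out, "qc_report") <- data.frame(
    rule = c("maf", "call_rate", "either"),
    removed = c(sum(!pass_maf), sum(!pass_cr), sum(!keep)))
  out
}

#' @export
apply_qc.genotype_set <- function(x, maf_min = 0.05, call_rate_min = 0.30) {
  nn <- colSums(!is.na(x$dosages))
  p <- colSums(x$dosages, na.rm = TRUE) / (2 * nn)
  maf <- pmin(p, 1 - p)
  call_rate <- nn / nrow(x$dosages)
  qc_core(x, maf, call_rate, maf_min, call_rate_min)
}

#' @export
apply_qc.haplotype_set <- function(x, maf_min = 0.05, call_rate_min = 0.30) {
  nn <- colSums(!is.na(x$alleles))
  p <- colSums(x$alleles, na.rm = TRUE) / nn
  maf <- pmin(p, 1 - p)
  call_rate <- nn / nrow(x$alleles)
  qc_core(x, maf, call_rate, maf_min, call_rate_min)
}

#' Assign ancestral alleles by dataset-wide majority
#'
#' The ancestral allele at each variant is inferred as the most common allele
#' over all non-missing haplotypes; the other allele is derived. At an exact
#' 50/50 tie the reference allele is taken as ancestral and the site is
#' flagged; flagged sites are excluded from iHS standardization bins.
#'
#' @param h a `haplotype_set`.
#' @return `h` with an `ancestral` data.frame added: columns
#'   `ancestral_allele` (0 = REF, 1 = ALT), `derived_freq` and `tie`.
#' @export
assign_ancestral <- function(h) {
  stopifnot(inherits(h, "haplotype_set"))
  n1 <- colSums(h$alleles == 1L, na.rm = TRUE)
  n0 <- colSums(h$alleles == 0L, na.rm = TRUE)
  tie <- n1 == n0
  anc <- ifelse(n1 > n0, 1L, 0L)   # ties fall to 0 (= REF) by the ifelse
  tot <- n0 + n1
  derived_freq <- ifelse(anc == 1L, n0, n1) / tot
  derived_freq[tot == 0] <- NA_real_
  h$ancestral <- data.frame(ancestral_allele = anc,
                            derived_freq = derived_freq, tie = tie)
  h
}
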