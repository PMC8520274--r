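#' Variant metadata table
#'
#' Builds the per-variant metadata table shared by haplotype and genotype
#' containers. Positions must be strictly increasing within each chromosome
#' and chromosome labels must come from the declared autosome set.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based physical positions (bp).
#' @param ref,alt nucleotide codes (single characters); `alt` is the allele
#'   coded 1 in haplotype matrices.
#' @param autosomes character vector of allowed chromosome labels, or `NULL`
#'   to accept any label.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
variant_table <- function(chrom, pos, ref = NULL, alt = NULL, autosomes = NULL) {
  m <- length(pos)
  stopifnot(length(chrom) == m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (!is.null(autosomes) && !all(chrom %in% as.character(autosomes))) {
    stop("variant_table: chromosome label outside the declared autosome set")
  }
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (any(diff(p) <= 0)) {
      stop("variant_table: positions not strictly increasing on chromosome ", cc)
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = as.character(ref),
             alt = as.character(alt), stringsAsFactors = FALSE)
}

#' Phased haplotype container
#'
#' Holds a matrix of phased alleles (0 = REF, 1 = ALT, `NA` = missing) with
#' one row per haplotype and one column per variant. Individual `i` owns rows
#' `2i - 1` and `2i`.
#'
#' @param alleles integer matrix, 2N haplotypes x M variants, entries in
#'   \{0, 1, NA\}.
#' @param sample_ids character vector of N sample labels.
#' @param variants variant table (see [variant_table()]) with M rows.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(alleles, sample_ids, variants) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L) stop("haplotype count must be even")
  if (nrow(alleles) != 2L * length(sample_ids)) {
    stop("need exactly two haplotypes per sample")
  }
  if (ncol(alleles) != nrow(variants)) {
    stop("allele columns must align 1:1 with variant rows")
  }
  ok <- alleles %in% c(0L, 1L, NA_integer_)
  if (!all(ok)) stop("haplotype alleles must be 0, 1 or NA")
  structure(list(alleles = alleles, sample_ids = as.character(sample_ids),
                 variants = variants),
            class = "haplotype_set")
}

#' Diploid genotype container
#'
#' Holds allele dosages (0, 1, 2 or `NA`) with one row per individual.
#'
#' @param dosages integer matrix N x M with entries in \{0, 1, 2, NA\}.
#' @param sample_ids character vector of N sample labels.
#' @param variants variant table with M rows.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(dosages, sample_ids, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != length(sample_ids)) stop("one dosage row per sample required")
  if (ncol(dosages) != nrow(variants)) stop("dosage columns must align with variants")
  if (!all(dosages %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  structure(list(dosages = dosages, sample_ids = as.character(sample_ids),
                 variants = variants),
            class = "genotype_set")
}

#' Collapse phased haplotypes to diploid dosages
#'
#' Dosage is the sum of the two member haplotypes; missing on either
#' haplotype yields a missing dosage.
#'
#' @param h a `haplotype_set`.
#' @return A `genotype_set` over the same samples and variants.
#' @export
haplotypes_to_genotypes <- function(h) {
  stopifnot(inherits(h, "haplotype_set"))
  n <- length(h$sample_ids)
  a <- h$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  b <- h$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_set(a + b, h$sample_ids, h$variants)
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes (%d samples) x %d variants on %d chromosome(s)\n",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles),
              length(unique(x$variants$chrom))))
  if (!is.null(x$ancestral)) cat("  ancestral alleles assigned\n")
  invisible(x)
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d samples x %d variants on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variants$chrom))))
  invisible(x)
}

# Subset a haplotype or genotype container to a variant index vector,
# preserving auxiliary per-variant fields (ancestral assignment).
subset_variants <- function(x, keep) {
  vt <- function(v) { v <- v[keep, , drop = FALSE]; rownames(v) <- NULL; v }
  if (inherits(x, "haplotype_set")) {
    out <- haplotype_set(x$alleles[, keep, drop = FALSE], x$sample_ids, vt(x$variants))
    if (!is.null(x$ancestral)) {
      out$ancestral <- x$ancestral[keep, , drop = FALSE]
      rownames(out$ancestral) <- NULL
    }
    out
  } else if (inherits(x, "genotype_set")) {
    genotype_set(x$dosages[, keep, drop = FALSE], x$sample_ids, vt(x$variants))
  } else {
    stop("unsupported container")
  }
}
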