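#' Genomic inbreeding coefficients (GRM diagonal, excess homozygosity,
#' uniting gametes)
#'
#' Computes, per individual, the three SNP-based inbreeding estimators that
#' GCTA's `--ibc` reports, with allele frequencies `p_j` estimated from the
#' analyzed sample itself and monomorphic SNPs excluded. With dosage
#' `x_ij` over the `m_i` non-missing SNPs of individual `i`:
#' \deqn{F_{GRM,i} = \frac{1}{m_i}\sum_j \frac{(x_{ij}-2p_j)^2}{2p_j(1-p_j)} - 1}
#' \deqn{F_{HOM,i} = \frac{O_{hom,i}-E_{hom,i}}{m_i-E_{hom,i}},\quad
#'   E_{hom,i} = \sum_j (1 - 2p_j(1-p_j))}
#' \deqn{F_{UNI,i} = \frac{1}{m_i}\sum_j
#'   \frac{x_{ij}^2-(1+2p_j)x_{ij}+2p_j^2}{2p_j(1-p_j)}}
#' Missing dosages are skipped per SNP with `m_i` adjusted per individual.
#'
#' @param g a `genotype_set`.
#' @return A data.frame: `sample_id`, `n_snps_used`, `f_grm`, `f_hom`,
#'   `f_uni`.
#' @export
compute_ibc <- function(g) {
  stopifnot(inherits(g, "genotype_set"))
  x <- g$dosages
  nn <- colSums(!is.na(x))
  p <- colSums(x, na.rm = TRUE) / (2 * nn)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs after frequency estimation")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  if (any(p <= 0 | p >= 1)) stop("internal error: monomorphic SNP slipped the filter")
  het_var <- 2 * p * (1 - p)

  obs <- !is.na(x)
  m_i <- rowSums(obs)
  xs <- x; xs[!obs] <- 0L

  # F_GRM: (x - 2p)^2 / (2p(1-p)); expanded so missing cells contribute 0
  s_grm <- rowSums(sweep(xs^2, 2, het_var, "/")) -
    rowSums(sweep(xs, 2, 4 * p / het_var, "*")) +
    as.vector(obs %*% (4 * p^2 / het_var))
  f_grm <- s_grm / m_i - 1

  o_hom <- rowSums(obs & x != 1L, na.rm = TRUE)
  e_hom <- as.vector(obs %*% (1 - het_var))
  f_hom <- (o_hom - e_hom) / (m_i - e_hom)

  s_uni <- rowSums(sweep(xs^2, 2, het_var, "/")) -
    rowSums(sweep(xs, 2, (1 + 2 * p) / het_var, "*")) +
    as.vector(obs %*% (2 * p^2 / het_var))
  f_uni <- s_uni / m_i

  data.frame(sample_id = g$sample_ids, n_snps_used = as.integer(m_i),
             f_grm = f_grm, f_hom = f_hom, f_uni = f_uni,
             row.names = NULL)
}

#' Write inbreeding coefficients in GCTA .ibc layout
#'
#' Columns `ID`, `NOMISS`, `Fhat1` (GRM diagonal), `Fhat2` (excess
#' homozygosity), `Fhat3` (uniting gametes), tab separated.
#'
#' @param ibc result of [compute_ibc()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ibc_tsv <- function(ibc, path) {
  utils::write.table(
    data.frame(ID = ibc$sample_id, NOMISS = ibc$n_snps_used,
               Fhat1 = ibc$f_grm, Fhat2 = ibc$f_hom, Fhat3 = ibc$f_uni),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
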