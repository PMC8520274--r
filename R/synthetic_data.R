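#' Simulation configuration
#'
#' Bundles every knob of the haplotype simulator. Defaults emulate a dense
#' reduced-representation genotyping panel in a commercial dairy cattle
#' population at desk scale: a few hundred diploids, 10,000 SNPs irregularly
#' spaced over a 150-Mb chromosome (mean spacing ~15 kb), a uniform
#' minor-allele-frequency spectrum on [0.05, 0.5], and haplotype-block LD
#' from a founder-mosaic copying process.
#'
#' @param n_individuals number of diploid samples.
#' @param n_snps number of SNPs.
#' @param chromosome_length_bp chromosome length in bp.
#' @param chrom chromosome label.
#' @param n_founder_haplotypes number of founder haplotypes in the mosaic.
#' @param recombination_switch_prob per-SNP-step probability that a sample
#'   haplotype switches to a uniformly redrawn founder.
#' @param maf_range range of the uniform allele-frequency spectrum.
#' @param sweep list: `enabled`, `focal_index` (default middle SNP),
#'   `carrier_fraction` (beta in (0,1)), `halo_bp` (total span of the shared
#'   haplotype around the focus).
#' @param autozygosity list: `tract_rate_per_bp` (Poisson rate of tract
#'   starts per bp per individual) and `mean_tract_length_bp` (exponential
#'   mean).
#' @param error_rate per-cell genotype error probability.
#' @param missing_rate per-cell missingness probability.
#' @param seed RNG seed; a single stream drives the whole run.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 200, n_snps = 10000,
                       chromosome_length_bp = 150e6, chrom = "1",
                       n_founder_haplotypes = 20,
                       recombination_switch_prob = 0.01,
                       maf_range = c(0.05, 0.5),
                       sweep = list(enabled = FALSE, focal_index = NULL,
                                    carrier_fraction = 0.5, halo_bp = 2e6),
                       autozygosity = list(tract_rate_per_bp = 2e-8,
                                           mean_tract_length_bp = 2e6),
                       error_rate = 0.001, missing_rate = 0.01, seed = 1) {
  if (n_individuals < 1 || n_snps < 1) stop("degenerate config: need >=1 sample and >=1 SNP")
  if (n_snps > chromosome_length_bp) stop("more SNPs than base pairs")
  sweep <- utils::modifyList(list(enabled = FALSE, focal_index = NULL,
                                  carrier_fraction = 0.5, halo_bp = 2e6), sweep)
  autozygosity <- utils::modifyList(list(tract_rate_per_bp = 2e-8,
                                         mean_tract_length_bp = 2e6), autozygosity)
  stopifnot(sweep$carrier_fraction > 0, sweep$carrier_fraction < 1,
            recombination_switch_prob >= 0, recombination_switch_prob <= 1,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 chromosome_length_bp = chromosome_length_bp, chrom = chrom,
                 n_founder_haplotypes = n_founder_haplotypes,
                 recombination_switch_prob = recombination_switch_prob,
                 maf_range = maf_range, sweep = sweep,
                 autozygosity = autozygosity,
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_config")
}

#' Simulate neutral phased haplotypes
#'
#' Seeds the RNG from `cfg$seed`, draws irregular SNP positions, founder
#' haplotypes with allele frequencies from the configured spectrum, and
#' builds each of the 2N sample haplotypes as a first-order founder mosaic:
#' at each SNP step the copied founder is redrawn uniformly with probability
#' `recombination_switch_prob`. Subsequent simulator stages
#' ([overlay_sweep()], [pair_with_autozygosity()], [inject_noise()]) consume
#' the same RNG stream, so a full run is reproducible from the one seed.
#'
#' @param cfg a [sim_config()].
#' @return `list(haplotypes = haplotype_set, truth = list(...))`; the truth
#'   carries per-haplotype founder segments.
#' @export
simulate_neutral <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_snps; k <- cfg$n_founder_haplotypes
  nh <- 2L * cfg$n_individuals
  pos <- sort(sample.int(cfg$chromosome_length_bp, m))
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  founders <- matrix(stats::rbinom(k * m, 1L, rep(p, each = k)), nrow = k)
  hap <- matrix(0L, nrow = nh, ncol = m)
  founder_segments <- vector("list", nh)
  for (i in seq_len(nh)) {
    sw <- c(TRUE, stats::runif(m - 1) < cfg$recombination_switch_prob)
    starts <- which(sw)
    fid <- sample.int(k, length(starts), replace = TRUE)
    seg_len <- diff(c(starts, m + 1L))
    fid_per_snp <- rep(fid, seg_len)
    hap[i, ] <- founders[cbind(fid_per_snp, seq_len(m))]
    founder_segments[[i]] <- data.frame(start_snp = starts,
                                        end_snp = c(starts[-1] - 1L, m),
                                        founder = fid)
  }
  ids <- sprintf("ind%04d", seq_len(cfg$n_individuals))
  vt <- variant_table(rep(cfg$chrom, m), pos)
  list(haplotypes = haplotype_set(hap, ids, vt),
       truth = list(founder_segments = founder_segments, seed = cfg$seed))
}

#' Overlay a partial hard sweep
#'
#' Forces a fraction `carrier_fraction` of haplotypes (deterministic rounded
#' count, randomly chosen) to carry the derived allele (coded 1) at the
#' focal SNP plus one identical template haplotype across the halo
#' (`halo_bp / 2` to each side of the focus); all other haplotypes are
#' untouched. This is the long-shared-haplotype, intermediate-frequency
#' signal that the iHS scan targets.
#'
#' @param h a `haplotype_set`.
#' @param cfg a [sim_config()] with `sweep$enabled = TRUE` (otherwise `h`
#'   is returned unchanged).
#' @return `list(haplotypes, truth)`; truth records the focal SNP, carrier
#'   haplotype rows and the sweep interval.
#' @export
overlay_sweep <- function(h, cfg) {
  stopifnot(inherits(h, "haplotype_set"), inherits(cfg, "sim_config"))
  if (!isTRUE(cfg$sweep$enabled)) {
    return(list(haplotypes = h, truth = list(sweep_interval = NULL)))
  }
  m <- ncol(h$alleles); nh <- nrow(h$alleles)
  focal <- cfg$sweep$focal_index
  if (is.null(focal)) focal <- (m + 1L) %/% 2L
  if (focal < 1L || focal > m) stop("focal SNP index out of range")
  half <- cfg$sweep$halo_bp / 2
  fpos <- h$variants$pos[focal]
  lo <- fpos - half; hi <- fpos + half
  if (lo < 1 || hi > cfg$chromosome_length_bp) {
    warning("sweep halo truncated at chromosome boundary")
    lo <- max(lo, 1); hi <- min(hi, cfg$chromosome_length_bp)
  }
  halo_idx <- which(h$variants$pos >= lo & h$variants$pos <= hi)
  n_car <- as.integer(round(cfg$sweep$carrier_fraction * nh))
  carriers <- sample.int(nh, n_car)
  template <- h$alleles[carriers[1], halo_idx]
  template[is.na(template)] <- 0L
  template[halo_idx == focal] <- 1L
  h$alleles[carriers, halo_idx] <- matrix(template, nrow = n_car,
                                          ncol = length(halo_idx), byrow = TRUE)
  h$alleles[carriers, focal] <- 1L
  list(haplotypes = h,
       truth = list(focal_index = focal, focal_pos = fpos,
                    carriers = sort(carriers),
                    sweep_interval = data.frame(chrom = cfg$chrom,
                                                start = lo, end = hi)))
}

#' Pair haplotypes into diploids with forced autozygosity tracts
#'
#' Haplotypes 2i-1 and 2i form individual i. Per individual, tract start
#' points follow a Poisson process (`tract_rate_per_bp`) and tract lengths
#' are exponential (`mean_tract_length_bp`); inside a tract the second
#' haplotype is overwritten by the first, forcing homozygosity by descent.
#' Tracts are clipped at the chromosome end and recorded as truth.
#'
#' @param h a `haplotype_set`.
#' @param cfg a [sim_config()].
#' @return `list(genotypes = genotype_set, haplotypes, truth)`; truth holds
#'   a data.frame of tracts (`sample_id`, `chrom`, `start`, `end`).
#' @export
pair_with_autozygosity <- function(h, cfg) {
  stopifnot(inherits(h, "haplotype_set"), inherits(cfg, "sim_config"))
  n <- length(h$sample_ids)
  L <- cfg$chromosome_length_bp
  rate <- cfg$autozygosity$tract_rate_per_bp
  mu <- cfg$autozygosity$mean_tract_length_bp
  tracts <- list()
  pos <- h$variants$pos
  for (i in seq_len(n)) {
    n_tr <- stats::rpois(1, rate * L)
    if (n_tr == 0) next
    start <- sort(stats::runif(n_tr, 1, L))
    len <- stats::rexp(n_tr, rate = 1 / mu)
    end <- pmin(start + len, L)
    for (t in seq_len(n_tr)) {
      idx <- which(pos >= start[t] & pos <= end[t])
      if (length(idx)) {
        h$alleles[2L * i, idx] <- h$alleles[2L * i - 1L, idx]
      }
    }
    tracts[[length(tracts) + 1L]] <- data.frame(
      sample_id = h$sample_ids[i], chrom = cfg$chrom,
      start = start, end = end)
  }
  truth_tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(sample_id = character(), chrom = character(),
               start = numeric(), end = numeric())
  list(genotypes = haplotypes_to_genotypes(h), haplotypes = h,
       truth = list(tracts = truth_tracts))
}

#' Inject genotyping error and missingness
#'
#' Each dosage cell is independently flipped to one of the two other dosage
#' values with probability `error_rate`, then set missing with probability
#' `missing_rate`. Masks of the perturbed cells are returned as truth.
#'
#' @param g a `genotype_set`.
#' @param cfg a [sim_config()].
#' @return `list(genotypes, error_mask, missing_mask)` (logical matrices).
#' @export
inject_noise <- function(g, cfg) {
  stopifnot(inherits(g, "genotype_set"), inherits(cfg, "sim_config"))
  d <- g$dosages
  err <- matrix(stats::runif(length(d)) < cfg$error_rate, nrow = nrow(d)) &
    !is.na(d)
  if (any(err)) {
    old <- d[err]
    shift <- sample(c(1L, 2L), sum(err), replace = TRUE)
    d[err] <- (old + shift) %% 3L
  }
  miss <- matrix(stats::runif(length(d)) < cfg$missing_rate, nrow = nrow(d))
  d[miss] <- NA_integer_
  list(genotypes = genotype_set(d, g$sample_ids, g$variants),
       error_mask = err, missing_mask = miss)
}

#' Write annotation fixtures consistent with a simulated coordinate space
#'
#' Emits a toy gene GFF3, a QTL TSV (`chrom start end trait trait_class`)
#' and an eQTL TSV (`chrom pos gene tissue type`) whose coordinates fall
#' inside the simulated chromosome, for desk-scale annotation tests.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param n_genes,n_qtls,n_eqtls table sizes.
#' @return Named character vector of the three file paths.
#' @export
write_fixture_annotations <- function(cfg, dir, n_genes = 30, n_qtls = 12,
                                      n_eqtls = 20) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- cfg$chromosome_length_bp
  gs <- sort(sample.int(L - 60000L, n_genes))
  ge <- gs + sample(5000:50000, n_genes, replace = TRUE)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               paste(cfg$chrom, "sim", "gene", gs, ge, ".", "+", ".",
                     sprintf("ID=gene%03d;Name=GENE%03d", seq_len(n_genes),
                             seq_len(n_genes)), sep = "\t")), gff)
  qs <- sort(sample.int(L - 3000000L, n_qtls))
  qe <- qs + sample(200000:2000000, n_qtls, replace = TRUE)
  qtl <- file.path(dir, "qtl.tsv")
  utils::write.table(
    data.frame(chrom = cfg$chrom, start = qs, end = qe,
               trait = sprintf("trait%02d", seq_len(n_qtls)),
               trait_class = sample(c("health", "reproduction", "other"),
                                    n_qtls, replace = TRUE)),
    qtl, sep = "\t", quote = FALSE, row.names = FALSE)
  ep <- sort(sample.int(L, n_eqtls))
  eqtl <- file.path(dir, "eqtl.tsv")
  utils::write.table(
    data.frame(chrom = cfg$chrom, pos = ep,
               gene = sprintf("GENE%03d", sample.int(n_genes, n_eqtls, replace = TRUE)),
               tissue = sample(c("liver", "blood", "mammary", "adipose"),
                               n_eqtls, replace = TRUE),
               type = sample(c("cis", "trans"), n_eqtls, replace = TRUE,
                             prob = c(0.8, 0.2))),
    eqtl, sep = "\t", quote = FALSE, row.names = FALSE)
  c(gff3 = gff, qtl = qtl, eqtl = eqtl)
}
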