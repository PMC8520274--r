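#' Parameters for PLINK-style ROH detection
#'
#' Defaults reproduce the PLINK 1.9 `--homozyg` setup commonly used for
#' dense cattle panels: a 100-SNP sliding window allowing 1 heterozygote
#' and 5 missing calls, hit proportion 0.05, at least 1 SNP per 50 kb,
#' splits at inter-SNP gaps over 100 kb, and a strict >1 Mb length floor.
#'
#' @param window_snps SNPs per sliding window.
#' @param max_het_per_window heterozygous calls tolerated per window.
#' @param max_missing_per_window missing calls tolerated per window.
#' @param hit_proportion_threshold minimum fraction of covering windows
#'   that must be homozygous for a SNP to qualify.
#' @param max_gap_bp maximum distance between consecutive SNPs in a run.
#' @param min_length_bp minimum segment length (strict: kept when longer).
#' @param min_snps_per_segment minimum SNPs per segment.
#' @param min_density_bp_per_snp maximum bp per SNP inside a segment.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 100, max_het_per_window = 1,
                       max_missing_per_window = 5,
                       hit_proportion_threshold = 0.05,
                       max_gap_bp = 100000, min_length_bp = 1000000,
                       min_snps_per_segment = 100,
                       min_density_bp_per_snp = 50000) {
  p <- list(window_snps = as.integer(window_snps),
            max_het_per_window = max_het_per_window,
            max_missing_per_window = max_missing_per_window,
            hit_proportion_threshold = hit_proportion_threshold,
            max_gap_bp = max_gap_bp, min_length_bp = min_length_bp,
            min_snps_per_segment = min_snps_per_segment,
            min_density_bp_per_snp = min_density_bp_per_snp)
  stopifnot(all(vapply(p, function(x) x >= 0, TRUE)), p$min_length_bp >= 1)
  structure(p, class = "roh_params")
}

# Rolling sum of x over windows of w consecutive entries.
roll_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Detect runs of homozygosity
#'
#' Per individual and chromosome: (1) every window of `window_snps`
#' consecutive SNPs is scored homozygous when it contains at most
#' `max_het_per_window` heterozygous and `max_missing_per_window` missing
#' calls; (2) each SNP's hit proportion is the fraction of windows covering
#' it that are homozygous, and the SNP qualifies when that proportion
#' reaches `hit_proportion_threshold`; (3) maximal runs of qualifying SNPs
#' become candidate segments, split wherever consecutive SNPs are more than
#' `max_gap_bp` apart, trimmed to homozygous non-missing endpoints, and —
#' because the hit-proportion rule lets runs bleed a few SNPs into
#' heterozygous flanking sequence — decomposed into their maximal
#' subsegments containing at most one heterozygous call instead of being
#' discarded outright; (4) segments are kept when longer than
#' `min_length_bp`, containing at least `min_snps_per_segment` SNPs, at
#' most `min_density_bp_per_snp` bp per SNP, and at most one heterozygous
#' call. Segment boundaries are the first and last member SNP positions;
#' length is end - start.
#'
#' @param g a `genotype_set`, position-sorted within chromosomes.
#' @param params a [roh_params()].
#' @return A `roh_segments` data.frame: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`.
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "genotype_set"), inherits(params, "roh_params"))
  out <- list()
  for (cc in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == cc)
    pos <- g$variants$pos[idx]
    if (any(diff(pos) <= 0)) stop("genotypes not position-sorted on chromosome ", cc)
    if (length(idx) < params$window_snps) {
      warning("chromosome ", cc, " has fewer than ", params$window_snps,
              " SNPs; skipped")
      next
    }
    for (i in seq_along(g$sample_ids)) {
      dos <- g$dosages[i, idx]
      segs <- roh_one(dos, pos, params)
      if (nrow(segs)) {
        segs$sample_id <- g$sample_ids[i]
        segs$chrom <- cc
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start_bp = integer(), end_bp = integer(), n_snps = integer(),
               length_bp = integer(), sample_id = character(),
               chrom = character())
  res <- res[, c("sample_id", "chrom", "start_bp", "end_bp", "n_snps",
                 "length_bp")]
  rownames(res) <- NULL
  class(res) <- c("roh_segments", "data.frame")
  res
}

# Decompose [a, b] into non-overlapping subsegments each containing at most
# one heterozygous call: take the longest span bounded by (but excluding)
# two hets (leftmost on ties), then recurse on what is left of either side.
clean_subsegments <- function(het_idx, a, b) {
  hs <- het_idx[het_idx >= a & het_idx <= b]
  if (length(hs) <= 1L) return(matrix(c(a, b), ncol = 2))
  bnd <- c(a - 1L, hs, b + 1L)
  best <- NULL; best_len <- -1L
  for (i in seq_len(length(bnd) - 2L)) {
    s <- bnd[i] + 1L; e <- bnd[i + 2L] - 1L
    if (e - s > best_len) { best_len <- e - s; best <- c(s, e, bnd[i], bnd[i + 2L]) }
  }
  out <- matrix(c(best[1], best[2]), ncol = 2)
  if (best[3] - 1L >= a) out <- rbind(out, Recall(het_idx, a, best[3] - 1L))
  if (best[4] + 1L <= b) out <- rbind(out, Recall(het_idx, best[4] + 1L, b))
  out
}

# Single-individual single-chromosome scan; dos and pos aligned.
roh_one <- function(dos, pos, params) {
  m <- length(dos)
  w <- params$window_snps
  het <- !is.na(dos) & dos == 1L
  miss <- is.na(dos)
  homwin <- roll_sum(het, w) <= params$max_het_per_window &
    roll_sum(miss, w) <= params$max_missing_per_window
  nw <- length(homwin)
  cumhom <- c(0, cumsum(homwin))
  i <- seq_len(m)
  first_w <- pmax(1L, i - w + 1L)
  last_w <- pmin(nw, i)
  hits <- cumhom[last_w + 1L] - cumhom[first_w]
  covering <- last_w - first_w + 1L
  qualify <- hits / covering >= params$hit_proportion_threshold

  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer())
  if (!any(qualify)) return(empty)
  r <- rle(qualify)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  segs <- list()
  het_idx <- which(het)
  trim <- function(s, e) {
    while (s <= e && (het[s] || miss[s])) s <- s + 1L
    while (e >= s && (het[e] || miss[e])) e <- e - 1L
    c(s, e)
  }
  for (k in which(r$values)) {
    a <- run_start[k]; b <- run_end[k]
    # split the run at over-long gaps between consecutive SNPs
    cut_after <- which(diff(pos[a:b]) > params$max_gap_bp)
    bounds <- c(a - 1L, a - 1L + cut_after, b)
    for (j in seq_len(length(bounds) - 1L)) {
      se <- trim(bounds[j] + 1L, bounds[j + 1L])
      if (se[1] >= se[2]) next
      # a run may carry more than the tolerated single het near its edges;
      # report its maximal <=1-het subsegments rather than discarding it
      pieces <- clean_subsegments(het_idx, se[1], se[2])
      for (pr in seq_len(nrow(pieces))) {
        pe <- trim(pieces[pr, 1], pieces[pr, 2])
        s <- pe[1]; e <- pe[2]
        if (s >= e) next
        len <- pos[e] - pos[s]
        nsnp <- e - s + 1L
        if (len > params$min_length_bp &&
            nsnp >= params$min_snps_per_segment &&
            len / nsnp <= params$min_density_bp_per_snp &&
            sum(het[s:e]) <= 1L) {
          segs[[length(segs) + 1L]] <- data.frame(
            start_bp = pos[s], end_bp = pos[e], n_snps = nsnp,
            length_bp = len)
        }
      }
    }
  }
  if (length(segs)) do.call(rbind, segs) else empty
}

#' Length-class summary of ROH segments
#'
#' Classifies segments into the left-closed length classes [1, 2), [2, 4),
#' [4, 8) and [8, Inf) Mb and reports count, percent of total, mean and SD
#' of length (Mb), and genome coverage percent
#' (sum of class lengths / (genome length x individuals) x 100),
#' plus a totals row.
#'
#' @param segs a `roh_segments` data.frame.
#' @param genome_length_bp total autosome length in bp.
#' @param n_individuals number of genotyped individuals.
#' @return A data.frame with one row per class plus `total`.
#' @export
classify_and_summarize <- function(segs, genome_length_bp, n_individuals) {
  if (nrow(segs) == 0) stop("no ROH segments to summarize")
  mb <- segs$length_bp / 1e6
  cls <- cut(mb, breaks = c(1, 2, 4, 8, Inf), right = FALSE,
             labels = c("1-2Mb", "2-4Mb", "4-8Mb", ">8Mb"))
  per_class <- lapply(levels(cls), function(lv) {
    x <- mb[!is.na(cls) & cls == lv]
    data.frame(class = lv, n = length(x),
               mean_mb = if (length(x)) mean(x) else NA_real_,
               sd_mb = if (length(x) > 1) stats::sd(x) else NA_real_,
               coverage_pct = sum(x) * 1e6 /
                 (genome_length_bp * n_individuals) * 100)
  })
  tab <- do.call(rbind, per_class)
  tab$percent <- tab$n / sum(tab$n) * 100
  total <- data.frame(class = "total", n = sum(tab$n), mean_mb = mean(mb),
                      sd_mb = stats::sd(mb),
                      coverage_pct = sum(mb) * 1e6 /
                        (genome_length_bp * n_individuals) * 100,
                      percent = 100)
  out <- rbind(tab, total)[, c("class", "n", "percent", "mean_mb", "sd_mb",
                               "coverage_pct")]
  rownames(out) <- NULL
  out
}

#' Totals from class-level ROH statistics
#'
#' Recomputes the derived columns of a length-class summary from the
#' class-level counts, mean lengths and coverages alone: the total count,
#' per-class percentages (rounded to integers, displayed with two
#' decimals in reports), the count-weighted overall mean length (2
#' decimals) and the summed genome coverage.
#'
#' @param counts per-class segment counts.
#' @param mean_lengths_mb per-class mean lengths in Mb.
#' @param coverage_pct per-class genome coverage percentages (optional).
#' @return A list: `total_n`, `percent` (rounded), `weighted_mean_mb`
#'   (rounded to 2 decimals), `total_coverage_pct`.
#' @export
roh_class_totals <- function(counts, mean_lengths_mb, coverage_pct = NULL) {
  stopifnot(length(counts) == length(mean_lengths_mb))
  total <- sum(counts)
  list(total_n = total,
       percent = round(counts / total * 100),
       weighted_mean_mb = round(sum(counts * mean_lengths_mb) / total, 2),
       total_coverage_pct = if (is.null(coverage_pct)) NULL else
         sum(coverage_pct))
}

#' Per-chromosome ROH summary
#'
#' Counts segments per chromosome and averages, over all individuals, the
#' percentage of each chromosome covered by that individual's ROH
#' (individuals without ROH on a chromosome contribute zero).
#'
#' @param segs a `roh_segments` data.frame.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param n_individuals number of genotyped individuals.
#' @return A data.frame: `chrom`, `n_segments`, `mean_coverage_pct`.
#' @export
per_chromosome_summary <- function(segs, chrom_lengths, n_individuals) {
  chroms <- names(chrom_lengths)
  if (is.null(chroms)) stop("chrom_lengths must be a named vector")
  if (!all(segs$chrom %in% chroms)) stop("segment on an undeclared chromosome")
  bad <- segs$end_bp > chrom_lengths[segs$chrom]
  if (any(bad)) stop("segment extends beyond the declared chromosome length")
  out <- lapply(chroms, function(cc) {
    s <- segs[segs$chrom == cc, , drop = FALSE]
    per_ind <- tapply(s$length_bp, s$sample_id, sum)
    cov <- sum(per_ind) / chrom_lengths[[cc]] / n_individuals * 100
    data.frame(chrom = cc, n_segments = nrow(s), mean_coverage_pct = cov)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
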