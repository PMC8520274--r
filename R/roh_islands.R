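#' Per-SNP ROH incidence across individuals
#'
#' For each SNP, the incidence is the fraction of individuals with at least
#' one ROH segment covering it (`start_bp <= pos <= end_bp`); multiple
#' overlapping segments of the same individual count once.
#'
#' @param segs a `roh_segments` data.frame.
#' @param variants a variant table (`chrom`, `pos`).
#' @param n_individuals number of genotyped individuals.
#' @return An `incidence_track` data.frame: `chrom`, `pos`, `incidence`.
#' @export
snp_incidence <- function(segs, variants, n_individuals) {
  counts <- integer(nrow(variants))
  for (cc in unique(variants$chrom)) {
    vi <- which(variants$chrom == cc)
    s <- segs[segs$chrom == cc, , drop = FALSE]
    if (nrow(s) == 0) next
    snp_ir <- IRanges::IRanges(start = variants$pos[vi],
                               width = 1L)
    seg_ir <- IRanges::IRanges(start = s$start_bp, end = s$end_bp)
    ov <- IRanges::findOverlaps(snp_ir, seg_ir)
    if (length(ov) == 0) next
    pair <- unique(data.frame(snp = S4Vectors::queryHits(ov),
                              ind = s$sample_id[S4Vectors::subjectHits(ov)]))
    tab <- table(pair$snp)
    counts[vi[as.integer(names(tab))]] <- as.integer(tab)
  }
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    incidence = counts / n_individuals)
  class(out) <- c("incidence_track", "data.frame")
  out
}

#' Call ROH islands from an incidence track
#'
#' Selects the top `top_fraction` of SNPs by ROH incidence (nearest-rank
#' empirical threshold, ties included) and merges maximal runs of
#' consecutive selected SNPs on a chromosome into islands. Islands are
#' retained when they contain at least `min_snps` SNPs and every member
#' SNP's incidence strictly exceeds `occurrence_floor`. Island length is
#' reported as end - start of the first and last member SNP positions.
#'
#' @param track an `incidence_track` from [snp_incidence()].
#' @param top_fraction empirical tail fraction of SNPs selected.
#' @param occurrence_floor minimum per-SNP occurrence (strict) for a
#'   retained island.
#' @param min_snps minimum SNPs per island.
#' @param bridge_gap number of consecutive below-threshold SNPs an island
#'   may bridge (0 = strict adjacency).
#' @return A data.frame of islands: `chrom`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_snps`, `min_incidence`, `max_incidence`; attribute
#'   `threshold` carries the empirical cutoff.
#' @export
call_islands <- function(track, top_fraction = 0.01, occurrence_floor = 0.30,
                         min_snps = 5, bridge_gap = 0) {
  stopifnot(inherits(track, "incidence_track"), nrow(track) > 0)
  inc <- track$incidence
  k <- ceiling(top_fraction * length(inc))
  thr <- sort(inc, decreasing = TRUE)[k]
  if (length(unique(inc)) == 1L) {
    warning("degenerate incidence distribution: all SNPs tied at the threshold")
  }
  if (thr < occurrence_floor) {
    warning("empirical top-", top_fraction * 100,
            "% threshold (", signif(thr, 3),
            ") is below the occurrence floor; the floor dominates")
  }
  selected <- inc >= thr
  islands <- list()
  for (cc in unique(track$chrom)) {
    on_c <- which(track$chrom == cc)
    sel <- selected[on_c]
    if (!any(sel)) next
    if (bridge_gap > 0) {
      r <- rle(sel)
      gapfill <- !r$values & r$lengths <= bridge_gap
      inner <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
      r$values[gapfill & inner] <- TRUE
      sel <- inverse.rle(r)
    }
    r <- rle(sel)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      ii <- on_c[starts[j]:ends[j]]
      if (length(ii) < min_snps) next
      if (!all(inc[ii] > occurrence_floor)) next
      islands[[length(islands) + 1L]] <- data.frame(
        chrom = cc, start_bp = track$pos[ii[1]],
        end_bp = track$pos[ii[length(ii)]],
        length_bp = track$pos[ii[length(ii)]] - track$pos[ii[1]],
        n_snps = length(ii), min_incidence = min(inc[ii]),
        max_incidence = max(inc[ii]))
    }
  }
  out <- if (length(islands)) do.call(rbind, islands) else
    data.frame(chrom = character(), start_bp = integer(),
               end_bp = integer(), length_bp = integer(),
               n_snps = integer(), min_incidence = numeric(),
               max_incidence = numeric())
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}
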