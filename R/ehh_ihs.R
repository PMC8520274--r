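#' Extended haplotype homozygosity decay around a core SNP
#'
#' EHH at a marker x is the fraction of carrier-haplotype pairs (haplotypes
#' carrying the core allele) that are identical over the closed marker
#' interval between the core and x. Haplotypes with a missing allele
#' anywhere in the interval are dropped from that and all further distances
#' on that side; the denominator stays at choose(n_carriers, 2), so the
#' decay is non-increasing away from the core.
#'
#' @param h a `haplotype_set`.
#' @param core_index variant index of the core SNP.
#' @param allele core allele (0 or 1).
#' @return An `ehh_decay` object: `core_index`, `allele`, `core_pos` and a
#'   `grid` data.frame (`index`, `pos`, `ehh`) sorted by position, spanning
#'   the core's chromosome and including the core itself (EHH = 1).
#' @export
compute_ehh <- function(h, core_index, allele) {
  stopifnot(inherits(h, "haplotype_set"), allele %in% c(0L, 1L))
  cc <- h$variants$chrom[core_index]
  idx <- which(h$variants$chrom == cc)
  sub <- h$alleles[, idx, drop = FALSE]
  core_local <- match(core_index, idx)
  pos <- as.numeric(h$variants$pos[idx])
  dec <- cpp_ehh_decay(sub, pos, core_local, as.integer(allele))
  grid <- data.frame(index = idx[dec$index], pos = pos[dec$index],
                     ehh = dec$ehh)
  grid <- grid[order(grid$pos), ]
  rownames(grid) <- NULL
  structure(list(core_index = core_index, allele = as.integer(allele),
                 core_pos = h$variants$pos[core_index], grid = grid),
            class = "ehh_decay")
}

# Trapezoidal integral of one side of a decay grid, walking outward from the
# core. `pos` and `ehh` are ordered core-outward with the core first.
ihh_one_side <- function(pos, ehh, ehh_cutoff, max_gap_bp) {
  area <- 0
  any_segment <- FALSE
  if (length(pos) >= 2) {
    for (k in 2:length(pos)) {
      gap <- abs(pos[k] - pos[k - 1])
      if (gap > max_gap_bp) break
      if (ehh[k] < ehh_cutoff) break
      area <- area + 0.5 * (ehh[k - 1] + ehh[k]) * gap
      any_segment <- TRUE
    }
  }
  list(area = area, any = any_segment)
}

#' Integrated EHH (iHH) from a decay curve
#'
#' Trapezoidal integral of EHH over physical distance. Each side is
#' truncated at the last marker with EHH at or above `ehh_cutoff` (the
#' segment crossing below the cutoff is excluded), and at the near edge of
#' any inter-marker gap exceeding `max_gap_bp`. The total is the sum of the
#' two sides; a single-marker side contributes zero.
#'
#' @param decay an `ehh_decay` from [compute_ehh()].
#' @param ehh_cutoff EHH truncation level.
#' @param max_gap_bp maximum tolerated inter-marker gap in bp.
#' @return iHH in bp-EHH units; attribute `untruncatable` is `TRUE` when no
#'   segment qualified on either side.
#' @export
compute_ihh <- function(decay, ehh_cutoff = 0.05, max_gap_bp = 200000) {
  stopifnot(inherits(decay, "ehh_decay"))
  g <- decay$grid
  left <- g[g$pos <= decay$core_pos, ]
  left <- left[order(left$pos, decreasing = TRUE), ]
  right <- g[g$pos >= decay$core_pos, ]
  l <- ihh_one_side(left$pos, left$ehh, ehh_cutoff, max_gap_bp)
  r <- ihh_one_side(right$pos, right$ehh, ehh_cutoff, max_gap_bp)
  out <- l$area + r$area
  attr(out, "untruncatable") <- !(l$any || r$any)
  out
}

#' Integrated haplotype score (iHS) for every eligible SNP
#'
#' For each SNP with derived-allele frequency inside
#' `[maf_min, 1 - maf_min]`, integrates the EHH decay of the ancestral and
#' derived core alleles (iHH_A, iHH_D) and forms the raw score
#' `ln(iHH_A / iHH_D)`, then standardizes it to mean 0 / SD 1 within
#' derived-allele-frequency bins: `std = (raw - E_p) / SD_p` with the
#' sample (n-1) standard deviation. SNPs in bins with fewer than
#' `min_bin_n` members, ancestral-tie SNPs, and SNPs with a zero or
#' undefined iHH are flagged and left unstandardized.
#'
#' @param h a `haplotype_set` with ancestral alleles assigned
#'   (see [assign_ancestral()]).
#' @param maf_min minimum derived-allele frequency for eligibility.
#' @param ehh_cutoff,max_gap_bp truncation parameters passed to the
#'   integration (see [compute_ihh()]).
#' @param bin_width width of the derived-frequency bins on (0, 1).
#' @param min_bin_n minimum bin membership for standardization.
#' @return An `ihs_result` data.frame: `chrom`, `pos`, `derived_freq`,
#'   `ihh_a`, `ihh_d`, `raw_ihs`, `std_ihs`, `bin_id`, `flag`. Attribute
#'   `bins` holds the per-bin mean, SD and member count.
#' @export
compute_ihs <- function(h, maf_min = 0.05, ehh_cutoff = 0.05,
                        max_gap_bp = 200000, bin_width = 0.05,
                        min_bin_n = 10) {
  stopifnot(inherits(h, "haplotype_set"))
  if (is.null(h$ancestral)) stop("call assign_ancestral() before compute_ihs()")
  df <- h$ancestral$derived_freq
  tie <- h$ancestral$tie
  eligible <- !is.na(df) & df >= maf_min & df <= 1 - maf_min
  m <- ncol(h$alleles)
  ihh <- matrix(NA_real_, m, 2)
  for (cc in unique(h$variants$chrom)) {
    idx <- which(h$variants$chrom == cc)
    ihh[idx, ] <- cpp_ihh_scan(h$alleles[, idx, drop = FALSE],
                               as.numeric(h$variants$pos[idx]),
                               as.integer(h$ancestral$ancestral_allele[idx]),
                               eligible[idx], ehh_cutoff, max_gap_bp)
  }
  raw <- log(ihh[, 1] / ihh[, 2])
  bad <- eligible & (!is.finite(raw))
  raw[!is.finite(raw)] <- NA_real_

  flag <- rep("", m)
  flag[!eligible] <- "ineligible"
  flag[bad] <- "zero_ihh"
  flag[eligible & tie] <- "tie"

  bin_id <- as.integer(ceiling(df / bin_width))
  bin_id[is.na(df)] <- NA_integer_
  in_bins <- !is.na(raw) & !tie & eligible
  bins <- data.frame(bin_id = sort(unique(bin_id[in_bins])))
  bins$lower <- (bins$bin_id - 1) * bin_width
  bins$upper <- bins$bin_id * bin_width
  bins$n <- vapply(bins$bin_id, function(b) sum(in_bins & bin_id == b), 0L)
  bins$mean <- vapply(bins$bin_id, function(b)
    mean(raw[in_bins & bin_id == b]), 0.0)
  bins$sd <- vapply(bins$bin_id, function(b)
    stats::sd(raw[in_bins & bin_id == b]), 0.0)

  std <- rep(NA_real_, m)
  for (k in seq_len(nrow(bins))) {
    b <- bins$bin_id[k]
    members <- in_bins & bin_id == b
    if (bins$n[k] < min_bin_n || is.na(bins$sd[k]) || bins$sd[k] <= 0) {
      flag[members] <- "small_bin"
      next
    }
    std[members] <- (raw[members] - bins$mean[k]) / bins$sd[k]
  }
  out <- data.frame(chrom = h$variants$chrom, pos = h$variants$pos,
                    derived_freq = df, ihh_a = ihh[, 1], ihh_d = ihh[, 2],
                    raw_ihs = raw, std_ihs = std, bin_id = bin_id,
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("ihs_result", "data.frame")
  attr(out, "bins") <- bins
  out
}

#' Windowed |iHS| scan
#'
#' Tiles each chromosome with half-open windows of `width_bp` starting at 0
#' and stepping `step_bp` (consecutive windows overlap by half their width
#' at the defaults). The window statistic is the mean |standardized iHS| of
#' contained SNPs. Windows with fewer than `min_snps_per_window` scored SNPs
#' are excluded from the empirical distribution. Candidates are the windows
#' whose statistic reaches the top `top_fraction` of that distribution
#' (nearest-rank threshold, ties included), or — in fixed-threshold mode —
#' the windows at or above `fixed_threshold`.
#'
#' @param ihs an `ihs_result` from [compute_ihs()].
#' @param width_bp window width in bp.
#' @param step_bp window step in bp.
#' @param top_fraction empirical tail fraction defining candidates.
#' @param min_snps_per_window minimum scored SNPs per eligible window.
#' @param fixed_threshold if non-`NULL`, use this |iHS| cutoff instead of
#'   the empirical quantile.
#' @return A `window_scan` data.frame: `chrom`, `start`, `end`, `n_snps`,
#'   `mean_abs_ihs`, `eligible`, `candidate`; attribute `threshold`.
#' @export
scan_windows <- function(ihs, width_bp = 500000, step_bp = 250000,
                         top_fraction = 0.01, min_snps_per_window = 3,
                         fixed_threshold = NULL) {
  stopifnot(inherits(ihs, "ihs_result"))
  scored <- !is.na(ihs$std_ihs)
  if (!any(scored)) stop("no standardized iHS scores to scan")
  wins <- list()
  for (cc in unique(ihs$chrom)) {
    on_c <- ihs$chrom == cc & scored
    if (!any(on_c)) next
    pos <- ihs$pos[on_c]
    val <- abs(ihs$std_ihs[on_c])
    starts <- seq(0, max(pos), by = step_bp)
    stat <- numeric(length(starts)); n <- integer(length(starts))
    for (k in seq_along(starts)) {
      inw <- pos >= starts[k] & pos < starts[k] + width_bp
      n[k] <- sum(inw)
      stat[k] <- if (n[k] > 0) mean(val[inw]) else NA_real_
    }
    wins[[cc]] <- data.frame(chrom = cc, start = starts,
                             end = starts + width_bp, n_snps = n,
                             mean_abs_ihs = stat)
  }
  w <- do.call(rbind, wins)
  rownames(w) <- NULL
  w$eligible <- w$n_snps >= min_snps_per_window
  if (!any(w$eligible)) stop("no windows with enough SNPs to scan")
  es <- w$mean_abs_ihs[w$eligible]
  if (is.null(fixed_threshold)) {
    k <- ceiling(top_fraction * length(es))
    thr <- sort(es, decreasing = TRUE)[k]
    if (length(unique(es)) == 1L) {
      warning("degenerate |iHS| distribution: all window statistics equal; ",
              "every eligible window tied at the threshold")
    }
  } else {
    thr <- fixed_threshold
  }
  w$candidate <- w$eligible & !is.na(w$mean_abs_ihs) & w$mean_abs_ihs >= thr
  class(w) <- c("window_scan", "data.frame")
  attr(w, "threshold") <- thr
  w
}

#' Merge candidate windows into maximal candidate regions
#'
#' Overlapping or adjacent candidate windows on the same chromosome are
#' merged; the per-region score is the mean of the member windows' mean
#' |iHS| statistics.
#'
#' @param scan a `window_scan` from [scan_windows()].
#' @return A data.frame of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `mean_abs_ihs` (empty if there are no candidates).
#' @export
merge_candidate_windows <- function(scan) {
  stopifnot(inherits(scan, "window_scan"))
  cand <- scan[scan$candidate, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      mean_abs_ihs = numeric())
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(match(cand$chrom, unique(cand$chrom)), cand$start), ]
  regions <- list()
  cur <- cand[1, ]
  stats <- cur$mean_abs_ihs
  for (k in seq_len(nrow(cand))[-1]) {
    row <- cand[k, ]
    if (row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      stats <- c(stats, row$mean_abs_ihs)
    } else {
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = cur$chrom, start = cur$start, end = cur$end,
        n_windows = length(stats), mean_abs_ihs = mean(stats))
      cur <- row
      stats <- row$mean_abs_ihs
    }
  }
  regions[[length(regions) + 1L]] <- data.frame(
    chrom = cur$chrom, start = cur$start, end = cur$end,
    n_windows = length(stats), mean_abs_ihs = mean(stats))
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}
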