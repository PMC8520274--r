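# Independent reference implementations used to cross-check the package's
# optimized code paths on small panels. Everything here is written directly
# from the statistic definitions with plain loops.

# EHH at marker x for the given core allele: fraction of carrier pairs
# identical over the closed interval [core, x]; carriers with a missing
# call anywhere in the interval cannot contribute identical pairs.
oracle_ehh <- function(hap, core, allele, x) {
  carriers <- which(!is.na(hap[, core]) & hap[, core] == allele)
  n <- length(carriers)
  if (n < 2) stop("oracle: <2 carriers")
  rng <- min(core, x):max(core, x)
  keep <- carriers[vapply(carriers, function(i)
    !anyNA(hap[i, rng]), TRUE)]
  ident <- 0L
  if (length(keep) >= 2) {
    for (i in seq_len(length(keep) - 1)) {
      for (j in (i + 1):length(keep)) {
        if (all(hap[keep[i], rng] == hap[keep[j], rng])) ident <- ident + 1L
      }
    }
  }
  ident / choose(n, 2)
}

# Exhaustive ROH reference for one individual / one chromosome, following
# the documented detector contract step by step with explicit loops.
oracle_roh <- function(dos, pos, p) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer())
  m <- length(dos); w <- p$window_snps
  if (m < w) return(empty)
  het <- !is.na(dos) & dos == 1L
  miss <- is.na(dos)
  nw <- m - w + 1L
  homwin <- logical(nw)
  for (k in seq_len(nw)) {
    win <- k:(k + w - 1L)
    homwin[k] <- sum(het[win]) <= p$max_het_per_window &&
      sum(miss[win]) <= p$max_missing_per_window
  }
  qual <- logical(m)
  for (i in seq_len(m)) {
    ws <- intersect(seq_len(nw), (i - w + 1L):i)
    qual[i] <- mean(homwin[ws]) >= p$hit_proportion_threshold
  }
  trim <- function(s, e) {
    while (s <= e && (het[s] || miss[s])) s <- s + 1L
    while (e >= s && (het[e] || miss[e])) e <- e - 1L
    c(s, e)
  }
  clean_pieces <- function(a, b) {
    hs <- which(het)[which(het) >= a & which(het) <= b]
    if (length(hs) <= 1L) return(list(c(a, b)))
    bnd <- c(a - 1L, hs, b + 1L)
    best <- NULL; best_len <- -1L
    for (i in seq_len(length(bnd) - 2L)) {
      s <- bnd[i] + 1L; e <- bnd[i + 2L] - 1L
      if (e - s > best_len) { best_len <- e - s; best <- c(s, e, bnd[i], bnd[i + 2L]) }
    }
    out <- list(c(best[1], best[2]))
    if (best[3] - 1L >= a) out <- c(out, clean_pieces(a, best[3] - 1L))
    if (best[4] + 1L <= b) out <- c(out, clean_pieces(best[4] + 1L, b))
    out
  }
  segs <- empty
  i <- 1L
  while (i <= m) {
    if (!qual[i]) { i <- i + 1L; next }
    j <- i
    while (j < m && qual[j + 1L]) j <- j + 1L
    sub_start <- i
    subs <- list()
    if (j > i) {
      for (k in i:(j - 1L)) {
        if (pos[k + 1L] - pos[k] > p$max_gap_bp) {
          subs <- c(subs, list(c(sub_start, k)))
          sub_start <- k + 1L
        }
      }
    }
    subs <- c(subs, list(c(sub_start, j)))
    for (sb in subs) {
      se <- trim(sb[1], sb[2])
      if (se[1] >= se[2]) next
      for (pc in clean_pieces(se[1], se[2])) {
        pe <- trim(pc[1], pc[2])
        s <- pe[1]; e <- pe[2]
        if (s >= e) next
        len <- pos[e] - pos[s]
        nsnp <- e - s + 1L
        if (len > p$min_length_bp && nsnp >= p$min_snps_per_segment &&
            len / nsnp <= p$min_density_bp_per_snp &&
            sum(het[s:e]) <= 1L) {
          segs <- rbind(segs, data.frame(start_bp = pos[s], end_bp = pos[e],
                                         n_snps = nsnp, length_bp = len))
        }
      }
    }
    i <- j + 1L
  }
  segs[order(segs$start_bp), , drop = FALSE]
}

# All-pairs interval overlap by double loop.
oracle_overlap <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      os <- max(a$start[i], b$start[j])
      oe <- min(a$end[i], b$end[j])
      if (oe - os > 0) {
        out[[length(out) + 1L]] <- data.frame(
          a_label = a$label[i], b_label = b$label[j], ov_length = oe - os)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a_label = character(), b_label = character(),
               ov_length = numeric())
}
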