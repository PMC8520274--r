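#' Genomic interval table
#'
#' Validates a set of genomic intervals (`start < end`; length is
#' `end - start` throughout the package).
#'
#' @param chrom chromosome labels.
#' @param start,end interval bounds in bp.
#' @param label optional interval labels.
#' @return A data.frame: `chrom`, `start`, `end`, `label`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NULL) {
  if (any(start >= end)) stop("genomic interval with start >= end")
  if (is.null(label)) label <- sprintf("region%03d", seq_along(start))
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), label = as.character(label),
             stringsAsFactors = FALSE)
}

# Closed-interval IRanges view used for overlap queries.
as_iranges <- function(x) IRanges::IRanges(start = x$start, end = x$end)

#' All overlapping interval pairs between two sets
#'
#' Reports every pair on the same chromosome with a positive-length
#' intersection `[max(starts), min(ends)]`.
#'
#' @param a,b interval data.frames (`chrom`, `start`, `end`, optional
#'   `label`).
#' @return A data.frame with one row per overlapping pair: the two labels
#'   and coordinates plus `ov_start`, `ov_end`, `ov_length`.
#' @export
overlap_intervals <- function(a, b) {
  out <- list()
  for (cc in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == cc); bi <- which(b$chrom == cc)
    ov <- IRanges::findOverlaps(as_iranges(a[ai, ]), as_iranges(b[bi, ]),
                                minoverlap = 1L)
    if (length(ov) == 0) next
    qa <- ai[S4Vectors::queryHits(ov)]
    qb <- bi[S4Vectors::subjectHits(ov)]
    os <- pmax(a$start[qa], b$start[qb])
    oe <- pmin(a$end[qa], b$end[qb])
    keep <- oe - os > 0
    if (!any(keep)) next
    out[[cc]] <- data.frame(
      chrom = cc,
      a_label = if ("label" %in% names(a)) a$label[qa][keep] else qa[keep],
      a_start = a$start[qa][keep], a_end = a$end[qa][keep],
      b_label = if ("label" %in% names(b)) b$label[qb][keep] else qb[keep],
      b_start = b$start[qb][keep], b_end = b$end[qb][keep],
      ov_start = os[keep], ov_end = oe[keep],
      ov_length = (oe - os)[keep])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), a_label = character(),
               a_start = numeric(), a_end = numeric(),
               b_label = character(), b_start = numeric(),
               b_end = numeric(), ov_start = numeric(),
               ov_end = numeric(), ov_length = numeric())
  rownames(res) <- NULL
  res
}

#' Annotate candidate regions with overlapping features
#'
#' A region is "within" a feature class when it overlaps at least one
#' feature of that class (any overlap, not containment). Feature labels are
#' deduplicated per region; regions without features are retained with an
#' empty list.
#'
#' @param regions interval data.frame (`chrom`, `start`, `end`, `label`).
#' @param features interval data.frame with a `label` column and, for QTL
#'   tables, a `trait_class` column.
#' @return A list: `per_region` (data.frame with a comma-joined `features`
#'   column and `n_features`), and, when `trait_class` is present,
#'   `class_counts` (regions overlapping at least one feature of each
#'   class) and `both_count` (regions hitting both `health` and
#'   `reproduction`).
#' @export
annotate_regions <- function(regions, features) {
  pairs <- overlap_intervals(regions, features)
  feat_by_region <- split(pairs$b_label, pairs$a_label)
  feats <- lapply(regions$label, function(l) unique(feat_by_region[[l]]))
  per_region <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    label = regions$label,
    n_features = vapply(feats, length, 0L),
    features = vapply(feats, function(f)
      paste(f, collapse = ","), ""))
  out <- list(per_region = per_region)
  if ("trait_class" %in% names(features)) {
    cls_of <- stats::setNames(features$trait_class, features$label)
    hit_classes <- lapply(feats, function(f) unique(cls_of[f]))
    classes <- sort(unique(features$trait_class))
    out$class_counts <- stats::setNames(vapply(classes, function(cl)
      sum(vapply(hit_classes, function(h) cl %in% h, TRUE)), 0L), classes)
    out$both_count <- sum(vapply(hit_classes, function(h)
      all(c("health", "reproduction") %in% h), TRUE))
  }
  out
}

qtl_classes <- c("health", "reproduction", "other")

#' Read a QTL interval table
#'
#' Tab-separated columns `chrom`, `start`, `end`, `trait`, `trait_class`;
#' the class must come from the controlled vocabulary
#' (health, reproduction, other).
#'
#' @param path TSV file path.
#' @return An interval data.frame with `label` (trait) and `trait_class`.
#' @export
read_qtl_table <- function(path) {
  q <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "trait", "trait_class")
  if (!all(need %in% names(q))) {
    stop("QTL table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !q$trait_class %in% qtl_classes
  if (any(bad)) {
    stop("unknown trait_class value(s): ",
         paste(unique(q$trait_class[bad]), collapse = ", "))
  }
  out <- genomic_intervals(q$chrom, q$start, q$end, label = q$trait)
  out$trait_class <- q$trait_class
  out
}

#' Read gene features from a GFF3 file
#'
#' Reads the nine standard GFF3 columns, keeps rows of the requested
#' feature type, and uses the `Name` (falling back to `ID`) attribute as
#' the label.
#'
#' @param path GFF3 file path.
#' @param type feature type to keep (default `"gene"`).
#' @return An interval data.frame (`chrom`, `start`, `end`, `label`).
#' @export
read_gene_features <- function(path, type = "gene") {
  g <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         col.names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attributes"))
  g <- g[g$type == type, , drop = FALSE]
  if (nrow(g) == 0) stop("no '", type, "' features in ", path)
  nm <- vapply(g$attributes, function(a) {
    get1 <- function(key) {
      m <- regmatches(a, regexpr(sprintf("(?:^|;)%s=([^;]+)", key), a,
                                 perl = TRUE))
      if (length(m)) sub(sprintf(".*%s=", key), "", m) else NA_character_
    }
    v <- get1("Name")
    if (is.na(v)) v <- get1("ID")
    if (is.na(v)) v <- a
    v
  }, "", USE.NAMES = FALSE)
  genomic_intervals(g$seqid, g$start, g$end, label = nm)
}

#' Read an eQTL record table
#'
#' Tab-separated columns `chrom`, `pos`, `gene`, `tissue`, `type`
#' (`cis` or `trans`).
#'
#' @param path TSV file path.
#' @return A data.frame of eQTL records.
#' @export
read_eqtl_table <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "gene", "tissue", "type")
  if (!all(need %in% names(e))) {
    stop("eQTL table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(e$type %in% c("cis", "trans"))) stop("eQTL type must be cis or trans")
  if (any(e$pos < 1)) stop("eQTL position must be >= 1")
  e$chrom <- as.character(e$chrom)
  e
}

#' Match SNPs to eQTL records by exact coordinate
#'
#' Exact `(chrom, pos)` join between a variant table and an eQTL table;
#' duplicate eQTL rows are collapsed with a warning. The summary counts
#' matched SNPs and, per type, matched records and distinct tissues.
#'
#' @param snps a variant table (`chrom`, `pos`).
#' @param eqtls an eQTL data.frame (see [read_eqtl_table()]).
#' @return A list: `matches` (joined rows) and `summary`
#'   (`n_matched_snps`, `records_by_type`, `tissues_by_type`).
#' @export
match_snps_to_eqtls <- function(snps, eqtls) {
  dup <- duplicated(eqtls)
  if (any(dup)) {
    warning(sum(dup), " duplicate eQTL row(s) collapsed")
    eqtls <- eqtls[!dup, , drop = FALSE]
  }
  key_snp <- paste(snps$chrom, snps$pos)
  key_e <- paste(eqtls$chrom, eqtls$pos)
  hit <- key_e %in% key_snp
  matches <- eqtls[hit, , drop = FALSE]
  rownames(matches) <- NULL
  by_type <- split(matches, factor(matches$type, levels = c("cis", "trans")))
  list(matches = matches,
       summary = list(
         n_matched_snps = length(unique(key_e[hit])),
         records_by_type = vapply(by_type, nrow, 0L),
         tissues_by_type = vapply(by_type, function(d)
           length(unique(d$tissue)), 0L)))
}
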