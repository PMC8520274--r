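#' Pipeline configuration
#'
#' Validates an end-to-end run configuration. Exactly one input source is
#' allowed: a phased VCF (`vcf` path) or a simulation block (`sim`, a
#' [sim_config()] or a list of its arguments). Annotation file paths are
#' optional; when omitted the annotation stage is skipped.
#'
#' @param vcf path to a phased VCF, or `NULL`.
#' @param sim a [sim_config()] or argument list, or `NULL`.
#' @param autosomes chromosome labels retained from a VCF.
#' @param qc list of QC thresholds (`maf_min`, `call_rate_min`).
#' @param ihs list of iHS parameters passed to [compute_ihs()] and
#'   [scan_windows()] (`maf_min`, `ehh_cutoff`, `max_gap_bp`, `bin_width`,
#'   `min_bin_n`, `width_bp`, `step_bp`, `top_fraction`,
#'   `min_snps_per_window`, `fixed_threshold`).
#' @param roh a [roh_params()].
#' @param islands list of island parameters (`top_fraction`,
#'   `occurrence_floor`, `min_snps`).
#' @param annotation list of file paths (`gff3`, `qtl`, `eqtl`), or `NULL`.
#' @param stages character vector of stages to run, a subset of
#'   `c("qc", "ihs", "roh", "islands", "ibc", "annotate")`.
#' @param seed RNG seed for the run.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, sim = NULL,
                            autosomes = as.character(1:29),
                            qc = list(maf_min = 0.05, call_rate_min = 0.30),
                            ihs = list(), roh = roh_params(),
                            islands = list(top_fraction = 0.01,
                                           occurrence_floor = 0.30,
                                           min_snps = 5),
                            annotation = NULL,
                            stages = c("qc", "ihs", "roh", "islands", "ibc",
                                       "annotate"),
                            seed = 1) {
  if (is.null(vcf) == is.null(sim)) {
    stop("exactly one of 'vcf' or 'sim' must be given")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    sim <- do.call(sim_config, sim)
  }
  all_stages <- c("qc", "ihs", "roh", "islands", "ibc", "annotate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if ("islands" %in% stages && !"roh" %in% stages) {
    stop("the islands stage requires the roh stage")
  }
  structure(list(vcf = vcf, sim = sim, autosomes = autosomes, qc = qc,
                 ihs = ihs, roh = roh, islands = islands,
                 annotation = annotation, stages = stages, seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full selection-signature pipeline
#'
#' Executes QC, the iHS scan, ROH detection, island calling, inbreeding
#' coefficients and region annotation (each stage skippable via the config)
#' and writes every stage table plus a run manifest to `out_dir`. With a
#' fixed config seed, two runs produce byte-identical outputs. A stage
#' failure aborts with the stage name; tables already written are kept.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly: config echo, seed, per-stage row
#'   counts and package version.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = if (!is.null(config$sim)) config$sim$seed else
                     config$seed,
                   package_version = as.character(utils::packageVersion("hoofprint")),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$sim)) {
    cfg <- config$sim
    sim <- stage("simulate", {
      nt <- simulate_neutral(cfg)
      sw <- overlay_sweep(nt$haplotypes, cfg)
      pa <- pair_with_autozygosity(sw$haplotypes, cfg)
      nz <- inject_noise(pa$genotypes, cfg)
      write_phased_vcf(sw$haplotypes, file.path(out_dir, "simulated.vcf"))
      if (!is.null(sw$truth$sweep_interval)) {
        write_tsv(sw$truth$sweep_interval, file.path(out_dir, "truth_sweep.tsv"))
      }
      write_tsv(pa$truth$tracts, file.path(out_dir, "truth_tracts.tsv"))
      list(h = sw$haplotypes, g = nz$genotypes)
    })
    h <- sim$h; g <- sim$g
    manifest$stages$simulate <- list(n_individuals = length(h$sample_ids),
                                     n_snps = ncol(h$alleles))
  } else {
    h <- stage("read_vcf", read_phased_vcf(config$vcf, config$autosomes))
    g <- haplotypes_to_genotypes(h)
    manifest$stages$read_vcf <- list(n_individuals = length(h$sample_ids),
                                     n_snps = ncol(h$alleles))
  }

  if ("qc" %in% config$stages) {
    res <- stage("qc", {
      g2 <- do.call(apply_qc, c(list(g), config$qc))
      h2 <- subset_variants(h, match(paste(g2$variants$chrom, g2$variants$pos),
                                     paste(h$variants$chrom, h$variants$pos)))
      write_tsv(attr(g2, "qc_report"), file.path(out_dir, "qc_report.tsv"))
      list(g = g2, h = h2)
    })
    g <- res$g
    h <- res$h
    manifest$stages$qc <- list(n_snps_retained = ncol(g$dosages))
  }

  regions_ihs <- NULL
  if ("ihs" %in% config$stages) {
    regions_ihs <- stage("ihs", {
      hh <- assign_ancestral(h)
      ihs_args <- config$ihs[intersect(names(config$ihs),
                                       names(formals(compute_ihs)))]
      ihs <- do.call(compute_ihs, c(list(hh), ihs_args))
      win_args <- config$ihs[intersect(names(config$ihs),
                                       names(formals(scan_windows)))]
      scan <- do.call(scan_windows, c(list(ihs), win_args))
      regions <- merge_candidate_windows(scan)
      write_tsv(as.data.frame(ihs), file.path(out_dir, "ihs_per_snp.tsv"))
      write_tsv(as.data.frame(scan), file.path(out_dir, "ihs_windows.tsv"))
      write_tsv(regions, file.path(out_dir, "ihs_regions.tsv"))
      writeLines(paste(regions$chrom, regions$start, regions$end, sep = "\t"),
                 file.path(out_dir, "ihs_regions.bed"))
      regions
    })
    manifest$stages$ihs <- list(n_candidate_regions = nrow(regions_ihs))
  }

  segs <- NULL
  if ("roh" %in% config$stages) {
    segs <- stage("roh", {
      s <- detect_roh(g, config$roh)
      write_tsv(data.frame(FID = s$sample_id, IID = s$sample_id,
                           CHR = s$chrom, POS1 = s$start_bp,
                           POS2 = s$end_bp, KB = s$length_bp / 1000,
                           NSNP = s$n_snps),
                file.path(out_dir, "roh_segments.tsv"))
      s
    })
    manifest$stages$roh <- list(n_segments = nrow(segs))
  }

  islands <- NULL
  if ("islands" %in% config$stages) {
    islands <- stage("islands", {
      track <- snp_incidence(segs, g$variants, length(g$sample_ids))
      isl_args <- config$islands[intersect(names(config$islands),
                                           names(formals(call_islands)))]
      isl <- do.call(call_islands, c(list(track), isl_args))
      write_tsv(as.data.frame(track), file.path(out_dir, "roh_incidence.tsv"))
      write_tsv(isl, file.path(out_dir, "roh_islands.tsv"))
      isl
    })
    manifest$stages$islands <- list(n_islands = nrow(islands))
  }

  if ("ibc" %in% config$stages) {
    ibc <- stage("ibc", {
      res <- compute_ibc(g)
      write_ibc_tsv(res, file.path(out_dir, "inbreeding.ibc.tsv"))
      res
    })
    manifest$stages$ibc <- list(n_individuals = nrow(ibc))
  }

  if ("annotate" %in% config$stages) {
    if (is.null(config$annotation)) {
      manifest$stages$annotate <- list(skipped = "no annotation files supplied")
    } else {
      n_sets <- stage("annotate", {
        regs <- list()
        if (!is.null(regions_ihs) && nrow(regions_ihs)) {
          regs$ihs <- genomic_intervals(regions_ihs$chrom, regions_ihs$start,
                                        regions_ihs$end)
        }
        if (!is.null(islands) && nrow(islands)) {
          regs$roh <- genomic_intervals(islands$chrom, islands$start_bp,
                                        islands$end_bp)
        }
        for (src in names(regs)) {
          if (!is.null(config$annotation$gff3)) {
            genes <- read_gene_features(config$annotation$gff3)
            ann <- annotate_regions(regs[[src]], genes)
            write_tsv(ann$per_region,
                      file.path(out_dir, paste0(src, "_region_genes.tsv")))
          }
          if (!is.null(config$annotation$qtl)) {
            qtl <- read_qtl_table(config$annotation$qtl)
            ann <- annotate_regions(regs[[src]], qtl)
            write_tsv(ann$per_region,
                      file.path(out_dir, paste0(src, "_region_qtls.tsv")))
            write_tsv(data.frame(class = names(ann$class_counts),
                                 n_regions = as.integer(ann$class_counts)),
                      file.path(out_dir, paste0(src, "_qtl_class_counts.tsv")))
          }
        }
        if (!is.null(config$annotation$eqtl)) {
          eq <- read_eqtl_table(config$annotation$eqtl)
          mt <- match_snps_to_eqtls(g$variants, eq)
          write_tsv(mt$matches, file.path(out_dir, "eqtl_matches.tsv"))
        }
        if (length(regs) >= 2) {
          write_tsv(overlap_intervals(regs$ihs, regs$roh),
                    file.path(out_dir, "ihs_roh_overlap.tsv"))
        }
        length(regs)
      })
      manifest$stages$annotate <- list(n_region_sets = n_sets)
    }
  }

  manifest$config <- config_echo(config)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

# Flatten the config into plain lists for the manifest echo.
config_echo <- function(config) {
  ce <- unclass(config)
  if (!is.null(ce$sim)) ce$sim <- unclass(ce$sim)
  ce$roh <- unclass(ce$roh)
  ce
}
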