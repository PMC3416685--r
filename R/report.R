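#' Read a known-variant (dbSNP-like) site set
#'
#' Accepts either a VCF (positions and alternate alleles taken from the
#' records) or a TSV with columns chrom, pos (1-based) and optionally alt.
#'
#' @param path file path.
#' @return data.frame `chrom`, `pos` (0-based) and, when available, `alt`.
#' @export
read_known_sites <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    return(data.frame(chrom = fix[, "CHROM"],
                      pos = as.numeric(fix[, "POS"]) - 1,
                      alt = fix[, "ALT"], stringsAsFactors = FALSE))
  }
  has_header <- grepl("chrom|pos", first, ignore.case = TRUE)
  d <- utils::read.table(path, sep = "\t", header = has_header,
                         stringsAsFactors = FALSE)
  names(d)[1:2] <- c("chrom", "pos")
  if (ncol(d) >= 3L) names(d)[3] <- "alt"
  d$pos <- as.numeric(d$pos) - 1
  d
}

#' Off-target SNP yield relative to the in-target count
#'
#' @param inside_count,near_count,far_count SNP counts per region class.
#' @return list with `outside_total` (near + far) and `ratio_percent`
#'   (rounded percentage of the outside total over the inside count; `NA`
#'   when `inside_count` is 0).
#' @examples
#' offtarget_yield(65231, 44854, 39195)  # outside 84049, ratio 129
#' @export
offtarget_yield <- function(inside_count, near_count, far_count) {
  outside <- near_count + far_count
  list(
    outside_total = outside,
    ratio_percent = if (inside_count > 0)
      round(100 * outside / inside_count) else NA_real_
  )
}

#' Mean capture-target length from kit geometry
#'
#' @param region_count number of targets in the kit.
#' @param total_bases total targeted bases.
#' @return mean target length, rounded to the nearest bp.
#' @examples
#' mean_target_length(165637, 37.8e6)  # 228
#' @export
mean_target_length <- function(region_count, total_bases) {
  stopifnot(region_count >= 1)
  round(total_bases / region_count)
}

#' Published per-platform reference counts for three capture platforms
#'
#' Kit geometry (region count, targeted bases) and per-class filtered SNP
#' counts reported for three widely used capture platforms (Agilent
#' SureSelect v1, Illumina TrueSeq, and the 1000 Genomes Project Pilot 3
#' exon capture). Shipped as a worked-example input table for the
#' off-target yield arithmetic.
#'
#' @return data.frame with columns `platform`, `n_regions`, `total_bases`,
#'   `inside_snps`, `near_snps`, `far_snps`.
#' @export
platform_reference <- function() {
  path <- system.file("extdata", "platform_reference.tsv",
                      package = "offtargetQC", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Estimate the off-target enrichment decay rate from a boundary profile
#'
#' Fits `depth ~ A * exp(-k * distance) + B` by nonlinear least squares to
#' the outside limb of a boundary depth profile and returns the decay rate
#' `k` with its standard error. Distances closer than about half a read
#' length are excluded because pileup smooths the profile across the
#' boundary there.
#'
#' The decay rate's uncertainty is best assessed at the boundary level:
#' when `reads`/`regions` are supplied, the profile is computed from
#' isolated boundaries only and the standard error is obtained by
#' bootstrap resampling of boundaries (the pointwise `nls` standard error
#' ignores the strong correlation of neighbouring profile positions and is
#' far too small).
#'
#' @param profile data.frame from [boundary_depth_profile()] (ignored when
#'   `reads` is given).
#' @param range distances (bp) used in the fit, default 40..200.
#' @param start optional named list of starting values (`A`, `k`, `B`).
#' @param reads,regions optional read data.frame and [target_regions]; when
#'   given, an isolated-boundary profile is computed and bootstrapped.
#' @param n_boot bootstrap replicates (default 100).
#' @return list with `decay`, `se`, `n_boundaries` and the `nls` fit.
#' @export
estimate_enrichment_decay <- function(profile = NULL, range = c(40, 200),
                                      start = NULL, reads = NULL,
                                      regions = NULL, n_boot = 100) {
  fit1 <- function(distance, depth) {
    d <- data.frame(distance = distance, mean_depth = depth)
    d <- d[d$distance >= range[1] & d$distance <= range[2], ]
    s <- if (is.null(start))
      list(A = max(d$mean_depth) * 2, k = 0.01, B = min(d$mean_depth))
    else start
    stats::nls(mean_depth ~ A * exp(-k * distance) + B, data = d, start = s,
               control = stats::nls.control(maxiter = 200))
  }
  if (!is.null(reads)) {
    bp <- boundary_profile_matrix(reads, regions, boundaries = "isolated")
    mean_prof <- colMeans(bp$mat)
    fit <- fit1(bp$offsets, mean_prof)
    ks <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(bp$mat), replace = TRUE)
      f <- tryCatch(fit1(bp$offsets, colMeans(bp$mat[idx, , drop = FALSE])),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else stats::coef(f)[["k"]]
    }, 0)
    return(list(decay = stats::coef(fit)[["k"]],
                se = stats::sd(ks, na.rm = TRUE),
                n_boundaries = nrow(bp$mat), fit = fit))
  }
  fit <- fit1(profile$distance, profile$mean_depth)
  co <- summary(fit)$coefficients
  list(decay = co["k", "Estimate"], se = co["k", "Std. Error"],
       n_boundaries = NA_integer_, fit = fit)
}

#' Run the full off-target quality evaluation
#'
#' Orchestrates the pipeline: target regions, read filtering and coverage
#' summaries, boundary depth profile, SNP filtering and per-class
#' summaries, known-site overlap, chip concordance (including at
#' strand-imbalanced positions), positional annotation of far SNPs, indel
#' counts and off-target yield. Optionally writes every table as TSV.
#'
#' @param bed target-region BED file.
#' @param sam aligned reads (SAM or BAM).
#' @param vcf multi-sample variant calls (VCF).
#' @param dbsnp optional known-sites file (VCF or TSV).
#' @param chip optional chip genotype TSV.
#' @param gene_model optional labeled gene-model BED (exon/ncRNA/gene).
#' @param near near-threshold D in bp (default 200).
#' @param min_mapq,min_gq,min_depth,indel_min_qual filter thresholds
#'   (defaults 20, 20, 5, 1000).
#' @param out_dir optional directory for TSV outputs.
#' @param gc compute the per-position GC summaries (slowest step).
#' @param verbose log per-stage counts.
#' @return object of class `study_report`.
#' @export
run_study <- function(bed, sam, vcf, dbsnp = NULL, chip = NULL,
                      gene_model = NULL, near = 200, min_mapq = 20,
                      min_gq = 20, min_depth = 5, indel_min_qual = 1000,
                      out_dir = NULL, gc = TRUE, verbose = TRUE) {
  for (f in c(bed, sam, vcf, dbsnp, chip, gene_model))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  say <- function(...) if (verbose) message(...)

  regions <- read_bed(bed)
  say("regions: ", regions$region_count, " targets, ",
      regions$total_bases, " bases")

  reads <- read_alignments(sam)
  fr <- filter_reads(reads, min_mapq = min_mapq, regions = regions,
                     near = near)
  say("reads: ", nrow(reads), " -> ", nrow(fr$reads), " after MAPQ >= ",
      min_mapq, " and duplicate removal")
  chrom_lengths <- infer_chrom_lengths(reads, regions)
  profile <- boundary_depth_profile(fr$reads, regions,
                                    chrom_lengths = chrom_lengths)
  coverage <- class_coverage_summary(fr$reads, regions, near = near,
                                     chrom_lengths = chrom_lengths, gc = gc)
  insert_frac <- insert_size_fraction(fr$reads)
  high_far <- find_high_depth_far_regions(fr$reads, regions, near = near,
                                          min_depth = 100, min_length = 100,
                                          chrom_lengths = chrom_lengths)

  calls <- read_vcf_calls(vcf)
  fs <- filter_snps(calls, min_gq = min_gq, min_depth = min_depth,
                    regions = regions, near = near)
  say("snp genotypes: ", fs$counts$before[1], " -> ", fs$counts$after[1],
      " after GQ >= ", min_gq, " and depth >= ", min_depth)
  known <- if (!is.null(dbsnp)) read_known_sites(dbsnp) else NULL
  snp_summary <- summarize_snps_by_class(fs$calls, regions, near = near,
                                         known = known)
  nn <- snp_summary$by_class$n_genotypes
  yield <- offtarget_yield(nn[1], nn[2], nn[3])
  indel_counts <- count_indels_by_qual(calls, min_qual = indel_min_qual,
                                       regions = regions, near = near)

  concord <- NULL
  if (!is.null(chip)) {
    chipg <- read_chip_genotypes(chip)
    depth <- depth_vectors(fr$reads, chrom_lengths)
    cp <- unique(chipg[, c("chrom", "pos")])
    cp$depth <- vapply(seq_len(nrow(cp)), function(i) {
      d <- depth[[cp$chrom[i]]]
      p <- cp$pos[i]
      if (!is.null(d) && p >= 0 && p < length(d)) d[p + 1L] else 0
    }, 0)
    concord <- list(
      overall = overall_consistency(fs$calls, chipg, mode = "homref",
                                    depth = cp, min_depth = min_depth,
                                    exclude = fs$dropped),
      het = het_consistency(calls, chipg, min_gq = min_gq),
      strand = strand_imbalance_consistency(fr$reads, fs$calls, chipg,
                                            min_depth = min_depth,
                                            min_gq = min_gq,
                                            chrom_lengths = chrom_lengths)
    )
    say("concordance: overall ",
        sprintf("%.3f", concord$overall$overall_rate), ", het ",
        sprintf("%.3f", concord$het$het_rate))
  }

  annotation <- NULL
  if (!is.null(gene_model)) {
    gm <- read_gene_model(gene_model)
    snv <- fs$calls[!fs$calls$is_indel &
                      fs$calls$gt %in% c("het", "hom"), , drop = FALSE]
    far <- snv[classify_position(regions, snv$chrom, snv$pos, near) == "far", ]
    far_sites <- unique(far[, c("chrom", "pos")])
    cat_f <- annotate_positional(far_sites$chrom, far_sites$pos, gm)
    annotation <- as.data.frame(table(category = cat_f),
                                responseName = "n_sites")
  }

  report <- structure(
    list(
      regions = summarize_regions(regions),
      read_counts = fr$counts,
      boundary_profile = profile,
      coverage = coverage,
      insert_size_fraction = insert_frac,
      high_depth_far = high_far,
      snp_filter_counts = fs$counts,
      snp_by_class = snp_summary$by_class,
      snp_depth_histogram = snp_summary$depth_histogram,
      yield = yield,
      indel_counts = indel_counts,
      concordance = concord,
      annotation = annotation,
      params = list(near = near, min_mapq = min_mapq, min_gq = min_gq,
                    min_depth = min_depth, indel_min_qual = indel_min_qual)
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_report_tables(report, out_dir)
  report
}

# Write the report's tables as TSV files under `dir`.
write_report_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, name) write_tsv(d, file.path(dir, name))
  w(report$read_counts, "read_counts.tsv")
  w(report$boundary_profile, "boundary_profile.tsv")
  w(report$coverage$breadth, "coverage_breadth.tsv")
  mds <- report$coverage$min_depth_sites
  w(cbind(class = rownames(mds), mds), "min_depth_sites.tsv")
  if (!is.null(report$coverage$gc)) w(report$coverage$gc, "gc_content.tsv")
  w(report$snp_filter_counts, "snp_filter_counts.tsv")
  w(report$snp_by_class, "snp_by_class.tsv")
  dh <- as.data.frame(report$snp_depth_histogram)
  w(cbind(depth = rownames(dh), dh), "snp_depth_histogram.tsv")
  if (!is.null(report$annotation)) w(report$annotation, "annotation.tsv")
  w(data.frame(class = names(report$indel_counts),
               n = as.integer(report$indel_counts)), "indel_counts.tsv")
  if (!is.null(report$concordance)) {
    cc <- report$concordance
    w(data.frame(
      metric = c("overall_rate", "het_rate", "n_forward_only",
                 "n_reverse_only", "strand_overall_rate", "strand_het_rate"),
      value = c(cc$overall$overall_rate, cc$het$het_rate,
                cc$strand$n_forward_only, cc$strand$n_reverse_only,
                cc$strand$overall$overall_rate, cc$strand$het$het_rate)
    ), "concordance.tsv")
  }
  w(data.frame(inside = report$snp_by_class$n_genotypes[1],
               near = report$snp_by_class$n_genotypes[2],
               far = report$snp_by_class$n_genotypes[3],
               outside_total = report$yield$outside_total,
               ratio_percent = report$yield$ratio_percent), "yield.tsv")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Off-target capture QC report\n")
  cat(sprintf("  targets: %d regions, %s bases (mean %d bp)\n",
              x$regions$region_count,
              format(x$regions$total_bases, big.mark = ","),
              x$regions$mean_length))
  rc <- x$read_counts
  all_row <- rc[rc$class == "all", ]
  cat(sprintf("  reads: %d before filter, %d after\n",
              all_row$before, all_row$after))
  for (k in c("inside", "near", "far")) {
    r <- rc[rc$class == k, ]
    if (nrow(r))
      cat(sprintf("    %-7s %8d (%.1f%%)\n", k, r$after,
                  100 * r$after / all_row$after))
  }
  sb <- x$snp_by_class
  cat("  SNPs (filtered genotypes):\n")
  for (i in seq_len(nrow(sb)))
    cat(sprintf("    %-7s %8d  Ti/Tv %.2f%s\n", sb$class[i],
                sb$n_genotypes[i], sb$titv[i],
                if (!is.na(sb$pct_in_dbsnp[i]))
                  sprintf("  dbSNP %.1f%%", sb$pct_in_dbsnp[i]) else ""))
  cat(sprintf("  off-target yield: %d outside vs %d inside (%d%%)\n",
              x$yield$outside_total, sb$n_genotypes[1],
              as.integer(x$yield$ratio_percent)))
  if (!is.null(x$concordance)) {
    cat(sprintf("  concordance: overall %.3f, het %.3f\n",
                x$concordance$overall$overall_rate,
                x$concordance$het$het_rate))
    cat(sprintf("  strand-imbalanced positions: %d forward-only, %d reverse-only\n",
                x$concordance$strand$n_forward_only,
                x$concordance$strand$n_reverse_only))
  }
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  invisible(object)
}
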