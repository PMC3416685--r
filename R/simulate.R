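#' Simulation configuration for targeted-capture data
#'
#' Bundles every parameter of the capture-data generator. Defaults describe
#' a small but realistically structured exome-capture experiment: a 5 Mb
#' genome carrying 2,000 capture targets of mean length 228 bp, 40x mean
#' on-target depth decaying exponentially off-target onto a low background,
#' 72 bp reads with ~170 bp inserts, class-specific transition
#' probabilities (0.75 inside/near targets for an exon-like Ti/Tv of 3,
#' 2/3 far for a genome-wide Ti/Tv of 2), genotype-quality/depth-correlated
#' call errors, an error-free chip truth set, and a few strand-biased
#' targets and high-depth far blocks.
#'
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @param genome_length total genome size in bp.
#' @param n_chromosomes number of equally sized chromosomes.
#' @param n_targets number of capture targets across the genome.
#' @param target_length_mean,target_length_sd target length distribution (bp).
#' @param near_threshold near/far distance threshold D in bp.
#' @param depth_inside mean depth inside targets.
#' @param enrichment_decay per-bp exponential decay rate of off-target
#'   enrichment.
#' @param far_background_depth mean background depth far from targets.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert-size distribution (bp).
#' @param insert_long_fraction fraction of pairs drawn from a long
#'   (500-2000 bp) insert tail.
#' @param ti_prob_inside,ti_prob_outside per-SNV transition probability for
#'   sites inside/near targets vs far.
#' @param snv_rate per-bp polymorphism probability.
#' @param het_fraction fraction of non-reference genotypes that are
#'   heterozygous.
#' @param carrier_prob per-sample probability of carrying a non-reference
#'   genotype at a polymorphic site.
#' @param n_samples samples in the VCF/chip outputs.
#' @param seq_error_low,seq_error_high per-genotype miscall probability in
#'   the noisy stratum (GQ < 20 or depth < 5) vs the clean stratum.
#' @param chip_error_rate per-genotype chip miscall probability.
#' @param chip_fraction fraction of polymorphic sites present on the chip.
#' @param chip_monomorphic extra invariant chip positions genome-wide.
#' @param chip_missing_rate per-genotype chip no-call probability.
#' @param dbsnp_fraction probability a polymorphic site is in the
#'   known-sites catalogue.
#' @param gc_inside,gc_outside GC base probability inside targets vs
#'   elsewhere.
#' @param strand_bias_fraction fraction of targets whose reads are forced
#'   onto a single strand.
#' @param high_depth_far_blocks,high_depth_block_length,high_depth_block_depth
#'   number, length (bp) and added depth of abnormally covered far blocks.
#' @param mapq_low_fraction fraction of reads with MAPQ below 20.
#' @param dup_fraction fraction of duplicate-flagged reads.
#' @param softclip_fraction,indel_cigar_fraction fractions of reads emitted
#'   with soft-clipped / indel-containing CIGARs.
#' @param n_indels number of indel sites in the VCF.
#' @return object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 5e6,
                       n_chromosomes = 2L,
                       n_targets = 2000L,
                       target_length_mean = 228,
                       target_length_sd = 60,
                       near_threshold = 200,
                       depth_inside = 40,
                       enrichment_decay = 0.02,
                       far_background_depth = 3,
                       read_length = 72L,
                       insert_mean = 170,
                       insert_sd = 30,
                       insert_long_fraction = 0.058,
                       ti_prob_inside = 0.75,
                       ti_prob_outside = 2 / 3,
                       snv_rate = 0.001,
                       het_fraction = 2 / 3,
                       carrier_prob = 0.5,
                       n_samples = 4L,
                       seq_error_low = 0.25,
                       seq_error_high = 0.003,
                       chip_error_rate = 0,
                       chip_fraction = 0.3,
                       chip_monomorphic = 2000L,
                       chip_missing_rate = 0.005,
                       dbsnp_fraction = 0.77,
                       gc_inside = 0.506,
                       gc_outside = 0.464,
                       strand_bias_fraction = 0.05,
                       high_depth_far_blocks = 2L,
                       high_depth_block_length = 300L,
                       high_depth_block_depth = 200,
                       mapq_low_fraction = 0.08,
                       dup_fraction = 0.02,
                       softclip_fraction = 0.02,
                       indel_cigar_fraction = 0.01,
                       n_indels = 150L) {
  cfg <- as.list(environment())
  probs <- c("insert_long_fraction", "ti_prob_inside", "ti_prob_outside",
             "snv_rate", "het_fraction", "carrier_prob", "seq_error_low",
             "seq_error_high", "chip_error_rate", "chip_fraction",
             "chip_missing_rate", "dbsnp_fraction", "gc_inside", "gc_outside",
             "strand_bias_fraction", "mapq_low_fraction", "dup_fraction",
             "softclip_fraction", "indel_cigar_fraction")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  pos <- c("genome_length", "n_chromosomes", "n_targets",
           "target_length_mean", "near_threshold", "depth_inside",
           "read_length", "insert_mean")
  for (p in pos) if (cfg[[p]] <= 0) stop(p, " must be > 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Capture simulation config:",
      format(x$genome_length, big.mark = ","), "bp genome,",
      x$n_targets, "targets,", x$depth_inside, "x inside depth, seed",
      x$seed, "\n")
  invisible(x)
}

sim_chrom_lengths <- function(config) {
  len <- floor(config$genome_length / config$n_chromosomes)
  stats::setNames(rep(len, config$n_chromosomes),
                  paste0("chr", seq_len(config$n_chromosomes)))
}

#' Generate non-overlapping capture targets
#'
#' Target lengths are sampled around `target_length_mean` and placed with
#' random gaps so that intervals are disjoint and non-adjacent.
#' Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param bed_path optional path; when given the targets are also written
#'   as a 3-column BED file.
#' @return a [target_regions] object.
#' @export
generate_targets <- function(config, bed_path = NULL) {
  set.seed(config$seed)
  lens <- sim_chrom_lengths(config)
  per_chrom <- round(config$n_targets / config$n_chromosomes)
  rows <- list()
  for (ch in names(lens)) {
    L <- lens[[ch]]
    tl <- pmax(50, round(stats::rnorm(per_chrom, config$target_length_mean,
                                      config$target_length_sd)))
    gap_total <- L - sum(tl)
    if (gap_total < 2L * (per_chrom + 1L))
      stop("infeasible packing: targets nearly fill the chromosome")
    # exponential gaps: target spacing behaves like a Poisson process
    g_raw <- stats::rexp(per_chrom + 1L)
    g <- 1L + floor(g_raw * (gap_total - (per_chrom + 1L)) / sum(g_raw))
    starts <- cumsum(g[seq_len(per_chrom)]) + c(0, cumsum(tl[-per_chrom]))
    rows[[ch]] <- data.frame(chrom = ch, start = starts, end = starts + tl)
  }
  d <- do.call(rbind, rows)
  if (!is.null(bed_path)) {
    writeLines(sprintf("%s\t%d\t%d", d$chrom, as.integer(d$start),
                       as.integer(d$end)), bed_path)
  }
  target_regions(d$chrom, d$start, d$end)
}

# Deterministic layout shared by the read and genotype generators:
# expected per-position depth, high-depth far blocks, strand-biased targets.
sim_layout <- function(config, targets) {
  set.seed(config$seed + 11L)
  lens <- sim_chrom_lengths(config)
  lambda <- list()
  blocks <- list()
  for (ch in names(lens)) {
    L <- lens[[ch]]
    d <- distance_to_nearest(targets, ch, 0:(L - 1L))
    lam <- ifelse(d == 0, config$depth_inside,
                  config$depth_inside * exp(-config$enrichment_decay *
                                              pmin(d, 5000)) +
                    config$far_background_depth)
    lambda[[ch]] <- lam
  }
  n_blocks <- config$high_depth_far_blocks
  if (n_blocks > 0) {
    chs <- sample(names(lens), n_blocks, replace = TRUE)
    for (i in seq_len(n_blocks)) {
      ch <- chs[i]
      d <- distance_to_nearest(targets, ch, 0:(lens[[ch]] - 1L))
      cand <- which(d > config$near_threshold + 500 +
                      config$high_depth_block_length) - 1L
      ctr <- sample(cand, 1L)
      s <- ctr - floor(config$high_depth_block_length / 2)
      e <- s + config$high_depth_block_length
      lambda[[ch]][(s + 1L):e] <- lambda[[ch]][(s + 1L):e] +
        config$high_depth_block_depth
      blocks[[i]] <- data.frame(chrom = ch, start = s, end = e,
                                depth = config$high_depth_block_depth)
    }
  }
  tg <- do.call(rbind, lapply(names(targets$chroms), function(ch)
    data.frame(chrom = ch, start = targets$chroms[[ch]][, 1],
               end = targets$chroms[[ch]][, 2])))
  k <- round(config$strand_bias_fraction * nrow(tg))
  biased <- NULL
  if (k > 0) {
    idx <- sample(nrow(tg), k)
    biased <- tg[idx, , drop = FALSE]
    biased$strand <- sample(c("+", "-"), k, replace = TRUE)
    rownames(biased) <- NULL
  }
  list(lambda = lambda,
       blocks = if (length(blocks)) do.call(rbind, blocks) else NULL,
       biased = biased)
}

# Deterministic reference-like genome with class-dependent GC content.
sim_genome <- function(config, targets) {
  set.seed(config$seed + 7L)
  lens <- sim_chrom_lengths(config)
  out <- list()
  bases <- c("A", "C", "G", "T")
  for (ch in names(lens)) {
    L <- lens[[ch]]
    inside <- distance_to_nearest(targets, ch, 0:(L - 1L)) == 0
    gc <- ifelse(inside, config$gc_inside, config$gc_outside)
    is_gc <- stats::runif(L) < gc
    pick <- stats::runif(L) < 0.5
    code <- ifelse(is_gc, ifelse(pick, 2L, 3L), ifelse(pick, 1L, 4L))
    out[[ch]] <- list(code = code, str = paste(bases[code], collapse = ""))
  }
  out
}

#' Simulate aligned capture reads
#'
#' Read start positions follow the layout's expected-depth surface (flat
#' inside targets, exponential decay plus background outside, plus
#' high-depth far blocks), so pileup depth reproduces the configured
#' enrichment profile. Reads carry a MAPQ mixture, duplicate flags, paired
#' insert sizes with a long tail, mostly ungapped CIGARs plus a fraction of
#' soft-clipped and indel-containing ones, and per-position strand sampling
#' that honours the strand-biased targets.
#'
#' @param config a [sim_config()].
#' @param targets a [target_regions] object from [generate_targets()].
#' @param sam_path optional path for a coordinate-sorted SAM file.
#' @return list with `reads` (data.frame in [read_alignments()] layout),
#'   `truth_depth`, `truth_fwd`, `truth_rev` (per-chromosome pileup depth
#'   vectors of all emitted reads), `truth_fwd_filt`/`truth_rev_filt`
#'   (same restricted to MAPQ >= 20 non-duplicate reads), `layout`
#'   (expected-depth surface, high-depth blocks, strand-biased targets)
#'   and `sam_path`.
#' @export
simulate_reads <- function(config, targets, sam_path = NULL) {
  layout <- sim_layout(config, targets)
  genome <- sim_genome(config, targets)
  set.seed(config$seed + 1L)
  lens <- sim_chrom_lengths(config)
  L <- config$read_length
  half <- floor(L / 2)
  parts <- list()
  for (ch in names(lens)) {
    clen <- lens[[ch]]
    w <- layout$lambda[[ch]]
    w[seq_len(half)] <- 0
    w[(clen - half):clen] <- 0
    cdf <- cumsum(w)
    n <- round(cdf[clen] / L)
    u <- stats::runif(n) * cdf[clen]
    centers <- findInterval(u, cdf) + 1L        # 1-based center positions
    start0 <- pmin(pmax(centers - 1L - half, 0L), clen - L - 10L)
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    if (!is.null(layout$biased)) {
      b <- layout$biased[layout$biased$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(b))) {
        hit <- start0 >= (b$start[i] - L) & start0 < (b$end[i] + L)
        strand[hit] <- b$strand[i]
      }
    }
    low <- stats::runif(n) < config$mapq_low_fraction
    mapq <- integer(n)
    mapq[low] <- sample(0:19, sum(low), replace = TRUE)
    top <- stats::runif(n) < 0.8
    mapq[!low] <- ifelse(top[!low], 60L,
                         sample(20:59, sum(!low), replace = TRUE))
    dup <- stats::runif(n) < config$dup_fraction
    kind <- sample(c("m", "s", "i", "d"), n, replace = TRUE,
                   prob = c(1 - config$softclip_fraction -
                              config$indel_cigar_fraction,
                            config$softclip_fraction,
                            config$indel_cigar_fraction / 2,
                            config$indel_cigar_fraction / 2))
    cigar <- rep(sprintf("%dM", L), n)
    cigar[kind == "s"] <- sprintf("5S%dM7S", L - 12L)
    cigar[kind == "d"] <- sprintf("30M2D%dM", L - 30L)
    cigar[kind == "i"] <- sprintf("20M3I%dM", L - 23L)
    g <- genome[[ch]]$str
    seq <- substring(g, start0 + 1L, start0 + L)
    ssel <- which(kind == "s")
    seq[ssel] <- substring(g, start0[ssel] + 1L - 5L, start0[ssel] + L - 5L)
    dsel <- which(kind == "d")
    seq[dsel] <- paste0(substring(g, start0[dsel] + 1L, start0[dsel] + 30L),
                        substring(g, start0[dsel] + 33L, start0[dsel] + 32L + L - 30L))
    isel <- which(kind == "i")
    seq[isel] <- paste0(substring(g, start0[isel] + 1L, start0[isel] + 20L),
                        "ACG",
                        substring(g, start0[isel] + 21L, start0[isel] + 20L + L - 23L))
    q <- pmin(41L, pmax(2L, round(stats::rnorm(n, 36, 3))))
    qchars <- strsplit(intToUtf8(q + 33L), "")[[1]]
    qual <- strrep(qchars, L)
    long <- stats::runif(n) < config$insert_long_fraction
    isize <- ifelse(long,
                    round(stats::runif(n, 501, 2000)),
                    pmax(L, round(stats::rnorm(n, config$insert_mean,
                                               config$insert_sd))))
    isize <- ifelse(strand == "+", isize, -isize)
    parts[[ch]] <- data.frame(
      qname = sprintf("r_%s_%07d", ch, seq_len(n)),
      flag = 1L + 2L + 64L +
        ifelse(strand == "-", 16L, 32L) + ifelse(dup, 1024L, 0L),
      chrom = ch, pos = start0, mapq = mapq, strand = strand,
      cigar = cigar, seq = seq, qual = qual, isize = isize,
      is_duplicate = dup, stringsAsFactors = FALSE
    )
  }
  reads <- do.call(rbind, parts)
  reads <- reads[order(reads$chrom, reads$pos, reads$qname), , drop = FALSE]
  rownames(reads) <- NULL
  if (!is.null(sam_path)) write_sam(reads, lens, sam_path)
  pass <- reads$mapq >= 20 & !reads$is_duplicate
  list(
    reads = reads,
    truth_depth = depth_vectors(reads, lens),
    truth_fwd = depth_vectors(reads[reads$strand == "+", , drop = FALSE], lens),
    truth_rev = depth_vectors(reads[reads$strand == "-", , drop = FALSE], lens),
    truth_fwd_filt = depth_vectors(reads[pass & reads$strand == "+", ,
                                         drop = FALSE], lens),
    truth_rev_filt = depth_vectors(reads[pass & reads$strand == "-", ,
                                         drop = FALSE], lens),
    layout = layout,
    sam_path = sam_path
  )
}

# Write a coordinate-sorted SAM file (text) for a reads data.frame.
write_sam <- function(reads, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  L <- nchar(reads$seq)
  pnext <- pmax(1L, reads$pos + 1L + abs(reads$isize) - L)
  body <- paste(reads$qname, as.integer(reads$flag), reads$chrom,
                as.integer(reads$pos + 1), as.integer(reads$mapq),
                reads$cigar, "=", as.integer(pnext),
                as.integer(reads$isize), reads$seq, reads$qual, sep = "\t")
  con <- file(path, open = "wb")  # binary mode: stable newlines
  writeLines(c(hdr, body), con, sep = "\n")
  close(con)
  invisible(path)
}

# Map a truth genotype code (0 ref / 1 het / 2 hom-alt) through a miscall.
flip_genotype <- function(g, err, u) {
  out <- g
  out[err & g == 1L] <- ifelse(u[err & g == 1L] < 0.5, 0L, 2L)
  out[err & g == 2L] <- 1L
  out[err & g == 0L] <- 1L
  out
}

#' Simulate genotype truth, sequencing calls, chip calls and known sites
#'
#' Places true SNVs at `snv_rate` with class-specific transition
#' probabilities, then derives per-sample sequencing genotype calls whose
#' depth follows the positional expected-depth surface and whose genotype
#' quality is a noisy increasing function of depth. Miscalls occur at
#' `seq_error_low` in the noisy stratum (GQ < 20 or depth < 5) and
#' `seq_error_high` otherwise. Chip genotypes carry independent errors and
#' occasional missing calls, and include extra invariant (monomorphic)
#' positions. All outputs are deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param targets a [target_regions] object.
#' @param dir optional output directory; when given, writes `calls.vcf`,
#'   `chip.tsv`, `known_sites.tsv` and a `truth/` subdirectory.
#' @return list with `sites` (truth site table: chrom, pos, ref, alt,
#'   class, in_dbsnp, on_chip, lambda), `genotypes` (long truth/called
#'   table), `chip` (data.frame in [read_chip_genotypes()] layout),
#'   `known` (chrom, pos, alt), `indels` (site table), and any file paths.
#' @export
simulate_genotypes_and_calls <- function(config, targets, dir = NULL) {
  layout <- sim_layout(config, targets)
  genome <- sim_genome(config, targets)
  set.seed(config$seed + 2L)
  lens <- sim_chrom_lengths(config)
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", C = "T", G = "A", T = "C")
  site_parts <- list()
  for (ch in names(lens)) {
    clen <- lens[[ch]]
    n_s <- stats::rbinom(1L, clen, config$snv_rate)
    pos0 <- sort(sample.int(clen, n_s)) - 1L
    d <- distance_to_nearest(targets, ch, pos0)
    cls <- class_from_distance(d, config$near_threshold)
    ref <- bases[genome[[ch]]$code[pos0 + 1L]]
    ti_p <- ifelse(cls == "far", config$ti_prob_outside, config$ti_prob_inside)
    is_ti <- stats::runif(n_s) < ti_p
    tv_choice <- stats::runif(n_s) < 0.5
    alt <- ifelse(is_ti, transition_of[ref], NA)
    # transversion partners: for purines {C,T}, for pyrimidines {A,G}
    purine <- ref %in% c("A", "G")
    alt[!is_ti] <- ifelse(purine[!is_ti],
                          ifelse(tv_choice[!is_ti], "C", "T"),
                          ifelse(tv_choice[!is_ti], "A", "G"))
    site_parts[[ch]] <- data.frame(
      chrom = ch, pos = pos0, ref = ref, alt = unname(alt),
      class = as.character(cls),
      in_dbsnp = stats::runif(n_s) < config$dbsnp_fraction,
      on_chip = stats::runif(n_s) < config$chip_fraction,
      lambda = layout$lambda[[ch]][pos0 + 1L],
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, site_parts)
  rownames(sites) <- NULL
  ns <- nrow(sites)
  samples <- sprintf("S%02d", seq_len(config$n_samples))

  geno <- list()
  for (s in samples) {
    nonref <- stats::runif(ns) < config$carrier_prob
    het <- stats::runif(ns) < config$het_fraction
    truth <- ifelse(nonref, ifelse(het, 1L, 2L), 0L)
    dp <- stats::rpois(ns, sites$lambda)
    gq <- round(pmin(99, pmax(0, 2 * pmin(dp, 15) + 25 +
                                stats::rnorm(ns, 0, 10) - 40 * (dp < 5))))
    eps <- ifelse(gq < 20 | dp < 5, config$seq_error_low, config$seq_error_high)
    err <- stats::runif(ns) < eps
    called <- flip_genotype(truth, err, stats::runif(ns))
    chip_err <- stats::runif(ns) < config$chip_error_rate
    chip_g <- flip_genotype(truth, chip_err, stats::runif(ns))
    chip_missing <- stats::runif(ns) < config$chip_missing_rate
    ref_reads <- ifelse(called == 1L, stats::rbinom(ns, dp, 0.5),
                        ifelse(called == 0L, dp, 0L))
    geno[[s]] <- data.frame(
      sample = s, site = seq_len(ns), truth = truth, called = called,
      dp = dp, gq = gq, err = err, chip = chip_g,
      chip_missing = chip_missing, ref_reads = ref_reads,
      stringsAsFactors = FALSE
    )
  }
  genotypes <- do.call(rbind, geno)
  rownames(genotypes) <- NULL

  # indel sites (uniform over the genome, one heterozygous carrier)
  ind_parts <- list()
  set_ch <- sample(names(lens), config$n_indels, replace = TRUE)
  for (ch in names(lens)) {
    k <- sum(set_ch == ch)
    if (k == 0) next
    p <- sort(sample.int(lens[[ch]] - 2L, k)) - 1L
    is_del <- stats::runif(k) < 0.5
    r1 <- bases[genome[[ch]]$code[p + 1L]]
    r2 <- bases[genome[[ch]]$code[p + 2L]]
    ref <- ifelse(is_del, paste0(r1, r2), r1)
    alt <- ifelse(is_del, r1, paste0(r1, sample(bases, k, replace = TRUE)))
    ind_parts[[ch]] <- data.frame(
      chrom = ch, pos = p, ref = ref, alt = alt,
      qual = round(stats::rlnorm(k, log(800), 0.8)),
      carrier = sample(samples, k, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  indels <- do.call(rbind, ind_parts)
  rownames(indels) <- NULL

  # chip table: polymorphic chip sites plus invariant positions
  chip_rows <- list()
  g_on <- genotypes[sites$on_chip[genotypes$site], , drop = FALSE]
  gsite <- sites[g_on$site, ]
  a1 <- ifelse(g_on$chip == 2L, gsite$alt, gsite$ref)
  a2 <- ifelse(g_on$chip == 0L, gsite$ref, gsite$alt)
  a1[g_on$chip_missing] <- "N"
  a2[g_on$chip_missing] <- "N"
  chip_rows$poly <- data.frame(
    sample = g_on$sample, chrom = gsite$chrom, pos = gsite$pos,
    a1 = a1, a2 = a2, stringsAsFactors = FALSE
  )
  if (config$chip_monomorphic > 0) {
    mch <- sample(names(lens), config$chip_monomorphic, replace = TRUE)
    mpos <- vapply(lens[mch], function(l) sample.int(l, 1L) - 1L, 0)
    mref <- vapply(seq_along(mch), function(i)
      bases[genome[[mch[i]]]$code[mpos[i] + 1L]], "")
    mono <- data.frame(chrom = mch, pos = as.numeric(mpos), ref = mref,
                       stringsAsFactors = FALSE)
    mono <- mono[!duplicated(paste(mono$chrom, mono$pos)), , drop = FALSE]
    chip_rows$mono <- do.call(rbind, lapply(samples, function(s)
      data.frame(sample = s, chrom = mono$chrom, pos = mono$pos,
                 a1 = mono$ref, a2 = mono$ref, stringsAsFactors = FALSE)))
  }
  chip <- do.call(rbind, chip_rows)
  chip <- chip[order(chip$sample, chip$chrom, chip$pos), , drop = FALSE]
  rownames(chip) <- NULL
  chip$missing <- chip$a1 == "N" | chip$a2 == "N"

  known <- sites[sites$in_dbsnp, c("chrom", "pos", "alt")]
  rownames(known) <- NULL

  paths <- list()
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    paths$vcf <- file.path(dir, "calls.vcf")
    write_sim_vcf(sites, genotypes, indels, samples, lens, paths$vcf)
    paths$chip <- file.path(dir, "chip.tsv")
    chip_out <- chip
    chip_out$pos <- format(chip_out$pos + 1, scientific = FALSE, trim = TRUE)
    write_tsv(chip_out[, c("sample", "chrom", "pos", "a1", "a2")], paths$chip)
    paths$known <- file.path(dir, "known_sites.tsv")
    known_out <- known
    known_out$pos <- format(known_out$pos + 1, scientific = FALSE, trim = TRUE)
    write_tsv(known_out, paths$known)
    paths$truth_sites <- file.path(dir, "truth", "sites.tsv")
    write_tsv(sites, paths$truth_sites)
    paths$truth_genotypes <- file.path(dir, "truth", "genotypes.tsv")
    write_tsv(genotypes, paths$truth_genotypes)
  }
  c(list(sites = sites, genotypes = genotypes, indels = indels,
         chip = chip, known = known, samples = samples), paths)
}

write_tsv <- function(d, path) {
  con <- file(path, open = "wb")
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  close(con)
  invisible(path)
}

# Emit a VCF 4.2 file for simulated SNV + indel calls.
write_sim_vcf <- function(sites, genotypes, indels, samples, chrom_lengths,
                          path) {
  gmat <- matrix(genotypes$called, nrow = nrow(sites))
  dmat <- matrix(genotypes$dp, nrow = nrow(sites))
  qmat <- matrix(genotypes$gq, nrow = nrow(sites))
  rmat <- matrix(genotypes$ref_reads, nrow = nrow(sites))
  keep <- rowSums(gmat > 0) > 0
  gt_str <- c("0/0", "0/1", "1/1")
  fmt_cell <- function(g, gq, dp, rr) {
    alt_reads <- dp - rr
    sprintf("%s:%d:%d:%d,%d", gt_str[g + 1L], gq, dp, rr, alt_reads)
  }
  pos1 <- format(sites$pos + 1, scientific = FALSE, trim = TRUE)
  rows_snv <- vapply(which(keep), function(i) {
    qual <- max(10, round(40 * sum(gmat[i, ] > 0) +
                            10 * mean(dmat[i, ])))
    cells <- fmt_cell(gmat[i, ], qmat[i, ], dmat[i, ], rmat[i, ])
    paste(c(sites$chrom[i], pos1[i], ".", sites$ref[i],
            sites$alt[i], qual, "PASS", "MQ=60;BQ=36", "GT:GQ:DP:AD",
            cells), collapse = "\t")
  }, "")
  rows_ind <- character(0)
  if (!is.null(indels) && nrow(indels) > 0) {
    ipos1 <- format(indels$pos + 1, scientific = FALSE, trim = TRUE)
    rows_ind <- vapply(seq_len(nrow(indels)), function(i) {
      cells <- ifelse(samples == indels$carrier[i],
                      "0/1:99:30:15,15", "0/0:99:30:30,0")
      paste(c(indels$chrom[i], ipos1[i], ".", indels$ref[i],
              indels$alt[i], indels$qual[i], "PASS", "MQ=60;BQ=36",
              "GT:GQ:DP:AD", cells), collapse = "\t")
    }, "")
  }
  body <- c(rows_snv, rows_ind)
  chrom_of <- sub("\t.*", "", body)
  pos_of <- as.numeric(vapply(strsplit(body, "\t"), `[`, "", 2L))
  body <- body[order(chrom_of, pos_of)]
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Filtered depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  con <- file(path, open = "wb")
  writeLines(c(hdr, body), con, sep = "\n")
  close(con)
  invisible(path)
}

#' Generate a labeled gene model around the capture targets
#'
#' Groups consecutive targets into genes (targets play the role of exons),
#' and scatters standalone ncRNA intervals into intergenic space. Useful
#' for exercising positional annotation.
#'
#' @param config a [sim_config()].
#' @param targets a [target_regions] object.
#' @param path optional BED4 output path.
#' @param exons_per_gene how many consecutive targets form one gene.
#' @param n_ncrna number of standalone ncRNA intervals.
#' @return data.frame `chrom`, `start`, `end`, `label`.
#' @export
generate_gene_model <- function(config, targets, path = NULL,
                                exons_per_gene = 5L, n_ncrna = 50L) {
  set.seed(config$seed + 3L)
  lens <- sim_chrom_lengths(config)
  rows <- list()
  for (ch in names(targets$chroms)) {
    m <- targets$chroms[[ch]]
    rows[[paste0(ch, "_exon")]] <- data.frame(
      chrom = ch, start = m[, 1], end = m[, 2], label = "exon")
    grp <- (seq_len(nrow(m)) - 1L) %/% exons_per_gene
    gs <- tapply(m[, 1], grp, min) - 300
    ge <- tapply(m[, 2], grp, max) + 300
    rows[[paste0(ch, "_gene")]] <- data.frame(
      chrom = ch, start = pmax(0, gs), end = pmin(lens[[ch]], ge),
      label = "gene")
  }
  nch <- sample(names(lens), n_ncrna, replace = TRUE)
  npos <- vapply(lens[nch], function(l) sample.int(l - 600L, 1L), 0)
  rows$ncrna <- data.frame(chrom = nch, start = npos, end = npos + 500,
                           label = "ncRNA")
  d <- do.call(rbind, rows)
  d <- d[order(d$chrom, d$start), ]
  rownames(d) <- NULL
  if (!is.null(path))
    writeLines(sprintf("%s\t%d\t%d\t%s", d$chrom, as.integer(d$start),
                       as.integer(d$end), d$label), path)
  d
}

#' Run the full capture-data simulation and write every output file
#'
#' Convenience wrapper producing `targets.bed`, `gene_model.bed`,
#' `reads.sam`, `calls.vcf`, `chip.tsv`, `known_sites.tsv` and truth
#' tables under `dir`, all deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with the in-memory objects of [simulate_reads()] and
#'   [simulate_genotypes_and_calls()], the `targets` set and all file
#'   paths.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bed <- file.path(dir, "targets.bed")
  targets <- generate_targets(config, bed_path = bed)
  gm_path <- file.path(dir, "gene_model.bed")
  gene_model <- generate_gene_model(config, targets, path = gm_path)
  sam <- file.path(dir, "reads.sam")
  sim_r <- simulate_reads(config, targets, sam_path = sam)
  sim_v <- simulate_genotypes_and_calls(config, targets, dir = dir)
  list(config = config, targets = targets, gene_model = gene_model,
       reads = sim_r, calls = sim_v,
       paths = list(bed = bed, gene_model = gm_path, sam = sam,
                    vcf = file.path(dir, "calls.vcf"),
                    chip = file.path(dir, "chip.tsv"),
                    known = file.path(dir, "known_sites.tsv")))
}
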