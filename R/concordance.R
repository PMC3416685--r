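#' Read SNP-array (chip) genotypes from a TSV file
#'
#' Expected columns: sample, chrom, pos (1-based), allele1, allele2. A
#' genotype of `N`/`N` (or `NN`) marks a missing call. Positions are
#' converted to 0-based coordinates.
#'
#' @param path TSV file (header optional; detected from the first line).
#' @return data.frame `sample`, `chrom`, `pos` (0-based), `a1`, `a2`,
#'   `missing`.
#' @export
read_chip_genotypes <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample", first, ignore.case = TRUE)
  d <- utils::read.table(path, sep = "\t", header = has_header,
                         stringsAsFactors = FALSE)
  names(d)[1:5] <- c("sample", "chrom", "pos", "a1", "a2")
  d$pos <- as.numeric(d$pos) - 1
  d$a1 <- toupper(d$a1); d$a2 <- toupper(d$a2)
  d$missing <- !(d$a1 %in% c("A", "C", "G", "T")) |
    !(d$a2 %in% c("A", "C", "G", "T"))
  d[, c("sample", "chrom", "pos", "a1", "a2", "missing")]
}

# Unordered genotype key "X/Y" with X <= Y.
geno_key <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

new_concordance_result <- function(n_overlap = 0L, n_consistent = 0L,
                                   n_het_chip = 0L, n_het_consistent = 0L,
                                   per_sample = NULL) {
  structure(
    list(
      n_overlap = n_overlap, n_consistent = n_consistent,
      overall_rate = if (n_overlap > 0) n_consistent / n_overlap else NA_real_,
      n_het_chip = n_het_chip, n_het_consistent = n_het_consistent,
      het_rate = if (n_het_chip > 0) n_het_consistent / n_het_chip else NA_real_,
      per_sample = per_sample
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  fmt <- function(r) if (is.na(r)) "undefined" else sprintf("%.3f", r)
  cat("Genotype concordance:\n")
  cat("  overall:", x$n_consistent, "/", x$n_overlap,
      "=", fmt(x$overall_rate), "\n")
  cat("  heterozygote:", x$n_het_consistent, "/", x$n_het_chip,
      "=", fmt(x$het_rate), "\n")
  invisible(x)
}

#' Overall genotype consistency between sequencing and chip calls
#'
#' Compares unordered genotypes at sample-by-position entries present on
#' both platforms (chip missing calls excluded). In `"homref"` mode, chip
#' entries with no sequencing call but pooled depth >= `min_depth` are
#' scored as implied reference-homozygous sequence genotypes; agreement is
#' then credited when the chip genotype is homozygous. `"strict"` mode
#' compares only genotypes emitted in the VCF.
#'
#' @param calls calls data.frame (columns `sample`, `chrom`, `pos`, `a1`,
#'   `a2`).
#' @param chip chip data.frame from [read_chip_genotypes()].
#' @param mode `"strict"` or `"homref"`.
#' @param depth for `"homref"` mode: data.frame `chrom`, `pos`, `depth` of
#'   pooled sequencing depth at chip positions.
#' @param min_depth minimum depth for an implied hom-ref call (default 5).
#' @param exclude optional data.frame (`sample`, `chrom`, `pos`) of entries
#'   that must not be compared — typically genotypes that were emitted in
#'   the VCF but removed by quality filtering, which are neither qualifying
#'   calls nor evidence of a reference-homozygous genotype.
#' @return a `concordance_result` (overall fields populated; per-sample
#'   rates in `$per_sample`).
#' @export
overall_consistency <- function(calls, chip, mode = c("strict", "homref"),
                                depth = NULL, min_depth = 5,
                                exclude = NULL) {
  mode <- match.arg(mode)
  chip <- chip[!chip$missing, , drop = FALSE]
  if (!is.null(exclude)) {
    ek <- paste(exclude$sample, exclude$chrom, exclude$pos)
    chip <- chip[!(paste(chip$sample, chip$chrom, chip$pos) %in% ek), ,
                 drop = FALSE]
  }
  ck <- paste(chip$sample, chip$chrom, chip$pos)
  sk <- paste(calls$sample, calls$chrom, calls$pos)
  m <- match(ck, sk)
  has_call <- !is.na(m)
  agree <- rep(NA, nrow(chip))
  agree[has_call] <- geno_key(chip$a1[has_call], chip$a2[has_call]) ==
    geno_key(calls$a1[m[has_call]], calls$a2[m[has_call]])
  used <- has_call
  if (mode == "homref" && !is.null(depth)) {
    dk <- paste(depth$chrom, depth$pos)
    dpos <- depth$depth[match(paste(chip$chrom, chip$pos), dk)]
    implied <- !has_call & !is.na(dpos) & dpos >= min_depth
    agree[implied] <- chip$a1[implied] == chip$a2[implied]
    used <- used | implied
  }
  per <- NULL
  if (any(used)) {
    per <- stats::aggregate(
      cbind(n = used, ok = used & agree %in% TRUE) ~ sample,
      data = data.frame(sample = chip$sample, used = used,
                        agree = agree %in% TRUE),
      FUN = sum
    )
    per$rate <- ifelse(per$n > 0, per$ok / per$n, NA_real_)
  }
  new_concordance_result(
    n_overlap = sum(used),
    n_consistent = sum(agree[used], na.rm = TRUE),
    per_sample = per
  )
}

#' Heterozygote genotype consistency between sequencing and chip calls
#'
#' Denominator: chip-heterozygous genotypes with a sequencing call of
#' genotype quality >= `min_gq` at the same sample and position.
#' Numerator: those where the sequencing genotype is the same unordered
#' heterozygote.
#'
#' @param calls calls data.frame (columns `sample`, `chrom`, `pos`, `a1`,
#'   `a2`, `gq`).
#' @param chip chip data.frame from [read_chip_genotypes()].
#' @param min_gq minimum sequencing genotype quality (default 20).
#' @return a `concordance_result` (het fields populated).
#' @export
het_consistency <- function(calls, chip, min_gq = 20) {
  chip <- chip[!chip$missing & chip$a1 != chip$a2, , drop = FALSE]
  sk <- paste(calls$sample, calls$chrom, calls$pos)
  m <- match(paste(chip$sample, chip$chrom, chip$pos), sk)
  qual <- !is.na(m) & !is.na(calls$gq[m]) & calls$gq[m] >= min_gq
  agree <- qual & geno_key(chip$a1, chip$a2) == geno_key(calls$a1[m], calls$a2[m])
  per <- NULL
  if (any(qual)) {
    per <- stats::aggregate(
      cbind(n = qual, ok = agree %in% TRUE) ~ sample,
      data = data.frame(sample = chip$sample, qual = qual,
                        agree = agree %in% TRUE),
      FUN = sum
    )
    per$rate <- ifelse(per$n > 0, per$ok / per$n, NA_real_)
  }
  new_concordance_result(
    n_het_chip = sum(qual),
    n_het_consistent = sum(agree, na.rm = TRUE),
    per_sample = per
  )
}

#' Concordance restricted to strand-imbalanced positions
#'
#' Identifies positions covered at depth >= `min_depth` whose covering
#' reads are all on the forward strand or all on the reverse strand and
#' that carry a chip genotype, then reports their counts and the overall
#' and heterozygote consistency rates restricted to those positions.
#'
#' @param reads MAPQ-filtered read data.frame.
#' @param calls calls data.frame.
#' @param chip chip data.frame from [read_chip_genotypes()].
#' @param min_depth minimum depth for a position to be considered
#'   (default 5).
#' @param min_gq minimum genotype quality for heterozygote consistency.
#' @param chrom_lengths optional named chromosome lengths.
#' @return list with `n_forward_only`, `n_reverse_only`, `positions`
#'   (data.frame chrom/pos/strand), `overall` and `het`
#'   (`concordance_result`s at those positions).
#' @export
strand_imbalance_consistency <- function(reads, calls, chip, min_depth = 5,
                                         min_gq = 20, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- infer_chrom_lengths(reads)
  fwd <- depth_vectors(reads[reads$strand == "+", , drop = FALSE], chrom_lengths)
  rev <- depth_vectors(reads[reads$strand == "-", , drop = FALSE], chrom_lengths)
  chip_ok <- chip[!chip$missing, , drop = FALSE]
  chip_pos <- unique(chip_ok[, c("chrom", "pos")])
  rows <- list()
  for (ch in names(chrom_lengths)) {
    p <- chip_pos$pos[chip_pos$chrom == ch]
    p <- p[p >= 0 & p < length(fwd[[ch]])]
    if (length(p) == 0L) next
    f <- fwd[[ch]][p + 1L]; r <- rev[[ch]][p + 1L]
    tot <- f + r
    one <- tot >= min_depth & (f == 0L | r == 0L)
    if (any(one))
      rows[[ch]] <- data.frame(chrom = ch, pos = p[one],
                               strand = ifelse(f[one] > 0, "+", "-"))
  }
  positions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = numeric(0), strand = character(0))
  rownames(positions) <- NULL
  pk <- paste(positions$chrom, positions$pos)
  chip_sub <- chip_ok[paste(chip_ok$chrom, chip_ok$pos) %in% pk, , drop = FALSE]
  calls_sub <- calls[paste(calls$chrom, calls$pos) %in% pk, , drop = FALSE]
  list(
    n_forward_only = sum(positions$strand == "+"),
    n_reverse_only = sum(positions$strand == "-"),
    positions = positions,
    overall = overall_consistency(calls_sub, chip_sub, mode = "strict"),
    het = het_consistency(calls_sub, chip_sub, min_gq = min_gq)
  )
}
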