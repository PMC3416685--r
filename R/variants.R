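#' Is a ref/alt substitution a transition?
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine (C<->T)
#' substitutions; the other eight ordered base pairs are transversions.
#'
#' @param ref,alt single reference/alternate bases (vectors allowed).
#' @return logical vector.
#' @export
is_transition <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T")))
    stop("alleles must be single bases A/C/G/T")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' Transition/transversion ratio of a call set
#'
#' Tallies each site-by-sample non-reference SNV genotype once; indels and
#' reference-homozygous genotypes are excluded. With zero transversions the
#' ratio is undefined and reported as `NA` (never infinity).
#'
#' @param calls a calls data.frame (see [read_vcf_calls()]); columns `ref`,
#'   `alt`, `is_indel` and `gt` are used when present.
#' @return object of class `titv_result`: list with `n_transitions`,
#'   `n_transversions`, `ratio`.
#' @export
titv_ratio <- function(calls) {
  keep <- rep(TRUE, nrow(calls))
  if ("is_indel" %in% names(calls)) keep <- keep & !calls$is_indel
  if ("gt" %in% names(calls)) keep <- keep & calls$gt %in% c("het", "hom")
  ref <- calls$ref[keep]; alt <- calls$alt[keep]
  ti <- if (length(ref)) sum(is_transition(ref, alt)) else 0L
  tv <- length(ref) - ti
  structure(
    list(n_transitions = as.integer(ti), n_transversions = as.integer(tv),
         ratio = if (tv > 0) ti / tv else NA_real_),
    class = "titv_result"
  )
}

#' @export
print.titv_result <- function(x, ...) {
  cat("Ti/Tv:", x$n_transitions, "transitions,", x$n_transversions,
      "transversions; ratio",
      if (is.na(x$ratio)) "undefined" else sprintf("%.2f", x$ratio), "\n")
  invisible(x)
}

#' Read per-sample variant calls from a VCF file
#'
#' Produces one row per site-by-sample genotyped entry. Multi-allelic
#' records are split into biallelic records; symbolic or non-SNV/indel
#' alleles are skipped with a warning. Positions are converted to 0-based
#' coordinates.
#'
#' @param path VCF 4.x file (GT required; GQ, DP, AD, site QUAL used when
#'   present).
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `sample`, `gt` ("ref", "het", "hom" for the alternate homozygote, or
#'   "miss"), `a1`, `a2` (genotype alleles), `gq`, `depth`,
#'   `allelic_balance` (reference-supporting fraction, `NA` when AD absent
#'   or genotype not heterozygous), `site_qual`, `is_indel`, plus `mq`/`bq`
#'   when the INFO field carries MQ/BQ.
#' @export
read_vcf_calls <- function(path) {
  empty <- data.frame(
    chrom = character(0), pos = numeric(0), ref = character(0),
    alt = character(0), sample = character(0), gt = character(0),
    a1 = character(0), a2 = character(0), gq = numeric(0),
    depth = numeric(0), allelic_balance = numeric(0),
    site_qual = numeric(0), is_indel = logical(0), mq = numeric(0),
    bq = numeric(0), stringsAsFactors = FALSE
  )
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) return(empty)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt_field <- fix[, "ALT"]
  n_alt <- lengths(strsplit(alt_field, ","))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gq_raw <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  dp_raw <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad_raw <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  info <- fix[, "INFO"]
  get_info_num <- function(key) {
    info2 <- ifelse(is.na(info), "", info)
    m <- regexpr(paste0("(^|;)", key, "=[-0-9.eE+]+"), info2)
    out <- rep(NA_real_, length(info))
    out[m > 0] <- as.numeric(sub(paste0(".*", key, "="), "",
                                 regmatches(info2, m)))
    out
  }
  mq <- get_info_num("MQ")
  bq <- get_info_num("BQ")
  samples <- colnames(gt_raw)
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(alt_field[i], ",")[[1]]
    symbolic <- grepl("[^ACGTNacgtn]", alts)  # <DEL>, breakends, '*'
    if (any(symbolic)) {
      warning("skipping symbolic allele(s) at ", fix[i, "CHROM"], ":",
              fix[i, "POS"], call. = FALSE)
    }
    for (ai in which(!symbolic)) {
      alt <- alts[ai]
      is_indel <- nchar(ref) != 1L || nchar(alt) != 1L
      gts <- gt_raw[i, ]
      a <- strsplit(gsub("\\|", "/", gts), "/")
      code <- vapply(a, function(x) {
        if (length(x) != 2L || any(x == ".")) return("miss")
        x <- as.integer(x)
        hit <- sum(x == ai)
        oth <- sum(x != 0 & x != ai)
        if (oth > 0) return("other")       # genotype uses a different alt
        if (hit == 2L) "hom" else if (hit == 1L) "het" else "ref"
      }, "")
      keep <- code != "other"
      ab <- rep(NA_real_, length(samples))
      if (!is.null(ad_raw)) {
        ad <- strsplit(ad_raw[i, ], ",")
        ab <- vapply(seq_along(ad), function(s) {
          x <- suppressWarnings(as.numeric(ad[[s]]))
          if (length(x) < ai + 1L || any(is.na(x[c(1L, ai + 1L)]))) return(NA_real_)
          tot <- x[1L] + x[ai + 1L]
          if (tot <= 0) NA_real_ else x[1L] / tot
        }, 0)
      }
      a1 <- ifelse(code %in% c("het"), ref, ifelse(code == "hom", alt, ref))
      a2 <- ifelse(code == "ref", ref, alt)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = unname(fix[i, "CHROM"]),
        pos = as.numeric(fix[i, "POS"]) - 1,
        ref = unname(ref), alt = unname(alt),
        sample = samples,
        gt = unname(code), a1 = unname(a1), a2 = unname(a2),
        gq = as.numeric(gq_raw[i, ]),
        depth = as.numeric(dp_raw[i, ]),
        allelic_balance = ab,
        site_qual = suppressWarnings(as.numeric(unname(fix[i, "QUAL"]))),
        is_indel = is_indel,
        mq = mq[i], bq = bq[i],
        stringsAsFactors = FALSE
      )[keep & code != "miss", , drop = FALSE]
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter genotype calls on genotype quality and depth
#'
#' @param calls calls data.frame.
#' @param min_gq minimum genotype quality (default 20).
#' @param min_depth minimum filtered depth (default 5).
#' @param regions optional [target_regions] for a per-class retention report.
#' @param near near-threshold D in bp.
#' @return list with `calls` (retained rows), `dropped` (removed rows) and
#'   `counts` (data.frame of before/after counts, per class when `regions`
#'   given).
#' @export
filter_snps <- function(calls, min_gq = 20, min_depth = 5,
                        regions = NULL, near = 200) {
  keep <- !is.na(calls$gq) & !is.na(calls$depth) &
    calls$gq >= min_gq & calls$depth >= min_depth
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- calls[!keep, , drop = FALSE]
  rownames(dropped) <- NULL
  counts <- data.frame(class = "all", before = nrow(calls), after = nrow(out))
  if (!is.null(regions)) {
    cls <- classify_position(regions, calls$chrom, calls$pos, near)
    tb <- table(cls); ta <- table(cls[keep])
    counts <- rbind(counts, data.frame(class = names(tb),
                                       before = as.integer(tb),
                                       after = as.integer(ta)))
  }
  list(calls = out, dropped = dropped, counts = counts)
}

#' Fraction of calls at known (dbSNP-like) positions
#'
#' @param calls calls data.frame (typically filtered, non-reference
#'   genotypes).
#' @param known data.frame of known sites with `chrom`, `pos` (0-based) and
#'   optionally `alt`.
#' @param match_alleles require the alternate allele to match as well as the
#'   position (default TRUE); with FALSE, position-only matching.
#' @param regions optional [target_regions] for a per-class breakdown.
#' @param near near-threshold D in bp.
#' @return percentage (0-100), or with `regions` a data.frame
#'   `class`, `n`, `n_known`, `pct_in_dbsnp`.
#' @export
dbsnp_overlap <- function(calls, known, match_alleles = TRUE,
                          regions = NULL, near = 200) {
  key <- if (match_alleles && "alt" %in% names(known))
    paste(calls$chrom, calls$pos, calls$alt) else paste(calls$chrom, calls$pos)
  kkey <- if (match_alleles && "alt" %in% names(known))
    paste(known$chrom, known$pos, known$alt) else paste(known$chrom, known$pos)
  hit <- key %in% kkey
  if (is.null(regions)) {
    if (nrow(calls) == 0L) return(0)
    return(100 * mean(hit))
  }
  cls <- classify_position(regions, calls$chrom, calls$pos, near)
  n <- as.integer(table(cls))
  nk <- as.integer(table(cls[hit]))
  data.frame(class = levels(cls), n = n, n_known = nk,
             pct_in_dbsnp = ifelse(n > 0, 100 * nk / n, NA_real_))
}

#' Depth histogram of filtered SNP genotypes
#'
#' Bins genotype depth at 5..19 plus a single ">=20" bin, the layout used
#' for off-target SNP depth tables.
#'
#' @param calls filtered calls data.frame (depth >= 5 expected).
#' @param regions optional [target_regions]; per-class columns when given.
#' @param near near-threshold D in bp.
#' @return named integer vector (bins "5".."19", "ge20"), or a matrix with
#'   one column per region class.
#' @export
snp_depth_histogram <- function(calls, regions = NULL, near = 200) {
  bins <- c(as.character(5:19), "ge20")
  hist1 <- function(d) {
    d <- d[!is.na(d)]
    b <- ifelse(d >= 20, "ge20", as.character(d))
    table(factor(b, levels = bins))
  }
  if (is.null(regions)) return(hist1(calls$depth))
  cls <- classify_position(regions, calls$chrom, calls$pos, near)
  m <- vapply(levels(cls), function(k) as.integer(hist1(calls$depth[cls == k])),
              integer(length(bins)))
  rownames(m) <- bins
  m
}

#' Per-class SNP summary: counts, Ti/Tv, dbSNP overlap, depth histogram
#'
#' @param calls filtered calls data.frame (non-reference genotypes are
#'   tallied; reference-homozygous rows are ignored).
#' @param regions a [target_regions] object.
#' @param near near-threshold D in bp.
#' @param known optional known-sites data.frame for dbSNP percentages.
#' @return list with `by_class` (data.frame: class, n_genotypes,
#'   n_per_sample_mean, titv, pct_in_dbsnp) and `depth_histogram` (matrix).
#' @export
summarize_snps_by_class <- function(calls, regions, near = 200, known = NULL) {
  snv <- calls[!calls$is_indel & calls$gt %in% c("het", "hom"), , drop = FALSE]
  cls <- classify_position(regions, snv$chrom, snv$pos, near)
  n_samples <- max(1L, length(unique(snv$sample)))
  rows <- lapply(levels(cls), function(k) {
    sub <- snv[cls == k, , drop = FALSE]
    tt <- titv_ratio(sub)
    data.frame(
      class = k,
      n_genotypes = nrow(sub),
      n_per_sample_mean = nrow(sub) / n_samples,
      titv = tt$ratio,
      pct_in_dbsnp = if (!is.null(known) && nrow(sub) > 0)
        dbsnp_overlap(sub, known) else NA_real_
    )
  })
  list(by_class = do.call(rbind, rows),
       depth_histogram = snp_depth_histogram(snv, regions, near))
}

#' Sweep filtering thresholds and track SNP count, Ti/Tv and concordance
#'
#' For each axis (e.g. genotype quality, depth, allelic balance, and site
#' MQ/BQ annotations when present) and each grid value, calls at or above
#' the threshold are retained and summarised. For the allelic-balance axis
#' the filter keeps calls with `min(ab, 1-ab) >= threshold` (heterozygotes
#' should sit near 0.5). Strata over dbSNP membership (all / in_dbsnp /
#' novel) and region (all / inside) are emitted when `known` / `regions`
#' are supplied.
#'
#' @param calls calls data.frame (unfiltered).
#' @param chip optional chip genotype data.frame (see
#'   [read_chip_genotypes()]); adds overall and heterozygote consistency.
#' @param axes named list of grids, e.g.
#'   `list(gq = seq(0, 50, 5), depth = 0:20)`. Axis names must be numeric
#'   columns of `calls` (`allelic_balance` gets the symmetric filter).
#' @param known optional known-sites data.frame.
#' @param regions optional [target_regions].
#' @param near near-threshold D in bp.
#' @return data.frame with columns `axis`, `threshold`, `dbsnp_stratum`,
#'   `region_stratum`, `n_snps`, `titv`, `overall_rate`, `het_rate`.
#' @export
threshold_sweep <- function(calls, chip = NULL,
                            axes = list(gq = seq(0, 50, by = 5),
                                        depth = seq(0, 20, by = 1)),
                            known = NULL, regions = NULL, near = 200) {
  stopifnot(all(vapply(axes, function(g) !is.unsorted(g), TRUE)))
  snv <- calls[!calls$is_indel, , drop = FALSE]
  in_dbsnp <- if (!is.null(known))
    paste(snv$chrom, snv$pos) %in% paste(known$chrom, known$pos) else NULL
  inside <- if (!is.null(regions))
    classify_position(regions, snv$chrom, snv$pos, near) == "inside" else NULL
  db_strata <- if (is.null(known)) "all" else c("all", "in_dbsnp", "novel")
  rg_strata <- if (is.null(regions)) "all" else c("all", "inside")
  out <- list()
  for (ax in names(axes)) {
    if (!ax %in% names(snv)) stop("unknown sweep axis: ", ax)
    x <- snv[[ax]]
    for (t in axes[[ax]]) {
      keep <- if (ax == "allelic_balance")
        !is.na(x) & pmin(x, 1 - x) >= t else !is.na(x) & x >= t
      for (ds in db_strata) for (rs in rg_strata) {
        m <- keep
        if (ds == "in_dbsnp") m <- m & in_dbsnp
        if (ds == "novel") m <- m & !in_dbsnp
        if (rs == "inside") m <- m & inside
        sub <- snv[m, , drop = FALSE]
        nonref <- sub[sub$gt %in% c("het", "hom"), , drop = FALSE]
        tt <- titv_ratio(nonref)
        ov <- ht <- NA_real_
        if (!is.null(chip) && nrow(sub) > 0) {
          ov <- overall_consistency(sub, chip, mode = "strict")$overall_rate
          ht <- het_consistency(sub, chip, min_gq = 0)$het_rate
        }
        out[[length(out) + 1L]] <- data.frame(
          axis = ax, threshold = t, dbsnp_stratum = ds, region_stratum = rs,
          n_snps = nrow(nonref), titv = tt$ratio,
          overall_rate = ov, het_rate = ht
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Read a labeled gene-model BED file
#'
#' Expects >=4 columns: chrom, start, end, label with labels `exon`,
#' `ncRNA` or `gene` (gene intervals contain their exons).
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end`, `label`.
#' @export
read_gene_model <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("gene model BED needs a 4th label column")
  names(d)[1:4] <- c("chrom", "start", "end", "label")
  bad <- setdiff(unique(d$label), c("exon", "ncRNA", "gene"))
  if (length(bad)) stop("unlabeled/unknown gene model interval type: ",
                        paste(bad, collapse = ", "))
  d[, 1:4]
}

#' Positional annotation of variant positions against a gene model
#'
#' Categories in precedence order: `exonic` (inside an exon), `splicing`
#' (within 2 bp of an exon boundary but not exonic), `ncRNA`, `intronic`
#' (inside a gene but none of the above), `intergenic`.
#'
#' @param chrom,pos vectors of chromosome and 0-based position.
#' @param gene_model data.frame from [read_gene_model()].
#' @param splice_bp distance from an exon boundary counted as splicing
#'   (default 2 bp).
#' @return factor with the five category levels.
#' @export
annotate_positional <- function(chrom, pos, gene_model, splice_bp = 2) {
  sets <- lapply(c("exon", "ncRNA", "gene"), function(lb) {
    d <- gene_model[gene_model$label == lb, , drop = FALSE]
    if (nrow(d) == 0L) NULL else target_regions(d$chrom, d$start, d$end)
  })
  names(sets) <- c("exon", "ncRNA", "gene")
  n <- length(pos)
  dist_exon <- if (is.null(sets$exon)) rep(Inf, n) else
    distance_to_nearest(sets$exon, chrom, pos)
  in_nc <- if (is.null(sets$ncRNA)) rep(FALSE, n) else
    distance_to_nearest(sets$ncRNA, chrom, pos) == 0
  in_gene <- if (is.null(sets$gene)) rep(FALSE, n) else
    distance_to_nearest(sets$gene, chrom, pos) == 0
  cat <- ifelse(dist_exon == 0, "exonic",
         ifelse(dist_exon <= splice_bp, "splicing",
         ifelse(in_nc, "ncRNA",
         ifelse(in_gene, "intronic", "intergenic"))))
  factor(cat, levels = c("exonic", "splicing", "ncRNA", "intronic", "intergenic"))
}

#' Count indel sites passing a site-quality threshold, by region class
#'
#' @param calls calls data.frame (indel rows identified by `is_indel`).
#' @param min_qual minimum site QUAL (default 1000, inclusive).
#' @param regions optional [target_regions].
#' @param near near-threshold D in bp.
#' @return named integer vector of distinct qualifying indel sites, per
#'   class (or a single total without `regions`).
#' @export
count_indels_by_qual <- function(calls, min_qual = 1000,
                                 regions = NULL, near = 200) {
  ind <- calls[calls$is_indel & !is.na(calls$site_qual) &
                 calls$site_qual >= min_qual, , drop = FALSE]
  sites <- unique(ind[, c("chrom", "pos")])
  if (is.null(regions)) return(c(all = nrow(sites)))
  cls <- classify_position(regions, sites$chrom, sites$pos, near)
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}
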