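#' Rescale Phred quality strings between ASCII offsets
#'
#' Older Illumina pipelines encoded base qualities as Phred+64; the Sanger
#' convention is Phred+33. This shifts every character by the offset
#' difference, leaving the underlying Phred values unchanged.
#'
#' @param quals character vector of quality strings.
#' @param from_offset current ASCII offset (64 for old Illumina).
#' @param to_offset desired ASCII offset (33 for Sanger).
#' @return character vector of rescaled quality strings.
#' @examples
#' phred_rescale("h", 64, 33)  # "I" (Q40)
#' @export
phred_rescale <- function(quals, from_offset = 64, to_offset = 33) {
  shift <- from_offset - to_offset
  vapply(quals, function(q) {
    codes <- utf8ToInt(q)
    if (any(codes < from_offset))
      stop("quality character below offset ", from_offset,
           ": wrong input encoding?")
    intToUtf8(codes - shift)
  }, "", USE.NAMES = FALSE)
}

# Parse CIGAR strings into per-read op/length tables.
parse_cigar <- function(cigar) {
  lens <- gregexpr("[0-9]+", cigar)
  ops <- gregexpr("[A-Z=]", cigar)
  lapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (is.na(cg) || cg == "*" || !grepl("^([0-9]+[MIDNSHP=X])+$", cg))
      stop("invalid CIGAR string: ", cg)
    l <- as.integer(regmatches(cg, lens[i])[[1]])
    o <- regmatches(cg, ops[i])[[1]]
    list(op = o, len = l)
  })
}

# Reference-consuming length of each CIGAR (M, D, N, =, X ops).
cigar_reference_length <- function(cigar) {
  simple <- grepl("^[0-9]+M$", cigar)
  out <- numeric(length(cigar))
  out[simple] <- as.numeric(sub("M$", "", cigar[simple]))
  if (any(!simple)) {
    cg <- cigar[!simple]
    bad <- is.na(cg) | cg == "*" | !grepl("^([0-9]+[MIDNSHP=X])+$", cg)
    if (any(bad)) stop("invalid CIGAR string: ", cg[which(bad)[1L]])
    toks <- regmatches(cg, gregexpr("[0-9]+[A-Z=]", cg))
    flat <- unlist(toks)
    len <- as.numeric(substr(flat, 1L, nchar(flat) - 1L))
    op <- substr(flat, nchar(flat), nchar(flat))
    grp <- rep(seq_along(toks), lengths(toks))
    ref <- rowsum(len * (op %in% c("M", "D", "N", "=", "X")), grp)
    out[!simple] <- ref[, 1]
  }
  out
}

#' Reference span of aligned reads after applying soft clips
#'
#' The effective span of a read is the reference interval it aligns to:
#' `[pos, pos + L)` where `L` sums the reference-consuming CIGAR operations
#' (M, D, N, =, X). Soft/hard clips and insertions consume no reference.
#'
#' @param pos 0-based leftmost mapped coordinate(s), or a data frame from
#'   [read_alignments()] (columns `pos`, `cigar`).
#' @param cigar CIGAR string(s), ignored when `pos` is a data frame.
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `width`.
#' @examples
#' effective_read_span(99, "5S60M7S")  # [99, 159), width 60
#' @export
effective_read_span <- function(pos, cigar = NULL) {
  if (is.data.frame(pos)) {
    cigar <- pos$cigar
    pos <- pos$pos
  }
  w <- cigar_reference_length(cigar)
  if (any(w == 0))
    stop("zero-length reference span (CIGAR with no reference-consuming ops)")
  data.frame(start = pos, end = pos + w, width = w)
}

#' Read aligned reads from a SAM or BAM file
#'
#' Plain-text SAM input is converted on the fly with Rsamtools. Unmapped
#' records are dropped. Positions are converted to 0-based coordinates.
#'
#' @param path SAM or BAM file.
#' @param keep_unmapped keep unmapped records (default FALSE).
#' @return data.frame with columns `qname`, `flag`, `chrom`, `pos` (0-based),
#'   `mapq`, `strand` ("+"/"-"), `cigar`, `seq`, `qual`, `isize`,
#'   `is_duplicate`.
#' @export
read_alignments <- function(path, keep_unmapped = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
               "isize", "seq", "qual")
    )
  )[[1]]
  df <- data.frame(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos - 1L,
    mapq = res$mapq,
    strand = as.character(res$strand),
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    isize = res$isize,
    is_duplicate = Rsamtools::bamFlagTest(res$flag, "isDuplicate"),
    stringsAsFactors = FALSE
  )
  if (!keep_unmapped) {
    mapped <- !Rsamtools::bamFlagTest(res$flag, "isUnmappedQuery") & !is.na(res$pos)
    df <- df[mapped, , drop = FALSE]
    rownames(df) <- NULL
  }
  df$isize[is.na(df$isize)] <- 0L
  df
}

#' Classify reads by the majority-of-bases rule
#'
#' A read is `inside` if at least half of the bases of its effective
#' (soft-clip-adjusted) reference span fall inside a target region; failing
#' that it is `near` if at least half of its span bases lie within `near` bp
#' of the nearest target (distance-0 bases count towards this too); else
#' `far`.
#'
#' @param reads data.frame with `chrom`, `pos` (0-based) and `cigar` columns.
#' @param regions a [target_regions] object.
#' @param near near-threshold D in bp.
#' @return factor with levels `inside`, `near`, `far`.
#' @export
classify_read <- function(reads, regions, near = 200) {
  span <- effective_read_span(reads)
  expanded <- expand_regions(regions, near)
  n_in <- covered_bases(regions, reads$chrom, span$start, span$end)
  n_within <- covered_bases(expanded, reads$chrom, span$start, span$end)
  half <- span$width / 2
  factor(ifelse(n_in >= half, "inside",
                ifelse(n_within >= half, "near", "far")),
         levels = c("inside", "near", "far"))
}

#' Filter reads on mapping quality and duplicate flag
#'
#' @param reads data.frame from [read_alignments()].
#' @param min_mapq minimum MAPQ retained (default 20).
#' @param drop_duplicates drop duplicate-flagged reads (default TRUE).
#' @param regions optional [target_regions]; when given, before/after counts
#'   are broken down by read class.
#' @param near near-threshold used for the per-class breakdown.
#' @return list with `reads` (the retained rows) and `counts`, a data.frame
#'   with columns `class`, `before`, `after` (class "all" plus the three
#'   region classes when `regions` is supplied).
#' @export
filter_reads <- function(reads, min_mapq = 20, drop_duplicates = TRUE,
                         regions = NULL, near = 200) {
  keep <- reads$mapq >= min_mapq
  if (drop_duplicates) keep <- keep & !reads$is_duplicate
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  counts <- data.frame(class = "all", before = nrow(reads), after = nrow(out))
  if (!is.null(regions)) {
    cls <- classify_read(reads, regions, near)
    tab_b <- table(cls)
    tab_a <- table(cls[keep])
    counts <- rbind(counts, data.frame(
      class = names(tab_b),
      before = as.integer(tab_b),
      after = as.integer(tab_a)
    ))
  }
  list(reads = out, counts = counts)
}

# Chromosome lengths implied by reads and regions (used when the caller
# does not supply them).
infer_chrom_lengths <- function(reads, regions = NULL) {
  span <- effective_read_span(reads)
  lens <- tapply(span$end, reads$chrom, max)
  lens <- stats::setNames(as.numeric(lens), names(lens))
  if (!is.null(regions)) {
    for (ch in names(regions$chroms)) {
      m <- max(regions$chroms[[ch]][, 2])
      lens[ch] <- max(lens[ch], m, na.rm = TRUE)
    }
  }
  lens
}

# Per-chromosome pileup depth vectors (element p+1 = depth at 0-based p),
# counting each read over its full effective reference span.
depth_vectors <- function(reads, chrom_lengths) {
  span <- effective_read_span(reads)
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[ch]])
    sel <- reads$chrom == ch
    ev <- numeric(len + 1L)
    if (any(sel)) {
      s <- pmin(span$start[sel], len) + 1L
      e <- pmin(span$end[sel], len) + 1L
      ev_s <- tabulate(s, nbins = len + 1L)
      ev_e <- tabulate(e, nbins = len + 1L)
      ev <- ev_s - ev_e
    }
    out[[ch]] <- cumsum(ev)[seq_len(len)]
  }
  out
}

#' Mean depth around target-region boundaries
#'
#' For every boundary of every (merged) target interval, per-base depth is
#' tallied at signed offsets from the boundary: negative offsets are inside
#' the target (up to `inside` bp), positive offsets outside (up to `outside`
#' bp). Offsets falling beyond chromosome ends count as depth 0; the mean is
#' taken over all boundaries.
#'
#' @param reads filtered read data.frame.
#' @param regions a [target_regions] object.
#' @param inside,outside extent of the profile in bp (defaults 50 and 200).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data.frame with columns `distance` (-inside..-1, 1..outside) and
#'   `mean_depth`.
#' @export
boundary_depth_profile <- function(reads, regions, inside = 50, outside = 200,
                                   chrom_lengths = NULL,
                                   boundaries = c("all", "isolated"),
                                   isolation_margin = 500) {
  bp <- boundary_profile_matrix(reads, regions, inside, outside,
                                chrom_lengths, match.arg(boundaries),
                                isolation_margin)
  data.frame(distance = bp$offsets,
             mean_depth = if (nrow(bp$mat) > 0) colMeans(bp$mat)
             else numeric(length(bp$offsets)))
}

# Per-boundary depth matrix underlying boundary_depth_profile(): one row
# per target boundary, one column per signed offset. boundaries =
# "isolated" keeps only boundaries with no other target interval within
# (outside + isolation_margin) bp on the outside side, which removes
# contamination of the decay tail by neighbouring targets.
boundary_profile_matrix <- function(reads, regions, inside = 50,
                                    outside = 200, chrom_lengths = NULL,
                                    boundaries = "all",
                                    isolation_margin = 500) {
  if (is.null(chrom_lengths)) chrom_lengths <- infer_chrom_lengths(reads, regions)
  depth <- depth_vectors(reads, chrom_lengths)
  offsets <- c(-(inside:1), 1:outside)
  # left boundary at start s: offset -k -> s + k - 1, +k -> s - k
  f_left <- ifelse(offsets < 0, -offsets - 1, -offsets)
  # right boundary at end e: offset -k -> e - k, +k -> e - 1 + k
  f_right <- ifelse(offsets < 0, offsets, offsets - 1)
  mats <- list()
  for (ch in names(regions$chroms)) {
    m <- regions$chroms[[ch]]
    d <- depth[[ch]]
    if (is.null(d)) d <- numeric(0)
    len <- length(d)
    s <- m[, 1]; e <- m[, 2]
    keep_l <- rep(TRUE, length(s)); keep_r <- keep_l
    if (boundaries == "isolated") {
      win <- outside + isolation_margin
      keep_l <- covered_bases(regions, ch, pmax(0, s - win), s) == 0
      keep_r <- covered_bases(regions, ch, e, e + win) == 0
    }
    P <- rbind(outer(s[keep_l], f_left, "+"), outer(e[keep_r], f_right, "+"))
    V <- matrix(0, nrow(P), ncol(P))
    ok <- P >= 0 & P < len
    V[ok] <- d[P[ok] + 1L]
    mats[[ch]] <- V
  }
  list(offsets = offsets, mat = do.call(rbind, mats))
}

# Integer base codes: A=1, C=2, G=3, T=4, others NA.
base_code_table <- function() {
  tab <- rep(NA_integer_, 128L)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("a")] <- 1L
  tab[utf8ToInt("C")] <- 2L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("g")] <- 3L
  tab[utf8ToInt("T")] <- 4L; tab[utf8ToInt("t")] <- 4L
  tab
}

# Aligned (0-based reference position, base code) pairs for one read with an
# arbitrary CIGAR. Returns a list(refpos, code).
aligned_base_pairs_one <- function(pos, cigar, seq, code_tab) {
  p <- parse_cigar(cigar)[[1]]
  refpos <- integer(0)
  qidx <- integer(0)
  r <- pos; q <- 1L
  for (j in seq_along(p$op)) {
    op <- p$op[j]; l <- p$len[j]
    if (op %in% c("M", "=", "X")) {
      refpos <- c(refpos, r:(r + l - 1L))
      qidx <- c(qidx, q:(q + l - 1L))
      r <- r + l; q <- q + l
    } else if (op %in% c("I", "S")) {
      q <- q + l
    } else if (op %in% c("D", "N")) {
      r <- r + l
    }
  }
  codes <- code_tab[utf8ToInt(seq)][qidx]
  list(refpos = refpos, code = codes)
}

# Per-chromosome majority base code at every covered position.
# Returns list of integer vectors (NA where uncovered / no bases).
majority_base_vectors <- function(reads, chrom_lengths, chunk = 100000L) {
  code_tab <- base_code_table()
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[ch]])
    sel <- which(reads$chrom == ch)
    counts <- integer(4L * len)
    simple <- grepl("^[0-9]+M$", reads$cigar[sel])
    # fast path: ungapped reads, fully vectorised in chunks
    si <- sel[simple]
    chunk_starts <- if (length(si)) seq(1L, length(si), by = chunk) else integer(0)
    for (start_i in chunk_starts) {
      idx <- si[start_i:min(start_i + chunk - 1L, length(si))]
      w <- nchar(reads$seq[idx])
      refpos <- rep(reads$pos[idx], times = w) + (sequence(w) - 1L)
      codes <- code_tab[utf8ToInt(paste(reads$seq[idx], collapse = ""))]
      ok <- !is.na(codes) & refpos >= 0L & refpos < len
      enc <- refpos[ok] * 4L + codes[ok]
      counts <- counts + tabulate(enc, nbins = 4L * len)
    }
    gapped <- sel[!simple]
    if (length(gapped)) {
      pairs <- lapply(gapped, function(i)
        aligned_base_pairs_one(reads$pos[i], reads$cigar[i],
                               reads$seq[i], code_tab))
      refpos <- unlist(lapply(pairs, `[[`, "refpos"))
      codes <- unlist(lapply(pairs, `[[`, "code"))
      ok <- !is.na(codes) & refpos >= 0L & refpos < len
      counts <- counts + tabulate(refpos[ok] * 4L + codes[ok],
                                  nbins = 4L * len)
    }
    cm <- matrix(counts, nrow = 4L)
    maj <- max.col(t(cm), ties.method = "first")
    maj[colSums(cm) == 0L] <- NA_integer_
    out[[ch]] <- maj
  }
  out
}

#' Coverage, GC and quality summaries by region class
#'
#' Summarises a filtered read set per region class (`inside`, `near`,
#' `far`): read counts and fractions, breadth of coverage at depth >= 1 and
#' >= 5, counts of sites covered at minimum depths 5..10, GC content of
#' covered positions (majority read base per position; for the `far` class
#' additionally stratified at depth >= 10/20/30), and MAPQ / base-quality
#' histograms.
#'
#' @param reads filtered read data.frame (see [filter_reads()]).
#' @param regions a [target_regions] object.
#' @param near near-threshold D in bp.
#' @param chrom_lengths optional named vector of chromosome lengths; inferred
#'   from the data when absent.
#' @param gc whether to compute per-position GC summaries (the costly part).
#' @return list with components `read_counts` (data.frame class/n/fraction),
#'   `breadth` (class, breadth_ge1, breadth_ge5, n_positions),
#'   `min_depth_sites` (class x minimum depth 5..10 counts), `gc`
#'   (data.frame class, stratum, gc_percent, n_positions), `mapq_hist` and
#'   `bq_hist` (per-class histograms).
#' @export
class_coverage_summary <- function(reads, regions, near = 200,
                                   chrom_lengths = NULL, gc = TRUE) {
  if (is.null(chrom_lengths)) chrom_lengths <- infer_chrom_lengths(reads, regions)
  depth <- depth_vectors(reads, chrom_lengths)
  rcls <- classify_read(reads, regions, near)
  read_counts <- as.data.frame(table(class = rcls), responseName = "n")
  read_counts$fraction <- read_counts$n / max(1L, nrow(reads))

  # per-position class, depth, and (optionally) majority base, per chromosome
  maj <- if (gc) majority_base_vectors(reads, chrom_lengths) else NULL
  cls_levels <- c("inside", "near", "far")
  breadth <- data.frame(class = cls_levels, breadth_ge1 = NA_real_,
                        breadth_ge5 = NA_real_, n_positions = 0)
  mds <- matrix(0, nrow = 3, ncol = 6,
                dimnames = list(cls_levels, paste0("ge", 5:10)))
  gc_rows <- list()
  npos <- c(inside = 0, near = 0, far = 0)
  cov1 <- c(inside = 0, near = 0, far = 0)
  cov5 <- c(inside = 0, near = 0, far = 0)
  gc_acc <- list()  # stratum name -> c(gc_positions, covered_positions) per class
  strata <- list(inside = "ge1", near = "ge1", far = c("ge10", "ge20", "ge30"))
  for (ch in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[ch]])
    pcls <- classify_position(regions, ch, 0:(len - 1L), near)
    d <- depth[[ch]]
    for (k in cls_levels) {
      m <- pcls == k
      npos[k] <- npos[k] + sum(m)
      cov1[k] <- cov1[k] + sum(d[m] >= 1)
      cov5[k] <- cov5[k] + sum(d[m] >= 5)
      for (j in 5:10) mds[k, j - 4L] <- mds[k, j - 4L] + sum(d[m] >= j)
      if (gc) {
        for (st in strata[[k]]) {
          min_d <- as.integer(sub("ge", "", st))
          mm <- m & d >= min_d & !is.na(maj[[ch]])
          key <- paste(k, st)
          prev <- gc_acc[[key]]
          if (is.null(prev)) prev <- c(0, 0)
          gc_acc[[key]] <- prev + c(sum(maj[[ch]][mm] %in% c(2L, 3L)), sum(mm))
        }
      }
    }
  }
  breadth$breadth_ge1 <- as.numeric(cov1 / pmax(1, npos))
  breadth$breadth_ge5 <- as.numeric(cov5 / pmax(1, npos))
  breadth$n_positions <- as.numeric(npos)
  if (gc) {
    for (key in names(gc_acc)) {
      parts <- strsplit(key, " ")[[1]]
      v <- gc_acc[[key]]
      gc_rows[[key]] <- data.frame(
        class = parts[1], stratum = parts[2],
        gc_percent = if (v[2] > 0) 100 * v[1] / v[2] else NA_real_,
        n_positions = v[2]
      )
    }
  }
  mapq_hist <- lapply(stats::setNames(cls_levels, cls_levels), function(k)
    table(factor(reads$mapq[rcls == k], levels = 0:60)))
  bq_hist <- lapply(stats::setNames(cls_levels, cls_levels), function(k) {
    quals <- reads$qual[rcls == k]
    if (length(quals) == 0L) return(table(factor(integer(0), levels = 0:45)))
    q <- utf8ToInt(paste(quals, collapse = "")) - 33L
    q <- q[q >= 0]
    table(factor(pmin(q, 45L), levels = 0:45))
  })
  list(
    read_counts = read_counts,
    breadth = breadth,
    min_depth_sites = as.data.frame.matrix(mds),
    gc = if (gc) do.call(rbind, c(gc_rows, list(make.row.names = FALSE))) else NULL,
    mapq_hist = mapq_hist,
    bq_hist = bq_hist
  )
}

#' Fraction of aligned reads with insert size within a limit
#'
#' @param reads read data.frame (column `isize`; 0 means unpaired/unknown).
#' @param limit maximum absolute insert size counted (default 500 bp).
#' @return fraction of reads with `0 < |isize| <= limit` among reads with a
#'   recorded insert size.
#' @export
insert_size_fraction <- function(reads, limit = 500) {
  is <- abs(reads$isize)
  paired <- is > 0
  if (!any(paired)) return(NA_real_)
  mean(is[paired] <= limit)
}

#' Detect abnormally high-depth regions far from targets
#'
#' Finds maximal runs of `far`-class positions whose pileup depth is at
#' least `min_depth`, keeping runs of at least `min_length` bp. Such regions
#' typically reflect homology between off-target sequence and capture baits.
#'
#' @param reads filtered read data.frame.
#' @param regions a [target_regions] object.
#' @param near near-threshold D in bp.
#' @param min_depth minimum depth of a reported run.
#' @param min_length minimum run length in bp.
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `mean_depth`, ordered by chromosome and start.
#' @export
find_high_depth_far_regions <- function(reads, regions, near = 200,
                                        min_depth = 100, min_length = 100,
                                        chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- infer_chrom_lengths(reads, regions)
  depth <- depth_vectors(reads, chrom_lengths)
  rows <- list()
  for (ch in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[ch]])
    pcls <- classify_position(regions, ch, 0:(len - 1L), near)
    hit <- (pcls == "far") & (depth[[ch]] >= min_depth)
    r <- rle(as.vector(hit))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_length
    for (i in which(keep)) {
      s0 <- starts[i] - 1L; e0 <- ends[i]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s0, end = e0,
        mean_depth = mean(depth[[ch]][starts[i]:ends[i]])
      )
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_depth = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}
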