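#' Capture target region sets
#'
#' A `target_regions` object holds the capture intervals of an exome or
#' targeted-sequencing kit as merged, sorted, per-chromosome interval tables
#' in 0-based half-open coordinates. Overlapping or book-ended input
#' intervals are merged on construction, so the stored set is always
#' pairwise disjoint and sorted by start within each chromosome.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector of 0-based inclusive start coordinates.
#' @param end integer vector of 0-based exclusive end coordinates.
#' @param label optional character vector of interval labels (kept only for
#'   unmerged bookkeeping; merged intervals drop labels).
#'
#' @return An object of class `target_regions`: a list with elements
#'   `chroms` (named list of two-column integer matrices `start`,`end`),
#'   `region_count` and `total_bases` (both computed after merging).
#' @examples
#' tr <- target_regions(c("chr1", "chr1"), c(100L, 150L), c(200L, 300L))
#' tr$region_count  # 1 after merging
#' tr$total_bases   # 200
#' @export
target_regions <- function(chrom, start, end, label = NULL) {
  if (length(chrom) == 1L) chrom <- rep_len(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric interval coordinates")
  if (any(start < 0)) stop("interval start < 0")
  if (any(start >= end)) stop("interval start >= end")
  chroms <- list()
  for (ch in unique(as.character(chrom))) {
    i <- which(chrom == ch)
    m <- merge_intervals(start[i], end[i])
    chroms[[ch]] <- m
  }
  structure(
    list(
      chroms = chroms,
      region_count = sum(vapply(chroms, nrow, 0L)),
      total_bases = sum(vapply(chroms, function(m) sum(m[, 2] - m[, 1]), 0))
    ),
    class = "target_regions"
  )
}

# Merge possibly overlapping/adjacent intervals into a disjoint sorted set.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L) {
    hi <- cummax(end)
    # a new merged block begins where the start exceeds the running max end
    new_block <- c(TRUE, start[-1L] > hi[-length(hi)])
    grp <- cumsum(new_block)
    start <- start[new_block]
    end <- as.numeric(tapply(end, grp, max))
  }
  cbind(start = start, end = end)
}

#' Read capture target regions from a BED file
#'
#' Reads a >=3-column BED file (tab- or space-separated, 0-based half-open)
#' and returns the merged [target_regions] set. Lines starting with
#' `track`, `browser` or `#` are skipped.
#'
#' @param path path to a BED file.
#' @return A [target_regions] object.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("BED file has no interval lines: ", path)
  fields <- strsplit(lines[idx], "[ \t]+")
  n <- vapply(fields, length, 0L)
  if (any(n < 3L))
    stop("malformed BED line ", idx[which(n < 3L)[1L]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop("malformed BED line ", idx[bad[1L]], ": non-integer coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1L]], ": start >= end (or negative)")
  target_regions(chrom, start, end)
}

#' Distance from positions to the nearest target region
#'
#' Distance is measured in gap bases: a position inside an interval has
#' distance 0 and the first base outside an interval has distance 1 (so
#' "within 200 bp" means distance <= 200). Positions on chromosomes with no
#' target intervals get `Inf`.
#'
#' @param regions a [target_regions] object.
#' @param chrom chromosome name(s); length 1 or `length(pos)`.
#' @param pos 0-based position(s).
#' @return numeric vector of distances (0 for inside; `Inf` off-chromosome).
#' @examples
#' tr <- target_regions("chr1", 1000L, 1228L)
#' distance_to_nearest(tr, "chr1", c(1227, 1427, 1428))  # 0 200 201
#' @export
distance_to_nearest <- function(regions, chrom, pos) {
  stopifnot(inherits(regions, "target_regions"))
  pos <- as.numeric(pos)
  if (any(pos < 0, na.rm = TRUE)) stop("pos must be >= 0")
  chrom <- as.character(chrom)
  if (length(chrom) == 1L) {        # fast path: one chromosome
    m <- regions$chroms[[chrom]]
    if (is.null(m)) return(rep(Inf, length(pos)))
    return(nearest_gap_distance(m, pos))
  }
  chrom <- rep_len(chrom, length(pos))
  out <- rep(Inf, length(pos))
  for (ch in unique(chrom)) {
    m <- regions$chroms[[ch]]
    if (is.null(m)) next
    sel <- which(chrom == ch)
    out[sel] <- nearest_gap_distance(m, pos[sel])
  }
  out
}

# Gap distance of positions p to a sorted disjoint interval matrix.
nearest_gap_distance <- function(m, p) {
  s <- unname(m[, 1]); e <- unname(m[, 2])
  i <- findInterval(p, s)            # last interval with start <= p
  ip <- pmax(i, 1L)
  dl <- p - (e[ip] - 1)              # gap to the interval on the left
  dl[i < 1L] <- Inf
  dr <- rep(Inf, length(p))
  r_ok <- i < length(s)
  dr[r_ok] <- s[i[r_ok] + 1L] - p[r_ok]
  d <- pmin(dl, dr)
  d[i >= 1L & p < e[ip]] <- 0        # inside
  d
}

#' Classify positions by distance to the nearest target region
#'
#' Positions are classified `inside` (distance 0), `near` (distance between
#' 1 and `near` bp inclusive) or `far` (further than `near` bp, including
#' chromosomes with no targets at all).
#'
#' @inheritParams distance_to_nearest
#' @param near near-threshold D in bp (default 200).
#' @return factor with levels `inside`, `near`, `far`.
#' @export
classify_position <- function(regions, chrom, pos, near = 200) {
  stopifnot(near > 0)
  d <- distance_to_nearest(regions, chrom, pos)
  class_from_distance(d, near)
}

class_from_distance <- function(d, near) {
  code <- 1L + as.integer(d > 0) + as.integer(d > near)
  structure(code, levels = c("inside", "near", "far"), class = "factor")
}

#' Summarise a target region set
#'
#' @param regions a [target_regions] object (non-empty).
#' @return list with `region_count`, `total_bases` and `mean_length`
#'   (total bases / region count, rounded to the nearest bp).
#' @examples
#' # SureSelect v1-style geometry: 165,637 regions spanning 37.8 Mb
#' r <- summarize_regions(target_regions("chr1", 0L, 100L))
#' @export
summarize_regions <- function(regions) {
  stopifnot(inherits(regions, "target_regions"))
  if (regions$region_count < 1L) stop("empty target region set")
  list(
    region_count = regions$region_count,
    total_bases = regions$total_bases,
    mean_length = round(regions$total_bases / regions$region_count)
  )
}

#' @export
print.target_regions <- function(x, ...) {
  s <- summarize_regions(x)
  cat("Target region set:", s$region_count, "merged intervals on",
      length(x$chroms), "chromosome(s)\n")
  cat("  total bases:", format(s$total_bases, big.mark = ","),
      " mean length:", s$mean_length, "bp\n")
  invisible(x)
}

#' @export
summary.target_regions <- function(object, ...) {
  s <- summarize_regions(object)
  structure(s, class = "summary.target_regions")
}

#' @export
print.summary.target_regions <- function(x, ...) {
  cat("regions:", x$region_count, " bases:", x$total_bases,
      " mean length:", x$mean_length, "bp\n")
  invisible(x)
}

# Expand every interval by `flank` bp on both sides and re-merge.
expand_regions <- function(regions, flank) {
  ch <- names(regions$chroms)
  if (length(ch) == 0L) return(regions)
  parts <- lapply(ch, function(c0) {
    m <- regions$chroms[[c0]]
    data.frame(chrom = c0, start = pmax(0, m[, 1] - flank), end = m[, 2] + flank)
  })
  d <- do.call(rbind, parts)
  target_regions(d$chrom, d$start, d$end)
}

# Number of bases of [start, end) covered by the merged interval set on
# `chrom`. Vectorised over parallel start/end vectors via prefix sums.
covered_bases <- function(regions, chrom, start, end) {
  chrom <- rep_len(as.character(chrom), length(start))
  out <- numeric(length(start))
  for (ch in unique(chrom)) {
    m <- regions$chroms[[ch]]
    sel <- which(chrom == ch)
    if (is.null(m)) next
    s <- m[, 1]; e <- m[, 2]
    pre <- c(0, cumsum(e - s))        # covered bases before interval i+1
    a <- start[sel]; b <- end[sel]
    # coverage of [0, x): full intervals before index k plus partial overlap
    cov_to <- function(x) {
      k <- findInterval(x, s)
      partial <- ifelse(k >= 1L, pmax(0, pmin(x, e[pmax(k, 1L)]) - s[pmax(k, 1L)]), 0)
      pre[k + 1L] - (e[pmax(k, 1L)] - s[pmax(k, 1L)]) * (k >= 1L) + partial
    }
    out[sel] <- cov_to(b) - cov_to(a)
  }
  out
}
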