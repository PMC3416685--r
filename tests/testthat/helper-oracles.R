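# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops over raw interval tables.

# Gap distance of a position to the nearest interval, scanning every
# interval. `ivs` is a data.frame chrom/start/end (0-based half-open).
oracle_distance <- function(ivs, chrom, pos) {
  best <- Inf
  for (i in seq_len(nrow(ivs))) {
    if (ivs$chrom[i] != chrom) next
    s <- ivs$start[i]; e <- ivs$end[i]
    d <- if (pos >= s && pos < e) 0
    else if (pos < s) s - pos
    else pos - (e - 1)
    if (d < best) best <- d
  }
  best
}

oracle_class <- function(ivs, chrom, pos, near) {
  d <- oracle_distance(ivs, chrom, pos)
  if (d == 0) "inside" else if (d <= near) "near" else "far"
}

# Reference span length by walking CIGAR tokens one at a time.
oracle_cigar_ref_len <- function(cigar) {
  total <- 0
  rest <- cigar
  while (nchar(rest) > 0) {
    m <- regmatches(rest, regexpr("^[0-9]+[MIDNSHP=X]", rest))
    if (length(m) == 0) stop("bad cigar")
    n <- as.integer(substr(m, 1, nchar(m) - 1))
    op <- substr(m, nchar(m), nchar(m))
    if (op %in% c("M", "D", "N", "=", "X")) total <- total + n
    rest <- substr(rest, nchar(m) + 1, nchar(rest))
  }
  total
}

# Majority-of-bases read class: classify every base of the reference span
# individually, then apply the >= half rules.
oracle_read_class <- function(ivs, chrom, start, ref_len, near) {
  n_in <- 0; n_within <- 0
  for (p in start:(start + ref_len - 1)) {
    d <- oracle_distance(ivs, chrom, p)
    if (d == 0) n_in <- n_in + 1
    if (d <= near) n_within <- n_within + 1
  }
  if (n_in >= ref_len / 2) "inside"
  else if (n_within >= ref_len / 2) "near"
  else "far"
}

# Heterozygote consistency by explicit nested-loop join.
oracle_het_consistency <- function(seq_df, chip_df, min_gq = 20) {
  den <- 0; num <- 0
  for (i in seq_len(nrow(chip_df))) {
    if (chip_df$missing[i] || chip_df$a1[i] == chip_df$a2[i]) next
    hit <- NULL
    for (j in seq_len(nrow(seq_df))) {
      if (seq_df$sample[j] == chip_df$sample[i] &&
          seq_df$chrom[j] == chip_df$chrom[i] &&
          seq_df$pos[j] == chip_df$pos[i]) { hit <- j; break }
    }
    if (is.null(hit) || is.na(seq_df$gq[hit]) || seq_df$gq[hit] < min_gq) next
    den <- den + 1
    # identical unordered genotype (alleles may repeat, compare sorted)
    same <- paste(sort(c(chip_df$a1[i], chip_df$a2[i])), collapse = "/") ==
      paste(sort(c(seq_df$a1[hit], seq_df$a2[hit])), collapse = "/")
    if (same) num <- num + 1
  }
  list(den = den, num = num)
}

# Ti/Tv by looking each substitution up in an explicit transition list.
oracle_titv <- function(ref, alt) {
  transitions <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  ti <- 0; tv <- 0
  for (i in seq_along(ref)) {
    hit <- FALSE
    for (tr in transitions)
      if (ref[i] == tr[1] && alt[i] == tr[2]) hit <- TRUE
    if (hit) ti <- ti + 1 else tv <- tv + 1
  }
  list(ti = ti, tv = tv)
}

# Per-position pileup by looping reads and incrementing counters.
oracle_pileup <- function(starts, widths, len) {
  depth <- integer(len)
  for (i in seq_along(starts)) {
    lo <- starts[i] + 1
    hi <- min(len, starts[i] + widths[i])
    if (hi >= lo) depth[lo:hi] <- depth[lo:hi] + 1L
  }
  depth
}

# Random valid CIGAR built from query/reference-consuming ops, always with
# at least one M so the span is non-empty.
random_cigar <- function() {
  n_ops <- sample(1:5, 1)
  ops <- c("M", sample(c("M", "I", "D", "S", "N", "X", "="), n_ops,
                       replace = TRUE))
  ops <- sample(ops)
  paste0(sample(1:40, length(ops), replace = TRUE), ops, collapse = "")
}
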