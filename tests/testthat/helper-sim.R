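# Shared small simulation fixture, generated once per test run.

tiny_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed, genome_length = 2e5, n_chromosomes = 2L,
                   n_targets = 40L, n_samples = 3L, chip_monomorphic = 100L,
                   n_indels = 20L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.fixture_env <- new.env(parent = emptyenv())

tiny_sim <- function() {
  if (is.null(.fixture_env$tiny)) {
    dir <- file.path(tempdir(), "offtargetqc_tiny_sim")
    .fixture_env$tiny <- simulate_study(tiny_config(), dir)
  }
  .fixture_env$tiny
}

# data.frame of raw intervals for oracle use
intervals_df <- function(regions) {
  do.call(rbind, lapply(names(regions$chroms), function(ch)
    data.frame(chrom = ch, start = regions$chroms[[ch]][, 1],
               end = regions$chroms[[ch]][, 2])))
}

# Minimal read data.frame constructor for unit tests.
make_reads <- function(chrom, pos, cigar, mapq = 60L, strand = "+",
                       isize = 0L, dup = FALSE, seq = NULL, qual = NULL) {
  n <- length(pos)
  chrom <- rep_len(chrom, n); cigar <- rep_len(cigar, n)
  mapq <- rep_len(mapq, n); strand <- rep_len(strand, n)
  isize <- rep_len(isize, n); dup <- rep_len(dup, n)
  qlen <- vapply(cigar, function(cg) {
    toks <- regmatches(cg, gregexpr("[0-9]+[A-Z=]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]$", "", toks))[
      substr(toks, nchar(toks), nchar(toks)) %in% c("M", "I", "S", "=", "X")])
  }, 0)
  if (is.null(seq)) seq <- strrep("A", qlen)
  if (is.null(qual)) qual <- strrep("I", qlen)
  data.frame(qname = sprintf("r%04d", seq_len(n)), flag = 0L, chrom = chrom,
             pos = pos, mapq = mapq, strand = strand, cigar = cigar,
             seq = seq, qual = qual, isize = isize, is_duplicate = dup,
             stringsAsFactors = FALSE)
}
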