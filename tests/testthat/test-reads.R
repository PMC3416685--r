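test_that("phred rescaling shifts ASCII codes and preserves values", {
  expect_equal(phred_rescale("@", 64, 33), "!")
  expect_equal(phred_rescale("h", 64, 33), "I")
  s <- "IIIHH!#5"
  expect_equal(phred_rescale(phred_rescale(s, 33, 64), 64, 33), s)
  expect_error(phred_rescale("!", 64, 33), "encoding")
})

test_that("effective read span applies soft clips via the CIGAR", {
  expect_equal(effective_read_span(99, "72M"),
               data.frame(start = 99, end = 171, width = 72))
  expect_equal(effective_read_span(99, "5S60M7S")$end, 159)
  expect_equal(effective_read_span(99, "30M5D30M")$width, 65)
  expect_equal(effective_read_span(99, "20M3I20M")$width, 40)
  expect_error(effective_read_span(0, "10Q"), "CIGAR")
  expect_error(effective_read_span(0, "10S"), "zero-length")
})

test_that("reference span matches a token-walking oracle on random CIGARs", {
  set.seed(404)
  cigars <- replicate(400, random_cigar())
  got <- effective_read_span(rep(0, 400), cigars)$width
  want <- vapply(cigars, oracle_cigar_ref_len, 0, USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("reads are classified by the majority of their span bases", {
  # target [1000, 1030): span 60 with exactly 30 bases inside -> inside
  tr <- target_regions("chr1", 1000L, 1030L)
  r <- make_reads("chr1", c(970, 971), "60M")
  cls <- classify_read(r, tr, near = 200)
  expect_equal(as.character(cls), c("inside", "inside"))
  # 29 inside, rest near -> near
  r2 <- make_reads("chr1", 969, "60M")
  expect_equal(as.character(classify_read(r2, tr, near = 200)), "near")
  # entirely beyond D -> far
  r3 <- make_reads("chr1", 5000, "60M")
  expect_equal(as.character(classify_read(r3, tr, near = 200)), "far")
})

test_that("read classes match the per-base oracle on random reads", {
  set.seed(505)
  ivs <- data.frame(chrom = "chr1", start = sample(seq(0, 4000, 40), 12))
  ivs$end <- ivs$start + sample(20:60, 12, replace = TRUE)
  tr <- target_regions(ivs$chrom, ivs$start, ivs$end)
  mivs <- intervals_df(tr)
  pos <- sample(0:4500, 300, replace = TRUE)
  r <- make_reads("chr1", pos, "30M")
  got <- as.character(classify_read(r, tr, near = 100))
  want <- vapply(pos, function(p)
    oracle_read_class(mivs, "chr1", p, 30, 100), "")
  expect_equal(got, want)
})

test_that("read filtering honours MAPQ and duplicate flags with exact counts", {
  r <- make_reads("chr1", 1:100, "30M",
                  mapq = rep(c(0L, 19L, 20L, 60L), 25),
                  dup = rep(c(FALSE, FALSE, FALSE, TRUE), each = 25))
  out <- filter_reads(r, min_mapq = 20, drop_duplicates = TRUE)
  expect_equal(out$counts$after,
               sum(r$mapq >= 20 & !r$is_duplicate))
  all0 <- filter_reads(make_reads("chr1", 1:5, "30M", mapq = 0L))
  expect_equal(nrow(all0$reads), 0L)
  ident <- filter_reads(r, min_mapq = 0, drop_duplicates = FALSE)
  expect_equal(nrow(ident$reads), nrow(r))
})

test_that("read class counts partition the filtered read set", {
  sim <- tiny_sim()
  fr <- filter_reads(sim$reads$reads, regions = sim$targets)
  cc <- fr$counts
  expect_equal(sum(cc$after[cc$class != "all"]), cc$after[cc$class == "all"])
})

test_that("pileup depth totals equal summed reference lengths", {
  set.seed(606)
  pos <- sample(0:900, 200, replace = TRUE)
  cigars <- sample(c("50M", "20M5D25M", "5S40M", "30M3I17M"), 200,
                   replace = TRUE)
  r <- make_reads("chr1", pos, cigars)
  dv <- offtargetQC:::depth_vectors(r, c(chr1 = 1200))
  spans <- effective_read_span(r)
  expect_equal(sum(dv$chr1), sum(spans$width))
  # against the looping pileup oracle
  expect_equal(as.integer(dv$chr1),
               oracle_pileup(spans$start, spans$width, 1200))
})

test_that("boundary depth profile is flat under uniform coverage and shifts with the data", {
  tr <- target_regions("chr1", 2000L, 2400L)
  # perfectly uniform tiling at depth 10: 10 staggered full tilings
  starts <- as.vector(outer(seq(0, 7960, by = 40), 0:9 * 4, "+"))
  r <- make_reads("chr1", starts, "40M")
  prof <- boundary_depth_profile(r, tr, chrom_lengths = c(chr1 = 8005))
  expect_true(all(abs(prof$mean_depth - 10) <= 1e-9))
  # no reads -> all-zero profile
  prof0 <- boundary_depth_profile(r[0, ], tr, chrom_lengths = c(chr1 = 8005))
  expect_true(all(prof0$mean_depth == 0))
  # translation equivariance: shifting reads and target together
  shift <- 500L
  tr2 <- target_regions("chr1", 2000L + shift, 2400L + shift)
  r2 <- make_reads("chr1", starts + shift, "40M")
  prof2 <- boundary_depth_profile(r2, tr2, chrom_lengths = c(chr1 = 8505))
  expect_equal(prof2$mean_depth, prof$mean_depth)
})

test_that("coverage summary reports breadth and depth-stratified sites", {
  tr <- target_regions("chr1", 1000L, 1100L)
  r <- make_reads("chr1", 1020, "60M")
  cs <- class_coverage_summary(r, tr, near = 200,
                               chrom_lengths = c(chr1 = 1500), gc = FALSE)
  b <- cs$breadth
  expect_equal(b$breadth_ge1[b$class == "inside"], 0.6)
  expect_equal(b$breadth_ge5[b$class == "inside"], 0)
})

test_that("site depth counts match a brute-force pileup on a toy genome", {
  set.seed(707)
  tr <- target_regions("chr1", c(2000L, 6000L), c(2300L, 6400L))
  pos <- sample(0:9000, 3000, replace = TRUE)
  r <- make_reads("chr1", pos, "50M")
  cs <- class_coverage_summary(r, tr, near = 200,
                               chrom_lengths = c(chr1 = 10000), gc = FALSE)
  depth <- oracle_pileup(pos, rep(50, 3000), 10000)
  cls <- vapply(0:9999, function(p)
    oracle_class(intervals_df(tr), "chr1", p, 200), "")
  for (k in c("inside", "near", "far")) {
    for (j in 5:10) {
      expect_equal(cs$min_depth_sites[k, paste0("ge", j)],
                   sum(depth >= j & cls == k))
    }
  }
})

test_that("GC content recovers the configured inside/outside contrast", {
  sim <- tiny_sim()
  fr <- filter_reads(sim$reads$reads, regions = sim$targets)
  cs <- class_coverage_summary(fr$reads, sim$targets, gc = TRUE)
  gi <- cs$gc[cs$gc$class == "inside", ]
  cfg <- tiny_config()
  se_i <- 100 * sqrt(cfg$gc_inside * (1 - cfg$gc_inside) / gi$n_positions)
  expect_lt(abs(gi$gc_percent - 100 * cfg$gc_inside), 3 * se_i)
  expect_gt(gi$gc_percent,
            cs$gc$gc_percent[cs$gc$class == "near" & cs$gc$stratum == "ge1"])
})

test_that("insert size fraction counts pairs within the limit", {
  r <- make_reads("chr1", 1:4, "30M", isize = c(150L, 150L, 150L, 150L))
  expect_equal(insert_size_fraction(r), 1)
  r2 <- make_reads("chr1", 1:2, "30M", isize = c(100L, 600L))
  expect_equal(insert_size_fraction(r2), 0.5)
  set.seed(808)
  is <- sample(c(-900:-1, 1:900), 500, replace = TRUE)
  r3 <- make_reads("chr1", seq_len(500), "30M", isize = as.integer(is))
  expect_equal(insert_size_fraction(r3, 500), mean(abs(is) <= 500))
})

test_that("high-depth far regions are maximal runs split by sub-threshold bases", {
  tr <- target_regions("chr1", 0L, 100L)
  # far block at 5000..5299 with depth 2 from two stacked reads per pos
  starts <- rep(seq(5000, 5299, by = 1), 2)
  r <- make_reads("chr1", starts, "1M")
  hits <- find_high_depth_far_regions(r, tr, min_depth = 2, min_length = 100,
                                      chrom_lengths = c(chr1 = 6000))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 5000)
  expect_equal(hits$end, 5300)
  expect_equal(hits$mean_depth, 2)
  # a single sub-threshold base splits the run in two
  r2 <- make_reads("chr1", rep(setdiff(5000:5299, 5150), 2), "1M")
  hits2 <- find_high_depth_far_regions(r2, tr, min_depth = 2,
                                       min_length = 100,
                                       chrom_lengths = c(chr1 = 6000))
  expect_equal(nrow(hits2), 2L)
  # flat depth below threshold -> nothing
  none <- find_high_depth_far_regions(r, tr, min_depth = 5, min_length = 10,
                                      chrom_lengths = c(chr1 = 6000))
  expect_equal(nrow(none), 0L)
})

test_that("simulated SAM files round-trip through the alignment reader", {
  sim <- tiny_sim()
  back <- read_alignments(sim$paths$sam)
  df <- sim$reads$reads
  expect_equal(nrow(back), nrow(df))
  back <- back[order(back$chrom, back$pos, back$qname), ]
  df <- df[order(df$chrom, df$pos, df$qname), ]
  rownames(back) <- rownames(df) <- NULL
  for (col in c("qname", "chrom", "pos", "mapq", "strand", "cigar", "seq",
                "qual", "isize", "is_duplicate"))
    expect_equal(back[[col]], df[[col]], info = col)
})
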