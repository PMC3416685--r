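make_calls <- function(ref, alt, gt = "het", gq = 99, depth = 30,
                       chrom = "chr1", pos = NULL, sample = "S01",
                       is_indel = FALSE, site_qual = 100, ab = NA) {
  n <- max(length(ref), length(alt), length(gt), length(pos))
  if (is.null(pos)) pos <- seq_len(n) * 10
  ref <- rep_len(ref, n); alt <- rep_len(alt, n); gt <- rep_len(gt, n)
  data.frame(chrom = rep_len(chrom, n), pos = pos, ref = ref, alt = alt,
             sample = rep_len(sample, n), gt = gt,
             a1 = ifelse(gt == "hom", alt, ref),
             a2 = ifelse(gt == "ref", ref, alt),
             gq = rep_len(gq, n), depth = rep_len(depth, n),
             allelic_balance = rep_len(ab, n),
             site_qual = rep_len(site_qual, n),
             is_indel = rep_len(is_indel, n), stringsAsFactors = FALSE)
}

test_that("transition detection covers all twelve ordered substitutions", {
  expect_true(is_transition("A", "G"))
  expect_false(is_transition("A", "C"))
  b <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = b, alt = b, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_equal(sum(is_transition(pairs$ref, pairs$alt)), 4L)
  expect_equal(sum(!is_transition(pairs$ref, pairs$alt)), 8L)
  expect_error(is_transition("A", "A"), "differ")
  expect_error(is_transition("A", "N"), "single bases")
})

test_that("Ti/Tv counts non-reference SNV genotypes and handles edge cases", {
  calls <- make_calls(c("A", "G", "C", "T", "A", "A"),
                      c("G", "A", "T", "C", "C", "T"))
  tt <- titv_ratio(calls)
  expect_equal(tt$n_transitions, 4L)
  expect_equal(tt$n_transversions, 2L)
  expect_equal(tt$ratio, 2)
  # reference-homozygous and indel rows are excluded
  calls2 <- rbind(calls, make_calls("A", "G", gt = "ref", pos = 100),
                  make_calls("A", "AT", is_indel = TRUE, pos = 200))
  expect_equal(titv_ratio(calls2)$n_transitions, 4L)
  # empty input and zero transversions
  expect_equal(titv_ratio(calls[0, ])$n_transitions, 0L)
  expect_true(is.na(titv_ratio(calls[0, ])$ratio))
  expect_true(is.na(titv_ratio(make_calls("A", "G"))$ratio))
  expect_equal(titv_ratio(make_calls("A", "G"))$n_transitions, 1L)
})

test_that("Ti/Tv matches the lookup-table oracle on random substitutions", {
  set.seed(909)
  b <- c("A", "C", "G", "T")
  ref <- sample(b, 1000, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(b, r), 1), "")
  tt <- titv_ratio(make_calls(ref, alt, pos = seq_len(1000)))
  want <- oracle_titv(ref, alt)
  expect_equal(tt$n_transitions, want$ti)
  expect_equal(tt$n_transversions, want$tv)
})

test_that("genotype filtering applies GQ and depth thresholds exactly", {
  set.seed(111)
  calls <- make_calls("A", "G", gq = sample(0:60, 500, replace = TRUE),
                      depth = sample(0:30, 500, replace = TRUE),
                      pos = seq_len(500))
  out <- filter_snps(calls, min_gq = 20, min_depth = 5)
  expect_equal(nrow(out$calls), sum(calls$gq >= 20 & calls$depth >= 5))
  expect_equal(nrow(out$calls) + nrow(out$dropped), nrow(calls))
  expect_equal(nrow(filter_snps(make_calls("A", "G", gq = 19))$calls), 0L)
  expect_equal(nrow(filter_snps(calls, 0, 0)$calls), nrow(calls))
})

test_that("known-site overlap percentages count position and allele matches", {
  calls <- make_calls("A", "G", pos = c(10, 20, 30, 40))
  expect_equal(dbsnp_overlap(calls, data.frame(chrom = character(0),
                                               pos = numeric(0))), 0)
  known_all <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40), alt = "G")
  expect_equal(dbsnp_overlap(calls, known_all), 100)
  # allele-aware vs position-only matching
  known_mm <- data.frame(chrom = "chr1", pos = c(10, 20), alt = c("G", "T"))
  expect_equal(dbsnp_overlap(calls, known_mm), 25)
  expect_equal(dbsnp_overlap(calls, known_mm, match_alleles = FALSE), 50)
})

test_that("SNP depth histograms bin 5..19 with a pooled >=20 bin", {
  h <- snp_depth_histogram(make_calls("A", "G", depth = 5))
  expect_equal(as.integer(h["5"]), 1L)
  expect_equal(sum(h), 1)
  h2 <- snp_depth_histogram(make_calls("A", "G", depth = c(20, 25, 300),
                                       pos = 1:3))
  expect_equal(as.integer(h2["ge20"]), 3L)
  set.seed(222)
  calls <- make_calls("A", "G", depth = sample(5:40, 300, replace = TRUE),
                      pos = seq_len(300))
  expect_equal(sum(snp_depth_histogram(calls)), 300)
})

test_that("threshold sweeps keep counts monotone and match unfiltered stats", {
  sim <- tiny_sim()
  calls <- read_vcf_calls(sim$paths$vcf)
  chip <- read_chip_genotypes(sim$paths$chip)
  known <- read_known_sites(sim$paths$known)
  sw <- threshold_sweep(calls, chip = chip, known = known,
                        regions = sim$targets,
                        axes = list(gq = c(0, 10, 20, 30),
                                    depth = c(0, 2, 5, 10)))
  for (ax in unique(sw$axis)) {
    for (ds in unique(sw$dbsnp_stratum)) {
      for (rs in unique(sw$region_stratum)) {
        n <- sw$n_snps[sw$axis == ax & sw$dbsnp_stratum == ds &
                         sw$region_stratum == rs]
        expect_true(all(diff(n) <= 0))
      }
    }
  }
  # a threshold below every observed value reproduces unfiltered statistics
  base <- sw[sw$axis == "gq" & sw$threshold == 0 &
               sw$dbsnp_stratum == "all" & sw$region_stratum == "all", ]
  snv <- calls[!calls$is_indel & calls$gt %in% c("het", "hom"), ]
  expect_equal(base$n_snps, nrow(snv))
  expect_equal(base$titv, titv_ratio(snv)$ratio)
})

test_that("positional annotation follows the documented precedence", {
  gm <- data.frame(
    chrom = "chr1",
    start = c(1000, 1500, 900, 5000),
    end = c(1100, 1600, 2000, 5500),
    label = c("exon", "exon", "gene", "ncRNA")
  )
  got <- annotate_positional(
    rep("chr1", 7), c(1050, 1101, 1300, 5200, 8000, 1100, 1102), gm)
  expect_equal(as.character(got),
               c("exonic",     # inside exon
                 "splicing",   # exactly 2 bp past the exon end, inside gene
                 "intronic",   # inside gene, away from exons
                 "ncRNA", "intergenic",
                 "splicing",   # first base past the exon end
                 "intronic"))  # 3 bp out: beyond the splice window
  # a position on a chromosome with no genes is intergenic
  expect_equal(as.character(annotate_positional("chr9", 100, gm)),
               "intergenic")
  # every position gets exactly one category
  set.seed(333)
  cat_all <- annotate_positional(rep("chr1", 500),
                                 sample(0:6000, 500), gm)
  expect_false(anyNA(cat_all))
  expect_error(read_gene_model(textConnection("x")), "label")
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10\tpromoter", bad)
  expect_error(read_gene_model(bad), "promoter")
})

test_that("indel counts use an inclusive site-quality threshold per class", {
  tr <- target_regions("chr1", 100L, 200L)
  calls <- make_calls("A", "AT", is_indel = TRUE,
                      site_qual = c(999, 1000, 2000),
                      pos = c(150, 250, 5000))
  cnt <- count_indels_by_qual(calls, min_qual = 1000, regions = tr)
  expect_equal(sum(cnt), 2L)
  expect_equal(unname(cnt["near"]), 1L)
  expect_equal(unname(cnt["far"]), 1L)
  none <- count_indels_by_qual(make_calls("A", "G"), regions = tr)
  expect_equal(sum(none), 0L)
})

test_that("multi-allelic records split and symbolic alleles are skipped", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S01", "S02"), collapse = "\t"),
    "chr1\t101\t.\tA\tG,T\t50\tPASS\t.\tGT:GQ:DP\t0/1:40:12\t0/2:35:9",
    "chr1\t201\t.\tC\t<DEL>\t50\tPASS\t.\tGT:GQ:DP\t0/1:40:12\t0/0:35:9",
    "chr1\t301\t.\tG\tGA\t900\tPASS\t.\tGT:GQ:DP\t1/1:60:20\t0/0:35:9"
  ), vcf)
  expect_warning(calls <- read_vcf_calls(vcf), "symbolic")
  # site 101 splits into A>G (S01 het) and A>T (S02 het)
  s101 <- calls[calls$pos == 100, ]
  expect_equal(nrow(s101), 2L)
  expect_equal(s101$alt[s101$sample == "S01"], "G")
  expect_equal(s101$alt[s101$sample == "S02"], "T")
  expect_true(all(s101$gt == "het"))
  # the symbolic record contributes nothing
  expect_equal(nrow(calls[calls$pos == 200, ]), 0L)
  # the indel is flagged
  expect_true(all(calls$is_indel[calls$pos == 300]))
  expect_equal(calls$gt[calls$pos == 300 & calls$sample == "S01"], "hom")
})
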