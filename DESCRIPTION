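Package: offtargetQC
Title: Quality Assessment of Exome-Capture Sequence Data Outside Target Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how much usable sequence and variant information
    a targeted-capture (exome) experiment yields outside its designed capture
    intervals. Genomic positions, aligned reads, and SNP calls are stratified
    by distance to the nearest target region (inside, within a near threshold,
    or far), and per-stratum quality is summarised via depth and
    coverage-breadth profiles, GC content, mapping and base quality
    distributions, transition/transversion ratios, known-variant (dbSNP)
    overlap, and genotype concordance against an orthogonal SNP-array
    platform, including at strand-imbalanced positions. A deterministic
    simulator of targeted-capture data (BED/SAM/VCF/TSV outputs with
    distance-decaying off-target enrichment, class-specific Ti/Tv spectra,
    correlated genotype-quality/depth noise, strand bias, and high-depth
    off-target blocks) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
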