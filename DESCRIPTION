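Package: afstats
Title: Allele-Sharing Statistics from Precomputed Population Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes allele-frequency-based statistics widely used in
    population genomics: average pairwise distances, f3-, f4- and
    D-statistics, f4-ratios, admixture/contamination-corrected f4,
    minor-allele-count-stratified D and ascertainment-based "enhanced" D,
    all with standard errors from a weighted block jackknife.  Population
    allele frequencies are precomputed once from a PLINK panel into a
    compact frequency store that is streamed one site at a time, keeping
    memory use low.  Low-depth sequencing data (for example ancient DNA)
    can be merged into a store as pseudo-haploid random-allele calls drawn
    from BAM files with mapping/base-quality filters and read-end
    trimming.  Includes automated enumeration wrappers with plotting,
    treemix export, a synthetic-data generator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    parallel,
    Rsamtools,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
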