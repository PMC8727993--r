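# Fixtures are built in code at test time.

# A tiny handcrafted store: 2 populations, 6 sites on 2 chromosomes with a
# known allele-pair composition (2 transitions: snp2 C/T, snp5 G/A).
fixture_store_small <- function() {
  sites <- data.frame(
    chrom = c("1", "1", "1", "2", "2", "2"),
    pos = c(10L, 5000020L, 9000000L, 100L, 200L, 300L),
    snpid = paste0("snp", 1:6),
    alleleA = c("A", "C", "G", "A", "G", "C"),
    alleleB = c("C", "T", "T", "T", "A", "G"),
    stringsAsFactors = FALSE)
  pops <- data.frame(name = c("P1", "P2"), ploidy = "diploid",
                     n_ind = c(2L, 2L), stringsAsFactors = FALSE)
  countA <- matrix(c(3L, 4L, 0L, 2L, 1L, 4L,
                     1L, 0L, 2L, 0L, 4L, 2L), ncol = 2)
  total <- matrix(c(4L, 4L, 4L, 4L, 2L, 4L,
                    4L, 2L, 4L, 0L, 4L, 4L), ncol = 2)
  afstats:::.new_freqstore(sites, pops, countA, total)
}

fixture_store_random <- function(n_sites, n_pops, seed = 1L,
                                 n_chrom = 3L) {
  simulate_freqstore(independent_graph(n_pops), n_sites, seed = seed,
                     n_chrom = n_chrom)
}

# Handcrafted read set around one site (chrom "1", pos 100, alleles A/C),
# read length 21, no clipping, so off_end = 20 - off_start.  Metadata is
# returned alongside the BAM so tests can enumerate eligibility rules
# independently.
fixture_bam_reads <- function() {
  data.frame(
    qname = paste0("r", 1:10),
    mapq = c(30L, 29L, 30L, 30L, 30L, 30L, 30L, 30L, 30L, 35L),
    baseq = c(20L, 20L, 19L, 20L, 20L, 20L, 20L, 20L, 20L, 25L),
    off_start = c(10L, 10L, 10L, 4L, 5L, 16L, 15L, 9L, 10L, 12L),
    base = c("A", "A", "C", "A", "C", "A", "A", "G", "A", "C"),
    dup = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
            TRUE, FALSE),
    stringsAsFactors = FALSE)
}

fixture_bam_site <- function() {
  data.frame(chrom = "1", pos = 100L, snpid = "snp1",
             alleleA = "A", alleleB = "C", stringsAsFactors = FALSE)
}

write_fixture_bam <- function(dir = tempfile("bamfix")) {
  dir.create(dir, showWarnings = FALSE)
  meta <- fixture_bam_reads()
  read_len <- 21L
  mk_seq <- function(off, base) {
    paste0(strrep("T", off), base, strrep("T", read_len - off - 1L))
  }
  reads <- data.frame(
    qname = meta$qname,
    flag = ifelse(meta$dup, 1024L, 0L),
    chrom = "1",
    pos = 100L - meta$off_start,
    mapq = meta$mapq,
    cigar = paste0(read_len, "M"),
    seq = vapply(seq_len(nrow(meta)),
                 function(i) mk_seq(meta$off_start[i], meta$base[i]), ""),
    qual = vapply(meta$baseq, function(q) {
      strrep(intToUtf8(q + 33L), read_len)
    }, ""),
    stringsAsFactors = FALSE)
  bam <- afstats:::.write_sam_bam(reads, c("1" = 200L),
                                  file.path(dir, "fixture"))
  list(bam = bam, meta = meta, site = fixture_bam_site())
}

# Independent eligibility oracle over the fixture metadata (off_end
# derived from the fixed geometry; duplicates always excluded).
fixture_eligible_oracle <- function(meta, min_mapq, min_baseq, trim) {
  off_end <- 20L - meta$off_start
  keep <- !meta$dup & meta$mapq >= min_mapq & meta$baseq >= min_baseq &
    meta$off_start >= trim & off_end >= trim
  meta$base[keep]
}
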