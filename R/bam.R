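# Pseudo-haploid random-allele calling from BAM/CRAM files at panel sites.
# One eligible base is drawn uniformly per site; if it matches neither
# panel allele (a third allele) the call is missing.  Eligibility: mapping
# quality, base quality, and a read-end trim measured in read-sequence
# coordinates over the aligned (non-soft-clipped) bases.

#' Describe one BAM/CRAM sample and its filters
#'
#' @param path BAM/CRAM file (must be indexed).
#' @param sample sample name.
#' @param pop population name the sample is merged under.
#' @param min_mapq minimum mapping quality (reads below are ignored).
#' @param min_baseq minimum base quality (bases below are ignored).
#' @param trim_bp number of bases ignored from each read end; a base at
#'   0-based offset `trim_bp - 1` from either end is excluded, one at
#'   `trim_bp` is kept.
#' @return a `bam_sample_spec`.
#' @export
bam_sample_spec <- function(path, sample, pop, min_mapq = 30L,
                            min_baseq = 20L, trim_bp = 0L) {
  stopifnot(trim_bp >= 0L)
  structure(list(path = path, sample = sample, pop = pop,
                 min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 trim_bp = as.integer(trim_bp)),
            class = "bam_sample_spec")
}

#' Read a BAM list file
#'
#' One line per BAM, six tab-separated fields: path, sample, population,
#' minimum mapping quality, minimum base quality, trim length.
#'
#' @param path list file path.
#' @return a list of [bam_sample_spec()] objects.
#' @export
read_bamlist <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad)) {
    stop("BAM list ", path, " line ", keep[bad[1L]],
         ": expected 6 tab-separated fields", call. = FALSE)
  }
  lapply(parts, function(p) {
    bam_sample_spec(p[1L], p[2L], p[3L], as.integer(p[4L]),
                    as.integer(p[5L]), as.integer(p[6L]))
  })
}

# Map site chromosome labels onto BAM target names, tolerating a "chr"
# prefix mismatch in either direction.  NA where unresolvable.
.resolve_contigs <- function(chroms, targets) {
  out <- ifelse(chroms %in% targets, chroms, NA_character_)
  alt <- paste0("chr", chroms)
  out <- ifelse(is.na(out) & alt %in% targets, alt, out)
  alt2 <- sub("^chr", "", chroms)
  ifelse(is.na(out) & alt2 %in% targets, alt2, out)
}

# Locate the query base aligned to reference position `pos` for one read.
# Returns NULL when the position falls in a deletion/skip or outside the
# alignment; otherwise base, base quality, and 0-based offsets from both
# ends of the aligned (non-soft-clipped) read sequence.
.read_base_at <- function(pos, rpos, cigar, seq, qual) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops)) return(NULL)
  len <- as.integer(sub(".$", "", ops))
  op <- substr(ops, nchar(ops), nchar(ops))
  ref <- rpos
  q <- 0L
  qhit <- NA_integer_
  for (k in seq_along(op)) {
    o <- op[k]
    if (o %in% c("M", "=", "X")) {
      if (pos >= ref && pos < ref + len[k]) {
        qhit <- q + (pos - ref) + 1L
        break
      }
      ref <- ref + len[k]
      q <- q + len[k]
    } else if (o %in% c("I", "S")) {
      q <- q + len[k]
    } else if (o %in% c("D", "N")) {
      if (pos >= ref && pos < ref + len[k]) return(NULL)
      ref <- ref + len[k]
    }
    # H and P consume neither
  }
  if (is.na(qhit)) return(NULL)
  softs <- op == "S"
  lead_s <- if (length(op) && softs[1L]) len[1L] else
    if (length(op) > 1L && op[1L] == "H" && softs[2L]) len[2L] else 0L
  no <- length(op)
  trail_s <- if (softs[no]) len[no] else
    if (no > 1L && op[no] == "H" && softs[no - 1L]) len[no - 1L] else 0L
  L <- nchar(seq)
  list(base = substr(seq, qhit, qhit),
       baseq = utf8ToInt(substr(qual, qhit, qhit)) - 33L,
       off_start = qhit - 1L - lead_s,
       off_end = (L - trail_s) - qhit)
}

# Per-site eligible bases for one spec.  Returns a list (one character
# vector per site).  Duplicate, secondary, supplementary and unmapped
# alignments are excluded up front.
.eligible_bases <- function(spec, sites) {
  if (!file.exists(spec$path)) {
    stop("missing BAM/CRAM file: ", spec$path, call. = FALSE)
  }
  bai <- c(paste0(spec$path, ".bai"), sub("\\.bam$", ".bai", spec$path),
           paste0(spec$path, ".crai"))
  if (!any(file.exists(bai))) {
    stop("BAM/CRAM index not found for ", spec$path,
         " (run samtools index)", call. = FALSE)
  }
  targets <- names(Rsamtools::scanBamHeader(spec$path)[[1L]]$targets)
  contig <- .resolve_contigs(sites$chrom, targets)
  if (all(is.na(contig))) {
    stop("no site chromosome matches any contig in ", spec$path,
         " (targets: ", paste(head(targets, 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  n <- nrow(sites)
  elig <- rep(list(character(0)), n)
  ok <- which(!is.na(contig))
  if (!length(ok)) return(elig)
  gr <- GenomicRanges::GRanges(contig[ok],
                               IRanges::IRanges(sites$pos[ok],
                                                sites$pos[ok]))
  param <- Rsamtools::ScanBamParam(
    which = gr,
    what = c("pos", "mapq", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(spec$path, param = param)
  for (k in seq_along(ok)) {
    r <- res[[k]]
    if (!length(r$pos)) next
    seqs <- as.character(r$seq)
    quals <- as.character(r$qual)
    keep <- character(0)
    for (j in seq_along(r$pos)) {
      mq <- r$mapq[j]
      if (is.na(mq) || mq < spec$min_mapq) next
      hit <- .read_base_at(sites$pos[ok[k]], r$pos[j], r$cigar[j],
                           seqs[j], quals[j])
      if (is.null(hit)) next
      if (hit$baseq < spec$min_baseq) next
      if (hit$off_start < spec$trim_bp || hit$off_end < spec$trim_bp) next
      keep <- c(keep, hit$base)
    }
    elig[[ok[k]]] <- keep
  }
  elig
}

# Deterministic per-site seed from (run seed, chrom, pos), so serial and
# parallel merging agree and distinct sites draw independently.  The
# chromosome label is normalized ("chr" prefix stripped) so equivalent
# naming conventions draw identically.
.site_seed <- function(seed, chrom, pos) {
  h <- 0
  for (ch in utf8ToInt(sub("^chr", "", chrom))) h <- (h * 31 + ch) %% 1e9
  as.integer((seed %% 1e6 * 7919 + h * 2 + pos * 13) %% 2147483647)
}

.draw_calls <- function(elig, sites, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  n <- nrow(sites)
  calls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    k <- length(elig[[i]])
    if (k == 0L) next
    set.seed(.site_seed(seed, sites$chrom[i], sites$pos[i]))
    b <- elig[[i]][sample.int(k, 1L)]
    calls[i] <- if (b == sites$alleleA[i]) "A"
                else if (b == sites$alleleB[i]) "B"
                else NA_character_   # third allele -> missing
  }
  calls
}

#' Pseudo-haploid random-allele calls at panel sites
#'
#' At every site, one base is drawn uniformly among the eligible bases of
#' the overlapping reads (mapping quality, base quality and read-end trim
#' filters applied; duplicates and secondary/supplementary alignments
#' excluded).  A drawn base equal to `alleleA` yields call `"A"`, equal to
#' `alleleB` yields `"B"`, and any other base — a would-be tri-allelic
#' site — yields a missing call, as does a site with no eligible base.
#' Draws are seeded per site from `(seed, chrom, pos)`, so results are
#' reproducible and independent of processing order.
#'
#' @param spec a [bam_sample_spec()].
#' @param sites data frame with `chrom`, `pos`, `alleleA`, `alleleB`
#'   (typically a store's `$sites`).
#' @param seed integer seed.
#' @return character vector over \{`"A"`, `"B"`, `NA`\}, one per site.
#' @export
pseudo_haploid_calls <- function(spec, sites, seed = 1L) {
  stopifnot(inherits(spec, "bam_sample_spec"))
  elig <- .eligible_bases(spec, sites)
  .draw_calls(elig, sites, seed)
}

#' Merge BAM samples into a frequency store
#'
#' Runs [pseudo_haploid_calls()] for each spec and appends one haploid
#' population per spec via [merge_counts()], in list order.
#'
#' @param store a `freqstore` or prefix.
#' @param specs a list of [bam_sample_spec()] (e.g. from [read_bamlist()]).
#' @param out_prefix optional prefix for writing the merged store.
#' @param seed integer seed for the random-allele draws.
#' @param nthr worker processes for per-spec calling.
#' @return the merged `freqstore`.
#' @export
add_bams <- function(store, specs, out_prefix = NULL, seed = 1L,
                     nthr = 1L) {
  store <- .materialize(store)
  if (inherits(specs, "bam_sample_spec")) specs <- list(specs)
  callsets <- if (nthr > 1L) {
    parallel::mclapply(specs, pseudo_haploid_calls, sites = store$sites,
                       seed = seed, mc.cores = nthr)
  } else {
    lapply(specs, pseudo_haploid_calls, sites = store$sites, seed = seed)
  }
  for (k in seq_along(specs)) {
    calls <- callsets[[k]]
    if (inherits(calls, "try-error")) {
      stop("calling failed for ", specs[[k]]$path, call. = FALSE)
    }
    nA <- sum(calls == "A", na.rm = TRUE)
    nB <- sum(calls == "B", na.rm = TRUE)
    message(specs[[k]]$sample, ": ", nA, " A calls, ", nB, " B calls, ",
            sum(is.na(calls)), " missing")
    if (nA + nB == 0L) {
      warning("all calls missing for ", specs[[k]]$pop,
              " (empty or fully filtered BAM)", call. = FALSE)
    }
    store <- merge_counts(store, specs[[k]]$pop, calls)
  }
  if (!is.null(out_prefix)) write_freqstore(store, out_prefix)
  store
}

#' Export pseudo-haploid calls as a PLINK fileset
#'
#' Calls are written as homozygous diploid genotypes (`A` as two copies of
#' A1, `B` as zero, missing as missing); the bim mirrors the panel sites.
#' A companion `<out_prefix>_clust` cluster file is written so the fileset
#' feeds straight back into [read_plink()] + [build_freqs()].
#'
#' @param spec a [bam_sample_spec()].
#' @param sites panel sites (`chrom`, `pos`, `snpid`, `alleleA`, `alleleB`).
#' @param out_prefix output PLINK prefix.
#' @param seed integer seed.
#' @return the calls, invisibly.
#' @export
bam_to_plink <- function(spec, sites, out_prefix, seed = 1L) {
  calls <- pseudo_haploid_calls(spec, sites, seed)
  geno <- matrix(ifelse(is.na(calls), NA_integer_,
                        ifelse(calls == "A", 2L, 0L)), ncol = 1L)
  fam <- data.frame(fid = spec$pop, iid = spec$sample,
                    stringsAsFactors = FALSE)
  write_plink(out_prefix, geno, sites, fam)
  writeLines(paste(spec$pop, spec$sample, spec$pop, sep = "\t"),
             paste0(out_prefix, "_clust"))
  invisible(calls)
}
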