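# PLINK 1 binary filesets (bed/bim/fam), SNP-major layout only.

# 2-bit genotype codes -> copies of the bim A1 allele.
# 00 = hom A1 (2), 01 = missing (NA), 10 = het (1), 11 = hom A2 (0).
.bed_decode_lut <- local({
  lut <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
  map <- c(2L, NA_integer_, 1L, 0L)
  for (b in 0:255) {
    for (k in 0:3) {
      lut[b + 1L, k + 1L] <- map[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L]
    }
  }
  lut
})

#' Read a PLINK binary genotype panel
#'
#' Reads a PLINK v1 bed/bim/fam fileset (SNP-major) together with an
#' optional 3-column cluster file (family ID, individual ID, population)
#' assigning individuals to populations.  Genotypes are returned as copies
#' of the bim A1 allele (0, 1, 2, or `NA` for missing).
#'
#' Individuals present in the fam file but absent from the cluster file are
#' dropped with a warning.  Multi-allelic sites, indels and missing allele
#' codes in the bim file are rejected: filter the panel to bi-allelic SNPs
#' with plink first.
#'
#' @param bed_prefix path prefix of the fileset (without `.bed`).
#' @param clustfile optional path to the tab-separated cluster file.
#' @return an object of class `plink_panel`: a list with `geno` (sites x
#'   individuals integer matrix), `sites` (data frame with `chrom`, `snpid`,
#'   `pos`, `alleleA`, `alleleB`; `alleleA` is the counted A1 allele),
#'   `ind` (data frame with `fid`, `iid`, `pop`) and `pop_order` (population
#'   labels in cluster-file order).
#' @export
read_plink <- function(bed_prefix, clustfile = NULL) {
  bedf <- paste0(bed_prefix, ".bed")
  bimf <- paste0(bed_prefix, ".bim")
  famf <- paste0(bed_prefix, ".fam")
  for (f in c(bedf, bimf, famf)) {
    if (!file.exists(f)) stop("missing PLINK file: ", f, call. = FALSE)
  }
  bim <- read.table(bimf, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "integer", "character", "character"))
  if (ncol(bim) != 6L) stop("bim file must have 6 columns")
  names(bim) <- c("chrom", "snpid", "cm", "pos", "alleleA", "alleleB")
  bad <- !(bim$alleleA %in% c("A", "C", "G", "T")) |
         !(bim$alleleB %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop(sum(bad), " bim row(s) carry non-SNP alleles (indels, missing or ",
         "non-ACGT codes), first offending id: ",
         bim$snpid[which(bad)[1L]], call. = FALSE)
  }
  if (any(bim$alleleA == bim$alleleB)) {
    stop("bim row(s) with identical A1/A2 alleles", call. = FALSE)
  }
  fam <- read.table(famf, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(fam) != 6L) stop("fam file must have 6 columns")
  names(fam) <- c("fid", "iid", "pid", "mid", "sex", "pheno")

  n_ind <- nrow(fam)
  n_snp <- nrow(bim)
  bpv <- (n_ind + 3L) %/% 4L
  raw <- readBin(bedf, "raw", n = file.info(bedf)$size)
  if (length(raw) < 3L ||
      raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("not a PLINK v1 .bed file (bad magic bytes)", call. = FALSE)
  }
  if (raw[3L] != as.raw(0x01)) {
    stop(".bed file is not SNP-major (mode byte ",
         sprintf("0x%02x", as.integer(raw[3L])),
         "); re-export with plink --make-bed", call. = FALSE)
  }
  body <- raw[-(1:3)]
  if (length(body) != n_snp * bpv) {
    stop(".bed size (", length(body), " data bytes) does not match bim x fam",
         " dimensions (expected ", n_snp * bpv, ")", call. = FALSE)
  }
  vals <- .bed_decode_lut[as.integer(body) + 1L, , drop = FALSE]
  slots <- matrix(t(vals), nrow = 4L * bpv)        # slots x snps
  geno <- t(slots[seq_len(n_ind), , drop = FALSE]) # snps x individuals
  colnames(geno) <- fam$iid

  ind <- data.frame(fid = fam$fid, iid = fam$iid, pop = NA_character_,
                    stringsAsFactors = FALSE)
  pop_order <- character(0)
  if (!is.null(clustfile)) {
    cl <- .read_clust(clustfile)
    m <- match(ind$iid, cl$iid)
    absent <- is.na(m)
    if (any(absent)) {
      warning(sum(absent), " individual(s) absent from cluster file dropped: ",
              paste(head(ind$iid[absent], 5L), collapse = ", "),
              if (sum(absent) > 5L) ", ..." else "", call. = FALSE)
    }
    keep <- !absent
    geno <- geno[, keep, drop = FALSE]
    ind <- ind[keep, , drop = FALSE]
    rownames(ind) <- NULL
    ind$pop <- cl$pop[m[keep]]
    pop_order <- unique(cl$pop[cl$iid %in% ind$iid])
  }
  structure(list(geno = geno,
                 sites = bim[, c("chrom", "snpid", "pos",
                                 "alleleA", "alleleB")],
                 ind = ind,
                 pop_order = pop_order),
            class = "plink_panel")
}

.read_clust <- function(path) {
  if (!file.exists(path)) stop("missing cluster file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("cluster file ", path, ": expected 3 tab-separated columns at line ",
         bad[1L], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(fid = m[, 1L], iid = m[, 2L], pop = m[, 3L],
             stringsAsFactors = FALSE)
}

#' Write a PLINK binary genotype panel
#'
#' Inverse of [read_plink()]: writes a bed/bim/fam fileset in SNP-major
#' layout.  `geno` holds copies of `sites$alleleA` (the A1 allele).
#'
#' @param prefix output path prefix.
#' @param geno sites x individuals integer matrix with values 0/1/2/`NA`.
#' @param sites data frame with columns `chrom`, `snpid`, `pos`, `alleleA`,
#'   `alleleB`.
#' @param fam data frame with columns `fid` and `iid` (remaining fam columns
#'   are filled with placeholder values if absent).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(prefix, geno, sites, fam) {
  n_snp <- nrow(geno)
  n_ind <- ncol(geno)
  stopifnot(nrow(sites) == n_snp, nrow(fam) == n_ind)
  bpv <- (n_ind + 3L) %/% 4L
  # copies of A1 -> 2-bit code (padding slots encoded as 0b00, ignored on read)
  code <- ifelse(is.na(geno), 1L, c(3L, 2L, 0L)[geno + 1L])
  slots <- matrix(0L, nrow = 4L * bpv, ncol = n_snp)
  slots[seq_len(n_ind), ] <- t(code)
  i1 <- seq(1L, 4L * bpv, by = 4L)
  bytes <- slots[i1, , drop = FALSE] +
    4L  * slots[i1 + 1L, , drop = FALSE] +
    16L * slots[i1 + 2L, , drop = FALSE] +
    64L * slots[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)

  bim <- data.frame(sites$chrom, sites$snpid, 0L, sites$pos,
                    sites$alleleA, sites$alleleB)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam_out <- data.frame(fam$fid, fam$iid, 0L, 0L, 0L, -9L)
  write.table(fam_out, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
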