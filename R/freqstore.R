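# The frequency store: per-population allele-A counts and chromosome totals
# for an ordered set of bi-allelic SNP sites, with a four-file on-disk
# layout:
#   <prefix>_freqs.gz  gzip text, one row per site, one tab-separated
#                      "countA,total" field per population (column order =
#                      <prefix>_pop order)
#   <prefix>_pos       chrom, pos (1-based), snpid, alleleA, alleleB
#   <prefix>_chrs      chrom, first row index, last row index (1-based)
#   <prefix>_pop       population name, ploidy, n_individuals
# total = 0 encodes missing data for that population at that site.

.new_freqstore <- function(sites, pops, countA = NULL, total = NULL,
                           prefix = NULL) {
  st <- structure(list(sites = sites, pops = pops, countA = countA,
                       total = total, prefix = prefix),
                  class = "freqstore")
  .validate_freqstore(st)
  st
}

.validate_freqstore <- function(st) {
  sites <- st$sites
  stopifnot(all(c("chrom", "pos", "snpid", "alleleA", "alleleB") %in%
                  names(sites)),
            all(c("name", "ploidy", "n_ind") %in% names(st$pops)))
  if (anyDuplicated(st$pops$name)) {
    stop("duplicate population names in store", call. = FALSE)
  }
  if (!all(st$pops$ploidy %in% c("diploid", "haploid"))) {
    stop("ploidy must be 'diploid' or 'haploid'", call. = FALSE)
  }
  r <- rle(sites$chrom)
  if (anyDuplicated(r$values)) {
    stop("sites are not grouped by chromosome", call. = FALSE)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(starts)) {
    p <- sites$pos[starts[k]:ends[k]]
    if (is.unsorted(p)) {
      stop("sites on chromosome ", r$values[k],
           " are not sorted by position", call. = FALSE)
    }
  }
  if (any(sites$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  if (!is.null(st$countA)) {
    stopifnot(nrow(st$countA) == nrow(sites),
              ncol(st$countA) == nrow(st$pops),
              nrow(st$total) == nrow(sites),
              ncol(st$total) == nrow(st$pops))
    if (any(st$countA < 0L) || any(st$countA > st$total)) {
      stop("counts must satisfy 0 <= countA <= total", call. = FALSE)
    }
  }
  invisible(st)
}

#' @export
print.freqstore <- function(x, ...) {
  cat("frequency store:", nrow(x$sites), "sites,", nrow(x$pops),
      "populations\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = " "), "\n")
  cat("  populations:", paste(head(x$pops$name, 8L), collapse = " "),
      if (nrow(x$pops) > 8L) "..." else "", "\n")
  if (is.null(x$countA)) cat("  counts: on disk (", x$prefix, ")\n", sep = "")
  invisible(x)
}

# Load on-disk counts into memory if needed.
.materialize <- function(x) {
  if (is.character(x)) x <- read_freqstore(x)
  stopifnot(inherits(x, "freqstore"))
  if (is.null(x$countA)) {
    if (is.null(x$prefix)) stop("store has neither counts nor a file prefix")
    x <- read_freqstore(x$prefix)
  }
  x
}

.store_meta <- function(x) {
  if (is.character(x)) x <- read_freqstore(x, load_counts = FALSE)
  stopifnot(inherits(x, "freqstore"))
  x
}

#' Build a frequency store from a genotype panel
#'
#' Tallies, for every SNP site and every population, the number of observed
#' copies of the counted allele (bim A1) and the number of observed
#' chromosomes.  For a diploid population the total at a site is twice the
#' number of individuals with a non-missing genotype; a site where every
#' individual of a population is missing gets `countA = 0, total = 0`.
#'
#' @param panel a `plink_panel` from [read_plink()], read with a cluster
#'   file so that individuals carry population assignments.
#' @param out_prefix optional path prefix; when given the four-file store
#'   layout is written via [write_freqstore()].
#' @return a `freqstore` object (counts in memory).
#' @export
build_freqs <- function(panel, out_prefix = NULL) {
  stopifnot(inherits(panel, "plink_panel"))
  if (all(is.na(panel$ind$pop))) {
    stop("panel has no population assignments; pass a cluster file to ",
         "read_plink()", call. = FALSE)
  }
  if (anyDuplicated(panel$sites$snpid)) {
    stop("duplicate SNP ids in panel: ",
         panel$sites$snpid[anyDuplicated(panel$sites$snpid)], call. = FALSE)
  }
  pops <- panel$pop_order
  if (length(pops) == 0L) pops <- unique(panel$ind$pop)
  if (length(pops) == 0L) stop("zero populations", call. = FALSE)
  n_snp <- nrow(panel$sites)
  countA <- matrix(0L, n_snp, length(pops))
  total <- matrix(0L, n_snp, length(pops))
  n_ind <- integer(length(pops))
  for (k in seq_along(pops)) {
    idx <- which(panel$ind$pop == pops[k])
    n_ind[k] <- length(idx)
    g <- panel$geno[, idx, drop = FALSE]
    countA[, k] <- as.integer(rowSums(g, na.rm = TRUE))
    total[, k] <- 2L * as.integer(rowSums(!is.na(g)))
  }
  pops_df <- data.frame(name = pops, ploidy = "diploid", n_ind = n_ind,
                        stringsAsFactors = FALSE)
  st <- .new_freqstore(panel$sites[, c("chrom", "pos", "snpid",
                                       "alleleA", "alleleB")],
                       pops_df, countA, total)
  if (!is.null(out_prefix)) write_freqstore(st, out_prefix)
  st
}

#' Write a frequency store to its four-file layout
#'
#' @param store a `freqstore` with counts in memory.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_freqstore <- function(store, prefix) {
  store <- .materialize(store)
  fields <- matrix(paste0(store$countA, ",", store$total),
                   nrow = nrow(store$countA))
  lines <- do.call(paste, c(lapply(seq_len(ncol(fields)),
                                   function(j) fields[, j]),
                            list(sep = "\t")))
  con <- gzfile(paste0(prefix, "_freqs.gz"), "w")
  writeLines(lines, con)
  close(con)

  sites <- store$sites
  write.table(data.frame(sites$chrom, sites$pos, sites$snpid,
                         sites$alleleA, sites$alleleB),
              paste0(prefix, "_pos"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  r <- rle(sites$chrom)
  ends <- cumsum(r$lengths)
  write.table(data.frame(r$values, ends - r$lengths + 1L, ends),
              paste0(prefix, "_chrs"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(store$pops$name, store$pops$ploidy,
                         store$pops$n_ind),
              paste0(prefix, "_pop"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a frequency store
#'
#' @param prefix path prefix of the four-file layout.
#' @param load_counts if `FALSE`, only site and population metadata are
#'   loaded; counts are streamed from disk on demand (see [stream_sites()]).
#' @return a `freqstore` object.
#' @export
read_freqstore <- function(prefix, load_counts = TRUE) {
  posf <- paste0(prefix, "_pos")
  popf <- paste0(prefix, "_pop")
  chrf <- paste0(prefix, "_chrs")
  frqf <- paste0(prefix, "_freqs.gz")
  for (f in c(posf, popf, chrf, frqf)) {
    if (!file.exists(f)) stop("missing store file: ", f, call. = FALSE)
  }
  sites <- read.table(posf, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = c("character", "integer", "character",
                                     "character", "character"))
  names(sites) <- c("chrom", "pos", "snpid", "alleleA", "alleleB")
  pops <- read.table(popf, header = FALSE, stringsAsFactors = FALSE,
                     colClasses = c("character", "character", "integer"))
  names(pops) <- c("name", "ploidy", "n_ind")
  chrs <- read.table(chrf, header = FALSE, stringsAsFactors = FALSE,
                     colClasses = c("character", "integer", "integer"))
  names(chrs) <- c("chrom", "first", "last")
  if (!identical(chrs$chrom, rle(sites$chrom)$values)) {
    stop("_chrs file does not match _pos chromosome runs", call. = FALSE)
  }
  countA <- total <- NULL
  if (load_counts) {
    con <- gzfile(frqf, "r")
    lines <- readLines(con)
    close(con)
    cm <- .parse_count_lines(lines, nrow(pops))
    if (nrow(cm$countA) != nrow(sites)) {
      stop("_freqs.gz row count (", nrow(cm$countA),
           ") does not match _pos (", nrow(sites), ")", call. = FALSE)
    }
    countA <- cm$countA
    total <- cm$total
  }
  .new_freqstore(sites, pops, countA, total, prefix = prefix)
}

.parse_count_lines <- function(lines, n_pops) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_pops)
  if (length(bad)) {
    stop("frequency file row ", bad[1L], " has ", lengths(parts)[bad[1L]],
         " fields, expected ", n_pops, call. = FALSE)
  }
  v <- unlist(parts, use.names = FALSE)
  list(countA = matrix(as.integer(sub(",.*$", "", v)),
                       nrow = length(lines), ncol = n_pops, byrow = TRUE),
       total = matrix(as.integer(sub("^[^,]*,", "", v)),
                      nrow = length(lines), ncol = n_pops, byrow = TRUE))
}

# Chunked pull-style reader over a store's count rows.  Returns a function
# yielding list(index, sites, countA, total) or NULL when exhausted.  Reads
# from the gzip file when counts are not in memory, so memory use is
# bounded by the chunk size.
.chunk_reader <- function(x, chunk_size = 4096L) {
  x <- .store_meta(x)
  n_pops <- nrow(x$pops)
  if (!is.null(x$countA)) {
    i <- 0L
    n <- nrow(x$sites)
    function() {
      if (i >= n) return(NULL)
      idx <- (i + 1L):min(i + chunk_size, n)
      i <<- idx[length(idx)]
      list(index = idx,
           sites = x$sites[idx, , drop = FALSE],
           countA = x$countA[idx, , drop = FALSE],
           total = x$total[idx, , drop = FALSE])
    }
  } else {
    con <- gzfile(paste0(x$prefix, "_freqs.gz"), "r")
    done <- FALSE
    i <- 0L
    function() {
      if (done) return(NULL)
      lines <- readLines(con, n = chunk_size)
      if (length(lines) == 0L) {
        close(con)
        done <<- TRUE
        return(NULL)
      }
      cm <- .parse_count_lines(lines, n_pops)
      idx <- (i + 1L):(i + length(lines))
      i <<- idx[length(idx)]
      list(index = idx,
           sites = x$sites[idx, , drop = FALSE],
           countA = cm$countA, total = cm$total)
    }
  }
}

.resolve_pops <- function(meta, pops_needed) {
  idx <- match(pops_needed, meta$pops$name)
  if (anyNA(idx)) {
    stop("unknown population(s): ",
         paste(pops_needed[is.na(idx)], collapse = ", "),
         "; available: ", paste(meta$pops$name, collapse = ", "),
         call. = FALSE)
  }
  idx
}

# Allele-pair classifications (order-insensitive).
.pair_key <- function(a, b) paste0(pmin(a, b), pmax(a, b))
.is_transition <- function(a, b) .pair_key(a, b) %in% c("AG", "CT")
.is_strand_ambiguous <- function(a, b) .pair_key(a, b) %in% c("AT", "CG")

#' Stream usable sites from a frequency store
#'
#' Returns an iterator function yielding one site at a time: a list with
#' `site` (one-row data frame), `freq`, `countA` and `total` (named by
#' population), or `NULL` when exhausted.  Only sites where every requested
#' population has at least one observed chromosome are yielded.  With
#' `transversions_only = TRUE`, sites whose allele pair is \{C,T\} or
#' \{G,A\} are skipped; A/T and C/G pairs are transversions and are kept
#' unless `drop_strand_ambiguous` is also set.  When counts are on disk the
#' iterator reads fixed-size chunks, so memory use does not grow with the
#' number of sites.
#'
#' @param x a `freqstore` or a store prefix.
#' @param pops_needed population names that must be covered (defaults to all).
#' @param transversions_only drop transition (C/T, G/A) sites.
#' @param drop_strand_ambiguous additionally drop A/T and C/G sites.
#' @param chunk_size rows read per chunk when streaming from disk.
#' @return a zero-argument function; call repeatedly until it returns `NULL`.
#' @export
stream_sites <- function(x, pops_needed = NULL, transversions_only = FALSE,
                         drop_strand_ambiguous = FALSE, chunk_size = 4096L) {
  meta <- .store_meta(x)
  if (is.null(pops_needed)) pops_needed <- meta$pops$name
  idx <- .resolve_pops(meta, pops_needed)
  reader <- .chunk_reader(x, chunk_size)
  buf <- list()
  pos <- 0L
  function() {
    repeat {
      if (pos < length(buf)) {
        pos <<- pos + 1L
        return(buf[[pos]])
      }
      chunk <- reader()
      if (is.null(chunk)) return(NULL)
      tot <- chunk$total[, idx, drop = FALSE]
      keep <- rowSums(tot < 1L) == 0L
      a <- chunk$sites$alleleA
      b <- chunk$sites$alleleB
      if (transversions_only) keep <- keep & !.is_transition(a, b)
      if (drop_strand_ambiguous) keep <- keep & !.is_strand_ambiguous(a, b)
      w <- which(keep)
      buf <<- lapply(w, function(r) {
        ca <- chunk$countA[r, idx]
        t_ <- chunk$total[r, idx]
        list(site = chunk$sites[r, , drop = FALSE],
             freq = setNames(ca / t_, pops_needed),
             countA = setNames(as.integer(ca), pops_needed),
             total = setNames(as.integer(t_), pops_needed))
      })
      pos <<- 0L
    }
  }
}

#' Append a pseudo-haploid population to a frequency store
#'
#' Adds one haploid population whose per-site counts encode a single
#' sampled allele: call `"A"` becomes `countA = 1, total = 1`, call `"B"`
#' becomes `countA = 0, total = 1`, and a missing call (`NA`) becomes
#' `countA = 0, total = 0`.  Existing columns are unchanged.
#'
#' @param store a `freqstore` (or prefix).
#' @param new_pop name for the appended population.
#' @param calls character vector over \{`"A"`, `"B"`, `NA`\}, one per store
#'   site.
#' @param out_prefix optional prefix; when given the merged store is written.
#' @return the merged `freqstore`.
#' @export
merge_counts <- function(store, new_pop, calls, out_prefix = NULL) {
  store <- .materialize(store)
  stopifnot(is.character(new_pop), length(new_pop) == 1L)
  if (length(calls) != nrow(store$sites)) {
    stop("calls length (", length(calls), ") does not equal store site ",
         "count (", nrow(store$sites), ")", call. = FALSE)
  }
  if (new_pop %in% store$pops$name) {
    stop("population name collision: ", new_pop, call. = FALSE)
  }
  ok <- is.na(calls) | calls %in% c("A", "B")
  if (!all(ok)) {
    stop("calls must be 'A', 'B' or NA (first bad value: ",
         calls[which(!ok)[1L]], ")", call. = FALSE)
  }
  ca <- as.integer(!is.na(calls) & calls == "A")
  tot <- as.integer(!is.na(calls))
  countA <- cbind(store$countA, ca, deparse.level = 0)
  total <- cbind(store$total, tot, deparse.level = 0)
  dimnames(countA) <- dimnames(total) <- NULL
  st <- .new_freqstore(store$sites,
                       rbind(store$pops,
                             data.frame(name = new_pop, ploidy = "haploid",
                                        n_ind = 1L)),
                       countA, total)
  if (!is.null(out_prefix)) write_freqstore(st, out_prefix)
  st
}
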