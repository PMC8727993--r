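# treemix export: per-population "countA,countB" rows, space-separated,
# gzip-compressed, with a population-name header.

#' Convert a frequency store to treemix input files
#'
#' Writes two gzip text files: `<out_prefix>_ALL_tm.gz` with every retained
#' site and `<out_prefix>_TV_tm.gz` restricted to transversion
#' polymorphisms (C/T and G/A allele pairs removed — useful for ancient
#' DNA).  Each row holds one `countA,countB` field per selected population
#' (`countB = total - countA`); treemix has no missing-data code, so sites
#' where any selected population has no observed chromosomes are dropped
#' from both files.
#'
#' @param store a `freqstore` or store prefix.
#' @param pops_of_interest either a character vector of population names or
#'   the path of a file listing one population per line; output column
#'   order follows it.
#' @param out_prefix output path prefix.
#' @return invisibly, a list with the two file paths (`all`, `tv`) and the
#'   number of sites written to each (`n_all`, `n_tv`).
#' @export
freqs_to_treemix <- function(store, pops_of_interest, out_prefix) {
  store <- .materialize(store)
  poi <- pops_of_interest
  if (length(poi) == 1L && file.exists(poi)) {
    poi <- readLines(poi)
    poi <- trimws(poi)
    poi <- poi[nzchar(poi)]
  }
  idx <- .resolve_pops(store, poi)
  ca <- store$countA[, idx, drop = FALSE]
  tot <- store$total[, idx, drop = FALSE]
  keep <- rowSums(tot < 1L) == 0L
  tv <- keep & !.is_transition(store$sites$alleleA, store$sites$alleleB)

  header <- paste(poi, collapse = " ")
  fields <- matrix(paste0(ca, ",", tot - ca), nrow = nrow(ca))
  body <- do.call(paste, c(lapply(seq_len(ncol(fields)),
                                  function(j) fields[, j]),
                           list(sep = " ")))
  write_one <- function(path, rows) {
    con <- gzfile(path, "w")
    writeLines(c(header, body[rows]), con)
    close(con)
    sum(rows)
  }
  f_all <- paste0(out_prefix, "_ALL_tm.gz")
  f_tv <- paste0(out_prefix, "_TV_tm.gz")
  n_all <- write_one(f_all, keep)
  n_tv <- write_one(f_tv, tv)
  invisible(list(all = f_all, tv = f_tv, n_all = n_all, n_tv = n_tv))
}
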