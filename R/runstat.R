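# Single-statistic drivers: one streaming pass over the site counts,
# per-site kernel -> per-block sums -> weighted block jackknife.  The
# automated wrappers enumerate a free slot over all store populations.

.KINDS <- c("dist", "f3", "f4", "d", "f4ratio", "corrected_f4",
            "enhanced_d", "mac_d")

.kind_slots <- function(kind) {
  switch(kind,
         dist = c("h1", "h2"),
         f3 = c("target", "h1", "h2"),
         f4 = c("h1", "h2", "h3", "h4"),
         d = c("h1", "h2", "h3", "h4"),
         enhanced_d = c("h1", "h2", "h3", "h4"),
         mac_d = c("h1", "h2", "h3", "h4"),
         f4ratio = c("h1", "h2", "h3", "h4", "x"),
         corrected_f4 = c("h1", "h2", "h3", "h4", "x"))
}

.stat_label <- function(kind, s) {
  switch(kind,
         dist = sprintf("dist(%s,%s)", s$h1, s$h2),
         f3 = sprintf("f3(%s;%s,%s)", s$target, s$h1, s$h2),
         f4 = sprintf("f4(%s,%s;%s,%s)", s$h1, s$h2, s$h3, s$h4),
         d = sprintf("D(%s,%s;%s,%s)", s$h1, s$h2, s$h3, s$h4),
         enhanced_d = sprintf("Denh(%s,%s;%s,%s)", s$h1, s$h2, s$h3, s$h4),
         mac_d = sprintf("Dmac(%s,%s;%s,%s|%s)", s$h1, s$h2, s$h3, s$h4,
                         s$strat_pop),
         f4ratio = sprintf("f4ratio(%s,%s;%s,%s|%s)", s$h1, s$h2, s$h3,
                           s$h4, s$x),
         corrected_f4 = sprintf("corrf4(%s,%s;%s,%s|%s)", s$h1, s$h2, s$h3,
                                s$h4, s$x))
}

#' Describe a statistic to compute
#'
#' Bundles a statistic kind, its population slots and its options.  Slots
#' by kind: `dist` uses `h1`, `h2`; `f3` uses `target` (the population whose
#' drift is measured, e.g. the outgroup in an outgroup-f3) plus `h1`, `h2`;
#' `f4`/`d`/`enhanced_d`/`mac_d` use `h1`..`h4`; `f4ratio` and
#' `corrected_f4` additionally use `x` (the denominator's substitute for
#' `h3`, respectively the admixture proxy replacing `h2`).
#'
#' @param kind one of `r paste0('"', .KINDS, '"', collapse = ", ")`.
#' @param h1,h2,h3,h4,target,x population names as required by `kind`.
#' @param transversions_only restrict to transversion sites.
#' @param drop_strand_ambiguous additionally drop A/T and C/G sites.
#' @param correct f3 finite-sample bias correction (diploid targets only).
#' @param minp,maxp,pstep admixture-proportion grid for `corrected_f4`
#'   (endpoints inclusive).
#' @param strat_pop population whose minor-allele count stratifies `mac_d`.
#' @param mac_range optional integer vector of minor-allele counts to keep.
#' @param ascertainment list of `list(pop =, fixed = "A"|"B", min_total =)`
#'   entries for `enhanced_d` (see [ascertain_enhanced()]).
#' @param block_span_bp jackknife block length in bp (default 5 Mb).
#' @param block_n_sites optional fixed number of usable sites per block.
#' @return a `stat_request`.
#' @export
stat_request <- function(kind, h1 = NULL, h2 = NULL, h3 = NULL, h4 = NULL,
                         target = NULL, x = NULL,
                         transversions_only = FALSE,
                         drop_strand_ambiguous = FALSE,
                         correct = FALSE,
                         minp = 0, maxp = 0.5, pstep = 0.025,
                         strat_pop = NULL, mac_range = NULL,
                         ascertainment = NULL,
                         block_span_bp = 5e6, block_n_sites = NULL) {
  kind <- match.arg(kind, .KINDS)
  req <- list(kind = kind, h1 = h1, h2 = h2, h3 = h3, h4 = h4,
              target = target, x = x,
              transversions_only = isTRUE(transversions_only),
              drop_strand_ambiguous = isTRUE(drop_strand_ambiguous),
              correct = isTRUE(correct),
              minp = minp, maxp = maxp, pstep = pstep,
              strat_pop = strat_pop, mac_range = mac_range,
              ascertainment = ascertainment,
              block_span_bp = block_span_bp, block_n_sites = block_n_sites)
  missing <- .kind_slots(kind)[vapply(req[.kind_slots(kind)], is.null, TRUE)]
  if (length(missing)) {
    stop(kind, " requires slot(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (kind == "mac_d" && is.null(req$strat_pop)) {
    stop("mac_d requires strat_pop", call. = FALSE)
  }
  if (kind == "enhanced_d" &&
      (is.null(req$ascertainment) || !length(req$ascertainment))) {
    stop("enhanced_d requires an ascertainment scheme", call. = FALSE)
  }
  if (kind == "corrected_f4") {
    if (!(minp >= 0 && minp <= maxp && maxp < 1 && pstep > 0)) {
      stop("grid must satisfy 0 <= minp <= maxp < 1 and pstep > 0",
           call. = FALSE)
    }
  }
  structure(req, class = "stat_request")
}

.c_grid <- function(minp, maxp, pstep) {
  v <- seq(minp, maxp + pstep * 1e-8, by = pstep)
  v[v <= maxp + pstep * 1e-8]
}

#' Compute one statistic from a frequency store
#'
#' Streams the store once: usable sites (all involved populations covered,
#' optional transversion/ascertainment filters) feed the per-site kernel;
#' per-site terms are summed within genomic blocks; the weighted block
#' jackknife yields the estimate, standard error and Z-score.  For
#' `corrected_f4` the whole admixture-proportion grid reuses a single
#' pass's block sums; for `mac_d` a single pass bins blocks per
#' minor-allele-count stratum.
#'
#' @param store a `freqstore` or store prefix.
#' @param req a [stat_request()].
#' @return an `afstat` for single statistics; a `stat_table` data frame
#'   (one row per grid value or stratum) for `corrected_f4` and `mac_d`.
#' @export
run_stat <- function(store, req) {
  stopifnot(inherits(req, "stat_request"))
  meta <- .store_meta(store)
  kind <- req$kind
  slotnames <- .kind_slots(kind)
  slots <- req[slotnames]

  cover <- unlist(slots, use.names = FALSE)
  if (kind == "mac_d") cover <- c(cover, req$strat_pop)
  asc_pops <- character(0)
  if (kind == "enhanced_d") {
    asc_pops <- vapply(req$ascertainment, function(e) e$pop, "")
  }
  cover <- unique(c(cover, asc_pops))
  .resolve_pops(meta, cover)                 # fail fast on unknown names
  pop_index <- function(nm) match(nm, meta$pops$name)

  if (kind == "f3" && req$correct) {
    pl <- meta$pops$ploidy[pop_index(req$target)]
    if (pl != "diploid") {
      stop("f3 bias correction is invalid for a ", pl,
           " (pseudo-haploid) target", call. = FALSE)
    }
  }

  chrom_levels <- unique(meta$sites$chrom)
  cover_idx <- pop_index(cover)
  use_span <- is.null(req$block_n_sites)
  chrom_counter <- new.env(parent = emptyenv())
  reader <- .chunk_reader(store)
  acc <- list()

  repeat {
    chunk <- reader()
    if (is.null(chunk)) break
    tot <- chunk$total[, cover_idx, drop = FALSE]
    usable <- rowSums(tot < 1L) == 0L
    a <- chunk$sites$alleleA
    b <- chunk$sites$alleleB
    if (req$transversions_only) usable <- usable & !.is_transition(a, b)
    if (req$drop_strand_ambiguous) {
      usable <- usable & !.is_strand_ambiguous(a, b)
    }
    if (kind == "enhanced_d") {
      ai <- pop_index(asc_pops)
      usable <- usable & ascertain_enhanced(
        chunk$countA[, ai, drop = FALSE], chunk$total[, ai, drop = FALSE],
        req$ascertainment)
    }
    w <- which(usable)
    if (length(w) == 0L) next

    pfreq <- function(nm) {
      j <- pop_index(nm)
      chunk$countA[w, j] / chunk$total[w, j]
    }
    term2 <- NULL
    term <- switch(kind,
      dist = site_dist(pfreq(req$h1), pfreq(req$h2)),
      f3 = site_f3(pfreq(req$target), pfreq(req$h1), pfreq(req$h2),
                   n_t = chunk$total[w, pop_index(req$target)],
                   correct = req$correct),
      f4 = site_f4(pfreq(req$h1), pfreq(req$h2), pfreq(req$h3),
                   pfreq(req$h4)),
      d = ,
      enhanced_d = ,
      mac_d = site_d(pfreq(req$h1), pfreq(req$h2), pfreq(req$h3),
                     pfreq(req$h4)),
      f4ratio = {
        term2 <- site_f4(pfreq(req$h1), pfreq(req$h2), pfreq(req$x),
                         pfreq(req$h4))
        site_f4(pfreq(req$h1), pfreq(req$h2), pfreq(req$h3), pfreq(req$h4))
      },
      corrected_f4 = {
        term2 <- site_f4(pfreq(req$h1), pfreq(req$x), pfreq(req$h3),
                         pfreq(req$h4))
        site_f4(pfreq(req$h1), pfreq(req$h2), pfreq(req$h3), pfreq(req$h4))
      })

    chroms <- chunk$sites$chrom[w]
    chri <- match(chroms, chrom_levels)
    if (use_span) {
      bidx <- as.integer(floor((chunk$sites$pos[w] - 1) /
                                 req$block_span_bp))
    } else {
      # running ordinal of usable sites within each chromosome
      bidx <- integer(length(w))
      rr <- rle(chroms)
      e2 <- cumsum(rr$lengths)
      s2 <- e2 - rr$lengths + 1L
      for (k in seq_along(s2)) {
        cn <- rr$values[k]
        start <- if (is.null(chrom_counter[[cn]])) 0L else chrom_counter[[cn]]
        ord <- start + seq_len(rr$lengths[k]) - 1L
        chrom_counter[[cn]] <- start + rr$lengths[k]
        bidx[s2[k]:e2[k]] <- ord %/% req$block_n_sites
      }
    }
    bkey <- sprintf("%06d.%010d", chri, bidx)
    stratum <- rep(NA_integer_, length(w))
    if (kind == "mac_d") {
      j <- pop_index(req$strat_pop)
      stratum <- mac_stratum(chunk$countA[w, j], chunk$total[w, j])
      if (!is.null(req$mac_range)) {
        keep <- stratum %in% req$mac_range
        if (!any(keep)) next
        bkey <- bkey[keep]; stratum <- stratum[keep]
        term$num <- term$num[keep]; term$den <- term$den[keep]
        w <- w[keep]
      }
    }
    mat <- cbind(num = term$num, den = term$den, m = 1,
                 num2 = if (is.null(term2)) 0 else term2$num)
    grp <- paste(bkey, stratum)
    sums <- rowsum(mat, group = grp)
    first <- !duplicated(grp)
    acc[[length(acc) + 1L]] <- data.frame(
      grp = rownames(sums), bkey = bkey[first][order(grp[first])],
      stratum = stratum[first][order(grp[first])],
      sums, stringsAsFactors = FALSE, row.names = NULL)
  }

  if (length(acc) == 0L) {
    stop("no usable sites for ", .stat_label(kind, req), call. = FALSE)
  }
  all_ <- do.call(rbind, acc)
  sums <- rowsum(as.matrix(all_[, c("num", "den", "m", "num2")]),
                 group = all_$grp)
  first <- !duplicated(all_$grp)
  info <- all_[first, c("grp", "bkey", "stratum")]
  info <- info[match(rownames(sums), info$grp), ]
  ord <- order(info$bkey, info$stratum)
  sums <- sums[ord, , drop = FALSE]
  info <- info[ord, , drop = FALSE]
  label <- .stat_label(kind, req)

  if (kind %in% c("dist", "f3", "f4")) {
    return(weighted_jackknife(sums[, "num"], sums[, "m"], sums[, "m"],
                              label = label))
  }
  if (kind %in% c("d", "enhanced_d")) {
    return(weighted_jackknife(sums[, "num"], sums[, "den"], sums[, "m"],
                              label = label))
  }
  if (kind == "f4ratio") {
    return(ratio_of_stats(sums[, "num"], sums[, "num2"], sums[, "m"],
                          label = label))
  }
  if (kind == "corrected_f4") {
    grid <- .c_grid(req$minp, req$maxp, req$pstep)
    rows <- lapply(grid, function(cc) {
      res <- weighted_jackknife(
        corrected_f4(sums[, "num"], sums[, "num2"], cc),
        sums[, "m"], sums[, "m"], label = label)
      cbind(data.frame(c = cc), as.data.frame(res))
    })
    tab <- do.call(rbind, rows)
    class(tab) <- c("stat_table", "data.frame")
    attr(tab, "free_col") <- "c"
    return(tab)
  }
  # mac_d: one jackknife per minor-allele-count stratum
  strata <- sort(unique(info$stratum))
  rows <- list()
  for (s in strata) {
    sel <- info$stratum == s
    if (sum(sel) < 2L) {
      warning("MAC stratum ", s, " spans fewer than two blocks; dropped",
              call. = FALSE)
      next
    }
    res <- weighted_jackknife(sums[sel, "num"], sums[sel, "den"],
                              sums[sel, "m"], label = label)
    rows[[length(rows) + 1L]] <- cbind(data.frame(stratum = s),
                                       as.data.frame(res))
  }
  if (!length(rows)) stop("no MAC stratum spans two blocks", call. = FALSE)
  tab <- do.call(rbind, rows)
  class(tab) <- c("stat_table", "data.frame")
  attr(tab, "free_col") <- "stratum"
  tab
}

.result_row <- function(res, slots) {
  sl <- as.data.frame(slots[!vapply(slots, is.null, TRUE)],
                      stringsAsFactors = FALSE)
  if (inherits(res, "afstat")) {
    cbind(as.data.frame(res)["label"], sl,
          as.data.frame(res)[c("estimate", "se", "z", "n_sites",
                               "n_blocks")])
  } else {
    cbind(res["label"], sl, res[setdiff(names(res), "label")])
  }
}

#' Enumerate a statistic over all candidate populations
#'
#' Computes one statistic per population `X` in the store, with the other
#' slots fixed: the automated counterpart of running [run_stat()] in a
#' loop.  Candidates are all store populations minus the fixed slots and
#' the exclude list, in store order; results are independent of `nthr`
#' (parallel runs return exactly the serial table).
#'
#' @param store a `freqstore` or prefix.
#' @param kind statistic kind (see [stat_request()]).
#' @param fixed named list of fixed slot values, e.g.
#'   `list(h1 = "Pop1", h4 = "Out")`.
#' @param free_slot name of the enumerated slot (`"h2"`, `"h3"`, ...).
#' @param exclude additional population names to skip.
#' @param nthr number of worker processes.
#' @param ... further options passed to [stat_request()].
#' @return a `stat_table` data frame, one row per candidate.
#' @export
enumerate_fixed <- function(store, kind, fixed, free_slot,
                            exclude = character(0), nthr = 1L, ...) {
  store <- .materialize(store)
  fixed_vals <- unlist(fixed, use.names = FALSE)
  if (anyDuplicated(fixed_vals)) {
    stop("fixed slot populations must be distinct", call. = FALSE)
  }
  stopifnot(free_slot %in% .kind_slots(kind))
  .resolve_pops(store, fixed_vals)
  candidates <- setdiff(store$pops$name, c(fixed_vals, exclude))
  if (length(candidates) < 1L) {
    stop("no candidate populations left to enumerate", call. = FALSE)
  }
  worker <- function(p) {
    args <- c(list(kind = kind), fixed, setNames(list(p), free_slot),
              list(...))
    res <- run_stat(store, do.call(stat_request, args))
    row <- .result_row(res, c(fixed, setNames(list(p), free_slot)))
    row
  }
  res <- if (nthr > 1L) {
    parallel::mclapply(candidates, worker, mc.cores = nthr)
  } else {
    lapply(candidates, worker)
  }
  err <- vapply(res, inherits, TRUE, "try-error")
  if (any(err)) {
    stop("enumeration failed for ", candidates[which(err)[1L]], ": ",
         attr(res[[which(err)[1L]]], "condition")$message, call. = FALSE)
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  class(tab) <- c("stat_table", "data.frame")
  attr(tab, "free_col") <- free_slot
  tab
}

#' Write a result table as tab-separated text
#'
#' @param tab a `stat_table`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_result_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.auto_out <- function(out_prefix, kind, slots) {
  paste(out_prefix, kind,
        paste(unlist(slots, use.names = FALSE), collapse = "_"), sep = "_")
}

.auto_finish <- function(tab, kind, slots, out_prefix, catfile, legfile,
                         multiplier, annotate_z, sort_by_estimate = TRUE) {
  if (!is.null(out_prefix)) {
    base <- .auto_out(out_prefix, kind, slots)
    write_result_table(tab, paste0(base, ".tsv"))
    emit_plot(tab, catfile = catfile, legfile = legfile,
              error_bar_multiplier = multiplier, out_prefix = base,
              annotate_z = annotate_z, sort_by_estimate = sort_by_estimate)
  }
  tab
}

#' Automated f3 wrapper: f3(target; h1, X) for every X
#'
#' @param store a `freqstore` or prefix.
#' @param h1 fixed reference population.
#' @param target f3 target population (e.g. the outgroup).
#' @param exclude populations to skip.
#' @param nthr worker processes.
#' @param catfile,legfile optional plot category/legend files
#'   (see [emit_plot()]).
#' @param out_prefix when given, writes `<base>.tsv`, `<base>.pdf` and
#'   `<base>.plotspec`.
#' @param ... options passed to [stat_request()].
#' @return a `stat_table`.
#' @export
auto_f3 <- function(store, h1, target, exclude = character(0), nthr = 1L,
                    catfile = NULL, legfile = NULL, out_prefix = NULL, ...) {
  tab <- enumerate_fixed(store, "f3", list(h1 = h1, target = target),
                         "h2", exclude = exclude, nthr = nthr, ...)
  .auto_finish(tab, "f3", list(h1, target), out_prefix, catfile, legfile,
               multiplier = 1.96, annotate_z = FALSE)
}

#' Automated pairwise-distance wrapper: dist(h1, X) for every X
#'
#' @inheritParams auto_f3
#' @return a `stat_table`.
#' @export
auto_dist <- function(store, h1, exclude = character(0), nthr = 1L,
                      catfile = NULL, legfile = NULL, out_prefix = NULL,
                      ...) {
  tab <- enumerate_fixed(store, "dist", list(h1 = h1), "h2",
                         exclude = exclude, nthr = nthr, ...)
  .auto_finish(tab, "dist", list(h1), out_prefix, catfile, legfile,
               multiplier = 1.96, annotate_z = FALSE)
}

#' Automated D wrapper: D(h1, h2; X, h4) for every X
#'
#' @inheritParams auto_f3
#' @param h2,h4 the remaining fixed slots.
#' @return a `stat_table`.
#' @export
auto_d <- function(store, h1, h2, h4, exclude = character(0), nthr = 1L,
                   catfile = NULL, legfile = NULL, out_prefix = NULL, ...) {
  tab <- enumerate_fixed(store, "d", list(h1 = h1, h2 = h2, h4 = h4),
                         "h3", exclude = exclude, nthr = nthr, ...)
  .auto_finish(tab, "d", list(h1, h2, h4), out_prefix, catfile, legfile,
               multiplier = 3.3, annotate_z = TRUE)
}

#' Automated f4 wrapper: f4(h1, h2; X, h4) for every X
#'
#' @inheritParams auto_d
#' @return a `stat_table`.
#' @export
auto_f4 <- function(store, h1, h2, h4, exclude = character(0), nthr = 1L,
                    catfile = NULL, legfile = NULL, out_prefix = NULL, ...) {
  tab <- enumerate_fixed(store, "f4", list(h1 = h1, h2 = h2, h4 = h4),
                         "h3", exclude = exclude, nthr = nthr, ...)
  .auto_finish(tab, "f4", list(h1, h2, h4), out_prefix, catfile, legfile,
               multiplier = 3.3, annotate_z = TRUE)
}

#' Automated enhanced-D wrapper: ascertained D(h1, h2; X, h4) for every X
#'
#' @inheritParams auto_d
#' @param ascertainment scheme list, see [ascertain_enhanced()].
#' @return a `stat_table`.
#' @export
auto_enhd <- function(store, h1, h2, h4, ascertainment,
                      exclude = character(0), nthr = 1L, catfile = NULL,
                      legfile = NULL, out_prefix = NULL, ...) {
  asc_pops <- vapply(ascertainment, function(e) e$pop, "")
  tab <- enumerate_fixed(store, "enhanced_d",
                         list(h1 = h1, h2 = h2, h4 = h4), "h3",
                         exclude = unique(c(exclude, asc_pops)),
                         nthr = nthr, ascertainment = ascertainment, ...)
  .auto_finish(tab, "enhd", list(h1, h2, h4), out_prefix, catfile, legfile,
               multiplier = 3.3, annotate_z = TRUE)
}

#' Admixture-corrected f4 over a proportion grid
#'
#' Computes `(f4(h1,h2;h3,h4) - c * f4(h1,x;h3,h4)) / (1 - c)` for every
#' `c` in `minp, minp + pstep, ..., <= maxp`, reusing one pass's block sums.
#'
#' @inheritParams auto_f3
#' @param h1,h2,h3,h4 f4 slots; `x` is the admixture proxy replacing `h2`.
#' @param x admixture/contamination proxy population.
#' @param minp,maxp,pstep the proportion grid.
#' @return a `stat_table` with a `c` column.
#' @export
auto_corrf4 <- function(store, h1, h2, h3, h4, x, minp = 0, maxp = 0.5,
                        pstep = 0.025, catfile = NULL, legfile = NULL,
                        out_prefix = NULL, ...) {
  req <- stat_request("corrected_f4", h1 = h1, h2 = h2, h3 = h3, h4 = h4,
                      x = x, minp = minp, maxp = maxp, pstep = pstep, ...)
  tab <- run_stat(store, req)
  .auto_finish(tab, "corrf4", list(h1, h2, h3, h4, x), out_prefix, catfile,
               legfile, multiplier = 3.3, annotate_z = TRUE,
               sort_by_estimate = FALSE)
}

#' Minor-allele-count-stratified D
#'
#' Computes D(h1, h2; h3, h4) separately within strata of the minor-allele
#' count of `strat_pop`, in one pass.
#'
#' @inheritParams auto_corrf4
#' @param strat_pop stratifying population.
#' @param mac_range optional integer vector of counts to keep.
#' @return a `stat_table` with a `stratum` column.
#' @export
auto_macd <- function(store, h1, h2, h3, h4, strat_pop, mac_range = NULL,
                      catfile = NULL, legfile = NULL, out_prefix = NULL,
                      ...) {
  req <- stat_request("mac_d", h1 = h1, h2 = h2, h3 = h3, h4 = h4,
                      strat_pop = strat_pop, mac_range = mac_range, ...)
  tab <- run_stat(store, req)
  .auto_finish(tab, "macd", list(h1, h2, h3, h4, strat_pop), out_prefix,
               catfile, legfile, multiplier = 3.3, annotate_z = TRUE,
               sort_by_estimate = FALSE)
}
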