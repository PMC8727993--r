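# Genomic blocking and the weighted block jackknife for ratio-of-sums
# statistics.

#' Assign sorted sites to contiguous genomic blocks
#'
#' Blocks are windows of `block_span_bp` base pairs within a chromosome
#' (boundaries at `floor((pos - 1) / block_span_bp)`); blocks never span
#' chromosomes, and windows containing no usable site are dropped, so `g`
#' counts only non-empty blocks.  For panels without meaningful physical
#' positions, `block_n_sites` switches to fixed-size site-count blocks
#' within each chromosome.
#'
#' @param chrom chromosome label per usable site (grouped).
#' @param pos 1-based position per usable site (sorted within chromosome).
#' @param block_span_bp block length in base pairs (default 5 Mb).
#' @param block_n_sites optional: sites per block instead of a physical span.
#' @return a `block_table`: list with `block` (dense 1..g id per site), `m`
#'   (per-block site counts), `g` and `n`.
#' @export
assign_blocks <- function(chrom, pos, block_span_bp = 5e6,
                          block_n_sites = NULL) {
  stopifnot(length(chrom) == length(pos))
  if (length(pos) == 0L) stop("no usable sites to block", call. = FALSE)
  r <- rle(as.character(chrom))
  if (anyDuplicated(r$values)) {
    stop("sites are not grouped by chromosome", call. = FALSE)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  within <- integer(length(pos))
  for (k in seq_along(starts)) {
    span <- starts[k]:ends[k]
    p <- pos[span]
    if (is.unsorted(p)) {
      stop("positions on chromosome ", r$values[k], " are not sorted",
           call. = FALSE)
    }
    if (is.null(block_n_sites)) {
      stopifnot(block_span_bp > 0)
      within[span] <- floor((p - 1) / block_span_bp)
    } else {
      stopifnot(block_n_sites >= 1L)
      within[span] <- (seq_along(span) - 1L) %/% block_n_sites
    }
  }
  key <- paste(rep(seq_along(r$values), r$lengths), within)
  id <- match(key, unique(key))
  m <- tabulate(id)
  structure(list(block = id, m = m, g = length(m), n = length(id)),
            class = "block_table")
}

#' Weighted block-jackknife estimate for a ratio of sums
#'
#' For a statistic of the form `theta = sum(N_j) / sum(D_j)` over `g`
#' genomic blocks with weights `m_j` (usable sites per block), computes the
#' delete-one-block estimates `theta_(-j)`, the bias-corrected estimate and
#' the weighted jackknife standard error with `h_j = n / m_j`:
#' \deqn{\tilde\theta = g\hat\theta - \sum_j (1 - 1/h_j)\,\hat\theta_{(-j)}}
#' \deqn{se^2 = \frac{1}{g} \sum_j \frac{(h_j\hat\theta - (h_j - 1)
#'   \hat\theta_{(-j)} - \tilde\theta)^2}{h_j - 1}}
#' With equal weights this reduces to the classical delete-one block
#' jackknife.  A block whose removal would zero the denominator is merged
#' into its neighbour (with a message).
#'
#' @param N,D per-block numerator and denominator sums.
#' @param m per-block usable-site counts.
#' @param label descriptive label carried into the result.
#' @return an `afstat`: list with `estimate`, `se`, `z`, `n_sites`,
#'   `n_blocks`, `label`.
#' @export
weighted_jackknife <- function(N, D, m, label = "") {
  stopifnot(length(N) == length(D), length(D) == length(m))
  if (length(m) < 2L) stop("need at least two blocks", call. = FALSE)
  if (sum(D) == 0) {
    stop("statistic denominator is zero over all usable sites",
         call. = FALSE)
  }
  repeat {
    bad <- which(sum(D) - D == 0)
    if (length(bad) == 0L) break
    if (length(N) <= 2L) {
      stop("cannot jackknife: removing a block zeroes the denominator and ",
           "fewer than two blocks would remain after merging", call. = FALSE)
    }
    j <- bad[1L]
    k <- if (j == 1L) 2L else j - 1L
    message("block ", j, " merged into its neighbour: leave-one-out ",
            "denominator would be zero")
    N[k] <- N[k] + N[j]
    D[k] <- D[k] + D[j]
    m[k] <- m[k] + m[j]
    N <- N[-j]; D <- D[-j]; m <- m[-j]
  }
  g <- length(m)
  n <- sum(m)
  theta <- sum(N) / sum(D)
  theta_j <- (sum(N) - N) / (sum(D) - D)
  h <- n / m
  theta_tilde <- g * theta - sum((1 - 1 / h) * theta_j)
  pseudo <- h * theta - (h - 1) * theta_j
  se <- sqrt(mean((pseudo - theta_tilde)^2 / (h - 1)))
  z <- if (se > 0) theta / se else if (theta == 0) 0 else sign(theta) * Inf
  structure(list(estimate = theta, se = se, z = z,
                 n_sites = n, n_blocks = g, label = label),
            class = "afstat")
}

#' Jackknife for a ratio of two statistics sharing one block table
#'
#' Applies the weighted block jackknife to `theta = sum(num) / sum(den)`
#' where `num` and `den` are per-block numerator sums of two statistics
#' computed on the same usable-site set, deleting each block from both
#' simultaneously.  Used for f4-ratios.
#'
#' @param num_blocks,den_blocks per-block numerator sums of the two
#'   statistics.
#' @param m shared per-block usable-site counts.
#' @param label descriptive label.
#' @return an `afstat`.
#' @export
ratio_of_stats <- function(num_blocks, den_blocks, m, label = "") {
  if (sum(den_blocks) == 0) {
    stop("denominator statistic sums to zero across blocks", call. = FALSE)
  }
  weighted_jackknife(num_blocks, den_blocks, m, label = label)
}

#' @export
print.afstat <- function(x, ...) {
  cat(if (nzchar(x$label)) x$label else "statistic", "\n")
  cat(sprintf("  estimate %.6g  se %.6g  Z %.3f  (%d sites, %d blocks)\n",
              x$estimate, x$se, x$z, x$n_sites, x$n_blocks))
  invisible(x)
}

#' @export
as.data.frame.afstat <- function(x, ...) {
  data.frame(label = x$label, estimate = x$estimate, se = x$se, z = x$z,
             n_sites = x$n_sites, n_blocks = x$n_blocks,
             stringsAsFactors = FALSE)
}
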