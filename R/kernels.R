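# Per-site numeric kernels.  Each returns a list with vectors `num` and
# `den`: the statistic's point estimate is sum(num)/sum(den) over usable
# sites, and the same per-site terms feed the block jackknife.  All kernels
# are invariant to relabeling both alleles at a site (p -> 1 - p in every
# population simultaneously).

#' Per-site pairwise-distance term
#'
#' The probability that two chromosomes, one drawn from each population,
#' carry different alleles: `p1(1-p2) + p2(1-p1)`.
#'
#' @param p1,p2 allele-A frequencies in \[0, 1\] (vectorized).
#' @return list with `num` and `den` (den is 1 per site).
#' @export
site_dist <- function(p1, p2) {
  list(num = p1 * (1 - p2) + p2 * (1 - p1), den = rep(1, length(p1)))
}

#' Per-site f4 term
#'
#' `(p1 - p2)(p3 - p4)`, the covariance term underlying the four-population
#' test.  Antisymmetric under swapping h1 with h2 or h3 with h4.
#'
#' @param p1,p2,p3,p4 allele-A frequencies (vectorized).
#' @return list with `num` and `den` (den is 1 per site).
#' @export
site_f4 <- function(p1, p2, p3, p4) {
  list(num = (p1 - p2) * (p3 - p4), den = rep(1, length(p1)))
}

#' Per-site D-statistic terms
#'
#' Numerator `(p1 - p2)(p3 - p4)` equals the expected BABA minus ABBA
#' probability when one chromosome is drawn per population; the denominator
#' `(p1 + p2 - 2 p1 p2)(p3 + p4 - 2 p3 p4)` equals the expected ABBA plus
#' BABA probability.  D = sum(num)/sum(den) lies in \[-1, 1\] whenever the
#' summed denominator is positive.
#'
#' @param p1,p2,p3,p4 allele-A frequencies (vectorized).
#' @return list with `num` and `den`.
#' @export
site_d <- function(p1, p2, p3, p4) {
  list(num = (p1 - p2) * (p3 - p4),
       den = (p1 + p2 - 2 * p1 * p2) * (p3 + p4 - 2 * p3 * p4))
}

#' Per-site f3 term
#'
#' `(pt - pa)(pt - pb)`, the shared-drift statistic of the target relative
#' to references A and B (symmetric in A and B).  With `correct = TRUE`
#' the finite-sample bias of using the sample frequency of the target is
#' removed by subtracting `pt(1-pt)/(n_t - 1)`, where `n_t` is the number
#' of chromosomes observed in the target at the site.  The correction is
#' only valid for diploid targets and requires `n_t >= 2`.
#'
#' @param pt target allele-A frequency (vectorized).
#' @param pa,pb reference frequencies.
#' @param n_t target chromosome counts (required when `correct = TRUE`).
#' @param correct apply the finite-sample bias correction.
#' @return list with `num` and `den` (den is 1 per site).
#' @export
site_f3 <- function(pt, pa, pb, n_t = NULL, correct = FALSE) {
  num <- (pt - pa) * (pt - pb)
  if (correct) {
    if (is.null(n_t)) stop("n_t is required when correct = TRUE")
    if (any(n_t < 2L)) {
      stop("f3 bias correction requires at least 2 chromosomes in the ",
           "target at every usable site", call. = FALSE)
    }
    num <- num - pt * (1 - pt) / (n_t - 1)
  }
  list(num = num, den = rep(1, length(pt)))
}

#' Ascertainment predicate for enhanced D-statistics
#'
#' A site passes when every ascertainment population is fixed for its
#' required allele with at least the required number of observed
#' chromosomes.  "Fixed for A" means `countA == total`; "fixed for B"
#' means `countA == 0`.
#'
#' @param countA,total matrices (sites x ascertainment populations) whose
#'   column order matches `scheme`.
#' @param scheme list of entries `list(pop =, fixed = "A"|"B",
#'   min_total = )`.
#' @return logical vector, one element per site.
#' @export
ascertain_enhanced <- function(countA, total, scheme) {
  countA <- as.matrix(countA)
  total <- as.matrix(total)
  stopifnot(length(scheme) == ncol(countA), ncol(countA) == ncol(total))
  ok <- rep(TRUE, nrow(countA))
  for (k in seq_along(scheme)) {
    s <- scheme[[k]]
    stopifnot(s$fixed %in% c("A", "B"))
    min_total <- if (is.null(s$min_total)) 1L else s$min_total
    fixed <- if (s$fixed == "A") countA[, k] == total[, k]
             else countA[, k] == 0L
    ok <- ok & fixed & total[, k] >= min_total
  }
  ok
}

#' Minor-allele count of a site
#'
#' @param countA observed copies of allele A.
#' @param total observed chromosomes.
#' @return `min(countA, total - countA)`, vectorized.
#' @export
mac_stratum <- function(countA, total) {
  pmin(countA, total - countA)
}

#' Admixture/contamination-corrected f4 block sums
#'
#' Given per-block numerator sums of an observed f4 and of a proxy f4
#' computed on the identical usable-site set, returns the per-block
#' numerators of `(f4_obs - c * f4_proxy) / (1 - c)`; denominators (site
#' counts) are unchanged, so the correction composes with the weighted
#' block jackknife.
#'
#' @param num_obs,num_proxy per-block numerator sums (equal length).
#' @param c assumed admixture/contamination proportion, `0 <= c < 1`.
#' @return corrected per-block numerator sums.
#' @export
corrected_f4 <- function(num_obs, num_proxy, c) {
  stopifnot(length(num_obs) == length(num_proxy), length(c) == 1L)
  if (c < 0 || c >= 1) stop("admixture proportion c must satisfy 0 <= c < 1",
                            call. = FALSE)
  (num_obs - c * num_proxy) / (1 - c)
}
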