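# Synthetic-data generators: allele-frequency drift graphs (a truncated-
# normal drift model, not a coalescent simulator), genotype panels, count
# stores and toy BAMs.  Everything is deterministic under a seed so tests
# and calibrations are reproducible.

#' Define an allele-frequency drift graph
#'
#' A rooted topology in which each node's allele frequency is its parent's
#' frequency plus a zero-mean normal perturbation with branch-specific
#' standard deviation, clamped to \[0, 1\].  An admixed node first mixes
#' two ancestors (`p = prop * p_source + (1 - prop) * p_parent`) and then
#' drifts along its own branch.  Ancestral frequencies are uniform on
#' `anc_range`.  This is a drift-variance model chosen for statistical
#' transparency — expected f-statistics follow from shared branch
#' variances — not a demographic simulator.
#'
#' @param edges data frame with columns `node`, `parent` (`NA` for the
#'   root), `sd`; parents must be listed before their children.
#' @param admix optional data frame with columns `node`, `source`, `prop`
#'   (`0 < prop < 1`): `node` takes proportion `prop` of its frequency from
#'   `source` and `1 - prop` from its `parent`.
#' @param leaves optional data frame with columns `node`, `n_ind` (diploid
#'   sample sizes); defaults to every childless node with 10 individuals.
#' @param anc_range range of the ancestral allele-frequency distribution.
#' @return a `drift_graph`.
#' @export
drift_graph <- function(edges, admix = NULL, leaves = NULL,
                        anc_range = c(0.05, 0.95)) {
  stopifnot(all(c("node", "parent", "sd") %in% names(edges)))
  root <- edges$node[is.na(edges$parent)]
  if (length(root) != 1L) stop("graph must have exactly one root")
  for (i in seq_len(nrow(edges))) {
    p <- edges$parent[i]
    if (!is.na(p) && !(p %in% edges$node[seq_len(i - 1L)])) {
      stop("parent ", p, " of node ", edges$node[i],
           " is not defined earlier", call. = FALSE)
    }
  }
  if (!is.null(admix)) {
    stopifnot(all(c("node", "source", "prop") %in% names(admix)))
    if (any(admix$prop <= 0 | admix$prop >= 1)) {
      stop("admixture proportions must lie strictly between 0 and 1",
           call. = FALSE)
    }
    if (!all(admix$node %in% edges$node) ||
        !all(admix$source %in% edges$node)) {
      stop("admixture nodes/sources must appear in the edge list",
           call. = FALSE)
    }
  }
  if (is.null(leaves)) {
    childless <- setdiff(edges$node, edges$parent)
    leaves <- data.frame(node = childless, n_ind = 10L,
                         stringsAsFactors = FALSE)
  }
  structure(list(type = "drift", edges = edges, admix = admix,
                 leaves = leaves, anc_range = anc_range),
            class = "drift_graph")
}

#' Define an independent-frequencies "graph"
#'
#' Every population's allele frequency is drawn independently and
#' uniformly on `anc_range` at each site: the null model in which all
#' four-population statistics have expectation zero.
#'
#' @param n_pops number of populations (named `Pop1`, `Pop2`, ...).
#' @param n_ind diploid individuals per population.
#' @param anc_range frequency range.
#' @return a `drift_graph` of type `"independent"`.
#' @export
independent_graph <- function(n_pops, n_ind = 10L,
                              anc_range = c(0.05, 0.95)) {
  structure(list(type = "independent",
                 leaves = data.frame(node = paste0("Pop", seq_len(n_pops)),
                                     n_ind = as.integer(n_ind),
                                     stringsAsFactors = FALSE),
                 anc_range = anc_range),
            class = "drift_graph")
}

#' Preset drift graphs
#'
#' `"admixture"`: five populations — outgroup `O`, sisters `A` and `B`,
#' `C`, and `X` formed by mixing proportion `admix_prop` from the `A`/`B`
#' ancestor with `1 - admix_prop` from the `C` lineage.  Under this graph
#' the f4-ratio `f4(A,O;X,C) / f4(A,O;B,C)` has expectation `admix_prop`,
#' `D(X,C;A,O)` is positive, and `D(A,B;C,O)` is zero.  `"null"`: star
#' phylogeny with zero drift (all populations share each site's
#' frequency).  `"independent"`: see [independent_graph()].
#'
#' @param name preset name.
#' @param admix_prop admixture proportion for the `"admixture"` preset.
#' @param n_pops population count for `"null"`/`"independent"`.
#' @param n_ind diploid individuals per population.
#' @return a `drift_graph`.
#' @export
preset_graph <- function(name = c("admixture", "null", "independent"),
                         admix_prop = 0.3, n_pops = 4L, n_ind = 10L) {
  name <- match.arg(name)
  if (name == "independent") {
    return(independent_graph(n_pops, n_ind))
  }
  if (name == "null") {
    edges <- data.frame(node = c("root", paste0("Pop", seq_len(n_pops))),
                        parent = c(NA, rep("root", n_pops)),
                        sd = 0, stringsAsFactors = FALSE)
    leaves <- data.frame(node = paste0("Pop", seq_len(n_pops)),
                         n_ind = as.integer(n_ind),
                         stringsAsFactors = FALSE)
    return(drift_graph(edges, leaves = leaves))
  }
  edges <- data.frame(
    node   = c("root", "O",  "ABC", "C0", "C",  "AB", "A",  "B",  "X"),
    parent = c(NA,     "root", "root", "ABC", "C0", "ABC", "AB", "AB", "C0"),
    sd     = c(0,      0.08, 0.03,  0.02, 0.05, 0.05, 0.05, 0.05, 0.03),
    stringsAsFactors = FALSE)
  admix <- data.frame(node = "X", source = "AB", prop = admix_prop,
                      stringsAsFactors = FALSE)
  leaves <- data.frame(node = c("O", "A", "B", "C", "X"),
                       n_ind = as.integer(n_ind), stringsAsFactors = FALSE)
  drift_graph(edges, admix = admix, leaves = leaves)
}

#' Simulate per-population allele frequencies under a drift graph
#'
#' @param graph a `drift_graph`.
#' @param n_sites number of independent sites.
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @return matrix (sites x leaf populations) of allele-A frequencies.
#' @export
simulate_frequencies <- function(graph, n_sites, seed = NULL) {
  stopifnot(inherits(graph, "drift_graph"))
  if (!is.null(seed)) set.seed(seed)
  if (graph$type == "independent") {
    m <- matrix(runif(n_sites * nrow(graph$leaves), graph$anc_range[1L],
                      graph$anc_range[2L]),
                nrow = n_sites)
    colnames(m) <- graph$leaves$node
    return(m)
  }
  p <- list()
  for (i in seq_len(nrow(graph$edges))) {
    node <- graph$edges$node[i]
    parent <- graph$edges$parent[i]
    if (is.na(parent)) {
      base <- runif(n_sites, graph$anc_range[1L], graph$anc_range[2L])
    } else {
      base <- p[[parent]]
      if (!is.null(graph$admix)) {
        j <- match(node, graph$admix$node)
        if (!is.na(j)) {
          base <- graph$admix$prop[j] * p[[graph$admix$source[j]]] +
            (1 - graph$admix$prop[j]) * base
        }
      }
    }
    sdv <- graph$edges$sd[i]
    drifted <- if (sdv > 0) base + rnorm(n_sites, 0, sdv) else base
    p[[node]] <- pmin(1, pmax(0, drifted))
  }
  m <- do.call(cbind, p[graph$leaves$node])
  colnames(m) <- graph$leaves$node
  m
}

# Random site table: positions sorted within chromosomes, random ACGT
# allele pairs (all 6 unordered pairs equally likely, so 1/3 transitions).
.simulate_sites <- function(n_sites, n_chrom = 3L, chrom_len = 1e8) {
  per <- diff(round(seq(0, n_sites, length.out = n_chrom + 1L)))
  chrom <- rep(as.character(seq_len(n_chrom)), per)
  pos <- unlist(lapply(per, function(k) {
    sort(sample.int(chrom_len, k, replace = FALSE))
  }))
  pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                c("C", "G"), c("C", "T"), c("G", "T"))
  pick <- sample.int(6L, n_sites, replace = TRUE)
  swap <- sample(c(TRUE, FALSE), n_sites, replace = TRUE)
  a1 <- vapply(seq_len(n_sites),
               function(i) pairs[[pick[i]]][1L + swap[i]], "")
  a2 <- vapply(seq_len(n_sites),
               function(i) pairs[[pick[i]]][2L - swap[i]], "")
  data.frame(chrom = chrom, pos = as.integer(pos),
             snpid = paste0("snp", chrom, "_", pos),
             alleleA = a1, alleleB = a2, stringsAsFactors = FALSE)
}

#' Simulate a frequency store directly
#'
#' Draws per-population allele frequencies under `graph`, then per-site
#' allele counts as binomial draws over `2 * n_ind` chromosomes per
#' (diploid) population.  Positions are scattered over `n_chrom`
#' chromosomes so genomic blocking is exercised.
#'
#' @param graph a `drift_graph`.
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @param n_chrom chromosomes to spread sites over.
#' @param chrom_len chromosome length in bp.
#' @param missing_rate per population-site probability of missing data
#'   (`total = 0`).
#' @return a `freqstore`.
#' @export
simulate_freqstore <- function(graph, n_sites, seed = 1L, n_chrom = 3L,
                               chrom_len = 1e8, missing_rate = 0) {
  set.seed(seed)
  freqs <- simulate_frequencies(graph, n_sites)
  sites <- .simulate_sites(n_sites, n_chrom, chrom_len)
  n_pop <- ncol(freqs)
  chrn <- 2L * graph$leaves$n_ind
  countA <- matrix(0L, n_sites, n_pop)
  total <- matrix(0L, n_sites, n_pop)
  for (k in seq_len(n_pop)) {
    total[, k] <- chrn[k]
    if (missing_rate > 0) {
      total[runif(n_sites) < missing_rate, k] <- 0L
    }
    countA[, k] <- rbinom(n_sites, total[, k], freqs[, k])
  }
  pops <- data.frame(name = colnames(freqs), ploidy = "diploid",
                     n_ind = graph$leaves$n_ind, stringsAsFactors = FALSE)
  .new_freqstore(sites, pops, countA, total)
}

#' Simulate a PLINK genotype panel with a cluster file
#'
#' Draws per-population frequencies under `graph`, then per-individual
#' diploid genotypes as binomial(2, p) draws, and writes a bed/bim/fam
#' fileset plus a 3-column cluster file (`<out_prefix>_clust`).
#'
#' @param graph a `drift_graph`.
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @param out_prefix output PLINK prefix.
#' @param n_chrom,chrom_len genomic layout of the simulated sites.
#' @param missing_rate per genotype probability of missingness.
#' @return invisibly, a list with the prefix, the sites and the true
#'   frequencies.
#' @export
simulate_panel <- function(graph, n_sites, seed = 1L, out_prefix,
                           n_chrom = 3L, chrom_len = 1e8,
                           missing_rate = 0) {
  set.seed(seed)
  freqs <- simulate_frequencies(graph, n_sites)
  sites <- .simulate_sites(n_sites, n_chrom, chrom_len)
  pops <- colnames(freqs)
  n_ind <- setNames(graph$leaves$n_ind, graph$leaves$node)
  geno_cols <- list()
  iid <- character(0)
  popv <- character(0)
  for (p in pops) {
    for (j in seq_len(n_ind[[p]])) {
      g <- rbinom(n_sites, 2L, freqs[, p])
      if (missing_rate > 0) g[runif(n_sites) < missing_rate] <- NA_integer_
      geno_cols[[length(geno_cols) + 1L]] <- g
      iid <- c(iid, paste0(p, "_", j))
      popv <- c(popv, p)
    }
  }
  geno <- do.call(cbind, geno_cols)
  fam <- data.frame(fid = popv, iid = iid, stringsAsFactors = FALSE)
  write_plink(out_prefix, geno, sites, fam)
  writeLines(paste(popv, iid, popv, sep = "\t"),
             paste0(out_prefix, "_clust"))
  invisible(list(prefix = out_prefix, sites = sites, freqs = freqs))
}

# Write alignment records to SAM text and convert to a sorted, indexed
# BAM via Rsamtools.  `reads`: data.frame(qname, flag, chrom, pos, mapq,
# cigar, seq, qual).
.write_sam_bam <- function(reads, chrom_lens, out_prefix) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(chrom_lens), "\tLN:",
                  as.integer(chrom_lens)))
  body <- if (nrow(reads)) {
    paste(reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
          reads$cigar, "*", 0L, 0L, reads$seq, reads$qual, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, destination = out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Simulate a toy BAM for one individual at panel sites
#'
#' Per site, `Poisson(depth)` reads are generated; each carries one allele
#' of the individual's diploid genotype (heterozygotes emit either allele
#' with probability 1/2), flipped to the other panel allele with
#' probability `error_rate`.  The site base sits at a fixed offset inside
#' a synthetic read, and mapping/base qualities are constant so the
#' calling filters can be exercised by choosing thresholds around them.
#'
#' @param genotypes integer vector (copies of `alleleA`, 0/1/2, `NA` for
#'   missing) for one individual, one per site.
#' @param sites panel sites (`chrom`, `pos`, `alleleA`, `alleleB`).
#' @param out_prefix output BAM path prefix (without `.bam`).
#' @param depth mean read depth per site.
#' @param error_rate per-base probability of flipping to the other allele.
#' @param seed integer seed.
#' @param read_len synthetic read length.
#' @param site_offset 0-based offset of the site base within the read.
#' @param mapq,baseq qualities given to every simulated read/base.
#' @return the BAM path, invisibly.
#' @export
simulate_bam <- function(genotypes, sites, out_prefix, depth = 5,
                         error_rate = 0, seed = 1L, read_len = 21L,
                         site_offset = 10L, mapq = 60L, baseq = 37L) {
  stopifnot(length(genotypes) == nrow(sites),
            site_offset >= 0L, site_offset < read_len)
  set.seed(seed)
  reads <- list()
  qn <- 0L
  filler <- strrep("A", read_len)
  qual <- strrep(intToUtf8(baseq + 33L), read_len)
  for (i in seq_len(nrow(sites))) {
    g <- genotypes[i]
    if (is.na(g)) next
    n_reads <- rpois(1L, depth)
    if (n_reads == 0L) next
    start <- max(1L, sites$pos[i] - site_offset)
    offset <- sites$pos[i] - start          # may shrink near contig start
    a_prob <- g / 2
    for (r in seq_len(n_reads)) {
      base <- if (runif(1L) < a_prob) sites$alleleA[i] else sites$alleleB[i]
      if (error_rate > 0 && runif(1L) < error_rate) {
        base <- if (base == sites$alleleA[i]) sites$alleleB[i]
                else sites$alleleA[i]
      }
      seq <- paste0(substr(filler, 1L, offset), base,
                    substr(filler, offset + 2L, read_len))
      qn <- qn + 1L
      reads[[qn]] <- data.frame(qname = paste0("r", qn), flag = 0L,
                                chrom = sites$chrom[i], pos = start,
                                mapq = as.integer(mapq),
                                cigar = paste0(read_len, "M"),
                                seq = seq, qual = qual,
                                stringsAsFactors = FALSE)
    }
  }
  reads <- if (length(reads)) do.call(rbind, reads) else
    data.frame(qname = character(0), flag = integer(0),
               chrom = character(0), pos = integer(0), mapq = integer(0),
               cigar = character(0), seq = character(0),
               qual = character(0), stringsAsFactors = FALSE)
  lens <- tapply(sites$pos, sites$chrom, max) + read_len
  bam <- .write_sam_bam(reads, lens, out_prefix)
  invisible(bam)
}
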