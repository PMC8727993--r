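---
title: "Allele-sharing statistics with afstats: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-sharing statistics with afstats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(afstats)
```

## The problem

Population-genomic studies routinely ask how much genetic drift two
populations share, whether four populations are consistent with a tree,
and what fraction of a population's ancestry traces to an admixing
source.  The f- and D-statistic family answers these questions from
allele frequencies alone, which makes it usable for low-depth samples
(ancient DNA in particular) where diploid genotype calling is
unreliable: a single randomly sampled allele per site — a
*pseudo-haploid* call — is an unbiased draw from the underlying
frequency.

`afstats` organizes this workflow around a **frequency store**: per-site,
per-population counts of a designated allele (`countA`) and of observed
chromosomes (`total`), precomputed once from a PLINK panel.  Keeping
counts rather than frequencies costs nothing and preserves the
information needed for minor-allele-count stratification, the f3
finite-sample correction, and treemix export.

## Statistical model

All statistics are ratios of sums of per-site terms over "usable" sites
(sites where every involved population has `total >= 1`):

* distance: `num = p1(1-p2) + p2(1-p1)`, the probability two chromosomes
  drawn from the two populations differ; reported as the mean over
  usable sites.
* f4: `num = (p1-p2)(p3-p4)`; mean over usable sites.  The mean-versus-
  sum choice is unobservable in Z-scores and we adopt the mean.
* D: the same numerator, normalized per site by
  `(p1+p2-2p1p2)(p3+p4-2p3p4)`.  Enumerating the 16 possible single-
  chromosome draws shows these are exactly the expected BABA−ABBA and
  ABBA+BABA probabilities, so `sum(num)/sum(den)` is the classical
  ABBA−BABA statistic and lies in [−1, 1] whenever the summed
  denominator is positive.  Per-site zero denominators are harmless;
  only an all-zero denominator is an error.
* f3(target; A, B): `num = (pt-pa)(pt-pb)`.  With `correct = TRUE` the
  sampling bias of the target's sample frequency is removed by
  subtracting `pt(1-pt)/(n_t-1)`.  The correction assumes a binomial
  (diploid) sampling model, so it is refused for pseudo-haploid
  (haploid) targets — for those, the uncorrected statistic is still
  well defined and comparable across populations merged the same way.
* f4-ratio: `sum f4(h1,h2;h3,h4) / sum f4(h1,h2;x,h4)`, jackknifed as a
  ratio with both statistics accumulated in the same pass over the same
  usable-site set.  Under the classical five-population topology this
  estimates the admixture proportion.
* corrected f4: `(f4_obs − c·f4_proxy)/(1−c)` for a grid of assumed
  admixture/contamination proportions `c` (`minp`, `minp+pstep`, ...,
  inclusive of both endpoints when they align).  Both component f4s are
  accumulated in one pass so each grid value's jackknife is coherent;
  `c = 0` reproduces the plain f4 bit for bit.
* MAC-stratified D bins usable sites by `min(countA, total-countA)` of a
  designated stratifying population; pooling all strata reproduces the
  unstratified statistic exactly because strata partition the usable
  set.
* enhanced D restricts sites to those where chosen ascertainment
  populations are *fixed* (frequency exactly 0 or 1) with a minimum
  observed chromosome count.  The literature's ascertainment schemes
  vary; ours is a documented generalization (fixed state + minimum
  depth per ascertainer), not a byte-level reproduction of any one
  published scheme.

### Weighted block jackknife

Standard errors come from leave-one-block-out resampling over
contiguous genomic blocks (never spanning chromosomes), which absorbs
linkage between nearby sites.  With block sums `N_j`, `D_j`, weights
`m_j` (usable sites per block), `n = sum(m_j)`, `h_j = n/m_j` and
`theta = sum(N)/sum(D)`:

```
theta_tilde = g*theta - sum_j (1 - 1/h_j) * theta_(-j)
se^2 = (1/g) sum_j [h_j*theta - (h_j-1)*theta_(-j) - theta_tilde]^2 / (h_j - 1)
```

With equal weights this reduces algebraically to the classical
delete-one block jackknife; the test suite asserts the reduction to
1e-12.  Blocks with no usable sites are dropped before `g` is counted,
and a block whose removal would zero the denominator is merged into its
neighbour (with a message) rather than producing an undefined
pseudovalue.  Block weights count *statistic-usable* sites, not all
panel sites in the window: the weight is meant to reflect how much
information the block contributes to this statistic.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `block_span_bp` | 5e6 | jackknife block length (bp); 5 Mb comfortably exceeds the scale of linkage disequilibrium in vertebrate genomes |
| `block_n_sites` | unset | fixed usable-site-count blocks, for panels without meaningful physical positions |
| `transversions_only` | FALSE | drop C/T and G/A sites, immune to post-mortem C→T/G→A damage |
| `drop_strand_ambiguous` | FALSE | additionally drop A/T and C/G pairs (transversions, but strand-ambiguous when datasets are merged across platforms) |
| `min_mapq`, `min_baseq` | 30, 20 | BAM read/base quality floors |
| `trim_bp` | 0 | bases ignored from each read end; a base at 0-based offset `trim_bp−1` from either end is excluded, at `trim_bp` kept |
| `minp`, `maxp`, `pstep` | 0, 0.5, 0.025 | corrected-f4 proportion grid |

## Design choices

* **Counted allele.** The store counts the bim A1 allele per site.  All
  statistics are invariant to relabeling both alleles at a site, so the
  choice is safe; the invariance is tested.
* **File dialect.**  The store is four files: `<prefix>_freqs.gz` (gzip
  text, one row per site, tab-separated `countA,total` fields in
  `<prefix>_pop` column order), `<prefix>_pos` (chrom, 1-based pos, id,
  alleleA, alleleB), `<prefix>_chrs` (chromosome runs with first/last
  row), `<prefix>_pop` (name, ploidy, n individuals).  Missing data is
  `total = 0`, never NaN.  Byte-level compatibility with other tools'
  frequency files is not attempted; the dialect stores exactly the
  content the workflow needs and round-trips losslessly.
* **Streaming.**  Statistics read the gz file in fixed-size chunks;
  per-block partial sums are keyed by (chromosome index, window index),
  so chunk boundaries never affect results and memory is independent of
  site count.
* **Transversion filter keeps A/T and C/G.**  They are genuine
  transversions; a separate flag exists for strand-ambiguity-conscious
  users.
* **Pseudo-haploid sampling is draw-then-classify.**  One eligible base
  is drawn uniformly; if it is neither panel allele the call is missing
  even when allele-matching reads exist.  This is the strictest reading
  of the tri-allelic rule and avoids conditioning the draw on the panel.
* **Trim distance is measured over aligned, non-soft-clipped read
  coordinates** (damage is positional in the sequenced molecule;
  soft-clipped bases are part of the molecule's ends but are not
  eligible anyway, so excluding them from the distance is the
  conservative choice).  Duplicates and secondary/supplementary
  alignments are always excluded.
* **Per-site RNG.**  Each site's draw is seeded from (run seed,
  chromosome, position), so serial and parallel merging agree exactly
  and a site's call does not depend on how many other sites are
  processed.  Chromosome labels are normalized ("chr" prefix stripped)
  before seeding.
* **Concurrency contract.**  Wrappers accept `nthr`, but the contract is
  only that parallel output equals serial output (tested); statistics
  are deterministic.
* **Enumeration bookkeeping.**  `enumerate_fixed()` excludes exactly the
  fixed slots plus an explicit user exclude-list — a transparent rule in
  preference to replicating any particular dataset's bookkeeping.
* **treemix export** drops sites where any selected population is
  missing, because the format has no missing-data code.
* **Slot duplication.**  `run_stat()` permits duplicated slots (D with
  `h1 == h2` is exactly 0 and is a useful self-test); the enumeration
  wrappers require distinct fixed slots.

## The synthetic-data generator

`drift_graph()` implements a truncated-normal drift model: each node's
frequency is its parent's plus zero-mean Gaussian noise with
branch-specific sd, clamped to [0, 1]; admixed nodes mix two ancestors
linearly before their own drift; ancestral frequencies are uniform on
[0.05, 0.95].  Because expected f-statistics under this model are sums
of shared branch variances, planted signals have known sign and
magnitude: in the `"admixture"` preset (five populations, `X` drawing
proportion `c` from the `A`/`B` ancestor), the f4-ratio
`f4(A,O;X,C)/f4(A,O;B,C)` has expectation exactly `c`, which is what the
parameter-recovery checks exploit.  Sample sizes default to 10 diploid
individuals per population — a typical panel-population size — and
counts are binomial draws over the sampled chromosomes.

What the generator does **not** emulate: linkage (sites are
independent, so blocks test bookkeeping rather than real LD), selection,
nonequilibrium demography, genotyping error and reference bias.  Passing
tests therefore demonstrate correctness of the estimators and their
calibration under a clean frequency model, not robustness to every
artefact of real data.  The toy BAM generator plants reads with
configurable qualities at known offsets; it exercises the calling
filters, not a sequencing error model.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` use sizes chosen to give the
checks real statistical power while staying desk-scale: enumeration on a
164-population store (500 sites); 100 random jackknife instances;
1,000 null panels of 5,000 sites in 25 equal blocks for the calibration
of |Z| > 1.96 (nominal 5%, accepted inside the binomial 99% band — note
the jackknife Z is slightly heavy-tailed at 25 blocks, which the band
accommodates); 50 seeds of 50,000 sites for f4-ratio recovery of
`c = 0.3` within 3 se; 10,000 seeds for the pseudo-haploid sampling
distribution on a handcrafted 10-read alignment.

## Known limitations

* The f3 correction covers diploid binomial sampling only; there is no
  analogous correction for pseudo-haploid targets.
* No multiple-testing adjustment is applied across enumerated
  statistics; Z-scores are reported raw and should be interpreted
  accordingly when hundreds are scanned.
* Sex chromosomes receive no special ploidy handling.
* VCF input is out of scope; convert to PLINK with standard tools
  first.
* The drift-graph generator is a testing device, not a demographic
  simulator; use a coalescent simulator for realistic genome-scale
  benchmarks.
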