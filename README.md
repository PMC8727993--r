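# afstats

Allele-sharing statistics from precomputed population allele frequencies.

`afstats` is an R toolkit for exploratory population-genomic analysis of
SNP panels that may include low-depth (for example ancient-DNA) samples.
It follows a two-stage design: population allele frequencies are
precomputed **once** from a PLINK panel into a compact, streamable
*frequency store*; every statistic is then a single cheap pass over that
store, processing one chunk of sites at a time so memory use stays flat
no matter how many sites the panel has.

## What it computes

For allele-A frequencies `p1..p4` (and an f3 target `pt` with `n_t`
observed chromosomes), the per-site terms are

- pairwise distance: `p1(1−p2) + p2(1−p1)`
- f4: `(p1−p2)(p3−p4)`
- D: `(p1−p2)(p3−p4)` over `(p1+p2−2p1p2)(p3+p4−2p3p4)`
  (the expected BABA−ABBA over ABBA+BABA when one chromosome is drawn
  per population)
- f3: `(pt−pa)(pt−pb)`, optionally bias-corrected by
  `−pt(1−pt)/(n_t−1)` for diploid targets
- f4-ratio: `f4(h1,h2;h3,h4) / f4(h1,h2;x,h4)` — an admixture-proportion
  estimator
- admixture/contamination-corrected f4:
  `(f4(h1,h2;h3,h4) − c·f4(h1,x;h3,h4)) / (1−c)` over a grid of `c`
- minor-allele-count-stratified D and ascertainment-based "enhanced" D

Every statistic is reported with a standard error and Z-score from a
weighted block jackknife over contiguous genomic blocks (5 Mb by
default), the field's standard guard against linkage.

Low-depth samples are merged from BAM/CRAM as *pseudo-haploid calls*:
one random eligible base per panel site (mapping/base-quality filters,
read-end trimming against post-mortem damage; tri-allelic draws become
missing).  A store can also be exported to treemix input format.

## Worked example

Everything below runs on simulated data; no downloads are needed.

```r
library(afstats)

# a 5-population admixture scenario: X = 30% from the A/B ancestor
sim <- simulate_panel(preset_graph("admixture", admix_prop = 0.3),
                      n_sites = 50000, seed = 1,
                      out_prefix = "panel")

panel <- read_plink("panel", "panel_clust")
st <- build_freqs(panel, out_prefix = "panel_f")

run_stat(st, stat_request("d", h1 = "X", h2 = "C", h3 = "A", h4 = "O"))
#> D(X,C;A,O)
#>   estimate 0.00491591  se 0.000839375  Z 5.857  (50000 sites, 60 blocks)

run_stat(st, stat_request("f4ratio", h1 = "A", h2 = "O",
                          h3 = "X", h4 = "C", x = "B"))
#> f4ratio(A,O;X,C|B)
#>   estimate 0.338433  se 0.0477221  Z 7.092  (50000 sites, 60 blocks)
```

The positive, significant `D(X,C;A,O)` says X shares excess alleles with
A relative to C — the planted admixture — and the f4-ratio estimate
(0.34 ± 0.05 here) brackets the simulated proportion 0.3 within its
jackknife error.  The same quantities are available through the shell
interface installed under `exec/`:

```sh
afstats buildfreqs plinkpref=panel clustfile=panel_clust prefout=panel_f
afstats autod freqpref=panel_f h1=X h2=C h4=O outpref=res
afstats freqs2treemix freqpref=panel_f tmpref=tm popsofint=poi
```

Wrappers (`auto_f3()`, `auto_d()`, ...) enumerate one free slot over all
populations, write a tab-separated result table, a dot plot with
1.96·se (f3/dist) or 3.3·se (D/f4) error bars, and a plain-text
`.plotspec` mirror of the plot's content.  BAM samples are merged with
`add_bams()` given a 6-column list file (path, sample, population,
min MAPQ, min BASEQ, trim).

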