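---
title: "Methods: differential CpG methylation with a resampling null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential CpG methylation with a resampling null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdmc)
```

# The problem

Two groups of RRBS samples — say sperm from two cattle breeds — are compared
cytosine by cytosine. Three complications shape the design. First, bisulfite
sequencing reads an unmethylated C as T, so a genuine C→T polymorphism
segregating in either group is indistinguishable from unmethylation:
polymorphic positions must be removed, which requires group-level allele
frequencies from an external variant call set. Second, per-site read depth
is modest and variable, so only sites covered in every sample are testable
on equal footing. Third, the interesting questions are mostly *structural*
— are differential sites clustered, near SNPs, inside repeats? — and the
natural null for such questions is not parametric but empirical: random
control subsets of the tested, non-differential cytosines (r-Cs).

# Filtering

`filter_coverage()` keeps sites whose coverage reaches `min_cov` (default
10 reads) in **every** sample. `mask_snp_positions()` removes sites whose
cytosine position equals a retained SNP position; SNPs are retained when
the alternate-allele frequency exceeds `min_af = 0.10` in at least one
group, strictly ("more than 10%"). Two documented choices:

* The allele-frequency filter reads the **alternate** allele (not the
  minor allele); variant callers report ALT frequencies directly and the
  biological concern — a base that differs from the reference C/G — is an
  alternate-allele property.
* By default only the cytosine position itself is masked. A SNP at the
  paired guanine also corrupts calls on that strand, so `dyad_mode = TRUE`
  masks `pos + 1` (forward C) / `pos − 1` (reverse C) as well; it is off by
  default to match the narrower convention and keep the default behaviour
  minimal.

Cytosines on opposite strands of one CpG dyad are kept as separate sites —
dyad merging would make the 1-bp next-CpG distance class unobservable.

# The site test

`site_test()` / `call_dmcs()` use the likelihood-ratio test of the group
coefficient in a binomial logistic regression on pooled per-group counts,
computed in closed form as the G-test of independence on the 2 × 2 table,
with \(p = P(\chi^2_1 \ge G)\). Pooling means per-sample (biological)
variability is *not* modelled: the test is exactly a plain logistic
regression of methylation state on group, which keeps it fast, closed-form,
and exactly checkable against an independent oracle. Under the synthetic
generator (samples within a group share one methylation mean) the pooled
binomial model is correctly specified and the realized false-discovery
fraction at q ≤ 0.05 sits at or below the nominal level (see the
acceptance tests). On real data with extra-binomial scatter between
animals the pooled test is anti-conservative; that is the price of the
plain pooled logistic-regression design, and a beta-binomial or
quasi-likelihood variant is deliberately out of scope.

q-values are Benjamini–Hochberg over exactly the tested sites;
`select_high_confidence()` further keeps DMCs with `|delta| > 0.20` and a
nearest-SNP distance strictly greater than 100 bp (a site at exactly
100 bp is excluded).

# The resampling null and its t-test

`draw_subsets()` draws k = 10 subsets, each the size of the DMC set,
uniformly without replacement from the tested non-DMC sites. Subsets are
mutually independent (no partitioning rule is imposed), and subset *i* is
drawn under child seed `seed + i`, so enlarging k never changes earlier
subsets.

`subset_ttest()` compares the observed DMC statistic with the k subset
statistics by a two-sided t-test with k − 1 degrees of freedom. One design
point deserves emphasis. A textbook one-sample t-test of the subset values
against the observed value (standard error `s/√k`) answers "is the subset
*mean* equal to this constant" — but the observed statistic is not a
constant: under the null it carries the same sampling noise as each subset
value. Treating it as fixed inflates the statistic by roughly `√(k+1)` and
rejects a true null about half the time at k = 10. The default standard
error is therefore `s·√(1 + 1/k)` — the prediction-interval form, which is
exactly t-distributed under normal exchangeability and gives the nominal
5% size (verified by simulation in the test suite; empirical null
rejection over 50 simulated studies: 0/50). `var_adjust = FALSE` restores
the plain one-sample form for comparison with analyses that used it. The
test is two-sided; enrichment direction is reported separately.

With all subset values equal (a degenerate bin, e.g. no site within 2 bp
of any feature), the test reports p = 1 when the observed value equals the
common value and p = 0 with a warning otherwise.

# Proximity, stretches, repeats

* `nearest_distance()` is a linear-time merge against sorted feature
  positions; chromosomes without features give an infinite sentinel, which
  never counts toward any bin. "Up to t bp" is inclusive (≤ t).
  The same machinery serves SNP proximity and proximity to an external
  reference DMC list without any code-path change.
* `find_stretches()` emits maximal runs of ≥ `min_sites` sites with all
  consecutive gaps ≤ `max_gap` (default 2000 bp), by a single greedy pass
  over sorted positions; a quadratic oracle in the test suite confirms it
  on random instances. Stretches are computed *within* the DMC set (or
  within each subset), since the quantity of interest is adjacency of
  differential sites, and spans are reported inclusively
  (`end − start + 1`).
* `overlap_by_class()` counts a site for a repeat class when its 1-based
  position lies strictly inside the stored half-open interval bounds
  (`start < pos < end`); a site under several overlapping classes counts
  for each. `class_enrichment()` applies the subset t-test per class and
  Benjamini–Hochberg across classes, and labels direction by the sign of
  observed minus subset mean.

# Stage projection and QC

`pool_replicates()` sums counts within developmental stages;
`stage_filter()` keeps DMC sites with pooled coverage ≥ 5 in every stage.
`hierarchical_cluster()` uses 1 − Pearson correlation over
pairwise-complete sites with average linkage (Euclidean/complete are
available); constant columns have no defined correlation and are dropped
with a warning; trees are serialized as Newick. `pca_samples()` runs PCA
on per-sample methylation fractions, site-centered and unscaled, with a
deterministic sign convention. `global_methylation_stats()` calls a site
"methylated" when its pooled fraction reaches 0.5 — a descriptive default,
configurable, not a quantity with a canonical threshold.

# The synthetic generator

`sim_config()` fixes the study conditions the package is tested under:

| parameter | default | what it emulates |
|---|---|---|
| samples | 9 + 9 | two breed groups of nine animals |
| coverage | NB(mu = 30, size = 20) | RRBS depth around 30X with mild overdispersion |
| baseline methylation | 0.70·Beta(1,10) + 0.30·Beta(10,1) | bimodal CpG methylation; the 0.30 high-mode weight puts ~30% of sites in the methylated mode |
| CpGs | 20,000 on 2 × 5 Mb | desk-scale stand-in for a genome-wide RRBS site set |
| planted DMCs | 500, delta = 0.4 | sites whose group means differ by 0.4, shifted away from the nearer clipping bound [0.02, 0.98] so the magnitude is preserved |
| SNP coupling | 30% within 100 bp; 1,000 SNPs total | genetic–epigenetic association against a ~2% background near-SNP rate |
| repeats | 4 classes, ~2.4% of the genome each; first class 3× DMC density | repeat-associated differential methylation; the footprint is chosen so a 3× density is a well-posed, detectable condition (real mammalian genomes are ~50% repetitive, so a few percent per modelled class is conservative realism) |
| stretches | 3 runs of 12 DMCs, gaps 10–200 bp | long runs of adjacent co-differential CpGs |

The generator plants each structure directly (no rejection sampling):
stretch CpGs are laid down first, then the remaining positions, then DMCs
are drawn with repeat-class multipliers as weights, then SNPs are placed —
never on a CpG position, since such cytosines would be masked and the
planted signal silently destroyed. Truth and counts use separate seed
streams (`seed`, `seed + 1`), and everything is byte-reproducible from the
config.

What the generator does **not** emulate: per-sample library-size effects,
between-animal overdispersion, bisulfite conversion error, mapping bias,
strand structure (all simulated sites are strand-unknown), and spatial
correlation of methylation outside the planted structures. Passing tests
therefore demonstrate correctness of the machinery under the stated
sampling laws, not robustness to real-data artefacts.

Stage fixtures reuse the generator at 4 stages × 2 replicates with
NB(mu = 6) coverage — low enough that the 5X-in-all-stages filter
meaningfully prunes — and a per-stage global scaling (0.3, 0.4, 0.8, 1.0)
sketching a demethylation/remethylation wave.

# Numerical and degenerate-input choices

* G-statistic cells with zero observed count contribute 0 (the
  `x log x → 0` limit); degenerate margins give G = 0, p = 1; tiny negative
  rounding is clamped at 0. Sites with zero total reads in one group are
  untestable and are skipped with a warning.
* Coordinates are 1-based for point features; intervals are stored 0-based
  half-open and converted at the BED/RepeatMasker boundary. Interval
  stabbing uses the strict-interior rule stated above, applied uniformly.
* Chromosome matching is exact string equality; unshared chromosomes
  produce a warning, never silent alignment.
* Ties in hierarchical clustering resolve by column order (stats::hclust
  behaviour); the PCA sign convention makes projections reproducible
  across platforms.
* All simulations in the test suite run at the sizes stated in the tests
  themselves (20,000 CpGs × 18 samples for calibration/recovery studies;
  one 100,000-CpG run exercises the full pipeline), chosen as desk-scale
  versions of the study conditions.

# Known limitations

Pooled testing ignores animal-level variance (above). The r-Cs null
conditions on the observed DMC count and on the tested-site universe; it
does not model uncertainty in DMC calling itself. The repeat-class test
with k = 10 subsets estimates the null spread from 10 values, so its power
and family-wise behaviour at small per-class counts is limited — with a
~2.4% footprint class and ~500 DMCs, expected in-class counts are ~12 and
the sd estimate carries ~24% relative error; simultaneous "target flagged,
no other class flagged" outcomes are then not guaranteed in every seed even
for a genuine 3× effect. Larger k sharpens this at the cost of departing
from the canonical 10-subset design.
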