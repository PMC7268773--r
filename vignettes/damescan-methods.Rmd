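---
title: "Detecting differential allele-specific methylation with damescan"
author: "damescan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential allele-specific methylation with damescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damescan)
```

## The problem

Most of the genome is methylated symmetrically on both parental alleles.
Allele-specific methylation (ASM) — one allele methylated, the other not —
marks imprinted loci, the inactive X in female cells, and widespread
sequence-dependent ASM (SD-ASM) tied to heterozygous SNPs. Loss or gain of
ASM between conditions (for example cancer versus matched normal tissue) is
a refined form of differential methylation that an ordinary DMR analysis
often misses, because the average methylation change can be modest while
the allelic architecture changes completely.

damescan scores ASM per sample from bisulfite-sequencing reads and then
screens two-group cohorts for regions of consistent ASM change (DAMEs:
differentially allele-specifically methylated regions).

## The two ASM scores

**SNP-based score.** Reads overlapping a heterozygous SNP are partitioned
by their base at the SNP. For a CpG site $i$ covered on both alleles,

$$\mathrm{ASM}^i_{\mathrm{snp}} =
  \left| \frac{X^{ir}_M}{X^{ir}} - \frac{X^{ia}_M}{X^{ia}} \right|,$$

the absolute difference of methylation proportions between
reference-allele and alternative-allele reads. It lies in $[0,1]$, is
symmetric in the two alleles, and is missing (not zero) when either allele
is uncovered. It measures genuine SD-ASM but only exists near het SNPs.

**Tuple-based score.** Without genotype information, ASM leaves a
read-level signature: at a pair of nearby CpG sites, reads are a balanced
mixture of fully methylated (MM) and fully unmethylated (UU) molecules.
From the four read counts $X_{MM}, X_{MU}, X_{UM}, X_{UU}$ of a CpG pair,

$$\mathrm{ASM}^i_{\mathrm{tuple}} =
  \left| \log_{10}\frac{(X_{MM}+c)(X_{UU}+c)}{(X_{MU}+c)(X_{UM}+c)}
  \cdot w_i \right|,
\qquad
w_i = P(0.5-\epsilon < \theta_i < 0.5+\epsilon),$$

with $\theta_i \sim \mathrm{Beta}(\gamma + X_{MM}, \gamma + X_{UU})$. The
log-odds ratio rewards concordant reads over discordant ones; the weight
$w_i$ — the posterior probability that the MM:UU balance is within
$\epsilon$ of 50:50 — attenuates tuples dominated by one state, which
represent plain methylation, not allele specificity. A fully methylated
tuple ($X_{MM}=8$, rest 0) has a large log-odds ratio but
$w \approx 0.015$, so its score is pushed toward zero, while a balanced
tuple ($X_{MM}=X_{UU}=4$) keeps $w \approx 0.78$.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.5 | Beta prior weight penalizing one-sided tuples |
| `epsilon` | 0.2 | allowed departure of the MM proportion from 0.5 |
| `c` | 1 | pseudo-count in the log-odds ratio |
| `max_tuple_distance` | 150 bp | maximal CpG-pair span |

`epsilon` has the largest influence: smaller values demand a stricter
50:50 balance and lower every score (the score is non-decreasing in
`epsilon`, a property the tests verify). `gamma` only matters when it is
large relative to the counts. The pseudo-count `c` is our choice — a unit
pseudo-count keeps the log-odds a standard smoothed estimator — and is
configurable because no canonical value exists for it. The 150 bp cap
reflects that a read pair rarely spans more, so distant tuples are
dominated by chimeric evidence.

Tuples are located at the floored median of the two CpG C positions
(positions must be integers for clustering; flooring rather than rounding
is an arbitrary but fixed convention).

## From scores to DAMEs

1. **Filter**: cells with coverage of 5 reads or fewer become missing;
   positions observed in fewer than 80% of samples are dropped.
2. **Transform**: tuple scores are square-root transformed
   ($L = \sqrt{|\mathrm{ASM}|}$) to stabilize the mean–variance
   relationship; SNP scores enter the linear model untransformed (the
   arcsine transform `asin(sqrt(x))`, the variance-stabilizer for
   proportions, is available for exploratory work such as MDS).
3. **Model**: for each position, ordinary least squares of the score
   vector on a design matrix, $E(y_i) = X\beta_i$, with a contrast
   picking out the group effect. Missing cells are dropped per position
   (complete-case); positions left without residual degrees of freedom
   are dropped.
4. **Moderate**: residual variances are shrunk toward a common prior by
   empirical Bayes. The prior $(d_0, s_0^2)$ is estimated by
   moment-matching the distribution of log residual variances against a
   scaled-F model (trigamma inversion by Newton iteration; exact zero
   variances are offset to $10^{-5}\times$ the median rather than
   dropped, since runs of identical scores are informative about the
   variance spread). The moderated $t$ uses
   $\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and $d_0 + d$ degrees of
   freedom. The estimator is re-derived in this package; the test suite
   cross-checks it against the independent limma implementation to
   machine precision.
5. **Cluster and smooth**: positions at most `maxgap = 100` bp apart form
   clusters; within each cluster the coefficients are loess-smoothed
   (span expressed as 11 positions, degree 2, clusters smaller than
   `degree + 2` pass through unchanged — the procedure is named in the
   field's toolboxes but its window parameters are not, so these are our
   choices; local regression at degree 2 reproduces linear trends
   exactly, which the tests assert).

### Region p-values

**Permutation route.** Candidate regions are maximal runs of consecutive
positions within a cluster whose smoothed coefficient strictly exceeds
the threshold — the `K` quantile (default 0.7) of $|\tilde{\beta}|$ — with
a consistent sign. Each region's statistic is its area
$A = \sum |\tilde{\beta}|$. For every non-redundant reassignment of the
two group labels (distinct assignments up to a global swap, excluding the
observed one; $\binom{6}{3}/2 - 1 = 9$ for 3 vs 3), the fit–smooth–scan
pipeline is re-run with the threshold quantile recomputed inside the
permutation, and all null areas are pooled. A region's p-value is the
add-one proportion $(\#\{A_0 \ge A\} + 1)/(N_0 + 1)$ — never exactly
zero, and conservative by using $\ge$. Benjamini–Hochberg adjustment is
applied across regions. Recomputing the threshold per permutation (rather
than freezing the observed value) keeps the null pipeline exchangeable
with the observed one; fewer than 3 available permutations is an error
that points to the Simes route.

**Simes route.** Each cluster is summarized by
$p_c = \min_i \{ n p_{(i)}/i \}$ over its ordered position-level
p-values, valid under positive dependence of nearby CpG tests; clusters
are then BH-adjusted. This tests the global null that no position in the
cluster changed, and is the less stringent of the two strategies.

A DAME's direction is `gain` when the group of interest has the higher
ASM (positive contrast on the smoothed coefficient), `loss` otherwise.

## The synthetic-data module

Because the real cohorts behind the method are not redistributable, the
package ships generators with known truth at two levels.

**Read level** (`simulate_reads`): every read picks one of two alleles
with probability 0.5 and draws each CpG call Bernoulli with that allele's
methylation probability; region kinds encode imprinted loci
(0.95/0.05), X inactivation, SD-ASM (an allele-tagging SNP base is
written into the read), symmetric null regions, and genotype-free
heterogeneity. Reads serialize to SAM (with the methylation-call string
tag) and SNPs to VCF, so the exact file-reading paths are exercised.

**Score level** (`simulate_score_matrix`): positions are laid out in 200
clusters by default (sizes uniform on [5, 30], intra-cluster gaps uniform
on [2, 100] bp, inter-cluster gaps above `maxgap`); each position gets a
true allele differential from a mixture of 90% Beta(1, 8) and
10% Beta(5, 2) — a mostly symmetric methylome with an occasional
high-ASM tail — and each cell realizes the score as the absolute
difference of two binomial methylation proportions at a Poisson(30)
coverage split between alleles. Locus-level signal is therefore shared
across samples, and read-sampling noise is not. In 20% of clusters a
contiguous block of positions (uniform start, length at least 1) receives
one effect size — the Beta(1, 2.5) quantile at a Unif(0.35, 0.75) draw,
closed form $1-(1-u)^{1/2.5}$, so effects range over roughly 0.16–0.43 —
with random sign and a randomly chosen affected group; scores are
truncated to $[0,1]$. All draws flow from a single seed, and a fixed
configuration reproduces byte-identical output.

The default of 200 clusters (around 3,500 positions) keeps a full
permutation analysis of 10 simulation replicates in the low minutes on a
single core while leaving enough clusters for stable FDR estimates; it is
the problem size used throughout the tests and the acceptance script.

## What the simulations do and do not show

Under these conditions the permutation route controls the FDR with a wide
margin (mean empirical FDR at adjusted $p \le 0.05$ is essentially zero
across replicates and K thresholds) and the Simes route also stays below
the nominal level while being less conservative, consistent with its
global-null construction.

One relative ordering deserves honesty: on this synthetic baseline the
permutation route is *more* sensitive than the Simes route, whereas on
real cohorts the Simes route is the one usually reported as more
powerful. The reason is structural. Synthetic samples are exchangeable
and their noise is light-tailed binomial sampling, so permuted group
labels produce a clean pool of small null areas and the permutation
p-values become very sharp. Real ASM scores carry heavy-tailed,
sample-specific components — above all genotype-dependent ASM present in
only a subset of individuals — which inflate the permuted null areas and
blunt the permutation route, while the Simes route, floor-limited by the
$t$ tail at small sample sizes, is less affected. Passing the simulation
tests therefore demonstrates calibration and recovery of planted effects,
not the relative power ranking of the two FDR strategies on real data;
the generator deliberately does not model sample-specific ASM, tumor
heterogeneity, or capture-protocol coverage bias.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive everywhere internally (matching the
  CpG-pair table and VCF conventions); conversion to 0-based half-open
  happens only at the BED boundary, and a round-trip test pins it.
- A tuple or site absent from a sample is missing, never a zero score;
  zero would assert symmetric methylation that was not observed.
- Overlapping mate pairs are counted once per CpG (first mate wins) to
  avoid double-counting one molecule; minimum mapping quality 30 and
  minimum base quality 20 at the SNP are configurable defaults the
  upstream literature does not fix.
- A CpG linked to several SNPs is kept per (CpG, SNP) pair; collapsing to
  one row per CpG keeps the SNP with the highest combined allele
  coverage, which maximizes estimator precision.
- Ties at the region threshold are excluded (strictly above); if all
  $|\tilde{\beta}|$ are identical the threshold equals that value and no
  region is found.
- `make_clusters` accepts tied positions (distinct tuples can share a
  median) but rejects unsorted input.
- If every residual variance is zero the moderated t falls back to the
  ordinary t with a warning.

## Known limitations

The tuple score is a proxy: cellular heterogeneity (a mixture of fully
methylated and fully unmethylated cells) is indistinguishable from ASM in
bulk bisulfite data, and the score will flag it. The SNP score requires
het SNPs and both alleles covered, limiting it to a small fraction of the
genome. The differential module handles exactly two groups per contrast
(covariates may be added as design columns but multi-group F-tests are
out of scope), and the permutation route needs at least 3 vs 3 samples to
have enough label reassignments.
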