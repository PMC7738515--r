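---
title: "Methods: integrative analysis of multi-platform RPPA data"
author: "multiRppa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative analysis of multi-platform RPPA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiRppa)
```

## The problem

Reverse-phase protein arrays (RPPA) quantify proteins and phospho-proteins
in hundreds of samples at once by spotting lysates on slides and probing
each array with a single validated antibody. Because nearly every RPPA
laboratory runs a customised workflow — different arrayers, slide
chemistry, dilution schemes, detection dyes, scanners and normalisation
software — data from different platforms are not directly comparable, and
the robustness of RPPA-derived biomarkers across laboratories is a real
question. This package implements an integrative analysis for this
setting: per-platform processing of spot-level intensities, cross-platform
integration by antibody-wise median centring, unsupervised structure
discovery, a *clustered antibody antigen map* that scores whether distinct
antibodies and platforms agree about the same antigen, all-pairs
correlation statistics, and moderated differential testing of drug
responses. A synthetic-data generator with known ground truth emulates a
three-platform, six-cell-line, two-drug study design so that every stage
is testable end to end.

## The synthetic study generator

`defaultStudyDesign()` encodes the study layout: six breast cancer cell
lines (MCF7, MDA-MB-231, MDA-MB-468, MDA-MB-453, HCC1954, SKBR3, carrying
ER+/TNBC/Her2+ receptor-status labels), three treatments (DMSO vehicle,
lapatinib — an EGFR/Her2 kinase inhibitor — and selumetinib — a MEK
inhibitor), two timepoints (20 min, 24 h) and biological triplicates:
6 × 3 × 2 × 3 = 108 samples.

The latent ground truth for antigen class $a$ in sample $s$ is

$$x_{as} = \beta_{a,\mathrm{line}(s)} + \delta_{a,\mathrm{line}(s),
\mathrm{drug}(s),\mathrm{time}(s)} + \varepsilon_{as},
\qquad \varepsilon_{as} \sim N(0, \sigma_r^2),$$

on the log2 scale. Baselines $\beta$ are drawn once from $N(8, 1.5^2)$
log2 units under a fixed configuration seed (so the baseline table is
data, not randomness of a run); 1.5 log2 units of between-line spread is
typical of the cell-line heterogeneity seen in pan-cancer RPPA panels.
Drug effects $\delta$ are applied only in (cell line, drug) pairs flagged
sensitive — SKBR3 and HCC1954 for lapatinib, MDA-MB-231 for selumetinib —
and encode the expected pharmacodynamics: phospho-Erk1/2 collapses under
MEK inhibition (−2.0 log2 at 20 min, −2.5 at 24 h) with phospho-MEK1/2
feedback upregulation at 24 h (+1.5), and receptor/Akt/Erk
phosphorylation falls under lapatinib in the Her2-amplified lines. The
magnitudes are benchmarks chosen for testability, not estimates of any
particular dataset; replicate noise defaults to $\sigma_r = 0.25$ log2
units, consistent with the good replicate agreement expected of RPPA.

Each of the three platforms renders the latent matrix through its own
measurement model. The undiluted log2 spot signal of antibody $i$
(targeting class $a$) on sample $s$ is

$$y_{is} = g_i\, x_{a s} + o_i + \ell_s + e_{is}, \qquad
e_{is} \sim N(0, \sigma_{\mathrm{spot}}^2),$$

where $g_i \approx 1$ and $o_i$ are per-antibody gain and offset
(platform-level gain 1.00/1.06/0.94 with small per-antibody variation),
$\ell_s \sim N(0, 0.3^2)$ is a per-sample loading factor shared by all
antibodies (the total-protein confounder), and
$\sigma_{\mathrm{spot}} = 0.15$ log2 units. Serial two-fold dilution
subtracts exactly 1.0 log2 per step (4/6/4 steps per platform, in 3/2/2
technical replicates), and linear intensities are censored at a detection
floor of 0.25, chosen so that — as expected of a well-run platform —
fewer than 1% of undiluted spots fall below detection. A total-protein
stain series tracking $\ell_s$ is emitted alongside each panel. The
default panels carry 29/31/27 antibodies covering the same 25 antigen
classes on all three platforms, so 18 control samples yield 522/558/486
readings (1566 integrated) and the 108-sample study yields 9,396.

What the generator does *not* emulate: spatial array effects (print pins,
blocks, slide position), antibody cross-reactivity and off-target
binding, nonlinear saturation other than floor censoring, and
batch-to-batch antibody lot variation. Passing tests therefore show that
the analysis recovers structure under additive platform distortions and
a multiplicative loading confounder — not that it is robust to every
failure mode of real arrays.

## Per-platform processing

Technical replicates are collapsed by the median (robust to single bad
spots; the aggregation rule is a package choice, as replicate handling
differs between real platforms). Each (sample, antibody) dilution series
is fit by ordinary least squares of log2 intensity on the integer
dilution step; an in-range series has slope near −1, and
`qcDynamicRange()` reports the fraction of series with slope in
−1 ± 0.5 and the fraction flagged below detection. Two normalisation
strategies are provided, emulating the *distinct* in-house pipelines of
real platforms in simplified form: `"dilution_intercept"` takes the
fitted undiluted log2 intensity, and `"total_protein"` additionally
divides by the sample's total-protein stain intensity (equivalently,
subtracts the total-protein log2 intercept), removing the loading
factor. Platforms A and C default to total-protein normalisation and
platform B to the dilution intercept, so the integrated study mixes
normalisation strategies on purpose. Full re-implementations of
platform-specific normalisation suites are out of scope: what matters
for the integrative analysis is that the strategies are genuinely
different yet yield concordant data.

## Integration

Antibody targets are first classified into antigen classes; a synonym
table merges antibodies recognising a protein together with a close
isoform (e.g. a rule mapping Erk1 to Erk1/2 classifies both an Erk1 and
an Erk1/2 antibody as recognising Erk1/2), while distinct phospho-sites
remain distinct classes. Unique antibody identifiers of the form
`Her2_a` are assigned per antigen class in sorted supplier-reference
order, so the same catalogue antibody used on two platforms shares one
identifier and the assignment is independent of input order. Each
platform matrix is then median-centred antibody-wise (the median over
the analysed samples is subtracted from each antibody column), the
matrices are horizontally concatenated, and antigen classes not measured
on all three platforms are excluded entirely.

Two choices here were genuinely open. First, the centring subset: the
package centres over whichever sample set is being analysed (control-only
for the control analysis, all 108 for the drug-treated analysis), and
exposes the alternative — centring on all samples and then subsetting —
as a configuration switch, since either is defensible. Second, missing
values are carried, never imputed: downstream correlations and rank
distances use pairwise-complete observations, because imputation would
fabricate correlation structure in exactly the quantity under study.
(PCA, which requires complete data, is the one exception: it imputes
feature medians and records how many cells were imputed.)

## Clustering

Dissimilarities between antibody columns (or samples) are Spearman
distance $1 - r_s$ (average-tie ranks), Kendall distance $1 - \tau_b$,
or Euclidean distance. The $1 - r$ adaptation (rather than $(1 - r)/2$)
is recorded in output metadata; $\tau_b$ is the tie-corrected Kendall
variant, appropriate because centred intensity data contain ties.
Clustering is binary agglomerative with pairwise (unweighted) average
linkage: at each step the globally closest pair merges, with
inter-cluster distance the mean over member pairs. Ties are broken by
the lexicographically smallest pair of cluster creation indices, and at
each merge the earlier-created subtree becomes the left child — both
rules exist purely to make leaf order and merge sequence reproducible
across runs and platforms. Average linkage can produce height
inversions; the count is reported on the dendrogram object rather than
silently reordered away. Results are written as CDT/GTR/ATR
clustered-data-table files (node scores stored as 1 − height at full
precision, for all metrics, so heights round-trip exactly through the
bundled reader).

## The clustered antibody antigen map and concordance

The antigen map expands the clustered antibody columns into a matrix
whose rows are antigen classes in alphabetical order; the single filled
cell per column holds the antibody's fixed integer index within its
class (assigned by sorted identifier, enumerating from 1), so the map
reads antibody concordance directly off the dendrogram's leaf order.

Concordance scoring asks, per antigen class: does any of its antibodies
cluster with a same-class antibody from (a) another platform, (b) a
different antibody identifier? Because "clusters with" has no canonical
definition, the package formalises it and exposes the rule. The default
`"sibling"` rule takes, for each leaf, the set of leaves at minimal
cophenetic distance. On a tie-free tree this is exactly the sibling
subtree at the leaf's parent merge node; under tied merges — ubiquitous
with near-identical columns — it extends to the whole tie plateau, which
is the behaviour one wants: when six antibodies have identical profiles
they all "cluster together" even though the binary tree must pair them
up in some arbitrary order first. A `"k_cophenetic_neighbours"` rule
(default k = 3) is the configurable alternative. Summary fractions are
reported only over eligible classes (≥ 2 platforms, respectively ≥ 2
distinct antibodies), and the denominators are always reported alongside
the fractions, since a percentage with an unstated denominator is not
reproducible.

On noise-free data — the same latent antigens rendered identically on
all platforms (unit gain, no noise, no censoring; offsets are immaterial
because centring removes them) — both fractions are 1.0 for every
eligible class under every metric. Unit gain matters for the Euclidean
check specifically: Euclidean distance is not scale-invariant, so
per-antibody gain differences would make same-platform antibody twins
closer than cross-platform copies by construction, which is a statement
about the metric, not about platform agreement.

## Correlation statistics

Spearman correlations are computed for every unordered pair of
antibody-platform columns over pairwise-complete samples (pairs with
fewer than 3 complete observations are dropped and counted). Pairs are
labelled like-antigen, same-antibody (same identifier on different
platforms) and same-platform, and the distribution comparisons —
like-antigen versus all pairs, same versus different antibody, per
platform pair, same versus cross platform — return raw coefficient
vectors plus group medians. Kernel density estimates use a Gaussian
kernel with Silverman's rule-of-thumb bandwidth on 512 grid points
spanning the data ± 3 bandwidths. Median correlations of two groups are
compared by Fisher transformation,
$z = (\operatorname{atanh} m_1 - \operatorname{atanh} m_2) /
\sqrt{2/(n_{\mathrm{eff}} - 3)}$, with a two-sided normal p-value. This
test treats each median as a single correlation estimated from
$n_{\mathrm{eff}}$ independent samples — an approximation on two counts
(the pairs are mutually dependent, and a median of correlations is not a
correlation), which is why $n_{\mathrm{eff}}$ is an explicit parameter
(defaulting to the sample count underlying each correlation) and the
approximation is recorded in the result object.

## Differential testing

Drug-versus-vehicle contrasts use a moderated t-statistic
$t = (\bar{x}_A - \bar{x}_B)/(s_p\sqrt{1/n_A + 1/n_B} + s_0)$ with the
"artificial within-groups variance" constant $s_0 = 1$ by default added
to the pooled standard error, damping large statistics from near-zero
variance antibodies; $s_0 = 0$ recovers the classical pooled t. FDR is
controlled by label permutation. With 3 vs 3 replicates only
$\binom{6}{3} = 20$ balanced relabellings exist, so the package
enumerates them exactly rather than sampling 1,000 redundant
permutations, and reports the count used. Two of the twenty — the
observed assignment and its mirror — reproduce every true effect
verbatim; including them would put a hard floor of 2/20 = 10% on the
estimated FDR of any genuine effect, making a 5% threshold unattainable
by construction. They are therefore excluded, leaving 18 informative
splits. For a threshold $c$, $\widehat{\mathrm{FDR}}(c)$ is the mean
permutation count of $|t| \ge c$ divided by the observed count, and the
significant set is the largest one with
$\widehat{\mathrm{FDR}} \le 5\%$ (equivalently the smallest passing
cut); thresholding is on $|t|$ alone, i.e. two-sided and symmetric in
the volcano plane. Each (cell line, drug, timepoint) contrast is tested
independently.

Calibration under these conditions, measured by the package's own
checks: on null 3 vs 3 data with 50 antibodies the mean number of
5%-FDR calls is well below 1 per dataset, while effects of 5 standard
deviations are recovered with sensitivity above 0.95.

## Numerical and reproducibility choices

One top-level seed drives everything: per-stage seeds are derived
deterministically from it (kept below $2^{31}$), generators restore the
caller's RNG state, and re-running a pipeline configuration reproduces
every output byte for byte. Every written file carries a provenance
header (package version, stage, seed, configuration hash). Degenerate
inputs are handled explicitly rather than silently: all-floored dilution
series are flagged unquantifiable, non-positive values are set missing
with a warning before log2, all-missing antibody columns are dropped
with a warning at centring, zero-variance KDE input yields a flagged
spike, under-replicated groups yield flagged missing statistics, and
distance pairs with fewer than three complete observations propagate as
missing distances that clustering refuses. Oracle-style checks in the
test suite compare the dilution fits, rank distances, pooled t and
Fisher z against independent first-principles implementations at 1e-9,
and the clustering against a brute-force average-linkage reference on
hundreds of small random matrices (up to 7 leaves — small enough for the
$O(n^3)$ reference, large enough to exercise every tie and inversion
path). Stochastic checks (FDR calibration at 100 null datasets,
sensitivity at 50, concordance-vs-noise monotonicity at 20 seeds per
noise level) use problem sizes chosen to keep the full suite under a
minute of simulation while leaving Monte-Carlo error far from the
asserted bounds.

## Limitations

The pipeline analyses one study layout at a time and assumes all
platforms measured the same sample set. The permutation FDR is exact
only over balanced relabellings; unbalanced designs are supported but
their split spaces grow quickly and are subsampled. The Fisher z
comparison inherits the independence approximation described above.
Concordance percentages depend on the chosen neighbourhood rule — that
is precisely why the rule is explicit, configurable and reported with
its denominators.
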