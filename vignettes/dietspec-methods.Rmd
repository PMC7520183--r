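---
title: "Measuring cross-sectional diet specialization from scat metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cross-sectional diet specialization from scat metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietspec)
```

## The problem

A population of generalist predators can be a collection of individual
specialists. Distinguishing the two matters for predator–prey dynamics,
but it requires many diet observations per population, which is why scat
metabarcoding is attractive: each scat gives a compositional snapshot of
one individual's last few foraging bouts at species-level taxonomic
resolution. `dietspec` implements the full analysis chain for such data:
molecular sexing, diet proportioning, group-relative specialization
scoring, mixed-model comparison of its predictors, and prey–specialization
correlations, together with a generative simulator used to validate every
stage.

## The specialization metric

For sample $i$ with diet proportions $p_{ij}$ and its group's population
diet $q_j$, the proportional similarity index is

$$\mathrm{PS}_i = 1 - 0.5 \sum_j \lvert p_{ij} - q_j \rvert
             = \sum_j \min(p_{ij},\, q_j),$$

the overlap between individual and population resource use. The second
form (total overlap of two distributions) is used as an independent oracle
in the tests. Conventions that matter:

* **Population diet.** $q$ is the *unweighted* mean of member proportion
  vectors over the union of taxa observed in the group. Each scat counts
  equally regardless of read depth. This is the only convention under
  which the theoretical minimum $1/N$ is exact: a sole specialist on an
  otherwise untouched taxon has $\mathrm{PS} = 1 - 0.5[(1 - 1/N) +
  (1 - 1/N)] = 1/N$, which the suite asserts to machine precision.
* **Resource axis.** PSi is computed on species-level proportions within
  each group; order-level lumping (and the juvenile/adult salmon split) is
  used only for the correlation analysis.
* **Cross-sectional caveat.** One scat per individual measures transient
  intrapopulation feeding diversity, not persistent individual
  specialization; all group comparisons are relative, between samples
  collected and scored the same way.
* **Degenerate groups.** A single-member group compares a sample with
  itself; the package scores it PSi = 1 and flags it. Such groups never
  reach inference — the $N \ge 5$ retention filter removes them. (The
  packaged study table instead prints SI = 0.000 for its three $N = 1$
  groups; that printed value is preserved verbatim as data but is a
  reporting convention of the source, not a value this package would
  compute.)

## Sex assignment

Each scat is assayed twice with a ZFX probe and twice with a ZFY probe.
The decision rules are total over all 16 amplification patterns: male if
any ZFX *and* any ZFY amplified; female if any ZFX but no ZFY; otherwise
excluded (with the ZFY-only pattern tracked separately as it indicates
contamination risk rather than mere dropout). A male is misclassified as
female only when both ZFY reactions drop out. The per-reaction dropout
$q$ is estimated from males via the fraction $f$ with exactly one positive
ZFY reaction: conditional on classification as male,
$f = 2q(1-q)/(1-q^2) = 2q/(1+q)$, so $\hat q = f/(2-f)$ and the
two-reaction false-negative rate is $\hat q^2$. The source study does not
state its estimator; this conditional-binomial inversion is the minimal
probability model consistent with its description ("occurrence of only one
of the two ZFY reactions ... within a sample that was classified as
male"), and an unconditional variant (solving $f = 2q(1-q)$) is available
behind a flag. With $f = 0.2075$, $\hat q = 0.1158$ and
$\hat q^2 = 1.34\%$, matching the study's reported 1.35% to rounding.

## Diet profiles

Read counts are closed to proportions per sample (zero counts are
structural zeros, not missing). Orders are sums of member species;
closure is conserved. Salmonid proportions are split into juvenile and
adult pseudo-orders using hard-part ratios resolved through a fallback
chain — sample, then month (within location and year), then season
(within location and year, then a global season entry), then an all-adult
default — with the scope used reported. The split is applied per salmonid
species by default (a pooled variant exists) and conserves the
Salmoniformes total exactly. Benthic diet fractions sum the proportions of
benthic-annotated taxa; taxa of unknown habitat count as non-benthic and
their total share is warned about. The packaged habitat annotation is an
illustrative starter table for common Salish Sea prey, not a curated
authority — users should supply their own.

## Mixed models of logit(PSi)

Because PSi is doubly bounded, it is logit-transformed before modelling;
exact 1 (identical diets) is clamped to $1 - 10^{-6}$ with a warning
(PSi = 0 is impossible in retained groups since every sample contributes
to its own group diet, but the same clamp guards the lower boundary). The
model family is Gaussian REML fits of logit(PSi) on Sex, Month (unordered
categorical) and their interaction, each with random intercepts for Sample
Size, Location and Year. "Sample Size" enters as a categorical grouping
factor whose levels are the distinct group sizes — the only reading under
which a size can carry a random intercept. Optimization is delegated to
`lme4::lmer`; the package owns the family definition, AIC bookkeeping
($-2\,\mathrm{logLik} + 2k$, $k$ = fixed coefficients + variance
components + residual), Akaike weights
($w_i = e^{-\Delta_i/2} / \sum_k e^{-\Delta_k/2}$), and
variance-component $r^2$ (marginal: fixed-effect fitted-value variance
over the total; conditional: fixed plus random over the total). A random
factor observed at a single level is dropped with a warning rather than
crashing the fit; variance components estimated at zero warn and report 0.
Absolute AICs are data-dependent and never compared across datasets —
only weight arithmetic from a fixed model set is. Recomputing weights from
the packaged model table reproduces its third and fourth printed weights
(2.10e−07, 1.65e−11) but not the second (printed 0.03 where the formula
gives 3.1e−04); the package follows the formula.

## Correlations

All correlations are Spearman's rank (the data are heteroscedastic and
bounded). rho is the Pearson correlation of mid-ranks; p-values use
exhaustive permutation enumeration for $n \le 8$ and the
$t$-approximation above. (Enumeration to $n \le 10$ was considered and
rejected: $10!$ permutations buy no accuracy the $t$-approximation lacks
at that size.) Order–PSi correlations run over *all* samples of the
subset, zeros included; the per-order occurrence count is descriptive.
The Bonferroni divisor is the number of base orders (13 in the packaged
annotation, giving $\alpha = 0.0038$); the juvenile/adult pseudo-orders
inherit that threshold rather than inflating the divisor. The sample-size
bias diagnostic correlates group mean PSi with group size $N$; since
$1/N$ is strictly decreasing in $N$, this is exactly the negative of a
correlation with the theoretical minimum, and the $N$ orientation is
reported because it matches the sign convention of the published value
(−0.231). Sex-ratio pairing joins male and female groups sharing
location, month and year; percent female and the sample-weighted mean PSi
of the pair are correlated, by default over pairs whose two groups are
both retained (the source does not state its inclusion rule; this is the
conservative choice, and it is configurable).

## The simulator

`simulate_study()` generates complete studies under a
Dirichlet-multinomial model: per group a base diet
$q_0 \sim \mathrm{Dirichlet}(\alpha_0 \mathbf{1}_K)$ (default
$\alpha_0 = 0.35$ over the 30 annotated taxa, giving sparse, zero-rich
compositions typical of metabarcoding), individual diets
$p_i \sim \mathrm{Dirichlet}(c\, q_0)$, and counts
$\sim \mathrm{Multinomial}(d_i, p_i)$ with
$d_i \sim \mathrm{round(lognormal)}(\log 2000, 0.7)$ floored at 100
reads (depths are nuisance, not signal). The concentration $c$ is the one
specialization knob: mean PSi is monotone increasing in $c$, which the
acceptance suite verifies on a fixed grid with Monte Carlo error bars.
Defaults are the conditions of the motivating study: the group template
(keys and sexed sample sizes) is its 111-row group table; sexing uses a
0.25 sample-level extraction-failure rate with per-reaction dropouts 0.05
(ZFX) and 0.116 (ZFY), reproducing its ~75% success rate and ~1.35%
ZFY false-negative rate; and the concentrations (female 2, male 4) put
simulated mean PSi near the observed ≈ 0.4 with females more specialised.
Hard-part juvenile fractions are month-scope Beta(2, 2) draws. A truth
record (flat key-value parameters plus a per-sample table of true sex and
concentration) is emitted alongside every dataset so recovery tests never
reconstruct truth from outputs.

What the simulator does *not* emulate: PCR amplification bias between
taxa (the source applies no correction either), chimeras, spatial
movement or between-scat dependence from shared individuals. Passing
tests therefore demonstrate correctness of the estimators under a clean
compositional model, not robustness to amplification bias in real
metabarcoding data.

## Numerical choices

* Proportion closure is validated to $10^{-9}$; the salmon split
  conserves its order total to $10^{-12}$; PSi respects its group lower
  bound to $10^{-12}$.
* Bootstrap CIs are percentile bootstraps of the mean (default
  $R = 100{,}000$, 95%), reported both as bounds and as a single
  half-width; resampling is chunked so memory stays bounded, and a seed
  argument gives bit-identical intervals without touching the global RNG.
* Skewness and kurtosis are moment estimators ($m_3/m_2^{3/2}$,
  $m_4/m_2^2$); kurtosis is non-excess (normal = 3) by default — the
  reading consistent with the published pair (2.66 raw, 5.21
  transformed) — with an excess switch.
* All simulation draws derive from a single config seed via
  `withr::with_seed`; pipeline reruns with identical inputs and seed are
  byte-identical on disk.

## Problem sizes used by the test-suite

Statistical checks run at sizes chosen to make Monte Carlo error small
relative to the asserted effect: bootstrap coverage over 500 simulated
datasets ($n = 100$, $R = 2000$, asserted within 93–97%); dropout
recovery on $5\times 10^4$ simulated assays per grid point; PSi
monotonicity at 2000 replicate groups per concentration; mixed-model
recovery at $n = 2000$–5000 per fit with 100 replicates for the
interaction-ranking check.

## Known limitations and source-table inconsistencies

The packaged summary tables are stored exactly as printed in the source
study, and the printed tables are internally inconsistent. The sexing
count table is self-consistent (its cells reproduce every printed row,
column and grand total, 1,145). The group table's 111 rows, however, omit
three groups that the sexing counts imply (Comox 2012 July female, N = 13;
Cowichan Bay 2012 August male, N = 13; Fraser River 2013 September male,
N = 20). As a result the published accounting — 1,083 retained samples,
mean theoretical minimum 0.103, median 0.091, bias rho −0.231,
sample-weighted mean PSi 0.399 — was evidently computed on the fuller
data: from the printed table alone one obtains 1,036 samples in 86
retained groups, mean 0.1044, median 0.100, rho −0.256 and weighted mean
PSi 0.3885. Adding the three missing groups reproduces the published
mean and median (0.1032, 0.0909) and nearly the sample count (1,082),
but their per-group PSi values are printed nowhere, so full
reconstruction is impossible. `reproduce_reference_targets()` and the
acceptance tests report these comparisons honestly rather than adjusting
the data or the tolerances. Separately, the study's abstract reports
PSi = 0.392 (CI 0.013) where its results section reports 0.399
(CI 0.026); the package reproduces the results-section definition and
makes no attempt to reconcile the two.
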