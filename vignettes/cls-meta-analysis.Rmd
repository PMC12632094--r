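---
title: "Consensus ranking of chronological-lifespan screens with clsmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ranking of chronological-lifespan screens with clsmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clsmeta)
```

## The problem

Genome-wide gene-deletion screens of yeast chronological lifespan (CLS —
the time a non-dividing population stays viable in stationary phase)
disagree substantially: different media, strain backgrounds, ploidies,
auxotrophies and read-outs produce gene rankings whose pairwise Spearman
correlations are modest at best. No single screen can therefore be read as
"the" genetic landscape of chronological aging. `clsmeta` integrates such
heterogeneous screens into one consensus longevity ranking, quantifies why
the screens disagree, characterizes what the consensus ranking contains,
and estimates relative lifespans from competitive-aging validation assays.

Every stage also has a synthetic counterpart with recorded ground truth,
so the full pipeline is testable without any external download.

## Harmonization and concordance

Each screen enters as one representative lifespan value per gene deletion
(`load_screen_table()`), oriented so that larger means longer-lived; an
orientation flag handles screens whose native scale runs the other way.
Genes with missing values are dropped per dataset rather than imputed —
they are simply *not measured* by that screen. Ranks use the average-tie
convention (`rank_genes()`), which keeps downstream Spearman statistics
consistent; the rank sum is always N(N+1)/2.

Between-screen agreement is measured two ways:

* `spearman_matrix()` — tie-aware Spearman correlation over the genes
  shared by all screens, with two-sided p-values from the t
  approximation. A brute-force rank-difference oracle backs this in the
  tests.
* `tail_jaccard()` — Jaccard overlap of the top (long-lived) or bottom
  (short-lived) fraction of two screens' rankings, computed over their
  pairwise-shared genes; tail size is `floor(fraction * N)`, minimum 1.
  Overlap must be defined on a common universe, which is why tails are
  re-ranked within the shared genes rather than each screen's full list.

`shared_variable_model()` then regresses the pairwise correlations on
"shared condition" indicators — one indicator per experimental variable,
equal to 1 when both screens of a pair have the same level. The response
is the raw correlation (no Fisher transform: effects are read directly as
average changes in correlation), and constant indicators are dropped as
non-estimable rather than silently absorbed.

## Dataset reliability and weights

A curated catalog of deletions with validated long/short phenotypes from
small-scale assays (CFU counts, live/dead staining) serves as truth for
scoring each screen as a classifier. `roc_curve()` uses minus the rank as
the score, sweeps all thresholds (tied scores advance jointly, giving the
trapezoidal segment), and reports the area under the curve, which equals
the Mann–Whitney statistic `auc_mann_whitney()` — the probability that a
random long-lived deletion outranks a random short-lived one. The
long-lived class is the positive class by default; a flag flips it.
Catalog genes a screen never measured are skipped, and genes whose
curated evidence came from the same study can be excluded to avoid
common-source bias. `make_weights()` converts AUCs (or a priority vector,
or nothing) into normalized criterion weights.

## PROMETHEE II consensus ranking

The integration itself is PROMETHEE II outranking with the usual
preference function: on each criterion (screen) an alternative (gene) is
fully preferred to another exactly when its score is strictly larger —
ties carry no preference. Pairwise preferences are aggregated with the
criterion weights and averaged into net flows,

$$\phi(a) = \frac{1}{n-1}\sum_{b \neq a}\left[\pi(a,b) - \pi(b,a)\right],
\qquad \pi(a,b) = \sum_j w_j\,P_j(a,b),$$

and the consensus rank orders genes by decreasing phi-score. Exact phi
ties break lexicographically by gene identifier so the ranking is
deterministic.

Genes absent from some screens are the delicate part. `net_flows()`
aggregates over the criteria observed for *both* members of a pair and
offers two policies: `renormalize` (default) rescales the weights to sum
to one over those criteria, keeping phi in [−1, 1] and unbiased toward
zero for low-coverage genes; `zero_preference` leaves unobserved criteria
as zero contribution, shrinking low-coverage genes toward the middle.
Both are exposed because the choice can move printed ranks; sensitivity
analyses should run both. A pair with no mutually observed criterion
contributes zero preference either way (logged, never an error), and the
1/(n−1) normalizer always uses the total number of alternatives.

The default implementation groups genes by missingness pattern and counts
strictly-worse/strictly-better genes per criterion (for the usual
function, the summed preference of a gene over a group is just a count);
`method = "brute"` is the literal O(n²) sweep, and the two are held equal
to 1e-12 in the tests, alongside an independent outer-product oracle.

## Characterizing the consensus rank

* `rank_ecdf()` / `rank_shift_test()` — cumulative distribution of a gene
  set along the ranking against the uniform diagonal, with a Wilcoxon
  rank-sum test of set versus complement (normal approximation with tie
  correction; exact enumeration for groups of at most 8). Because the
  complement is the rest of the ranking, testing "set vs complement" and
  testing "set vs uniform placement" are the same test here.
* `tail_enrichment()` — one-sided hypergeometric over-representation of a
  set in the top or bottom `floor(fraction * N)` ranks (minimum 1; the
  rounding convention is ours to fix since only the fraction is ever
  stated). `tail_enrichment_sets()` applies it across a collection with
  Benjamini–Hochberg correction within that family only.
* `rank_value_correlation()` / `decile_trend()` — tie-aware Spearman
  correlation between rank and a per-gene covariate (growth rate,
  measured relative lifespan), and contiguous rank-bin means with t
  confidence intervals (deciles by default, each bin needing at least two
  genes). A growth-defect threshold of G < 0.95 is the conventional
  default for splitting pleiotropic from growth-neutral deletions.

## Preranked gene-set enrichment

`preranked_gsea()` runs the weighted running-sum statistic on phi-scores:
walking the ranked list, hits rise by $|\phi|^{p}$ (normalized by the hit
total; exponent 1 by default), misses fall by 1/(N − |S|), and the
enrichment score is the signed maximum deviation. The leading edge
collects the set genes before the maximum (positive ES) or after the
minimum (negative ES).

The null is a gene-label permutation: each permutation re-places the set
uniformly at random along the list. This is the only null available to a
preranked analysis — there are no sample-level data to permute. The
p-value is the add-one-smoothed fraction of same-sign permuted scores at
least as extreme, NES divides ES by the mean same-sign permuted |ES|, and
BH-FDR is applied across the retained sets. Sets are filtered to 10–100
genes *after* intersection with the ranked universe, since that is the
size that actually enters the statistic. A fully tied statistic makes the
ranking arbitrary, so ES is defined as 0 with p = 1. The permutation
inner loop is compiled (Rcpp); permutation pools are shared across sets
of equal size, which leaves marginal p-values unchanged under the null
and keeps cost proportional to the number of distinct sizes. The default
is 10,000 permutations and a mandatory seed.

`term_network()` links significant terms whose gene-content Jaccard index
strictly exceeds 0.1, clusters terms by average-linkage on 1 − Ji, and
names each cluster after its largest member term. The default cut height
of 0.75 groups terms sharing roughly a quarter of their content or more
through chains of overlap; it is a display-granularity choice, exposed as
a parameter.

## Transcriptional regulators

For each functional cluster's pooled leading-edge genes,
`regulator_association()` computes the fraction regulated by each TF of a
documented-regulation network and a one-sided hypergeometric p-value
against the gene universe; TFs are retained when p < 0.01 in at least one
cluster. This local-network association preserves the displayed quantity
(fraction of leading-edge genes regulated) of graph-ranking web services
while remaining fully reproducible offline. `classify_breadth()` labels
retained TFs global (significant in at least two thirds of clusters),
local (at most 2) or meso — the thresholds are configurable because the
breadth notion is qualitative.

## Competitive-aging survival model

In the validation assay, an RFP-tagged mutant and a CFP-tagged wild type
age together; aliquots taken at aging day $T_i$ regrow while a plate
reader records OD and both fluorescence channels at outgrowth hours
$t_j$. After per-channel background subtraction (mean of the
opposite-color single-strain reference wells at each sampling point,
floored at one fluorescence unit before the log; missing reference points
fall back to the nearest sampling point with a warning), the log ratio is
fitted per plate by one joint least squares:

$$\ln\frac{\mathrm{RFP}}{\mathrm{CFP}}\Big|_{w,T_i,t_j}
 = A_w + S_w T_i + G_w t_j + C_{T_i,t_j} + \varepsilon .$$

$A_w$ is the initial log viable-cell ratio, $S_w$ the survival slope per
aging day, $G_w$ the growth-rate difference per outgrowth hour, and
$C_{T_i,t_j}$ a plate-level systematic offset shared by all wells at each
sampling point. WT/WT wells have their S and G columns omitted — the
constraint S = G = 0 is exact, and these wells are what identifies C
(without them, a day-linear component of C would be confounded with a
common shift of all $S_w$). C carries a sum-to-zero constraint, the
minimal identifiability condition; its overall mean is absorbed by the
$A_w$. Only timepoints with OD inside a configurable window (defaults
0.02–1.0, where plate readers are linear) enter the fit, and rank
deficiency is reported by naming the unidentifiable columns. Relative
lifespan is L = 1 + S exactly.

## The synthetic generator

`simulate_screens()` draws a latent per-gene longevity effect
$\lambda \sim N(0,1)$ and per-screen scores
$\beta_d \lambda + N(0, \sigma_d^2)$ with optional monotone distortion
(identity, rank or logistic — all rank-preserving) and a uniform coverage
mask. The defaults — five screens, $\beta = 1$, $\sigma = 0.5$, 2000
genes in the scaled-down bundles — give pairwise correlations around 0.8,
i.e. an easier regime than real screens; they are the fixed conditions of
the end-to-end recovery checks, chosen so that recovery failures indicate
implementation faults rather than noise. Curated labels come from the
latent tails with a configurable flip rate; planted gene sets are drawn
by exponential tilting $e^{\pm s\lambda}$, which for a standard-normal
latent is exactly a $\lambda \pm s$ population; regulator networks plant
global and local TFs over supplied clusters; plates are generated from
the survival model forward with known A, S, G, C and Gaussian noise.
Everything is bit-reproducible from (parameters, seed), and each
generator returns its truth object alongside the data.

What the generator does *not* emulate: dataset-specific score
distributions and heavy tails, block (non-uniform) missingness beyond the
provided option, label curation biases, non-linear outgrowth kinetics and
optical saturation. Passing the recovery tests therefore demonstrates
correctness of the estimators under their own assumptions, not robustness
to every artifact of real screens.

## Numerical conventions

* Phi ties break lexicographically; generated rankings are fully
  deterministic given config + seed.
* Equal running-sum maxima of opposite sign resolve to the positive
  score.
* Weights must sum to one within 1e-12 after normalization; zero-weight
  criteria are exactly removable from any analysis.
* Tail and bin sizes always use `floor`, minimum 1.
* BH correction is applied within each analysis family (GSEA terms, ORA
  sets, TF-by-cluster tests) and never across families.

## Scales used by the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale: 2000-gene
universes, five screens, 40–2000 gene sets, 1000 permutations, and 200
plate wells. These sizes were chosen so every stage's statistical
behavior (oracle equivalence, type-I error, interval coverage, planted
recovery) is measurable in minutes while leaving the estimators identical
to what a full-genome run would use.

## Known limitations

* PROMETHEE II propagates no uncertainty from the input screens; rank
  stability under weight perturbation is the user's sensitivity analysis
  (`make_weights()` makes the schemes cheap to swap).
* The printed ranks of a historical analysis can be policy-sensitive for
  genes missing from some criteria; both missing-data policies should be
  reported.
* The regulator step measures association against a fixed documented
  network; it does not infer regulation and inherits the network's
  ascertainment biases.
* Cross-plate normalization of competitive-aging data is out of scope:
  C is per plate, and comparisons across plates ride on the shared WT/WT
  anchoring.
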