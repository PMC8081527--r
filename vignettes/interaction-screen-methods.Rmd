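---
title: "Scoring genetic interactions in paired CRISPRi fitness screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions in paired CRISPRi fitness screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

A pooled CRISPRi screen transforms a strain carrying an inducible dCas9
with a genome-wide sgRNA plasmid library (here modelled with five guides
per gene plus non-targeting controls), induces knockdown, and lets the
pool compete for a fixed number of growth generations. Sequencing the
plasmid pool before induction (t_start) and after growth (t_end) turns
guide abundances into a per-guide fitness readout. Running the same
library in two isogenic backgrounds — a reference strain and a deletion
mutant — and comparing per-guide fitness between them exposes genetic
interactions: genes whose knockdown is disproportionately harmful (or
beneficial) in the mutant.

`crisprigi` implements the full scoring path from raw count tables to
tiered interaction calls, plus a generative simulator used to calibrate
and stress-test the scoring.

## Per-guide fitness

Each sample column is first normalized by sample size. The default
target (`normalization_target = "mean_depth"`) scales every column to
the mean raw column total, which keeps normalized values on a
read-count-like scale so that the coverage filter below ("100 normalized
reads") retains its plain meaning; `"per_million"` (CPM) is available
when an absolute scale is preferred. Replicate columns of the same
(background, timepoint) are then summed — pooling increases effective
depth rather than averaging away Poisson noise — and the pooled columns
are normalized by sample size once more.

Guides with fewer than `min_norm_reads = 100` normalized reads in the
pooled start timepoint of a background are discarded there: with so few
starting reads the log-ratio is dominated by sampling noise and
pseudocount bias. The comparison is strict (`< 100` fails). The filter
is applied to the pooled, renormalized start column, the only point in
the workflow where a screen has a single start value per guide.

Fitness per guide and background is

$$\mathrm{log2FC} = \log_2\!\frac{\mathrm{norm\ reads}_{end} + 1}
{\mathrm{norm\ reads}_{start} + 1},$$

with +1 pseudocounts keeping full dropouts finite. Because induction
efficiency and bulk growth differ slightly between cultures, each
background is centred by subtracting the median log2FC of its
non-targeting control guides, anchoring neutral fitness at exactly 0.
Only controls that pass the coverage filter enter the median
(low-coverage controls carry pseudocount bias), and an even-sized
control set uses the conventional mean-of-middle-pair median. A guide
must pass the filter in *both* backgrounds to be comparable across
screens; one-sided survivors are excluded and reported rather than
silently dropped.

One consequence of the mean-depth target worth knowing: multiplying all
raw counts of one sample by a constant leaves every log2FC unchanged
under the CPM target exactly, but under `mean_depth` the common target
shifts with that sample's total, which moves the absolute scale feeding
the +1 pseudocount. The effect vanishes as depth grows and is orders of
magnitude below the noise floor at screen-typical depth, but tests of
exact invariance use the CPM target.

## Gene-level interaction scores

For every guide passing both filters, the interaction signal is

$$\Delta = \mathrm{log2FC}^{mut}_{centred} - \mathrm{log2FC}^{ref}_{centred},$$

and guides are ranked ascending: strongest synthetic-sick signal first,
strongest suppressor signal last. The **GI score** of a gene is the
signed median of its guides' $\Delta$ values — robust to one or two
inefficient or off-behaving guides out of five.

Significance uses the minimum hypergeometric (mHG) ranked-list test.
With $B$ guides of one gene among $N$ ranked guides, and $b_n$ of them
in the top $n$, the statistic is

$$\mathrm{mHG} = \min_{1 \le n \le N-1} \; P\big(X \ge b_n\big), \qquad
X \sim \mathrm{Hypergeom}(N, B, n),$$

the best prefix enrichment the ranking offers the gene. Because the
minimum optimizes over prefixes, the statistic is not a p-value; the
package computes the exact null p-value $P(\mathrm{mHG} \le s)$ under
uniform placement of the $B$ labels by dynamic programming over the
(ranks seen, labels seen) lattice. The DP is carried in probability
space: cell values are null path masses (all $\le 1$), rejected mass is
accumulated directly so small p-values suffer no cancellation, and no
counting-scale rescaling is needed. Cells are compared against the
rejection threshold with a relative tolerance of $10^{-9}$ so that exact
ties on the discrete tail support — which are common, since the observed
statistic is itself one of those tails — are classified identically
regardless of which numerical route produced them. The DP costs
$O(N B^2)$ per gene and is implemented in C++; at $N \approx 10^4$,
$B = 5$ a full screen of 2000 genes scores in seconds. A permutation
estimator with the add-one correction is kept in pure R as an
independent Monte-Carlo oracle, and an exhaustive-enumeration oracle
covers every labelling up to $N = 8$ in the tests.

Three design points were genuinely open:

* **Direction.** A single ranked list reads the synthetic-sick
  direction; suppressor interactions live at the other end. The test is
  run on the ascending and on the reversed list, and the smaller
  one-directional exact p-value is Bonferroni-doubled (capped at 1).
  This captures both interaction signs at a controlled cost — for a
  null gene the two one-sided p-values are negatively associated, so
  doubling is near-calibrated rather than conservative.
* **Ties.** Prefixes are only evaluated at cut points that do not split
  a block of tied $\Delta$ values. Exact ties are measure-zero in real
  data, but degenerate inputs (e.g. an all-zero delta table) would
  otherwise hand significance to whichever gene's guide ids happen to
  sort first; under the tie policy such lists give statistic 1 and
  p-value 1, and the statistic becomes invariant to the arbitrary
  within-tie order — which also makes background-swap antisymmetry
  exact. The null DP treats the realized order as fixed; in tied
  regions it is therefore (slightly) conservative.
* **Magnitude gates.** Hit tiers compare $|\mathrm{GI}|$ — FDR < 0.05
  with $|\mathrm{GI}| > 1$ (tier 1) or $> 2$ (tier 2) — while the
  signed score is reported. Synthetic-sick hits have negative medians,
  so a signed reading of "GI > 1" would exclude exactly the hits the
  tiers exist to flag.

p-values are corrected with Benjamini–Hochberg step-up FDR (the
standard choice when only "FDR" is specified); genes with no surviving
guides are excluded from the correction's $m$ and reported with absent
statistics.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the screen design the scoring targets:
2000 genes × 5 guides plus 100 non-targeting controls, two backgrounds,
17 generations of induced growth, two replicates, multinomial
sequencing at 10⁴ expected reads per guide at both timepoints. Growth
is deterministic exponential competition from uniform initial
abundances: guide $i$ targeting gene $g$ grows as
$2^{G \cdot s_g \cdot e_i}$ relative to controls, where $s_g$ is the
per-generation fitness effect in the active background and
$e_i \in [0.6, 1]$ the guide efficacy (linear partial-knockdown model —
the first-order choice, and the one that creates the within-gene guide
variability the mHG test must tolerate). Sequencing is the only noise
source; every sample draws one multinomial with a counter-derived
sub-seed so results are bitwise reproducible from the master seed and
independent of sample order.

Background fitness effects are 0 for 70% of genes and
$-|N(0, 0.1)|$ per generation for the rest — knockdowns are
overwhelmingly neutral-to-deleterious, and 0.1/generation puts the
deleterious tail at log2FC ≈ −2 to −5 over 17 generations, the range a
genome-wide knockdown screen occupies. Planted interactions add
−0.15/generation in the mutant background to 5% of genes, i.e. an
expected GI near −2 at the mean efficacy 0.8 — the strong-hit regime
the tier thresholds encode.

Deliberately **not** modelled: cloning or dilution bottlenecks (initial
abundances are uniform), growth noise and drift, dCas9 polar effects
and operon structure, guide off-targets, PCR jackpots. Passing the
calibration and recovery tests therefore shows the scoring behaves
correctly under multinomial sampling noise around exponential
competition; it does not show robustness to overdispersion from
bottlenecks or amplification, which real screens add on top. The
coverage filter and the rank-based test are the two components designed
to absorb such effects, but that absorption is not quantified here.

## Numerical and degenerate-input choices

* Rank ties break by (Δ, guide id) with byte-order comparison:
  deterministic across locales.
* The statistic caps at 1; a single-item list or a gene whose only
  guide sits at the last rank has no informative prefix and scores 1.
* `mhg_exact_pvalue()` refuses lattices beyond a configurable cell
  budget (default 10⁸) and points to the permutation fallback.
* A sample with zero total reads, a background whose controls all fail
  the filter, and a gene with no guides in the ranked list are each
  explicit, named errors or flagged rows — never silent zeros.
* Exact p-values are never 0 by construction (the observed placement
  itself has positive null mass); the permutation estimator uses the
  +1 correction for the same reason.

## Problem sizes used in the shipped checks

The test suite and the analysis scripts run the full default design
(2000 × 5 + 100 guides, depth 10⁴) for calibration and recovery —
about 15 s per screen — and smaller libraries (30–100 genes, depth
10³–10⁵) where a property is being isolated rather than integrated:
closed-form growth recovery uses 50 genes at depth 10⁵, Monte-Carlo
agreement uses ranked lists of length 1000 with 10⁵ permutations.
Enumeration oracles cover every labelling up to list length 8.

## Known limitations

* The exact null assumes exchangeable ranks; heteroscedastic guide
  noise (strongly depleted genes have noisier Δ) mildly violates this.
  At the shipped depth the null calibration stays within [0.045,
  0.06]; at much lower depth the test can become anti-conservative for
  strongly deleterious genes.
* The two-directional Bonferroni doubling assumes the two orientations
  compete; a study interested only in synthetic-sick interactions can
  halve the reported p-values conceptually, but the package does not
  expose a one-sided mode.
* GI magnitude tiers are on the median Δ, which saturates when t_end
  counts hit zero in only one background; with 17 generations and the
  default depth the floor sits near |Δ| ≈ 13, far from the tier
  thresholds.
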