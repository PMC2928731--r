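---
title: "Models and methods behind virophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind virophase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virophase)
```

virophase analyses short viral amplicons sequenced in both directions on a
Sanger instrument, with two complications that shape every design choice in
the package: samples can carry **two co-infecting haplotypes at unequal
abundance**, visible as double peaks in the chromatogram, and the sequences
evolve with **extreme among-site rate heterogeneity**, so a handful of
sites mutate recurrently while most never change. This vignette explains
the models, the tunable parameters, and the choices made where the design
was genuinely open.

## Phasing from double peaks

A site is accepted as heterozygous only when, on **both** strands
independently, the second-highest peak reaches at least `minor_ratio_min`
times the highest, and the two top base identities agree between strands.
Strand consistency is the load-bearing filter: dye blobs and polymerase
slippage produce secondary peaks on one strand, a genuine second haplotype
produces them on both.

* `minor_ratio_min` (default **0.25**, dimensionless intensity ratio): no
  published threshold exists for "two overlapping peaks", so the default
  was chosen once to sit well above the simulator's baseline-noise regime
  (noise SD ≤ 0.05 against a unit major peak) and well below the smallest
  minor-haplotype signal of interest (abundance ratio 0.6 gives a
  minor/major ratio of 0.67). It is configurable; raising it can only
  remove calls (a tested monotonicity property).
* Phasing assigns, at each heterozygous site, the strand-averaged major
  base to the high-abundance haplotype and the minor base to the
  low-abundance one; everywhere else both haplotypes carry the consensus.
  A consequence of the threshold: with noise-free signals the phase ∘
  simulate identity holds for abundance ratios in (0.5, 0.8] — beyond 0.8
  the minor peak drops below a 0.25 ratio by arithmetic, not by noise.
* Two failure modes are surfaced as errors rather than guesses: a site
  where the *major* base differs between strands (uninterpretable relative
  abundance; at the boundary regime of ratio 0.6 with noise SD 0.05 this
  occurs in a few percent of samples and is a refusal, not a wrong
  answer), and a site with three peaks above threshold on both strands
  (more than two haplotypes; out of scope by design).
* Records pass quality control iff their fraction of `N` bases is
  **strictly below 0.18** — the boundary case of exactly 18% fails.

## The substitution model

The likelihood engine implements the general time-reversible (GTR) model:
rate matrix $Q_{ij} = r_{ij}\pi_j$ with six exchangeabilities $r_{ij}$ and
stationary frequencies $\pi$, normalised so branch lengths are expected
substitutions per site. $P(t) = e^{Qt}$ is computed by eigendecomposition
of the $\pi$-symmetrised generator $D Q D^{-1}$, $D = \mathrm{diag}(\sqrt
\pi)$ — symmetric for any reversible model, hence numerically stable, and
the decomposition is cached per model.

Rate heterogeneity uses the discrete-gamma approximation: $K$
equal-probability categories (default **8**) whose rates are the
conditional means of a mean-one gamma with shape $\alpha$ within its
quantile bins. The bin mean is evaluated by the exact incomplete-gamma
identity ($E[X; a<X<b] = F_{\alpha+1}(b) - F_{\alpha+1}(a)$ for
$X \sim \Gamma(\alpha, \alpha)$), which is the closed form of the bin-mean
integral (the "mean" method, not the median method); a test checks it
against direct numerical integration. An invariant-site proportion
$p_{inv}$ mixes in a point mass at rate zero; a column with missing bases
counts as possibly-invariant for state $s$ iff every non-missing base
equals $s$, so the invariant mass of an all-`N` column is 1.

Site likelihoods are computed by Felsenstein pruning over unique site
patterns (with α ≪ 1 most columns are constant, so pattern compression
cuts the work by roughly an order of magnitude); `N` and `-` contribute
partial likelihood 1 for every state. Scaling is unnecessary at the
package's intended scale (tens of taxa): partial likelihoods stay far from
double-precision underflow.

## Optimization and tree search

`phylo_ml()` uses coordinate ascent in a fixed order — branch lengths,
then α, then $p_{inv}$, then exchangeabilities — repeating until the
log-likelihood improves by less than `tol_lnl` (default $10^{-4}$). Each
parameter gets a bounded golden-section line search (α on a log scale over
$[10^{-2}, 10^4]$, exchangeabilities over $[10^{-4}, 200]$ relative to
$r_{GT} = 1$, branch lengths over $[10^{-9}, 20]$). For the branch sweep
the tree is decomposed, per rate category, into downward partials $D_e$
and cross-edge contexts $F_e$ so that a candidate length for edge $e$
costs a single 4×4 product instead of a full pruning pass; caches are
rebuilt after each edge update to keep the ascent exactly monotone. Base
frequencies are fixed at their empirical counts ("+F" convention, counted
as three free parameters) — a deliberate trade of a negligible likelihood
gain for a much cheaper and more stable search.

Because the discrete-gamma family only approaches the homogeneous model in
the α → ∞ limit, a +Γ fit can numerically land a hair *below* its nested
null. Where a nested pair is compared (the pipeline's LRT stage), the
richer model is warm-started from the null's optimum and its likelihood is
floored at the null's — the null sits on the boundary of the richer
model's parameter space, so this floor is mathematically valid, never an
inflation.

Tree search is NNI hill climbing from a neighbor-joining start on
Jukes–Cantor distances (saturated pairs, $p \ge 0.75$, are capped and
flagged). All rearrangements of each internal edge are evaluated in a
deterministic order; the first move improving lnL by more than `tol_lnl`
is accepted and the scan restarts. This is the classic local search: it
recovers well-separated topologies (internal branches ≥ 0.1 at 1000
sites, a tested property) but can stop at local optima on hard instances —
SPR/TBR and bootstrap support are out of scope.

## Model comparison

The likelihood ratio statistic $2\Delta\ln L$ between nested fits is
referred to $\chi^2_{df}$ with $df$ = the difference in free-parameter
counts. For the +Γ addition $df = 1$ is used — the standard practice even
though the null value α = ∞ lies on the boundary, which makes the test
conservative (its type-I error runs below nominal; the calibration test
asserts ≤ 0.08 at the 0.05 level over 200 replicates rather than equality).
The model family is restricted to {JC, HKY, GTR} × {plain, +I, +Γ, +Γ+I}:
enough to span the hypotheses of interest without re-implementing a full
model-scan tool. One ambiguity was left generic on purpose: the
rate-heterogeneity LRT can be run as GTR vs GTR+Γ or GTR+I vs GTR+Γ+I;
`lrt()` accepts any nested pair and the pipeline defaults to the latter.

## Per-site steps and codon classification

`fitch_site_steps()` computes, per column, the minimum number of state
changes on the (arbitrarily rooted) ML topology by the Fitch set method,
with `N`/`-` carrying the full state set. The implementation uses
bitmasks and is shared with the label-association permutation test, which
uses the parsimony score of a categorical host label as its clustering
statistic.

Amino-acid classification needed a convention, since none is standard for
this situation: each variant base observed at a site is substituted, one
at a time, into the **column-consensus codon**, and the site is flagged
when any two variants translate differently. A flagged site hit at least
twice (`min_steps >= 2`) is a recurrent amino-acid replacement. In
pairwise synonymous counting, codons with two or more internal differences
(or missing context) are reported as `ambiguous` rather than silently
attributed. The reading frame defaults to offset 0 of the analysis window
and is configurable — the amplicon sits inside a long ORF, but the codon
offset of a trimmed window is a free parameter of the analysis.

The mutation-rate bound divides variable synonymous sites by (sequence
length × divergence time); treating every synonymous variant as a
substitution accumulated since the dated reference makes it an upper
bound. With 3–10 synonymous differences over 500 bp and 11 years this
spans 5.5 × 10⁻⁴ to 1.8 × 10⁻³ substitutions/site/year.

## The PHI recombination test

Two sites are incompatible when no single tree explains both. The refined
incompatibility score of a pair is computed **exactly** as the cycle rank
$E - V + C$ of the partition intersection graph (marginal states as
vertices, observed joint states as edges): zero iff the graph is a forest,
and for binary sites identical to the four-gamete test. Two exact
shortcuts make the all-pairs computation fast: states carried by a single
sequence only ever add leaf edges (they are masked without changing any
score), and pairs of two-state columns reduce to four cross-products of
indicator matrices evaluated for all pairs simultaneously.

PHI is the mean score over ordered informative-site pairs at most
`window` (default **100**, matching the statistic's published default)
alignment positions apart. The permutation null shuffles the order of the
informative sites — columns are preserved, spatial arrangement is
destroyed — and recombination shows up as *unusually compatible nearby
pairs*, so the p-value is $p = (1 + \#\{\varphi_{perm} \le
\varphi_{obs}\})/(n_{perm}+1)$, valid (super-uniform) by construction.
Fewer than two informative sites, or no pair inside the window, yields an
honest "untestable" flag rather than a p-value. Breakpoint localisation
(GARD-style) is a documented non-goal: the package answers only whether
recombination is detectable.

## The simulator: what it emulates, and what it does not

The generator reproduces the statistical structure of a small viral
Sanger panel: random coalescent-style genealogies with exponential branch
lengths (any exchangeable random tree suffices for testing — no claim of
demographic realism), GTR+Γ+I sequence evolution using the **same**
discrete-category approximation as the inference (sites draw a category
index uniformly, or rate zero with probability $p_{inv}$), two-haplotype
mixture peaks with the major haplotype at intensity `ratio` and the minor
at `1 − ratio` plus zero-truncated Gaussian noise on both strands
independently, and N-masking concentrated at fragment ends. Defaults
mirror the study conditions: 500 bp sequences, α ≈ 0.1 (the sharply
L-shaped regime), missing fraction below the 18% QC bound, mixture ratio
0.7 (the true abundance ratios in multiply-infected samples are unknown —
only "high" vs "low" peaks is observable — so the ratio is a free
simulation parameter).

Not emulated: dye-specific chromatogram artifacts, base-caller quality
scores, indels (the analysed window is treated as gap-free), and
PCR/RT errors. Passing tests therefore demonstrate correctness of the
*algorithms* under the stated stochastic model, not robustness to every
laboratory artifact.

## Numerical choices and degenerate inputs

* Transition matrices clip round-off negatives to zero and renormalise
  rows; detailed balance is asserted to $10^{-8}$ in tests.
* NJ ties are resolved by ape's internal order; negative NJ branch
  lengths are clamped to zero.
* JC distances at $p \ge 0.75$ (saturation) are capped (default 5) and
  flagged; downstream NJ proceeds with a warning.
* `lrt()` rejects non-nested inputs and a null likelihood above the
  alternative's (beyond $10^{-6}$) as contract errors.
* Degenerate inputs error early and specifically: single-category label
  tests, `n_taxa < 2`, `p_inv` outside $[0,1)$, empty records, negative
  intensities, non-contiguous peak-table positions.

## Problem sizes and reproducibility

All validation runs at what a laptop handles in minutes: likelihood
oracles enumerate internal states up to 5 taxa; Fitch oracles up to 6
leaves; parameter recovery uses 10 replicates of 8 taxa × 5000 sites;
type-I calibration uses 200 replicates each for the LRT (6 taxa × 120
sites) and PHI (8 taxa × 300 sites); PHI power uses ten 20-taxa × 1000-site
mosaics; phasing inversion uses 100 replicates at the boundary regime.
Every stochastic routine takes an explicit integer seed, restores the
caller's RNG state on exit, and the pipeline derives per-stage seeds
deterministically from one master seed, so identical configurations yield
byte-identical reports.

## Known limitations

Exactly two haplotypes per sample; no codon substitution models or dN/dS;
no partitioned models; no bootstrap; NNI-only search; single-linkage
missing-tolerant haplotype grouping can chain distinct haplotypes through
an N-rich record (strict identity is therefore the default census
policy); and α and $p_{inv}$ are jointly weakly identifiable on short
alignments — fits report both, but on 500 bp data only α should be
interpreted quantitatively.
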