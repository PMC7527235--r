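---
title: "The 3-step map alignment model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The 3-step map alignment model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological problem

The superior colliculus (SC) receives two superimposed visual maps: the
retino-collicular (RC) projection from retinal ganglion cells (RGCs) and the
cortico-collicular (CC) projection from layer-V neurons of primary visual
cortex. Visual function requires the two maps to be *aligned*: the retinal
and cortical axons representing the same point of visual space must
terminate at the same collicular location. `mapalign` implements a
three-step developmental model of how this alignment arises, together with
the statistics used to quantify map organization in wild-type and
Isl2-driven knock-in genotypes (ectopic EphA3 receptor or ephrin-A3 ligand
in the Isl2-positive half of the RGC population).

The three steps, run once per seeded simulation:

1. **RC map.** 100 RGCs, indexed along the nasal-temporal axis, are
   assigned to 100 collicular positions along the rostral-caudal axis by
   stochastic energy minimization (below).
2. **Ligand transposition.** Each retinal axon carries its own ephrin-A
   into the SC, so after step 1 the collicular ligand field is the retinal
   ephrin-A gradient *composed with the RC map*. A smooth flip map yields
   the flipped retinal curve; a duplicated map yields a double oscillatory
   gradient.
3. **CC map.** 100 V1 neurons, carrying their own EphA gradient, are mapped
   onto the SC against the transposed ligand of step 2. This is how a
   perturbation confined to the retina propagates to the cortical map.

## The energy model

A map is a bijection $t$ of $N$ source neurons onto $N$ collicular
positions — two axons can never occupy the same termination zone (axon
competition). Its affinity energy is $E = E_\mathrm{chem} +
E_\mathrm{act}$ with

$$E_\mathrm{chem} = \alpha \sum_i R(i)\, L(t_i), \qquad
  E_\mathrm{act} = -\frac{\gamma}{2} \sum_{i \neq j} C_{ij}\, U(t_i, t_j),$$

$$C_{ij} = e^{-|x_i - x_j| / (bN)}, \qquad
  U(t_i,t_j) = e^{-(t_i - t_j)^2 / (2d^2)}.$$

$E_\mathrm{chem}$ encodes forward Eph/ephrin signaling as repulsion: with
$\alpha > 0$, co-monotone receptor and ligand gradients drive high-receptor
axons to low-ligand territory. Only the pairwise swap difference
$\alpha\,(R(i)-R(j))(L(t_j)-L(t_i))$ is determined by that convention; the
sum above is the minimal total energy whose swap difference has this form.
$E_\mathrm{act}$ encodes correlated spontaneous activity under Hebbian
refinement: axons from nearby source positions (correlation $C$) are
rewarded for overlapping terminal arbors (overlap $U$).

The dynamics proposes, at each of $10^7$ iterations per run, a uniformly
random axon pair and exchanges their termination zones with probability
$p = 1/(1 + e^{\beta\,\Delta E})$, $\beta = 4$: energy-neutral swaps are
accepted half the time, strongly unfavorable ones essentially never. The
inner loop is written in C++ ($O(N)$ per proposal; the pair term
$C_{ij}U(t_i,t_j)$ is invariant under the swap and drops out). All
randomness — the Isl2 mask, the initial permutation, the proposal/acceptance
stream — derives from R's RNG, so a run is reproducible from `(genotype,
seed)`; ensemble run $r$ uses `seed + r - 1`.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 200 | chemical (forward signaling) strength |
| `gamma` | 1 | correlated-activity strength |
| `d` | 3 | SC interaction distance (percent of axis) |
| `b` | 0.11 | retinal correlation distance fraction ($R_\mathrm{corr} = bN = 11$) |
| `n_neurons` | 100 | array size per structure |
| `beta` | 4 | acceptance steepness |
| `iterations` | $10^7$ | proposals per map |

Gradients are evaluated on the integer grid $x \in \{1,\dots,100\}$ read as
percent of axis (the closed forms are defined on 0–100; the choice between
$\{1..100\}$ and $\{0..99\}$ shifts values by under 2% and is applied
uniformly). Orientations are fixed so that energy minimization itself
produces the biological layout: retina index 1 = nasal, SC index 1 =
rostral, V1 index 1 = the high-EphA pole. Temporal RGCs (high EphA) then
map rostrally (low ephrin-A), and V1's high-EphA pole maps rostrally
against the transposed gradient.

### Genotypes

Isl2-positive cells are drawn anew each run (50% of the population,
`assign_isl2()`). EphA3 knock-in adds 0.93 (het) or 1.86 (homo) receptor
units to Isl2$^+$ RGCs; ephrin-A3 knock-in adds ligand that travels with
the axon into the SC during transposition. The ectopic ephrin-A3 level per
allele is not constrained by the expression data behind the gradient
equations; the package default is 0.44 — one wild-type ephrin-A3 equivalent
per allele, doubled in homozygotes — exposed as
`genotype_spec("custom", efna3_increment = ...)` for sensitivity analysis.

## Map-organization statistics

All statistics operate on the `(source position, termination zone)` scatter
of a map and are deliberately agnostic about whether the map was simulated
or constructed.

**Intrinsic dispersion index (IDI)** — `idi()`. The mean squared deviation
$\sum_x (y(x) - \bar y)^2 / N$. Read with a global mean ("literal" mode),
any noise-free full-range map scores $(N^2-1)/12 = 833.25$ — a measure of
extent, not scatter. The default "detrended" mode therefore takes $\bar y$
to be the map's own LOESS profile, fitted per branch where branch structure
exists, so the IDI measures within-map scatter about the map's layout.
Branch labels are the Isl2 flags for RC maps; a CC axon inherits the flag
of the RGC sharing its termination zone (the transposed ligand it read came
from that axon). Both modes are exported; the mode is part of the output.

**Local intrinsic dispersion variation (IDV)** — `local_idv()`. The squared
termination difference of neighboring source cells,
$\sum (y(x+1)-y(x))^2$, summed in sliding windows of 10 source neurons
(step 1, window width exposed). Each window is indexed by the collicular
position its retinotopic identity targets in the canonical wild-type layout
so that RC and CC curves share one rostral-caudal axis; a smooth unit-slope
map scores $\mathrm{window}-1$ everywhere, while branch interleaving in a
duplicated map inflates the curve by orders of magnitude. The
**duplication threshold** (`idv_threshold()`) is the minimum over positions
of the per-position median over all wild-type RC and CC curves (the pooled
median lies between the RC and CC median curves). IDV curves are compared
by their above-threshold position sets (Jaccard index, `idv_jaccard()`;
both-empty defined as 1) and by the population covariance of the raw
curves (`idv_covariance()`).

**Alignment index (AI)** — `alignment_index()`. Because both maps are
bijections onto the same collicular grid, comparing raw termination
*distributions* is vacuous; alignment is a property of *which* inputs
share a termination zone. The AI pairs the retinal and cortical axon at
each collicular position and averages the absolute mismatch of their
source representations in common visual coordinates (the V1 axis oriented
so the wild-type RC and CC layouts superimpose; V1 index $v$ represents
retinal position $N+1-v$). A perfectly aligned pair scores 0, a constant
representation offset of $k$ scores $k$, and — the property that motivates
this pairing — a duplicated-but-aligned pair (EphA3 knock-in) scores as low
as wild type, while a dispersed cortical map over a normal retinal map
(ephrin-A3 knock-in) scores high. An alternative completion, pairing by
corresponding source index, conflates duplication with misalignment: in a
duplicated genotype the branch choice of the cortical cell paired to a
given RGC is uncorrelated with that RGC's Isl2 flag, so half the pairs sit
a branch offset apart and the index saturates near half the offset even
when every collicular point receives matched inputs. That reading was
rejected because it cannot call EphA3 knock-in maps aligned.

**LOESS profiling** — `loess_profile()`. `stats::loess` (span 0.75, degree
2, direct surface) through a map's scatter, optionally refitted $N$ times
leaving one point out; the per-position min/max envelope flags influential
points (widest near an outlier). Exact on collinear data.

**Collapse point** — `collapse_point()`. For partially duplicated maps:
per-branch LOESS profiles (span 0.3 — tight enough to track the merge
corner) are evaluated on the source grid; the merge onset is the
half-height crossing of the branch-separation profile, which is symmetric
under profile smoothing and therefore unbiased at a sharp merge, validated
by requiring the separation to fall below `merge_cutoff` (default 5 SC
units, about four wild-type residual standard deviations) at the temporal
end. Runs whose branches never come within the cutoff report `NA` (full
duplication), as do single maps.

**Kolmogorov–Smirnov comparison** — `ks_compare()`. Classical two-sample
$D$ (pooled-sample sweep of the two empirical CDFs) with the large-sample
critical value $c(\alpha)\sqrt{(n+m)/nm}$, $c(0.05) = 1.358$, for
comparing simulated termination distributions with sparse experimental
tracing tables (`read_experimental_maps()`).

**Uncertainty.** Ensemble medians carry bootstrap percentile 95% intervals
(10,000 resamples over runs, internally seeded so summaries are
deterministic; `median_ci()`).

## Synthetic fixtures

`make_fixture()` builds maps with known ground truth on the wild-type flip
layout: `single` (monotone + Gaussian jitter), `duplicated` (two
Isl2-labeled branches, each spanning the source axis over complementary SC
halves), `collapsing` (duplicated up to a programmed source fraction, then
merged, with a sub-position shoulder so the programmed fraction is sharp),
and `misaligned_pair` (an RC/CC pair with a programmed representation
shift, whose AI equals the shift exactly). Noise-free fixtures are exact
bijections; jittered fixtures keep continuous terminations so statistical
contracts hold exactly (the detrended IDI of a jittered single map
converges to $\sigma^2(N - \mathrm{df})/N$, a shade under the jitter
variance, because LOESS absorbs a few degrees of freedom).

Fixtures emulate the *geometry* of simulated maps — branch structure,
jitter, collapse, misalignment — with independent Gaussian noise. They do
not emulate the spatially correlated, competition-constrained noise of the
energy model, so fixture-based tests validate the metrics, not the
simulator; the simulator is validated separately (swap-energy oracle,
bijection invariants, convergence and phenotype tests).

## Numerical and design choices

- Initial state: uniformly random permutation (removes ordering bias; the
  dynamics, not the start, must produce topography).
- Proposals: uniform over axon pairs, with replacement across iterations;
  `i = j` proposals are discarded without counting as accepted moves.
- `swap_delta()` in R mirrors the C++ inner loop and agrees with
  brute-force energy recomputation to $10^{-9}$ relative tolerance (tested
  over 1000 random instances); the engine's incremental energy bookkeeping
  is checked against full recomputation at run end.
- Acceptance is computed in the numerically stable branch of the logistic,
  so $\Delta E = \pm1000$ neither overflows nor underflows into NaN.
- LOESS uses the direct surface (no interpolation grid) so leave-one-out
  refits are exact; per-branch fits fall back to the branch mean below 4
  points.
- Degenerate inputs: constant maps yield IDI 0 and an all-zero IDV curve;
  `idv_jaccard` defines the both-empty case as 1; maps smaller than the
  IDV window, non-bijective "simulated" tables and empty KS samples are
  rejected with explicit errors.

## Problem sizes

The full study conditions are 20 runs of $10^7$ proposals per genotype for
alignment ensembles and 10 runs for dispersion ensembles. Equilibrium map
statistics at $N = 100$ are already stable from about $10^6$ proposals
(ensembles at $10^6$ and $10^7$ agree within resampling error), so the test
suite runs 20 seeded runs of $10^6$ proposals per genotype and
`scripts/acceptance.R` uses $5 \times 10^6$; both choices are package
defaults for turnaround, not properties of the model, and `energy_params()`
accepts the full $10^7$.

## What the model reproduces, and known limitations

At the default parameterization the package reproduces the qualitative
genotype phenotypes: wild-type RC and CC maps are single and continuous;
EphA3-het maps are partially duplicated with the branches approaching each
other toward the temporal pole; EphA3-homo maps are fully duplicated with
no collapse; ephrin-A3 knock-ins keep a normal RC map while the CC map
disperses, dose-dependently, and the alignment-index ordering
Efna3-homo > Efna3-het > WT holds with non-overlapping bootstrap intervals.

Quantitatively, the default energy balance produces *tighter* maps than
the in-vivo and reference in-silico characterizations of these genotypes:
wild-type detrended IDI settles near 1.5 and AI near 1.0, the duplication
threshold near 27, and the heterozygous branch merge is confined to the
temporalmost few percent of the axis, whereas reported collapse points lie
near 74–82% of the nasal-temporal axis and reported wild-type dispersion
is several-fold larger. The discrepancy is energetic, not numerical: with
$\alpha/\gamma = 200$, leaving the chemoaffinity anti-rank order near the
collapse region costs roughly six times more energy than the activity term
can repay, so an early merge is thermodynamically inaccessible. Matching
the reported dispersion scale would require an activity-to-chemistry
balance roughly an order of magnitude stronger than the default
parameters encode; no single rescaling of $\alpha$, $\gamma$ or the
temperature was found that reproduces the dispersion, threshold, alignment
and collapse values simultaneously, so the defaults are kept as printed
and the gap is documented rather than tuned away. Sensitivity in this
direction can be explored directly via `energy_params()`.

Other limitations: the collicular sheet is one-dimensional (no
medial-lateral EphB/ephrin-B axis), arbors are points (bijection), there is
no annealing schedule, and compound mutants are out of scope.
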