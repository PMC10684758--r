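---
title: "Forecasting GPCR trajectory frames: models, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting GPCR trajectory frames: models, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrforecast)
```

## The problem

G protein-coupled receptors (GPCRs) are seven-transmembrane-helix
signalling proteins whose conformational dynamics — captured by
molecular-dynamics (MD) simulation as trajectories of 3D coordinates —
determine their pharmacology. This package treats one step of those
dynamics as a supervised regression problem: given five consecutive
frames of a coarse-grained trajectory, predict the next frame, and ask
how the prediction error distributes over the receptor's structural
regions (the stiff transmembrane bundle TM1–TM7 versus the flexible
intra- and extracellular loops).

The unit of representation is the residue center of mass: each amino
acid is reduced to the mass-weighted mean of its atom positions, so a
receptor of $N$ residues becomes a point in $\mathbb{R}^{3N}$ per frame
(for the 282-residue inactive-state receptor, $3N = 846$). Frames are
min–max normalised per feature to $[0,1]$, windowed into 5-in/1-out
samples at stride 1, forecast by one of four model families, and scored
after inversion to Ångström by the root-mean-square deviation

$$\mathrm{RMSD} = \sqrt{\frac{1}{S\,|R|}\sum_{s=1}^{S}\sum_{i \in R}
\lVert \hat{x}_{si} - x_{si} \rVert^2 }$$

pooled over samples $s$ and the residues $i$ of a region subset $R$.

## Regions

`default_region_map()` encodes the canonical half-open residue-id
intervals of the β2-adrenergic receptor: N-terminus [0,30), TM1 [30,61),
ICL1 [61,68), …, TM7 [306,329), C-terminus [329,344). Ids in [230,268)
are deliberately unmapped: the third intracellular loop is replaced by a
fusion partner in the source crystal structures and its residues do not
exist in the data. The gap is therefore a first-class "unmapped"
outcome of `assign_region()`, never an error. Region groups aggregate
intervals — `TM` = TM1∪…∪TM7, `ICL` = ICL1∪ICL2, `ECL` = ECL1∪ECL2∪ECL3
— and maps are user-overridable YAML files so other receptors or the
active-state numbering can be supplied.

A note on authority: two slightly different helix-boundary listings
circulate for this receptor (e.g. TM1 as [30,61) versus "helix 1
29–60"). The interval table used here is internally consistent and
half-open; the alternative listing disagrees by one residue at several
boundaries and is not used.

## Forecasters

Four families share one interface (`fit_forecaster()` / `predict()`):

* **persistence** — predicts the next frame to equal the last observed
  frame. Its RMSD is the per-step displacement of the trajectory itself,
  i.e. the flexibility of the molecule; we report it as the `MD-RMSD`
  column and treat it as the bar every trained model must clear.
* **random forest** — a multi-output tree ensemble on flattened windows
  ($5 \times 3N$ predictors), maximum depth $3N$, fixed random state.
  No installed R package offers native multi-output forests, so one
  `ranger` forest is grown per output dimension (100 trees each); this
  realises the same estimator at identical settings. `ranger` treats
  seed 0 as "unseeded", so the fixed random state is mapped through a
  deterministic seed derivation — fits remain bit-reproducible.
* **ULSTM** — LSTM(100) encoder over the 5-frame window → repeat-vector
  to a length-1 sequence → LSTM(100) decoder → time-distributed affine
  map to $3N$. With $3N = 846$ this is 544,646 parameters
  (378,800 + 80,400 + 85,446).
* **BLSTM** — the same encoder–decoder with both LSTM layers
  bidirectional at 50 units per direction, concatenated to a merged
  width of 100.
* **CNN-LSTM** — two same-padded 1-D convolutions (64 then 128 filters,
  kernel 9) with stride-1 max pooling (widths 3 and 2; time dimension
  5→3→2), dropout 0.2, batch normalisation, flatten (width 256),
  repeat-vector, LSTM(100), affine to $3N$: 789,974 parameters of which
  the 256 batch-norm moving statistics are non-trainable.

Architecture specs are declarative (`forecaster_spec`), and
`count_parameters()` computes every layer's parameter count from the
layer algebra alone — LSTM $4((d+u)u+u)$, conv1d $(kc+1)f$, batch norm
$4c$, affine $d_\mathrm{in}d_\mathrm{out}+d_\mathrm{out}$ — independent
of the training backend; the test suite asserts exact agreement between
the algebra and the instantiated weight arrays.

Because no deep-learning backend is available to R here, the package
carries its own compact engine: forward and backward passes for LSTM
(uni- and bidirectional), conv1d, max pooling, dropout, batch norm and
affine layers, trained with minibatch Adam (step 10⁻³, β₁ = 0.9,
β₂ = 0.999, ε = 10⁻⁷) on mean-squared error, batch size 32. Every layer
gradient is verified against central finite differences in the tests.
Choices the architecture tables leave open were fixed as follows:
cell activations are `relu` (recurrent gate activations stay sigmoid,
and the same `relu` is applied to the convolution outputs), dropout is
0.2, max-pool ties resolve to the earliest position, LSTM kernels are
Glorot-uniform with orthogonal recurrent matrices and unit forget-gate
bias, and the final affine layer maps to $3N$ (one published shape line
suggests a different width, but the published parameter count
$100 \cdot 846 + 846 = 85{,}446$ is only consistent with $3N$). The
printed parameter totals for the bidirectional variant admit no
integer unit count consistent with the printed shapes, so only its
shapes (merged width 100) are honoured and its totals are not asserted.

## Evaluation

`rmsd()` pools squared deviations over all (sample, residue) pairs
before the square root; an alternative per-sample average is exposed
behind a flag for sensitivity checks, since "average error over all
predictions" admits both readings. Pooling gives the clean aggregation
identity — the residue-count-weighted mean of squared per-region RMSDs
over a partition equals the squared overall RMSD — which the tests
assert to 1e-9.

`flexibility_md_rmsd()` computes the persistence RMSD between each
frame (from index 5 onward, the frames the forecasters are scored on)
and its predecessor. The flexibility column of the results tables is
interpreted as exactly this model-free step displacement: it is
commensurate with the forecasters' error and is how the flexibility
comparison is used. Deviation-from-mean (RMSF) and
deviation-from-reference are different quantities; `trajectory_rmsf()`
provides the former for generator checks.

`per_residue_rmsd()` feeds `write_bfactor_pdb()`: per-residue errors
are written into the B-factor column of a pseudo-atom PDB so any
structure viewer can colour-code them onto the fold.

## The resampled protocol

Per repetition: draw `n_sampled` trajectories (default 2000) without
replacement from the pool, split into 5 folds of `n_sampled/5` (400 at
default), train on four folds, score per-region RMSD on the hold-out
fold. Ten repetitions yield mean ± sd and 10-vector inputs to pairwise
two-sided t-tests, model-vs-model within region and region-vs-region
within model. Design points:

* **Normalisation is fit on the training folds only** and applied to
  the hold-out fold; whether the original analysis did this is
  unstated, but fitting on all data would leak the test range. RMSD is
  always computed after inversion to Ångström. Held-out values may fall
  outside $[0,1]$; that is expected and harmless. Features with zero
  training range normalise to 0 and invert to their constant.
* **Windows never span trajectories**; each trajectory of $F$ frames
  contributes $\max(0, F-5)$ samples (23 at the default 28 frames).
* **The hold-out RMSD alone enters the report** (per-fold validation
  scores are a by-product); one test RMSD per repetition matches how
  the repetition vectors are used.
* **t-tests**: Welch's unequal-variance form by default (robust when a
  model's repetition variance differs), pooled-variance Student's as an
  option. Flags are at 0.05 (*) and 0.01 (**) — the thresholds the
  results tables actually mark, which their accompanying text
  contradicts; the tables win. No multiple-testing correction is
  applied, matching the original analysis; the report records the
  number of comparisons. If both repetition vectors are constant the
  test is degenerate and p is defined as 1 (equal means) or 0.
* **TM-only variant**: the feature space is restricted to TM residues
  before windowing (dimension $3\,|TM|$); fold assignment is unchanged
  given the same seed, so the comparison isolates the feature set.

## The synthetic generator

Real trajectories for this receptor are access-restricted, so the
package ships a generator that emulates the study conditions: per
condition, 2000 trajectories × 28 frames at 500 ps spacing over an
idealised seven-helix bundle (straight antiparallel helices of exact
1.5 Å rise on a 12 Å ring, loops interpolated with an outward bulge,
ICL3-gap residues absent). Every coordinate follows a stationary AR(1)
/ Ornstein–Uhlenbeck process about its reference position:

$$x_{t+1} = \mu + \rho\,(x_t - \mu) + \eta,\qquad
\eta \sim \mathcal{N}\!\left(0, \sigma^2 (1-\rho^2)\right),$$

with frame 0 drawn from the stationary law
$\mathcal{N}(\mu, \sigma^2)$ (no burn-in). This is the simplest process
with the two properties the analysis exploits — temporal correlation
and region-dependent amplitude — and it has closed forms that serve as
test oracles: stationary per-coordinate variance $\sigma^2$, persistence
RMSD $\sigma\sqrt{6(1-\rho)}$, and Bayes-optimal one-step RMSD
$\sigma\sqrt{3(1-\rho^2)}$.

Defaults, chosen once: $\rho = 0.8$; $\sigma$ = 0.5 Å for TM helices,
1.5 Å for intracellular loops, 1.25 Å for extracellular loops, 1.0 Å
for the termini. The TM value makes the helices markedly stiffer than
the loops, the loop values land the per-step displacements at the
1–2 Å scale typical of such simulations, and the ICL > ECL ordering
gives the loop classes distinguishable flexibility. Per-trajectory
seeds derive deterministically from the master seed and the trajectory
index, so equal configs give bitwise-equal datasets.

**What the generator does not emulate — and what that means for the
tests.** Residues fluctuate independently: there are no collective
motions, no inter-residue correlations, no slow conformational
transitions. Real MD data are strongly low-rank — a few collective
modes carry most of the variance — which is precisely what lets a
100-unit bottleneck architecture reconstruct an 846-dimensional frame.
Independent coordinates are incompressible, so at full receptor width
no 100-unit encoder–decoder can out-predict persistence on this
synthetic data, whatever the training budget. Passing tests therefore
certify the machinery (correct gradients, correct protocol, correct
metrics, correct orderings), not full-scale predictive skill on real
trajectories. The learning-sanity check accordingly runs on a scaled
receptor (8 residues, 24 features — inside the bottleneck), where the
trained ULSTM must land between the Bayes bound and the persistence
baseline; the region-ordering check runs at full width, where relative
(not absolute) performance across regions is the claim being tested.

## Problem sizes used by the tests and scripts

Sizes were set so the full suite and the acceptance script each run in
a few minutes on one CPU: closed-form baselines use ≥10⁴ pooled
residue-steps (500 trajectories × 23 steps); the fold-arithmetic check
generates 2000 two-residue trajectories; region-ordering uses the full
306-residue synthetic receptor, 100 trajectories, ULSTM at 10 epochs;
learning sanity uses the 8-residue receptor, 300 trajectories, 100
epochs (the default epoch count); the t-test calibration simulates
2000 null pairs at $n = 10$. The analysis drivers under `analysis/` use
a reduced-resolution receptor for the per-output random forest and the
full receptor elsewhere; all of them scale to the production numbers
(2000 trajectories, 10 repetitions, 100 epochs) by changing the
protocol fields only.

## Known limitations

* One-step-ahead forecasting only; no multi-step rollout.
* The neural engine is CPU-bound and minibatch-serial; it is sized for
  the reduced protocols above, not for GPU-scale sweeps.
* RMSD is computed on absolute coordinates, without Kabsch
  superposition — the analyses compare positions in the simulation
  frame, not aligned structures.
* The generator's independence across residues limits what full-width
  learning experiments can show (see above); correlated residue motion
  is a natural extension.
* The bidirectional model's published parameter totals cannot be
  reconstructed from any consistent layer algebra and are not asserted.
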