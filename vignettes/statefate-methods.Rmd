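---
title: "Modeling drug-tolerant persister cell-state dynamics with statefate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug-tolerant persister cell-state dynamics with statefate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statefate)
```

## The scientific problem

Basal-like breast cancer cells survive targeted therapy as drug-tolerant
persisters (DTPs): low-proliferative populations that are not genetically
resistant and that occupy characteristic differentiation states, read out by
single-cell intensities of cytokeratin-19 (luminal), cytokeratin-14
(basal/myoepithelial) and vimentin (mesenchymal). Two mechanisms can enrich a
state under drug pressure: *Darwinian selection* (the other state is
selectively killed, no interconversion) and *transition-mediated* enrichment
(cells interconvert while dying at equal per-capita rates). statefate
implements the quantitative machinery to tell these apart on replicate-well
image-cytometry time courses, together with the surrounding analytics:
marker gating, state-frequency and diversity metrics, geneset-based
molecular heterogeneity scores, drug-screen phenotype profiling, and
Chou-Talalay synergy scoring. A synthetic-data module generates every input
with known ground truth, so the whole pipeline is testable end to end
without any external download.

## The population model

Each live cell is K14hi or K14lo; dead cells are absorbing. With per-step
probabilities of division ($a_{hi}, a_{lo}$), death ($d_{hi}, d_{lo}$) and
transition ($k_{hl}: \mathrm{hi}\!\to\!\mathrm{lo}$,
$k_{lh}: \mathrm{lo}\!\to\!\mathrm{hi}$), the expected compartment vector
$x = (n_{hi}, n_{lo}, n_{dead})$ evolves linearly and time-invariantly,
$x(t+1) = A(\theta)\,x(t)$ with

$$
A(\theta) = \begin{pmatrix}
1 + a_{hi} - d_{hi} - k_{hl} & k_{lh} & 0 \\
k_{hl} & 1 + a_{lo} - d_{lo} - k_{lh} & 0 \\
d_{hi} & d_{lo} & 1
\end{pmatrix}.
$$

One step equals the sampling interval (12 h); rates are therefore per-step
probabilities in $[0,1]$, and per live state the multiplier
$1 + a - d - k_{out}$ must be nonnegative. Linear time-invariance is a
deliberate parsimony choice: seven timepoints per well cannot support
time-varying rates without overfitting. The discrete-time parametrization
treats the rates as time-averaged per-step probabilities over the
measurement grid; a continuous-time variant is out of scope.

The stochastic counterpart (`simulatePopulation`) gives each live cell an
independent division draw at the start of the step (the daughter is credited
to the state of origin and is not at risk within that step) and one
categorical fate draw among die / switch / persist. With this event order the
ensemble mean equals the deterministic propagation *exactly*, which is the
property the test suite checks (1,000 replicates agree with $A^6 x_0$ to
well under 2% relative error). The more intuitive alternative — dividing
only survivors — biases the mean by $a(d+k)$ per step and was rejected for
that reason.

## What the generator emulates, and what it does not

`groundTruthConfig()` encodes the emulated design: 15 replicate wells per
arm sampled every 12 h over 72 h, a DMSO arm and a treated arm, roughly
2,000 cells per well at time zero with 27% K14hi. Absolute per-well cell
numbers are a fixture choice; only proportions and rates matter downstream. The default treated arm is
"transition-like": strong cytostasis ($a = 0.02$), equal per-capita death
($d = 0.02$), and a strong net K14lo-to-K14hi flux ($k_{lh} = 0.2$,
$k_{hl} = 0.005$) that carries the K14hi frequency from 27% to about 80%
over six steps — the four-fold-scale enrichment regime the MEK-inhibitor
response occupies. The control arm proliferates ($a = 0.35$ per 12 h,
a doubling time near 24 h) and sits close to its transition equilibrium.

Measured counts follow the assay's logic: cells that died during the
preceding interval are still in the imaged field and are gated in the state
they died from; cells dead longer than one interval have detached and left
both the counts and the death-fraction denominator. The reported death
fraction is therefore the currently-dying fraction. Reported counts carry
multiplicative lognormal noise (CV 0.10) and are rounded; 20% of the
post-baseline well-by-time records are masked as illegible, never at time
zero (the fitter needs initial conditions). Per-cell marker intensities are
lognormal, parametrized as (median, log-SD) per state and marker, with a
4-fold K14 separation between states at the defaults.

What the generator does *not* emulate: spatial structure or cell-cell
interaction, plate edge effects, segmentation errors, antibody batch
effects, or non-stationary rates. Passing tests therefore demonstrate the
estimators' correctness under the stated noise model, not robustness to
every artifact of real imaging data.

## Compartment estimation and the allocation rules

`estimateCompartments` turns measurements into model compartments. The dead
cells present at (well, t) are death fraction times measured total. Live
compartments subtract these dead cells from the measured state counts under
a hypothesis-specific allocation: the Darwinian spec subtracts all dead
cells from the K14lo count; the transition spec allocates them
proportionally to the state counts (equal per-capita death); the vehicle
arm always splits 50/50. "Equal proportions" is operationalized as equal
per-capita death; the literal 50/50 split is kept for the control arm, and
both rules are pluggable. The absorbing dead compartment is the running sum
of the per-timepoint dead estimates, nondecreasing by construction.
Negative live estimates (noise overshoot) are floored at zero and flagged.

## The constrained fit and alternating minimization

`fitDynamics` minimizes
$\sum_{w}\sum_t \lVert y_w(t+1) - A(\theta)\hat y_w(t)\rVert^2
+ \lambda\lVert\theta\rVert^2$
with wells pooled into one objective (one shared $\theta$ per arm).
$A(\theta)$ is linear in $\theta$, so given imputations this is a convex
quadratic program over the hypothesis's feasible region: equality
constraints (zeros such as $k_{hl} = k_{lh} = d_{hi} = 0$ for Darwinian
selection; ties such as $d_{hi} = d_{lo}$ and the EdU-derived
$a_{hi} = a_{lo}$, applied to all built-in hypotheses because S-phase
frequencies are indistinguishable between marker-high and marker-low
cells) are eliminated exactly; box bounds $[0,1]$ and the two per-state
population budgets remain as inequalities. The QP is solved by a small
exact primal active-set method (dense KKT solves; at most six variables),
which certifies the subproblem to solver precision; the tests verify it
against an independent quasi-Newton solve.

Illegible records are handled by alternating minimization: the
$\theta$-step solves the constrained QP given the current imputations, and
the imputation step replaces each well's masked records by the exact joint
least-squares minimizer of that well's trajectory terms given $\theta$ (a
small linear solve coupling consecutive masked timepoints). Because both
steps minimize the same objective, the recorded objective sequence is
provably nonincreasing — a property asserted on every fit. A one-step
forward-prediction imputation was considered and rejected: it does not
minimize the joint objective and cannot guarantee the monotone objective
the diagnostics promise; where masking is confined to trailing timepoints
the two rules coincide. Iteration stops when the relative objective change
drops below $10^{-8}$ (default cap 500 iterations); on complete data the
fit reduces to a single direct constrained solve. $\lambda$ defaults to
$10^{-3}$: counts are $O(10^3)$, so the data term dominates by many orders
of magnitude and the ridge only regularizes directions the data leave
unidentified.

## Hypothesis comparison

`compareHypotheses` fits each candidate on its own compartment estimates,
fits the vehicle arm once under the control spec, and propagates both
forward from mean time-zero conditions (treated wells, and the average over
all DMSO wells, respectively). Scoring must use one observation set for
every hypothesis, but live-compartment estimates are hypothesis-specific;
the comparison therefore scores fold changes (treated over vehicle) of
*apparent* state proportions — live cells plus cells newly dead in place —
which for the observed side come directly from the raw measured counts and
for the simulated side from a four-compartment augmentation that tracks
newly dead cells by state of origin. Hypotheses are ranked by the endpoint
absolute error $|y_{sim} - y_{obs}|$ averaged over the two states, with the
full-trajectory RMSE reported alongside. Under the default
transition-driven design the transition-mediated model wins essentially
always; under the converse design (no transitions, K14lo-only death at
$d_{lo} = 0.33$, the rate a selection-only account of a 27-to-80%
enrichment requires) the Darwinian model wins.

## Heterogeneity metrics

The Shannon index of a state-frequency vector is
$H' = -\sum_{P_i > 0} P_i \log P_i$. Conventions in the field vary between
natural log and log2; natural log is the default, base 2 is an option,
every output records the base, and $S$ counts only states actually
present. Molecular heterogeneity uses three disjoint 25-gene lineage sets
(luminal, myoepithelial, EMT) shipped as an editable *synthetic* GMT
fixture — plausible marker genes, not a curated signature. Genes are
Z-scored across samples with the population SD (denominator $n$); a
sample's cumulative score sums its 75 Z-scores, and the between-geneset
variance is the sample variance (denominator $n-1$, over exactly 3 values)
of its per-geneset mean Z. Geneset means are taken over Z-scores rather
than raw expression, for scale invariance across genes. One consequence,
verified in the tests: a sample high in
all three programs has the maximal cumulative score and the minimal — but
not exactly zero — between-geneset variance, because each geneset's
cross-sample distribution differs.

## Screen analytics

Viability is scaled between cell-free (0%) and vehicle (100%) controls.
Dose-response curves are log-logistic with the top pinned at 100 and
bottom (the projected maximal inhibition, Einf), EC50 and slope free;
the bottom is unconstrained because plateauing DTP-rich responses can
project below zero. Emax is the minimum observed percent-of-control,
always attained by a data point. Fitting uses Levenberg-Marquardt from a
coarse grid start with a simplex fallback; non-convergence is flagged with
Emax still reported. The pinned-top three-parameter choice is recorded in
the fit object.

Median-effect fits linearize $f_a/f_u = (D/D_m)^m$ by regressing
$\log(f_a/(1-f_a))$ on $\log D$; $f_a = 1 - \%\mathrm{control}/100$ is
clamped to $[0.005, 0.995]$ (configurable) and nonpositive points are
dropped with a warning, following standard median-effect practice near the
0% and 100% effect boundaries. For a fixed-ratio combination dosed
by total concentration, $CI_x = d_1/D_{x,1} + d_2/D_{x,2}$ at
$x \in \{0.75, 0.90\}$, with $D_x = D_m (x/(1-x))^{1/m}$.

Phenotype profiles are per-dose marker Z-score changes against DMSO wells
(control wells weighted equally regardless of cell count; ties at a gate
threshold are negative because "exceeding" is read strictly). Response
groups come from k-means on the Z-change vectors only — not
percent-of-control — with k-means++ initialization, best of 10 restarts,
k = 6 by default, deterministic given the seed.

## Numerical choices and degenerate inputs

- Gate thresholds: arithmetic mean MFI over pooled control cells, computed
  per experiment; dying-flagged cells are excluded from gating (dying cells
  stain non-specifically).
- Empty wells yield empty cell tables, not errors; empty groups are dropped
  from frequency tables with a warning; empty states report NA fractions.
- Zero-spread intensity models collapse to point masses (allowed);
  nonpositive location parameters are errors.
- Flat dose-response data bypass the nonlinear fit (bottom = mean,
  slope = 1, flagged convergent).
- Rate estimates landing within solver epsilon ($<10^{-6}$) outside the
  box or budget are projected back; fitted equality constraints hold to
  machine precision by construction.
- All generators draw through isolated RNG streams derived from explicit
  integer seeds; identical configs are bitwise reproducible.

## Problem sizes used in the tests

The test and acceptance workloads use the design above at its native scale
(15 wells x 7 timepoints x 2 arms), 20 seeds for rate-recovery summaries,
100 seeded replicates per discrimination design, 10,000 cells for gating
properties, 1,000 replicates for the stochastic-mean check, and a 40-drug,
6-archetype screen for clustering — sizes chosen to match the emulated
experiments while keeping a full run in the order of a minute.

## Known limitations

Two live states only (the interface is written against named compartments,
but nothing beyond two states is tested); no Bayesian or state-space
inference and no time-varying rates; the discrimination result is a
property of the stated noise model and designs, and real screens add plate
and batch effects the generator does not emulate; the synthetic genesets
stand in for curated lineage signatures and should be replaced by real ones
for any biological use.
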