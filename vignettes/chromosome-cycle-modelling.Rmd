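---
title: "Data-driven chromosome modelling across the cell cycle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven chromosome modelling across the cell cycle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromocycle)
```

## The model

`chromocycle` treats a chromosome segment as a beads-on-a-string polymer in
reduced units: each bead is one genomic bin (100 kb at production scale),
lengths are in the bond unit $\sigma$, energies in $\epsilon$ (temperatures
absorb the Boltzmann constant), times in $\tau$. The effective potential for
a cell stage is

$$V(\mathrm{Stage}) = V_{\mathrm{homopolymer}} + V_{\mathrm{Hi\text{-}C}}(\mathrm{Stage}),$$

where the homopolymer part encodes generic polymer physics and the Hi-C part
encodes stage-specific experimental information.

### Homopolymer terms

* **Bonds.** Harmonic pseudo-bonds, $\tfrac{1}{2}k_b(b - \sigma)^2$ with
  $k_b = 100\,\epsilon/\sigma^2$: stiff enough that bond lengths stay near
  $\sigma$ at the 0.0005 $\tau$ time step, soft enough for stable explicit
  integration.
* **Angles.** A linear-placement-favoured term $k_a(1 + \cos\theta)$
  ($k_a = 2\,\epsilon$), zero for a straight chain — a generic chain
  stiffness, not a persistence length fitted to physical nm/bp scales.
* **Soft core.** Pair repulsion using the Weeks–Chandler–Andersen form
  passed through a saturating clamp,
  $E(r) = E_{\mathrm{cap}}\tanh(\mathrm{WCA}(r)/E_{\mathrm{cap}})$ with
  $E_{\mathrm{cap}} = 4\,\epsilon$. The energy of any overlap is bounded by
  the cap, so chain strands can pass through one another: this emulates
  topoisomerase activity, which resolves topological entanglement in vivo.
  The clamp is smooth, so analytic forces match finite differences
  everywhere (the tests assert $10^{-5}$ relative agreement).
* **Confinement.** A half-harmonic spherical wall
  ($k_w = 100\,\epsilon/\sigma^2$) whose radius is set so beads of diameter
  $\sigma$ fill 10% of the sphere:
  $R = (\sigma/2)\,(N/0.10)^{1/3}$, i.e. $R \approx 8.61\,\sigma$ for the
  production 510-bead chain, mimicking the chromosome's share of nuclear
  volume.

### The Hi-C biasing potential and its contact proxy

The stage-specific term is linear in the contact observable,
$V_{\mathrm{Hi\text{-}C}} = \sum_{i<j} \alpha_{ij} f(r_{ij})$. A contact
probability is an ensemble property, so the per-configuration energy uses a
smooth indicator
$f(r) = \tfrac{1}{2}\left(1 + \tanh[\eta(r_c - r)]\right)$
($r_c = 1.8\,\sigma$, $\eta = 5\,\sigma^{-1}$) whose ensemble mean *is* the
simulated contact probability. The same kernel is used when measuring
contact maps from ensembles, keeping calibration and measurement
self-consistent. $\alpha$ is forced to zero on the diagonal and both first
off-diagonals: those contacts are pinned at probability 1 by the
normalization convention and held by the bond term, and biasing them would
fight the bonds.

### Contact-map convention

Input maps are normalized so neighbouring loci are always in contact:
the matrix is divided by the mean first-off-diagonal value, entries above 1
are clipped, and the adjacent band is set to exactly 1. We chose a single
global scale factor (rather than per-row scaling) because it preserves all
relative contact structure; the input is assumed to be already balanced
(e.g. ICE-corrected) upstream, which is out of scope here.

## Calibration (maximum entropy)

`calibrate()` iterates: sample annealed replica trajectories under the
current potential → estimate the contact map from the sampling windows →
update $\alpha_{ij} \mathrel{+}= \mathrm{lr}\,(P^{\mathrm{sim}}_{ij} -
P^{\mathrm{tgt}}_{ij})$, clamped to $\pm 10\,\epsilon$. Over-formed contacts
acquire positive (penalizing) couplings, starved contacts negative
(attractive) ones; the fixed point is $P^{\mathrm{sim}} = P^{\mathrm{tgt}}$.
Defaults: learning rate $2\,\epsilon$ per probability unit, MAE tolerance
0.02, divergence guard that halves the learning rate after three
consecutive MAE increases.

Two numerical choices matter at desk scale:

* **Sampling.** Each iteration anneals from $4\,\epsilon$ to $1\,\epsilon$
  (linear ramp — the simplest monotone schedule between the two stated
  endpoints) and samples only the second half of each trajectory. The
  production protocol uses a 250 $\tau$ ramp in 1000 $\tau$ trajectories
  with 100 replicas; the desk default shrinks this proportionally
  (10 $\tau$ ramp, 40 $\tau$ trajectories, 8 replicas) so a full
  calibration of a 60-bead chain runs in minutes on one CPU.
* **Iteration averaging.** With desk-scale sampling the per-iteration map
  estimate carries binomial noise comparable to the convergence tolerance.
  The estimate entering the error metric and the update is therefore an
  exponentially weighted moving average over iterations
  (`ema_weight = 0.5`), the standard stochastic-approximation remedy: near
  the fixed point the bias changes slowly, so averaging pools sampling
  noise away without extra simulation. Setting `ema_weight = 1` recovers
  the raw per-iteration estimate.

On the synthetic 60-locus interphase map the loop reaches a Pearson
correlation above 0.95 and MAE below 0.05 within ten iterations; the
acceptance suite recomputes this every run.

## Langevin engine

A BAOAB splitting integrates the Langevin equation at unit mass with the
production parameters (time step 0.0005 $\tau$, friction 10 $\tau^{-1}$),
so the free-bead diffusion coefficient is $D = T/\gamma = 0.1\,
\sigma^2/\tau$ at $T = 1\,\epsilon$. The test suite verifies the Einstein
relation to 10% and per-axis equipartition of a harmonic degree of freedom
to 5%. All noise flows through R's seeded RNG: a trajectory is
bit-reproducible given its seed, and replica seeds derive deterministically
from a base seed. Cold starts grow a self-avoiding-ish random walk inside
the confinement sphere and relax it by capped steepest descent; this choice
is free because annealing erases the start within the first ramp.

## Landscape switching

Transitions between stages are simulated out of equilibrium: structures
equilibrated under $V(\mathrm{Stage_1})$ continue under
$V(\mathrm{Stage_2})$ from $t = 0$ with no re-thermalization, and the
relaxation is recorded (checkpoints default to 1, 10, 100 and 1000 $\tau$).
Initial structures come from average-linkage agglomerative clustering of
the source ensemble on pairwise Kabsch-aligned RMSD (deterministic, no
cluster count to guess), taking two structures nearest the medoid from
every cluster whose population exceeds 0.2% of the ensemble. The paper-scale
protocol states those two numbers; the clustering algorithm itself is our
choice, since only "structural clustering" is specified, and a
contact-distance metric would be an equally valid alternative.

One deliberate deviation: the ensembles store positions only, so the
velocities at the switch are drawn fresh from the Maxwell–Boltzmann
distribution at the pre-switch temperature rather than carried over. For an
equilibrated source ensemble the two are identical in distribution —
positions and momenta are independent at equilibrium — so no observable
statistic is affected.

## Structural observables

* **Gyration geometry.** From the eigenvalues
  $\lambda_1 \ge \lambda_2 \ge \lambda_3$ of the centred, $1/N$-normalized
  gyration tensor: $R_g = \sqrt{\lambda_1 + \lambda_2 + \lambda_3}$ and
  $\Delta = \tfrac{3}{2}\sum_k(\lambda_k - \bar\lambda)^2/(\mathrm{tr}\,T)^2
  \in [0, 1]$ (0 = isotropic/sphere-like, 1 = rod). The square root in
  $R_g$ is required for dimensional consistency with
  $R_g^2 = \mathrm{tr}\,T$.
* **Free-energy landscape.** $-\ln p$ of the 2D $(R_g, \Delta)$ histogram
  in thermal units at the sampling temperature, minimum shifted to zero;
  only differences are meaningful.
* **Fluctuation matrix.** $M_{ij} = \langle \delta r_i \cdot \delta r_j
  \rangle$ over an ensemble aligned to its iterative mean: structures are
  centred, rotated onto the running mean by the optimal least-squares
  (Kabsch) rotation, and the mean is recomputed until it moves less than
  $10^{-8}\,\sigma$. The reference is the ensemble average, not any single
  representative — with a cluster representative the matrix would mix
  genuine fluctuation with the representative's own offset.
  `fluctuation_matrix()` refuses unaligned input because $M$ is
  alignment-dependent. $\Delta M(t) = M(t) - M(0)$ tracks how coherent
  motion develops after a switch.
* **Insulation and TADs.** Per-locus mean contact across a sliding
  $w \times w$ window (500 kb each side at production resolution), log2
  relative to the chromosome mean, masked within $w$ of the ends. TAD
  boundaries are local minima whose prominence over the flanking maxima
  exceeds 0.1 log2 units — the threshold is our choice, set once so the
  synthetic generator's planted boundaries separate cleanly from its noise
  floor.
* **Enhanced contacts and compartments.** Fine maps are summed into 1 Mb
  blocks; $\log_2(P_{\mathrm{obs}}/P_{\mathrm{exp}})$ uses the
  distance-decay expectation at the coarse scale and is masked where either
  term vanishes. The compartment profile is the first principal axis of
  that matrix with bins as observations. PCA determines an axis only up to
  sign, so a convention is needed: the bin class with higher short-range
  observed contact density is oriented positive. Self-contacts are excluded
  everywhere; they carry no structural information.

## Transition pathways

The evolution of an observable profile (insulation scores, or the flattened
upper triangle of the enhanced map) is projected into a 2-component PCA
plane. Masked features (insulation edge loci, undefined enhanced cells) are
excluded from the feature space globally, never imputed, so the mask cannot
generate variance. The fitting set combines stage means and checkpoint
means, giving axes that embed both endpoints and dynamics; each axis is
oriented so its largest-magnitude loading is positive. Exactly collinear
fitting sets are accepted (the second axis then spans the orthogonal
complement with ~zero variance); only a fully degenerate set is an error.
The null pathway interpolates contact maps linearly between the two stage
endpoints and passes each interpolate through the same observable; because
the unit-adjacent band is preserved under convex combination, interpolates
remain valid maps. `path_deviation()` scores the mean distance of the
simulated path to the interpolated polyline, normalized by the endpoint
separation, so 0 means "the transition is linear in observable space".

## The synthetic generator

`synthetic_spec()` emulates the phenomenology the analysis assumes, at
40–120 loci so every pipeline stage runs at desk scale: power-law distance
decay ($s^{-1}$ by default), multiplicative TAD block enrichment (three
equal blocks, factor 3), a plaid same-compartment factor (1.6) applied only
beyond 1.2 Mb separation, mild lognormal noise (sd 0.02), and a mitotic
mode with a uniform high band (half-width 6 loci) decaying sharply beyond.
Two generator-design details are deliberate:

* the compartment labels use a mixed-parity 1 Mb arrangement (A A B A B B)
  — a strictly alternating pattern is invisible to observed/expected at the
  coarse scale because every coarse diagonal is then label-homogeneous;
* the plaid factor is suppressed at short range so compartment transitions
  do not carve spurious insulation dips, keeping TAD calls attributable to
  the planted blocks.

`make_stage_series()` ramps the generator parameters linearly from
mitotic-like to interphase-like, so stage order is recoverable from the
insulation PCA — the desk analogue of the five experimental stages.

What the generator does **not** emulate: ICE-balancing artefacts, unmappable
bins, translocations, replication-timing structure, or the true decay
exponents of any specific chromosome. Passing tests therefore demonstrate
that the machinery is correct and self-consistent, not that it reproduces
any particular experimental dataset.

## Scale presets and problem sizes

`run_config("desk")` — 60 beads, 8 replicas, 40 $\tau$ annealed
trajectories, 10 calibration iterations, 100 $\tau$ switches — is the scale
at which the whole pipeline, including the test suite, runs on a single
CPU in minutes; all quantitative statements in the package's tests are made
at this scale. `run_config("paper")` restores the production protocol
(510 beads, 100 replicas, 1000 $\tau$ trajectories, 250 $\tau$ ramps,
checkpoints to 1000 $\tau$); it is provided for completeness and documented
as cluster-scale work, not exercised by the tests.

## Known limitations

* The soft-core cap makes topology fluid by construction; entanglement
  statistics are not meaningful in this model.
* Calibration quality is sampling-limited: at desk scale the MAE floor is
  set by ensemble size, not by the update rule.
* The bias update is the proportional fixed-point rule; no reweighting
  across iterations is attempted, so each iteration pays the full
  simulation cost.
* Checkpoint ensembles at early times pool frames from a short window
  (±25% of the checkpoint) to reach a usable sample size, trading a small
  amount of temporal blur for contact-map stability.
* A cooler/binary container adapter is not included; inputs are the
  plain-text dense or triples dialects.
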