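---
title: "A quantitative model of hippocampal episodic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quantitative model of hippocampal episodic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippomem)
```

## The model

`hippomem` is a rate-model simulator of the hippocampal circuit for episodic
memory. An episodic memory is treated as an arbitrary association — an
object in a particular place, an event at a particular time — stored in one
shot and later retrievable from any of its parts. The package implements
each stage of the standard quantitative account:

* **CA3** is an autoassociative (attractor) network: the recurrent
  collaterals between CA3 pyramidal cells carry Hebbian associative weights
  so that a set of co-active neurons becomes a stable state of the
  dynamics, retrievable from a partial cue (pattern completion).
* **The dentate gyrus** is a competitive network that converts entorhinal
  input (including periodic grid-cell codes) into sparse, well-separated
  granule-cell codes (pattern separation), producing place-like fields from
  grid input.
* **The mossy fibers** — the very sparse DG→CA3 projection, about 46
  contacts per CA3 cell — act as a randomizing selector: each event is
  assigned a near-random CA3 pattern, which keeps stored memories maximally
  distinct. They matter during storage, not recall.
* **The perforant path** is the numerically large but weak EC→CA3
  projection that delivers the retrieval cue, which the CA3 attractor then
  completes.
* **CA1** reads the completed CA3 pattern out through associatively
  modified Schaffer-collateral weights.
* **Temporal order** is represented by pools of "time-encoding" neurons:
  attractors that die of firing-rate adaptation and hand activity to the
  next pool, so that items associated with the pools replay in order.

## Sparseness and capacity

The population sparseness of a firing-rate vector is
$a = (\sum_i r_i/N)^2 / (\sum_i r_i^2/N)$; for binary patterns it is the
active fraction. The number of patterns an autoassociator with $C$
modifiable recurrent synapses per neuron can store and retrieve is
approximately

$$p_{\max} \simeq \frac{C}{a \ln(1/a)}\,k,$$

with $k$ roughly 0.2–0.3. The package exposes the formula
(`autoassoc_capacity()`, default $k = 0.235$, which reproduces the rat CA3
example: $C = 12{,}000$, $a = 0.02$, $p_{\max} \approx 36{,}000$), its
feedforward counterpart $C/(a_0 \ln(1/a_0))$ (`pattern_assoc_capacity()`),
and an empirical estimator (`measure_capacity()`) that recovers $k$ from
simulated networks.

```{r capacity}
autoassoc_capacity(C = 12000, a = 0.02)
connectivity_dilution(12000, 300000)     # CA3 recurrent dilution
connectivity_dilution(46, 1e6) * 100     # mossy-fiber sparseness, percent
```

## Storage and recall in CA3

Connectivity is diluted: each neuron receives exactly `C` contacts sampled
uniformly without replacement (no self-contacts; `allow_multiple = TRUE`
switches to sampling with replacement). Storage applies, on every existing
contact, the covariance rule
$\delta w_{ij} = \alpha\,(r_i - a)(r_j - a)$ — associative potentiation
plus the heterosynaptic depression that sparse codes need for high
capacity. The plain Hebb rule $\delta w_{ij} = \alpha\, r_i r_j$ is kept as
an option; because its weights only grow, it saturates at low loads and is
not the default.

Recall iterates a synchronous update: activations $h = W r / C$ plus a weak
persistent cue field, followed by k-winners-take-all at the target
sparseness (a surrogate for fast feedback inhibition holding the active
fraction fixed). Three numerical choices matter and are deliberate:

* **Persistent cue field** (`cue_gain`, default `a_target`). The cue is
  not just an initial condition: the cue pathway keeps firing while the
  recurrent collaterals complete the pattern. At desk scale this is also
  what makes retrieval interference-limited rather than dynamics-limited —
  with $aC = 5$ informative synapses per neuron, a transient cue is simply
  forgotten by the second update.
* **Two-step damping.** The drive is computed from the mean of the last
  two states. Fixed points are unchanged, but the period-2 limit cycles
  that parallel binary updates are prone to (observed as non-converging
  states hovering just below the retrieval criterion) are suppressed.
* **Deterministic tie-breaks** in `kwta()` (index order), so runs are
  exactly reproducible.

A graded `threshold-linear` mode keeps the winners' (shifted) activations
instead of binarizing; it propagates more evidence per step and measures a
higher empirical $k$, but the reference protocol below uses the binary
k-WTA dynamics.

## Empirical capacity protocol and what it shows

`measure_capacity()` stores `p` random binary patterns at sparseness `a`,
cues each probed pattern with a random half of its active units, and calls
it retrieved when the recalled/stored Pearson overlap is at least 0.7;
`p_max` is the largest load with at least 90% of probes retrieved, and
$k = p_{\max}\, a \ln(1/a) / C$. The reference problem size is $N = 2000$,
$C \in \{100, 200\}$, $a = 0.05$, three seeds, with the load grid laid out
in steps of 0.02 in $k$-units and 40 probe patterns per load (the
retrieved fraction is estimated from that probe sample).

At this scale the recovered factors are $k \approx 0.15$ at $C = 100$ and
$k \approx 0.20$ at $C = 200$ — below the theoretical ceiling of 0.3, but
with a visible finite-size dependence: a neuron at $C = 100$ samples only
$aC = 5$ synapses from a stored pattern's active set, and the quenched
fluctuation of that count costs capacity disproportionately. Fitting
$k(C) = k_\infty\,(1 - c/(aC))$ to the two measurements extrapolates to
$k_\infty \approx 0.24$, squarely in the theoretical range. The practical
consequence is that doubling $C$ from 100 to 200 at this scale more than
doubles the measured $p_{\max}$ (ratio ≈ 2.5–2.8): capacity is linear in
$C$ only once $aC$ is large enough that the sampling correction is
negligible, and a three-point regression of $p_{\max}$ on
$C \in \{100, 200, 400\}$ is already linear to $R^2 > 0.95$. Exceeding
capacity is catastrophic, not graceful: at twice the measured $p_{\max}$
the retrieved fraction collapses below 50%.

Duplicated contacts are the other connectivity experiment: when a fraction
of a neuron's contact slots is spent on doubled contacts with the same
presynaptic partner (multiplicity 2, hence doubled effective weight, at
matched total contacts), measured capacity drops strictly, and drops
further as the duplicated fraction rises — the quantitative rationale for
why recurrent cortical connectivity is diluted.

## Mixed continuous and discrete memories

A single attractor can hold memories that combine a continuous spatial
component with a discrete event component. `mixed_memory_spec()` encodes a
memory as a Gaussian bump (default $\sigma = 50$ index units — the bump
width is a free choice; the demonstration figure shows broad bumps but
prints no value) over a continuous sub-population (units 1–1000) plus a
binary subset in a discrete sub-population (units 1001–1500). Storing two
such memories with bumps at locations 300 and 500 and cueing with either
discrete component alone completes the corresponding bump; the decoded
population-vector center (`decode_bump_center()`, center of mass, 1-based
indices, non-periodic space, optional noise-floor threshold) lands within
a couple of units of the stored location. Retrieval is symmetric: cueing
with the bump alone reinstates the discrete component exactly.

```{r mixed}
specs <- list(
  mixed_memory_spec(300, 50, c(1, 1000), discrete_indices = 1001:1025),
  mixed_memory_spec(500, 50, c(1, 1000), discrete_indices = 1101:1125)
)
net <- ca3_network(build_diluted_connectivity(1500, 300, seed = 11),
                   a_target = 0.1, max_steps = 30)
recall_mixed(net, specs, cue_memory = 1, cue_component = "discrete")$decoded_center
```

## Dentate, mossy fibers, perforant path

Grid cells use the standard rectified three-cosine interference map
(spacing, orientation, phase; peak rate at lattice vertices). The dentate
competitive net is single-layer k-WTA competitive learning with unit-norm
divisive weight normalization; granule sparseness defaults to 0.02–0.05 at
simulation scale (the anatomical 10^6-cell scale is not simulated). On a
1 m linear track with 50 sampled positions and ~100 grid cells (spacings
cycled over 30/50/70 cm), training produces mostly single-field,
place-like units whose codes for well-separated positions are less
correlated than the grid codes they came from.

The mossy-fiber stage is a fixed random projection (46 contacts per CA3
unit; selection learning is left out since the account does not commit to
it being associative) followed by k-WTA. It is deterministic given the
projection, and strongly decorrelating: granule pairs correlated at 0.8
map to CA3 pairs correlated at ~0.5 or less. The perforant-path stage is a
Hebbian EC→CA3 pattern associator trained only at storage time; at recall
it turns a partial EC cue into a (possibly imperfect) CA3 cue that the
attractor completes.

## The one-trial object-place task

`run_object_place_task()` wires the stages together in the structure of
the one-trial object-place recall experiment: per trial, two events
(object 1 at place 1, object 2 at place 2) are stored once each —
DG/mossy route sets the CA3 pattern, the recurrent collaterals associate
it, the perforant path learns EC→CA3, CA1 learns CA3→place — and recall
presents one object alone; the behavioural response is a two-alternative
argmax over the two CA1 place codes.

The storage episode is modelled as extended in time: each plastic pathway
(recurrent, perforant-path, CA1 readout) learns from its own snapshot of
the storage-time CA3 state. With mossy-fiber drive the snapshots coincide,
because the MF input deterministically imposes the pattern. Without it the
weak perforant-path drive (gain 0.1 against intrinsic noise of s.d. 0.5)
is swamped, snapshots are unrelated, and the learned associations are
mutually inconsistent — this is how "too weak to drive the firing" is made
operational. The resulting predictions hold in the model: intact networks
reach ≥ 0.9 one-trial accuracy; silencing plasticity gives chance (0.5);
lesioning MF at storage collapses accuracy; lesioning MF at recall changes
nothing; lesioning the perforant path at recall collapses accuracy.

## Temporal order

`run_sequence()` integrates pools of threshold-linear, saturating rate
units coupled through pool means: within-pool weight 2.0, global
subtractive inhibition 1.2, background drive 0.3, subtractive adaptation
(gain 1.2, $\tau = 2$ time units against a rate constant of 0.1),
per-unit Gaussian input noise (s.d. 0.05 per Euler step, dt = 0.01), and
optionally a forward bias of 0.3 added to the weights from pool $i$ to
pool $i+1$. These values were chosen once to put the network in the
regime the theory describes and are documented here precisely because the
account itself gives no numbers: an active pool is a stable fixed point
without adaptation (so with zero noise and zero adaptation nothing ever
moves); with adaptation an attractor dies after roughly two time units and
the background drive lets a successor ignite.

The three proposed mechanisms map to modes: with forward bias the
successor is the next pool in line and replay order is the presentation
order (Kendall $\tau = 1$ for the modal sequence); with adaptation only,
the successor is the least recently active (least adapted) pool; a
per-pool vector of adaptation time constants gives the
multiple-time-constant variant. Items Hebbian-associated to pools
(`associate_items()`) are read out in dwell order by `recall_order()`.
Dwell times shorten as noise grows. Order recall stays reliable through
about five pools under the defaults; beyond that transitions become
irregular — the model's analogue of a short-term capacity limit, reported
here but not asserted as a specific number.

## Synthetic inputs

All fixtures are generated in code from seeds (`generate_patterns()`,
`generate_events()`, `grid_population()`): binary ensembles with exactly
$\lceil aN \rceil$ active units; graded ensembles with exponential rates
(the typical cortical rate distribution across stimuli) truncated at five
times the mean so single outliers cannot dominate a weight update, with
the support widened so the measured sparseness matches the target;
correlated pairs built by a shared active core with disjoint private
units. Generators are pure functions of their arguments and seed.

What the generators do **not** emulate: temporally structured spike
trains, rate autocorrelation across successive events, topographic
input correlations, oscillatory (theta/gamma) timing, or learning-induced
changes in the input statistics. Tests passing on these fixtures show
that the circuit mechanisms work as theorized under the theory's own
statistical assumptions — not that the parameters are fitted to any
recorded dataset.

## Problem sizes, tolerances, degenerate inputs

Simulated sizes (N of order 10^2–10^3, the capacity protocol at
$N = 2000$) are desk-scale choices; anatomical counts enter only through
the analytic formulas and the 46-contact mossy projection. Numerical
tolerances: grid periodicity holds to 10^-9; competitive weight rows are
unit-norm to 10^-9; k-WTA ties break by index. Degenerate inputs are
errors, not silent values: sparseness of an all-zero pattern, overlap of a
zero-variance pattern, decoding an empty spatial component, more events
than places, contact counts exceeding the population. A recall that does
not converge within `max_steps` is flagged in the result, not thrown.

## Known limitations

* Rate dynamics only: no integrate-and-fire spiking, no membrane or
  synaptic time constants in CA3 (the sequence module has first-order rate
  kinetics but is also not spiking), no theta-cycle structure.
* No path integration or idiothetic update of the continuous attractor,
  and no neurogenesis in the dentate stage.
* The empirical capacity factor $k$ carries the finite-size correction
  discussed above; reproducing the asymptotic linear scaling directly
  would need $aC \gtrsim 50$, beyond desk scale.
* CA1 is a plain heteroassociative readout; the competitive
  "recombination" role sometimes ascribed to CA1 is not modelled.
* The backprojection pathway that would reinstate neocortical activity
  from CA1 is out of scope.
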