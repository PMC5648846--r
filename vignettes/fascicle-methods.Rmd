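---
title: "Modelling axon growth, fasciculation and connectome formation in the tadpole spinal cord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling axon growth, fasciculation and connectome formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fascicle)
library(dplyr)
```

## The model

`fascicle` simulates the development of axonal wiring in a hatchling
*Xenopus* tadpole spinal cord, abstracted as a 2D rectangle: `x` is the
rostro-caudal distance from the midbrain (500–2000 µm), `y` the signed
dorso-ventral distance from the ventral midline (|y| < 145 µm; `y > 0` is
the left body side, the cord "opened like a book"). Seven neuron types are
modelled — sensory Rohon-Beard cells (RB), dorsolateral ascending and
commissural sensory interneurons (dla, dlc), ascending/commissural/
descending interneurons (aIN, cIN, dIN) and motoneurons (mn) — each with a
soma, a vertical dendritic segment, a primary axon and (for most types) a
secondary axon growing the opposite way from a branch point.

Axons elongate by a fixed step Δ (1 µm) per time unit, all at once, and
turn each step according to

$$\theta_{n+1}^A = \theta_n - G_{RC}(x,y)\,\sin\theta_n +
  G_{DV}(x,y)\,\cos\theta_n + \xi_n, \qquad \xi_n \sim U(-\alpha, \alpha)$$

where $G_{RC}$ and $G_{DV}$ are rostro-caudal and dorso-ventral guidance
cues and the projection through $\sin/\cos$ turns the growth cone
perpendicular to its heading. Axon–axon interaction blends in a second
angle from the nearest same-type axon point within radius $r$:

$$\theta_{n+1} = \theta_{n+1}^A + |s|\,\mathrm{wrap}(\theta^B - \theta_{n+1}^A),
\qquad \theta^B = \begin{cases}\theta_p & s > 0\\ \bar\theta_p & s < 0\end{cases}$$

with $s \in [-1, 1]$ the sensitivity (`s_pr` for primary, `s_se` for
secondary axons), $\theta_p$ the growth angle stored at the neighbouring
point and $\bar\theta_p$ the perpendicular pointing away from it. At
$s = 0$ axons ignore each other; at $|s| = 1$ the cues and noise have no
influence. Positive $s$ produces fasciculation (bundles), negative $s$
repulsion.

### Design choices in the angle update

Three details of the update rule were genuinely open and are resolved as
follows.

* **Circular blending.** The blend is computed as
  $\theta^A + |s|\,\mathrm{wrap}(\theta^B-\theta^A)$ with angles wrapped to
  $(-\pi, \pi]$, which equals the naive linear combination whenever the two
  angles are less than π apart and avoids wrap-around artifacts when they
  are not.
* **Axis alignment under attraction.** Fasciculation is adhesion along a
  fibre, so the attractor angle is the neighbouring fibre's *axis*:
  $\theta_p$ or $\theta_p + \pi$, whichever is closer to the current
  heading. Attracting literally to the stored growth direction makes every
  antiparallel encounter a forced U-turn; in a cord where descending
  secondary axons thread finished ascending bundles, that expels the
  secondaries from their tracts and inverts the barrier-gap results below.
  Co-directional encounters (including all of the package's exact |s| = 1
  fixtures) are unaffected by this choice.
* **Repulsion perpendicular.** Of $\theta_p \pm \pi/2$, the one whose unit
  vector points from the neighbour point toward the growth cone is used;
  the exact tie is resolved toward $\theta_p + \pi/2$.

### Environment, barriers and commissural growth

Three longitudinal soma barriers per side shape growth: the RB soma column
at $y = \pm137$ (x > 500), the dla/dlc column at $y = \pm127$ (x > 700) —
together bounding the dorsal tract that confines RB axons — and the
floor-plate boundary at $y = \pm25$ spanning the whole length, which only
commissural axons (dlc, cIN) may cross. A blocked step is clipped at the
intersection and the growth angle is replaced by the longitudinal direction
preserving the sign of the step's x-component: growth cones slide along
barriers rather than reflecting, which is what produces the long
longitudinal stretches seen along tract walls. The same sliding applies at
the dorsal/ventral arena edges. An axon reaching the rostral or caudal end
of the modelled section terminates there: a real axon would continue into
cord that is simply not modelled, and letting it slide vertically along the
arena edge would build an artificial full-height column of axon at
x = 500 µm.

Commissural axons start in a `pre_crossing` phase driven by a strong
ventral cue whose sign is anchored to the soma side, so the drive carries
the growth cone *through* the midline instead of reflecting it; once the
trajectory exits the floor plate contralaterally ($|y| \ge 25$ on the far
side) the phase flips to `crossed` and the type's regular parameters take
over (longitudinal with a weak dorsal drift — growth "against" the ventral
cue). Pre-crossing axons neither fasciculate, attract others, nor form
synapses, implementing the assumption that commissural neurons interact on
the contralateral side only.

### Gradient cues and their defaults

The model family this package implements optimizes per-type cue
sensitivities against measured axons; neither those parameter values nor
the field's functional form are available here, so the package ships a
simple two-parameter family per type and phase:
$G_{RC} = g_{rc}$ (constant; negative values attract the heading to the
ascending direction) and
$G_{DV} = k_{dv}\,\mathrm{sgn}(y)\,e^{-|y|/\lambda} + k_{off}$
(odd in $y$, so left and right sides mirror; $k_{dv} < 0$ pushes axons
ventrally, strongest near the floor plate). Defaults (`growth_params()`)
were chosen once to give each type its qualitative trajectory class —
near-longitudinal RB axons in the dorsal tract
($g_{rc} = -0.2$, $\alpha = 0.08$: stiff enough that an axon's DV
excursion over its length is a few µm, the regime in which soma barriers,
not chance, confine the tract), ventrally descending interneurons that turn
longitudinal near the floor plate, and commissural dives — and are
explicitly calibration targets for `pattern_search()`, not measured
constants.

### Populations, schedules and synapses

Neuron attributes are drawn from per-type *measurement tables* by a
smoothed bootstrap (`sample_generalized()`: uniform row choice plus
per-column Gaussian jitter). The packaged tables are synthetic Gaussian /
log-normal mixtures that mimic the qualitative anatomy (documented in
`make_measurement_tables()`); they stand in for measured data that lives in
prior work. Soma RC positions are laid on a uniform jittered grid; the two
body sides are mirror images in distribution.

Growth is organised in waves: primary pioneer axons (9 for RB, 4 for other
types, nearest to equally spaced RC positions) start together at t = 0;
followers start in rostro-caudal order at 200 time-unit intervals once the
pioneers of their group finish; all secondary axons wait until every
primary axon in the simulation is complete, then repeat the
pioneer/follower pattern. Secondary axons sprout at a branch point sampled
along the primary (for commissural neurons, at the first crossed-phase
point at or beyond it, since branching follows midline crossing) with an
initial angle drawn from a dedicated secondary-angle table, so their RC
direction opposes the primary's.

Synaptogenesis is geometric: every step segment is intersected exactly with
every dendritic segment, and each crossing independently becomes a synaptic
contact with probability $P[\text{pre type}, \text{post type}]$. Repeated
crossings of a pair can make repeated contacts — the connectome counts
contacts, not pairs. The packaged matrix is a placeholder (0.5 everywhere,
with RB receiving nothing and mn projecting nothing); every scientific
claim the package tests is independent of its values. Crossings from
pre-crossing segments, self-crossings, and — for commissural presynaptic
neurons — ipsilateral crossings are excluded.

### Reproducibility machinery

One master seed drives everything. Every axon consumes an independent
noise stream derived from (seed, neuron id, axon class) by a stable keyed
hash, so a trajectory is bit-identical whether the axon grows alone or in
company at $s = 0$ — a property the test suite asserts exactly, per axon.
The engine's inner loop is compiled (Rcpp); a pure-R single-axon reference
grower reproduces engine trajectories bit-for-bit (the two share an
op-for-op identical angle-wrap), and the engine's spatial-hash
nearest-neighbour query and segment-intersection kernels are tested for
exact agreement with brute-force oracles on a thousand random instances.

## Metrics

* `dv_distribution()` — histogram of trajectory-point DV positions
  (left-closed bins, final bin closed).
* `dv_dispersion()` — mean over RC slices of the SD of slice-crossing DV
  positions; the spread that fasciculation tightens.
* `bundle_stats()` — 1D gap clustering of slice crossings (default gap
  threshold 5 µm, slices every 50 µm): deterministic and testable, at the
  cost that bundles inside the 10-µm dorsal tract cannot be resolved — the
  baseline there is a single merged cluster, so bundle-count effects are
  measured on wide-field populations (dla), dispersion effects on the
  tract-confined RB population.
* `escape_fraction()` — percentage of axon points outside the dorsal
  tract, restricted to the tract's RC extent (x ≥ 700): rostral of the
  dla/dlc soma column the corridor has no ventral wall and "outside" is
  undefined. Even with intact barriers a small fraction (~3%) of points
  count as escaped — axons that dip below 127 µm in the unwalled rostral
  stretch and re-enter caudally *under* the barrier; what the engine
  guarantees exactly, and what the tests assert, is that no trajectory
  segment ever pierces a blocked barrier span.
* `tortuosity()` — arc length over end-to-end distance per axon.
* `isolated_din_count()` — dINs receiving no dIN→dIN contact, a marker of
  how fasciculation concentrates recurrent excitation.

## Calibration

`growth_cost()` compares simulated axons to target statistics:
$w_{dv}\,\|p - q\|_1$ on normalized DV histograms (points pooled over
replicates) plus $w_{tort}\,|T - T^*|/T^*$ on mean tortuosity, evaluated
with common random numbers so the cost is a deterministic function of the
parameters and is exactly zero when the generating parameters are evaluated
against their own targets. `pattern_search()` is a compass search: poll
±step per coordinate, accept the first strict improvement, halve the step
on a full poll failure; its best-so-far trace is monotone by construction.
The packaged recovery experiment (16 dla-like neurons, truth
$k_{dv} = -0.04$, $\alpha = 0.25$, start perturbed to (−0.06, 0.15),
12 replicates) recovers both parameters within 20%. The identifiability of
this scenario matters: for types whose axons pile against the floor-plate
barrier the DV distribution saturates in $k_{dv}$ and the two parameters
trade off along a ridge; the dla scenario, whose descent rate is
proportional to $k_{dv}$, separates them.

A general property of this model class: re-optimizing cue parameters *with*
fasciculation enabled cannot undo bundling: the sharpened DV peak is a
consequence of axon–axon attraction, not of cue sensitivities, so targets
generated without interaction are matched best by interaction-free growth.

## The spiking layer

`simulate_network()` maps a connectome onto single-compartment
conductance-based neurons (Na, K, leak; dINs add a slow K adaptation
current and an NMDA-like voltage-gated conductance that supports
pacemaker firing under sustained drive). Synaptic strength is the unitary
conductance times the anatomical contact count; each contact carries its
own delay (arc length to the contact / 1000 µm·ms⁻¹ + 1 ms synaptic
delay) served from an event queue; nearby same-side dINs are electrically
coupled. Integration is exponential-Euler at dt = 0.01 ms; halving dt
moves spike times by well under 0.5 ms. cIN and aIN contacts are
inhibitory, the rest excitatory.

The cellular parameters are package defaults tuned only for qualitative
behaviour: quiescence without input, touch-evoked bilateral activation,
dIN repetitive firing under NMDA-type drive. They do not reproduce the
precisely tuned physiology needed for an emergent 18 Hz swimming rhythm —
that is out of scope, and the swim/mid-cycle detectors
(`detect_swimming()`, `midcycle_din_count()`) are therefore validated on
*constructed* rasters whose ground truth is known exactly
(`make_synthetic_raster()`): alternating left/right motoneuron bursts are
binned by a 15 ms inter-spike gap, swimming requires ≥5 consecutive
strictly alternating cycles within 10–25 Hz, and a dIN is "mid-cycle" if
≥3 of its spikes fall in the middle half of its own side's burst
interval. The window rule is a documented package choice; there is
no canonical formula for it in the literature.

## What the synthetic data do and do not show

The measurement tables, toy scenarios and synthetic rasters are generators
with known structure, not data. Tests passing on them establish that the
machinery is correct — the update rule, barriers, phases, schedules,
detection and calibration behave exactly as specified — and that the
qualitative fasciculation phenomenology (bundle formation, DV sharpening,
synapse reduction, barrier-gap rescue, repulsive space-filling) emerges at
the packaged scale: populations of 30–126 neurons per experiment and a
~500-neuron full cord, far smaller in synapse count than the
connectomes this model family is typically run at. They do not show that the defaults match real
tadpole anatomy, and some fine-grained effects reported for the full-scale model are weak at
this scale with placeholder connection probabilities: the isolated-dIN
increase under fasciculation (no separation here) and the absolute synapse
totals. Both are reported, not asserted.

## Known limitations

* Axon shafts are static once laid; no retraction, turnover or zippering.
* Interactions are same-type only and first-neighbour only.
* The gradient family is a deliberately small parameterization; the
  evaluator in the reference grower is pluggable, the compiled engine
  implements the packaged family.
* The functional layer is an approximation; quantitative swim frequencies
  and synapse-count thresholds require cellular parameters not available
  in the source available to this package.
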