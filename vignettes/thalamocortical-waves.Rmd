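---
title: "Modelling travelling thalamocortical waves with tcwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling travelling thalamocortical waves with tcwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(tcwaves)
```

## The model

`tcwaves` simulates a closed-loop thalamocortical network as three coupled
60 x 60 sheets of two-state excitable neurons: a cortical layer (CX), the
excitatory thalamocortical relay layer (TC) and the inhibitory thalamic
reticular layer (RE), plus a reduced two-layer variant in which the
thalamus is collapsed into a single inhibitory layer (TH). Each cell
carries a fast voltage `v` with self-amplifying positive feedback, a slow
gating variable `eta` providing negative feedback, and a synaptic output
`s`:

$$\dot v = -(a_1 + a_2\eta)\,v + \frac{a_3 v^2}{a_4+v^2} + a_5 + r,\qquad
  \dot s = \frac{H(v) - s}{t_1\,(s_1 - H(v))},$$

with the synaptic gate $H(v) = (1+\tanh(120(v-0.1)))/2$ and the total
input drive $r$. Thalamic cells use the linear "type-3" gating law
$\dot\eta = -c_1\eta + c_2 v$: they fire a single spike to a step input,
rebound after release from inhibition, and (once past their bifurcation)
oscillate at a rate nearly independent of drive. Cortical cells use the
saturating "type-1" law
$\dot\eta = -d_1\eta + d_2 v_+^3/(d_3+v_+^3) + d_4$: a saddle-node
threshold whose firing rate grows continuously with drive.

In the phase plane the voltage nullcline has an inverted-N shape; the
gating nullcline is a line (type-3) or a bounded sigmoid (type-1). The
stable intersection `m` left of the nullcline's local minimum `p` (the
fold) is the resting state; the Euclidean distance between `m` and `p` is
the **activation threshold**. Drive raises the voltage nullcline, moving
`m` toward `p`; when they meet, stability is lost and self-sustained
oscillation begins.

```{r phaseplane}
rep <- phase_plane_report(tc_params())
rep$threshold
rep$equilibria
```

Two threshold knobs are exposed, matching the two gating laws: the slope
of the type-3 gating line (`with_threshold(p, scale = )`) and the type-1
offset `d4` (`with_threshold(p, offset = )`). Lowering either moves the
rest state toward the fold.

## Coupling and network architecture

Within the cortex each cell connects to its four lattice neighbours
(`build_lattice4()`), thinned uniformly or in dense clusters to a target
connectivity fraction by exact edge counting. 80% of cortical cells are
excitatory; their synapses enter with per-link gain
$w_E\,k_n/\sqrt{N}$, inhibitory ones with $w_I\,k_n/\sqrt{N}$.
TC and RE are reciprocally coupled: RE inhibits the four surrounding TC
cells through the cross map $C_{TH}$ (driving post-inhibitory rebound),
TC excites its matching RE cell. A fraction of thalamic cells (10%)
project to their matching cortical position, and 1% of cortical cells
project back to both thalamic layers — closing the loop. We implement
those cross-layer pathways as per-neuron (topographic) masks: the model
statement counts *neurons* ("10% of relay cells affect the cortex
directly"), and per-pair random matrices at those percentages would give
each cortical cell hundreds of simultaneously active presynaptic relay
cells, i.e. input gains far above the maximum gating damping, which
diverges in finite time. A general `random_bipartite()` builder is still
provided (and used by the reduced model, below).

Transmission delays are realised without delay differential equations:
the source synapse field drives a chain of "fictitious" type-3 elements
whose post-inhibitory rebound re-emits the pulse ~2 ms later. The
element's gating rate is calibrated (`calibrate_delay_element()`) so one
element delays a canonical rebound-shaped pulse by 2.0 ms; three in
series give ~5.8 ms. Because the per-element wait depends mildly on the
input pulse shape, the calibration pulse is itself rebound-shaped — the
waveform that actually traverses the network's rebound pathways.

### The reduced two-layer model

For the delay scenarios the thalamus is collapsed into one inhibitory
layer TH with strong lateral excitation over the 4-neighbour map and
long-range connections to and from a fully connected, all-excitatory
cortex. Here the TH-CX pathways *are* random bipartite at 10% of pairs:
each TH cell pools many cortical synapses (robust triggering), and each
cortical cell receives pooled, effectively long-range thalamic
inhibition — the delayed long-range antagonist that the wave-steering
scenarios need. "TH-CX connectivity 100% vs 90%" is then a per-cortical-
cell receive mask; its zeroed cells are the "uninhibited nodes" that
seed new waves.

Two printed parameter values required interpretation, recorded here as
the package's own choices. First, the lateral thalamic term is evaluated
as the cross map gathering the presynaptic product $L_v L_s$; gathering
$L_s$ alone and multiplying by the postsynaptic voltage would give an
input gain of $w_{TH}\times 4 = 60$/ms on the postsynaptic voltage —
above any attainable gating damping, so every explicit integrator
diverges within a millisecond. Second, the reduced thalamic gating pair
is used as `(c1, c2) = (0.2, 6)`: an excitable rest state requires the
gating-line slope to exceed ~16 (the line must pass above the fold), so
the slope is kept at the thalamic value 30 while retaining the four-fold
faster gating rate; with a slope of 3 the only equilibrium is a
depolarised state with saturated synapses and no wave propagation is
possible.

## Numerical scheme

The system is integrated by an explicit stochastic Euler scheme with one
refinement: after a spike the gating variable makes the voltage leak
$a_1 + a_2\eta$ reach several hundred per ms, so the linear-in-`v` leak
is treated implicitly whenever it is damping (unconditionally stable),
while all remaining terms stay explicit. The default step is
`dt = 0.005` ms: a plain explicit update is unconditionally unstable at
coarser steps ($\lambda\,dt > 2$), and halving `dt` changes short-horizon
solutions by well under 1% RMS. Three further safeguards are active, all
with the same rationale the model itself states for the reticular input
("saturated at a minimum to prevent numerical instabilities"): every
layer's input field is floored at -60; the type-3 gating variable is
floored at -1 (sustained strong inhibition would otherwise push `eta` so
negative that the leak changes sign and the voltage runs away — the
floor leaves rebound dynamics intact); and the type-1 Hill term is
evaluated on the rectified voltage $v_+$, since the printed cubic has a
pole at $v = -d_3^{1/3}$ that inhibitory input would otherwise cross.
Cortical noise (sd `sigma = 0.1`) enters per step scaled by
$\sqrt{dt}$ (diffusion contract); a per-step "input" mode and "off" are
available.

The absorbing boundary holds a one-cell ring of every layer at its
resting state: border cells are permanently unexcitable, so waves
terminate there instead of reflecting. (An equivalent high-threshold
gating offset is numerically stiffer for no behavioural difference.)

Initial conditions place every cell at its stable rest; scenarios start
by displacing the voltage of trigger cells (default: the centre cell,
+1.5).

## Scenario presets

`preset_catalog()` lists the named operating points: open loop (no
corticothalamic feedback, 99% excitatory), deterministic and stochastic
closed loop, uniform connectivity sweeps, single- and two-cluster
cortices, the reduced-model delay scenarios (0/2/4/6 ms), unconnected-
node wave steering, the node-line reverse oscillation, the spiral via a
ten-fold inhibition drop at t = 28 ms, the E/I scalings (reticular
inhibition x300, corticothalamic excitation x10, cortical excitation x2)
and an 80 x 80 lattice. Scheduled modifiers (weight scalings, threshold
blocks, stimuli, mid-run delay switches) are applied by the integrator at
their onset times and recorded in the run manifest.

```{r catalog}
preset_catalog()[, "name"]
```

## Wave analysis

Activity movies (voltage frames every 2 ms by default, pixel pitch
0.4 mm so a 60-cell sheet spans 24 mm) are quantified by:

* `segment_wavefront()` — thresholding plus 4-connected labelling; the
  default level is the midpoint between the movie's resting median and
  its spike peak.
* `wave_speed()` — for each *advancing* boundary pixel of frame n+1, the
  distance to the nearest boundary pixel of frame n, averaged and
  converted to cm/s. Restricting to advancing pixels makes the estimator
  exactly linear on rigidly translating fronts (a band moving 1 px/frame
  at the default calibration gives 20 cm/s).
* `kymograph()`, `dominant_frequency()` (spectral peak of the
  spatial-mean trace, excluding the zero bin; first 50 ms discarded),
  `wave_area_series()`, `wave_duration()`, `wave_direction()` (centroid
  displacement; 0 deg rightward, 90 deg upward).
* `lurch_index()` — the fraction of inter-frame intervals, over the
  front's expansion episode along a scan line, in which the leading edge
  fails to advance; temporal gaps count as stalls. A smooth
  constant-velocity front gives ~0, a staircase front its stall
  fraction. This operationalises the thalamic "staggered in time"
  pattern; since the thalamic front hops about one lattice step per
  2-3 ms, lurch analyses record frames every 0.5 ms so the stalls are
  resolved against the much faster cortical sweep.
* `compare_conditions()` — two-sample Student t test over seed
  batteries (5 seeds by default), as used for all condition contrasts.

The geometric fixture generator `make_movie()` (planar, radial,
rotating, staircase, constant; configurable speed, direction, period,
noise) provides ground-truth movies for all of these estimators; the
test suite recovers speed within 5%, direction within 5 degrees,
frequency within one spectral bin, and staircase stall fractions within
0.05. Fixtures are purely geometric — passing them validates the
measurement chain, not the dynamics.

```{r fixture}
mv <- make_movie("planar", speed = 1, n_frames = 30)
median(movie_speed_series(mv), na.rm = TRUE)   # 20 cm/s by construction
```

## What the simulated waves look like

At the reference operating point the model reproduces the qualitative
repertoire: an isolated thalamus supports a slow lurching wave (~20 cm/s,
stall fraction ~0.8) that extinguishes on its own, while an isolated
near-fully-excitatory cortex sweeps at ~10 lattice steps per frame
(~200 cm/s) and dies at the absorbing boundary; the closed loop sustains
activity beyond 400 ms in all layers, with cortical waves much faster
than thalamic ones.

The model's operating band is set by one calibration the model
definition itself prescribes: the cortical operational threshold is
chosen so that the closed-loop oscillations fall in the 10-20 Hz range.
With the printed gating offset alone the loop free-runs near 26 Hz in a
dense many-wavelet regime; the three-layer presets therefore raise the
cortical gating offset by +0.01, which moves the system into the sparse
discrete-wave regime (dominant frequency ~17-26 Hz and mean wave speeds
~50-150 cm/s across seeds). The two regimes coexist near this boundary,
so which one a given run settles into — and hence its exact mean-field
frequency and speed — remains seed-dependent; the package reports
whatever the requested seed produces.

## Problem sizes and runtimes

Correctness tests run at 16-24 cell lattices and tens of milliseconds;
the acceptance analyses run the full 60 x 60 geometry for 400 ms
(about 1.5 min per run on one core), 30-40 cell lattices for the
scaled-down condition contrasts, and seed batteries of 3-5. Because the
intracortical gain is normalised by $k_n/\sqrt N$, a smaller lattice is
intrinsically more excitable per link; scaled-down condition batteries
therefore rescale $k_n$ with $\sqrt N$ so the per-link gain — and with
it the thalamically paced wave regime — matches the 60 x 60 operating
point. The methods above are deterministic given the seed, including
connectivity realisation and noise.

## Known limitations

* No laminar cortical structure, long-range intra-layer axons,
  reticular bursting, or voltage-dependent synaptic conductances — the
  model is phenomenological by design.
* The multiplicative postsynaptic voltage factors of the excitatory
  cross-layer inputs make those drives vanish at `v = 0`; they are
  implemented literally, which leaves corticothalamic triggering
  marginal (the closed loop closes mainly through the
  cortex-to-reticular pathway).
* Exact magnitudes of the wave statistics are regime-dependent; ranges,
  orderings and trends are the reliable outputs.
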