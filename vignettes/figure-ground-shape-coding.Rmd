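---
title: "Figure-ground segregation and shape coding in a five-area spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Figure-ground segregation and shape coding in a five-area spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgspike)
```

## The model

`fgspike` simulates a feed-forward hierarchy of five areas of Izhikevich
neurons that (i) segregates a binary display into figure and ground and
(ii) classifies the figure by whether its borders are dominated by
vertical or horizontal segments, read out as the firing order of two
output cells.  The correspondence to the visual system is retina-like
relay (area 1), V1 (area 2), V2/V4 (areas 3–4) and IT (area 5).

Every neuron follows the standard two-variable quadratic
integrate-and-reset dynamics

$$\dot v = 0.04 v^2 + 5 v + 140 - u + I,\qquad \dot u = a\,(b v - u),$$

with a spike at $v \ge 30$ mV followed by $v \leftarrow c$,
$u \leftarrow u + d$.  Integration is forward Euler with `dt = 0.25` ms,
the membrane advanced in two half-steps (the scheme published with the
model).  Cells start at their stable resting point
($0.04v^2 + (5-b)v + 140 = 0$, negative root, $u = bv$), so an undriven
grid is exactly silent.

The per-step drives are

* area 1: $I_{1F} = w_1 T_F$ with $T_1$ the stimulus and $T_2$ its full
  contrast reversal (two polarity channels $F$);
* area 2: $I_{2F} = w_{2e}\, S_{1F} - |w_{2i}|\, \bar S_{1F}\mathbf 1$ —
  retinotopic excitation plus uniform global inhibition proportional to
  the area-wide mean activity;
* area 3: $I_{3Fj} = w_3\,\Theta(S_{2F} * f_j - 1)$ — a two-pixel
  difference filter per sub-channel $j$, thresholded by the step
  function, i.e. an oriented edge detector with one polarity per $j$;
* area 4: $I_{4Fj} = \kappa_4 w_4 \bar S_{3Fj}$ — the spatial mean of
  each detection map (one cell per channel and sub-channel);
* area 5: $I_{5i} = \sum_{F}\sum_j w_{5iFj} S_{4Fj}$ with
  $w_{51} = \begin{pmatrix}0&A&0&A\\0&B&0&B\end{pmatrix}$,
  $w_{52} = \begin{pmatrix}A&0&A&0\\B&0&B&0\end{pmatrix}$ and $B < A$.

The reference weights are $w_1 = 10$, $w_{2e} = 400$, $w_{2i} = -750$,
$w_3 = 500$, $w_4 = 5.0$, $A = 100$, $B = 5$ (model current units).
Spike maps $S$ enter the drives as exponentially filtered traces
(`update_trace`), and each stage reads the previous step's traces, so
propagation is synchronous with a one-step feed-forward delay and onsets
accumulate causally across areas.

## Stimuli

Displays are $N \times N$ binary arrays ($N = n + 2m$; the defaults
$n = 64$, $m = 6$, $N = 76$).  A framed polygon is white against black,
bounded by straight frame edges on three sides of the inner square and by
a single-valued "profile" column function on the fourth, with both
profile endpoints pinned at the mid-points of the top and bottom inner
edges.  The mid-point anchoring is what makes the total 4-adjacency
border length identical across the original and its mirror-, contrast-
and figure-ground-reversed versions, so the transforms are matched in
every low-level quantity except which region is figure.

The shipped fixtures are two deterministic profiles with exactly 1720
white pixels each (inner area ratio 0.42; 0.30 including the frame): a
shallow trapezoid whose borders are vertical-dominated ($B_v = 128 >
B_h = 82$) and a square wave that is horizontal-dominated ($B_h = 360 >
B_v = 128$).  The generator adjusts interior profile columns
deterministically to hit any requested white count, so identical inputs
give bit-identical images.  The circle controls are a centred rasterized
disc whose radius is solved by grid search for an inner ratio of 0.42,
either isolated ("disconnected") or joined to the top/bottom inner-edge
mid-points by a one-pixel bridge ("connected").  In raster form the
connected disc's figure-ground reversal does not conserve the border
total exactly (the figure touches the frame over 2 px, its complement
over roughly 250 px); `make_image_set` therefore enforces border
conservation only for polygon sets and records the flag for circles.

What the generator emulates is the *constraint structure* of the study
displays — mid-point-anchored profiles, matched white counts and border
totals, opposite orientation dominance — not their hand-drawn shapes,
which are not recoverable from the published material.  Passing tests
therefore certify the mechanism on constraint-equivalent stimuli, not
pixel-level reproduction of the original artwork.

## How segregation works, and the operating point

Area 1 fires only at white pixels.  In the channel where the figure is
white, figure cells receive $w_{2e} - |w_{2i}|\cdot(\text{white
fraction})$ per unit of presynaptic trace — net excitation for the small
figure region — while ground cells receive only the global inhibition.
In the opposite-polarity channel the figure region is black: there the
figure cells get *pure, strong* inhibition (the white fraction, and so
the global term, is large) and fire by post-inhibitory rebound, while
the white ground cells sit near zero net drive.  Both channels thus
highlight the same region, which is the definition of figure used
throughout: the smaller of the white and black pixel sets
(`figure_mask`).

Realizing that regime with the published weight values required three
deliberate choices, all exposed in `network_config`:

* **Input rhythm.** Area 1 uses tonic relay parameters
  $(a,b,c,d) = (0.1, 0.2, -65, 8)$, firing at a regular ~70 Hz under
  $w_1 = 10$.  Regular pulses matter: rebound needs periodic pauses in
  the inhibition, and a strongly adapting input yields either one
  rebound wave for every hyperpolarized cell or none — no
  figure/ground separation.
* **Split trace constants.** The relay synapses (area 1 to 2) use
  `tau_syn_input = 1` ms, so the global inhibition arrives as sharp
  pulses separated by genuine release windows; all later stages use
  `tau_syn = 5` ms, consistent with reading the drive equations as
  sustained mean currents.  A single shared constant cannot do both: at
  5 ms the inhibition never releases (a stable hyperpolarized fixed
  point, hence no rebound at any strength), at 1 ms the feature stages
  become pulse-driven and the weak $B$-weighted read-out path dies.
* **Area-2 cell type and start state.** Area 2 uses rebound-capable
  low-threshold cells $(0.06, 0.25, -57, 1)$, whose resting recovery
  value sits at the edge of the spiking regime, and starts them slightly
  depolarized (`v0_area2 = -55`, i.e. with elevated recovery), which
  absorbs the otherwise spurious rebound wave at stimulus onset.

Under this operating point the area-2 response is all-or-none per drive
class: strongly excited sites fire three-spike bursts every input cycle,
weakly excited sites single spikes, strongly inhibited sites rebound
periodically, moderately inhibited sites stay silent.  The binarization
threshold `theta_b * trace_sat` (0.9 × 2.5 = 2.25) is calibrated
*between* the steady trace peak of single-spike sites (≈ 2.1 at these
constants) and that of burst sites (≈ 2.45).  The consequence is a clean
separation of roles: *any* spiking marks a site as segregated (the
quantity behind the Dice and spiking-area measures), but only burst-level
activity propagates through the edge filters to areas 3–5.

This read-out explains every response ordering:

* Original and mirror displays drive the $A$-weighted $F{=}1$ row with
  burst-level figure activity — strong, early output; mirroring permutes
  sites within the spatial means and exchanges the two equal-weighted
  polarity filters per orientation, so the output is exactly invariant.
* Contrast-reversed displays swap the channels: the burst-level signal
  now travels the $B$-weighted $F{=}2$ row, giving the same winner with
  a later onset and fewer spikes.
* Figure-ground-reversed displays enlarge the white region, which
  weakens the net figure excitation below the burst threshold in
  $F{=}1$ and routes the rebound signal through $F{=}2$: nothing
  reaches the feature stages, and the output cells stay silent.  This is
  a *stronger* form of the reported suppression — the reference results
  show small but nonzero FG responses, whereas this operating point
  suppresses them completely.  All orderings (fewer spikes than any
  other transform, latest onset) hold strictly; comparisons treat a
  silent cell's onset as later than any spike time.

`kappa4 = 250` rescales the area-4 drive — the literal spatial mean of a
border map over $N^2 = 5776$ sites is a few parts in a thousand, far
below rheobase — while multiplying every sub-channel equally, so no
ordering is affected; `kappa4 = 1` restores the literal equation.

## Classification and experiments

The four filters pair a pixel with its right neighbour (even $j$,
vertical borders) or the pixel below (odd $j$, horizontal borders), one
polarity each; correlation is anchored at the first pixel of the pair
with zero padding, which never matters for framed stimuli because the
margins are black.  Cell 1 reads the even columns, cell 2 the odd ones,
so the cell whose orientation dominates the figure's border budget
receives the larger area-4 signal and fires first.  Rotating a display a
quarter turn maps each oriented border count onto the opposite
orientation bijectively, so the two cells' counts and onsets exchange
exactly.

`run_image_set_experiment`, `run_rotation_experiment` and
`run_circle_experiment` package these observables (per-member counts,
onsets, winners, area-2 spiking ratios) with verdict flags that are pure
functions of the stored numbers, plus the configuration hash for
reproducibility.  Decision rules: the winner is the cell with the
strictly earlier first spike, an exact tie falls to the larger count,
and two silent cells give no winner.

## Numerical choices and degenerate inputs

* `dt = 0.25` ms; the tonic-drive spike count changes by at most one
  when `dt` is halved, and matches a `dt = 0.01` reference integration
  within one spike.
* The step function in the filter stage is read as $\Theta(x) = 1$ iff
  $x \ge 0$ (detection iff correlation $\ge 1$); with binary maps this
  is exactly "the $-1$ pixel is 0 and the $+1$ pixel is 1".
* Uniform displays run fine through the network (an all-black stimulus
  silences channel 1 and saturates channel 2); classification of such
  degenerate inputs simply yields equal or absent responses and the
  winner falls to the tie rules.
* No noise is used anywhere by default; an optional seeded uniform
  initial-voltage jitter (`jitter_mv`, default 0) exists to break
  pathological synchrony, and its seed is part of the configuration.
  All shipped results are single deterministic runs, byte-identical
  across repetitions.

Simulated problem sizes throughout the package are the study's own:
76 × 76 grids, 100 ms at `dt = 0.25` ms (400 synchronous steps over
roughly 70 000 cells per run); the full experiment battery (two polygon
sets, rotation, two circle sets) is 17 such runs.

## Known limitations

* FG-reversed responses are fully suppressed rather than merely weaker
  (see above); the orderings, not the absolute FG spike counts, are the
  validated surface.
* The two fixture profiles are constraint-equivalent stand-ins, not the
  original hand-drawn silhouettes; likewise the circle geometry
  (radius, one-pixel bridges) is chosen by the stated area-ratio rule,
  so printed per-figure integers from the reference (e.g. specific
  spike counts for the circle) are not reproduction targets.
* Weights are fixed; the output matrices are treated as given "learned"
  weights and no learning rule is provided.
* The hierarchy is strictly feed-forward: no feedback, conductances,
  delays or plasticity.
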