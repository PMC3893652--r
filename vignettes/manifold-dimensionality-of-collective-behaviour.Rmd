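---
title: "Measuring collective behaviour as manifold dimensionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring collective behaviour as manifold dimensionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The idea

Groups of animals that coordinate — schooling fish, trailing ants, flocking
birds — occupy far fewer effective configurations than the same number of
independently moving individuals. `swarmdim` operationalises this as a
geometric definition: *collective behaviour is the existence of a
low-dimensional manifold on which the group's video frames are embedded*.
Each grey-scale frame of a video is a point in pixel space (a 960 × 640
frame is a point in R^614400). If the group is coordinated, the sequence of
frames lies near a low-dimensional manifold of that enormous space; if the
individuals move independently, it does not. No tracking of individuals is
required.

The dimensionality of that manifold is estimated with ISOMAP:

1. **Neighbour graph.** Connect each frame to its ν nearest frames by
   Euclidean distance in pixel space (default ν = 11; results are insensitive
   over roughly ν = 7–15). Non-neighbours get weight ∞ so that shortest paths
   cannot jump between branches of the manifold.
2. **Geodesics.** All-pairs shortest paths along the graph approximate
   on-manifold distances. Floyd–Warshall is the reference solver;
   a binary-heap Dijkstra from every source gives identical output
   (within 1e−9 on random graphs, tested) and is much faster on sparse
   neighbour graphs, so it is the default.
3. **Classical MDS.** Double-centre the squared geodesic matrix,
   eigendecompose, and read off nested coordinates.
4. **Residual variances.** For each candidate dimension d,
   R(d) = 1 − ρ²(geodesic distances, embedding distances using the first d
   coordinates). R(d) ∈ [0, 1]: 0 is a perfect d-dimensional account of the
   geodesics, 1 the worst. The estimated dimensionality d̂ is the smallest d
   with R(d) < 0.05. If no d ≤ d_max (= 11) passes, the trial is *censored*
   and carries the value d_max + 1 = 12 downstream — the top of the
   observer scale described below.

The definition of R as 1 − ρ² is the standard ISOMAP residual; it reproduces
the documented endpoint semantics (0 = perfect, 1 = worst) exactly.

## What the synthetic-data generator emulates

Field videos of animal groups are bulky and rarely redistributable, so the
package generates its own study materials: rendered particle-swarm clips of
the kind used to train human observers of collective behaviour.

* **Swarm model.** Discrete-time self-propelled particles: constant speed,
  headings updated by the circular mean of neighbours within an interaction
  radius (self included), plus an attraction heading toward the nearest of
  0–2 stimuli mixed in with a configurable weight, plus uniform angular
  noise on [−η, +η]. Boundaries are reflective (specular bounce) or periodic
  (wrap). The noise presets low/moderate/high = 0.1/1.0/2.5 rad span the
  ordered regime, the order–disorder transition, and the disordered regime.
  This Vicsek-family rule set is the field's standard minimal model for the
  phenomenology that matters here: alignment, stimulus attraction, and
  tunable noise.
* **Rendering.** Agents are dark filled discs (grey 30) on a light
  background (grey 220), matching animals filmed against an arena floor.
  The default test-scale frame is 160 × 107 — the 3:2 aspect of the
  960 × 640 experimental profile — with n = 300 frames, so a full synthetic
  study runs in minutes; `render_spec(960, 640)` plus `n = 900` frames is
  the full-scale profile. A pixel is foreground when its centre lies within
  `agent_radius` of the agent's scaled position: deterministic and checkable
  against per-pixel enumeration.
* **Observer scores.** Two independent integer scores per trial on a 1–12
  scale (low = most interaction), generated as
  clip(round(d̂_true + N(0, σ)), 1, 12). The affine map defaults to the
  identity because the observer scale was constructed to be directly
  comparable with the embedding dimensionality; σ defaults to 1 score point.

What the generator does **not** emulate: body articulation (limbs, posture),
occlusion, lighting variation, camera shake, or the gradual entry/exit of
individuals from the field of view. Passing tests therefore demonstrate the
correctness of the pipeline and its behaviour on idealised swarm imagery,
not performance on raw field video.

## Speed-scaled temporal sampling

Species move at very different speeds, so videos are sampled at a period
inversely proportional to the characteristic speed `v_pix` (pixels/frame):
`s = round(s_ref · v_ref / v_pix)`, floored at 1. The built-in presets
(`sampling_presets()`) — ants (T = 390 s, s = 13), fish with stimuli (30 s,
1), frogs and chickens (480 s, 16), humans and slowed no-stimulus fish
(600 s, 20), all at 30 fps — each retain exactly

```
floor((T * 30 - 1) / s) + 1 = 900
```

frames. Two conventions are worth noting. The sampling period is expressed
in *frames* throughout: the per-species values only produce the common
900-frame count under that unit. And grey levels are taken as the usual
integer range {0, …, 255}. Frame indices are 0-based with the first frame
always retained; when T × fps / s is not an integer, the count truncates
downward and the loader warns if a preset does not give 900.

Grey-scale conversion uses the broadcast-standard luminance weights
(0.299, 0.587, 0.114), rounded half away from zero. The three colour
channels of such footage are strongly correlated, so any fixed convention
serves; this one is documented and unit-tested.

## Numerical choices

* **Tie-breaks.** Neighbour-distance ties are resolved by ascending row
  index; component-size ties keep the component containing the lowest index.
  Both make runs exactly reproducible.
* **Symmetrisation.** The ν-NN relation is symmetrised by union (an edge
  exists if either endpoint names the other), consistent with edges being
  unordered pairs. Intersection symmetrisation would disconnect sparse
  regions more aggressively; union is the common default and keeps sparse
  regions connected.
* **Disconnected graphs.** ISOMAP is undefined across components, so the
  embedding uses the largest connected component; if it holds less than 90%
  of the points (configurable) the data are declared too sparse rather than
  silently truncated. Ties go to the lowest-index component.
* **MDS conventions.** Negative eigenvalues (non-Euclidean geodesics)
  contribute zero coordinates; each coordinate column's sign is fixed so its
  largest-magnitude entry is positive, making output reproducible across
  linear-algebra backends.
* **Distances.** Pairwise Euclidean distances are computed via the Gram
  identity in BLAS (clamping tiny negative squares to zero) — on flattened
  video this is an order of magnitude faster than naive pairwise loops.
* **Degenerate inputs.** Constant distance vectors make the correlation in
  R(d) undefined; R(d) is set to 1 with a warning. A constant ANOVA
  response is reported as F = 0, p = 1 rather than anova()'s 0/0.
* **Seeds.** All randomness derives from explicit seeds;
  per-trial seeds come from the master seed by a fixed integer recurrence
  kept below 2³¹. Simulation restores the caller's RNG state.

## Fixture geometry for dimensionality recovery

The `make_manifold_cloud()` fixtures are the ground truth for the
R(d) < 0.05 criterion: line and circle (intrinsic dimension 1), plane and
swiss roll (2), embedded in arbitrary ambient dimension by a seeded random
orthogonal map. Two geometric decisions matter for the swiss roll:

* Its two intrinsic extents are kept comparable (unrolled length ≈ 49,
  width 35). A strongly elongated strip — e.g. the 1.5-turn, width-21
  proportions common in machine-learning demos — is *effectively
  one-dimensional* under the 1 − ρ² criterion: R(1) ≈ 0.014 < 0.05, a
  result confirmed independently with vegan's geodesic distances. That is
  a property of the criterion, not a bug.
* The roll makes one full turn (t ∈ [1.5π, 3.5π]). With more turns the
  inter-coil gap (2π) shrinks relative to the sheet, and at n = 1000 points
  a handful of ν-NN edges cross the gap; even two such shortcut edges
  collapse the geodesic structure. With one turn the gap stays well clear
  of the ν-NN edge lengths for ν up to 15, and d̂ = 2 is recovered stably.

## The synthetic study and its statistics

`run_experiment()` mirrors the full study design: for each synthetic
"species" (the default pair differs only in noise level: aligned η = 0.1
vs erratic η = 2.5, eight agents in a small reflective arena) and each
stimulus condition (0, 1, or 2 attractive stimuli), it runs replicate
trials through simulate → render → embed, simulates paired observer scores,
selects the trials with minimum inter-observer disagreement per cell
(|score_A − score_B|, ties by trial id, default 3 of each cell), and then:

* Pearson correlation between d̂ and mean observer score, tested with
  t = r √((n−2)/(1−r²)) on n−2 df;
* two-way ANOVA of d̂ on species + condition (main effects by default, the
  convention for this design; the interaction term is configurable);
* per-species one-way ANOVAs of d̂ on condition;
* Fisher's protected LSD post-hocs using the pooled error mean square,
  *only* when the parent effect is significant at 0.05 — a non-significant
  omnibus F yields an explicitly empty table carrying the gate reason.

Censored trials enter these statistics at d_max + 1 = 12. This is a
deliberate, documented limitation: it compresses everything beyond the
inspected range onto one value and will understate differences among
strongly disordered groups. The ANOVAs are the textbook balanced
decompositions, and the one-way analysis is dimensionality ~ condition
(response ~ factor), consistent with the two-way model.

With one central stimulus, low-noise swarms school tightly around it and
their videos embed at small d̂ (typically 3–5 at the test scale), while
high-noise swarms remain censored — the stimulated conditions drive the
species effect exactly as stimulus-induced schooling does in the fish data.
Without stimuli neither synthetic species produces a recurrent
low-dimensional image manifold at the 300-frame test scale, so condition 0
is typically censored for both: a known limitation of the small frame
budget, not of the method.

Why a *small* arena with *few, large* agents for the rendered comparison:
binary-disc images decorrelate once the group translates by about one disc
diameter. For the neighbour graph to see the manifold of coordinated
states, the video must revisit similar images many times within the frame
budget, which requires the state space (arena) to be small relative to the
image decorrelation scale (disc size). Large sparse swarms of small discs
at this frame budget produce near-orthogonal frames and censor regardless
of coordination.

## Problem sizes used in the test suite

Ground-truth recovery runs at n = 200 (line), 400 in 100 ambient
dimensions (plane), and 1000 (swiss roll, ν swept 7–15); the rendered
low- vs high-noise comparison uses 10 paired seeds at the 160 × 107 /
300-frame profile; ANOVA calibration uses 2000 Monte-Carlo replicates of a
3 × 5 null design. These sizes were chosen so the full suite exercises
every stage at meaningful scale while completing in a few minutes.

## Known limitations

* The particle presets are plausible dynamical regimes of a minimal model,
  not reconstructions of any specific animal system.
* Binary-disc rendering makes image-space distances saturate quickly;
  smooth intensity profiles would extend the usable decorrelation range.
* Censored-at-12 coding, as above.
* ISOMAP here has no out-of-sample extension and no landmark variant;
  every trial is embedded from scratch.
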