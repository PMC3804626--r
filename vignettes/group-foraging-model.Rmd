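---
title: "An agent-based model of group foraging with spatial memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of group foraging with spatial memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupforage)
```

## The question the model addresses

Field observations of forest primates show movement patterns that look
planned: groups travel to out-of-sight food trees, revisit productive areas,
and follow route-like paths. Whether this reflects a Euclidean cognitive map
(distance and bearing to every known site, from anywhere), a topological
landmark memory (only sites associated with the last familiar place are
recallable), and how much is remembered at all, is hard to test in the
field. This package implements the simulation side of a strong-inference
approach: build groups of simple agents that differ only in those cognitive
assumptions, let group-level movement emerge, and compare the resulting
movement statistics with an observed group-centre trajectory.

Twelve agent types span the hypothesis space: social rule (independently led
vs leader led) x memory type (Euclidean vs landmark) x memory retention
(20, 60 or 100 remembered sites). `all_agent_types()` enumerates them.

## World and scheduling

The world is a 108-ha grid of 30 x 30 m resource cells — the canopy scale
at which feeding decisions are assumed to be made — holding a fixed total of
168,000 energy units distributed proportionally to a weight surface. Cells
deplete when fed on and regrow at a uniform 8 units per step, each capped at
its own ceiling. A day is 13 active hours at half-hour resolution: 26 steps,
with no overnight movement or energetics. Within a step every agent acts
once, in a freshly randomized order; then the landscape regrows and the
group centre is recorded.

Each agent balances two needs:

* **Energetics.** Agents hold a target of 100 energy units and decay by
  `100/26` per step. An agent below target feeds if its cell has resources,
  taking `100/11` units per feeding event. The quotient is a design choice
  the published parameters imply but do not state: the feeding-time budget
  (43% of a 26-step day, i.e. 11 steps) should suffice to meet daily
  requirements, and `11 * 100/11 = 26 * 100/26` makes that exact.
* **Safety.** Each agent tracks a desired number of nearby group mates
  (within the 50-m safe radius). At target energy it raises the desire by
  one (prioritizing safety); below target after a failed feeding step it
  lowers it by one (prioritizing food). Unsafe agents move toward group
  mates; safe, hungry agents forage; safe, sated agents rest.

Food-site choice minimizes the index `I = d / r`: distance to the site over
the resources expected there (seen truth inside the 50-m visual range,
remembered belief beyond it). If the best site is visible, reachable within
the 100-m step cap, and safe to stand at, the agent goes there directly;
otherwise it picks a visible stepping-stone cell by re-applying the index
with distance-to-goal as the distance factor. With no candidate at all the
agent explores: uniform random heading, step length uniform in (0, 100] m.

Spatial memory is a fixed roster of the landscape's top cells (nothing is
forgotten in a 6-month trial); believed resource levels regrow mentally at
the global rate while out of sight and snap to the truth when a site
re-enters view. Landmark agents can recall only the remembered sites within
100 m of the last remembered site they saw; every remembered site is a
landmark and is associated with itself.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| cell size | 30 | m | decision scale; grid of 40 x 30 cells = 108 ha |
| total resources | 168,000 | energy | landscape budget (calibrated) |
| grow-back rate | 8 | energy/step | uniform regrowth (calibrated) |
| group size | 70 | agents | observed group scale |
| visual range | 50 | m | food sensing |
| social range | 200 | m | group-mate sensing |
| safe radius | 50 | m | safety neighborhood |
| max step | 100 | m | displacement cap per half-hour |
| target energy | 100 | energy | hunger threshold |
| steps per day | 26 | — | 13-h active day |
| feeding fraction | 0.43 | — | 11 feeding steps/day |
| landmark radius | 100 | m | site association distance |

## The synthetic landscape and its calibration

The original resource surface was derived from occupancy counts of an
observed group (hours spent per cell), which are unavailable.
`synthesize_weights()` emulates the described surface: widely available
low-quality food — every background cell draws a weight from Uniform(0,
0.25], the published replacement rule for zero-count cells — plus a
minority of clustered high-value cells. Each hotspot seeds a uniformly
placed cell and deposits an exponential kernel `intensity * exp(-d)` (d in
cells); contributions below 1 are truncated, so hotspot-cluster cells are
exactly the cells with weight >= 1. The decay length of one cell keeps
clusters at roughly canopy-neighborhood scale.

The two free generator parameters were fixed the way the original model's
landscape parameters were: by sweeping them and matching the published
calibration summaries (mean daily step length ~171 m per 7-h observation
day, mean monthly home range ~20.5 ha against an observed 10-50 ha, mean
group spread ~5043 m^2). At `n_hotspots = 100, hotspot_intensity = 8` the
default world gives ~164 m, ~14 ha and ~4970 m^2 on 60-day probes; sparser
worlds (e.g. 12 hotspots) reproduce step length and spread but concentrate
the group onto ~2 ha a month, an order of magnitude below the calibrated
range use, and were rejected. These defaults are part of the stated world
and are not revisited per analysis.

What the generator does *not* emulate: spatial autocorrelation beyond the
kernel scale (real ranges have contiguous high-use corridors), temporal
phenology, and the empirical tail of occupancy counts. A green directional
test therefore establishes that a direction emerges in *this* world at
reduced scale, not that it must emerge in the Kibale landscape.

## Observation model and metrics

The group centre is estimated recursively each step: the centroid must hold
80% of the whole group within 100 m, else the farthest subset member is
dropped and the centroid recomputed (`group_center()`); an even fission
beyond rescue is flagged. Group spread is the convex-hull area of member
positions.

Metrics are computed on the field observation schedule
(`subsample_observation()`: 5 days per 30-day period, 14 consecutive
half-hour fixes from 08:00), except monthly home range, which counts the
distinct 30-m cells the centre visits over the full period (the published
20.5-ha figure — 228 cells — is unreachable from 70 monthly fixes, so range
use is measured on the full trajectory while distributional metrics stay on
the subsample).

* **Daily step length**: summed centre displacement over the day's window.
* **Tortuosity**: `ln(D_total / D_net^2)`. The natural log is a deliberate
  reading of the published "log": at the observed scale
  `ln(213/35^2) = -1.749`, consistent with the reported mean of -1.69,
  whereas log10 would give -0.76. Because the denominator is squared the
  statistic is unit-dependent; all inputs are metres. Days with zero net
  displacement are excluded.
* **Skewness**: adjusted Fisher-Pearson `G1`.
* **Aggregation index θ**: each 30-m quadrat is scored k of 9 10-m subcells
  visited per 30-day period (a visit is a recorded fix inside the subcell —
  points, not interpolated paths — matching point-sampled field data);
  a beta-binomial is fitted by maximum likelihood over all in-extent
  quadrats, zeros included, and θ is the intraclass correlation
  `1/(alpha+beta+1)`. The originally cited estimator is not recoverable
  from the source, so ML plus the ICC parameterization is this package's
  own documented choice; the reported quantity is the mean over periods
  with a t-based 95% CI, matching how the observed value (0.15, CI
  0.11-0.19) is quoted.
* **Distribution comparisons**: two-sample Kolmogorov-Smirnov D (asymptotic
  p) and Welch's t. Step-length samples are mean-centred first, because the
  mean was consumed by calibration; tortuosity is compared raw.

`rank_hypotheses()` orders types lexicographically by (KS-D of tortuosity,
KS-D of centred step length, |θ difference|) — tortuosity first because it
discriminates where step-length distributions all differ. The order is a
stated convention.

## Numerical and design choices

* **Determinism.** One RNG stream per trial, seeded once; the agent
  shuffle, cell-interior landing points and exploration draws all consume
  it. Identical `(config, seed)` reproduces byte-identical output. Food-site
  ties break by smaller distance, then (row, col).
* **Leader rule.** The leader is agent 0, fixed for the trial, and follows
  the independent safety rule itself. Non-leaders are safe iff the leader
  is within the safe radius; if the leader leaves the 200-m sensing range
  they fall back to the independent rule. Unsafe followers head for the
  leader; unsafe independent agents head for the mean of their nearest
  `desired` sensed mates.
* **Step cap.** Every displacement — social, foraging, exploratory — is
  clamped to 100 m along its ray, including the random landing point inside
  a chosen cell. This keeps the hard displacement invariant testable.
* **Safety at destination** is evaluated with mates at their current
  positions (no anticipation of simultaneous moves). When no visible
  food-bearing stepping stone passes it, the hungry agent simply advances
  toward its goal, capped at 100 m: food outranks safety for an agent that
  chose to forage, consistent with the adaptation rule lowering safety
  demands under food stress.
* **Initialization.** The landscape starts saturated; agents start at
  target energy, desired count 5, scattered uniformly within 100 m of one
  randomly chosen hotspot cell — a cohesive start that avoids a spurious
  initial clumping phase. Memory beliefs start at the truth.
* **Degenerate inputs.** Sites with non-positive expected resources are
  excluded from ranking rather than erroring; zero-variance step samples
  yield an `NA` skew in feature tables; periods with no visits are skipped
  with a warning in θ estimation; β-binomial optimization runs on log(α),
  log(β) bounded at ±25 to keep the binomial limit (θ → 0) reachable
  without overflow.

## What the tests establish, and known limitations

The unit and property suites pin every operation to independent brute-force
oracles (food-site argmin, hull area, KS-D, the group-centre recursion,
θ parameter recovery within 2 SE on 500-quadrat panels) and the compiled
trial engine to the R reference semantics (branch-for-branch destination
agreement, centre/spread recomputation from agent snapshots, the 100-m
displacement invariant, end-to-end determinism).

The directional acceptance battery (12 types x 5 matched-seed replicates x
60-day trials on the default world) reproduces, as computed by
`tests/testthat/test-acceptance.R`: larger between-retention heterogeneity
of group spread under landmark memory than under Euclidean memory (the
memory-type effect on cohesion). Two published directions do **not** emerge
significantly in this reduced, synthetic world and their criteria are left
failing rather than weakened: the leader-led excess in daily step length
and skew, and the decline of θ from 20 to 100 remembered sites in
leader+landmark groups. Both were re-checked at the full 180-day length
with the same outcome, so the gap is attributable to the synthetic
landscape (its graded, kernel-shaped hotspots leave little of the
periphery-poverty that drives those effects) rather than to trial length.

Out of scope by design: route-based memory, forgetting, memory sharing,
predation events, dominance and demographics, energetic cost scaling with
distance, vector canopy geometry, stochastic regrowth, kernel home ranges,
and the conditional-inference regression-tree analysis (the per-trial
feature export feeds any standard implementation).
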