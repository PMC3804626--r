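# groupforage

Agent-based simulation of collective foraging in a folivorous primate
group, built to discriminate among hypotheses about spatial-memory use from
group-level movement patterns.

Field data can show *that* a monkey group revisits food trees it cannot
see, but not *how* it remembers them. `groupforage` takes the
strong-inference route: simulate groups of simple agents that differ only
in their cognitive assumptions, let group movement emerge, and compare the
resulting movement statistics with an observed group-centre trajectory.
Twelve agent types cross

* **social rule** — independently led (safety referenced to any nearby
  mates) vs leader led (safety referenced to one fixed leader),
* **memory type** — Euclidean cognitive map (all remembered sites
  recallable from anywhere) vs landmark-based (only sites within 100 m of
  the last-seen remembered site), and
* **memory retention** — 20, 60 or 100 remembered sites.

## The model in brief

Agents forage on a 108-ha grid of 30 x 30 m depletable cells (168,000
energy units total, uniform regrowth of 8 units/step, per-cell ceilings)
over 26-step (13-h) days. Each agent holds a target of 100 energy units,
decays by 100/26 per step, and feeds 100/11 per event when hungry; a
desired-neighbor count adapts each step (up when sated, down after a failed
feed) to trade safety against food competition. Safe, hungry agents move to
the food site minimizing

```
I(x', y') = d((x, y), (x', y')) / r(x', y')
```

— distance over expected (seen or believed) resources — with detours
through safe visible stepping stones when the goal is remote. The group
centre is recorded each step by a recursive estimator (centroid must hold
80% of the group within 100 m, else the farthest member is dropped).
Trajectories are subsampled to the field schedule (5 days/month, 14
half-hour fixes/day) and summarized as daily step length and skew, path
tortuosity `ln(D_total / D_net^2)`, convex-hull group spread, grid-cell
home range, and the beta-binomial spatio-temporal aggregation index θ
(intraclass correlation over 9-subcell quadrat visit counts per 30-day
period). Simulated and observed distributions are compared with two-sample
Kolmogorov-Smirnov and Welch tests.

The per-step engine is compiled (Rcpp); a full 70-agent, 180-day trial runs
in about a second.

## Worked example

```r
library(groupforage)

cfg <- simulation_config("leader:landmark:20", days = 60, seed = 1)
trial <- run_trial(cfg)
trial
#> <foraging_trial> leader:landmark:20 | 70 agents, 60 days (1560 steps), seed 1

trial_features(trial)[, c("mean_step", "step_skew", "mean_tortuosity",
                          "mean_spread", "mean_home_range_ha", "theta")]
#>   mean_step step_skew mean_tortuosity mean_spread mean_home_range_ha theta
#> 1   141.271      1.18          -4.209    5291.117              9.675 0.238
```

Read: on the field observation schedule this leader-led, landmark-memory,
20-site group travels ~141 m per observation day with a positively skewed
step-length distribution (1.18; rare long travel days), highly convoluted
daily paths (tortuosity -4.2; more negative = more back-and-forth per net
displacement), spreads over ~5,300 m² (its foraging-competition proxy),
uses ~9.7 ha a month, and concentrates its visits (θ = 0.24; θ near 0
means binomially even range use, larger θ means few sites revisited
often — the observed group's value was 0.15).

Batteries over many types run with matched seeds so every type sees the
same worlds:

```r
plan <- experiment_plan(agent_types = all_agent_types()$label,
                        replicates = 5, base_seed = 1, days = 60)
res <- run_experiment(plan)          # res$features: one row per trial
res$aggregate                        # per-type means/SDs
# with an observed trajectory: res$comparisons and rank_hypotheses(res)
```

Command-line entry points live in `inst/cli/`:

```sh
Rscript inst/cli/simulate.R --agent-type leader:landmark:20 --seed 7 \
    --days 180 --out out/
Rscript inst/cli/experiment.R run --replicates 5 --days 60 --out exp/
Rscript inst/cli/experiment.R sweep --total 84000,168000,336000 --rate 4,8,16
```

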