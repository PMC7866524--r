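# flocknet

Proximity-based social networks, movement leadership and GNSS sampling
design for grazing livestock.

RTK-grade GNSS collars localise animals to ~0.1–0.2 m — precise enough
to resolve close contact (10–30 cm separations) between flock members
and build social networks directly from positions. `flocknet` is an R
package for the analysis chain such a deployment needs, plus a seeded
flock simulator with ground-truth logs so the whole chain is testable
without field data.

**Who it is for:** movement ecologists and precision-livestock
researchers working with high-accuracy animal trajectories; also useful
as a planning tool for choosing collar duty cycles before a deployment.

## What it computes

* **Fence-line accuracy** — point-to-segment distances from a boundary
  walk to fence lines interpolated from surveyed corners, and
  normalised error histograms. For per-coordinate noise σ the orthogonal
  error is half-normal with mean σ·√(2/π).
* **Movement leadership** — within 10-minute intervals, movers are
  ranked by the onset of their departure from the group: with *p*
  strictly earlier movers and a tied block of size *q*, each block
  member scores *n − p − q + 1*; non-movers score 0. For *n* = 7 a
  strict ordering gives 7…1, and two simultaneous first movers each
  receive 6. Per-interval ranks are summed into leader scores.
* **Proximity networks** — timegroup-aligned, threshold-bounded
  nearest-neighbour edge lists (directional, inclusive threshold),
  distinct-neighbour counts, and distance-weighted graphs for short
  windows.
* **Sampling regimes** — continuous (1 fix per *dt*), single-sample
  (1 fix per period) and burst (*on*/*off* duty cycle) schedules applied
  synchronously to all animals; per-animal neighbour-count recovery
  versus the continuous reference; analytic battery metrics
  (extension factor = cycle/on, power saving = off/cycle).
* **Synthetic flocks** — a two-state (graze/travel) formation model with
  a configurable leader propensity, exponential follower lags, planted
  close-contact bouts, and truncated Gaussian RTK-grade noise; returns
  the dataset plus ground-truth leader-event and contact logs.

## Worked example

Simulate 2 h of a 7-ewe flock with six 70 s contact bouts planted so
they span the burst on-windows but fall between the 5-minute single
samples, then compare sampling regimes:

```r
library(flocknet)

offs <- 610 + 600 * (0:5)
sch <- data.frame(animal1 = c("A","C","E","G","B","D"),
                  animal2 = c("B","D","F","A","C","E"),
                  t_start = offs, t_end = offs + 70)
sim <- simulate_flock(simulation_config(duration = 7200,
                                        contact_schedule = sch, seed = 11))

cmp <- compare_regimes(sim$dataset,
  list(regime_continuous(5), regime_single(300),
       regime_burst(60, 240), regime_burst(60, 540)),
  thresholds = c(0.20, 0.30))
unique(cmp[, .(regime, threshold, recovered)])
#>           regime threshold recovered
#> 1:  burst_60_240       0.2      TRUE
#> 2:  burst_60_240       0.3      TRUE
#> 3:  burst_60_540       0.2      TRUE
#> 4:  burst_60_540       0.3      TRUE
#> 5: continuous_5s       0.2      TRUE
#> 6: continuous_5s       0.3      TRUE
#> 7:   single_300s       0.2     FALSE
#> 8:   single_300s       0.3     FALSE
```

Both burst schedules (1 min on / 4 or 9 min off) recover every animal's
neighbour count exactly as continuous 5 s sampling does, while one fix
per 5 minutes misses the contacts outright — here every single-sample
count drops to 0 against continuous references of 1–2 neighbours. The
battery arithmetic for the first burst schedule:

```r
duty_cycle_metrics(regime_burst(60, 240))
#> $extension_factor
#> [1] 5
#> $power_saving
#> [1] 0.8
```

Leadership, on a 4 h simulation where animal A holds 50 % of the
initiation propensity:

```r
sim <- simulate_flock(simulation_config(duration = 14400, seed = 42,
  leader_propensity = c(0.5, rep(0.5/6, 6))))
movement_leaders(sim$dataset)$scores
#>    animal_id score
#> 1:         A    65
#> 2:         G    62
#> 3:         E    53
#> 4:         D    47
#> 5:         B    46
#> 6:         C    41
#> 7:         F    37
```

A led 12 of the 22 planted group movements in this run and tops the
summed rank score. See `vignette("flocknet-methods")` for the model,
parameter defaults and their rationale, and known limitations. A thin
command-line wrapper lives at `inst/cli/flocknet.R`
(`Rscript flocknet.R demo --out-dir out --seed 1`).

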