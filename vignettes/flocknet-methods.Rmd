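---
title: "Methods: proximity networks, movement leadership and sampling design in flocknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity networks, movement leadership and sampling design in flocknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocknet)
library(data.table)
```

# The problem

RTK-grade GNSS collars can localise grazing animals to roughly 0.1–0.2 m,
which is precise enough to resolve *close contact* between individuals —
separations of 10–30 cm — and therefore to build proximity-based social
networks (PBSNs) directly from positional data. flocknet implements the
analysis chain such a deployment needs:

1. **Positional accuracy** of a rover against fence lines interpolated
   from surveyed paddock corners (`fit_fence_lines()`, `fence_error()`,
   `error_histogram()`).
2. **Movement leadership**: within fixed 10-minute intervals, which
   animal moves away from the group first (`movement_leaders()`).
3. **Proximity networks**: thresholded nearest-neighbour edge lists and
   distance-weighted window graphs (`nearest_neighbour_edges()`,
   `window_graph()`).
4. **Sampling design**: what a duty-cycled receiver schedule loses
   relative to continuous sampling, and what it saves in battery
   (`apply_regime()`, `compare_regimes()`, `duty_cycle_metrics()`).

Because field datasets of this kind are rarely deposited, the package
ships a seeded flock simulator (`simulate_flock()`) whose ground-truth
logs make every stage testable end to end.

# Coordinates and data model

All analysis happens in local planar metres. Geographic input is
projected with an equirectangular projection about a reference point
(`project_to_local()`): $x = (\lambda-\lambda_0)\cos\phi_0 \cdot R\pi/180$,
$y = (\phi-\phi_0)\cdot R\pi/180$ with $R = 6\,371\,000$ m. Over a
~100 m × 70 m paddock the projection error is orders of magnitude below
the sub-metre thresholds that matter here (the tests verify < 0.5 %
disagreement with haversine distances within a 200 m window, and exact
invertibility to < 1 mm). No published datum/projection convention is
assumed for input data; the projection is this package's own choice and
is exactly invertible (`project_from_local()`).

Time is seconds since the dataset epoch; absolute timestamps matter only
at file I/O. Every fix carries a quality flag
(`RTK_FIXED, DGNSS, GNSS_3D, INVALID`). `INVALID` fixes are *retained* in
the stored dataset and excluded from every analysis through one filtered
view (`valid_fixes()`), so exclusions stay auditable.

# The flock simulator

`simulate_flock()` is deliberately simpler than a full social-force
model: the analyses need departures, followers and contacts — nothing
finer. The flock is a loose formation: animal $i$ holds a home offset on
a ring of radius `formation_radius` (default 5 m) around a shared
formation centre, and the simulation alternates two behavioural states.

**Grazing.** The centre drifts as a correlated random walk at
`graze_speed` (default 0.003 m/s ≈ 11 m/h), and each animal wanders
about its slot as an Ornstein–Uhlenbeck process with stationary s.d.
`wander_sigma` (default 0.2 m) and mean-reversion `cohesion_strength`
(default 0.05 per step). These defaults were set once, from two
requirements a field scientist would recognise: the flock visibly
drifts across the paddock over hours, yet an event-free 10-minute
interval almost never accumulates the 1 m displacement that the
leadership rule counts as movement. A sensitivity worth knowing about:
raising `graze_speed` toward 0.01 m/s makes grazing drift alone trigger
spurious movement onsets and degrades leadership recovery.

**Group movement events.** Events arrive as a renewal process with mean
spacing `3600/event_rate` seconds (default 6/h, about one per 10-minute
interval) and a refractory gap long enough that consecutive events never
overlap. An initiator is drawn from `leader_propensity`; it departs
immediately toward a new formation site ~`travel_distance` away at
`travel_speed`. Every follower departs after a delay
`follow_latency + Exp(follow_lag)` (defaults 15 s + Exp(20 s)), giving an
unambiguous true departure order. The fixed latency encodes that
followers react only after the initiator has visibly separated; it also
means the initiator's lead typically exceeds the 10 s rank tie window,
which is what makes the planted leader statistically recoverable at all.
With the latency at 0, the minimum of six exponential lags is ~3 s and
the initiator is almost always tied with its first followers.

Travel directions are rejection-sampled: a candidate direction is
accepted only if a numerical sweep of the whole event (staggered
departures included) keeps every animal pair at least 1.5 m apart. This
guarantee matters because close contact in the simulator is *planted,
never emergent*: the set of sub-threshold proximities must equal the
planted contact log exactly for the network-recovery oracle to be exact.

**Contact bouts.** Bouts are planted by steering one member of a pair to
a fixed separation `contact_distance` (default 0.15 m) from the other
for at least `contact_duration_min` (default 60 s), with a 10 s blend in
and out. Bout times are drawn per pair at `contact_bout_rate` (default
0.2/pair/h) with per-animal non-overlap, or supplied exactly via
`contact_schedule` for controlled experiments.

**Observation noise.** I.i.d. Gaussian noise with s.d. `noise_sigma`
(default 0.10 m, RTK grade) is added per coordinate, truncated at
±3σ. Truncation keeps every reported position inside the paddock
expanded by 3σ (a tested invariant) at the price of shrinking the
realised s.d. by ~1.3 %, far inside the ±10 % calibration the tests
check. GNSS error autocorrelation is deliberately not modelled; see
*Limitations*.

What passing tests on this generator do **not** show: real sheep do not
hold ring formations, real contacts arise from behaviour rather than
steering, and real RTK error is temporally correlated and
environment-dependent. The simulator validates the *analysis chain* —
bookkeeping, thresholds, rank arithmetic, regime geometry — not sheep
biology.

# Fence-line accuracy

`fit_fence_lines()` joins consecutive surveyed corners into segments
with outward unit normals (orientation from the ring's signed area).
`fence_error()` assigns each fix the *point-to-segment* distance to its
nearest segment, clamping the perpendicular foot to the endpoints —
infinite-line distances would double-count corners. An optional signed
mode reports positive-outside/negative-inside. For a rover with
per-coordinate noise σ walking the fence, the orthogonal error is
half-normal with mean $\sigma\sqrt{2/\pi}$ (≈ 0.0798 m at σ = 0.1),
which the acceptance tests reproduce within 10 %.

`error_histogram()` normalises bin counts to fractions (default bin
0.01 m, resolving errors over a 0–0.25 m range). A degenerate input
concentrated in one bin yields a count of 1.0 with a warning — the
normalisation, not a hard cap below 1, is the contract. Corner
interpolation of the survey is the primary method; an orthogonal
least-squares fit of the walked line would be a reasonable alternative
but is not asserted to be equivalent.

# Movement leadership

The analysis window is split into half-open intervals `[kL, (k+1)L)`
(default L = 600 s); a trailing partial interval is dropped with a
warning. Within an interval, an animal's **onset** is the earliest time
at which (a) its displacement from its interval-start position exceeds
`move_threshold` (default 1 m — the separation a human observer would
use to call an animal "moved away") and (b) it is more than
`separation_threshold` (default 1 m) from the centroid of the others'
start positions. An animal whose *net* displacement over the interval
stays under the threshold is a non-mover, so out-and-back excursions do
not count; whether movement should instead be judged mid-interval is
genuinely underdetermined, and the net-displacement rule is the
package's choice. Positions are smoothed with a centred 30 s moving
average first: 0.1–0.2 m jitter against a 1 m threshold would otherwise
produce occasional spurious onsets. This automated rule replaces what a
human would do by eye from trajectory plots; both thresholds and the
smoothing window are exposed.

**Ranks.** Movers are ordered by onset; onsets within `tie_window`
(default 10 s, anchored at each tied block's first onset) are
simultaneous. With $p$ movers strictly earlier and a tied block of size
$q$, every block member receives $n - p - q + 1$ — the block's lowest
value — and non-movers receive 0. For $n = 7$: a strict ordering gives
7…1; two simultaneous first movers each get 6 (not 7); seven animals
moving together all get 1. Only the leading-tie case is fixed by the
worked examples this rule generalises; handling of ties further down the
order follows the same block-minimum principle, and an exhaustive
brute-force oracle over all movement patterns of up to 4 animals pins the
closed form to the dealt-pool interpretation of the rule. Scores are the
per-animal sums of ranks over intervals — with four 1 h windows at 10 min
intervals, 24 values per animal.

# Proximity networks

Fixes are aligned into **timegroups** — half-open time bins keeping the
latest valid fix per animal per bin — before any neighbour detection.
`nearest_neighbour_edges()` then records, per timegroup and per focal
animal, the other animal at minimum Euclidean distance; the neighbour is
kept only if that distance is within the threshold, *inclusively*
("at a maximum of 30 cm" reads as an attained bound). Records are
directional (A's nearest need not be B's); `edge_pairs()` and
`neighbour_counts()` provide the undirected and per-animal summaries.
Distances are raw, unsmoothed positions: smoothing before proximity
detection would bias sub-metre distances downward during close passes.

`window_graph()` builds the dyadic graph for a short window (e.g. 30 s):
an undirected edge joins a pair iff their minimum simultaneous distance
within the window is under the threshold, weighted by that minimum.
Minimum rather than mean is used because windows are chosen for minimal
movement, where the two nearly coincide, and the minimum is robust to a
single animal stepping away briefly.

# Sampling regimes and battery arithmetic

`apply_regime()` reproduces what a duty-cycled receiver would have
recorded, synchronised across animals and anchored at `t = 0` (phase
configurable): continuous 1-in-`dt` sampling, single samples every
`period`, or bursts of `on` seconds at `rate` Hz followed by `off`
seconds silent. Retention is half-open `[k·cycle, k·cycle + on)`; all
counts follow floor arithmetic (6 h of 1 Hz data thinned to 5 s spacing
for 7 animals is exactly 30,240 fixes).

`compare_regimes()` recomputes per-animal distinct-neighbour counts
under each regime and flags a regime × threshold combination *recovered*
when every animal's count equals the continuous reference — per-animal
count equality, the granularity at which such comparisons are usually
plotted; a stricter edge-set comparison is available through
`edge_pairs()`. A provable geometry fact anchors the burst results: any
contact bout lasting at least `off + 1/rate` seconds must intersect an
on-window, so such bouts are never lost (tested on randomised
placements). Bouts shorter than the off-window are caught only if they
happen to span an on-window, and single samples every 5 min miss most
60–90 s bouts entirely.

`duty_cycle_metrics()` assumes battery draw proportional to receiver-on
time: extension factor `cycle/on`, power saving `off/cycle` — factor 5
and 80 % for 60 s on / 240 s off, factor 10 and 90 % for 60 s on / 540 s
off. Receivers take up to a minute to reacquire after power-up; this is
exposed as an optional `warmup` overhead (default 0) added to the
effective on-time rather than baked into the defaults.

# Numerical choices and degenerate inputs

* Regime retention uses a ±1 µs tolerance on the float modulo, so
  fractional-second timestamps cannot drop grid fixes.
* Nearest-neighbour ties (two others at identical distance) resolve to
  the first animal in table order, deterministically.
* `error_histogram()` warns rather than fails on single-bin inputs;
  empty inputs, empty windows, non-positive bins and thresholds are
  rejected with errors.
* Timegroups with one member are skipped with a single warning;
  an animal absent from an interval is excluded from that interval's
  ranking with a warning.
* The seeded RNG stream makes `simulate_flock()` bit-reproducible;
  pipeline runs echo seed, parameters and input digests to a manifest.

# Problem sizes in the test suite

The suite validates at the deployment's own scale — 7 animals at 1 Hz —
with windows from 10 minutes to 6 h depending on what the property
needs. Leadership recovery uses 100 seeded replicates of a 4 h window
(24 intervals, propensity 0.7 vs 0.05): the planted leader takes the
strict maximum score in at least 95 of 100. Network recovery checks that
planted contact pairs are *exactly* the connected pairs under continuous
5 s sampling at 0.20 m and 0.30 m thresholds. At a threshold exactly
equal to the planted 0.15 m separation, detection is marginal by
construction — measurement noise of ~0.14 m per coordinate pair makes
each sample a near coin flip — so exact recovery is only asserted for
thresholds above the contact distance.

# Limitations

* GNSS error is modelled as i.i.d. truncated Gaussian; real RTK error is
  autocorrelated and degrades under blockage — fix-quality simulation is
  out of scope.
* Contacts are planted, not emergent; association indices (SRI/HWI),
  permutation tests and community detection are outside the package's
  scope.
* The leadership rule is an automated stand-in for a visual procedure;
  its thresholds are exposed precisely because the visual original
  cannot be recovered exactly.
* Reacquisition error after receiver power-up, accelerometer-triggered
  sampling and trigger-switched RTK modes are documented design options,
  not implemented features.
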