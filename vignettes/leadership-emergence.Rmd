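---
title: "Leadership emergence in evolved foraging groups: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leadership emergence in evolved foraging groups: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

swarmlead simulates a group of four wheeled robots that must forage
*collectively*: reward accrues only while the whole group stands in the
same food zone, so the task is as much a social coordination problem as a
navigation one. This vignette documents the model, every tunable parameter
and why it has its default, the numerical choices, what the scripted
fixtures do and do not emulate, and the sizes used in the scaled-down
study.

## The world

The arena is a square of side 110 cm bounded by walls, with two grey
circular food zones of diameter 22 cm on a white floor. The zone centers
default to (27.5, 55) and (82.5, 55): the geometry requires two fixed,
disjoint, identical zones, and the symmetric midline placement is the
natural realization when no coordinates are prescribed. Each robot is a
circle of diameter 5.5 cm driven by two wheels.

Kinematics use the exact unicycle arc: with wheel speeds $v_l, v_r$
(cm/step), linear velocity is $(v_l+v_r)/2$ and angular velocity
$(v_r-v_l)/d$ with $d$ the chassis diameter (also the wheel separation).
One step advances the pose along a circular arc in closed form, so pure
rotation and pure translation are exact and there is no Euler drift; the
test suite checks agreement with 10x-finer explicit integration to
$10^{-3}$ cm over 100 steps. A time step has no physical duration — all
speeds are in cm/step, and the cap `wheel_speed_max = 1.3` cm/step gives a
robot-diameter-per-4-steps scale typical of miniature-robot simulation.

Collisions are not physical: whenever a chassis overlaps a wall or another
robot, the robot is teleported by `collision_displacement` (default 5.5
cm, one body length — "nearby") in a uniformly random direction to the
first legal position found, with a fresh random heading. A robot wedged
between a corner and a neighbour can have an *empty* legal set at the
nominal displacement, so the displacement doubles after every 1000
rejected draws; this guarantees termination without changing behaviour in
the generic case.

Zone membership uses the robot-center-inside-disc convention (the ground
sensor sits at the chassis center): a robot is on a zone iff its center is
strictly within 11 cm of the zone center. Initial placement is uniform
over the arena with non-overlapping chassis; placement inside food zones
is allowed by default (`exclude_zones_at_init` turns it off).

## The perceptive system

* **Retina.** Five RGB photoreceptors cover bearings $[-45°, +45°]$
  relative to the heading in 18° sectors (half-open on the right, except
  the last). A robot at center distance $D$ subtends a closed angular
  extent of half-angle $\arcsin(r/D)$ about its bearing ($r$ = chassis
  radius); a photoreceptor fires when its sector overlaps the extent of at
  least one robot and reports the normalized RGB triple of the *nearest*
  such robot (occlusion). Activation is binary per sector — there is no
  intensity falloff, because distance information is carried by how many
  sectors a robot covers, not by brightness. Walls and food zones are
  invisible to the retina. Identity colours are green (0,255,0), blue
  (0,0,255), light-blue (0,255,255) and yellow (255,255,0), normalized by
  255.
* **Smell.** Three sensors cover the quadrants $[0°,90°)$, $[90°,270°)$
  and $[270°,360°)$ of bearing toward the *nearest* zone center and are
  reported on two binary lines as (0,1), (1,0), (1,1) respectively. The
  two-line encoding needs a mapping and a disambiguation rule that are not
  forced by the sensor description; nearest-zone targeting is the minimal
  choice, and exactly one code is active every step — (0,0) never occurs.
* **Ground.** 1.0 on a zone, 0.0 elsewhere, consistent with zone
  membership by construction.

Sensors are deterministic; no noise model is included.

## The controller and its genotype

A feed-forward network of 24 neurons: 18 inputs (15 retina components
ordered R0,G0,B0,…,R4,G4,B4, the two smell lines S0,S1, the ground value
G), 4 hidden and 2 output logistic units. Output $o \in (0,1)$ maps
symmetrically onto a wheel speed $(2o-1)\,v_{max}$, so an untuned output
of 0.5 is a stopped wheel. The logistic activation and the symmetric
output map are package choices — standard for this robot family — since
only the topology is prescribed by the task.

The genotype is 688 bits: 86 parameters (72 input–hidden weights row-major
by input, 4 hidden biases, 8 hidden–output weights row-major by hidden
unit, 2 output biases) of 8 bits each, bytes mapping linearly onto
$[-5, +5]$ ($w = -5 + 10b/255$). The ordering is frozen in the archive
manifest (`map_version 1`).

## The Heterogeneous Genetic Algorithm

Each robot colour has its own population of 20 genotypes; populations are
evaluated jointly but ranked and reproduced separately, which sustains
genetic (hence behavioural) differentiation between team members. Per
generation:

1. **Scheduling.** One independent uniform permutation of 1..20 per
   population; trial $t$ teams the $t$-th elements. This realizes the
   required no-repeated-quadruple property *and* gives every genotype
   exactly one evaluation — without which separate ranking would be
   undefined for unevaluated genotypes. A genotype's generation fitness is
   its single trial's score; there is no cross-trial averaging.
2. **Evaluation.** Each trial runs 3000 steps of sense → think → move →
   collide. Fitness modes: `collective` (default; +1 to everyone per step
   with the whole group in the same zone), `individual` (+1 per step a
   robot is on any zone) and `mixed` (sum), the latter two kept as the
   rejected alternative scenarios.
3. **Reproduction.** Sort by descending fitness, ties broken by lower
   index (a determinism choice); the top 4 each produce 1 bit-identical
   elite and 4 offspring mutated by independent per-bit flips at 2%. The
   per-bit reading of "2% mutation" is the standard GA interpretation;
   population size is conserved at 20.

All randomness descends from one master seed through named substreams
(`init`, `schedule`, `trial`, `mutation`, …), so replications are exactly
reproducible, resumable, and component-wise replayable. The compiled trial
loop uses its own xorshift128+ stream seeded per trial, making trials
bit-identical across platforms.

## The measure battery

* **Barycenter test.** Each robot in turn is pinned motionless at the
  arena center; the other three run free for 20 trials of 3000 steps, over
  each of the last 20 generations' best teams (top-ranked genotype per
  population — the "best team" needs an operational definition and this is
  it). At every step the Euclidean distance between the pinned robot and
  the group barycenter (arithmetic mean of all four positions, $n=4$; a
  switch computes the free-robots-only variant) is accumulated. The
  leader is the argmin of the resulting quadruple.
* **Leadership measure.** The population standard deviation (divisor $n$)
  of the quadruple. With only four values the sample/population
  distinction is material, so the choice is frozen: divisor 4.
* **Individual fitness.** Free runs; per-robot count of steps on any zone,
  averaged over 20 trials x last 20 generations. A virtual skill index,
  never used for selection.
* **Collective fitness indicator.** Mean of the per-generation best trial
  score over the final 20 generations.
* **Capability of followers.** The identified leader is pinned at the
  center (the "fixed position" needs a coordinate; the center is neutral)
  and each follower's first step within `reach_radius = 11` cm (two body
  lengths; the reach criterion is not prescribed) is recorded, censored at
  3000. Final-generation team, 20 trials.
* **Mobility / vision of leaders.** Free runs of the final-generation
  team: distinct 5.5 cm grid cells visited (a 20 x 20 grid; bounded by
  400) and steps with any active photoreceptor, averaged over 20 trials.
* **Removal test.** Re-runs the final team with a named robot deleted from
  the world (invisible to sensors; the same-zone condition applies to the
  three survivors) against an intact baseline.

## Temporal analysis

The barycenter and individual-fitness protocols are re-run at every 10th
generation (single-generation versions) to produce temporal curves; the
collective curve comes from the stored fitness series. Curves are smoothed
with Friedman's super-smoother (`stats::supsmu`, default spans and bass —
the smoother's settings are not prescribed, and the defaults'
cross-validated span selection is the method's point), then differentiated
by central finite differences (one-sided at the ends) with respect to the
actual generation axis; on the uniform 10-generation grid this is a
constant rescale of per-sample units and leaves all argmax locations
unchanged, which is all the downstream analysis consumes. The "does skill
precede leadership?" question is answered by comparing the argmax
generations of the smoothed derivatives of the leader's individual-fitness
curve and of its *negated* barycenter curve (the barycenter falls as
leadership consolidates; negation has the same argmax as any
orientation-reversing affine map and is the simplest). Ties count as
"no" — the ordering must be strict.

Across replications, Pearson correlations (two-sided t test) link the
leadership measure to the collective fitness indicator, follower
capability to leader mobility, and mobility to vision. Leadership styles
are classified by sorting the leaders' vision counts and cutting at the
two largest consecutive gaps — lowest group passive, middle weak-active,
highest strong-active. This is a declared heuristic standing in for visual
inspection of the sorted bar plot; it is scale-invariant, degenerate
inputs (all equal) are flagged rather than forced into three classes, and
manual thresholds can override it.

## Scripted fixtures: what they emulate and what they do not

`make_fixture()` builds teams of hand-written controllers that mimic the
behavioural archetypes evolved runs exhibit: a leader driving straight to
a zone with colour-following followers (`passive_leader_group`), the same
with periodic spins (`weak_active_group`), an orbiting leader
(`strong_active_group`), four random walkers (`leaderless_group`) and a
stationary target with followers (`follower_only`). They share the world,
collision and logging machinery with evolved teams, so every measure runs
on them against constructible ground truth (closed-form orbit geometry,
kinematic reach times, exact cell and exposure counts).

They are test instruments, not models of evolved behaviour: scripted
policies read privileged state (exact positions), do not use the retina or
the neural controller, and produce stereotyped trajectories. Passing
fixture tests validates the *measures*, not the evolutionary dynamics;
emergence itself is checked by running the GA.

## Scaled-down study sizes

The full study — 30 replications x 600 generations x 20 trials x 3000
steps — is hours of CPU. The package's automated study uses 5
replications x 300 generations with the measure battery at its full 20
trials x 20 generations averaging depth; one replication takes well under
a minute in the compiled loop.

Two empirical facts about the scaled-down regime, established by pilot
runs and worth knowing before interpreting results:

* **Bootstrap failure.** Selection can only act once some trial earns
  nonzero collective fitness. Most replications bootstrap within the
  first ~75 generations and reach last-20 mean group fitness of
  1000–2000 (of 3000) by generation 300; a minority (roughly 1 in 10)
  never fire within 300 generations and stay at zero — the evolutionary
  search drifts from a single elite lineage while all fitness is tied at
  zero. Longer runs rescue some of these, which is consistent with the
  full study needing 600 generations. The emergence check therefore asks
  for improvement in at least 4 of 5 replications rather than all 5.
* **Leader identity is already stable.** In emergent scaled-down
  replications the barycenter argmin and the individual-fitness argmax
  coincide, as in the full-scale study.

## Known limitations

* No inertia, friction or wheel slip; collisions are teleports, not
  contact dynamics.
* No sensor noise; transfer to physical robots is out of scope.
* The style classifier needs enough replications for the three-group gap
  structure to exist; with 5 replications its labels are indicative only,
  and the headline correlations are computed but underpowered below the
  full 30 replications.
* Crossover, recurrent controllers and inter-population migration are
  deliberately absent.
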