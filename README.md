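# swarmlead

Agent-based simulation of leadership emergence in a small group of foraging
robots, with the evolutionary machinery and the measurement battery needed
to study it quantitatively.

Four simulated Khepera-like robots (circular chassis, 5.5 cm, differential
drive, distinctively coloured green / blue / light-blue / yellow) live in a
110 x 110 cm walled arena containing two grey circular food zones (22 cm
diameter) on a white floor. Each robot perceives the world through:

* a **linear RGB retina** — five photoreceptors covering a 90° field of
  view in 18° sectors, reporting the colour of the nearest robot in each
  sector (no range limit, no absolute position information);
* three **quadrant smell sensors** — a 2-bit code saying which body
  quadrant currently faces the nearest food zone;
* a **ground sensor** — 1 on a food zone, 0 on the floor.

A feed-forward neural network (18 inputs → 4 hidden → 2 outputs, logistic
units) maps these 18 signals to the two wheel speeds. All 86 weights and
biases are encoded 8 bits each in a 688-bit genotype, bytes mapping
linearly onto [-5, +5].

Controllers evolve under a **Heterogeneous Genetic Algorithm (HGA)**: each
robot colour has its own population of 20 genotypes, evaluated in mixed
teams (one permutation-scheduled trial per genotype per generation, 20
trials of 3000 steps) but **ranked and reproduced separately** — the top 4
genotypes of each population each produce 1 elite copy and 4 offspring
mutated at 2% per bit. Selection rewards only *collective* foraging: every
robot scores +1 for each time step on which the whole group stands in the
same food zone.

The scientific question is who ends up leading the group, and how you can
tell. The package implements the full measure battery:

| measure | what it quantifies |
|---|---|
| barycenter test | mean distance between a robot pinned at the arena center and the group centroid; the argmin identifies the leader |
| leadership measure | population SD of the four barycenter values — the strength of the leader/follower asymmetry |
| individual fitness | per-robot zone-reaching skill (virtual, never used for selection) |
| collective fitness indicator | mean best group fitness over the last 20 generations |
| capability of followers | steps followers need to reach a pinned leader |
| mobility of leaders | distinct 5.5 cm grid cells the leader visits per trial |
| vision of leaders | steps with at least one active retina photoreceptor |
| removal test | group fitness after deleting a follower or the leader |

plus temporal curve analysis (10-generation sampling, Friedman
super-smoothing via `stats::supsmu`, finite-difference derivatives, event
ordering between skill growth and leadership onset), Pearson correlations
across replications, and a largest-gap classifier that sorts leaders into
passive / weak-active / strong-active styles from their vision counts.

## Worked example

```r
library(swarmlead)
cfg <- arena_config()            # 110 cm arena, 2 zones, 3000-step trials

# evolve one replication (scaled down to 150 generations for the example)
rep1 <- run_replication(cfg, generations = 150, seed = 1)
rep1
#> <replication_result> seed 1, 150 generations
#>   best group fitness: final 749, last-20 mean 1304.8 (max possible 3000)

# who is the leader, and is it the most skilled robot?
ms <- measure_suite(rep1, cfg, seed = 101)
ms
#> <measure_suite_result>
#>   barycenter quadruple (cm): green=15.77, blue=16.59, light_blue=13.45, yellow=8.32
#>   leader: yellow   leadership measure: 3.221 cm
#>   individual fitness (steps): green=1828.4, blue=2191.1, light_blue=2201.5, yellow=2838.9
#>   collective fitness indicator: 1304.8
#>   ...
```

The yellow robot both hugs the group barycenter most closely when pinned
(8.3 cm vs 13–17 cm for the others) and reaches the food zones most often
on its own (2839 of 3000 steps) — the leader is the most skilled robot.

Scripted-controller fixtures (`make_fixture("passive_leader_group")`,
`"strong_active_group"`, `"leaderless_group"`, ...) generate trajectories
with known ground truth so every measure can be exercised without running
evolution.

A thin command-line front end is installed with the package
(`system.file("scripts", "swarmlead", package = "swarmlead")`) with
subcommands `evolve`, `measure`, `temporal`, `perturb`, `fixtures` and
`report`, all operating on plain-text run directories.

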