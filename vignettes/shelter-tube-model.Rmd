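---
title: "A stigmergic lattice model of termite shelter-tube construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stigmergic lattice model of termite shelter-tube construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheltertube)
```

## The system

Subterranean termites such as *Reticulitermes* connect the pieces of their
multiple-piece nests with covered galleries — shelter tubes — built from
wood, soil and excreta. Groups of workers taken from different colonies
and placed in identical arenas build strikingly different structures:
some cover the floor with a flat mat, some build many short tubes, some a
few long ones, and tubes preferentially run along the container wall
("edging" tubes). `sheltertube` implements a two-dimensional lattice
model in which this whole range of phenotypes emerges from one building
algorithm by varying only two group-level parameters:

* `alpha` — the fraction of workers actively engaged in construction, and
* `x` — the workers' sensitivity to the cement pheromone, which sets the
  strength of the positive feedback.

## The model

The arena is a 220 x 140 grid of 1 mm cells, the floor of the
experimental container. A circular nest disc of 1020 cells (the sawdust
block, nominal radius 18) sits at the centre of one long side, tangent to
the wall — the block both seeds construction and supplies unlimited
material. Each time step, `round(alpha * N)` active workers in turn pick
a work site: any vacant cell 4-adjacent to the structure (nest or built
cells). The probability of picking cell $i$ is

$$P_i = \frac{A_i}{\sum_{j \in S} A_j}, \qquad
  A_i = v_i \, \max(0,\; c_i + k_i - b\,d_i)^{x},$$

with the following ingredients.

* **Cement pheromone** $c_i$. Freshly attached material carries an
  attractive cement pheromone: each deposit adds $q = 0.3$ to the
  lattice, and at the end of every time step the field is multiplied by
  $1 - r$ with $r = 0.7$. A vacant candidate reads the largest value
  among its constructed 8-neighbours; a site that already holds fresh
  material reads its own value.
* **Edge preference** $k_i$. Cells within the border band (5 cells wide
  for 400-worker runs, 4 for 50-worker runs, the measured widths of
  edging tubes) have $k = 2$, all others $k = 1$: an edging tube needs
  roughly half the material of a free-standing one.
* **Distance discount** $b\,d_i$. $d_i$ is the shortest route from the
  nest through the structure (4-connected breadth-first distance; a cell
  touching the nest has $d = 0$), and $b = 1/360$ is scaled so that the
  discount cancels the edge preference once the entire container edge is
  constructed.
* **Direction memory** $v_i$. Tubes grow away from the nest. Every built
  cell records the beginning point of its construction: its own centre if
  it touches the nest or the container border, otherwise the beginning
  point inherited from its built neighbours (the centre of the distinct
  beginning points when two construction fronts merge). For a candidate
  reached via built neighbour $z$, $\theta$ is the angle between the
  vector from $z$'s beginning point to $z$ and the vector from $z$ to the
  candidate, and the contribution is $(1 + \cos\theta)/2$ — 1 straight
  ahead, 0 straight back, 1/2 sideways. Contributions from several built
  neighbours add; a candidate touching the nest gets a contribution of 1
  (founding has no direction). A step that leaves the edge band from
  inside it instead contributes the empirical constant 0.0007274: edging
  tubes rarely turn into the open floor.

Negative attraction bases (possible far from the nest) are clamped to
zero; if every candidate has zero attraction the choice falls back to
uniform, so a run cannot deadlock on a degenerate field state.

### Work sites and crowdedness

Two rules govern how much work one spot can absorb within a time step.

First, a lattice filled earlier in the current step remains a work site
for the remaining agents of that step: a worker drawn to it attaches
material on top, adding another $q$ of pheromone and of crowdedness.
This is the package's reading of how cement pheromone can accumulate
beyond a single deposit, and it is what arms the crowdedness rule: since
every lattice is *filled* exactly once, a model in which each lattice can
only ever receive one deposit keeps all crowdedness values in $\{0,
q\}$, and the exclusion threshold of $0.9 = 3q$ could never be reached —
the rule would be dead code. With repeated same-step visits, three
choices of one site raise it to exactly $3q = 0.9$.

Second, the crowdedness field implements the physical constraint that
many workers cannot pass through the same tube simultaneously. Each
choice deposits `crowd_increment` (default $q$) of crowdedness on the
chosen lattice. A vacant candidate whose constructed 8-neighbours have a
mean crowdedness of at least 0.9, or a worked site whose own crowdedness
has reached 0.9, is excluded from the choice set for the rest of the
step; at the step's end the field is reset, as workers return to the
nest to restock. At high `alpha` this is the dispersing force: many
agents saturate the attractive sites early in the step and the remainder
must build elsewhere, which is why large active fractions blur the tube
phenotype.

### Collisions

When two different shelter tubes meet, construction at the junction
stops. Two adjacent built cells are classified as belonging to different
tubes when their route distances differ by at least 10 (a genuine
junction of one tube with itself produces distance steps of 1); a
freshly built cell with such an 8-neighbour is a contact cell. When the
8-connected cluster of contact cells reaches 8, an 8 x 8 window centred
on the last-built cell is permanently removed from all future candidate
sets. Distances are compared before the shortcut created by the merge is
propagated through the distance field, so the pre-merge tube identities
are what is compared.

### Stopping

A run ends when 5700 lattices are filled for 400-worker groups and 1350
for 50-worker groups — the mean areas built in 30-day experiments. The
grid is recorded every 1000 constructed cells and at the final state.
An implementation also needs a stall policy, which the biology does not:
an agent that finds no admissible site skips its turn, and a run aborts
with status `"stalled"` after 100 consecutive step-wide stalls.

## What the parameters do

```{r, eval = FALSE}
p <- sim_params(group_size = 400, alpha = 0.05, x = 3)
tr <- sim_run(p, seed = 1)
tr
```

At `x = 3` and small `alpha`, the within-step accumulation makes fresh
sites self-reinforcing: $(c + 1)^3$ grows fast enough in $c$ that a site
visited twice is visited again, construction localizes into fingers, and
once a finger reaches the border band the doubled preference (cubed,
an eight-fold ratio) channels it into long edging tubes running along
the wall. At `x = 1` the same fluctuations decay and growth stays
near-circular — a mat spreading from the block. The nest's position
against the wall matters: it puts the band within reach of every
phenotype, and the along-edge perimeter is what separates them, matching
the empirical observation that colony differences in perimeter are
driven by the along-edge component. At `alpha = 0.25` a hundred workers
build per step, crowdedness shuts attractive sites down within the step,
and even sensitive groups spread — tube patterns need few, sensitive
workers.

## Morphometry

Patterns — simulated grids (nest plus built cells count as structure) or
photographed arenas — are quantified exactly as binary lattices at 1 px
= 1 mm: `binarize()` thresholds a grayscale image (Otsu by default),
`clean_pattern()` removes white 8-connected objects under 50 px (loose
sawdust, faeces, stray workers) and fills interior 4-connected holes
under 10 px, and `measure_pattern()` reports the area (white pixel
count) and the perimeter as the exact count of unit edges between white
and black-or-border, split into an along-edge part (edges owned by white
pixels within 3 px of the border) and the remainder. The unit-edge count
was chosen over smoothed estimators because it is bit-exact and
identical for simulation grids and rasterized photographs; boundaries of
holes that survive cleaning are included. On this metric, for fixed
area, the quasi-square is the most compact shape and a one-pixel snake
the least — the fixture generator provides both as calibration shapes.

## Statistics

Groups whose survival rate is at or below 0.5 are excluded before any
comparison (dead workers are buried in building material, which distorts
construction), and each structural measure (area; total, along-edge and
away-from-edge perimeter) is compared across colonies with a classical
fixed-effects one-way ANOVA per group size — no Welch correction and no
multiple-testing adjustment, mirroring the empirical analysis. The
empirical record workbook (`150623_data.xlsx`) is not redistributed;
`read_group_workbook()` ingests a local copy defensively (column names
are matched case-insensitively against common spellings) and
`group_table_fixture()` generates synthetic record tables with planted
effect sizes for calibration, which is how the type-I error and power of
the pipeline are tested.

## Numerical and design choices

* **Nest discretization.** A nominal radius of 18 and an area of 1020
  cells are not simultaneously achievable by any centre-in-disc
  rasterization; the nest is therefore the 1020 cells nearest the nest
  centre (ties broken by angle, then index), making the printed area
  exact and the construction deterministic.
* **Connectivity.** Structural adjacency (candidacy, route distance) is
  4-connected — tubes grow cell by cell across faces; field lookups
  (pheromone max, crowdedness mean, collision contact) are 8-connected —
  diagonal contact is physical contact.
* **Evaporation.** "Reduced at a rate r" is read as multiplication by
  `1 - r`: the rate is the fraction lost. The phenotype contrast is
  robust to the alternative reading (multiplication by `r`), which was
  checked explicitly during development.
* **Rounding.** The active-agent count rounds half-up with a floor of
  one (alpha times 50 is fractional at alpha = 0.05, 0.15, 0.25).
* **Sweep seeds.** `sim_sweep()` derives each run's seed from the base
  seed and the grid position with fixed strides, so any single run can
  be reproduced in isolation from its recorded seed.
* **Blocking window.** The 8 x 8 collision window is centred on the
  last-built cell (offsets -4..+3 in both axes, an unavoidable half-cell
  convention for an even window) and is permanent.

## Scale of the bundled checks

The test suite exercises full-scale runs (5700 and 1350 cells) for the
termination contract, and the phenotype comparison on a reduced design —
400 workers, 2000 constructed cells, 30 replicates per corner of
{alpha = 0.05, 0.25} x {x = 1, 3} — where the tube-versus-mat orderings
are already unambiguous (complete rank separation in the package's own
runs). Smaller arenas (for example 30 x 24 with a 13-cell nest) back the
unit tests of the choice rule, with exhaustive-scan, hand-arithmetic and
graph-library oracles.

## What the synthetic fixtures do and do not show

`pattern_fixture()` draws lattice-native mats, radial and edging tube
patterns, calibration squares, discs and snakes, without anti-aliasing,
so morphometry checks against analytic ground truth are exact. They
emulate the *geometry* of real arena photographs, not their radiometry:
real images add uneven lighting, colour casts and debris fields that the
programmatic Otsu threshold plus size-based cleaning handles only
approximately. Passing fixtures therefore validates the measurement
chain, not photograph acquisition. Likewise `group_table_fixture()`
draws normal within-colony noise; heavy-tailed or variance-heterogeneous
real measurements would call for the diagnostics a plain one-way ANOVA
does not provide.

## Known limitations

The model is strictly two-dimensional: piling of material (and hence
tube height), digging inside the sawdust block, and burial of corpses
are outside its scope. Pheromone does not diffuse; it acts only through
lattice adjacency. Agents are not spatially tracked between choices —
crowdedness along the worker's route is summarized by the per-site rule.
And the within-step work-site semantics, while forced by the printed
constants (the 0.9 threshold equals exactly three deposits of 0.3), is
an interpretive commitment: alternative readings in which each lattice
receives exactly one deposit make the crowdedness rule unreachable and
produce no sensitivity-driven phenotype contrast.
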