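---
title: "Model, calibration and state-space analysis in feedcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, calibration and state-space analysis in feedcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedcircuit)
```

## The model

feedcircuit implements an algebraic fixed-point model of the hypothalamic
control of food intake.  Twelve units, each standing for all neurons of one
anatomically and neurochemically defined subtype, form a feedforward
network: eight hypothalamic units (AgRP, POMC and NGABA in the arcuate
nucleus; OXT in the paraventricular hypothalamus; MCH, OX, LHGal and NT in
the lateral hypothalamus) project onto a four-unit output stage (the
catecholaminergic and GLP-1 NTS populations, VTA and NAc) that determines a
scalar food-intake level, FI.  Five substances drive the network: leptin,
ghrelin, CCK, serotonin (5HT) and glucose, all at level 1.0 in the normal
state (the unit scale is arbitrary; only changes relative to baseline ever
matter, so substance magnitudes are absorbed by the optimized weights).
Five drugs can be administered on top: risperidone, a 5HT2C agonist, a 5HT1B
agonist, exogenous alpha-MSH and exogenous GLP-1.

A unit's net input is the sum over its receptors of
sign x strength x (summed cognate ligand levels), plus an intrinsic bias;
its response is the net input plus any somatic stimulation, bounded at zero
(firing rates cannot be negative) and multiplied by a 0/1 lesion flag.  The
amount of each transmitter a unit releases equals its response.  Three
receptor modulations go beyond plain weighted sums:

* risperidone reduces the 5HT2C receptor strength on POMC by half the drug
  level, clamped at zero (the clamped, imperative form of the published
  update rule is adopted; the declarative rendition omits the clamp);
* the AgRP peptide is an inverse agonist at the melanocortin receptors on
  OXT: its delivered level is subtracted from the alpha-MSH ligand sum
  before weighting;
* the CCK receptor on the catecholaminergic NTS unit is gated: the CCK term
  enters the net input only while the sensitizing modulator sum
  (+leptin, -ghrelin, -orexin, +oxytocin, each weighted) is positive and
  both the CCK level and the receptor strength are positive.  This gate is
  the main source of switch-like behavior in the output stage.

The optimizable parameters are the 38 receptor strengths and 13 unit biases
(51 in all).  Signs live in the wiring, not the parameters, so strengths
are constrained nonnegative; strengths are bounded in [0, 5] and biases in
[-5, 5] during calibration.

Two open wiring details were resolved while keeping the 51-parameter
checksum: FI keeps an intrinsic bias (without one the food-intake element,
whose remaining inputs are inhibitory, would be identically zero, which
contradicts a medium baseline), and the catecholaminergic NTS unit reaches
FI only through its GLP-1 neighbor rather than through an additional direct
weight.  The melanocortin drive on OXT is carried by a single calibrated
strength (MCR): MC3R and MC4R share one variable in the published
parameterization's own nomenclature, they bind the same ligand sum with the
same inverse-agonist subtraction, and the two melanocortin-knockout
experiments have identical observed outcomes.

## Update semantics and the state space

The model has two update tiers.  Hypothalamic units update by *optional*
rules: an update is applicable whenever it would change the unit's stored
net input by more than the tolerance (1e-9), and an applicable update may or
may not fire.  Output-stage units and FI update by *forced* equations: after
every rule firing the output stage is recomputed immediately, in its fixed
feedforward order.  A state of the transition system is therefore one full
assignment of hypothalamic net inputs and responses (the output stage is a
function of them), and branching arises only from the order in which
hypothalamic units update.  Non-terminal states are interpreted as response
configurations in which neurons outside the modeled network hold some
subtype away from its equation-determined response.

All units start silent (net and response 0): a not-yet-updated unit
contributes nothing, which is what lets searches find configurations with,
for example, AgRP exactly 0.  `enumerate_states()` explores the tree
breadth-first, deduplicating states at tolerance 1e-9 on the rounded
hypothalamic nets and responses; configuration counts are counts of distinct
states.  The unique terminal state reached from the normal initial state
defines the baseline responses used by every relative criterion.  Because
the network is feedforward, the terminal state is the same along every
branch (confluence), and it must agree bit-for-bit at tolerance with the
imperative fixed point of `run_to_fixed_point()`, which sweeps all units
until no net input changes.  Both facts are asserted in the test suite, and
the toy-network oracle (`brute_force_enumerate()`, exhaustive recursion over
firing orders followed by set-collapse) checks the enumerator on hundreds of
small random feedforward networks.

Searches (`search_states()`) follow the one-or-more-rewrites convention:
the elaborated initial state is excluded.  Invariant checking
(`check_invariant()`) quantifies over every enumerated state including the
initial one, and reports the counterexample with the lexicographically
smallest state key so that a failing invariant always produces the same
witness.

## The truth table and the 30 percent criterion

Calibration targets a corpus of 32 published feeding experiments: receptor
and cell-type knockouts, opto- and chemogenetic stimulation and inhibition
of somata and of individual projections, and administration of hormones,
agonists and nutrients, each with its observed categorical effect on food
intake and, for the administration experiments, on POMC/AgRP/OXT activity
(39 scored observations in all; excitation/inhibition of a unit is treated
as increase/decrease of its response).  The encoding of each experiment is
listed in `inst/extdata/truth_table.csv` in a small manipulation grammar
documented in `?parse_manipulations`; the package-level choices are:

* receptor knockouts zero the receptor strength on every unit expressing it,
  cell-specific deletions only on the named units;
* "GABAergic neurons" means the GABAergic leptin-receptor-expressing units
  AgRP, NGABA, LHGal and NT;
* soma photo-/chemo-stimulation adds a configurable magnitude (default 5
  model units) to the unit's net input; chemo-inhibition and knockouts of a
  whole subtype clear its live flag;
* projection stimulation forces all transmitters delivered from the source
  to the named target to the stimulation level without engaging the soma's
  other projections; projection inhibition forces them to zero;
* administered substances double the endogenous level (leptin, ghrelin,
  glucose: 2.0); administered drugs set level 1.0 on a normal level of 0.

A simulated outcome counts as increased only when it exceeds 1.3 x its
baseline and decreased only below 0.7 x baseline (strict inequalities,
absolute comparison: a zero baseline makes any positive value an increase
and 0 vs 0 no change).  The truth-table error is the number of mismatched
observations, an integer in [0, 39]; rows with several scored observations
weigh proportionally more.

## Calibration

`calibrate()` minimizes the truth-table error with a real-coded
evolutionary search under seeded determinism.  The published protocol
(population 1000, 5100 generations, 1000 restarts on a cluster) is
configurable but not the default; the desk-scale default is population 200,
up to 2000 generations and up to 20 restarts, stopping at the first
zero-error vector.

Selection works on an annealed criterion: during the first part of a run
the change band used by selection is narrow (5 percent) and widens
gradually to the published 30 percent.  Early on, a narrow band rewards
networks in which every observation moves in the right *direction* - these
are the basins that remain feasible once the full threshold bites - while
degenerate networks that satisfy the loose criterion by collapsing the
food-intake range onto a two-point scale lose their advantage.  The
reported error is always computed at 30 percent.

The integer error surface is a staircase, so selection uses a shaped key:
the mismatch count plus a bounded term below 1 that (a) measures how far
each mismatched observation sits from its 30-percent boundary, (b) nudges
satisfied observations away from sitting exactly on a boundary, and (c)
penalizes baselines in which units are silent.  The ordering by mismatch
count is preserved exactly, and the term never turns a worse count into a
better key.  The liveliness term reflects a biological prior - every
modeled subtype is tonically active in the normal state - and, numerically,
keeps the search out of degenerate basins where half the network is floored
at zero and the error surface is locally flat.

Three operators generate offspring:

* self-adapted difference-vector crossover (each individual carries its own
  scale factor and crossover rate, resampled with probability 0.1);
* baseline-neutral pair moves: a receptor strength and its owner's bias move
  together, the bias compensating sign x (baseline ligand sum) x step, so
  that every baseline response is exactly unchanged.  These moves explore
  off-baseline behavior - which is where most truth-table constraints
  live - without disturbing already-satisfied baseline-relative
  classifications.  They exploit only network structure, not the content of
  the truth table;
* stall-triggered block re-randomization: after `stall_gens` generations
  without improvement, the worst quarter of the population is replaced by
  copies of the best genome with one or two whole unit parameter blocks
  redrawn uniformly, a large-neighborhood restart that allows basin-scale
  jumps.

Replacement is greedy one-to-one (an offspring replaces its parent when its
key is no worse), so the best key never worsens and runs are reproducible
from the seed alone.  The zero-error landscape of this model is a thin,
strongly coupled manifold - the experiments stimulating the AgRP-to-PVH
projection while blocking single PVH receptors pin several receptor sums
into narrow corridors - which is why structure-aware moves matter and why,
as in the original cluster-scale calibration where most runs failed, not
every desk-scale restart reaches zero error.

Every distinct zero-error genome encountered is archived;
`select_representatives()` orders the archive by Euclidean distance from
the zero vector and extracts the Near, Middle, Far and element-wise Average
vectors (the Average's error is re-evaluated, not assumed), and
`parameter_correlations()` reports the pairwise Pearson correlations across
the archive with entries at p >= 0.01 masked to zero (no multiple-testing
correction, by design).  The packaged archive in
`inst/extdata/archive_ga.csv` was produced with this GA during development
so that analyses and tests can run without re-calibrating; the original
study's own 42-vector archive is not published, so no cross-archive
comparison is possible.

## Reporting conventions

Because only response patterns matter, analyses express every unit's
response as a percentage of its maximum over the reachable set of the
parameterization under study (zero-maximum columns are reported as zero and
flagged).  Food intake is classed low (0-43), medium (44-80) or high
(81-100) percent of its maximum, with the integer break points extended to
the reals as low <= 43 and high >= 81.  In the invariant suites, "high" for
a unit means more than 30 percent above its baseline, "> 20%" means above
20 percent of the unit's maximum, and "fully active" (the LH-GABAergic
context) means the unit has updated - its rule is not pending - and its
equation-determined response is positive.

## Numerical choices

* change tolerance and state-key rounding: 1e-9;
* fixed-point sweeps are bounded by n_units + 1; exceeding the bound is
  reported as a violation of feedforwardness rather than silently iterated;
* enumeration carries a 1e6-state safety cap;
* GA bounds [0, 5] / [-5, 5]; distance ordering of archives uses raw
  (unnormalized) vectors - normalization to [0, 1] is a display option
  elsewhere, not part of the ordering;
* selection ties resolve in favor of the offspring, and all randomness
  flows from a single integer seed, so calibration is reproducible without
  a lexicographic tie-break.

## What the toys establish (and what they cannot)

The synthetic fixtures are 2-4 unit feedforward chains and random acyclic
networks with seeded weights in [0, 2] and biases in [-1, 1], all
rule-units.  They make the enumeration semantics fully checkable against
exhaustive recursion: completeness of the deduplicated reachable set,
first-reached layers, terminal sets, confluence and agreement with the
imperative fixed point.  They deliberately emulate only the semantics, not
the biology: no toy has an output stage, a receptor gate or a truth table,
so a green toy suite says nothing about calibration quality - that is what
the acceptance checks on the canonical network are for.

## Known limitations

* The wiring is a reconstruction from the published circuit description;
  the original supplementary parameter table is unavailable, so printed
  configuration counts that depend on the exact published parameter vectors
  (6 / 36 / 48 for the two paradox analyses) cannot be compared directly.
  The same searches are implemented and run under self-calibrated vectors.
* Desk-scale calibration finds zero-error vectors far less often per run
  than the fraction reported at cluster scale; restarts and the packaged
  archive compensate.
* No continuous-time dynamics, learning, dose-response curves, or VMH unit;
  the model is an algebraic fixed-point network by construction.
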