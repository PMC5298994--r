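---
title: "Methods: descriptor selection, pore profiling and assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor selection, pore profiling and assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreperm)
```

This vignette documents the models behind `poreperm`, the parameters that
matter, the design choices made where the underlying protocol left them
open, and what the synthetic-data tests do and do not establish.

## The classification problem

The data are small by design: a panel of 16 fluorescent tracers assayed
for uptake through Cx39 hemichannels (10 permeant, 6 non-permeant), and a
printed table of 11 molecular descriptors for the 9 molecules whose values
were published (6 permeant, 3 non-permeant). Neither molecular weight nor
net charge predicts permeability on this panel, which motivates searching
a large descriptor space for subsets that do.

**Filtering.** Descriptor software leaves holes: a descriptor that could
not be computed for more than one molecule, or that is 0 for all but one
molecule, carries no class information and is dropped
(`filter_noninformative()`). A descriptor missing for exactly one molecule
is kept — the filter rule only drops heavier damage — and the single hole
is imputed with the column mean so that distances are defined everywhere.
"Equal to 0" is exact equality on parsed values, matching how descriptor
programs emit hard zeros; no tolerance is applied.

**Standardization.** Descriptor scales in the packaged table span roughly
0.5 (RotBtFrac) to 1,800 (TDB10i). A Euclidean metric on raw values is
dominated by the large-magnitude columns, so `standardize()` (z-score,
n−1 denominator) is applied by default before any distance computation;
`run_ga(..., scale = FALSE)` reproduces the raw-value reading. Statistics
are computed once on the full matrix rather than per leave-one-out fold:
with n = 9 the fold-wise alternative changes each fold's scaling by one
observation, and the leaked quantity (a column mean/sd) is weak, but users
who care can standardize fold-wise outside and pass `scale = FALSE`.

**KNN under leave-one-out.** Each molecule is predicted from the other
n − 1 by majority vote among its k nearest neighbors, restricted to the
selected descriptors. The original description fixes neither k nor tie
policies, so the package declares them: k defaults to 1 (the smallest k
consistent with "KNN"; with n = 9–16, large k degenerates toward the
majority class), distance ties resolve to the lower molecule index
(stable matrix order), and vote ties resolve to `non_permeant` — the
conservative call for a permeability claim. The fitness of a subset is
the LOO correct count `n_correct`; the empty subset scores 0 by
convention.

## The genetic algorithm

Genomes are binary vectors, one bit per descriptor. The published
hyperparameters are kept as defaults: population 5,000; the 1,000 best
pass unaltered (elitism); the other 4,000 are children of uniformly drawn
elite pairs, combined by single-point crossover at a uniform random cut
and then point-mutated at 10⁻³ per bit. The initial population is the
all-ones genome, every singleton, and random genomes at density 0.5.

Choices the protocol left open, declared here:

* **Elite ranking ties** break by subset cardinality ascending
  (parsimony), then lexicographic bit order. The parsimony pressure is a
  package decision; it makes runs deterministic and drives the search
  toward small subsets once fitness saturates.
* **Parent sampling** is uniform with replacement over the elite;
  self-pairing is allowed (it yields clones that mutation then perturbs).
* **Termination** is unstated in the original description; the package
  stops at `max_generations` (default 200) or once the best subset is
  perfect (fitness = n) and unchanged for `stall_generations` (default
  20) consecutive generations.
* **Duplicates** are allowed after crossover; enforcing global uniqueness
  is ill-defined under elitism and is not attempted.
* **Fitness caching** keys on the genome bits: populations of thousands
  over ≤ 16 molecules re-evaluate many duplicates, and LOO-KNN fitness is
  a pure function of the genome.

Elitism guarantees the per-generation best fitness is non-decreasing;
the test suite asserts this on every run it makes. On the packaged table
the GA reaches 9/9 immediately — the initial singletons already contain
perfect classifiers such as TDB6e — so the interesting behavior is on
planted synthetic data (below).

## Class-range separation

`separation_report()` calls a descriptor separating when the permeant and
non-permeant value ranges are disjoint, and records which class sits
higher. On the packaged table, 8 descriptors separate with permeant
higher and 2 (RotBtFrac, VP-6) with permeant lower. ATSC5s is the odd one
out: although described as higher for permeant molecules, its printed
values put the entire permeant range (down to Evans blue at −311.14)
*below* the non-permeant range. The package reports what the numbers say
— disjoint ranges, permeant lower — and treats "ATSC5s follows the
permeant-higher trend" as false. ATSC5s is a centered autocorrelation
descriptor, so single extreme molecules can swing it by orders of
magnitude; range disjointness is a fragile notion for it at n = 9.

## Pore-radius profiling

The profile is computed on a fixed, straight axis: at each axial sample
p(z), the radius is the distance to the nearest van der Waals sphere
surface, `min_i(‖p(z) − x_i‖ − vdw_i)`, clamped to [0, cap]. Parameters
follow the published protocol: axis length 120 Å for hemichannels and
200 Å for gap junction channels, grid step 0.5 Å, scanning-radius cap
16 Å (samples with no atom within reach report the cap). The default axis
is the deposited Z axis through the alpha-carbon centroid, with the
extent centered on the atom z-range; crystal hemichannel structures are
deposited with the pore along Z. Hydrogens (absent from crystal
structures) are ignored; radii come from the Bondi table, overridable via
a named radii vector.

This "largest inscribed axis-centered sphere" definition is deterministic
and closed-form, which makes it testable to 1e−9 Å against analytic ring
geometries. It is not identical to slab-based free-volume accounting used
by cavity-detection plugins: where the pore wall is rough or the true
widest sphere sits off-axis, the two can differ by fractions of an
Ångström. The published structure benchmarks (4.5 Å constriction at the
N-terminal helix, ~14 Å maximum at the extracellular para-helix side of
the hCx26 hemichannel) are therefore treated as benchmark targets. The
packaged checks are fully self-contained — no structure downloads — and
exercise the same pipeline on a synthetic hemichannel-like ring stack
built to those dimensions; one subtlety is that for a stacked wall the inscribed radius
at the widest point is bounded by *neighboring* rings too, so the
generator keeps the wall clear of the full 14 Å inscribed sphere rather
than only dilating the apex ring.

## Assay quantification

**Junctional conductance.** `g_j = −I_b/(V_a − V_b)` with I_b in pA and
voltages in mV gives nS directly. The −60 mV holding potential of the
non-stepped cell is the protocol default. Zero transjunctional current at
every step — the Cx39 pairing result — maps to g_j = 0 identically.

**Event idealization.** `detect_events()` estimates closed and open
current levels by a deterministic two-level Lloyd split seeded at the 1%
and 99% quantiles, takes the closed level as the one nearer 0 pA
(leak-subtracted convention), thresholds at the half-amplitude point
(fraction configurable), and merges dwells shorter than `min_dwell_ms`
(default 2 ms, shortest first) into their neighbors. Amplitude is the
mean open-segment current minus baseline; transition times are 10–90%
crossings by linear interpolation, so an instantaneous sampled step reads
as ≤ 1 sample interval. A trace with a single current level is all-open
when that level is significantly nonzero and eventless otherwise — this
is what reconciles "a flat baseline trace has no events" with "a
always-open trace has P_o = 1". Half-amplitude thresholding was chosen
over HMM idealization for determinism and testability; at the
signal-to-noise of the simulated regime (≈4.5 pA openings, 0.5 pA noise)
the two agree.

**Conductance and open probability.** Per-event conductance is
`amplitude/(V − V_rev) × 1000` pS with V_rev = 0 by default (the observed
zero-current potential). The modal conductance is the center of the
highest histogram bin; bins are 5 pS wide and centered on multiples of
5 pS, mirroring the reporting granularity of the original "75 ± 5 pS".
P_o is total open time over total trace time.

**Dye uptake.** Per-phase slopes are ordinary least squares on all
in-phase samples with no outlier rejection (none is described in the
protocol); the report includes each phase's fold change against the
first phase and, with ≥ 3 phases, the percent block of the last phase
relative to the one before it (the control → trigger → blocker layout).

**Calcium signal.** The Fura-2 ratio F340/F380 elementwise, with a hard
error on non-positive F380.

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of their parameters and a seed.

* `gen_descriptor_dataset()` plants informative columns at
  Normal(±effect/2, 1) per class among Normal(0, 1) noise columns —
  the structure of the descriptor table (few separating columns among
  many) without its correlation structure. Real descriptors are heavily
  mutually correlated and non-Gaussian; recovery results on planted data
  therefore show the GA's search works, not that 11 selected descriptors
  on 9 real molecules generalize.
* `gen_channel_trace()` is a two-state Markov chain: the user gives P_o
  and the mean open dwell (default 100 ms, in the range implied by
  ~20 ms transition kinetics and second-scale openings), and the mean
  closed dwell follows as `open·(1 − P_o)/P_o`, avoiding an
  over-determined specification. No bleaching, capacitive transients,
  subconductance states or multi-channel superposition are modeled.
* `gen_uptake_trace()` is piecewise-linear mean fluorescence, continuous
  at phase breakpoints, sampled every 0.5 min (the 30 s imaging
  cadence), plus Gaussian noise.
* `gen_pore_geometry()` places pseudo-atoms on rings; at a ring plane the
  inscribed radius is exactly `ring_radius − vdw`, giving the profiler an
  analytic oracle with no discretization error radially. Written PDB
  files use carbon records; exact per-atom radii live on the in-memory
  atom set, since the PDB format cannot carry them.

## Problem sizes used in the packaged checks

The test suite and the acceptance script run the GA at population 500
(elite 100, offspring 400) on the 9 × 11 table and on planted datasets of
20 molecules × 500 descriptors (5 informative, 3-sd effect, 5 seeds), and
channel-recovery simulations of 40 s at 5 kHz over g ∈ [60, 90] pS and
P_o ∈ {0.3, 0.9} with 0.5 pA noise. These sizes were chosen as the
smallest at which every behavior of interest — convergence of the search,
planted-descriptor recovery, and parameter recovery at realistic
signal-to-noise — is clearly expressed, while the published
hyperparameters (5,000/1,000/4,000) remain the package defaults.

## Known limitations

* With n = 9 labelled molecules, LOO-KNN fitness saturates at 9 for many
  subsets; which perfect subset the GA reports is decided by the declared
  parsimony tie-break, not by the data.
* The fixed-axis profiler understates the pore radius wherever the true
  widest inscribed sphere sits off the chosen axis, and the default axis
  assumes the deposited Z orientation.
* The event detector assumes a single unitary amplitude per trace; traces
  with multiple conductance classes will idealize to the dominant one.
* `uptake_rate()` fits each phase independently; it does not model the
  continuity of the underlying fluorescence at phase boundaries.
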