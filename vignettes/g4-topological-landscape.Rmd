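---
title: "Methods: the G-quadruplex topological landscape in g4topo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the G-quadruplex topological landscape in g4topo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4topo)
```

## The model

A unimolecular G-quadruplex (G4) core is four G-tracts standing on the
corners of a square, joined by three loops. Each loop is one of five
types: a propeller loop (`+p`/`-p`) joins the bottom of one tract to the
top of an adjacent tract so the two tracts run parallel; a lateral loop
(`+l`/`-l`) joins adjacent tracts within one tetrad and antiparallelises
them; a diagonal loop (`d`) joins diagonally opposite tracts within one
tetrad. Signs give the clockwise (`+`) or anticlockwise (`-`) progression
of the strand viewed from the top of the core.

`trace_topology()` walks the implied strand path: corner indices increase
clockwise in that view, the first tract sits at corner 0 running up,
`+`/`-` loops step the corner index by +1/-1 and `d` by +2 (mod 4),
propellers keep the tract direction while laterals and diagonals flip it
and stay on the face where the previous tract exits. A loop triple is a
valid topology when the walk (i) visits all four corners exactly once and
(ii) never puts two diagonal loops on the same tetrad face. Exactly 26 of
the 125 triples survive, partitioned by signed step pattern into
8 (+1,+1,+1), 8 (-1,-1,-1), 4 (+1,+2,-1), 4 (-1,+2,+1) and the two
diagonal-propeller-diagonal forms. The corner labelling and the
clockwise-positive convention are pure conventions; results are
rotation-invariant, and the convention is pinned empirically by the
long-distance rule below.

Crossing the 26 topologies with per-tetrad hydrogen-bond polarities
(LP/RP, `enumerate_polarity_patterns()`) and loop lengths of 1-4 nt per
position yields the conformational grid of `enumerate_conformations()`:
64 loop-length triples x 26 topologies x 8 polarity patterns = 13,312
three-tetrad conformations, and 6,656 two-tetrad conformations with 4
polarity patterns.

## Short- versus long-distance propellers

Whether a propeller loop can take the short way between its attachment
points depends on the tilt of the tracts, i.e. on helicity. Algebra on
the helical geometry reduces this to a counting rule
(`classify_propellers_rule()`): under right-handed (RH) helicity a `+p`
loop is long-distance (LD) iff 0 or 2 nonpropeller loops precede it
(5'→3'), and a `-p` loop is LD iff exactly 1 precedes it; left-handed
(LH) helicity swaps the conditions. The derivation: a propeller spans a
quarter turn plus or minus the twist accumulated across the core, and
which sign applies depends on whether the walk currently exits at the top
or the bottom — which flips at every nonpropeller loop.

Two independent implementations are kept deliberately separate:

* the closed-form rule above (normative), and
* a geometric classifier (`unwrap_projection()` +
  `classify_propellers_geometric()`) that unrolls the core into a plane,
  places tracts as tilted columns, and thresholds the in-plane distance
  between each propeller's attachment points.

The unwrap lays tracts left-to-right in strand order along the cumulative
angular coordinate of the unwrap direction (set by the first signed
loop's sign; this also puts the 5' end on the left edge for `-` and on
the right edge for `+` starts, via a mirrored plotting coordinate — the
in-plane distances used for classification are mirror-invariant). A loop
whose winding opposes the unwrap direction connects to the periodic image
of its end tract one full turn back, so drawn distances reflect the arc
the loop actually traverses. Layout constants (tract spacing 1.0, tilt
0.35 per tetrad level, level spacing 0.5, all in tract-spacing units) are
arbitrary; only the separation of the two distance populations matters.
At these defaults the short- and long-distance populations are disjoint
(1.04 vs 1.97 units over all 52 topology x helicity cases), and the
threshold is taken as the midpoint of the widest gap in the pooled
distance distribution — a rule-independent construction, so the
rule-vs-geometry agreement on all 52 cases is a genuine cross-check.

The same dichotomy is reproduced in 3D: `build_scaffold()` places one
backbone anchor per guanine position on a cylinder (radius 1.0 nm, rise
0.34 nm per tetrad, twist 30°/tetrad signed by helicity — canonical
nucleic-acid stacking values, configurable), and
`shortest_surface_path()` measures the geodesic on a guard cylinder
(anchor radius + 0.2 nm probe) winding only in the loop's mandated
direction, length \(\sqrt{\Delta z^2 + (r\,\Delta\phi)^2}\). On the
default three-tetrad scaffold every LD path (3.21 nm) is longer than
every SD path (0.93 nm), and two-tetrad LD paths are shorter than
three-tetrad ones, consistent with laxer length constraints in
two-tetrad G4s. The exact surface-path construction used with MD
ensembles is not public; this single-winding cylinder geodesic is a
deliberate idealisation, so absolute nanometre values are indicative
only and are never asserted in tests.

## Loop-length feasibility

`g4_rules()` encodes minimal loop lengths: lateral ≥ 2 nt (a
`strict_lateral = FALSE` switch admits the single known 1-nt `+l`
structure), diagonal ≥ 3 nt, short-distance propeller ≥ 1 nt,
long-distance propeller ≥ 5 nt. The LD minimum is a deliberate
binarisation of a graded reality (3-4-nt LD loops are rare but not
impossible); it is exposed as a parameter rather than hard-coded.
Two-tetrad cores use the same rule set by default even though their LD
paths are shorter; callers can pass a laxer rule set per tetrad count.
Feasibility of a conformation checks each loop against the minimum for
its type, with the SD/LD minimum selected by the helicity-dependent
classification. `design_search()` ranks loop-length triples by how few
competitor topologies remain feasible; for the experimentally unreported
`-pd+p` topology it recovers the (1, ≥3, 1) design window, with
`-p-p-p` as the single competitor.

## The foldability pipeline

A conformation is foldable when the RMSD of its guanine core to the
class reference is strictly below the class threshold
(`label_foldable()`); thresholds are the 99th percentile of
folded-state RMSD fluctuations (`rmsd_threshold()`, empirical percentile
with linear interpolation between order statistics — `quantile()` type 7,
frozen for reproducibility). The shipped defaults (0.104, 0.079,
0.083 nm for 3-tetrad RH, 2-tetrad RH, 2-tetrad LH) correspond to
reference MD fluctuation distributions of solved structures; they are
data, not fitted quantities, and the package can recompute thresholds
from any supplied trace. `kabsch_rmsd()` provides the underlying
superposition (SVD Kabsch, proper rotations only).

Aggregations mirror the standard foldability summaries: topology x total
loop length maps (rows ordered by decreasing mean foldability; empty
cells are missing, not zero), per-feature means by loop type/length and
position, and two-loop combination tables. A gradient-boosted classifier
(`fit_foldability_classifier()`, xgboost, depth 4, eta 0.3, single
thread) reports precision of the foldable class over label-stratified
10-fold cross-validation; precision is the metric and foldable the
positive class by assumption. Feature attribution
(`exact_shapley_attribution()`) is exact coalition Shapley over seven
grouped players (loop type I-III, loop length I-III, polarity): the
value of a coalition is the prediction of a model retrained on exactly
those features, the empty coalition predicts the base rate, and all
2^7 = 128 coalition models are enumerated, so the efficiency, symmetry
and dummy axioms hold to numerical precision rather than approximately.
Signed per-value attributions (mean Shapley value of records carrying a
given feature value) are reported alongside mean-absolute importances;
signed means are used because attribution direction is part of the
scientific claim.

## The synthetic-data generator

`generate_records()` emulates the statistical structure of an MD
foldability screen, not its physics. Fold probability is logistic with
additive effects: base log-odds 0.3; +0.3 per nt of total loop length,
saturating at 12 nt; a per-LD-propeller penalty 1.3 + 5.2/min(L, 5)
log-odds units (harshest at 1 nt, relieved with loop length, constant
from 5 nt); and a hard penalty of 8 for diagonal < 3 nt or lateral <
2 nt. These magnitudes were calibrated once against the qualitative
foldability scale of the MD screen the generator emulates — near-zero
foldability for 1-nt LD loops, low tens of percent at 2-4 nt, a
near-ceiling all-SD topology and near-floor all-LD topology — and are
not tuned thereafter. RMSD values are emitted from truncated normals
(folded: mean 0.06, sd 0.015 nm; misfolded: mean 0.20, sd 0.05 nm;
lower bound 0) so that the default thresholds separate the classes. A
label-noise rate (default 0.05) flips the emitted state relative to the
structural outcome, which the stored `true_foldable` column retains.
Randomness is driven by per-conformation streams derived from a global
seed plus a hash of the conformation id, so any subset of the grid
reproduces identically.

Two numerical notes. First, with the default emissions about 2.7% of the
misfolded mass lies below the 0.104 nm threshold, so end-to-end label
recovery at full defaults incurs a small irreducible excess error beyond
the configured noise; the test suite verifies the recovery error against
the analytic expectation (noise plus closed-form truncated-normal
leakage), and verifies the pure noise-recovery property in a
configuration whose emissions are well clear of the thresholds
(misfolded mean 0.30, sd 0.03 nm). Second, because coalition Shapley on
enumerated grids is observational, feature co-occurrence shapes
position-II attributions: II=`+p` co-occurs with LD-bearing position-I
loops, so its signed attribution need not be favourable even though its
own LD probability is lower than II=`-p`'s. The robust, tested claims
are the position-I signs (RH: `-p` favourable, `+p` unfavourable) and
the reversal of all propeller contrasts under helicity change.

What the generator does not emulate: MD energetics and kinetics,
polarity-pattern effects (polarity enters the grid and the classifier
but carries no generative effect), nucleobase-dependent loop chemistry
(loops are all-T by design), G-register exchange, bulged tracts and
multimolecular G4s. Consequently, passing tests demonstrate that the
pipeline recovers the structure the generator put in — not that real G4
foldability follows these numbers. MD-derived quantities (foldable
fractions, per-topology percentages, CV precision, threshold values) are
reproducible only by ingesting per-conformation tables derived from the
deposited structures; the pipeline's ingest path accepts such tables in
the package TSV schema.

## Problem sizes and determinism

The analyses under `analysis/` use the full grids (13,312 + 2 x 6,656
records), 10-fold CV, and a 3,000-record subsample for the
128-coalition attribution stage; the test suite exercises the same code
on full grids for counting/labelling properties and on subsamples of
600-1,800 records for retraining-based attribution, with 1e5 draws for
percentile checks. All stochastic steps take explicit seeds; pipeline
runs with equal configurations produce byte-identical artifacts, and the
run manifest records stage notes, file checksums and a configuration
hash.

## Known limitations

* The validity criterion (corner distinctness + diagonal-face
  disjointness) reproduces the accepted count of 26 and every named
  member, but it is this package's formalisation; other equivalent
  formulations exist.
* The surface-path construction is an idealisation (see above); only the
  SD/LD dichotomy and orderings are meaningful.
* Binary feasibility compresses a graded foldability landscape; use the
  foldability pipeline when the gradation matters.
* Exact Shapley is limited to 12 grouped features by design; beyond that
  the function refuses rather than silently approximating.
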