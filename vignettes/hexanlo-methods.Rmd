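---
title: "Designing hexaphyrin NLO switches: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing hexaphyrin NLO switches: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexanlo)
```

## The design problem

Hexaphyrins are expanded porphyrins with six pyrrole-type rings bridged by
six meso-carbons (sites R1–R6). They interconvert between redox states and
π-conjugation topologies — the antiaromatic Hückel rectangle `28R`, the
aromatic Hückel `26R`, and the singly-twisted Möbius `28M` — and the first
hyperpolarizability β changes dramatically across these states. A pair of
states therefore behaves as a molecular nonlinear-optical (NLO) switch: the
`28R` conformer, which is usually centrosymmetric and hence has
β<sub>HRS</sub> ≈ 0, plays the OFF state, while `26R` (redox switching) or
`28M` (topology switching) plays the ON state. Meso-substituents tune both
states, and the design question is which substitution maximizes the ON/OFF
contrast. `hexanlo` implements the full computational loop around that
question except the quantum chemistry itself: tensor reduction, contrast
objectives, the combinatorial substitution space, a greedy inverse-design
optimizer, and geometry descriptors.

## From a β tensor to β~HRS~

The hyper-Rayleigh-scattering intensity of freely tumbling molecules,
detected perpendicular to the propagation plane, is governed by two
isotropic orientational averages of the 3×3×3 tensor β(−2ω; ω, ω):

$$\beta_{HRS} = \sqrt{\langle\beta^2_{ZZZ}\rangle +
\langle\beta^2_{ZXX}\rangle}, \qquad
DR = \frac{\langle\beta^2_{ZZZ}\rangle}{\langle\beta^2_{ZXX}\rangle}.$$

`orientational_averages()` implements the standard closed forms for a
tensor with intrinsic SHG symmetry (β<sub>ijk</sub> = β<sub>ikj</sub>) and
**no** further Kleinman symmetry — the frequency-dependent tensors of
near-resonant chromophores do not satisfy full index permutation symmetry,
so the weaker assumption is the safe one. The expansions contain eleven
terms each, with coefficients 1/7, 4/35, 2/35, 1/35, 4/105, 1/105 and
2/105; transcription slips in such coefficient tables are notoriously easy,
so the package carries its own independent referee:
`mc_rotational_average()` draws Haar-uniform rotations (unit quaternions
from the normalized 4D Gaussian), rotates the tensor and averages the
squared laboratory components by brute force. The closed forms were
verified against this oracle (and, for ⟨β²<sub>ZZZ</sub>⟩, against the
exact sixth-moment pairing sum of a uniform unit vector) to well below
Monte-Carlo resolution; the test suite re-runs the comparison for dozens of
random tensors at 10⁶ samples, requiring agreement within three standard
errors.

Two conventions worth stating explicitly:

* β<sub>HRS</sub> is the **square root** of the sum of the two averages.
  Writing the invariant without the root would leave it in units of
  β² — dimensionally inconsistent with the atomic-unit β values it is
  compared against.
* Tensors are symmetrized in their last two indices on construction and on
  file read (disable with `symmetrize = FALSE`). Units are atomic units
  throughout; no conversion is attempted.

Tensors travel as JSON (`hexanlo-beta-v1`): 27 components keyed
`"xxx"`…`"zzz"`, a `frequency_eV` tag (0 = static; a file without the tag
is read as static with a warning), and an optional `sparse` flag that
permits omitting zero components. Unknown keys and non-numeric values are
parse errors naming the offending key.

## Switch contrasts

Two figures of merit are implemented (`evaluate_switch()`):

* **ratio**: β<sub>HRS</sub>(ON) / β<sub>HRS</sub>(OFF). A centrosymmetric
  OFF state drives the denominator to zero and the ratio to infinity, which
  would make structures incomparable during optimization. The standard
  regularization is applied: when β<sub>HRS</sub>(OFF) < 10 a.u. the
  denominator is replaced by 0.001 a.u. Both numbers are configuration
  parameters defaulting to those values.
* **difference**: β<sub>HRS</sub>(ON) − β<sub>HRS</sub>(OFF); no
  regularization needed, and a negative value is meaningful.

The OFF state is assigned by chemical role (`28R` by convention), never by
magnitude. When the nominal OFF state has the larger response, the result
carries `reversed = TRUE` (equivalently ratio < 1, difference < 0) rather
than silently swapping labels — reversals are a real design outcome worth
surfacing, not an error.

A corollary of the clamp that the package's validation exploits: whenever
the OFF beta is stored as exactly 0, ratio = difference / 0.001, so ratio
and difference are exactly collinear across any set of
centrosymmetric-OFF switches and an OLS fit gives R² = 1 identically.
`contrast_correlation()` computes that R² from the residual and total sums
of squares directly (avoiding the perfect-fit warnings of `summary.lm`).

## The substitution space

A `substitution_pattern()` partitions R1–R6 into groups constrained to
carry the same fragment:

| pattern | groups | space size (7 fragments) |
|---|---|---|
| `FULL` | {R1..R6} | 7 |
| `A2B2C2` | {R1,R4}, {R2,R5}, {R3,R6} | 343 |
| `A3B3` | {R1,R3,R5}, {R2,R4,R6} | 49 |
| `A2BC2D` | {R1,R3}, {R2}, {R4,R6}, {R5} | 2401 |

`A2B2C2` pairs sites facing each other diagonally across the macrocycle.
The `A2BC2D` grouping is reconstructed from the explicit site mentions in
the source analyses (methyls on R1/R3, a lone R2, strong acceptors on
R4/R6, one on R5). The `A3B3` membership is the alternating partition —
the natural outcome of assembling the macrocycle from meso-substituted
dipyrromethene plus aryl aldehyde — but the published depiction is
graphical only, so the partition is an inference; it is isolated inside
`substitution_pattern()` so a correction would touch one table, not the
algorithms.

The optimization library (`substituent_library()`) holds exactly the seven
fragments used in the design campaigns: NO2, CN, F, H, CH3, OH, NH2, each
tagged EWG/EDG/neutral and mesomeric/inductive. PhF5 exists in the
reference tables (`include_phf5 = TRUE`) but is excluded from the default
search library.

Canonical keys `STATE(label_label_…)` (e.g. `26R(NH2_OH_NH2)`) name
structures; they serve as cache keys, fixture join keys, and trajectory
records. `is_formally_centrosymmetric()` encodes the symmetry rule: a
`28R` whose site map is invariant under R1↔R4, R2↔R5, R3↔R6 is predicted
Ci — a *formal* prediction that reference data may override, since
geometry relaxation can break the symmetry (NO2-disubstituted `28R`
relaxes to C2 with β<sub>HRS</sub> ≈ 10³ a.u.).

## Best-first search

`run_bfs()` is a greedy site-by-site maximizer. From a seeded uniform
random assignment it visits groups in fixed ascending order (configurable);
for each group it evaluates every library fragment with all other groups
frozen and accepts the strictly best improvement. Sweeps repeat until a
full sweep accepts nothing or `max_global_sweeps` (default 10) is reached.
Design choices that the literature leaves open, decided here:

* *Strict improvement.* Equal-valued candidates never replace the
  incumbent; with ties allowed the search could cycle, so strictness buys a
  termination guarantee for free.
* *Tie-break.* Among equal best *improving* candidates, the earlier library
  entry wins — deterministic and library-order-stable.
* *Site order.* Fixed ascending by default. Randomizing the order per sweep
  is a one-line configuration change but is off by default so that a seed
  fully determines the trajectory.
* *Both states per evaluation.* The objective is a contrast, so one
  "evaluation" prices both the ON and the OFF structure; the evaluator
  contract returns `c(on=, off=)`.
* *Caching.* Results are memoized by canonical key + frequency, so no
  structure is ever evaluated twice; with `cache_file` set, evaluations are
  appended to a JSONL file and reloaded on restart, making interrupted
  campaigns resumable.
* *Error policy.* An evaluator failure either aborts (`"abort"`) or scores
  the candidate −∞ (`"minus_inf"`), the latter being the right choice for
  reference-table evaluators that cover only part of a space.

Under the independent-site approximation (ISA) — an additive property
landscape — optimizing sites one at a time is exact, and the test suite
verifies BFS against `exhaustive_search()` (the enumeration oracle, guarded
at 10⁵ points) on additive landscapes for 20 seeds over the 343-point
`A2B2C2` space. With couplings the greedy result is only bounded by the
exhaustive optimum, and the accepted-objective sequence is checked to be
monotone. Converged runs touch strictly fewer structures than the space
holds — the point of inverse design.

## Evaluators

**Reference tables.** `load_fixtures()` ships the transcribed DFT results
for the parent macrocycles, the fully substituted switch series, the
pairwise disubstitution prestudy and the published campaign optima
(β<sub>HRS</sub> at 0, 0.653 and 1.165 eV where printed, plus geometry and
aromaticity descriptors where printed). Values printed as "≈0" are stored
as exactly 0 with symmetry `Ci`; the C2 exceptions carry their nonzero
betas. Loading validates every row — non-negative betas, the 0 ⇒ Ci
convention, key uniqueness — and recomputes every transcribed contrast
cell from its ON/OFF betas. Ratios must agree within 1%; differences
within 1% of the printed value *or* of the combined ON+OFF magnitude,
whichever is larger, because a difference of two 3-significant-digit
operands can legitimately disagree with the printed difference by more
than 1% of itself (the cyano redox pair: stored 1640 − 1170 = 470 vs
printed 465). The descriptor columns (Λ, NICS, AV1245, AV_min, Δη, Φ_p, Π)
are read-only metadata: the package never regenerates wavefunction-based
aromaticity indices, and the printed Π values are not regeneration targets
(see below). Because only printed structures are covered, BFS over
fixture evaluators is meaningful only on covered sub-spaces; full-space
search testing uses synthetic landscapes.

**Synthetic landscapes.** `synthetic_landscape()` builds a seeded,
deterministic stand-in for the DFT surface with the same gross anatomy:
log-normal per-(group, fragment) base contributions around 2 500 a.u. for
the ON state and 300 a.u. for the OFF state (spread ×2–3, matching the
10³–10⁴ a.u. range of the reference ON states and the 10²–10³ a.u.
non-centrosymmetric OFF states), optional Gaussian pairwise couplings
(default σ = 500 a.u., making the ISA imperfect as observed in practice;
set 0 for exactly additive), and the centrosymmetry rule: a formally
centrosymmetric `28R` scores exactly 0 unless a symmetry-breaker fragment
(default NO2) appears. Absolute values keep every synthetic β ≥ 0. What
the synthetic model deliberately does **not** emulate: resonance
enhancement near one-photon poles, conformational multiplicity of the
relaxed structures, and any correlation between a fragment's electronic
character and its contribution — so passing search tests demonstrates
optimizer correctness, not chemistry.

**External evaluator.** `external_evaluator()` defines the file protocol
toward a real quantum-chemistry backend: a request JSON (key, state,
per-site map, frequency) per structure, a `hexanlo-beta-v1` tensor file
as the response, reduced through `beta_hrs()` on pickup. Missing or
malformed responses surface as evaluator failures for the BFS error
policy. Tests exercise the protocol with stub responders.

## Geometry descriptors

Ring planes are total-least-squares fits (smallest singular vector of the
centered ring coordinates); a collinear ring is a reported plane-fit
error.

* **Φ_p** (torsional ring strain): the mean over the six cyclic neighbor
  pairs of the unsigned angle in [0°, 90°] between ring planes.
* **Π** (π-conjugation index): the product over cyclic neighbor pairs of
  the cosine between consecutively orientation-propagated ring normals.
  Each fitted normal enters the cyclic product exactly twice, so the
  arbitrary sign of a plane normal cancels and the product is
  well-defined: positive for an untwisted (Hückel) loop, negative when
  the orientation reverses once around the loop (Möbius), magnitude ≤ 1,
  and cos(θ)⁶ exactly for six uniformly tilted coplanar-normal rings. The
  published definition of Π traces to prior work whose exact formula
  (per-atom p-orbital axes vs ring normals) is not reproduced in the text;
  this implementation reproduces the documented sign behavior and
  magnitude range and lives behind a single function (`pi_index()`) so it
  can be swapped without touching anything else. Printed Π values are
  treated as fixture metadata, never as targets.
* **Topology**: sign of Π (`classify_topology()`); Π = 0 (orthogonal
  neighbor planes) is an explicit indeterminate error rather than a silent
  class. A Hückel macrocycle with Π ≥ 0.30 is flagged aromatic-by-Π.
* **Inversion center**: centroid as the candidate center, greedy
  same-element nearest-neighbor matching of each atom against the inverted
  set with bijectivity enforced, tolerance 0.1 Å by default — adequate for
  exact and near-exact Ci structures, which is the regime where the
  β<sub>HRS</sub> = 0 rule applies.

`synthetic_hexaphyrin()` generates test frames: six N+4C pentagons on a
circle. In Hückel mode the six ring normals are constructed so the six
cyclic inter-plane angles equal the requested values *exactly* (signs of
the intermediate tilts are searched, the sixth normal closes the loop on a
two-cone intersection, and an infeasible angle sequence errors); in Möbius
mode the normal tilts outward and completes half a turn around the loop,
yielding the single orientation reversal. Every geometry test therefore
has an analytically known expected value.

## Numerical choices and degenerate inputs

* Rotation matrices are validated to 1e-8 (orthogonality and det +1).
* β<sub>HRS</sub> rotation invariance is asserted at 1e-9 relative.
* Depolarization ratio is `NA` when ⟨β²<sub>ZXX</sub>⟩ = 0 (zero tensor).
* The 0/0 switch pair evaluates to difference 0 and clamped ratio 0.
* Exhaustive search refuses spaces above 10⁵ points.
* All stochastic components (Monte-Carlo sampling, initial assignments,
  synthetic landscapes) take explicit seeds and restore the caller's RNG
  state.

## Problem sizes used by the shipped tests

The test suite verifies the Monte-Carlo agreement at 10⁶ samples for 50
random tensors, BFS-vs-exhaustive equality for 20 seeds on the 343-point
`A2B2C2` space plus 5 coupled landscapes, and the full fixture
revalidation; the complete suite runs in about a minute on one CPU. These
sizes give the oracle comparisons three-standard-error resolution below
0.5% on the averages while keeping the suite fast; nothing in the
methodology changes at larger n.

## Known limitations

* No quantum chemistry: β tensors, relaxed geometries, aromaticity indices
  and free energies come from outside (files or tables); the package
  computes everything downstream of a β value or tensor.
* The formal centrosymmetry rule predicts symmetry from the substitution
  pattern alone; relaxation can break it, and only reference data or a real
  backend can say when.
* Frequency handling is bookkeeping (tags, per-frequency clamping and
  caching); no dispersion model connects β values across frequencies.
* The A3B3 site partition is an inference (above).
* Π is a geometric proxy defined on ring planes, not a wavefunction
  overlap measure.
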