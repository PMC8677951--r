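# hexanlo

Inverse design of hexaphyrin-based nonlinear-optical (NLO) molecular
switches in R.

Hexaphyrins — expanded porphyrins with six pyrrole-type rings — hop between
redox states and π-conjugation topologies (the antiaromatic Hückel
rectangle **28R**, the aromatic Hückel **26R**, the singly-twisted Möbius
**28M**), and their hyper-Rayleigh-scattering first hyperpolarizability
β<sub>HRS</sub> changes by orders of magnitude in the process: the usually
centrosymmetric **28R** has β<sub>HRS</sub> ≈ 0 (the OFF state), while
**26R** or **28M** responds at 10³–10⁴ a.u. (the ON state). Decorating the
six meso-positions R1–R6 with electron-donating or -withdrawing groups
tunes both states at once. `hexanlo` is the computational scaffolding for
finding good decorations — everything downstream of a β tensor or β value;
the quantum chemistry that produces those inputs stays outside.

## What it computes

**Tensor reduction.** For a 3×3×3 tensor β(−2ω; ω, ω) with intrinsic SHG
symmetry, the two isotropic orientational averages and

  β_HRS = sqrt(⟨β²_ZZZ⟩ + ⟨β²_ZXX⟩),   DR = ⟨β²_ZZZ⟩ / ⟨β²_ZXX⟩

using the standard non-Kleinman closed forms (coefficients 1/7, 4/35, 2/35,
1/35, 4/105, 1/105, 2/105, …), plus a Monte-Carlo rotational-averaging
oracle (Haar-uniform quaternion rotations) that independently verifies
them. Tensors travel as JSON (`hexanlo-beta-v1` dialect).

**Switch contrasts.** The two figures of merit of a switch with states
ON/OFF: the ratio β_HRS(ON)/β_HRS(OFF) — with the OFF-state clamping rule
(denominator → 0.001 a.u. when β_HRS(OFF) < 10 a.u.) that keeps
centrosymmetric OFF states comparable — and the difference
β_HRS(ON) − β_HRS(OFF). ON/OFF reversals are reported, not relabelled.

**Chemical space.** Substitution patterns (`FULL`, `A2B2C2`, `A3B3`,
`A2BC2D`) over sites R1–R6, the 7-fragment library (NO2, CN, F, H, CH3,
OH, NH2), enumeration, canonical structure keys like `26R(NH2_OH_NH2)`,
and the formal centrosymmetry rule for substituted **28R**.

**Best-first search.** Greedy site-by-site contrast maximization with
strict-improvement acceptance, caching (optionally persisted JSONL, so
runs resume), pluggable evaluators — packaged DFT reference tables, seeded
synthetic landscapes with centrosymmetry cancellation, or a file-based
external-evaluator protocol — and an exhaustive-search oracle.

**Geometry descriptors.** From XYZ + ring-index sidecar files: torsional
ring strain Φ_p (mean inter-ring plane angle), the signed π-conjugation
index Π (positive Hückel, negative Möbius), topology classification, and
inversion-center detection.

## Worked example

```r
library(hexanlo)

# a dominant-diagonal tensor: the textbook single-component limit
b <- array(0, c(3, 3, 3)); b[3, 3, 3] <- 1000
beta_hrs(beta_tensor(b))
#> beta_HRS = 414.039 a.u. (frequency 0 eV)
#>   <beta2_ZZZ> = 142857  <beta2_ZXX> = 28571.4  DR = 5
```

414.04 = 1000·sqrt(6/35): a single β_zzz component contributes 1/7 and
1/35 to the two averages, and their 5:1 ratio is the dipolar limit of the
depolarization ratio.

```r
# the unsubstituted redox switch, from the packaged reference tables
fx <- load_fixtures()
lookup <- table_evaluator(fx)
pair <- switch_pair(lookup("26R(H)"), lookup("28R(H)"))
evaluate_switch(pair, "ratio")
#> switch 26R (ON, beta = 2347 a.u.) / 28R (OFF, beta = 0 a.u.)
#>   ratio = 2.347e+06 [clamped]   difference = 2347 a.u.
```

The centrosymmetric **28R** OFF state is stored as exactly 0 a.u., the
clamp replaces the denominator by 0.001 a.u., and the ratio lands at
2.35×10⁶ — the parent-switch figure the design campaigns start from.

```r
# inverse design on a seeded synthetic landscape (343-point A2B2C2 space)
lib <- substituent_library()
spec <- synthetic_landscape("A2B2C2", lib, seed = 1)
res <- run_bfs("A2B2C2", lib, synthetic_evaluator(spec),
               bfs_config(seed = 1, objective = "ratio"))
res
#> BFS A2B2C2: best ratio objective = 2.3752e+07 after 2 sweep(s) (converged)
#>   best structure: CN_H_CH3 | evaluations 31, cache_hits 6
```

31 evaluations out of 343 possible structures — the "only a fraction of
the space" economy that makes inverse design attractive.

```r
# topology descriptors of a synthetic singly-twisted frame
topology_descriptors(synthetic_hexaphyrin(moebius = TRUE))
#> $phi_p           47.9 (degrees)
#> $pi_index        -0.0593
#> $topology        "Moebius"
#> $aromatic_by_pi  FALSE
#> $centrosymmetric FALSE
```

A command-line interface wraps the same functions
(`inst/cli/hexanlo hrs|contrast|descriptors|fixtures|optimize|make-synthetic`);
see `?hexanlo_cli`.

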