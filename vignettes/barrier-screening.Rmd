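---
title: "Screening enzyme mutants by interpolated reaction barriers"
author: "BarrierScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening enzyme mutants by interpolated reaction barriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BarrierScreen)
```

## The method

BarrierScreen estimates how point mutations in an enzyme's active site
change the activation barrier of the rate-limiting chemical step, and
ranks mutants by that barrier to nominate candidates for experimental or
higher-level computational follow-up. The archetypal application is a
retaining glycoside hydrolase: the rate-limiting glycosylation step
carries the system from the enzyme–substrate complex (**ES**) to the
covalent glycosyl–enzyme intermediate (**GE**), while the nucleophile
carboxylate oxygen (O^ε^) attacks the anomeric carbon (C~1~) and the
leaving group departs.

The barrier is mapped by *adiabatic mapping* (constrained linear
interpolation). A single geometric reaction coordinate is used:

$$x_1 = \lVert \mathbf{r}_{\mathrm{O}^\epsilon} - \mathbf{r}_{\mathrm{C}_1} \rVert .$$

Given correspondence-matched ES and GE endpoint structures, intermediate
frames are linear blends of the Cartesian coordinates,
$c_k = (1-t_k)\,c_{\mathrm{ES}} + t_k\,c_{\mathrm{GE}}$ with
$t_k = k/(n+1)$, so the $x_1$ targets form an arithmetic progression.
Each frame is then relaxed by an energy engine with $x_1$ held at its
target, and the profile energies $E_0,\dots,E_{n+1}$ give the barrier

$$\Delta E^\ddagger = E_{\max} - \min_{k < \arg\max} E_k ,$$

i.e. the highest energy minus the lowest energy *before* the highest
point. If the maximum falls on the last frame (or the first), no barrier
is evaluated and the profile is rejected — a deliberately conservative
rule, since such profiles indicate that the interpolation did not
bracket a transition-state-like region. Constraining only one distance
leaves the engine free to handle the synchronicity of concerted
bond-breaking/forming events.

Only a single-point mutation's effect *relative to the wild type*
(ΔΔE^‡^) is meant to be interpreted: the method trades quantitative
accuracy for throughput.

## Endpoint derivation pathways

Preparing mutant endpoints admits several orderings of the modeling
steps (mutate, optimize, rebuild the substrate link). `planPathway()`
encodes five:

* **1–2** (wild type): the GE is optimized first (it is conformationally
  least mobile thanks to the covalent link); the ES is derived from it by
  deleting the O^ε^–C~1~ bond, re-forming the glycosidic bond to the
  leaving group (`deriveESfromGE()`), and re-optimizing.
* **3**: mutate ES and GE independently and optimize both. Because the
  two endpoints are optimized independently, outer-region coordinates
  differ slightly between them, so Cartesian constraints cannot be
  applied; requesting them is a configuration error.
* **4**: build the mutant ES from the wild-type ES. Two independent
  side-chain builds can leave the mutated side chain differently
  oriented in ES and GE, which produces non-physical interpolation
  geometries.
* **5** (default): mutate and optimize the GE only, then assemble the
  mutant ES by transplanting the wild-type ES substrate coordinates into
  the mutant protein (`extractAndModifySubstrate()`). The mutated side
  chain is identically oriented at both endpoints by construction; this
  is the cheapest and most robust scheme and is what `screenMutants()`
  runs.

## Constraints

Full-protein relaxation of every frame is too expensive for hundreds of
mutants. `buildConstraints()` freezes all atoms of protein residues with
no atom within a *layer radius* of the active center, inheriting their
coordinates from the preceding optimized state. The production setting
is a 10 Å layer; constrained screening systematically lowers absolute
barriers, so the recommendation is to re-compute the most promising hits
unconstrained and interpret constrained barriers relatively. The two
reaction-coordinate atoms are never members of the constraint set K;
during frame relaxation they are frozen separately (see below).

## Side-chain construction

Interactive mutagenesis tools are replaced by a deterministic,
documented procedure (`buildSideChain()`): backbone atoms (N, CA, C, O
and C^β^ where present) keep their coordinates bit-exactly; the new side
chain is placed from ideal internal-coordinate templates (generic bond
lengths and angles, all 20 canonical amino acids); its χ dihedrals are
chosen by exhaustive 30° grid search (up to χ~4~) minimizing a
hard-sphere clash score against the fixed environment (van der Waals
radii scaled by 0.8), then refined by ±10° coordinate descent in 5°
steps. Ties resolve to the first grid point, so the build is fully
deterministic; the `seed` argument is reserved for future stochastic
refinement. If after refinement any new atom remains closer than 1.5 Å
to a non-bonded environment atom the mutant is flagged
`DISCARDED_MODELING` — the analog of side chains (prolines and tyrosines
in compact pockets, typically) that simply cannot be built, which a
screening campaign discards rather than repairs.

## Validity filters

A screen discards rather than fixes. `screenMutants()` retains every
mutant in its report with one of: `DISCARDED_MODELING` (unbuildable side
chain), `LEWIS_FAILURE` (the engine cannot assign a valence structure),
`CHARGE_MISMATCH` (engine-reported total charge differs from the formal
charge under standard protonation — `formalCharge()` with ASP/GLU −1,
LYS/ARG +1, HIS neutral ε-tautomer, zwitterionic termini; the histidine
convention is a documented default, overridable via
`ProtonationRules`), `CLOSE_CONTACT` (a frame places non-bonded atoms
closer than `dmin`), `TIMEOUT` (walltime policy), and profile-shape
rejections from the barrier rule.

## Engines

`runEngine()` dispatches a uniform job contract. The *external* engine
writes a MOPAC-dialect input deck — keyword line (method label, MOZYME,
`GNORM`, `CUTOFF`, `EPS`, `CHARGE`, `CHARGES`), then per-atom Cartesian
lines with 0/1 optimization flags — executes the configured binary and
parses heat of formation, final geometry, reported charge and failure
phrases (an editable regex list, since message wording varies across
engine versions). Defaults follow the settings at which stationary-point
energies converge in practice: gradient norm 1.0 kcal/(mol·Å), NDDO
cutoff 15 Å, continuum solvent with ε~r~ = 78. A missing binary is a
configuration error, never a silent fallback. Reorthogonalized
single-point energies are modeled as a second engine pass
(`reorthogonalize = TRUE`), recorded alongside the optimization
energies; following practice, the raw (non-reorthogonalized) energies
are the default basis of analysis, and `reorthoAgreement()` quantifies
how often the two variants agree qualitatively (lower/higher than wild
type) below a barrier cap.

The *surrogate* engine exists so the whole pipeline is testable with no
quantum-chemistry program. Its energy along $x_1$ is a symmetric quartic
double-well with exact zero minima at the two basins plus a flat-topped
compact bump $B\,(1-u^4)^3$ centered between them, so the analytic
barrier is exactly `wellHeight + B` and can be programmed per mutant
label; non-reacting atoms feel harmonic tethers. Because mutant offsets
enter the bump height additively, programmed single-mutant effects are
exactly additive in doubles unless a pair deviation is programmed —
which is precisely the property the additivity analysis
(`expected = b1 + b2 − bWT`) should recover. Optimization is BFGS with
the analytic gradient; convergence is declared when the largest per-atom
gradient norm falls below the configured `gnorm`.

## The x~1~ freeze and other numerical choices

* **Freezing x~1~** during frame relaxation is implemented by fixing the
  Cartesian coordinates of *both* defining atoms. Fixing one atom and a
  distance is not expressible in per-atom optimization flags; fixing
  both atoms fixes the distance exactly and writes naturally into the
  engine deck.
* **Frame count**: 10 intermediate frames plus the two optimized
  endpoints (12 profile points). The endpoints are included as profile
  points; with the surrogate surface the discrete-sampling error of the
  barrier decreases monotonically with frame count (checked at n = 4,
  10, 50 in the tests).
* **Glycosidic bond**: ES derivation places the leaving-group oxygen at
  1.43 Å (standard C–O) along the former O^ε^→C~1~ direction, rigid-body
  translating the leaving fragment; nothing else moves.
* **Close contacts**: default `dmin` 0.7 Å, configurable; pairs within a
  residue or in the link registry are exempt.
* **Tie-breaks**: the profile argmax takes the first occurrence;
  per-position winners break barrier ties alphabetically by target
  residue; ranking ties break by label. All deterministic.
* **Barriers** are reported at 0.1 kcal/mol in summaries; full precision
  is retained internally.
* **TST conversion**: `eyringDG()`/`eyringK()` implement
  $\Delta G^\ddagger = RT\ln\!\big(k_BT/(h\,k_{cat})\big)$ with CODATA
  2018 constants. The default temperature is 313.15 K, the assay
  temperature of the reference kinetics for the wild-type enzyme; it is
  an explicit parameter everywhere.

## The toy system and what it does (not) show

`makeToySystem()` builds a deterministic miniature complex: a
two-fragment substrate (sugar analog with C~1~; leaving-group fragment
with its phenolic oxygen), a static carboxylate nucleophile analog, and
a shell of mutable residues with real N/CA/C/O/C^β^ backbones placed at
controlled radii, so the 4 Å active-site rule selects exactly the
programmed inner shell (plus the nucleophile, which is by construction
always in substrate contact). The substrate is the moving partner
between ES and GE, mirroring the real geometry change and exercising the
substrate-transplant step of pathway 5. Programmed "clash" positions are
caged by blocker pseudo-atoms placed on the residue's χ~1~ circle, which
makes every rebuilt side chain beyond C^β^ unbuildable there — a
constructive guarantee, not a statistical one.

Together with the surrogate surface this gives complete, programmable
ground truth: a screen must recover the programmed barriers (to within
the discretization error of 12-point profiles, well under 0.1 kcal/mol
at the default well/bump widths), the programmed ranking, the programmed
discards, and exact additivity. What passing these tests does **not**
show: anything about the accuracy of a real semiempirical energy
function, real rotamer preferences, protonation-state effects, solvent,
or conformational averaging. The toy validates the *orchestration* —
bookkeeping, derivation pathways, constraint handling, filters,
statistics — which is exactly the part this package owns; the energy
model is delegated.

Problem sizes used by the shipped tests and the acceptance script (a
12-residue shell, 30-mutant screens, 12-frame profiles, 10^3^ random
profiles for the barrier-rule oracle) were chosen as the smallest sizes
at which every code path above is exercised.

## Worked example

```{r example, eval = FALSE}
toy <- makeToySystem(toySystemSpec(
    nResidues = 8, nActive = 3, seed = 7,
    mutantOffsets = c(A11W = -11.6, V13T = 3.0)))
surf <- makeSurface(toy$groundTruth)
res <- screenMutants(toy$es, toy$ge, toy$rc,
                     mutants = list(mutationSpec("A", 11, "A", "W"),
                                    mutationSpec("A", 13, "V", "T")),
                     surface = surf)
rankMutants(res$records)
```

## Known limitations

* Only the first (glycosylation-like) chemical step is modeled; a mutant
  that lowers this barrier may raise the barrier of a subsequent step.
* Standard protonation states only; positions whose experimental
  behavior hinges on shifted pK~a~ values will be mis-ranked.
* Linear Cartesian interpolation cannot describe strongly curvilinear
  paths; the conservative profile-rejection rule mitigates but does not
  remove this.
* The focus is the turnover number; binding (and hence specificity) is
  out of scope.
* Side-chain building is geometric (hard-sphere) only — no
  electrostatics, no backbone relaxation.
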