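---
title: "Methods: grid electrostatics, similarity trees and kinetic prediction"
author: "epogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid electrostatics, similarity trees and kinetic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the
choices behind them: what is computed, under which assumptions, which
knobs matter, and what a passing test does and does not establish.

## 1. The reduced charge model

Comparative surface electrostatics needs charges and radii, but for
family-level comparison the *differences* between members carry the
signal, not the absolute accuracy of any one charge set. The default
model is therefore deliberately minimal and fully documented:

* one net point charge per ionizable residue — Arg +1 on CZ, Lys +1 on
  NZ, Asp −1 on CG, Glu −1 on CD; His neutral (its pKa sits near
  physiological pH and either choice is defensible; neutral is the
  conservative one and is configurable through the charge table);
* termini uncharged by default;
* per-element radii (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å,
  default 1.70 Å).

Full per-atom charge sets (e.g. from an external PQR preparation) flow
through unchanged with `assign_charges(mode = "keep")`. For side-chain
*stub* models — mutants truncated to CB, and the synthetic helices,
which carry no atoms beyond CB — the canonical site atom does not
exist; `fallback = "cb"` places the residue's net charge on CB
instead. The fallback is opt-in so that a genuinely incomplete
experimental structure still fails loudly.

## 2. Mutant panels as charge arithmetic

All substitutions truncate the side chain to CB, relabel the residue,
and give CB the target's net charge. No rotamer is rebuilt: the
published mutant experiments this machinery emulates (a
directed-evolution panel at four recognition-loop positions, and a
Lys/Arg-to-alanine scanning panel) act electrostatically through
charge deletion, which the stub preserves exactly. Two consequences
are documented rather than hidden:

* neutral-to-neutral swaps (e.g. N260L) change labels only — their
  electrostatic effect under the reduced model is nil;
* the net-charge change of a panel equals the table-implied sum, which
  the tests verify per set (note that a panel containing a
  neutral-to-Arg swap alongside an Arg-to-Ala deletion has a *zero*
  table-implied net change).

Sets are applied atomically: every spec is validated first (wild-type
identity, backbone completeness, CB presence) and any failure aborts
the whole set with all failures listed.

## 3. The linearized Poisson–Boltzmann solver

The solver discretizes

$$\nabla\!\cdot\!\left(\varepsilon(\mathbf r)\nabla\phi\right)
  - \varepsilon_s\,\kappa^2 a(\mathbf r)\,\phi = -4\pi C \rho$$

on a regular grid with a 7-point stencil, harmonic-mean face
dielectrics, trilinear charge spreading onto the 8 surrounding nodes,
and successive over-relaxation (SOR) until the relative residual
$\lVert A\phi - b\rVert_2 / \lVert b\rVert_2$ falls below the
tolerance. Potentials are in kT/e throughout; the single conversion to
kcal/mol/e (× 0.5922 at 298.15 K) happens at the kinetics boundary, so
no quantity is ever converted twice. The Coulomb constant
$C = e^2/(4\pi\varepsilon_0 k_BT)$ is bundled as 560.74 Å at 298.15 K.

Defaults, all recorded in the attributes of every solved grid:
protein dielectric $\varepsilon_{in} = 4$, solvent
$\varepsilon_{out} = 78.4$, 0.15 M 1:1 salt, 298.15 K, grid spacing
$h = 1$ Å, padding 15 Å, ion probe 2 Å, tolerance $10^{-6}$,
$\omega = 2/(1+\sin(\pi/\max n))$. None of these reproduce any
specific published APBS setup — the source analyses never reported
their parameters — so the defaults are chosen to be standard,
explicit, and cheap enough for property-based testing.

Assumptions worth knowing:

* **Linear PB.** Fine for comparative work at moderate charge
  densities; not for absolute solvation energies.
* **Sphere-union dielectric boundary.** The protein interior is the
  union of (non-inflated) atom spheres; no solvent-excluded surface is
  constructed. This smooths the boundary relative to an SES and makes
  the solver fully specified and testable.
* **Dirichlet boundary from ion-excluded monopoles.** Each charge
  contributes $Cq\,e^{-\kappa(d-a)}/(\varepsilon_s d\,(1+\kappa a))$
  with $a$ = radius + ion probe — the exact exterior solution for an
  ion-excluded sphere. Using the naive $e^{-\kappa d}/d$ monopole
  instead biases the whole box low by ~10% at 0.15 M; this is a
  property of the physics, and the analytic oracle in the tests uses
  the corrected form (which is still proportional to
  $e^{-\kappa r}/r$).

Validation is entirely against closed forms: Coulomb and screened
monopoles in uniform dielectric within 5% over 5–15 Å, error
shrinking under grid refinement, linearity in the charges, mirror
symmetry, and sign consistency of the boundary.

## 4. Skins, anchors, similarity

Potentials of two superposed structures are compared over a *skin*:
grid points whose distance to the nearest atom surface lies in
$[\sigma, \sigma + \delta]$, defaults $\sigma = 3$ Å, $\delta = 4$ Å —
the PIPSA convention, far enough out to be insensitive to the
dielectric boundary discretization, close enough to see the charge
pattern. Pairwise comparisons use the *intersection* of the two
members' skins so both fields are defined at every compared point.

For TRD-focused comparison the skin is intersected with a 35 Å sphere
centred on the CA centroid of a recognition-domain motif (CFT in
eukaryotic MT2 enzymes, corresponding spatially to TLS and VQA in the
two bacterial anchors). The anchor must be computed *after*
superposition; the package refuses potential grids with different grid
specifications rather than resampling, which keeps interpolation error
out of the similarity numbers.

The Hodgkin index is the default
($SI = 2\Sigma ab/(\Sigma a^2 + \Sigma b^2)$; sensitive to magnitude
differences), Carbó is available
($\Sigma ab/\sqrt{\Sigma a^2\,\Sigma b^2}$; scale-free per field), and
the electrostatic distance is $D = \sqrt{2 - 2\,SI} \in [0, 2]$.
Whether published distance values in this family derive from whole-skin
or anchored comparisons was never stated by their authors; both modes
are provided and neither claims to reproduce unpublished matrices.

## 5. Trees

Epograms are UPGMA dendrograms (average linkage, merge at height
$d/2$): the convention of PIPSA's own clustering. Ties on the minimum
distance are broken lexicographically on the sorted pair of cluster
representative labels, making trees bit-reproducible. Sequence trees
use Saitou–Nei neighbor joining (delegated to `ape::nj`, the
field-standard implementation) with negative branch lengths clamped to
zero under a warning; tests validate NJ against additivity and
closed-form three-taxon solutions rather than against ape itself.

## 6. The qPIPSA kinetic stage

The model is a proportionality between pairwise differences: an
increase of one ln unit in kcat/Km corresponds to a fixed *decrease*
in mean anchored surface potential (slope in kcal/mol/e per ln unit).
Design choices:

* **Antisymmetrized, through-origin fit.** Every pair $(x, y)$
  contributes $(-x, -y)$; a zero kinetic difference must map to a zero
  potential difference, so the intercept is fixed at 0 by default
  (fit-intercept available behind a flag). The slope is
  $s = \Sigma(\Delta\ln\cdot\Delta EP)/\Sigma(\Delta\ln)^2$.
* **ΔEP operationalization.** The mean over the anchored pairwise
  skin of $\phi_a - \phi_b$, converted once to kcal/mol/e. The source
  analyses say only "differences in electrostatic potentials" of
  surface residues near the active site; this explicit choice is
  recorded in output metadata.
* **Two-anchor degeneracy.** With only two experimentally
  characterized enzymes the fit is a one-pair ratio; the model allows
  it but flags $R^2$ as non-informative. How a published $R^2$ of
  0.9512 was obtained from two anchors is not explained in the source
  and is not reproduced here.
* Predictions anchor on each reference separately
  ($\ln_t = \ln_{ref} + \Delta EP/s$) and report the mean and the
  max−min spread across references.

## 7. What the synthetic generator emulates — and what it does not

`make_qpipsa_benchmark()` builds the *stated world* of the recovery
test: 20 enzymes, generator slope −0.1046 kcal/mol/e per ln unit,
Gaussian noise of 0.05 ln units, one fixed seed, grid spacing 1 Å,
padding 15 Å. The base scaffold is an 18-residue ideal α-helix
(`AKEACFTKEKAKEKAKEA`): long enough to carry the CFT anchor motif plus
ten charged sites, short enough that one LPBE solve takes well under a
second. Variants delete one to six random charged residues through the
mutator, and ln(kcat/Km) values are *generated* from the pipeline's
own anchored mean potential differences —
$\ln_i = \ln_{ref} + \Delta EP(i, 0)/s^* + \varepsilon_i$ — so that
refitting exercises exactly the path real data would take. The anchor
value $\ln_{ref} = \ln(1.2\times10^7)$ is the experimentally measured
bacterial reference efficiency.

What a green recovery test establishes: the solver, skin, anchoring,
unit conversion and fit compose without sign errors or unit drift, and
the fit's noise sensitivity is as designed. What it does **not**
establish: that real methyltransferase potentials follow the linear
law, that the scale of real ΔEP values matches helical toys, or
anything about the published per-species predictions — those depend on
unpublished homology-model potentials and are explicitly out of
acceptance. Helices also differ from globular proteins in every way
that does not matter to these checks (no buried core, no real TRD
geometry, no substrate).

## 8. Numerical choices and degenerate inputs

* PDB parsing: first model of multi-model files; alternate locations
  resolved to highest occupancy, ties to the lowest altloc letter;
  author residue numbering preserved end-to-end (published mutant
  positions are quoted in author numbering).
* Coordinates parse to 0.001 Å (PDB fixed columns); PQR is
  whitespace-delimited with optional chain field.
* An all-zero potential pair has no defined similarity index — error,
  not NaN. An empty skin (δ = 0, or a grid that misses the molecule)
  is an error naming the remedy. A pairwise mask that comes out empty
  names the offending pair.
* Ramachandran regions are coarse rectangles (α and β favored cores, a
  left-handed α box favored only for glycine, 20° allowed margins);
  they classify an ideal helix as 100% favored and a (60°, −60°)
  non-glycine conformation as disallowed, but make no claim of
  agreement with density-based maps (PROCHECK-style percentages are
  not reproduced).
* Qres uses the Gaussian of CA–CA internal-distance differences with
  $\sigma_{ij} = |i-j|^{0.15}$ and excludes pairs closer than 3 in
  sequence; the gap-penalized $Q_H$ extension is not implemented.
* The p-distance machinery provides both pairwise and complete
  deletion because the source's supplementary table is ambiguous about
  which it used (it describes per-pair removal yet reports one final
  site count).

## 9. Known limitations

* The reduced charge model cannot see neutral-polar mutations or
  charge redistribution within a side chain.
* The sphere-union dielectric boundary underestimates burial for deep
  pockets; similarity values are comparable *within* a run of this
  package but not numerically interchangeable with APBS+PIPSA output.
* Stub mutants keep the wild-type backbone; conformational relaxation
  is out of scope.
* With two kinetic anchors the prediction spread is an interval, not a
  statistical error bar.
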