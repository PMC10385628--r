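---
title: "Methods: interface contacts, enrichment and influence zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface contacts, enrichment and influence zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactzones)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic fixtures do and do not demonstrate
about real data.

## The promolecule density model

All interface constructions run on *promolecule* densities: each atom
contributes a spherically averaged, non-interacting atomic density at its
nuclear position, and a molecule's density is the occupancy-weighted sum.
Per element the radial density is a sum of exponential shells,

$$\rho_{\mathrm{elem}}(r) = \sum_k c_k\, e^{-z_k r},$$

one shell per principal quantum shell. The decay constants $z_k$ (Å⁻¹) come
from Slater-screened effective nuclear charges, and each coefficient is
fixed as $c_k = n_k z_k^3 / 8\pi$ so the shell integrates *exactly* to its
$n_k$ electrons; hydrogen uses the exact ground-state density. The table
ships as plain text (`inst/extdata/promolecule_density.tsv`) and the
normalization is verified by quadrature in the test suite. This spherical
model replaces aspherical multipolar electron densities everywhere in the
package: the Hirshfeld construction is standardly defined on promolecule
densities, the spherical form is fully reproducible from a small table, and
the substitution is recorded in every output's provenance block. The cost is
that subtle density features (lone-pair anisotropy, bond density) are
absent, which shifts absolute surface areas slightly but leaves the
ratio-based contact statistics essentially untouched.

## Hirshfeld interface construction

The interface between sides $a$ and $b$ is the $w = 0.5$ level set of the
Hirshfeld weight $w = \rho_a/(\rho_a + \rho_b)$. The implementation:

1. samples $\rho_a$ and $\rho_b$ on a common regular grid (default spacing
   0.2 Å, margin 4 Å beyond the joint bounding box, both configurable);
2. extracts the level set by **marching tetrahedra**: each grid cube is
   split into six tetrahedra sharing a body diagonal and crossings are
   linearly interpolated along tetrahedron edges. The tetrahedral split was
   chosen over classic marching cubes because it has no ambiguous sign
   cases, so no case table is needed and the mesh is watertight by
   construction;
3. trims solvent-exposed surface: a facet is kept only where the electron
   density at its midpoint exceeds the cutoff (default 0.0013 e/Å³). By
   default the *total* density $\rho_a + \rho_b$ is tested; whether the
   original rule tests total or partner-side density is not documented
   anywhere we could verify, so the partner-side variant is available as
   `cutoff_on = "partner"` and the choice is recorded in the mesh metadata;
4. refines the trimmed rim: facets whose vertices/midpoint disagree about
   the cutoff are subdivided recursively (default depth 2, i.e. up to 16
   sub-facets) before the keep-by-midpoint rule is applied. This makes the
   retained area a midpoint-quadrature of the trimmed region whose rim error
   shrinks with subdivision, so area convergence under grid refinement is a
   property of the algorithm rather than of a particular fixture;
5. assigns each facet to the atom on either side with the largest individual
   density contribution at the midpoint (ties broken by atom order). The
   argmax-of-density rule is consistent with the density-partitioning spirit
   of the Hirshfeld construction; a nearest-atom alternative is available
   (`assign_rule = "nearest"`) and recorded in the metadata.

Degenerate inputs are contracts, not crashes: if no grid cell straddles
$w = 0.5$, or the cutoff removes everything, the result is an *empty* patch
set flagged `meta$empty`, because an empty interface is a legitimate answer
(e.g. two oxygens 3.2 Å apart have their entire bisector below the default
cutoff — oxygen density decays fast).

## Contact types and enrichment arithmetic

Atoms carry one of six types: `C` (carbon; sulfur is classed here too, as a
polarizable hydrophobic atom — the reference interface contains no sulfur),
`Hc` (hydrogen on carbon), `N` (nitrogen; the sp² peptide/guanidinium
nitrogens without a free lone pair are treated as hydrophobic, and a
per-atom override exists for nitrogens a user wants counted hydrophilic),
`Ho/n` (hydrogen on N or O), `O` (oxygen) and `W` (water oxygen; waters are
modelled as bare oxygens, so a `W` site subsumes its hydrogens). Typing
requires protonated models; a riding-hydrogen placer with
neutron-normalized X–H bond lengths (C–H 1.083, N–H 1.009, O–H 0.967 Å) is
provided for structures deposited without hydrogens.

With facet areas in hand, for each side $S_X$ is the percent of interface
area attributed to type $X$; $C_{XY}$ is the percent of area joining $X$ on
one side with $Y$ on the other, pooled over the unordered pair (the
convention that makes the contact table a single triangle); the
random-mixing expectation is the probability product
$R_{XY} = (S^a_X S^b_Y + S^a_Y S^b_X)/100$ (self-pairs
$R_{XX} = S^a_X S^b_X/100$); and the enrichment is $E = C/R$. $E$ is only
reported where $R$ exceeds 0.05 percentage points — below that the ratio is
noise — and undefined values are `NA` by default (printed as 0 in the
table-layout output, matching the usual presentation of impossible
self-contacts). Reports round shares to one decimal and enrichments to two.

The grouped summary sums member shares per class (hydrophobic
{C, Hc, N} vs hydrophilic {Ho/n, O, W}) and reapplies the same formulas. On
the packaged NRP1-b1/KDKPPR composition this arithmetic gives the
hydrophobic self-enrichment 1.26 and the hydrophilic self-enrichment 1.38;
published prose around the same table attaches those two numbers to the
opposite labels, which the arithmetic does not support — this package
follows the arithmetic and flags the discrepancy here rather than silently
relabelling.

## The random-mixing null and its calibration

`make_random_patches()` draws facet types on the two sides independently
from stated compositions — exactly the null hypothesis behind $R_{XY}$ — so
every well-defined enrichment should be statistically indistinguishable
from 1. The calibration test uses $n = 2\times10^5$ facets: for a pair with
$R = p$ (as a fraction), the sampling standard deviation of $E$ is
$\sqrt{p(1-p)/n}/p$, which at the reporting floor $p = 0.01$ is about 2.2%,
so the acceptance band $E \in [0.93, 1.07]$ is a ≥3σ bound for every
reported pair. At much smaller $n$ the same band would be only ~1σ at the
floor, which is why the generator default is deliberately large; the draw
costs milliseconds.

## Nucleophilic influence zones

The potential is the vacuum Coulomb sum $\phi(\mathbf r) = \sum_i q_i/|\mathbf
r - \mathbf r_i|$ in reduced units of e/Å (× 332.0637 for kcal·mol⁻¹·e⁻¹),
with the field evaluated analytically. There is no dielectric screening:
the influence zones are meant as a qualitative map of electrostatic
steering, and solvent screening would shrink but not re-route the basins'
topology near the protein surface. Field lines follow
$d\mathbf r/ds = \mathbf E/|\mathbf E|$ — the force direction on a positive
test charge, so lines run *toward* nucleophilic sites — integrated with
fixed-step RK4 (default 0.05 Å). Termination: entering the capture radius
of any atom (default 0.4 Å, applied to *every* atom so lines ending on
non-target nucleophiles are classified "other sink" instead of being forced
into a target basin), leaving the domain box (escaped), or field magnitude
below 1e-8 / arc length beyond 200 Å (stagnated; a start at an exact field
zero stagnates immediately). Seeds are the voxel centers of the analysis
grid outside any capture sphere; basin volume is voxel count × voxel
volume. None of the tracer settings are documented for the original
influence-zone software, so the defaults here were chosen by convergence
testing — the suite checks that halving the step relabels under 1% of
seeds and that mirror-symmetric systems give equal basin volumes — not
inherited from any reference. Ligand exclusion is a first-class parameter,
since influence zones are conventionally computed from the protein's field
with the ligand removed.

## Fluctuation analytics

Superposition is the SVD (Kabsch) solution restricted to proper rotations;
a reflection-favoring case is resolved to the best proper rotation.
`rmsd_series()` superposes each frame onto the reference on the stated
selection (typically backbone heavy atoms) and reports the selection RMSD —
the standard trajectory drift monitor. `rmsf()` first aligns all frames on
the backbone (or a user selection) onto the first frame, then measures each
atom's root mean square excursion; the fluctuation center is the ensemble
mean position by default, with `about = "reference"` available because
published legends often fix the *alignment* reference without stating the
*fluctuation* center. `rmstd_from_b()` implements
$\mathrm{RMSTD} = \sqrt{B/8\pi^2}$ exactly, with the exact inverse.
Per-residue profiles use Cα atoms and skip (with a warning) residues
lacking one. Profile agreement uses plain Pearson correlation.

For an isotropic Gaussian ensemble with per-coordinate σ the population RMSF
is $\sigma\sqrt3$; the suite verifies recovery within 5% at σ = 0.2 Å and
2000 frames. Alignment consumes six rigid-body degrees of freedom and
deflates the measured RMSF by roughly $\sqrt{1 - 6/3N}$ for $N$ aligned
atoms (~2% at $N = 50$), which is inside that tolerance and is why the
fixture uses dozens of atoms rather than a handful.

## Isoelectric points

`isoelectric_point()` solves for zero Henderson–Hasselbalch net charge by
bisection. The bracket (not just the charge) is converged, because around
the pI the charge curve is nearly flat whenever all pKa values are remote
from the root — a two-group peptide like GG illustrates this: its pI is the
midpoint of the terminal pKa values, yet the net charge within ±0.1 pH of it
is already below 1e-4. The shipped pKa set is the EMBOSS table; since pI
estimates are pKa-set dependent, results should be quoted with the set name,
and custom named vectors are accepted.

## What the synthetic fixtures do and do not show

The generators emulate the *structural* ingredients the analyses consume:
known interface geometry (two-atom complexes, where the interface is an
exact bisector plane), controlled chemical composition (random complexes and
patch draws), known field-line topology (monopole/dipole/mirror charge
systems) and known positional statistics (Gaussian ensembles). Passing tests
therefore demonstrate correctness of the geometry, the counting and the
estimators. They do not demonstrate chemical realism: random complexes have
no covalent structure, Gaussian ensembles have no correlated motions, and
point charges have no multipolar anisotropy or solvent screening. Claims
about a real protein–peptide complex should rest on the deposited-structure
pipeline (`run_enrich()` on a protonated model), not on the fixtures.

## Problem sizes and defaults

The suite and the acceptance script run at desk scale by design: interface
grids of ~10⁵–10⁶ voxels (0.1–0.3 Å spacing on Å-sized fixtures), 2×10⁵
null facets, 16³ tracer seed grids, 2000-frame ensembles of 50 atoms. All
are generator parameters, so larger studies only change arguments, not
code.

## Known limitations

* Spherical promolecule densities and unscreened point charges are
  deliberate simplifications; absolute areas, potentials and basin extents
  inherit their bias, ratios and topologies much less so.
* Crystallographic symmetry expansion is out of scope: contact listings and
  interfaces see only the chains supplied, so packing analyses require
  pre-expanded coordinates.
* Hydrogen placement is geometric (riding, arbitrary torsions at terminal
  sites) and does not predict protonation states or rotamer flips.
* Binary trajectory formats are not read; ensembles come from multi-model
  PDB (an adapter to `mol_ensemble` is a one-line `array` call for anything
  else).
* Fingerprint (d_i/d_e) plots and interfaces among more than two bodies are
  not implemented.
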