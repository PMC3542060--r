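---
title: "molcraft: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molcraft: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

molcraft is a headless molecular editing and analysis core: an editable
molecule document, chemical file I/O, editor semantics (valence-driven
hydrogen adjustment, bond-order cycling, fragment insertion), measurement
and bond-centric geometry manipulation, Gaussian-orbital evaluation from
formatted-checkpoint output, marching-cubes isosurface extraction, and
scene export for ray tracing. This vignette records the models behind each
piece, the conventions the package commits to, and the numerical choices a
maintainer would otherwise have to reverse-engineer.

## The molecule document

A `molecule` is an environment-backed S3 object with reference semantics:
editing operations (`add_atom()`, `add_bond()`, `remove_atom()`,
`adjust_hydrogens()`, the `set_*` geometry edits) mutate the document in
place and return the handle the caller needs — an id or a count — exactly
as an interactive editor would. This was a deliberate departure from R's
usual copy-on-modify style: the API is a transcript of editor gestures, and
returning a whole new molecule from every gesture would force the caller to
thread state through each call while discarding the natural return value
(the new atom's id). `clone_molecule()` restores value semantics when a
snapshot is needed.

Ids are write-once and monotonically assigned, never recycled. A held id
therefore either still resolves or fails loudly; there is no way to
silently alias a deleted atom. Removing an atom removes every incident
bond, so bond endpoints always resolve — the test suite fuzzes this with
random edit scripts.

Coordinates are Cartesian Angstrom everywhere in the document; fractional
coordinates exist only transiently inside the supercell construction. The
quantum layer works in Bohr internally, and the single conversion constant
(0.52917721067 A/Bohr) lives in one place.

Embedded element data: IUPAC standard atomic weights (5 decimals), the
Cordero 2008 covalent radii (hence r_cov(H) = 0.31 A), Bondi van der Waals
radii, and the CPK-style display palette. Bond perception adds a single
bond wherever the interatomic distance is below the covalent-radius sum
plus a tolerance; the 0.45 A default is the common heuristic and is
exposed as an argument. Elements past barium fall back to conservative
defaults (1.50 / 1.70 A) — adequate for display and perception, not for
metrology.

## Valence model and hydrogen placement

The hydrogen adjuster targets the neutral lowest-common valences
(H 1, B 3, C 4, N 3, O 2, F 1, Si 4, P 3, S 2, halogens 1); any element
without an entry has target 0 and is never touched. Formal charges are
deliberately ignored: the rule reproduces the simple editor behaviour, and
charged or hypervalent species (S(VI), P(V)) are out of scope — the table
keeps the lowest common valence rather than guessing.

The deficiency of an atom is its target valence minus its order-weighted
bond sum, so a double bond counts twice. Deficient atoms gain single-bonded
hydrogens at tabulated X–H distances (C–H 1.09, N–H 1.01, O–H 0.96 A,
1.00 A otherwise); over-bonded atoms lose hydrogen neighbours, highest id
first, which makes removal deterministic. New directions come from
idealized templates chosen by steric number (existing neighbours plus
slots): tetrahedral, trigonal, linear. With existing neighbours the
template is rotated onto them by a Kabsch alignment (SVD with the
determinant forced positive), and the unused template slots become the new
bond directions. Lone pairs are not modelled, so a bare oxygen receives
linearly opposed hydrogens; fixtures that need textbook geometry (water at
104.5 degrees) construct it explicitly. The adjuster is idempotent — a
second pass is a no-op — and that property is tested on every fixture.

## Geometry operations

Measurements are the standard Euclidean definitions; the dihedral is
signed by the right-hand rule about the b–c axis and reported in
(−180, 180]. Degenerate inputs (coincident points, collinear dihedral
frames) raise errors rather than returning NaN, because a silent NaN in a
pipeline is far harder to find than an early failure.

Bond-centric edits move one rigid side: the fragment reachable from the
later-listed atom without crossing the manipulated bond. When the bond lies
in a ring the graph does not split, and only the named atom moves — the
least surprising deterministic fallback. Set-then-measure closes to 1e-6
or better; this is the invariant the implementation is written against.
One subtlety recorded here because it cost a sign error once: a positive
right-hand rotation of the far side about b→c *decreases* the measured
torsion, so `set_dihedral()` rotates by (current − target).

`align()` applies a proper rigid transform (Rodrigues rotation plus
translation); all pairwise distances are preserved to 1e-9 and the
operation is idempotent.

## Quantum evaluation

The checkpoint parser reads the fixed-layout key/value sections and
supports shell type codes 0 (s), 1 (p), −1 (sp, split into an s and a p
shell sharing exponents), 2 (Cartesian d) and −2 (pure d). Anything higher
is rejected with an explicit "not supported" error — honest scope, not an
approximation. Open-shell data is likewise rejected; occupations are
closed-shell, two electrons in each of the lowest n/2 orbitals.

Each primitive is normalized as

N = (2a/pi)^(3/4) * sqrt((8a)^L l! m! n! / ((2l)! (2m)! (2n)!)),

and the contraction is then renormalized analytically so the contracted
function has unit self-overlap (checkpoint contraction coefficients assume
normalized primitives). The renormalization factor is component-
independent within a shell, so one representative component suffices.
Cartesian d components follow the checkpoint order XX, YY, ZZ, XY, XZ, YZ;
pure d functions are the standard combinations of the *normalized*
Cartesians —

d(z2) = zz − (xx + yy)/2, d(xz) = xz, d(yz) = yz,
d(x2−y2) = (sqrt(3)/2)(xx − yy), d(xy) = xy

— in the order z2, xz, yz, x2−y2, xy. The coefficients are fixed by
requiring unit norm given the Cartesian overlap structure, and the whole
convention is pinned by an oracle test: pure-d values must equal the
explicit user-level Cartesian combination at random points to 1e-10.

Orbitals are the LCAO sum psi_i = sum_mu C[mu, i] phi_mu, the density the
closed-shell sum rho = 2 sum_occ psi_i^2. Every grid point is an
independent pure evaluation, so `generate_cube()` may partition the grid
into slabs and schedule them in any order (or across forked workers)
without changing a single bit of the output — asserted bitwise in the
tests. The default grid is the atom bounding box padded by 3 A at 0.2 A
spacing, with a 2-point minimum per axis for degenerate extents.

Slater-type orbitals (for codes that use them) are evaluated as
R(r) Y_lm with R = N r^(n−1) exp(−zeta r), N = (2 zeta)^(n+1/2) /
sqrt((2n)!), and real spherical harmonics up to l = 2.

Validation quadrature uses the midpoint rule on a 96^3 grid over a
10-Bohr box — cheap enough to run in the routine suite, fine enough that
every basis function integrates to 1 within 1e-3 and the H2 fixture
density holds 2.00 +/- 0.02 electrons.

## Marching cubes

The extractor is the classic per-cell algorithm: the 8-corner
inside/outside pattern (inside means value >= isovalue; exact ties count
as inside, for determinism) indexes a 256-case triangle table; vertices
are placed on cell edges by linear interpolation t = (iso − v1)/(v2 − v1).
The corner and edge numbering is documented in a comment block at the top
of the implementation.

Rather than transcribing the published 256-entry table, the package
derives it at first use from the cell topology: on every face the surface
chords pair up the cut edges so that the below-isovalue corners are
isolated, cut edges then chain into closed loops (each cut edge is paired
on exactly two faces), and each loop is fan-triangulated with the
orientation chosen toward the outside region. Because the chord rule is a
pure function of the face pattern, two cells sharing a face always agree
on it — including the two ambiguous face patterns — so the mesh is
watertight by construction. This is the same case semantics as the classic
table with a uniform ambiguity resolution instead of the table's mixed
one; no asymptotic decider is applied, which at the smooth-field,
fine-grid operating point (molecular orbitals at 0.2 A spacing, default
display isovalue 0.02) is a documented limitation rather than an error
source. The implementation is equivalence-tested against an independent
reference implementation on random smooth fields (vertex-set Hausdorff
distance under half a voxel).

Shared vertices are produced by keying vertices on global grid edges, so
watertightness and the Euler characteristic (V − E + F = 2 for the sphere
test) hold exactly, not after welding. Triangles with area below 1e-12 are
dropped. Normals are central-difference gradients, trilinearly
interpolated at the vertices, normalized and oriented toward decreasing
scalar value; a vanishing gradient falls back to the incident-triangle
average.

Convergence behaviour on the analytic sphere field: area error 0.09 % at
64^3 and 0.02 % at 128^3 — the expected roughly quadratic decay.

## Scenes and export

`build_scene()` implements the four standard representations. Defaults a
practitioner would want to know: ball-and-stick spheres at 0.25 x the van
der Waals radius (exposed as `ball_scale`), stick radius 0.12 A, double
and triple bonds as parallel cylinders offset 0.15 A in the plane of the
bond and the Cartesian axis least aligned with it (deterministic, so
exports are reproducible), every bond cylinder split at the midpoint so
each half carries its atom's color. The camera looks down −z at the
centroid from 2.5 bounding radii.

Color schemes: the element palette; index and distance through a linear
blue-to-red gradient normalized to the observed range (a degenerate range
maps to the blue end); partial charge through a red-white-blue diverging
map centered at zero; a constant custom color; and an explicit atom-id
selection color. Pattern-based (substructure-query) coloring was
deliberately replaced by the id-set variant: matching needs a
cheminformatics engine and is out of scope, while the testable core — color
a chosen subset — survives.

POV-Ray output is deterministic text with fixed 6-decimal numbers;
opacity below 1 becomes a `transmit` term. The writers emit `\n` endings
and C-locale numbers only.

## File formats

CML is the native document format. The dialect is the minimal molecular
convention subset — `<atom id elementType x3 y3 z3 [formalCharge]>`,
`<bond atomRefs2 order>` with orders "1"/"2"/"3" — and any other child of
`<molecule>` is preserved verbatim across a read/write cycle, honouring
the format's extensibility without interpreting what it carries. No
namespace or schema version is claimed; the subset is documented here
instead of guessed. Cube files follow the de-facto dialect (two comment
lines, Bohr geometry, values six per line in scientific notation with the
first axis outermost and the third innermost), and the negative-atom-count
header convention for orbital cubes is read and written. The PDB reader is
a fixed-column ATOM/HETATM subset with element inference from the atom
name when columns 77–78 are empty; connectivity, altlocs and models are
out of scope. Input-deck generation is a thin deterministic template in
two style families — enough to preview and diff, deliberately not a job
manager.

## Fixtures and what passing tests show

All test inputs are generated in code: textbook molecules at idealized
geometries, analytic scalar fields, seeded random tree-connected molecules
(a self-contained linear congruential stream, so R's global random state
is never touched), and a minimal H2 checkpoint whose two MO coefficient
vectors are the symmetry-forced +/- 1/sqrt(2(1 +/- S)) with the overlap S
computed analytically from the Gaussian product formula at generation
time. The embedded three-Gaussian hydrogen contraction is the familiar
minimal-basis fit to a unit-exponent Slater function.

This emulates the *structure* of quantum output — layout, shell codes,
unit conventions, coefficient ordering — with orbitals that are exact in
the idealized two-function model. It does not emulate an SCF calculation:
there is no Fock operator, no correlation, no convergence noise, and no
real-world checkpoint quirks (extra sections, unusual orderings from other
codes). Passing the electron-conservation and orthonormality checks
therefore validates the evaluation pipeline, not any quantum chemistry;
conversely, a real checkpoint that parses will be evaluated with exactly
the conventions stated above.

## Known limitations

- f and g shells, open-shell densities, and non-checkpoint quantum output
  formats are rejected, not approximated.
- The valence table is neutral and lowest-common; formal charge does not
  shift targets.
- Marching cubes uses uniform chord-based ambiguity resolution; thin
  features near the sampling limit can still be topologically wrong, as
  with any non-decider marching cubes.
- The PDB subset ignores CONECT records; run `perceive_bonds()` if
  connectivity is needed.
- Supercell replication bonds within images only; cross-image bonds are a
  `perceive_bonds()` call away but are not created implicitly.
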