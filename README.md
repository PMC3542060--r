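# molcraft

A headless molecular editing, analysis and visualization-export core for
R. It is aimed at computational chemists and tool builders who want the
*engine* of a molecular editor — the semantic molecule document, the file
formats, the quantum-output evaluation and the isosurface machinery —
available as scriptable library calls and a small CLI, with no graphical
stack attached.

What it covers:

- **Molecule document** — atoms, bonds, optional crystallographic unit
  cell; stable ids; formula (Hill order), weight, supercell replication,
  covalent-radius bond perception.
- **File I/O** — CML (native, with verbatim preservation of unknown
  elements), XYZ, Gaussian cube (including the negative-atom-count
  orbital convention), a minimal PDB subset, and deterministic quantum
  input-deck templates.
- **Editor semantics** — valence-driven hydrogen adjustment, bond-order
  cycling (1 → 2 → 3 → 1), element mutation, fragment insertion from a
  built-in library.
- **Geometry** — distance / angle / signed dihedral, rigid alignment to
  the coordinate frame, bond-centric edits (set a length, angle or
  torsion; the fragment on the far side moves as a rigid unit), property
  tables.
- **Quantum evaluation** — Gaussian formatted-checkpoint parsing (s, p,
  sp, Cartesian d, pure d), molecular orbitals and electron density at
  arbitrary points, cube-grid generation whose output is bitwise
  independent of worker count, Slater-type orbitals.
- **Surfaces** — marching-cubes isosurface extraction with shared
  vertices (watertight meshes), gradient normals, mesh diagnostics, OBJ
  export.
- **Scene export** — ball-and-stick / stick / wireframe / van der Waals
  scenes with element, index, distance, charge and custom color schemes,
  written as deterministic POV-Ray text.

## The core model

A molecular orbital is the standard LCAO expansion over contracted
Gaussian basis functions,

    psi_i(r) = sum_mu C[mu, i] phi_mu(r),
    phi_mu(r) = sum_k c_k N_k x^l y^m z^n exp(-a_k r^2),

with per-primitive normalization
`N = (2a/pi)^(3/4) sqrt((8a)^L l! m! n! / ((2l)!(2m)!(2n)!))` and an
analytic contraction renormalization; the closed-shell density is
`rho = 2 sum_occ psi_i^2`. Scalar fields evaluated on a regular grid are
turned into triangle meshes by the classic 256-case marching-cubes
algorithm with linear edge interpolation and gradient normals. Every
convention that such a pipeline needs pinned down (Cartesian d order,
pure-d combinations, cube-file nesting, Bohr/Angstrom boundaries) is
documented in `vignettes/molcraft-methods.Rmd` and enforced by oracle
tests.

## Worked example

From hydrogen checkpoint to a watertight density isosurface:

```r
library(molcraft)

w <- make_molecule("water")
w
#> <molecule> 'water'
#>   3 atoms, 2 bonds
#>   formula H2O, weight 18.015 g/mol
property_tables(w)$angles
#>   a b c degrees
#> 1 2 1 3   104.5

p <- parse_fchk(make_h2_fchk())          # 2 basis functions, 2 MOs
g <- default_grid(p$molecule, padding = 3, spacing = 0.2)
cube <- generate_cube(p$basis, p$mos, "density", g)
cube
#> <volgrid> 31 x 31 x 35 points (angstrom)
#>   values in [2.14289e-17, 0.355025]

mesh <- marching_cubes(cube, 0.02)
mesh
#> <trimesh> 406 vertices, 808 triangles (iso = 0.02)
mesh_stats(mesh)[c("area", "watertight")]
#> $area
#> [1] 10.75203
#> $watertight
#> [1] TRUE
```

The density peaks at 0.355 electrons/Bohr^3 between the nuclei, and the
0.02 isosurface is a single closed surface of about 10.8 A^2 wrapping the
bond. The same pipeline is available from a shell via the wrapper in
`inst/cli/`:

```sh
molcraft cube h2.fchk --density -o rho.cube
molcraft isosurface rho.cube --iso 0.02 -o rho.obj
molcraft render water.cml --rep ballstick -o water.pov
```

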