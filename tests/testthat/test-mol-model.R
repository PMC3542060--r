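test_that("atoms and bonds are created with stable, never-recycled ids", {
  m <- molecule()
  a <- add_atom(m, 6, c(0, 0, 0))
  expect_equal(n_atoms(m), 1)
  expect_equal(n_bonds(m), 0)
  b <- add_atom(m, 6, c(1.5, 0, 0))
  expect_false(a == b)
  expect_error(add_atom(m, 0, c(0, 0, 0)), "atomic number")
  expect_error(add_atom(m, 6, c(0, 0, Inf)), "finite")

  bd <- add_bond(m, a, b, 1L)
  expect_equal(n_bonds(m), 1)
  expect_error(add_bond(m, a, a), "itself")
  expect_error(add_bond(m, b, a), "already bonded")
  expect_error(add_bond(m, a, 999L), "no atom")

  remove_atom(m, b)
  c_ <- add_atom(m, 8, c(2, 0, 0))
  expect_gt(c_, b)  # ids are write-once and monotone
})

test_that("removing an atom removes every incident bond", {
  m <- make_molecule("ethane")
  expect_equal(n_bonds(m), 7)
  # brute-force count of bonds incident to the first carbon
  incident <- sum(bonds(m)$a1 == 1 | bonds(m)$a2 == 1)
  expect_equal(incident, 4)
  remove_atom(m, 1)
  expect_equal(n_bonds(m), 7 - incident)
  expect_error(remove_atom(m, 99L), "no atom")

  single <- molecule()
  id <- add_atom(single, 2, c(0, 0, 0))
  remove_atom(single, id)
  expect_equal(n_atoms(single), 0)
})

test_that("referential integrity holds under random edit scripts", {
  rng <- 0
  for (seed in 1:5) {
    m <- make_random_molecule(seed, 8)
    set.seed(seed)
    for (step in 1:40) {
      op <- sample(3, 1)
      if (op == 1) {
        add_atom(m, sample(c(1, 6, 7, 8), 1), rnorm(3, sd = 4))
      } else if (op == 2 && n_atoms(m) > 1) {
        ids <- sample(atoms(m)$id, 2)
        key <- paste(min(ids), max(ids))
        if (!key %in% paste(bonds(m)$a1, bonds(m)$a2)) {
          add_bond(m, ids[1], ids[2], sample(3, 1))
        }
      } else if (op == 3 && n_atoms(m) > 1) {
        remove_atom(m, sample(atoms(m)$id, 1))
      }
      expect_true(all(bonds(m)$a1 %in% atoms(m)$id))
      expect_true(all(bonds(m)$a2 %in% atoms(m)$id))
      expect_false(any(duplicated(atoms(m)$id)))
      expect_false(any(duplicated(paste(bonds(m)$a1, bonds(m)$a2))))
    }
  }
})

test_that("molecular formula follows Hill order and weight sums masses", {
  expect_equal(molecular_formula(make_molecule("water")), "H2O")
  expect_equal(molecular_weight(make_molecule("water")), 18.015,
               tolerance = 0.01 / 18)
  expect_equal(molecular_formula(make_molecule("glycine")), "C2H5NO2")
  empty <- molecule()
  expect_equal(molecular_formula(empty), "")
  expect_equal(molecular_weight(empty), 0)
  # no carbon -> purely alphabetical
  m <- molecule()
  add_atom(m, 17, c(0, 0, 0)); add_atom(m, 11, c(2.4, 0, 0))
  expect_equal(molecular_formula(m), "ClNa")
})

test_that("molecular weight is additive over disconnected fragments", {
  a <- make_molecule("water")
  b <- make_molecule("methane")
  both <- molecule()
  insert_fragment(both, a)
  insert_fragment(both, b, c(20, 0, 0))
  expect_equal(molecular_weight(both),
               molecular_weight(a) + molecular_weight(b))
})

test_that("supercell replication scales counts and lattice exactly", {
  m <- make_molecule("water")
  expect_error(build_supercell(m, 2, 2, 2), "unit cell")
  set_unit_cell(m, 3, 4, 5, 90, 90, 90)
  sc <- build_supercell(m, 2, 2, 2)
  expect_equal(n_atoms(sc), 8 * n_atoms(m))
  expect_equal(n_bonds(sc), 8 * n_bonds(m))

  idm <- build_supercell(m, 1, 1, 1)
  expect_equal(atom_positions(idm), atom_positions(m),
               ignore_attr = TRUE)

  sc2 <- build_supercell(m, 2, 1, 1)
  expect_equal(unit_cell(sc2)$a, 6)
  expect_equal(unit_cell(sc2)$b, 4)
  expect_equal(unit_cell(sc2)$c, 5)

  # stoichiometry scales exactly per element
  counts <- table(atoms(m)$number)
  counts_sc <- table(atoms(sc)$number)
  expect_equal(as.vector(counts_sc), 8 * as.vector(counts))
})

test_that("bond perception uses covalent radii plus tolerance", {
  m <- molecule()
  add_atom(m, 1, c(0, 0, 0)); add_atom(m, 1, c(0.74, 0, 0))
  expect_equal(perceive_bonds(m, tolerance = 0.45), 1L)
  expect_equal(perceive_bonds(m, tolerance = 0.45), 0L)  # no duplicates

  far <- molecule()
  add_atom(far, 1, c(0, 0, 0)); add_atom(far, 1, c(5, 0, 0))
  expect_equal(perceive_bonds(far), 0L)

  # 0.74 > 2 * 0.31 + 0.1, so a tight tolerance finds nothing
  tight <- molecule()
  add_atom(tight, 1, c(0, 0, 0)); add_atom(tight, 1, c(0.74, 0, 0))
  expect_equal(perceive_bonds(tight, tolerance = 0.1), 0L)
})

test_that("bond perception is invariant under rigid motion and atom order", {
  set.seed(11)
  base <- make_random_molecule(3, 8)
  ref <- clone_molecule(base)
  ref$bonds <- ref$bonds[0, ]
  n_ref <- perceive_bonds(ref)
  for (k in 1:5) {
    tf <- random_rigid_transform()
    moved <- apply_rigid(base, tf)
    moved$bonds <- moved$bonds[0, ]
    expect_equal(perceive_bonds(moved), n_ref)
  }
})
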