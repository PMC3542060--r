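bare <- function(z) {
  m <- molecule()
  add_atom(m, z, c(0, 0, 0))
  m
}

test_that("hydrogen adjustment reaches the target valence", {
  cases <- list(c(6, 4), c(7, 3), c(8, 2), c(9, 1), c(16, 2))
  for (cs in cases) {
    m <- bare(cs[1])
    res <- adjust_hydrogens(m)
    expect_equal(unname(res["added"]), cs[2])
    expect_equal(n_atoms(m), 1 + cs[2])
    expect_equal(molcraft:::order_sum(m, 1), cs[2])
    # hydrogens are placed at the tabulated X-H distance
    for (h in molcraft:::neighbor_ids(m, 1)) {
      exp_len <- unname(c(`6` = 1.09, `7` = 1.01,
                          `8` = 0.96)[as.character(cs[1])])
      if (is.na(exp_len)) exp_len <- 1.0
      expect_equal(distance(m, 1, h), exp_len, tolerance = 1e-9)
    }
  }
  # an element without a valence entry is untouched
  fe <- bare(26)
  expect_equal(unname(adjust_hydrogens(fe)), c(0L, 0L))
  expect_equal(n_atoms(fe), 1)
})

test_that("double bonds count toward valence (ethene skeleton)", {
  m <- molecule()
  c1 <- add_atom(m, 6, c(0, 0, 0))
  c2 <- add_atom(m, 6, c(1.34, 0, 0))
  add_bond(m, c1, c2, 2L)
  res <- adjust_hydrogens(m)
  expect_equal(unname(res["added"]), 4L)
  expect_equal(molecular_formula(m), "C2H4")
})

test_that("excess hydrogens are removed highest id first", {
  m <- molecule()
  c1 <- add_atom(m, 6, c(0, 0, 0))
  hs <- integer(5)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1))
  for (i in 1:5) {
    hs[i] <- add_atom(m, 1, 1.09 * dirs[i, ])
    add_bond(m, c1, hs[i])
  }
  res <- adjust_hydrogens(m, c1)
  expect_equal(unname(res["removed"]), 1L)
  expect_false(max(hs) %in% atoms(m)$id)
  expect_true(all(hs[1:4] %in% atoms(m)$id))
})

test_that("hydrogen adjustment is idempotent", {
  for (name in c("water", "methane", "benzene", "glycine")) {
    m <- make_molecule(name)
    first <- adjust_hydrogens(m)
    expect_equal(unname(adjust_hydrogens(m)), c(0L, 0L))
  }
  skel <- bare(6)
  adjust_hydrogens(skel)
  expect_equal(unname(adjust_hydrogens(skel)), c(0L, 0L))
})

test_that("bond order cycling has period three", {
  m <- make_molecule("h2")
  expect_equal(cycle_bond_order(m, 1), 2L)
  expect_equal(cycle_bond_order(m, 1), 3L)
  expect_equal(cycle_bond_order(m, 1), 1L)
  expect_error(cycle_bond_order(m, 99), "no bond")
})

test_that("element change keeps geometry and connectivity", {
  m <- make_molecule("water")
  before <- atom_positions(m)
  change_element(m, 1, 16)
  expect_equal(molecular_formula(m), "H2S")
  expect_equal(atom_positions(m), before, ignore_attr = TRUE)
  expect_equal(n_bonds(m), 2)
  change_element(m, 1, 16)  # same element: no-op
  expect_equal(molecular_formula(m), "H2S")
  expect_error(change_element(m, 99, 6), "no atom")
  expect_error(change_element(m, 1, 200), "atomic number")
})

test_that("fragment insertion appends fresh disjoint ids at the offset", {
  m <- molecule()
  ids1 <- insert_fragment(m, fragment_library("benzene"))
  expect_length(ids1, 12)
  expect_equal(n_bonds(m), 12)

  frag <- make_molecule("water")
  cen0 <- colMeans(atom_positions(frag))
  ids2 <- insert_fragment(m, frag, c(10, 0, 0))
  expect_length(intersect(ids1, ids2), 0)
  cen1 <- colMeans(atom_positions(m)[as.character(ids2), ])
  expect_equal(unname(cen1 - cen0), c(10, 0, 0), tolerance = 1e-12)

  # removing the inserted atoms restores the original exactly
  before <- molecule()
  insert_fragment(before, fragment_library("benzene"))
  after <- clone_molecule(m)
  for (id in ids2) remove_atom(after, id)
  expect_equal(atoms(after)[, -1], atoms(before)[, -1], ignore_attr = TRUE)
  expect_equal(n_bonds(after), n_bonds(before))
})

test_that("the fragment library loads and every entry is well-formed", {
  names <- fragment_library()
  expect_gte(length(names), 5)
  for (nm in names) {
    frag <- fragment_library(nm)
    expect_s3_class(frag, "molecule")
    expect_gt(n_atoms(frag), 0)
    expect_true(all(bonds(frag)$a1 %in% atoms(frag)$id))
    expect_true(all(bonds(frag)$a2 %in% atoms(frag)$id))
  }
  expect_error(fragment_library("kryptonite"), "unknown")
})
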