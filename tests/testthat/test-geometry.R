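test_that("distance, angle and dihedral follow their definitions", {
  m <- molecule()
  a <- add_atom(m, 6, c(0, 0, 0))
  b <- add_atom(m, 6, c(1, 0, 0))
  c_ <- add_atom(m, 6, c(1, 1, 0))
  expect_equal(distance(m, a, b), 1)
  expect_equal(angle(m, a, b, c_), 90)

  lin <- molecule()
  for (x in 0:2) add_atom(lin, 6, c(x, 0, 0))
  expect_equal(angle(lin, 1, 2, 3), 180)

  # dihedral against an independent two-plane-normal oracle
  m4 <- molecule()
  p <- rbind(c(0.2, 1.1, -0.3), c(0, 0, 0), c(1.5, 0.1, 0.2),
             c(2.0, 1.2, 1.1))
  for (i in 1:4) add_atom(m4, 6, p[i, ])
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  # magnitude from the two plane normals, sign from the right-hand rule
  # about b -> c
  mag <- acos(sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))) * 180 / pi
  oracle <- sign(sum(cr(n2, n1) * b2)) * mag
  expect_equal(dihedral(m4, 1, 2, 3, 4), oracle, tolerance = 1e-9)

  co <- molecule()
  add_atom(co, 6, c(0, 0, 0)); add_atom(co, 6, c(0, 0, 0))
  expect_error(distance(co, 1, 1), "distinct")
  expect_error(angle(co, 1, 2, 1), "distinct")
  collin <- molecule()
  for (x in 0:3) add_atom(collin, 6, c(x, 0, 0))
  expect_error(dihedral(collin, 1, 2, 3, 4), "collinear")
})

test_that("measurements are invariant under random rigid transforms", {
  set.seed(99)
  m <- make_molecule("glycine")
  d0 <- distance(m, 1, 2)
  a0 <- angle(m, 1, 2, 3)
  t0 <- dihedral(m, 1, 2, 3, 4)
  for (k in 1:100) {
    tf <- random_rigid_transform()
    moved <- apply_rigid(m, tf)
    expect_equal(distance(moved, 1, 2), d0, tolerance = 1e-9)
    expect_equal(angle(moved, 1, 2, 3), a0, tolerance = 1e-9)
    expect_lt(ang_diff(dihedral(moved, 1, 2, 3, 4), t0), 1e-9)
  }
})

test_that("alignment puts atom1 at the origin and atom2 on the axis", {
  h2 <- make_molecule("h2")
  tf <- align(h2, 1, 2, "z")
  expect_lt(max(abs(atom_positions(h2)[1, ])), 1e-9)
  expect_equal(unname(atom_positions(h2)[2, ]), c(0, 0, 0.74),
               tolerance = 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)

  g <- make_molecule("glycine")
  before <- as.matrix(dist(atom_positions(g)))
  align(g, 3, 7, "x")
  expect_lt(max(abs(atom_positions(g)[3, ])), 1e-9)
  p2 <- atom_positions(g)[7, ]
  expect_gt(p2[1], 0)
  expect_lt(max(abs(p2[2:3])), 1e-9)
  after <- as.matrix(dist(atom_positions(g)))
  expect_lt(max(abs(after - before)), 1e-9)

  # idempotence
  snap <- atom_positions(g)
  align(g, 3, 7, "x")
  expect_lt(max(abs(atom_positions(g) - snap)), 1e-9)

  co <- molecule()
  add_atom(co, 6, c(1, 1, 1)); add_atom(co, 6, c(1, 1, 1))
  expect_error(align(co, 1, 2, "z"), "coincident")
  single <- molecule()
  add_atom(single, 6, c(3, -2, 5))
  align(single, 1)
  expect_lt(max(abs(atom_positions(single))), 1e-9)
})

test_that("set-then-measure identities hold for bond-centric edits", {
  h2 <- make_molecule("h2")
  set_bond_length(h2, 1, 1.0)
  expect_equal(distance(h2, 1, 2), 1.0, tolerance = 1e-6)
  expect_error(set_bond_length(h2, 1, -1), "positive")

  w <- make_molecule("water")
  set_angle(w, 2, 1, 3, 104.5)
  expect_equal(angle(w, 2, 1, 3), 104.5, tolerance = 1e-6)
  set_angle(w, 2, 1, 3, 38.2)
  expect_equal(angle(w, 2, 1, 3), 38.2, tolerance = 1e-6)

  e <- make_molecule("ethane")
  for (target in c(60, -60, 175, 0.5)) {
    set_dihedral(e, 3, 1, 2, 6, target)
    expect_equal(dihedral(e, 3, 1, 2, 6), target, tolerance = 1e-6)
  }
})

test_that("the moving side is the fragment holding the later-listed atom", {
  e <- make_molecule("ethane")
  p_c1_h <- atom_positions(e)[3, ]
  set_bond_length(e, 1, 2.0)  # stretch C-C; side of atom2 (second C) moves
  expect_equal(unname(atom_positions(e)[3, ]), unname(p_c1_h))
  expect_equal(distance(e, 1, 2), 2.0, tolerance = 1e-9)
  # hydrogens of the moved carbon kept their internal geometry
  expect_equal(distance(e, 2, 6), 1.09, tolerance = 1e-9)

  # in a ring only the named atom (the bond's second atom) moves
  ring <- make_molecule("benzene")
  others <- atom_positions(ring)[as.character(3:12), ]
  ring_bond <- bonds(ring)$id[bonds(ring)$a1 == 1 & bonds(ring)$a2 == 2]
  p2_before <- atom_positions(ring)["2", ]
  set_bond_length(ring, ring_bond, 1.6)
  expect_equal(distance(ring, 1, 2), 1.6, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(atom_positions(ring)["2", ], p2_before)))
  after <- atom_positions(ring)[as.character(3:12), ]
  expect_equal(after, others, tolerance = 1e-12)
})

test_that("property tables enumerate bonds, angles and torsions once", {
  w <- property_tables(make_molecule("water"))
  expect_equal(nrow(w$bonds), 2)
  expect_equal(nrow(w$angles), 1)
  expect_equal(nrow(w$torsions), 0)
  expect_equal(w$molecule$formula, "H2O")

  me <- property_tables(make_molecule("methane"))
  expect_equal(nrow(me$bonds), 4)
  expect_equal(nrow(me$angles), choose(4, 2))

  et <- property_tables(make_molecule("ethane"))
  expect_equal(nrow(et$torsions), 9)
  # canonical angle rows: first flank smaller than last
  expect_true(all(et$angles$a < et$angles$c))
  expect_false(any(duplicated(et$angles[, c("a", "b", "c")])))
})
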