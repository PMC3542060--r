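test_that("the H2 checkpoint fixture parses to the documented layout", {
  p <- parse_fchk(make_h2_fchk())
  expect_equal(n_atoms(p$molecule), 2)
  expect_length(p$basis$shells, 2)
  expect_equal(p$basis$nbf, 2)
  expect_equal(p$mos$n_mo, 2)
  expect_equal(distance(p$molecule, 1, 2), 0.74, tolerance = 1e-6)
  # generated coefficients satisfy c^2 * 2 (1 + S) = 1 by construction
  s <- molcraft:::contracted_s_overlap(molcraft:::.h_minimal_exponents,
                                       molcraft:::.h_minimal_coeffs,
                                       0.74 / molcraft:::.bohr_to_angstrom)
  # the checkpoint stores coefficients at 8-decimal printed precision
  expect_equal(p$mos$C[1, 1]^2 * 2 * (1 + s), 1, tolerance = 1e-7)
  expect_equal(p$mos$C[1, 2]^2 * 2 * (1 - s), 1, tolerance = 1e-7)
  # before printing, the generated coefficients are exact by construction
  expect_equal((1 / sqrt(2 * (1 + s)))^2 * 2 * (1 + s), 1,
               tolerance = 1e-12)
})

test_that("overlap shrinks monotonically with bond length", {
  lens <- c(0.5, 0.74, 1.2, 2.0)
  ss <- vapply(lens, function(L) {
    molcraft:::contracted_s_overlap(molcraft:::.h_minimal_exponents,
                                    molcraft:::.h_minimal_coeffs,
                                    L / molcraft:::.bohr_to_angstrom)
  }, numeric(1))
  expect_true(all(diff(ss) < 0))
  # brute-force numeric overlap oracle at one distance
  p <- parse_fchk(make_h2_fchk(0.74))
  q <- midpoint_grid(72, 6)
  phi <- all_basis_values(p$basis, q$points)
  expect_equal(quad_overlap(phi[, 1], phi[, 2], q$h3), ss[2],
               tolerance = 1e-3)
})

test_that("sp shells split and the full shell set parses", {
  p <- parse_fchk(make_spd_fchk())
  types <- vapply(p$basis$shells, `[[`, character(1), "type")
  expect_equal(types, c("s", "s", "p", "d_cartesian", "d_pure"))
  expect_equal(p$basis$nbf, 16)

  truncated <- sub("N=          32", "N=          40",
                   make_spd_fchk(), fixed = TRUE)
  expect_error(parse_fchk(truncated), "truncated|multiple")

  lines <- strsplit(make_h2_fchk(), "\n")[[1]]
  no_shells <- lines[!grepl("^Shell types", lines)]
  no_shells <- no_shells[-(which(grepl("^Number of primitives", no_shells)) - 1)]
  expect_error(parse_fchk(paste(lines[!grepl("Shell types|^\\s+0\\s+0\\s*$",
                                             lines)], collapse = "\n")),
               "Shell types")

  f_shell <- sub(" {11}0 {11}0", "          3           0",
                 make_h2_fchk())
  expect_error(parse_fchk(f_shell), "not supported")
})

test_that("single basis functions match closed forms", {
  b <- gaussian_basis(list(list(atom = 1, type = "s", exponents = 1,
                                coefficients = 1)),
                      centers = matrix(0, 1, 3))
  expect_equal(evaluate_basis_function(b, 1, 1, c(0, 0, 0)),
               (2 / pi)^0.75, tolerance = 1e-10)
  bp <- gaussian_basis(list(list(atom = 1, type = "p", exponents = 0.7,
                                 coefficients = 1)),
                       centers = matrix(0, 1, 3))
  for (comp in 1:3) {
    expect_equal(evaluate_basis_function(bp, 1, comp, c(0, 0, 0)), 0)
  }
  expect_error(evaluate_basis_function(b, 2, 1, c(0, 0, 0)), "range")
  expect_error(evaluate_basis_function(b, 1, 2, c(0, 0, 0)), "component")
})

test_that("every fixture basis function is normalized (quadrature oracle)", {
  q <- midpoint_grid(64, 5)
  phi <- all_basis_values(make_fixture_basis(), q$points)
  norms <- colSums(phi^2) * q$h3
  expect_equal(unname(norms), rep(1, ncol(phi)), tolerance = 1e-3)
})

test_that("pure d equals the explicit Cartesian combination", {
  expo <- c(0.9, 0.35); coef <- c(0.55, 0.6)
  b6 <- gaussian_basis(list(list(atom = 1, type = "d_cartesian",
                                 exponents = expo, coefficients = coef)),
                       centers = matrix(0, 1, 3))
  b5 <- gaussian_basis(list(list(atom = 1, type = "d_pure",
                                 exponents = expo, coefficients = coef)),
                       centers = matrix(0, 1, 3))
  set.seed(5)
  pts <- matrix(rnorm(3000, sd = 1.5), ncol = 3)
  c6 <- all_basis_values(b6, pts)
  c5 <- all_basis_values(b5, pts)
  oracle <- cbind(c6[, 3] - 0.5 * c6[, 1] - 0.5 * c6[, 2],
                  c6[, 5], c6[, 6],
                  sqrt(3) / 2 * (c6[, 1] - c6[, 2]),
                  c6[, 4])
  expect_lt(max(abs(c5 - oracle)), 1e-10)
})

test_that("MO evaluation follows the LCAO expansion", {
  p <- parse_fchk(make_h2_fchk())
  mid <- matrix(c(0, 0, 0), ncol = 3)
  s <- molcraft:::contracted_s_overlap(molcraft:::.h_minimal_exponents,
                                       molcraft:::.h_minimal_coeffs,
                                       0.74 / molcraft:::.bohr_to_angstrom)
  phi_mid <- all_basis_values(p$basis, mid)[1, 1]
  expect_equal(evaluate_mo(p$basis, p$mos, 1, mid),
               2 * phi_mid / sqrt(2 * (1 + s)), tolerance = 1e-7)
  expect_lt(abs(evaluate_mo(p$basis, p$mos, 2, mid)), 1e-9)
  expect_error(evaluate_mo(p$basis, p$mos, 3, mid), "range")

  zero <- molecular_orbitals(matrix(0, 2, 1), n_alpha = 1, n_beta = 1)
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(evaluate_mo(p$basis, zero, 1, pts), rep(0, 10))
})

test_that("density is non-negative, symmetric and decays", {
  p <- parse_fchk(make_h2_fchk())
  set.seed(2)
  pts <- matrix(rnorm(300, sd = 2), ncol = 3)
  rho <- evaluate_density(p$basis, p$mos, pts)
  expect_true(all(rho >= 0))
  swapped <- pts[, c(1, 2, 3)]
  swapped[, 3] <- -swapped[, 3]  # centers sit at +/- z
  expect_equal(evaluate_density(p$basis, p$mos, swapped), rho,
               tolerance = 1e-12)
  expect_lt(evaluate_density(p$basis, p$mos, c(50, 0, 0)), 1e-12)

  odd <- molecular_orbitals(p$mos$C, n_alpha = 2, n_beta = 1)
  expect_error(evaluate_density(p$basis, odd, c(0, 0, 0)), "open-shell")
})

test_that("Slater orbitals match their closed forms and normalize", {
  s1 <- slater_function(n = 1, l = 0, m = 0, zeta = 1)
  expect_equal(slater_normalization(s1), 2)
  expect_equal(evaluate_slater(s1, c(0, 0, 0)), 2 * sqrt(1 / (4 * pi)))

  # radial-grid quadrature oracle: integral of phi^2 = 1
  r <- seq(5e-4, 40, by = 1e-3)
  for (fn in list(s1, slater_function(n = 2, l = 1, m = 0, zeta = 1.3),
                  slater_function(n = 3, l = 2, m = 2, zeta = 2.0))) {
    radial <- slater_normalization(fn) * r^(fn$n - 1) * exp(-fn$zeta * r)
    expect_equal(sum(radial^2 * r^2) * 1e-3, 1, tolerance = 1e-3)
  }
  pz <- slater_function(n = 2, l = 1, m = 0, zeta = 1.1)
  expect_equal(evaluate_slater(pz, c(1.2, -0.7, 0)), 0)
  expect_error(slater_function(n = 1, l = 1), "n >= l")
  expect_error(slater_function(zeta = -1), "positive")
})

test_that("default grids wrap the molecule and honour the degenerate rule", {
  single <- molecule()
  add_atom(single, 6, c(0, 0, 0))
  g <- default_grid(single, padding = 3, spacing = 0.2)
  expect_equal(g$counts, c(31L, 31L, 31L))

  pair <- molecule()
  add_atom(pair, 1, c(0, 0, 0)); add_atom(pair, 1, c(1, 0, 0))
  g0 <- default_grid(pair, padding = 0, spacing = 0.5)
  expect_equal(g0$counts[2:3], c(2L, 2L))

  gsmall <- default_grid(single, padding = 2, spacing = 0.2)
  glarge <- default_grid(single, padding = 4, spacing = 0.2)
  expect_true(all(glarge$origin < gsmall$origin))
  top_s <- gsmall$origin + (gsmall$counts - 1) * diag(gsmall$axes)
  top_l <- glarge$origin + (glarge$counts - 1) * diag(glarge$axes)
  expect_true(all(top_l > top_s))
  expect_error(default_grid(molecule()), "empty")
})

test_that("cube generation is pure: worker count cannot change the bytes", {
  p <- parse_fchk(make_h2_fchk())
  g <- default_grid(p$molecule, padding = 2, spacing = 0.35)
  c1 <- generate_cube(p$basis, p$mos, list(mo = 1), g, workers = 1)
  c4 <- generate_cube(p$basis, p$mos, list(mo = 1), g, workers = 4)
  expect_identical(c1$values, c4$values)
  # cube value at a grid point equals the direct evaluation there
  pt <- grid_points(c1)[17, , drop = FALSE]
  expect_equal(c1$values[17],
               evaluate_mo(p$basis, p$mos, 1,
                           pt / molcraft:::.bohr_to_angstrom),
               tolerance = 1e-12)
  d <- generate_cube(p$basis, p$mos, "density", g)
  expect_true(all(d$values >= 0))
  expect_error(generate_cube(p$basis, p$mos, "everything", g), "target")
})
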