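# Deterministic generators for test inputs: textbook molecules, a minimal
# H2 checkpoint file with analytically derived MO coefficients, analytic
# scalar fields, and seeded random molecules. Everything here is built in
# code; nothing is downloaded or read from disk.

#' Textbook molecule fixtures
#'
#' Idealized geometries built from standard bond lengths and angles
#' (e.g. water r(OH) = 0.9572 A, angle 104.5 degrees; H2 r = 0.74 A;
#' benzene r(CC) = 1.397 A with alternating formal bond orders).
#'
#' @param name One of "water", "methane", "ethene", "ethane", "benzene",
#'   "ethanol", "glycine", "h2".
#' @return A [molecule()].
#' @export
make_molecule <- function(name) {
  switch(name,
    water = {
      m <- molecule("water")
      o <- add_atom(m, 8, c(0, 0, 0))
      th <- 104.5 * pi / 180
      h1 <- add_atom(m, 1, c(0.9572, 0, 0))
      h2 <- add_atom(m, 1, 0.9572 * c(cos(th), sin(th), 0))
      add_bond(m, o, h1); add_bond(m, o, h2)
      m
    },
    h2 = {
      m <- molecule("h2")
      a <- add_atom(m, 1, c(0, 0, 0))
      b <- add_atom(m, 1, c(0, 0, 0.74))
      add_bond(m, a, b)
      m
    },
    methane = {
      m <- molecule("methane")
      c0 <- add_atom(m, 6, c(0, 0, 0))
      s <- 1.09 / sqrt(3)
      for (d in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
        h <- add_atom(m, 1, s * d)
        add_bond(m, c0, h)
      }
      m
    },
    ethene = {
      m <- molecule("ethene")
      c1 <- add_atom(m, 6, c(0, 0, 0))
      c2 <- add_atom(m, 6, c(1.339, 0, 0))
      add_bond(m, c1, c2, 2L)
      a <- 121.3 * pi / 180; rch <- 1.086
      for (s in c(1, -1)) {
        h <- add_atom(m, 1, rch * c(cos(a), s * sin(a), 0))
        add_bond(m, c1, h)
      }
      for (s in c(1, -1)) {
        h <- add_atom(m, 1, c(1.339, 0, 0) + rch * c(-cos(a), s * sin(a), 0))
        add_bond(m, c2, h)
      }
      m
    },
    ethane = {
      m <- molecule("ethane")
      c1 <- add_atom(m, 6, c(0, 0, 0))
      c2 <- add_atom(m, 6, c(1.536, 0, 0))
      add_bond(m, c1, c2)
      cosb <- -1 / 3; sinb <- sqrt(8) / 3; rch <- 1.09
      for (phi in c(0, 2, 4) * pi / 3) {  # staggered: offset by pi/3 on C2
        h <- add_atom(m, 1, rch * c(cosb, sinb * cos(phi), sinb * sin(phi)))
        add_bond(m, c1, h)
      }
      for (phi in c(1, 3, 5) * pi / 3) {
        h <- add_atom(m, 1, c(1.536, 0, 0) +
                        rch * c(-cosb, sinb * cos(phi), sinb * sin(phi)))
        add_bond(m, c2, h)
      }
      m
    },
    benzene = {
      m <- molecule("benzene")
      rcc <- 1.397; rch <- 1.08
      cid <- integer(6)
      for (k in 0:5) {
        th <- k * pi / 3
        cid[k + 1] <- add_atom(m, 6, rcc * c(cos(th), sin(th), 0))
      }
      for (k in 0:5) {
        th <- k * pi / 3
        h <- add_atom(m, 1, (rcc + rch) * c(cos(th), sin(th), 0))
        add_bond(m, cid[k + 1], h)
      }
      for (k in 1:6) {
        add_bond(m, cid[k], cid[k %% 6 + 1], if (k %% 2 == 1) 2L else 1L)
      }
      m
    },
    ethanol = {
      m <- molecule("ethanol")
      c1 <- add_atom(m, 6, c(0, 0, 0))
      c2 <- add_atom(m, 6, c(1.512, 0, 0))
      th <- (180 - 109.47) * pi / 180
      o <- add_atom(m, 8, c(1.512, 0, 0) + 1.43 * c(cos(th), sin(th), 0))
      add_bond(m, c1, c2); add_bond(m, c2, o)
      oh_dir <- c(cos(th * 2), sin(th * 2), 0)
      h <- add_atom(m, 1, pos_of(m, o) + 0.96 * c(1, 0.3, 0) / vnorm(c(1, 0.3, 0)))
      add_bond(m, o, h)
      adjust_hydrogens(m)
      m
    },
    glycine = {
      m <- molecule("glycine")
      n <- add_atom(m, 7, c(0, 0, 0))
      ca <- add_atom(m, 6, c(1.45, 0, 0))
      th <- (180 - 109.47) * pi / 180
      cc <- add_atom(m, 6, c(1.45, 0, 0) + 1.52 * c(cos(th), sin(th), 0))
      add_bond(m, n, ca); add_bond(m, ca, cc)
      pcc <- pos_of(m, cc)
      back <- unitv(pos_of(m, ca) - pcc)
      # carboxyl plane: +/- 120 degrees from the C-CA direction
      rot <- function(v, ang) {
        c(cos(ang) * v[1] - sin(ang) * v[2],
          sin(ang) * v[1] + cos(ang) * v[2], 0)
      }
      o1 <- add_atom(m, 8, pcc + 1.23 * rot(back, 2 * pi / 3))
      o2 <- add_atom(m, 8, pcc + 1.36 * rot(back, -2 * pi / 3))
      add_bond(m, cc, o1, 2L); add_bond(m, cc, o2, 1L)
      h <- add_atom(m, 1, pos_of(m, o2) + 0.96 * unitv(pos_of(m, o2) - pcc))
      add_bond(m, o2, h)
      adjust_hydrogens(m)
      m
    },
    stop(sprintf("unknown fixture molecule '%s'", name), call. = FALSE)
  )
}

# Minimal-basis hydrogen s contraction (the familiar three-Gaussian fit to a
# unit-exponent Slater 1s; generator data, embedded for self-containment).
.h_minimal_exponents <- c(3.42525091, 0.62391373, 0.16885540)
.h_minimal_coeffs <- c(0.15432897, 0.53532814, 0.44463454)

# Overlap of two identical normalized contracted s functions at distance
# r_bohr, from the closed-form Gaussian product formula.
contracted_s_overlap <- function(exponents, coeffs, r_bohr) {
  g <- outer(exponents, exponents, "+")
  pref <- (4 * outer(exponents, exponents) / g^2)^0.75
  dd <- outer(coeffs, coeffs)
  norm0 <- sum(dd * pref)
  s <- sum(dd * pref * exp(-outer(exponents, exponents) * r_bohr^2 / g))
  s / norm0
}

#' Generate a minimal H2 formatted-checkpoint fixture
#'
#' Writes a complete fchk text for H2 in a minimal s-only basis. The two MO
#' coefficient vectors are the symmetry-forced bonding/antibonding
#' combinations `+/- 1/sqrt(2(1 +/- S))`, with the overlap S evaluated
#' analytically from the Gaussian product formula at generation time, so the
#' resulting orbitals are exactly normalized in the idealized two-function
#' model.
#'
#' @param bond_length Internuclear distance, Angstrom (default 0.74).
#' @return The fchk file content as a single string.
#' @export
make_h2_fchk <- function(bond_length = 0.74) {
  if (!is.finite(bond_length) || bond_length <= 0) {
    stop("bond length must be positive", call. = FALSE)
  }
  r_bohr <- bond_length / .bohr_to_angstrom
  s <- contracted_s_overlap(.h_minimal_exponents, .h_minimal_coeffs, r_bohr)
  cplus <- 1 / sqrt(2 * (1 + s))
  cminus <- 1 / sqrt(2 * (1 - s))
  coords <- c(0, 0, -r_bohr / 2, 0, 0, r_bohr / 2)
  paste0(
    "h2 fixture, minimal s basis\n",
    "SP        RHF                                            Gen\n",
    fchk_scalar("Number of atoms", 2L),
    fchk_scalar("Charge", 0L),
    fchk_scalar("Multiplicity", 1L),
    fchk_scalar("Number of electrons", 2L),
    fchk_scalar("Number of alpha electrons", 1L),
    fchk_scalar("Number of beta electrons", 1L),
    fchk_scalar("Number of basis functions", 2L),
    fchk_array("Atomic numbers", c(1L, 1L)),
    fchk_array("Current cartesian coordinates", coords),
    fchk_array("Shell types", c(0L, 0L)),
    fchk_array("Number of primitives per shell", c(3L, 3L)),
    fchk_array("Shell to atom map", c(1L, 2L)),
    fchk_array("Primitive exponents", rep(.h_minimal_exponents, 2)),
    fchk_array("Contraction coefficients", rep(.h_minimal_coeffs, 2)),
    fchk_array("Alpha Orbital Energies", c(-0.578, 0.670)),
    fchk_array("Alpha MO coefficients",
               c(cplus, cplus, cminus, -cminus)))
}

#' Generate a single-atom fchk exercising every supported shell type
#'
#' One neon-labelled center carrying an s, an sp, a Cartesian d and a pure d
#' shell (16 basis functions), with two placeholder MOs. Exponents and
#' contractions are generator data chosen to be well-conditioned.
#'
#' @return The fchk file content as a single string.
#' @export
make_spd_fchk <- function() {
  nbf <- 16L
  c1 <- rep(0, nbf); c1[1] <- 1
  c2 <- rep(0, nbf); c2[2] <- 1
  paste0(
    "spd fixture, one center, shells s/sp/d6/d5\n",
    "SP        RHF                                            Gen\n",
    fchk_scalar("Number of atoms", 1L),
    fchk_scalar("Charge", 0L),
    fchk_scalar("Multiplicity", 1L),
    fchk_scalar("Number of electrons", 2L),
    fchk_scalar("Number of alpha electrons", 1L),
    fchk_scalar("Number of beta electrons", 1L),
    fchk_scalar("Number of basis functions", nbf),
    fchk_array("Atomic numbers", 10L),
    fchk_array("Current cartesian coordinates", c(0, 0, 0)),
    fchk_array("Shell types", c(0L, -1L, 2L, -2L)),
    fchk_array("Number of primitives per shell", c(2L, 2L, 2L, 1L)),
    fchk_array("Shell to atom map", c(1L, 1L, 1L, 1L)),
    fchk_array("Primitive exponents",
               c(2.5, 0.8, 1.2, 0.4, 0.9, 0.35, 0.6)),
    fchk_array("Contraction coefficients",
               c(0.4, 0.7, 0.5, 0.6, 0.55, 0.6, 1.0)),
    fchk_array("P(S=P) Contraction coefficients",
               c(0, 0, 0.45, 0.65, 0, 0, 0)),
    fchk_array("Alpha Orbital Energies", c(-1.0, -0.5)),
    fchk_array("Alpha MO coefficients", c(c1, c2)))
}

fchk_scalar <- function(key, value) {
  if (is.integer(value)) {
    sprintf("%-40s   I     %12d\n", key, value)
  } else {
    sprintf("%-40s   R     %22.15E\n", key, value)
  }
}

fchk_array <- function(key, values) {
  if (is.integer(values)) {
    head <- sprintf("%-40s   I   N=%12d\n", key, length(values))
    body <- format_chunks(sprintf("%12d", values), 6)
  } else {
    head <- sprintf("%-40s   R   N=%12d\n", key, length(values))
    body <- format_chunks(sprintf("%16.8E", values), 5)
  }
  paste0(head, body)
}

format_chunks <- function(fields, per_line) {
  idx <- split(seq_along(fields), (seq_along(fields) - 1) %/% per_line)
  paste0(paste(vapply(idx, function(i) paste0(fields[i], collapse = ""),
                      character(1)), collapse = "\n"), "\n")
}

#' Analytic scalar-field grids
#'
#' Samples an analytic field on a cubic grid centered at the origin, for
#' isosurface and I/O tests: `sphere` is the signed field
#' `x^2 + y^2 + z^2 - R^2`, `plane` the signed distance to a plane through
#' the origin, `gaussian` a unit-height Gaussian bump.
#'
#' @param field One of "sphere", "plane", "gaussian".
#' @param n Points per axis (>= 2).
#' @param extent Half-width of the cube, Angstrom.
#' @param R Sphere radius (sphere field).
#' @param normal Plane normal (plane field).
#' @param sigma Gaussian width (gaussian field).
#' @return A [volumetric_grid()] in Angstrom units.
#' @export
make_field_grid <- function(field = c("sphere", "plane", "gaussian"),
                            n = 32, extent = 3,
                            R = 1, normal = c(0, 0, 1), sigma = 1) {
  field <- match.arg(field)
  if (n < 2) stop("need at least 2 points per axis", call. = FALSE)
  ax <- seq(-extent, extent, length.out = n)
  f <- switch(field,
    sphere = function(x, y, z) x^2 + y^2 + z^2 - R^2,
    plane = {
      nm <- unitv(normal)
      function(x, y, z) x * nm[1] + y * nm[2] + z * nm[3]
    },
    gaussian = function(x, y, z) exp(-(x^2 + y^2 + z^2) / (2 * sigma^2)))
  vals <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) {
    vals[, , k] <- outer(ax, ax, function(x, y) f(x, y, ax[k]))
  }
  step <- if (n > 1) ax[2] - ax[1] else 0
  volumetric_grid(origin = c(-extent, -extent, -extent),
                  axes = diag(3) * step,
                  values = vals, unit = "angstrom")
}

# Minimal deterministic linear congruential generator so fixtures never
# touch R's global random stream.
lcg_new <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- as.numeric(seed %% 2147483647)
  if (e$state <= 0) e$state <- e$state + 2147483646
  e
}

lcg_unif <- function(rng, n = 1) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    rng$state <- (16807 * rng$state) %% 2147483647
    out[i] <- rng$state / 2147483647
  }
  out
}

#' Seeded random tree-connected molecule
#'
#' Builds a reproducible pseudo-random molecule for fuzz and property tests:
#' atoms are drawn from C/N/O/H, connected as a tree (atom i bonds to a
#' random earlier atom), placed at 1.5 A from their parent in a random
#' direction, re-sampled until every pairwise distance is at least 1.0 A.
#' The generator is a self-contained linear congruential stream keyed by
#' `seed`; R's global random state is never touched.
#'
#' @param seed Integer seed.
#' @param n_atoms Number of atoms (>= 1).
#' @return A [molecule()].
#' @export
make_random_molecule <- function(seed, n_atoms) {
  if (n_atoms < 1) stop("need at least one atom", call. = FALSE)
  rng <- lcg_new(seed)
  elements <- c(6L, 7L, 8L, 1L)
  m <- molecule(sprintf("random-%d", seed))
  first <- add_atom(m, elements[ceiling(lcg_unif(rng) * 4)], c(0, 0, 0))
  ids <- first
  for (i in seq_len(n_atoms - 1)) {
    parent <- ids[ceiling(lcg_unif(rng) * length(ids))]
    p0 <- pos_of(m, parent)
    pos <- NULL
    for (try in 1:200) {
      u <- lcg_unif(rng, 2)
      z <- 2 * u[1] - 1
      phi <- 2 * pi * u[2]
      r <- sqrt(max(0, 1 - z^2))
      dirv <- c(r * cos(phi), r * sin(phi), z)
      cand <- p0 + 1.5 * dirv * (1 + 0.1 * (try - 1))
      dmin <- min(sqrt(rowSums(sweep(atom_positions(m), 2, cand)^2)))
      if (dmin >= 1.0) { pos <- cand; break }
    }
    if (is.null(pos)) pos <- p0 + c(2 * i, 0, 0)
    id <- add_atom(m, elements[ceiling(lcg_unif(rng) * 4)], pos)
    add_bond(m, parent, id)
    ids <- c(ids, id)
  }
  m
}
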