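# Quantum output handling: formatted-checkpoint parsing, Gaussian- and
# Slater-type orbital evaluation, molecular orbitals and electron density on
# arbitrary point sets, and volumetric-grid generation.
#
# All quantum-mechanical lengths are Bohr internally; the molecule document
# and grids used for display are Angstrom. One conversion constant is the
# single source of truth.

#' @name bohr
#' @title Bohr/Angstrom conversion constant
#' @description 0.52917721067 Angstrom per Bohr, used by every unit
#'   conversion in the package.
NULL
.bohr_to_angstrom <- 0.52917721067

#' Volumetric scalar grid
#'
#' A regularly spaced scalar field with cube-file semantics: an origin,
#' three step vectors (rows of `axes`), per-axis counts, and optionally the
#' `nx * ny * nz` values as a 3D array. Geometry is in the declared `unit`.
#'
#' @param origin Numeric length-3 grid origin.
#' @param axes 3x3 matrix, step vectors as rows.
#' @param values Optional 3D numeric array; its `dim` gives the counts.
#' @param counts Per-axis point counts (needed when `values` is absent).
#' @param unit "angstrom" or "bohr".
#' @return An object of class `volgrid`.
#' @export
volumetric_grid <- function(origin, axes, values = NULL, counts = NULL,
                            unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  if (is.null(counts)) {
    if (is.null(values)) stop("need values or counts", call. = FALSE)
    counts <- dim(values)
  }
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(counts < 2)) {
    stop("grid needs at least 2 points per axis", call. = FALSE)
  }
  if (!is.null(values)) {
    values <- array(as.numeric(values), dim = counts)
  }
  structure(list(origin = origin, axes = axes, counts = counts,
                 values = values, unit = unit), class = "volgrid")
}

#' @export
print.volgrid <- function(x, ...) {
  cat(sprintf("<volgrid> %d x %d x %d points (%s)%s\n",
              x$counts[1], x$counts[2], x$counts[3], x$unit,
              if (is.null(x$values)) ", no values" else ""))
  if (!is.null(x$values)) {
    cat(sprintf("  values in [%.6g, %.6g]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

#' All grid point coordinates
#'
#' @param grid A [volumetric_grid()].
#' @return `n x 3` matrix in the grid's unit; rows ordered with the first
#'   axis index varying fastest (matching `array` linearization of the
#'   values).
#' @export
grid_points <- function(grid) {
  n <- grid$counts
  i <- rep(seq_len(n[1]) - 1, times = n[2] * n[3])
  j <- rep(rep(seq_len(n[2]) - 1, each = n[1]), times = n[3])
  k <- rep(seq_len(n[3]) - 1, each = n[1] * n[2])
  cbind(grid$origin[1] + i * grid$axes[1, 1] + j * grid$axes[2, 1] +
          k * grid$axes[3, 1],
        grid$origin[2] + i * grid$axes[1, 2] + j * grid$axes[2, 2] +
          k * grid$axes[3, 2],
        grid$origin[3] + i * grid$axes[1, 3] + j * grid$axes[2, 3] +
          k * grid$axes[3, 3])
}

voxel_volume <- function(grid) abs(det(grid$axes))

# --- Gaussian basis ---------------------------------------------------------

# Cartesian exponent triples per shell type, in checkpoint convention order:
# d Cartesian XX, YY, ZZ, XY, XZ, YZ.
.cart_components <- list(
  s = matrix(c(0, 0, 0), ncol = 3, byrow = TRUE),
  p = matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE),
  d = matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2, 1, 1, 0, 1, 0, 1, 0, 1, 1),
             ncol = 3, byrow = TRUE))

shell_nbf <- function(type) {
  switch(type, s = 1L, p = 3L, d_cartesian = 6L, d_pure = 5L,
         stop(sprintf("unsupported shell type '%s'", type), call. = FALSE))
}

#' Construct a Gaussian basis
#'
#' @param shells List of shells; each a list with `atom` (1-based center
#'   index), `type` ("s", "p", "d_cartesian", "d_pure"), `exponents`
#'   (Bohr^-2) and `coefficients` (contraction coefficients over normalized
#'   primitives, same length).
#' @param centers `n_atom x 3` matrix of center positions, Bohr.
#' @return An object of class `gaussian_basis` with an `nbf` field; f- and
#'   higher shells are rejected.
#' @export
gaussian_basis <- function(shells, centers) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  for (sh in shells) {
    if (!sh$type %in% c("s", "p", "d_cartesian", "d_pure")) {
      stop(sprintf(
        "shell type '%s' is not supported (only s, p and d shells are)",
        sh$type), call. = FALSE)
    }
    if (length(sh$exponents) < 1 ||
        length(sh$exponents) != length(sh$coefficients)) {
      stop("shell exponent/coefficient lengths differ or are empty",
           call. = FALSE)
    }
    if (any(sh$exponents <= 0)) {
      stop("primitive exponents must be positive", call. = FALSE)
    }
    if (sh$atom < 1 || sh$atom > nrow(centers)) {
      stop("shell refers to a missing center", call. = FALSE)
    }
  }
  nbf <- sum(vapply(shells, function(s) shell_nbf(s$type), integer(1)))
  structure(list(shells = shells, centers = centers, nbf = nbf),
            class = "gaussian_basis")
}

#' @export
print.gaussian_basis <- function(x, ...) {
  cat(sprintf("<gaussian_basis> %d shells, %d basis functions, %d centers\n",
              length(x$shells), x$nbf, nrow(x$centers)))
  invisible(x)
}

#' Molecular-orbital coefficient set
#'
#' @param coefficients `nbf x n_mo` matrix, one column per MO.
#' @param energies Optional orbital energies, Hartree.
#' @param n_alpha,n_beta Electron counts.
#' @return An object of class `molecular_orbitals`.
#' @export
molecular_orbitals <- function(coefficients, energies = NULL,
                               n_alpha, n_beta) {
  coefficients <- as.matrix(coefficients)
  structure(list(C = coefficients, energies = energies,
                 n_alpha = as.integer(n_alpha), n_beta = as.integer(n_beta),
                 n_mo = ncol(coefficients)),
            class = "molecular_orbitals")
}

# Per-primitive Cartesian normalization constant.
gto_norm <- function(alpha, lmn) {
  l <- lmn[1]; m <- lmn[2]; n <- lmn[3]
  L <- l + m + n
  (2 * alpha / pi)^0.75 *
    sqrt((8 * alpha)^L * factorial(l) * factorial(m) * factorial(n) /
           (factorial(2 * l) * factorial(2 * m) * factorial(2 * n)))
}

dfact <- function(k) if (k <= 0) 1 else prod(seq(k, 1, by = -2))

# Contraction self-overlap of a shell built from normalized primitives;
# component-independent, so the (L,0,0) representative is used. The shell's
# effective coefficients are scaled by 1/sqrt of this, forcing unit
# self-overlap analytically.
contraction_self_overlap <- function(exponents, coeffs, L) {
  lmn <- c(L, 0, 0)
  nk <- vapply(exponents, gto_norm, numeric(1), lmn = lmn)
  g <- outer(exponents, exponents, "+")
  i0 <- (pi / g)^1.5 * dfact(2 * L - 1) / (2 * g)^L
  sum(outer(coeffs * nk, coeffs * nk) * i0)
}

shell_L <- function(type) switch(type, s = 0L, p = 1L, 2L)

# Evaluate all basis functions at a set of points (Bohr).
# Returns an n_points x nbf matrix, columns in checkpoint function order.
basis_matrix <- function(basis, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  np <- nrow(points)
  out <- matrix(0, np, basis$nbf)
  col <- 1L
  for (sh in basis$shells) {
    ctr <- basis$centers[sh$atom, ]
    dx <- points[, 1] - ctr[1]
    dy <- points[, 2] - ctr[2]
    dz <- points[, 3] - ctr[3]
    r2 <- dx * dx + dy * dy + dz * dz
    E <- exp(outer(r2, sh$exponents, function(a, b) -b * a))
    L <- shell_L(sh$type)
    renorm <- 1 / sqrt(contraction_self_overlap(sh$exponents,
                                                sh$coefficients, L))
    comp <- .cart_components[[switch(sh$type, s = "s", p = "p", "d")]]
    ncart <- nrow(comp)
    cart <- matrix(0, np, ncart)
    for (ci in seq_len(ncart)) {
      lmn <- comp[ci, ]
      ck <- sh$coefficients * renorm *
        vapply(sh$exponents, gto_norm, numeric(1), lmn = lmn)
      ang <- rep(1, np)
      if (lmn[1] > 0) ang <- ang * dx^lmn[1]
      if (lmn[2] > 0) ang <- ang * dy^lmn[2]
      if (lmn[3] > 0) ang <- ang * dz^lmn[3]
      cart[, ci] <- ang * drop(E %*% ck)
    }
    if (sh$type == "d_pure") {
      # checkpoint pure-d order: z^2, xz, yz, x^2-y^2, xy, expressed in the
      # normalized Cartesian six (XX, YY, ZZ, XY, XZ, YZ)
      pure <- cbind(
        cart[, 3] - 0.5 * cart[, 1] - 0.5 * cart[, 2],
        cart[, 5],
        cart[, 6],
        sqrt(3) / 2 * (cart[, 1] - cart[, 2]),
        cart[, 4])
      out[, col:(col + 4L)] <- pure
      col <- col + 5L
    } else {
      out[, col:(col + ncart - 1L)] <- cart
      col <- col + ncart
    }
  }
  out
}

#' Evaluate one basis function
#'
#' @param basis A [gaussian_basis()].
#' @param shell_index 1-based shell index.
#' @param component 1-based component within the shell (s: 1; p: x,y,z;
#'   Cartesian d: XX,YY,ZZ,XY,XZ,YZ; pure d: z2, xz, yz, x2-y2, xy).
#' @param point Length-3 position, Bohr.
#' @return The basis-function value.
#' @export
evaluate_basis_function <- function(basis, shell_index, component, point) {
  if (shell_index < 1 || shell_index > length(basis$shells)) {
    stop("shell index out of range", call. = FALSE)
  }
  offs <- c(0, cumsum(vapply(basis$shells,
                             function(s) shell_nbf(s$type), integer(1))))
  nb <- shell_nbf(basis$shells[[shell_index]]$type)
  if (component < 1 || component > nb) {
    stop("component out of range for this shell", call. = FALSE)
  }
  phi <- basis_matrix(basis, matrix(point, ncol = 3))
  phi[1, offs[shell_index] + component]
}

#' Evaluate a molecular orbital or the electron density at points
#'
#' `evaluate_mo()` computes the LCAO expansion
#' `psi_i(r) = sum_mu C[mu, i] phi_mu(r)`; `evaluate_density()` the
#' closed-shell density `rho(r) = 2 sum_occ psi_i(r)^2` with the lowest
#' `n_electrons / 2` orbitals doubly occupied. Open-shell data (unequal
#' alpha/beta counts) is rejected.
#'
#' @param basis A [gaussian_basis()].
#' @param mos A [molecular_orbitals()].
#' @param mo_index 1-based orbital index.
#' @param points One position (length 3) or an `n x 3` matrix, Bohr.
#' @return Numeric vector of values (a scalar for a single point).
#' @export
evaluate_mo <- function(basis, mos, mo_index, points) {
  if (mo_index < 1 || mo_index > mos$n_mo) {
    stop(sprintf("MO index %d out of range (1..%d)", mo_index, mos$n_mo),
         call. = FALSE)
  }
  phi <- basis_matrix(basis, points)
  drop(phi %*% mos$C[, mo_index])
}

#' @rdname evaluate_mo
#' @export
evaluate_density <- function(basis, mos, points) {
  nocc <- occupied_count(mos)
  phi <- basis_matrix(basis, points)
  psi <- phi %*% mos$C[, seq_len(nocc), drop = FALSE]
  2 * drop(rowSums(psi * psi))
}

occupied_count <- function(mos) {
  nel <- mos$n_alpha + mos$n_beta
  if (mos$n_alpha != mos$n_beta) {
    stop("open-shell (unequal alpha/beta) data is not supported",
         call. = FALSE)
  }
  nocc <- nel %/% 2L
  if (nocc < 1 || nocc > mos$n_mo) {
    stop("electron count inconsistent with the orbital set", call. = FALSE)
  }
  nocc
}

# --- Slater-type orbitals ---------------------------------------------------

#' Slater-type orbital
#'
#' @param center Length-3 position, Bohr.
#' @param n,l,m Quantum numbers; `n >= l + 1`, `|m| <= l`, `l <= 2`.
#' @param zeta Exponent, Bohr^-1, > 0.
#' @return An object of class `slater_function`.
#' @export
slater_function <- function(center = c(0, 0, 0), n = 1, l = 0, m = 0,
                            zeta = 1) {
  if (zeta <= 0) stop("zeta must be positive", call. = FALSE)
  if (n < l + 1) stop("need n >= l + 1", call. = FALSE)
  if (abs(m) > l) stop("need |m| <= l", call. = FALSE)
  if (l > 2) stop("only s, p and d Slater functions are supported",
                  call. = FALSE)
  structure(list(center = as.numeric(center), n = as.integer(n),
                 l = as.integer(l), m = as.integer(m), zeta = zeta),
            class = "slater_function")
}

#' Radial normalization of a Slater function
#'
#' `N = (2 zeta)^(n + 1/2) / sqrt((2n)!)`, so that the radial part
#' `N r^(n-1) exp(-zeta r)` has unit norm.
#' @param fn A [slater_function()].
#' @return The normalization constant.
#' @export
slater_normalization <- function(fn) {
  (2 * fn$zeta)^(fn$n + 0.5) / sqrt(factorial(2 * fn$n))
}

#' Evaluate a Slater-type orbital
#'
#' Real-harmonic form `R(r) Y_lm(theta, phi)` with
#' `R(r) = N r^(n-1) exp(-zeta r)`.
#'
#' @param fn A [slater_function()].
#' @param points One position (length 3) or an `n x 3` matrix, Bohr.
#' @return Numeric vector of values.
#' @export
evaluate_slater <- function(fn, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  dx <- points[, 1] - fn$center[1]
  dy <- points[, 2] - fn$center[2]
  dz <- points[, 3] - fn$center[3]
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  nrm <- slater_normalization(fn)
  radial <- nrm * ifelse(r == 0 & fn$n == 1, 1, r^(fn$n - 1)) * exp(-fn$zeta * r)
  if (fn$l == 0) {
    y <- sqrt(1 / (4 * pi))
    return(drop(radial * y))
  }
  rs <- ifelse(r == 0, 1, r)  # angular part is 0 at the center for l > 0
  ang <- if (fn$l == 1) {
    switch(as.character(fn$m),
           "0" = dz / rs, "1" = dx / rs, "-1" = dy / rs) * sqrt(3 / (4 * pi))
  } else {
    switch(as.character(fn$m),
           "0" = sqrt(5 / (16 * pi)) * (3 * dz^2 / rs^2 - 1),
           "1" = sqrt(15 / (4 * pi)) * dx * dz / rs^2,
           "-1" = sqrt(15 / (4 * pi)) * dy * dz / rs^2,
           "2" = sqrt(15 / (16 * pi)) * (dx^2 - dy^2) / rs^2,
           "-2" = sqrt(15 / (4 * pi)) * dx * dy / rs^2)
  }
  ang[r == 0] <- 0
  drop(radial * ang)
}

# --- Formatted checkpoint parsing -------------------------------------------

#' Parse a Gaussian formatted-checkpoint file
#'
#' Reads the fixed-layout key/value sections and returns the molecule (in
#' Angstrom), the Gaussian basis (centers in Bohr) and the alpha MO
#' coefficient matrix. Shell type codes map 0 to s, 1 to p, -1 to an sp pair
#' (split into an s and a p shell sharing exponents), 2 to Cartesian d and
#' -2 to pure d; anything higher is rejected as unsupported.
#'
#' @param text The file content as a single string or character vector of
#'   lines.
#' @return A list with elements `molecule`, `basis`, `mos`.
#' @export
parse_fchk <- function(text) {
  lines <- split_lines(text)
  sec <- fchk_sections(lines)
  need <- function(key, kind = "array") {
    v <- sec[[key]]
    if (is.null(v)) {
      stop(sprintf("checkpoint is missing mandatory section '%s'", key),
           call. = FALSE)
    }
    v
  }
  natom <- need("Number of atoms")
  zs <- as.integer(need("Atomic numbers"))
  coords <- need("Current cartesian coordinates")
  if (length(zs) != natom || length(coords) != 3 * natom) {
    stop("atom count and coordinate section disagree", call. = FALSE)
  }
  pos_bohr <- matrix(coords, ncol = 3, byrow = TRUE)

  mol <- molecule("fchk import")
  for (i in seq_len(natom)) {
    add_atom(mol, zs[i], pos_bohr[i, ] * .bohr_to_angstrom)
  }

  stypes <- as.integer(need("Shell types"))
  nprim <- as.integer(need("Number of primitives per shell"))
  smap <- as.integer(need("Shell to atom map"))
  expo <- need("Primitive exponents")
  coef <- need("Contraction coefficients")
  spcoef <- sec[["P(S=P) Contraction coefficients"]]
  if (length(stypes) != length(nprim) || length(stypes) != length(smap)) {
    stop("shell definition sections disagree in length", call. = FALSE)
  }
  shells <- list()
  off <- 0L
  for (i in seq_along(stypes)) {
    idx <- off + seq_len(nprim[i])
    off <- off + nprim[i]
    e <- expo[idx]; c1 <- coef[idx]
    tcode <- stypes[i]
    if (tcode == 0) {
      shells[[length(shells) + 1]] <- list(atom = smap[i], type = "s",
                                           exponents = e, coefficients = c1)
    } else if (tcode == 1) {
      shells[[length(shells) + 1]] <- list(atom = smap[i], type = "p",
                                           exponents = e, coefficients = c1)
    } else if (tcode == -1) {
      if (is.null(spcoef)) {
        stop("sp shell present but no P(S=P) contraction coefficients",
             call. = FALSE)
      }
      shells[[length(shells) + 1]] <- list(atom = smap[i], type = "s",
                                           exponents = e, coefficients = c1)
      shells[[length(shells) + 1]] <- list(atom = smap[i], type = "p",
                                           exponents = e,
                                           coefficients = spcoef[idx])
    } else if (tcode == 2) {
      shells[[length(shells) + 1]] <- list(atom = smap[i],
                                           type = "d_cartesian",
                                           exponents = e, coefficients = c1)
    } else if (tcode == -2) {
      shells[[length(shells) + 1]] <- list(atom = smap[i], type = "d_pure",
                                           exponents = e, coefficients = c1)
    } else {
      stop(sprintf(
        "shell type code %d is not supported (f and higher shells)", tcode),
        call. = FALSE)
    }
  }
  basis <- gaussian_basis(shells, pos_bohr)
  nbf_declared <- sec[["Number of basis functions"]]
  if (!is.null(nbf_declared) && nbf_declared != basis$nbf) {
    stop(sprintf("declared %d basis functions but shells define %d",
                 nbf_declared, basis$nbf), call. = FALSE)
  }

  cvec <- need("Alpha MO coefficients")
  if (length(cvec) %% basis$nbf != 0) {
    stop(sprintf(
      "MO coefficient count %d is not a multiple of %d basis functions",
      length(cvec), basis$nbf), call. = FALSE)
  }
  C <- matrix(cvec, nrow = basis$nbf)  # stored MO-major: column per MO
  na <- sec[["Number of alpha electrons"]]
  nb <- sec[["Number of beta electrons"]]
  if (is.null(na) || is.null(nb)) {
    nel <- need("Number of electrons")
    na <- ceiling(nel / 2); nb <- nel - na
  }
  mos <- molecular_orbitals(C, energies = sec[["Alpha Orbital Energies"]],
                            n_alpha = na, n_beta = nb)
  list(molecule = mol, basis = basis, mos = mos)
}

fchk_sections <- function(lines) {
  out <- list()
  i <- 3L  # first two lines are free-text header
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (nchar(ln) < 43) { i <- i + 1L; next }
    key <- trimws(substr(ln, 1, 40))
    kind <- trimws(substr(ln, 41, 44))
    rest <- substr(ln, 45, nchar(ln))
    if (!kind %in% c("I", "R", "C")) { i <- i + 1L; next }
    if (grepl("^\\s*N=", rest)) {
      cnt <- as.integer(sub(".*N=\\s*", "", rest))
      vals <- numeric(0)
      i <- i + 1L
      while (length(vals) < cnt && i <= n) {
        tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        vals <- c(vals, as.numeric(tok))
        i <- i + 1L
      }
      if (length(vals) < cnt) {
        stop(sprintf("section '%s' truncated: expected %d values, found %d",
                     key, cnt, length(vals)), call. = FALSE)
      }
      out[[key]] <- vals[seq_len(cnt)]
    } else {
      out[[key]] <- as.numeric(trimws(rest))
      i <- i + 1L
    }
  }
  out
}

split_lines <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
}

# --- Grid generation --------------------------------------------------------

#' Default cube-grid specification around a molecule
#'
#' Axis-aligned bounding box of the atoms expanded by `padding` on every
#' side, sampled uniformly at `spacing`; an axis with zero extent still gets
#' the 2-point minimum.
#'
#' @param mol A non-empty [molecule()].
#' @param padding Box padding, Angstrom (default 3).
#' @param spacing Grid step, Angstrom (default 0.2).
#' @return A `volgrid` without values (Angstrom), usable as the `grid`
#'   argument of [generate_cube()].
#' @export
default_grid <- function(mol, padding = 3.0, spacing = 0.2) {
  stopifnot_molecule(mol)
  if (n_atoms(mol) == 0) stop("empty molecule", call. = FALSE)
  pos <- atom_positions(mol)
  lo <- apply(pos, 2, min) - padding
  hi <- apply(pos, 2, max) + padding
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L)
  volumetric_grid(origin = lo, axes = diag(3) * spacing, counts = counts,
                  unit = "angstrom")
}

#' Fill a grid with molecular-orbital or density values
#'
#' Evaluates the requested scalar at every grid point. Each point is an
#' independent pure evaluation, so the grid is filled in slabs whose
#' scheduling (and the `workers` count) cannot change the result: outputs
#' are bitwise identical for any worker count.
#'
#' @param basis A [gaussian_basis()].
#' @param mos A [molecular_orbitals()].
#' @param target `list(mo = i)` for orbital `i`, or `"density"`.
#' @param grid A `volgrid` (with or without values; geometry is used).
#' @param workers Number of forked workers for slab evaluation (default 1).
#' @return The grid with `values` filled in.
#' @export
generate_cube <- function(basis, mos, target, grid, workers = 1L) {
  pts <- grid_points(grid)
  if (grid$unit == "angstrom") pts <- pts / .bohr_to_angstrom
  fun <- if (identical(target, "density")) {
    function(p) evaluate_density(basis, mos, p)
  } else if (is.list(target) && !is.null(target$mo)) {
    function(p) evaluate_mo(basis, mos, target$mo, p)
  } else {
    stop("target must be list(mo = i) or \"density\"", call. = FALSE)
  }
  np <- nrow(pts)
  chunk_size <- 20000L
  starts <- seq(1L, np, by = chunk_size)
  eval_chunk <- function(s) {
    idx <- s:min(s + chunk_size - 1L, np)
    fun(pts[idx, , drop = FALSE])
  }
  pieces <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(starts, eval_chunk, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(starts, eval_chunk)
  }
  vals <- unlist(pieces, use.names = FALSE)
  volumetric_grid(grid$origin, grid$axes,
                  values = array(vals, dim = grid$counts), unit = grid$unit)
}
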