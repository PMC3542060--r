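# Shared helpers: quadrature oracles, rigid transforms, and the external
# marching-cubes reference.

# Midpoint-rule quadrature grid over a centered cube: n^3 points, returns
# the point matrix and the voxel volume.
midpoint_grid <- function(n, half_width) {
  h <- 2 * half_width / n
  ax <- -half_width + h * (0.5 + seq_len(n) - 1)
  list(points = as.matrix(expand.grid(ax, ax, ax)), h3 = h^3)
}

# Independent overlap quadrature of two value vectors on a midpoint grid.
quad_overlap <- function(f, g, h3) sum(f * g) * h3

# Random rotation (QR of a Gaussian matrix, det forced to +1) + translation.
random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = rnorm(3, sd = 5))
}

apply_rigid <- function(mol, tf) {
  out <- clone_molecule(mol)
  pos <- atom_positions(out)
  newpos <- sweep(pos %*% t(tf$rotation), 2, -tf$translation)
  for (i in seq_len(nrow(pos))) {
    set_atom_position(out, as.integer(rownames(pos)[i]), newpos[i, ])
  }
  out
}

# Marching cubes from scikit-image through the system python, as an
# implementation-independent reference. Grids are exchanged as plain text;
# vertices come back in 0-based index coordinates (matching a unit-spacing
# grid with origin 0).
skimage_marching_cubes <- function(values, level) {
  n <- dim(values)
  fin <- tempfile(fileext = ".txt")
  fout <- tempfile(fileext = ".txt")
  writeLines(as.character(c(n, as.vector(values))), fin)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from skimage import measure\n",
    "raw = np.loadtxt(%s)\n",
    "n = raw[:3].astype(int); vals = raw[3:].reshape(tuple(n), order='F')\n",
    "verts, faces, _, _ = measure.marching_cubes(vals, level=%.17g)\n",
    "np.savetxt(%s, verts)\n"),
    deparse(fin), level, deparse(fout))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("reference marching-cubes run failed")
  as.matrix(read.table(fout))
}

# Smallest circular difference between two angles in degrees (so a torsion
# of 180 and -180 compare equal).
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Directed + reverse Hausdorff distance between two point sets (chunked).
hausdorff <- function(a, b) {
  one_way <- function(p, q) {
    worst <- 0
    for (s in seq(1, nrow(p), by = 500)) {
      idx <- s:min(s + 499, nrow(p))
      d2 <- outer(rowSums(p[idx, , drop = FALSE]^2), rowSums(q^2), "+") -
        2 * p[idx, , drop = FALSE] %*% t(q)
      worst <- max(worst, sqrt(pmax(apply(d2, 1, min), 0)))
    }
    worst
  }
  max(one_way(a, b), one_way(b, a))
}

# Unit-spacing index-coordinate grid around values (for reference
# comparisons).
index_grid <- function(values) {
  volumetric_grid(c(0, 0, 0), diag(3), values = values, unit = "angstrom")
}

# Smooth random field: a few Gaussian bumps on [-2, 2]^3.
random_smooth_field <- function(n = 24, n_bumps = 3) {
  ax <- seq(-2, 2, length.out = n)
  ctr <- matrix(runif(3 * n_bumps, -1, 1), ncol = 3)
  amp <- runif(n_bumps, 0.5, 1.5)
  vals <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) {
    for (i in seq_len(n_bumps)) {
      vals[, , k] <- vals[, , k] + amp[i] * outer(ax, ax, function(x, y) {
        exp(-((x - ctr[i, 1])^2 + (y - ctr[i, 2])^2 + (ax[k] - ctr[i, 3])^2))
      })
    }
  }
  vals
}

# Basis-function values at a point set (through the public per-function
# evaluator shape, vectorized internally).
all_basis_values <- function(basis, points) {
  molcraft:::basis_matrix(basis, points)
}

# A compact single-center basis exercising s, p, Cartesian d and pure d.
make_fixture_basis <- function() {
  gaussian_basis(list(
    list(atom = 1, type = "s", exponents = c(2.5, 0.8),
         coefficients = c(0.4, 0.7)),
    list(atom = 1, type = "p", exponents = c(1.2, 0.4),
         coefficients = c(0.5, 0.6)),
    list(atom = 1, type = "d_cartesian", exponents = c(0.9, 0.35),
         coefficients = c(0.55, 0.6)),
    list(atom = 1, type = "d_pure", exponents = c(0.6),
         coefficients = c(1.0))),
    centers = matrix(0, 1, 3))
}
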