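# Measurement, alignment and bond-centric manipulation.

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector in geometric construction",
                      call. = FALSE)
  v / n
}

pos_of <- function(mol, id) {
  i <- atom_row(mol, id)
  as.numeric(mol$atoms[i, c("x", "y", "z")])
}

#' Measure distances, angles and dihedrals
#'
#' Standard Euclidean definitions: `distance(a, b)` in Angstrom; `angle(a, b,
#' c)` is the angle at vertex `b` in degrees; `dihedral(a, b, c, d)` is the
#' signed torsion about the `b - c` axis, right-hand rule, in `(-180, 180]`
#' degrees.
#'
#' @param mol A [molecule()].
#' @param a,b,c,d Atom ids; must be distinct where the definition requires
#'   it. Coincident or collinear defining points raise an error rather than
#'   returning NaN.
#' @return A numeric scalar.
#' @examples
#' w <- make_molecule("water")
#' angle(w, 2, 1, 3)
#' @export
distance <- function(mol, a, b) {
  stopifnot_molecule(mol)
  if (a == b) stop("distance needs two distinct atoms", call. = FALSE)
  vnorm(pos_of(mol, a) - pos_of(mol, b))
}

#' @rdname distance
#' @export
angle <- function(mol, a, b, c) {
  stopifnot_molecule(mol)
  if (length(unique(c(a, b, c))) != 3) {
    stop("angle needs three distinct atoms", call. = FALSE)
  }
  u <- pos_of(mol, a) - pos_of(mol, b)
  v <- pos_of(mol, c) - pos_of(mol, b)
  if (vnorm(u) < 1e-9 || vnorm(v) < 1e-9) {
    stop("coincident atoms in angle definition", call. = FALSE)
  }
  cosang <- sum(unitv(u) * unitv(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' @rdname distance
#' @export
dihedral <- function(mol, a, b, c, d) {
  stopifnot_molecule(mol)
  if (length(unique(c(a, b, c, d))) != 4) {
    stop("dihedral needs four distinct atoms", call. = FALSE)
  }
  p1 <- pos_of(mol, a); p2 <- pos_of(mol, b)
  p3 <- pos_of(mol, c); p4 <- pos_of(mol, d)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("collinear atoms make the dihedral undefined", call. = FALSE)
  }
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Rodrigues rotation taking unit vector u onto unit vector w.
rotation_between <- function(u, w) {
  u <- unitv(u); w <- unitv(w)
  v <- cross3(u, w)
  s <- vnorm(v); cth <- sum(u * w)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any axis orthogonal to u (deterministic pick)
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitv(cross3(u, ref))
    return(rotation_about(axis, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

rotation_about <- function(axis, theta) {
  a <- unitv(axis)
  ct <- cos(theta); st <- sin(theta)
  outer(a, a) * (1 - ct) + diag(3) * ct +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * st
}

#' Align a molecule to the coordinate frame
#'
#' Applies a rigid transform (rotation + translation) placing `atom1` at the
#' origin and, if `atom2` is given, `atom2` on the non-negative chosen axis.
#' Internal geometry is untouched: all pairwise distances are preserved.
#'
#' @param mol A [molecule()]; coordinates are modified in place.
#' @param atom1 Atom id moved to the origin.
#' @param atom2 Optional second atom id defining the axis direction.
#' @param axis One of "x", "y", "z" (default "z").
#' @return The applied transform, a list with `rotation` (3x3) and
#'   `translation` (length 3) such that `new = rotation %*% old + translation`.
#' @export
align <- function(mol, atom1, atom2 = NULL, axis = c("z", "x", "y")) {
  stopifnot_molecule(mol)
  axis <- match.arg(axis)
  p1 <- pos_of(mol, atom1)
  rot <- diag(3)
  if (!is.null(atom2)) {
    p2 <- pos_of(mol, atom2)
    if (vnorm(p2 - p1) < 1e-9) {
      stop("alignment atoms are coincident", call. = FALSE)
    }
    e <- c(x = 1, y = 2, z = 3)[[axis]]
    target <- c(0, 0, 0); target[e] <- 1
    rot <- rotation_between(p2 - p1, target)
  }
  pos <- atom_positions(mol)
  newpos <- sweep(pos, 2, p1) %*% t(rot)
  set_all_positions(mol, newpos)
  list(rotation = rot, translation = as.numeric(-rot %*% p1))
}

# The side of bond (ba, bb) that moves: atoms reachable from `mover` without
# crossing the bond. If the graph does not split (ring), only `mover` moves.
moving_side <- function(mol, ba, bb, mover) {
  side <- reachable_side(mol, mover, ba, bb)
  if (ba %in% side && bb %in% side) mover else side
}

#' Bond-centric edits: set a length, angle or dihedral
#'
#' Each edit moves one side of the manipulated bond as a rigid unit: the
#' fragment reachable from the later-listed atom without crossing the bond.
#' If the bond lies in a ring (the graph does not split), only the named atom
#' moves. Re-measuring afterwards returns the set value.
#'
#' @param mol A [molecule()]; modified in place.
#' @param bond Bond id for `set_bond_length()`.
#' @param length New length, Angstrom, > 0.
#' @param a,b,c,d Atom ids as in the corresponding measurement.
#' @param degrees Target angle or torsion in degrees.
#' @return The molecule, invisibly.
#' @export
set_bond_length <- function(mol, bond, length) {
  stopifnot_molecule(mol)
  if (!is.finite(length) || length <= 0) {
    stop("bond length must be positive", call. = FALSE)
  }
  i <- bond_row(mol, bond)
  a1 <- mol$bonds$a1[i]; a2 <- mol$bonds$a2[i]
  p1 <- pos_of(mol, a1); p2 <- pos_of(mol, a2)
  dirv <- unitv(p2 - p1)
  shift <- dirv * (length - vnorm(p2 - p1))
  side <- moving_side(mol, a1, a2, a2)
  rows <- atom_row(mol, side)
  mol$atoms[rows, c("x", "y", "z")] <-
    sweep(as.matrix(mol$atoms[rows, c("x", "y", "z")]), 2, -shift)
  invisible(mol)
}

#' @rdname set_bond_length
#' @export
set_angle <- function(mol, a, b, c, degrees) {
  stopifnot_molecule(mol)
  cur <- angle(mol, a, b, c)
  pb <- pos_of(mol, b)
  u <- pos_of(mol, a) - pb; v <- pos_of(mol, c) - pb
  ax <- cross3(u, v)
  if (vnorm(ax) < 1e-9) {
    # collinear arms: any axis orthogonal to u works; deterministic pick
    ref <- if (abs(unitv(u)[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- cross3(u, ref)
  }
  rot <- rotation_about(ax, (degrees - cur) * pi / 180)
  side <- moving_side(mol, b, c, c)
  side <- setdiff(side, b)
  rows <- atom_row(mol, side)
  p <- as.matrix(mol$atoms[rows, c("x", "y", "z")])
  mol$atoms[rows, c("x", "y", "z")] <-
    sweep(sweep(p, 2, pb) %*% t(rot), 2, -pb)
  invisible(mol)
}

#' @rdname set_bond_length
#' @export
set_dihedral <- function(mol, a, b, c, d, degrees) {
  stopifnot_molecule(mol)
  cur <- dihedral(mol, a, b, c, d)
  pb <- pos_of(mol, b); pc <- pos_of(mol, c)
  # a positive rotation of the far side about b->c decreases the measured
  # right-hand-rule torsion, hence the sign
  rot <- rotation_about(pc - pb, (cur - degrees) * pi / 180)
  side <- moving_side(mol, b, c, d)
  side <- setdiff(side, c(b, c))
  rows <- atom_row(mol, side)
  p <- as.matrix(mol$atoms[rows, c("x", "y", "z")])
  mol$atoms[rows, c("x", "y", "z")] <-
    sweep(sweep(p, 2, pb) %*% t(rot), 2, -pb)
  invisible(mol)
}

#' Property tables
#'
#' Tabulates the molecule the way a property-dialog would: every atom, every
#' bond with its length, every connected angle triple (each unordered triple
#' once, canonicalized so the first flanking id is smaller than the last),
#' every connected torsion quadruple, and a one-row molecule summary with
#' formula, weight and counts.
#'
#' @param mol A [molecule()].
#' @return A list of data frames: `atoms`, `bonds`, `angles`, `torsions`,
#'   `molecule`.
#' @export
property_tables <- function(mol) {
  stopifnot_molecule(mol)
  at <- mol$atoms
  atoms_tab <- data.frame(id = at$id, element = if (nrow(at)) {
    element_symbol(at$number)
  } else character(0), at[, c("number", "x", "y", "z", "formal_charge")])

  bd <- mol$bonds
  bonds_tab <- cbind(bd, length = if (nrow(bd)) {
    vapply(seq_len(nrow(bd)),
           function(i) distance(mol, bd$a1[i], bd$a2[i]), numeric(1))
  } else numeric(0))

  angles <- list()
  for (b in at$id) {
    nb <- sort(neighbor_ids(mol, b))
    if (length(nb) >= 2) {
      pairs <- utils::combn(nb, 2)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; c_ <- pairs[2, k]
        angles[[length(angles) + 1]] <- data.frame(
          a = a, b = b, c = c_, degrees = angle(mol, a, b, c_))
      }
    }
  }
  angles_tab <- if (length(angles)) do.call(rbind, angles) else
    data.frame(a = integer(), b = integer(), c = integer(),
               degrees = numeric())

  torsions <- list()
  for (i in seq_len(nrow(bd))) {
    b <- bd$a1[i]; c_ <- bd$a2[i]
    for (a in sort(setdiff(neighbor_ids(mol, b), c_))) {
      for (d in sort(setdiff(neighbor_ids(mol, c_), b))) {
        if (a == d) next  # three-membered ring wrap-around
        torsions[[length(torsions) + 1]] <- data.frame(
          a = a, b = b, c = c_, d = d,
          degrees = dihedral(mol, a, b, c_, d))
      }
    }
  }
  torsions_tab <- if (length(torsions)) do.call(rbind, torsions) else
    data.frame(a = integer(), b = integer(), c = integer(), d = integer(),
               degrees = numeric())

  mol_tab <- data.frame(
    title = mol$title,
    formula = molecular_formula(mol),
    weight = molecular_weight(mol),
    n_atoms = nrow(at), n_bonds = nrow(bd))

  list(atoms = atoms_tab, bonds = bonds_tab, angles = angles_tab,
       torsions = torsions_tab, molecule = mol_tab)
}
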