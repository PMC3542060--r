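# Editable molecular document.
#
# A molecule is an environment-backed S3 object: editor operations
# (add_atom, add_bond, remove_atom, ...) mutate it in place and return the
# handle the caller needs (an atom id, a bond id, a count), mirroring how a
# document is edited in an interactive builder. Atom and bond ids are
# write-once and monotonically assigned; they are never recycled within a
# molecule's lifetime, so a held id either resolves or errors cleanly.

#' Create an empty molecule
#'
#' @param title Optional document title (carried through CML/XYZ output).
#' @return An object of class `molecule`: an editable document holding atoms
#'   (element, Cartesian position in Angstrom, formal and optional partial
#'   charge), bonds (two atom ids and an integer order 1-3) and optionally a
#'   crystallographic unit cell.
#' @examples
#' mol <- molecule("water")
#' o <- add_atom(mol, 8, c(0, 0, 0))
#' h1 <- add_atom(mol, 1, c(0.96, 0, 0))
#' add_bond(mol, o, h1)
#' n_atoms(mol)
#' @export
molecule <- function(title = "") {
  mol <- new.env(parent = emptyenv())
  mol$atoms <- data.frame(
    id = integer(), number = integer(),
    x = numeric(), y = numeric(), z = numeric(),
    formal_charge = integer(), partial_charge = numeric())
  mol$bonds <- data.frame(
    id = integer(), a1 = integer(), a2 = integer(), order = integer())
  mol$unit_cell <- NULL
  mol$title <- as.character(title)[1]
  mol$extra_properties <- list()
  mol$next_atom_id <- 1L
  mol$next_bond_id <- 1L
  class(mol) <- "molecule"
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s\n",
              if (nzchar(x$title)) sQuote(x$title) else "(untitled)"))
  cat(sprintf("  %d atoms, %d bonds%s\n", nrow(x$atoms), nrow(x$bonds),
              if (is.null(x$unit_cell)) "" else ", unit cell"))
  if (nrow(x$atoms) > 0) {
    cat(sprintf("  formula %s, weight %.3f g/mol\n",
                molecular_formula(x), molecular_weight(x)))
  }
  invisible(x)
}

#' @export
format.molecule <- function(x, ...) {
  sprintf("<molecule: %d atoms, %d bonds>", nrow(x$atoms), nrow(x$bonds))
}

stopifnot_molecule <- function(mol) {
  if (!inherits(mol, "molecule")) stop("not a molecule object", call. = FALSE)
  invisible(mol)
}

#' Atom and bond counts, tables and positions
#'
#' @param mol A [molecule()].
#' @return `n_atoms()`/`n_bonds()` integer counts; `atoms()`/`bonds()` copies
#'   of the underlying tables (safe to keep, they do not alias the document);
#'   `atom_positions()` an `n x 3` matrix of Cartesian coordinates in
#'   Angstrom with atom ids as rownames.
#' @export
n_atoms <- function(mol) nrow(stopifnot_molecule(mol)$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(mol) nrow(stopifnot_molecule(mol)$bonds)

#' @rdname n_atoms
#' @export
atoms <- function(mol) stopifnot_molecule(mol)$atoms

#' @rdname n_atoms
#' @export
bonds <- function(mol) stopifnot_molecule(mol)$bonds

#' @rdname n_atoms
#' @export
atom_positions <- function(mol) {
  stopifnot_molecule(mol)
  p <- as.matrix(mol$atoms[, c("x", "y", "z")])
  rownames(p) <- mol$atoms$id
  p
}

atom_row <- function(mol, id) {
  i <- match(id, mol$atoms$id)
  if (any(is.na(i))) {
    stop(sprintf("no atom with id %s", paste(id[is.na(i)], collapse = ", ")),
         call. = FALSE)
  }
  i
}

bond_row <- function(mol, id) {
  i <- match(id, mol$bonds$id)
  if (any(is.na(i))) {
    stop(sprintf("no bond with id %s", paste(id[is.na(i)], collapse = ", ")),
         call. = FALSE)
  }
  i
}

#' Edit a molecule: atoms and bonds
#'
#' `add_atom()` appends an atom and returns its id; `add_bond()` connects two
#' existing atoms and returns the bond id; `remove_atom()` deletes an atom
#' together with every incident bond; `remove_bond()` deletes one bond. Ids
#' are assigned monotonically and never reused.
#'
#' @param mol A [molecule()]; modified in place.
#' @param number Atomic number, integer in `[1, 118]`.
#' @param position Numeric length-3 Cartesian position, Angstrom.
#' @param formal_charge Integer formal charge (default 0).
#' @param partial_charge Optional numeric partial charge.
#' @param a1,a2 Atom ids to connect; must exist, be distinct and not already
#'   bonded.
#' @param order Integer bond order, one of 1, 2, 3.
#' @param id Atom (or bond) id to remove.
#' @return `add_atom()` and `add_bond()` the new integer id, invisibly for
#'   the removers.
#' @export
add_atom <- function(mol, number, position, formal_charge = 0L,
                     partial_charge = NA_real_) {
  stopifnot_molecule(mol)
  if (length(number) != 1) stop("one atom at a time", call. = FALSE)
  check_atomic_number(number)
  position <- as.numeric(position)
  if (length(position) != 3 || any(!is.finite(position))) {
    stop("position must be a finite length-3 vector", call. = FALSE)
  }
  id <- mol$next_atom_id
  mol$next_atom_id <- id + 1L
  mol$atoms <- rbind(mol$atoms, data.frame(
    id = id, number = as.integer(number),
    x = position[1], y = position[2], z = position[3],
    formal_charge = as.integer(formal_charge),
    partial_charge = as.numeric(partial_charge)))
  id
}

#' @rdname add_atom
#' @export
add_bond <- function(mol, a1, a2, order = 1L) {
  stopifnot_molecule(mol)
  atom_row(mol, c(a1, a2))
  if (a1 == a2) stop("cannot bond an atom to itself", call. = FALSE)
  if (!order %in% 1:3) stop("bond order must be 1, 2 or 3", call. = FALSE)
  lo <- min(a1, a2); hi <- max(a1, a2)
  dup <- mol$bonds$a1 == lo & mol$bonds$a2 == hi
  if (any(dup)) {
    stop(sprintf("atoms %d and %d are already bonded", lo, hi), call. = FALSE)
  }
  id <- mol$next_bond_id
  mol$next_bond_id <- id + 1L
  mol$bonds <- rbind(mol$bonds, data.frame(
    id = id, a1 = lo, a2 = hi, order = as.integer(order)))
  id
}

#' @rdname add_atom
#' @export
remove_atom <- function(mol, id) {
  stopifnot_molecule(mol)
  i <- atom_row(mol, id)
  mol$atoms <- mol$atoms[-i, , drop = FALSE]
  keep <- mol$bonds$a1 != id & mol$bonds$a2 != id
  mol$bonds <- mol$bonds[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  rownames(mol$bonds) <- NULL
  invisible(mol)
}

#' @rdname add_atom
#' @export
remove_bond <- function(mol, id) {
  stopifnot_molecule(mol)
  i <- bond_row(mol, id)
  mol$bonds <- mol$bonds[-i, , drop = FALSE]
  rownames(mol$bonds) <- NULL
  invisible(mol)
}

#' Move atoms
#'
#' @param mol A [molecule()].
#' @param id Atom id.
#' @param position New Cartesian position, Angstrom.
#' @export
set_atom_position <- function(mol, id, position) {
  stopifnot_molecule(mol)
  i <- atom_row(mol, id)
  position <- as.numeric(position)
  if (length(position) != 3 || any(!is.finite(position))) {
    stop("position must be a finite length-3 vector", call. = FALSE)
  }
  mol$atoms[i, c("x", "y", "z")] <- position
  invisible(mol)
}

set_all_positions <- function(mol, pos) {
  mol$atoms[, c("x", "y", "z")] <- pos
  invisible(mol)
}

#' Deep-copy a molecule document
#'
#' Molecules have reference semantics; `clone_molecule()` gives an
#' independent copy.
#' @param mol A [molecule()].
#' @return A new `molecule` with identical contents and id counters.
#' @export
clone_molecule <- function(mol) {
  stopifnot_molecule(mol)
  out <- molecule(mol$title)
  for (f in ls(mol)) assign(f, get(f, envir = mol), envir = out)
  out
}

#' Molecular formula and weight
#'
#' The formula follows Hill order: carbon first, then hydrogen, then all
#' other elements alphabetically; with no carbon present, all elements are
#' alphabetical. The weight is the sum of standard atomic masses.
#'
#' @param mol A [molecule()].
#' @return A character scalar (empty string for an empty molecule) or the
#'   weight in g/mol.
#' @examples
#' molecular_formula(make_molecule("water"))
#' @export
molecular_formula <- function(mol) {
  stopifnot_molecule(mol)
  if (nrow(mol$atoms) == 0) return("")
  counts <- table(element_symbol(mol$atoms$number))
  syms <- names(counts)
  if ("C" %in% syms) {
    first <- intersect(c("C", "H"), syms)
    rest <- sort(setdiff(syms, first))
    ord <- c(first, rest)
  } else {
    ord <- sort(syms)
  }
  paste0(vapply(ord, function(s) {
    n <- counts[[s]]
    if (n == 1) s else paste0(s, n)
  }, character(1)), collapse = "")
}

#' @rdname molecular_formula
#' @export
molecular_weight <- function(mol) {
  stopifnot_molecule(mol)
  if (nrow(mol$atoms) == 0) return(0.0)
  sum(atomic_mass(mol$atoms$number))
}

#' Crystallographic unit cell
#'
#' `set_unit_cell()` attaches a cell from lattice parameters; `unit_cell()`
#' returns it (or `NULL`). The derived 3x3 cell matrix holds the lattice
#' vectors as rows, with the conventional orientation a along x and b in the
#' xy plane.
#'
#' @param mol A [molecule()].
#' @param a,b,c Lattice lengths, Angstrom, > 0.
#' @param alpha,beta,gamma Lattice angles, degrees, each in (0, 180).
#' @return `unit_cell()` a list with fields `a,b,c,alpha,beta,gamma,matrix`.
#' @export
set_unit_cell <- function(mol, a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot_molecule(mol)
  lens <- c(a, b, c); angs <- c(alpha, beta, gamma)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("cell lengths must be positive", call. = FALSE)
  }
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  m <- cell_matrix(a, b, c, alpha, beta, gamma)
  if (abs(det(m)) < 1e-10) stop("degenerate unit cell", call. = FALSE)
  mol$unit_cell <- list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                        gamma = gamma, matrix = m)
  invisible(mol)
}

#' @rdname set_unit_cell
#' @export
unit_cell <- function(mol) stopifnot_molecule(mol)$unit_cell

cell_matrix <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v1 <- c(a, 0, 0)
  v2 <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 < 0) stop("inconsistent cell angles", call. = FALSE)
  v3 <- c(cx, cy, sqrt(cz2))
  rbind(v1, v2, v3, deparse.level = 0)
}

#' Build a supercell
#'
#' Replicates the molecule `na x nb x nc` times along its lattice vectors.
#' Replica atoms are translated by integer lattice combinations; the new cell
#' lengths are scaled by the repeat counts. Bonds are replicated within each
#' image (no bonding across images; run [perceive_bonds()] afterwards for
#' that).
#'
#' @param mol A [molecule()] with a unit cell.
#' @param na,nb,nc Positive integer repeat counts.
#' @return A new `molecule` (the input is untouched).
#' @export
build_supercell <- function(mol, na, nb, nc) {
  stopifnot_molecule(mol)
  uc <- mol$unit_cell
  if (is.null(uc)) stop("molecule has no unit cell", call. = FALSE)
  reps <- c(na, nb, nc)
  if (any(reps < 1) || any(reps != as.integer(reps))) {
    stop("repeat counts must be positive integers", call. = FALSE)
  }
  out <- molecule(mol$title)
  out$extra_properties <- mol$extra_properties
  for (i in seq_len(na) - 1L) {
    for (j in seq_len(nb) - 1L) {
      for (k in seq_len(nc) - 1L) {
        shift <- i * uc$matrix[1, ] + j * uc$matrix[2, ] + k * uc$matrix[3, ]
        idmap <- integer(0)
        for (r in seq_len(nrow(mol$atoms))) {
          at <- mol$atoms[r, ]
          nid <- add_atom(out, at$number, c(at$x, at$y, at$z) + shift,
                          at$formal_charge, at$partial_charge)
          idmap[[as.character(at$id)]] <- nid
        }
        for (r in seq_len(nrow(mol$bonds))) {
          bd <- mol$bonds[r, ]
          add_bond(out, idmap[[as.character(bd$a1)]],
                   idmap[[as.character(bd$a2)]], bd$order)
        }
      }
    }
  }
  set_unit_cell(out, uc$a * na, uc$b * nb, uc$c * nc,
                uc$alpha, uc$beta, uc$gamma)
  out
}

#' Distance-based bond perception
#'
#' Adds a single bond between every unbonded atom pair whose separation is
#' below the sum of the two covalent radii plus `tolerance`. Existing bonds
#' are never touched or duplicated.
#'
#' @param mol A [molecule()]; modified in place.
#' @param tolerance Slack added to the covalent-radius sum, Angstrom
#'   (default 0.45, a common heuristic).
#' @return The number of bonds created, invisibly the molecule via its
#'   reference semantics.
#' @export
perceive_bonds <- function(mol, tolerance = 0.45) {
  stopifnot_molecule(mol)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  n <- nrow(mol$atoms)
  if (n < 2) return(0L)
  pos <- atom_positions(mol)
  rad <- covalent_radius(mol$atoms$number)
  ids <- mol$atoms$id
  have <- paste(mol$bonds$a1, mol$bonds$a2)
  created <- 0L
  d <- as.matrix(stats::dist(pos))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] < rad[i] + rad[j] + tolerance) {
        key <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]))
        if (!key %in% have) {
          add_bond(mol, ids[i], ids[j], 1L)
          created <- created + 1L
        }
      }
    }
  }
  created
}

# Adjacency helpers used by builder/geometry -------------------------------

neighbor_ids <- function(mol, id) {
  b <- mol$bonds
  c(b$a2[b$a1 == id], b$a1[b$a2 == id])
}

# Sum of bond orders at an atom.
order_sum <- function(mol, id) {
  b <- mol$bonds
  sum(b$order[b$a1 == id | b$a2 == id])
}

# Atom ids reachable from `from` without crossing the bond (ba, bb).
reachable_side <- function(mol, from, ba, bb) {
  seen <- from
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (id in frontier) {
      for (nb in neighbor_ids(mol, id)) {
        blocked <- (id == ba && nb == bb) || (id == bb && nb == ba)
        if (!blocked && !nb %in% seen) nxt <- c(nxt, nb)
      }
    }
    seen <- c(seen, nxt)
    frontier <- unique(nxt)
  }
  unique(seen)
}
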