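# Editor semantics: valence-driven hydrogen adjustment, bond-order cycling,
# element mutation, fragment insertion.

# Idealized direction templates by steric number (existing neighbors + slots
# to fill). Units vectors; deterministic order so placement is reproducible.
direction_template <- function(m) {
  s <- 1 / sqrt(3)
  switch(as.character(m),
    "1" = rbind(c(1, 0, 0)),
    "2" = rbind(c(1, 0, 0), c(-1, 0, 0)),
    "3" = rbind(c(1, 0, 0),
                c(-0.5, sqrt(3) / 2, 0),
                c(-0.5, -sqrt(3) / 2, 0)),
    rbind(c(s, s, s), c(s, -s, -s), c(-s, s, -s), c(-s, -s, s)))
}

# Rotation (via Kabsch/SVD, det forced to +1) aligning the first k template
# directions with the existing neighbor directions.
template_rotation <- function(template_k, existing) {
  h <- t(template_k) %*% existing
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Adjust hydrogens to satisfy valence
#'
#' For every targeted heavy atom with a nonzero target valence the hydrogen
#' count is adjusted so the sum of bond orders reaches the target: deficient
#' atoms get new single-bonded hydrogens at the standard X-H distance on the
#' least-crowded directions; atoms over their valence lose excess hydrogen
#' neighbors, highest atom id first. Atoms whose element has no entry in the
#' valence table (target 0) are left untouched, as are hydrogens themselves
#' when already bonded.
#'
#' @param mol A [molecule()]; modified in place.
#' @param atom_id Optional single atom id to restrict the adjustment to;
#'   default treats every atom.
#' @return Integer vector `c(added = , removed = )`.
#' @examples
#' m <- molecule()
#' add_atom(m, 6, c(0, 0, 0))
#' adjust_hydrogens(m)   # c(added = 4, removed = 0) -> methane
#' @export
adjust_hydrogens <- function(mol, atom_id = NULL) {
  stopifnot_molecule(mol)
  targets <- if (is.null(atom_id)) mol$atoms$id else {
    atom_row(mol, atom_id)
    atom_id
  }
  added <- 0L; removed <- 0L
  for (id in targets) {
    if (!id %in% mol$atoms$id) next  # removed as an excess H of an earlier atom
    z <- mol$atoms$number[atom_row(mol, id)]
    target <- .target_valences[z]
    if (target == 0L) next
    if (z == 1L && length(neighbor_ids(mol, id)) > 0) next
    d <- target - order_sum(mol, id)
    if (d > 0) {
      place_hydrogens(mol, id, d)
      added <- added + d
    } else if (d < 0) {
      nb <- neighbor_ids(mol, id)
      hnb <- nb[mol$atoms$number[atom_row(mol, nb)] == 1L]
      # only single-bonded hydrogens are candidates for removal
      hnb <- sort(hnb, decreasing = TRUE)
      take <- utils::head(hnb, -d)
      for (h in take) remove_atom(mol, h)
      removed <- removed + length(take)
    }
  }
  c(added = added, removed = removed)
}

place_hydrogens <- function(mol, id, d) {
  z <- mol$atoms$number[atom_row(mol, id)]
  len <- if (as.character(z) %in% names(.xh_lengths)) {
    .xh_lengths[[as.character(z)]]
  } else .xh_default
  p0 <- pos_of(mol, id)
  nb <- neighbor_ids(mol, id)
  k <- length(nb)
  m <- k + d
  tpl <- direction_template(m)
  if (k == 0) {
    dirs <- tpl[seq_len(d), , drop = FALSE]
  } else {
    existing <- t(vapply(nb, function(n) unitv(pos_of(mol, n) - p0),
                         numeric(3)))
    kk <- min(k, nrow(tpl))
    rot <- template_rotation(tpl[seq_len(kk), , drop = FALSE],
                             existing[seq_len(kk), , drop = FALSE])
    rest <- tpl[setdiff(seq_len(nrow(tpl)), seq_len(kk)), , drop = FALSE]
    dirs <- rest %*% rot
    if (nrow(dirs) < d) {
      # more hydrogens requested than template slots; repel from centroid
      extra <- -colSums(existing)
      if (vnorm(extra) < 1e-8) extra <- c(0, 0, 1)
      dirs <- rbind(dirs, matrix(unitv(extra), nrow = d - nrow(dirs),
                                 ncol = 3, byrow = TRUE))
    }
    dirs <- dirs[seq_len(d), , drop = FALSE]
  }
  for (r in seq_len(d)) {
    h <- add_atom(mol, 1L, p0 + dirs[r, ] * len)
    add_bond(mol, id, h, 1L)
  }
}

#' Cycle a bond order
#'
#' Advances the order of an existing bond through the editor cycle
#' single -> double -> triple -> single.
#'
#' @param mol A [molecule()]; modified in place.
#' @param bond_id Bond id.
#' @return The new integer order.
#' @export
cycle_bond_order <- function(mol, bond_id) {
  stopifnot_molecule(mol)
  i <- bond_row(mol, bond_id)
  new_order <- mol$bonds$order[i] %% 3L + 1L
  mol$bonds$order[i] <- new_order
  new_order
}

#' Change an atom's element
#'
#' Position, charges and all bonds are preserved; only the atomic number
#' changes.
#'
#' @param mol A [molecule()]; modified in place.
#' @param atom_id Atom id.
#' @param number New atomic number in `[1, 118]`.
#' @return The molecule, invisibly.
#' @export
change_element <- function(mol, atom_id, number) {
  stopifnot_molecule(mol)
  check_atomic_number(number)
  i <- atom_row(mol, atom_id)
  mol$atoms$number[i] <- as.integer(number)
  invisible(mol)
}

#' Insert a fragment
#'
#' Appends a copy of the fragment's atoms and bonds with fresh ids,
#' translated by `offset`. No bonds to pre-existing atoms are created; use
#' the returned ids to connect or transform the new piece.
#'
#' @param mol A [molecule()]; modified in place.
#' @param fragment A `molecule` (e.g. from [make_molecule()] or
#'   [fragment_library()]).
#' @param offset Numeric length-3 translation, Angstrom.
#' @return Integer vector of the newly created atom ids, in fragment atom
#'   order.
#' @export
insert_fragment <- function(mol, fragment, offset = c(0, 0, 0)) {
  stopifnot_molecule(mol)
  stopifnot_molecule(fragment)
  offset <- as.numeric(offset)
  if (length(offset) != 3 || any(!is.finite(offset))) {
    stop("offset must be a finite length-3 vector", call. = FALSE)
  }
  idmap <- integer(0)
  for (r in seq_len(nrow(fragment$atoms))) {
    at <- fragment$atoms[r, ]
    nid <- add_atom(mol, at$number, c(at$x, at$y, at$z) + offset,
                    at$formal_charge, at$partial_charge)
    idmap[[as.character(at$id)]] <- nid
  }
  for (r in seq_len(nrow(fragment$bonds))) {
    bd <- fragment$bonds[r, ]
    add_bond(mol, idmap[[as.character(bd$a1)]],
             idmap[[as.character(bd$a2)]], bd$order)
  }
  unname(idmap)
}

#' Built-in fragment library
#'
#' @param name Optional fragment name; with no argument, the available names.
#' @return A character vector of names, or the named fragment as a
#'   [molecule()].
#' @export
fragment_library <- function(name = NULL) {
  available <- c("water", "methane", "ethene", "ethane", "benzene",
                 "ethanol", "glycine", "h2")
  if (is.null(name)) return(available)
  if (!name %in% available) {
    stop(sprintf("unknown fragment '%s'", name), call. = FALSE)
  }
  make_molecule(name)
}

#' Target valence lookup
#'
#' The neutral lowest-common valences used by [adjust_hydrogens()]:
#' H 1, B 3, C 4, N 3, O 2, F 1, Si 4, P 3, S 2, Cl 1, Br 1, I 1; every other
#' element 0 (no automatic hydrogens).
#'
#' @param z Atomic number(s).
#' @return Integer vector of target valences.
#' @export
target_valence <- function(z) {
  check_atomic_number(z)
  .target_valences[z]
}
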