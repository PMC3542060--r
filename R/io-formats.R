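# XYZ, Gaussian cube and minimal PDB I/O, plus quantum input-deck text
# generation. All writers emit "\n" line endings and C-locale numbers.

#' Read and write XYZ
#'
#' Standard XYZ layout: atom count, comment line (carries the molecule
#' title), then one `symbol x y z` line per atom in Angstrom. A count that
#' does not match the body is an error.
#'
#' @param text XYZ file content.
#' @param mol A [molecule()].
#' @return `read_xyz()` a [molecule()]; `write_xyz()` a single string.
#' @export
read_xyz <- function(text) {
  lines <- split_lines(text)
  if (length(lines) < 2) stop("XYZ input too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("first XYZ line must be the atom count", call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(sprintf("XYZ header declares %d atoms but %d lines follow",
                 n, length(body)), call. = FALSE)
  }
  mol <- molecule(title = trimws(lines[2]))
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 4) {
      stop(sprintf("malformed XYZ atom line %d", i + 2), call. = FALSE)
    }
    z <- element_number(tok[1])
    if (is.na(z)) {
      z <- suppressWarnings(as.integer(tok[1]))
      if (is.na(z)) stop(sprintf("unknown element '%s' on line %d",
                                 tok[1], i + 2), call. = FALSE)
    }
    add_atom(mol, z, as.numeric(tok[2:4]))
  }
  mol
}

#' @rdname read_xyz
#' @export
write_xyz <- function(mol) {
  stopifnot_molecule(mol)
  at <- mol$atoms
  lines <- c(as.character(nrow(at)), mol$title,
             if (nrow(at)) sprintf("%-2s %14.6f %14.6f %14.6f",
                                   element_symbol(at$number),
                                   at$x, at$y, at$z))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read and write Gaussian cube files
#'
#' Cube semantics: two comment lines, origin and three axis records in Bohr,
#' atom records, then the scalar values nested with the first axis outermost
#' and the third innermost, six values per line. Geometry is converted
#' Bohr to Angstrom on read and back on write. A negative atom count in the
#' header signals a trailing orbital-index record, surfaced as `mo_indices`.
#'
#' @param text Cube file content.
#' @param mol A [molecule()] (positions in Angstrom).
#' @param grid A [volumetric_grid()] with values.
#' @param mo_indices Optional integer orbital indices to record in the
#'   header convention.
#' @return `read_cube()` a list with `molecule`, `grid` (Angstrom) and
#'   `mo_indices` (`NULL` when absent); `write_cube()` a single string.
#' @export
read_cube <- function(text) {
  lines <- split_lines(text)
  if (length(lines) < 6) stop("cube input too short", call. = FALSE)
  toks <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  hdr <- as.numeric(toks(3))
  natom <- as.integer(hdr[1])
  has_mo <- natom < 0
  natom <- abs(natom)
  origin_bohr <- hdr[2:4]
  counts <- integer(3); axes_bohr <- matrix(0, 3, 3)
  for (a in 1:3) {
    v <- as.numeric(toks(3 + a))
    counts[a] <- as.integer(v[1])
    axes_bohr[a, ] <- v[2:4]
  }
  mol <- molecule("cube import")
  for (i in seq_len(natom)) {
    v <- as.numeric(toks(6 + i))
    add_atom(mol, as.integer(v[1]), v[3:5] * .bohr_to_angstrom)
  }
  cursor <- 6 + natom + 1
  mo_indices <- NULL
  if (has_mo) {
    v <- as.numeric(toks(cursor))
    mo_indices <- as.integer(v[-1][seq_len(v[1])])
    cursor <- cursor + 1
  }
  vals <- numeric(0)
  if (cursor <= length(lines)) {
    vals <- as.numeric(unlist(strsplit(trimws(lines[cursor:length(lines)]),
                                       "\\s+")))
    vals <- vals[!is.na(vals)]
  }
  expected <- prod(counts)
  if (length(vals) != expected) {
    stop(sprintf("cube value section: expected %d values, found %d",
                 expected, length(vals)), call. = FALSE)
  }
  # file order: x outermost, z innermost -> array indexed [ix, iy, iz]
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  grid <- volumetric_grid(origin_bohr * .bohr_to_angstrom,
                          axes_bohr * .bohr_to_angstrom,
                          values = arr, unit = "angstrom")
  list(molecule = mol, grid = grid, mo_indices = mo_indices)
}

#' @rdname read_cube
#' @export
write_cube <- function(mol, grid, mo_indices = NULL) {
  stopifnot_molecule(mol)
  if (is.null(grid$values)) stop("grid has no values", call. = FALSE)
  to_bohr <- if (grid$unit == "angstrom") 1 / .bohr_to_angstrom else 1
  origin <- grid$origin * to_bohr
  axes <- grid$axes * to_bohr
  at <- mol$atoms
  natom_field <- if (is.null(mo_indices)) nrow(at) else -nrow(at)
  out <- c(
    sprintf("molcraft cube: %s", mol$title),
    "scalar field",
    sprintf("%5d%12.6f%12.6f%12.6f", natom_field,
            origin[1], origin[2], origin[3]),
    vapply(1:3, function(a) {
      sprintf("%5d%12.6f%12.6f%12.6f", grid$counts[a],
              axes[a, 1], axes[a, 2], axes[a, 3])
    }, character(1)),
    if (nrow(at)) sprintf("%5d%12.6f%12.6f%12.6f%12.6f",
                          at$number, as.numeric(at$number),
                          at$x / .bohr_to_angstrom,
                          at$y / .bohr_to_angstrom,
                          at$z / .bohr_to_angstrom))
  if (!is.null(mo_indices)) {
    out <- c(out, paste0(sprintf("%5d", c(length(mo_indices), mo_indices)),
                         collapse = ""))
  }
  # x outermost, z innermost; each (x, y) scanline starts a new line
  n <- grid$counts
  vlines <- character(0)
  for (ix in seq_len(n[1])) {
    for (iy in seq_len(n[2])) {
      row <- grid$values[ix, iy, ]
      pieces <- split(row, (seq_along(row) - 1) %/% 6)
      vlines <- c(vlines, vapply(pieces, function(p) {
        paste0(sprintf("%13.5E", p), collapse = "")
      }, character(1)))
    }
  }
  paste0(paste(c(out, vlines), collapse = "\n"), "\n")
}

#' Read ATOM/HETATM records from PDB text
#'
#' A minimal fixed-column reader: coordinates from columns 31-54, element
#' from columns 77-78 when present, otherwise inferred from the atom name
#' (digits stripped, two-letter symbol tried before one-letter). No CONECT,
#' altloc or model handling.
#'
#' @param text PDB file content.
#' @return A [molecule()].
#' @export
read_pdb_atoms <- function(text) {
  lines <- split_lines(text)
  mol <- molecule("pdb import")
  for (i in seq_along(lines)) {
    ln <- lines[i]
    rec <- toupper(substr(ln, 1, 6))
    if (!startsWith(rec, "ATOM") && !startsWith(rec, "HETATM")) next
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop(sprintf("unparseable coordinates on line %d", i), call. = FALSE)
    }
    el <- trimws(substr(ln, 77, 78))
    z <- if (nzchar(el)) element_number(el) else NA_integer_
    if (is.na(z)) {
      name <- gsub("[0-9']", "", trimws(substr(ln, 13, 16)))
      z <- element_number(substr(name, 1, 2))
      if (is.na(z)) z <- element_number(substr(name, 1, 1))
      if (is.na(z)) {
        stop(sprintf("cannot infer element on line %d", i), call. = FALSE)
      }
    }
    add_atom(mol, z, xyz)
  }
  mol
}

#' Generate a quantum input deck
#'
#' Deterministic text template in one of two styles resembling the common
#' input layouts of general-purpose quantum codes: a keyword block built
#' from theory, basis, charge and multiplicity, followed by one
#' `symbol x y z` coordinate line per atom. Changing one option regenerates
#' the deck with only the affected token changed.
#'
#' @param mol A non-empty [molecule()].
#' @param code_style "gamess" or "nwchem" (the two template families).
#' @param charge Total charge.
#' @param multiplicity Spin multiplicity, >= 1.
#' @param theory Method keyword (default "HF").
#' @param basis Basis-set keyword (default "STO-3G").
#' @return The input deck as a single string.
#' @export
generate_input_deck <- function(mol, code_style = c("gamess", "nwchem"),
                                charge = 0L, multiplicity = 1L,
                                theory = "HF", basis = "STO-3G") {
  stopifnot_molecule(mol)
  code_style <- match.arg(code_style)
  if (n_atoms(mol) == 0) stop("empty molecule", call. = FALSE)
  if (multiplicity < 1) stop("multiplicity must be >= 1", call. = FALSE)
  at <- mol$atoms
  if (code_style == "gamess") {
    coords <- sprintf("%-2s %5.1f %14.6f %14.6f %14.6f",
                      element_symbol(at$number), as.numeric(at$number),
                      at$x, at$y, at$z)
    lines <- c(
      sprintf(" $CONTRL SCFTYP=%s RUNTYP=ENERGY ICHARG=%d MULT=%d $END",
              if (multiplicity == 1) "RHF" else "ROHF",
              as.integer(charge), as.integer(multiplicity)),
      sprintf(" $BASIS GBASIS=%s $END", basis),
      " $DATA",
      if (nzchar(mol$title)) mol$title else "molecule",
      "C1",
      coords,
      " $END")
  } else {
    coords <- sprintf(" %-2s %14.6f %14.6f %14.6f",
                      element_symbol(at$number), at$x, at$y, at$z)
    lines <- c(
      "start molecule",
      sprintf("title \"%s\"", if (nzchar(mol$title)) mol$title else
        "molecule"),
      sprintf("charge %d", as.integer(charge)),
      "geometry units angstroms",
      coords,
      "end",
      "basis",
      sprintf(" * library %s", basis),
      "end",
      sprintf("task %s energy", tolower(theory)))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
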