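# Chemical Markup Language I/O — the native document format.
#
# Dialect: the common molecular-convention subset. Atoms are written as
# <atom id elementType x3 y3 z3 [formalCharge]> inside <atomArray>, bonds as
# <bond atomRefs2="ai aj" order="1|2|3"> inside <bondArray>. Any other child
# element of <molecule> is preserved verbatim across a read/write cycle
# (CML's extensibility contract). No namespace is emitted: the subset is
# deliberately minimal and documented here rather than tied to a schema
# version.

#' Read and write CML
#'
#' `read_cml()` accepts a CML string (or file content) and returns the
#' molecule; unknown child elements of `<molecule>` are kept in the
#' document's `extra_properties` and re-emitted by `write_cml()`.
#' Malformed XML fails with the parser's line diagnostics; a bond whose
#' `atomRefs2` mentions an undefined atom id is an error.
#'
#' @param text CML document text.
#' @param mol A [molecule()].
#' @return `read_cml()` a [molecule()]; `write_cml()` a single string.
#' @export
read_cml <- function(text) {
  doc <- xml2::read_xml(paste(split_lines(text), collapse = "\n"))
  root <- if (xml2::xml_name(doc) == "molecule") doc else {
    hit <- xml2::xml_find_first(doc, ".//molecule")
    if (inherits(hit, "xml_missing")) {
      stop("no <molecule> element found", call. = FALSE)
    }
    hit
  }
  mol <- molecule(title = xml2::xml_attr(root, "title", default = ""))

  atom_nodes <- xml2::xml_find_all(root, "./atomArray/atom")
  idmap <- integer(0)
  for (node in atom_nodes) {
    cml_id <- xml2::xml_attr(node, "id")
    sym <- xml2::xml_attr(node, "elementType")
    z <- element_number(sym)
    if (is.na(z)) {
      stop(sprintf("unknown element '%s' in atom '%s'", sym, cml_id),
           call. = FALSE)
    }
    xyz <- as.numeric(c(xml2::xml_attr(node, "x3"),
                        xml2::xml_attr(node, "y3"),
                        xml2::xml_attr(node, "z3")))
    if (any(is.na(xyz))) {
      stop(sprintf("atom '%s' lacks numeric x3/y3/z3 coordinates", cml_id),
           call. = FALSE)
    }
    fc <- xml2::xml_attr(node, "formalCharge")
    id <- add_atom(mol, z, xyz,
                   formal_charge = if (is.na(fc)) 0L else as.integer(fc))
    idmap[[cml_id]] <- id
  }

  for (node in xml2::xml_find_all(root, "./bondArray/bond")) {
    refs <- strsplit(trimws(xml2::xml_attr(node, "atomRefs2")), "\\s+")[[1]]
    if (length(refs) != 2 || !all(refs %in% names(idmap))) {
      stop(sprintf("bond atomRefs2 '%s' references undefined atoms",
                   xml2::xml_attr(node, "atomRefs2")), call. = FALSE)
    }
    ord <- xml2::xml_attr(node, "order")
    ord <- if (is.na(ord)) 1L else as.integer(ord)
    add_bond(mol, idmap[[refs[1]]], idmap[[refs[2]]], ord)
  }

  extras <- list()
  for (child in xml2::xml_children(root)) {
    nm <- xml2::xml_name(child)
    if (!nm %in% c("atomArray", "bondArray")) {
      extras[[length(extras) + 1]] <- as.character(child)
    }
  }
  mol$extra_properties <- extras
  mol
}

#' @rdname read_cml
#' @export
write_cml <- function(mol) {
  stopifnot_molecule(mol)
  doc <- xml2::xml_new_root("molecule")
  if (nzchar(mol$title)) xml2::xml_set_attr(doc, "title", mol$title)
  aa <- xml2::xml_add_child(doc, "atomArray")
  for (r in seq_len(nrow(mol$atoms))) {
    at <- mol$atoms[r, ]
    node <- xml2::xml_add_child(aa, "atom")
    xml2::xml_set_attr(node, "id", paste0("a", at$id))
    xml2::xml_set_attr(node, "elementType", element_symbol(at$number))
    xml2::xml_set_attr(node, "x3", num_token(at$x))
    xml2::xml_set_attr(node, "y3", num_token(at$y))
    xml2::xml_set_attr(node, "z3", num_token(at$z))
    if (at$formal_charge != 0L) {
      xml2::xml_set_attr(node, "formalCharge", as.character(at$formal_charge))
    }
  }
  if (nrow(mol$bonds) > 0) {
    ba <- xml2::xml_add_child(doc, "bondArray")
    for (r in seq_len(nrow(mol$bonds))) {
      bd <- mol$bonds[r, ]
      node <- xml2::xml_add_child(ba, "bond")
      xml2::xml_set_attr(node, "atomRefs2",
                         sprintf("a%d a%d", bd$a1, bd$a2))
      xml2::xml_set_attr(node, "order", as.character(bd$order))
    }
  }
  for (extra in mol$extra_properties) {
    frag <- tryCatch(xml2::read_xml(extra), error = function(e) NULL)
    if (!is.null(frag)) xml2::xml_add_child(doc, frag)
  }
  as.character(doc)
}

# Locale-independent fixed-point coordinate token.
num_token <- function(x) sprintf("%.6f", x)
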