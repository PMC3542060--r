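# Painter abstraction: molecule + representation + color scheme -> a
# renderer-independent scene of spheres, cylinders and meshes, exported as
# POV-Ray text.

#' Atom color schemes
#'
#' `color_scheme()` builds a scheme descriptor; `color_atoms()` applies it,
#' returning one RGB triple per atom:
#' * `element` — the embedded CPK-style palette by atomic number;
#' * `atom_index` — atom position in the document mapped through a linear
#'   blue-to-red gradient normalized to the index range;
#' * `distance` — distance from a reference atom, same gradient (a
#'   degenerate range maps everything to the low/blue end);
#' * `charge` — partial charge through a red-white-blue diverging map
#'   centered at 0 (missing charges count as 0);
#' * `custom` — one fixed RGB for every atom;
#' * `selection` — a fixed RGB for an explicit atom-id set, the element
#'   palette elsewhere.
#'
#' @param kind One of "element", "atom_index", "charge", "distance",
#'   "custom", "selection".
#' @param rgb Length-3 RGB in `[0,1]` (custom/selection).
#' @param reference_atom Reference atom id (distance).
#' @param atom_ids Atom-id set (selection).
#' @param scheme A scheme from `color_scheme()`.
#' @param mol A [molecule()].
#' @return `color_atoms()`: an `n_atoms x 3` matrix with values in `[0,1]`.
#' @export
color_scheme <- function(kind = c("element", "atom_index", "charge",
                                  "distance", "custom", "selection"),
                         rgb = c(1, 0, 0), reference_atom = NULL,
                         atom_ids = integer(0)) {
  kind <- match.arg(kind)
  if (kind %in% c("custom", "selection")) {
    rgb <- as.numeric(rgb)
    if (length(rgb) != 3 || any(rgb < 0) || any(rgb > 1)) {
      stop("rgb must be three values in [0,1]", call. = FALSE)
    }
  }
  structure(list(kind = kind, rgb = rgb, reference_atom = reference_atom,
                 atom_ids = atom_ids), class = "color_scheme")
}

# blue (low) -> red (high), linear
gradient_rgb <- function(x01) {
  x01 <- pmin(pmax(x01, 0), 1)
  cbind(x01, 0.2 + 0 * x01, 1 - x01)
}

# red (negative) - white (0) - blue (positive), diverging
diverging_rgb <- function(x) {
  lim <- max(abs(x), 1e-12)
  s <- x / lim
  r <- ifelse(s < 0, 1, 1 - s)
  g <- 1 - abs(s)
  b <- ifelse(s < 0, 1 + s, 1)
  cbind(r, g, b)
}

#' @rdname color_scheme
#' @export
color_atoms <- function(scheme, mol) {
  stopifnot_molecule(mol)
  if (!inherits(scheme, "color_scheme")) {
    stop("not a color scheme", call. = FALSE)
  }
  at <- mol$atoms
  n <- nrow(at)
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  switch(scheme$kind,
    element = .element_colors[at$number, , drop = FALSE],
    atom_index = {
      x <- seq_len(n) - 1
      gradient_rgb(if (n > 1) x / (n - 1) else rep(0, n))
    },
    distance = {
      if (is.null(scheme$reference_atom)) {
        stop("distance scheme needs a reference atom", call. = FALSE)
      }
      p0 <- pos_of(mol, scheme$reference_atom)
      d <- sqrt(rowSums(sweep(atom_positions(mol), 2, p0)^2))
      rng <- range(d)
      gradient_rgb(if (diff(rng) > 1e-12) (d - rng[1]) / diff(rng) else
        rep(0, n))
    },
    charge = {
      q <- at$partial_charge
      q[is.na(q)] <- 0
      diverging_rgb(q)
    },
    custom = matrix(scheme$rgb, n, 3, byrow = TRUE),
    selection = {
      cols <- .element_colors[at$number, , drop = FALSE]
      hit <- at$id %in% scheme$atom_ids
      cols[hit, ] <- matrix(scheme$rgb, sum(hit), 3, byrow = TRUE)
      cols
    })
}

#' Build a renderer-independent scene
#'
#' Translates a molecule into spheres and cylinders:
#' * `ball_and_stick` — one sphere per atom (`ball_scale` times the van der
#'   Waals radius, default 0.25) plus bond cylinders; double/triple bonds
#'   become 2/3 parallel cylinders offset by 0.15 A in a deterministic
#'   reference plane (the Cartesian axis least aligned with the bond);
#' * `stick` — spheres at the stick radius for smooth joints plus cylinders;
#' * `vdw` — full van der Waals spheres, no cylinders;
#' * `wireframe` — thin cylinders only.
#' Every bond cylinder is split at the bond midpoint so each half carries
#' its atom's color.
#'
#' @param mol A non-empty [molecule()].
#' @param representation One of "ball_and_stick", "stick", "vdw",
#'   "wireframe".
#' @param scheme A [color_scheme()] (default element colors).
#' @param ball_scale Sphere radius as a fraction of the VdW radius for
#'   ball-and-stick.
#' @param stick_radius Cylinder radius, Angstrom.
#' @param opacity Opacity in (0, 1].
#' @return An object of class `scene`: data frames `spheres` and
#'   `cylinders`, a list `meshes`, and a default `camera` looking down -z at
#'   the centroid from 2.5 bounding radii.
#' @export
build_scene <- function(mol,
                        representation = c("ball_and_stick", "stick",
                                           "vdw", "wireframe"),
                        scheme = color_scheme("element"),
                        ball_scale = 0.25, stick_radius = 0.12,
                        opacity = 1) {
  stopifnot_molecule(mol)
  representation <- match.arg(representation)
  if (n_atoms(mol) == 0) stop("empty molecule", call. = FALSE)
  if (opacity <= 0 || opacity > 1) {
    stop("opacity must be in (0, 1]", call. = FALSE)
  }
  at <- mol$atoms
  cols <- color_atoms(scheme, mol)
  rownames(cols) <- at$id
  pos <- atom_positions(mol)

  sph <- NULL
  if (representation != "wireframe") {
    radii <- switch(representation,
      ball_and_stick = ball_scale * vdw_radius(at$number),
      stick = rep(stick_radius, nrow(at)),
      vdw = vdw_radius(at$number))
    sph <- data.frame(x = at$x, y = at$y, z = at$z, radius = radii,
                      r = cols[, 1], g = cols[, 2], b = cols[, 3],
                      opacity = opacity)
  } else {
    sph <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      radius = numeric(0), r = numeric(0), g = numeric(0),
                      b = numeric(0), opacity = numeric(0))
  }

  cyl <- list()
  if (representation != "vdw") {
    radius <- if (representation == "wireframe") 0.02 else stick_radius
    for (rix in seq_len(nrow(mol$bonds))) {
      bd <- mol$bonds[rix, ]
      p1 <- pos[as.character(bd$a1), ]
      p2 <- pos[as.character(bd$a2), ]
      nseg <- if (representation == "ball_and_stick") bd$order else 1L
      segr <- if (nseg > 1) radius * 0.6 else radius
      offsets <- multi_bond_offsets(p1, p2, nseg)
      mid <- (p1 + p2) / 2
      for (s in seq_len(nseg)) {
        off <- offsets[s, ]
        for (half in 1:2) {
          aid <- if (half == 1) bd$a1 else bd$a2
          ends <- if (half == 1) list(p1, mid) else list(mid, p2)
          cc <- cols[as.character(aid), ]
          cyl[[length(cyl) + 1]] <- data.frame(
            x1 = ends[[1]][1] + off[1], y1 = ends[[1]][2] + off[2],
            z1 = ends[[1]][3] + off[3],
            x2 = ends[[2]][1] + off[1], y2 = ends[[2]][2] + off[2],
            z2 = ends[[2]][3] + off[3],
            radius = segr, r = cc[1], g = cc[2], b = cc[3],
            opacity = opacity)
        }
      }
    }
  }
  cyl <- if (length(cyl)) do.call(rbind, cyl) else
    data.frame(x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
               x2 = numeric(0), y2 = numeric(0), z2 = numeric(0),
               radius = numeric(0), r = numeric(0), g = numeric(0),
               b = numeric(0), opacity = numeric(0))

  centroid <- colMeans(pos)
  brad <- max(sqrt(rowSums(sweep(pos, 2, centroid)^2)), 1)
  camera <- list(position = centroid + c(0, 0, 2.5 * brad),
                 target = centroid, up = c(0, 1, 0))
  structure(list(spheres = sph, cylinders = cyl, meshes = list(),
                 camera = camera), class = "scene")
}

# Perpendicular offsets for n parallel bond cylinders, 0.15 A apart, in the
# plane spanned by the bond and the Cartesian axis least aligned with it.
multi_bond_offsets <- function(p1, p2, n) {
  if (n == 1) return(matrix(0, 1, 3))
  dirv <- unitv(p2 - p1)
  axis_pick <- which.min(abs(dirv))
  ref <- c(0, 0, 0); ref[axis_pick] <- 1
  perp <- unitv(cross3(dirv, ref))
  steps <- seq(-(n - 1) / 2, (n - 1) / 2, length.out = n)
  outer(steps * 0.15, perp)
}

#' Attach a mesh to a scene
#'
#' @param scene A `scene` from [build_scene()].
#' @param mesh A [triangle_mesh()].
#' @param rgb Length-3 RGB color.
#' @param opacity Opacity in (0, 1].
#' @return The scene with the mesh appended.
#' @export
scene_add_mesh <- function(scene, mesh, rgb = c(0.2, 0.4, 1), opacity = 0.6) {
  if (!inherits(scene, "scene")) stop("not a scene", call. = FALSE)
  scene$meshes[[length(scene$meshes) + 1]] <-
    list(mesh = mesh, rgb = as.numeric(rgb), opacity = opacity)
  scene
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d spheres, %d cylinders, %d meshes\n",
              nrow(x$spheres), nrow(x$cylinders), length(x$meshes)))
  invisible(x)
}

#' Export a scene to POV-Ray
#'
#' Deterministic text: camera, two point lights, one `sphere {}` per scene
#' sphere, `cylinder {}` per cylinder and `mesh2 {}` per mesh. All numbers
#' are fixed 6-decimal; repeated calls on the same scene are byte-identical.
#' Opacity below 1 is emitted as a `transmit` term.
#'
#' @param scene A `scene`.
#' @return POV-Ray scene text.
#' @export
write_povray <- function(scene) {
  if (!inherits(scene, "scene")) stop("not a scene", call. = FALSE)
  v3 <- function(p) sprintf("<%.6f, %.6f, %.6f>", p[1], p[2], p[3])
  cam <- scene$camera
  out <- c(
    "// molcraft POV-Ray export",
    "#version 3.7;",
    "global_settings { assumed_gamma 1.0 }",
    "background { color rgb <1.000000, 1.000000, 1.000000> }",
    sprintf("camera { location %s look_at %s up %s right x*1.333333 }",
            v3(cam$position), v3(cam$target), v3(cam$up)),
    sprintf("light_source { %s color rgb <1, 1, 1> }",
            v3(cam$position + c(10, 10, 10))),
    sprintf("light_source { %s color rgb <0.5, 0.5, 0.5> }",
            v3(cam$position + c(-10, 5, 10))))

  finish <- "finish { ambient 0.2 diffuse 0.8 specular 0.3 }"
  pigment <- function(r, g, b, opacity) {
    if (opacity < 1) {
      sprintf("pigment { color rgb <%.6f, %.6f, %.6f> transmit %.6f }",
              r, g, b, 1 - opacity)
    } else {
      sprintf("pigment { color rgb <%.6f, %.6f, %.6f> }", r, g, b)
    }
  }
  sp <- scene$spheres
  for (i in seq_len(nrow(sp))) {
    out <- c(out, sprintf("sphere { %s, %.6f %s %s }",
                          v3(c(sp$x[i], sp$y[i], sp$z[i])), sp$radius[i],
                          pigment(sp$r[i], sp$g[i], sp$b[i], sp$opacity[i]),
                          finish))
  }
  cy <- scene$cylinders
  for (i in seq_len(nrow(cy))) {
    out <- c(out, sprintf("cylinder { %s, %s, %.6f %s %s }",
                          v3(c(cy$x1[i], cy$y1[i], cy$z1[i])),
                          v3(c(cy$x2[i], cy$y2[i], cy$z2[i])),
                          cy$radius[i],
                          pigment(cy$r[i], cy$g[i], cy$b[i], cy$opacity[i]),
                          finish))
  }
  for (mm in scene$meshes) {
    out <- c(out, povray_mesh2(mm$mesh, mm$rgb, mm$opacity))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

povray_mesh2 <- function(mesh, rgb, opacity) {
  v <- mesh$vertices
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(character(0))
  lines <- c("mesh2 {",
             sprintf("  vertex_vectors { %d,", nrow(v)),
             paste0("    ", sprintf("<%.6f, %.6f, %.6f>%s", v[, 1], v[, 2],
                                    v[, 3],
                                    c(rep(",", nrow(v) - 1), ""))),
             "  }")
  if (!is.null(mesh$normals)) {
    nm <- mesh$normals
    lines <- c(lines,
               sprintf("  normal_vectors { %d,", nrow(nm)),
               paste0("    ", sprintf("<%.6f, %.6f, %.6f>%s", nm[, 1],
                                      nm[, 2], nm[, 3],
                                      c(rep(",", nrow(nm) - 1), ""))),
               "  }")
  }
  lines <- c(lines,
             sprintf("  face_indices { %d,", nrow(tr)),
             paste0("    ", sprintf("<%d, %d, %d>%s", tr[, 1] - 1,
                                    tr[, 2] - 1, tr[, 3] - 1,
                                    c(rep(",", nrow(tr) - 1), ""))),
             "  }",
             sprintf("  pigment { color rgb <%.6f, %.6f, %.6f>%s }",
                     rgb[1], rgb[2], rgb[3],
                     if (opacity < 1) sprintf(" transmit %.6f", 1 - opacity)
                     else ""),
             "}")
  lines
}
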