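test_that("sphere isosurface area, topology and normals are right", {
  g <- make_field_grid("sphere", n = 48, extent = 1.5, R = 1)
  mesh <- marching_cubes(g, 0)
  st <- mesh_stats(mesh)
  expect_equal(st$area, 4 * pi, tolerance = 0.02)
  expect_true(st$watertight)
  edges <- st$n_triangles * 3 / 2
  expect_equal(st$n_vertices - edges + st$n_triangles, 2)  # Euler sphere

  # normals: unit length, radial within 2 degrees, toward decreasing field
  lens <- sqrt(rowSums(mesh$normals^2))
  expect_lt(max(abs(lens - 1)), 1e-6)
  radial <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  dots <- rowSums(radial * mesh$normals)
  expect_true(all(dots < 0))  # field decreases toward the center
  dev <- acos(pmin(1, abs(dots))) * 180 / pi
  expect_lt(mean(dev), 2)
})

test_that("area error shrinks roughly quadratically with resolution", {
  errs <- vapply(c(16, 32, 64), function(n) {
    st <- mesh_stats(marching_cubes(make_field_grid("sphere", n = n,
                                                    extent = 1.5, R = 1), 0))
    abs(st$area - 4 * pi) / (4 * pi)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[3], 4)  # at least ~h^2-ish over two doublings
})

test_that("emitted vertices interpolate back to the isovalue", {
  set.seed(31)
  vals <- random_smooth_field(n = 20)
  g <- index_grid(vals)
  mesh <- marching_cubes(g, 0.6, normals = FALSE)
  interp <- molcraft:::trilinear(vals, mesh$vertices)
  expect_lt(max(abs(interp - 0.6)), 0.02)
})

test_that("degenerate grids behave as documented", {
  flat <- volumetric_grid(c(0, 0, 0), diag(3),
                          values = array(1, c(3, 3, 3)), unit = "angstrom")
  expect_equal(nrow(marching_cubes(flat, 5)$triangles), 0)    # all below
  expect_equal(nrow(marching_cubes(flat, -5)$triangles), 0)   # all above
  expect_equal(nrow(marching_cubes(flat, 1)$triangles), 0)    # constant = iso
  expect_error(marching_cubes(flat, NaN), "finite")
})

test_that("the in-repo marching cubes matches the reference on smooth fields", {
  set.seed(7)
  for (trial in 1:3) {
    vals <- random_smooth_field(n = 20)
    mesh <- marching_cubes(index_grid(vals), 0.5, normals = FALSE)
    ref <- skimage_marching_cubes(vals, 0.5)
    expect_lt(hausdorff(mesh$vertices, ref), 0.5)  # half a voxel
  }
})

test_that("isosurface pairs split the positive and negative lobes", {
  p <- parse_fchk(make_h2_fchk())
  g <- default_grid(p$molecule, padding = 2.5, spacing = 0.25)
  anti <- generate_cube(p$basis, p$mos, list(mo = 2), g)
  pair <- isosurface_pair(anti, 0.05)
  expect_gt(nrow(pair$positive$triangles), 0)
  expect_gt(nrow(pair$negative$triangles), 0)
  # the antibonding orbital is antisymmetric: equal lobe sizes
  expect_equal(nrow(pair$positive$triangles), nrow(pair$negative$triangles))

  bond <- generate_cube(p$basis, p$mos, list(mo = 1), g)
  pair2 <- isosurface_pair(bond, 0.05)
  expect_gt(nrow(pair2$positive$triangles), 0)
  expect_equal(nrow(pair2$negative$triangles), 0)  # nodeless

  dens <- generate_cube(p$basis, p$mos, "density", g)
  expect_equal(nrow(isosurface_pair(dens, 0.01)$negative$triangles), 0)
  expect_error(isosurface_pair(dens, -0.1), "positive")
})

test_that("planar fields give planar normals; mesh stats count correctly", {
  g <- make_field_grid("plane", n = 12, extent = 2, normal = c(0, 0, 1))
  mesh <- marching_cubes(g, 0.001)
  expect_lt(max(abs(sweep(mesh$normals, 2, c(0, 0, -1)))), 1e-6)

  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1, 2, 3), 1))
  st <- mesh_stats(tri)
  expect_equal(st$area, 0.5)
  expect_false(st$watertight)
  empty <- triangle_mesh(matrix(numeric(0), ncol = 3),
                         matrix(integer(0), ncol = 3))
  expect_equal(mesh_stats(empty)$n_triangles, 0)
  expect_equal(mesh_stats(empty)$area, 0)
})

test_that("traversal order cannot matter: equal grids give equal meshes", {
  set.seed(13)
  vals <- random_smooth_field(n = 14)
  m1 <- marching_cubes(index_grid(vals), 0.5)
  m2 <- marching_cubes(index_grid(vals + 0), 0.5)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$triangles, m2$triangles)
})

test_that("OBJ output lists every vertex, normal and face", {
  g <- make_field_grid("sphere", n = 12, extent = 1.5, R = 1)
  mesh <- marching_cubes(g, 0)
  obj <- write_obj(mesh)
  lines <- strsplit(obj, "\n")[[1]]
  expect_equal(sum(startsWith(lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "vn ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$triangles))
})
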