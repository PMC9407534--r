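# parametric scenario generators

test_that("notched plate: node sets, slit topology, element size, symmetry", {
  m <- gen_notched_plate(2, 1, 0.5, 0.05)
  expect_true(all(c("left", "right", "top", "bottom", "notch_tip",
                    "slit_upper", "slit_lower") %in% names(m$node_sets)))
  expect_length(m$node_sets$notch_tip, 1L)
  tip <- m$vertices[m$node_sets$notch_tip, ]
  expect_equal(unname(tip[1:2]), c(0.5, 0.5), tolerance = 1e-12)

  # every edge within target_h in the tip zone (and, uniform grid: overall,
  # up to the sqrt(2) hypotenuse)
  ed <- gelfrac:::mesh_edges(m)
  len <- sqrt(rowSums((m$vertices[ed$i, ] - m$vertices[ed$j, ])^2))
  expect_lte(max(len), 0.05 * sqrt(2) + 1e-12)

  # the slit is a true topological slit: upper and lower flank vertices are
  # distinct points at identical coordinates...
  up <- m$node_sets$slit_upper; lo <- m$node_sets$slit_lower
  expect_gt(length(up), 0)
  expect_equal(length(up), length(lo))
  expect_true(length(intersect(up, lo)) == 0)
  # ...and a face path from just above to just below the slit cannot cross
  # it: split the mesh by cutting all faces touching the tip vertex and the
  # region right of it; flanks must fall in different face components
  tr <- m$triangles
  keep <- m$vertices[tr[, 1], 1] < 0.5 - 1e-9 &
    m$vertices[tr[, 2], 1] < 0.5 - 1e-9 &
    m$vertices[tr[, 3], 1] < 0.5 - 1e-9
  sub <- m
  sub$triangles <- tr[keep, , drop = FALSE]
  comp <- gelfrac:::face_components(sub)
  touches <- function(set) unique(comp[apply(sub$triangles, 1,
                                             function(t3) any(t3 %in% set))])
  expect_length(intersect(touches(up), touches(lo)), 0)

  # mirror-symmetric by construction
  v <- m$vertices
  key <- paste(round(v[, 1], 9), round(1 - v[, 2], 9))
  expect_true(all(key %in% paste(round(v[, 1], 9), round(v[, 2], 9))))

  validate_trimesh(m)
  expect_error(gen_notched_plate(2, 1, 0, 0.1),
               class = "gelfrac_precondition_error")
  expect_error(gen_notched_plate(2, 1, 1.5, 0.1),
               class = "gelfrac_precondition_error")
  expect_error(gen_notched_plate(2, 1, 0.5, 1e-4),
               class = "gelfrac_meshing_error")
})

test_that("perforated sphere patch: radii, boundary loops, node sets", {
  m <- gen_perforated_sphere_patch(1, 0.05, 3L, "octant", target_h = 0.06)
  expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 1)), 1e-8)
  expect_equal(gelfrac:::boundary_loop_count(m), 4L)  # outer + 3 holes
  expect_true(all(c("pole", "pole_cap", "equator", "sym_x0", "sym_y0") %in%
                    names(m$node_sets)))
  expect_length(m$node_sets$pole, 1L)
  expect_gt(length(m$node_sets$equator), 3L)
  validate_trimesh(m)

  q <- gen_perforated_sphere_patch(2, 0.1, 2L, "quadrant", target_h = 0.15)
  expect_lt(max(abs(sqrt(rowSums(q$vertices^2)) - 2)), 1e-8)
  expect_equal(gelfrac:::boundary_loop_count(q), 3L)
  # quadrant spans both signs of x
  expect_gt(max(q$vertices[, 1]), 1)
  expect_lt(min(q$vertices[, 1]), -1)

  expect_error(gen_perforated_sphere_patch(1, 0.2, 3L, "octant", 0.06),
               class = "gelfrac_precondition_error")
  expect_error(gen_perforated_sphere_patch(1, 0.09, 8L, "octant", 0.06),
               class = "gelfrac_layout_error")
})

test_that("fiber strip: dimensions, thickness, connectivity", {
  m <- gen_fiber_strip(4, 1, 0.1, n_fibers = 4L, n_crosslinks = 3L,
                       target_h = 0.05)
  expect_equal(range(m$vertices[, 1]), c(0, 4))
  expect_equal(range(m$vertices[, 2]), c(0, 1))
  expect_true(all(m$thickness == 0.1))
  expect_equal(max(gelfrac:::face_components(m)), 1L)
  expect_true(all(lengths(m$node_sets[c("left", "right", "center")]) > 0))
  validate_trimesh(m)

  expect_error(gen_fiber_strip(4, 1, 0.1, n_fibers = 1L, n_crosslinks = 3L,
                               target_h = 0.05),
               class = "gelfrac_precondition_error")
  expect_error(gen_fiber_strip(4, 1, 0.1, n_fibers = 4L, n_crosslinks = 3L,
                               target_h = 0.5),
               class = "gelfrac_precondition_error")
})

test_that("cap with patch: regions, rim, monotone patch area", {
  m <- gen_cap_with_patch(1, 0.8, 0.5, target_h = 0.15)
  expect_setequal(unique(m$element_region), c("hydrogel", "substrate"))
  expect_gt(length(m$node_sets$rim), 3L)
  validate_trimesh(m)

  areas <- vapply(c(0.2, 0.4, 0.6), function(a) {
    mm <- gen_cap_with_patch(1, 0.8, a, target_h = 0.15)
    sum(triangle_areas(mm)[mm$element_region == "hydrogel"]) /
      sum(triangle_areas(mm))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))

  expect_error(gen_cap_with_patch(1, 0.8, 0, target_h = 0.15),
               class = "gelfrac_precondition_error")
})

test_that("generators are deterministic for fixed parameters", {
  a <- gen_notched_plate(2, 1, 0.5, 0.1)
  b <- gen_notched_plate(2, 1, 0.5, 0.1)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$triangles, b$triangles)
  s1 <- gen_perforated_sphere_patch(1, 0.05, 3L, "octant", 0.08)
  s2 <- gen_perforated_sphere_patch(1, 0.05, 3L, "octant", 0.08)
  expect_identical(s1$vertices, s2$vertices)
})

test_that("icosphere is closed, unit-radius and consistently oriented", {
  ic <- gen_icosphere(1, 2)
  expect_length(boundary_vertices(ic), 0L)
  expect_lt(max(abs(sqrt(rowSums(ic$vertices^2)) - 1)), 1e-12)
  expect_equal(nrow(ic$triangles), 20L * 4L^2)
  validate_trimesh(ic)   # includes winding consistency
})
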