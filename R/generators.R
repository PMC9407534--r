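# Parametric mesh generators -------------------------------------------------
#
# All generators are deterministic for a fixed parameter set: default
# layouts contain no randomized placement, so no seed is consumed. Planar
# meshes are placed in the z = 0 plane; all meshes are oriented consistently
# (planar: +z normals; spherical: outward normals).

# partition [a,b] with spacing <= h, optionally forcing interior breakpoints
grid_coords <- function(a, b, h, force = numeric(0)) {
  brk <- sort(unique(c(a, b, force[force > a + 1e-12 & force < b - 1e-12])))
  out <- numeric(0)
  for (k in seq_len(length(brk) - 1L)) {
    n <- max(1L, ceiling((brk[k + 1L] - brk[k]) / h - 1e-9))
    out <- c(out, seq(brk[k], brk[k + 1L], length.out = n + 1L)[-(n + 1L)])
  }
  c(out, b)
}

# structured triangulation of the tensor grid xs x ys in z = 0 (CCW from +z)
struct_rect <- function(xs, ys) {
  nx <- length(xs); ny <- length(ys)
  verts <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- id(i, j); v10 <- id(i + 1L, j); v01 <- id(i, j + 1L); v11 <- id(i + 1L, j + 1L)
  tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  list(vertices = verts, triangles = tris)
}

# drop vertices unused by any triangle; remap triangle indices and node sets
compact_mesh_arrays <- function(verts, tris, node_sets = list()) {
  used <- sort(unique(as.integer(tris)))
  map <- integer(nrow(verts)); map[used] <- seq_along(used)
  tris2 <- matrix(map[tris], ncol = 3)
  sets2 <- lapply(node_sets, function(ix) {
    ix <- ix[ix %in% used]
    sort(unique(map[ix]))
  })
  list(vertices = verts[used, , drop = FALSE], triangles = tris2,
       node_sets = sets2)
}

#' Generate a notched rectangular plate (SENT specimen)
#'
#' Flat strip `[0, length] x [0, width]` in the z = 0 plane with a single
#' horizontal edge notch at mid-height (`y = width/2`), entering from the
#' left edge (`x = 0`) and ending at `x = notch_length`. The notch is a true
#' topological slit: nodes along the slit are duplicated into an upper and a
#' lower copy, so face-adjacency cannot cross it; only the tip vertex is
#' shared. The mesh is constructed as a structured top half mirrored about
#' the mid-plane, so it is exactly mirror-symmetric.
#'
#' Node sets: `"left"`, `"right"`, `"top"`, `"bottom"`, `"notch_tip"`,
#' `"slit_upper"`, `"slit_lower"`.
#'
#' @param length,width plate dimensions (dimensionless reference length).
#' @param notch_length slit length, `0 < notch_length < length/2`.
#' @param target_h target element size; every edge in the mesh (including
#'   the notch-tip zone) is `<= target_h` up to roundoff (hypotenuses up to
#'   `sqrt(2) * target_h`).
#' @param thickness shell thickness (default 0.1).
#' @param max_elements guard against infeasible grading requests.
#' @return a [trimesh()].
#' @export
gen_notched_plate <- function(length, width, notch_length, target_h,
                              thickness = 0.1, max_elements = 2e5) {
  if (!(notch_length > 0) || !(notch_length < length / 2))
    stop_gelfrac("precondition_error",
                 "notch_length must satisfy 0 < notch_length < length/2")
  if (!(target_h > 0)) stop_gelfrac("precondition_error", "target_h must be > 0")
  mid <- width / 2
  n_est <- 4 * ceiling(length / target_h + 2) * ceiling(mid / target_h + 1)
  if (n_est > max_elements)
    stop_gelfrac("meshing_error", sprintf(
      "requested grading yields ~%g elements (> %g)", n_est, max_elements))
  xs <- grid_coords(0, length, target_h, force = notch_length)
  ys <- grid_coords(mid, width, target_h)
  half <- struct_rect(xs, ys)
  nv <- nrow(half$vertices)
  vb <- half$vertices
  vb[, 2] <- 2 * mid - vb[, 2]                       # mirror about y = mid
  tb <- half$triangles[, c(1L, 3L, 2L)] + nv         # reverse winding
  verts <- rbind(half$vertices, vb)
  tris <- rbind(half$triangles, tb)
  # weld mirrored midline nodes back onto the originals for x >= notch_length
  tol <- 1e-9 * max(length, width)
  on_mid <- abs(half$vertices[, 2] - mid) < tol
  weldable <- on_mid & half$vertices[, 1] >= notch_length - tol
  map <- seq_len(2L * nv)
  map[nv + which(weldable)] <- which(weldable)
  tris <- matrix(map[tris], ncol = 3)
  xv <- verts[, 1]; yv <- verts[, 2]
  slit_half <- which(on_mid & half$vertices[, 1] < notch_length - tol)
  slit_upper <- slit_half
  slit_lower_raw <- nv + slit_half
  sets <- list(
    left = which(abs(xv) < tol),
    right = which(abs(xv - length) < tol),
    top = which(abs(yv - width) < tol),
    bottom = which(abs(yv) < tol),
    notch_tip = which(abs(xv - notch_length) < tol & abs(yv - mid) < tol &
                        seq_len(2L * nv) <= nv),
    slit_upper = slit_upper,
    slit_lower = slit_lower_raw
  )
  cm <- compact_mesh_arrays(verts, tris, sets)
  trimesh(cm$vertices, cm$triangles, node_sets = cm$node_sets,
          thickness = thickness)
}

# --- octahedron-based sphere patches ---------------------------------------

# regular subdivision of one spherical triangle with corner unit vectors
# (rows of `corners`), k subdivisions per edge; returns vertices on the unit
# sphere plus faces (outward orientation fixed afterwards by the caller)
octant_patch <- function(corners, k) {
  # barycentric lattice
  verts <- matrix(0, (k + 1) * (k + 2) / 2, 3)
  idx <- function(i, j) {            # i = 0..k, j = 0..k-i (row-major)
    # offset of row i: sum_{r<i} (k - r + 1)
    as.integer(i * (k + 1) - i * (i - 1) / 2 + j + 1)
  }
  for (i in 0:k) for (j in 0:(k - i)) {
    m <- k - i - j
    p <- (i * corners[1, ] + j * corners[2, ] + m * corners[3, ]) / k
    verts[idx(i, j), ] <- p / sqrt(sum(p^2))
  }
  tris <- matrix(0L, k * k, 3)
  t <- 0L
  for (i in 0:(k - 1)) for (j in 0:(k - 1 - i)) {
    t <- t + 1L
    tris[t, ] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
    if (j < k - 1 - i) {
      t <- t + 1L
      tris[t, ] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  list(vertices = verts, triangles = tris[seq_len(t), , drop = FALSE])
}

# weld duplicate vertices (exact up to tol) across concatenated patches
weld_vertices <- function(verts, tris, tol = 1e-9) {
  key <- paste(round(verts[, 1] / tol), round(verts[, 2] / tol),
               round(verts[, 3] / tol))
  first <- match(key, key)
  uniq <- sort(unique(first))
  map <- integer(nrow(verts)); map[uniq] <- seq_along(uniq)
  tris2 <- matrix(map[first][tris], ncol = 3)
  list(vertices = verts[uniq, , drop = FALSE], triangles = tris2)
}

# orient all faces outward from the origin
orient_outward <- function(verts, tris) {
  e1 <- verts[tris[, 2], ] - verts[tris[, 1], ]
  e2 <- verts[tris[, 3], ] - verts[tris[, 1], ]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cen <- (verts[tris[, 1], ] + verts[tris[, 2], ] + verts[tris[, 3], ]) / 3
  flip <- rowSums(n * cen) < 0
  tris[flip, ] <- tris[flip, c(1L, 3L, 2L), drop = FALSE]
  tris
}

sphere_patch_unit <- function(symmetry, k) {
  ez <- c(0, 0, 1); ex <- c(1, 0, 0); ey <- c(0, 1, 0)
  octs <- list(rbind(ex, ey, ez))
  if (symmetry == "quadrant") octs <- c(octs, list(rbind(ey, -ex, ez)))
  verts <- NULL; tris <- NULL
  for (oc in octs) {
    p <- octant_patch(oc, k)
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, p$vertices)
    tris <- rbind(tris, p$triangles + off)
  }
  w <- weld_vertices(verts, tris)
  w$triangles <- orient_outward(w$vertices, w$triangles)
  w
}

#' Generate a perforated spherical shell patch
#'
#' Octant (one eighth of the sphere, used for the compression scenario) or
#' quadrant (one quarter, used for shear) of a sphere of radius `R`,
#' discretized by regular subdivision of the octahedral spherical triangles
#' (good element quality, all vertices exactly on the sphere). `n_holes`
#' circular perforations of radius `r_hole` are carved on a regular layout
#' along the mid-latitude circle (polar angle pi/4), emulating a porous
#' drug-capsule membrane.
#'
#' Node sets: `"pole"` (the +z apex), `"equator"` (z = 0 boundary),
#' `"symmetry_edges"` (vertices on the symmetry planes y = 0 and, for the
#' octant, x = 0).
#'
#' @param R sphere radius.
#' @param r_hole hole radius (must satisfy `r_hole < R/10`).
#' @param n_holes number of holes (>= 0).
#' @param symmetry `"octant"` or `"quadrant"`.
#' @param target_h target element size.
#' @param thickness shell thickness (default `0.01 * R`; the reference
#'   thickness of a thin capsule membrane).
#' @param hole_theta polar angle of the hole-center circle (default pi/4).
#' @param cap_angle polar half-angle of the `"pole_cap"` node set used to
#'   spread an indentation load over a finite contact patch (default 0.3).
#' @return a [trimesh()].
#' @export
gen_perforated_sphere_patch <- function(R, r_hole, n_holes = 3L,
                                        symmetry = c("octant", "quadrant"),
                                        target_h, thickness = NULL,
                                        hole_theta = pi / 4, cap_angle = 0.3) {
  symmetry <- match.arg(symmetry)
  if (!(r_hole < R / 10))
    stop_gelfrac("precondition_error", "r_hole must be < R/10")
  if (!(target_h > 0)) stop_gelfrac("precondition_error", "target_h must be > 0")
  if (is.null(thickness)) thickness <- 0.01 * R
  if (hole_theta <= 0 || hole_theta >= pi / 2)
    stop_gelfrac("precondition_error", "hole_theta must be in (0, pi/2)")
  k <- max(4L, ceiling((pi / 2) * R / target_h))
  w <- sphere_patch_unit(symmetry, k)
  verts <- w$vertices; tris <- w$triangles
  # hole layout: centers on the mid-latitude circle theta = pi/4
  phimax <- if (symmetry == "octant") pi / 2 else pi
  ang_r <- r_hole / R
  if (n_holes > 0L) {
    phis <- phimax * seq_len(n_holes) / (n_holes + 1L)
    if (n_holes > 1L) {
      sep <- (phis[2] - phis[1]) * sin(hole_theta)  # chordal spacing on circle
      if (sep < 2.5 * ang_r)
        stop_gelfrac("layout_error",
                     "holes overlap: reduce n_holes or r_hole")
    }
    centers <- cbind(sin(hole_theta) * cos(phis), sin(hole_theta) * sin(phis),
                     rep(cos(hole_theta), n_holes))
    cen <- (verts[tris[, 1], ] + verts[tris[, 2], ] + verts[tris[, 3], ]) / 3
    cen <- cen / sqrt(rowSums(cen^2))
    keep <- rep(TRUE, nrow(tris))
    for (h in seq_len(n_holes)) {
      gd <- acos(pmin(1, pmax(-1, cen %*% centers[h, ])))
      keep <- keep & gd > ang_r
    }
    tris <- tris[keep, , drop = FALSE]
  }
  tol <- 1e-7
  sets <- list(
    pole = which(abs(verts[, 3] - 1) < tol),
    pole_cap = which(acos(pmin(1, verts[, 3])) <= cap_angle + tol),
    equator = which(abs(verts[, 3]) < tol),
    sym_x0 = if (symmetry == "octant") which(abs(verts[, 1]) < tol)
    else integer(0),
    sym_y0 = which(abs(verts[, 2]) < tol),
    symmetry_edges = if (symmetry == "octant")
      which(abs(verts[, 1]) < tol | abs(verts[, 2]) < tol)
    else which(abs(verts[, 2]) < tol)
  )
  cm <- compact_mesh_arrays(verts * R, tris, sets)
  mesh <- trimesh(cm$vertices, cm$triangles, node_sets = cm$node_sets,
                  thickness = thickness)
  if (n_holes > 0L && boundary_loop_count(mesh) != 1L + n_holes)
    stop_gelfrac("layout_error", sprintf(
      "hole layout produced %d boundary loops (expected %d); refine target_h",
      boundary_loop_count(mesh), 1L + n_holes))
  mesh
}

#' Generate a fibered strip (idealized cell-culture scaffold)
#'
#' Planar lattice in `[0, length] x [0, width]` (z = 0) of `n_fibers`
#' longitudinal strips connected by `n_crosslinks` transverse strips, an
#' idealization of a nanofiber scaffold sheet. Fiber and crosslink widths
#' equal `width / (2*n_fibers - 1)` so fibers and gaps alternate evenly.
#'
#' Node sets: `"left"`, `"right"` (the clamped ends), `"center"` (vertices
#' in the central transverse band, where an out-of-plane displacement
#' mimicking the weight of a cultured cell is applied).
#'
#' @param length,width,thickness strip dimensions (defaults of the bundled
#'   demo: 4, 1, 0.1).
#' @param n_fibers number of longitudinal fibers (>= 2).
#' @param n_crosslinks number of transverse crosslink strips (>= 1).
#' @param target_h target element size; must be smaller than the fiber
#'   width.
#' @return a [trimesh()].
#' @export
gen_fiber_strip <- function(length, width, thickness, n_fibers = 4L,
                            n_crosslinks = 3L, target_h) {
  if (n_fibers < 2L)
    stop_gelfrac("precondition_error", "n_fibers must be >= 2")
  if (n_crosslinks < 1L)
    stop_gelfrac("precondition_error", "n_crosslinks must be >= 1")
  wf <- width / (2 * n_fibers - 1)
  if (!(target_h > 0) || target_h >= wf)
    stop_gelfrac("precondition_error", sprintf(
      "target_h must be in (0, fiber width = %.4g)", wf))
  fib_lo <- (2 * seq_len(n_fibers) - 2) * wf
  fib_hi <- fib_lo + wf
  cl_cen <- length * seq_len(n_crosslinks) / (n_crosslinks + 1L)
  cl_lo <- cl_cen - wf / 2; cl_hi <- cl_cen + wf / 2
  xs <- grid_coords(0, length, target_h, force = c(cl_lo, cl_hi))
  ys <- grid_coords(0, width, target_h, force = c(fib_lo, fib_hi))
  g <- struct_rect(xs, ys)
  cen <- (g$vertices[g$triangles[, 1], 1:2] + g$vertices[g$triangles[, 2], 1:2] +
            g$vertices[g$triangles[, 3], 1:2]) / 3
  in_fiber <- rep(FALSE, nrow(cen))
  for (f in seq_len(n_fibers))
    in_fiber <- in_fiber | (cen[, 2] > fib_lo[f] & cen[, 2] < fib_hi[f])
  in_cl <- rep(FALSE, nrow(cen))
  for (s in seq_len(n_crosslinks))
    in_cl <- in_cl | (cen[, 1] > cl_lo[s] & cen[, 1] < cl_hi[s])
  tris <- g$triangles[in_fiber | in_cl, , drop = FALSE]
  if (!nrow(tris)) stop_gelfrac("meshing_error", "empty fiber lattice")
  tol <- 1e-9 * max(length, width)
  xv <- g$vertices[, 1]
  sets <- list(
    left = which(abs(xv) < tol),
    right = which(abs(xv - length) < tol),
    center = which(abs(xv - length / 2) <= wf / 2 + tol)
  )
  cm <- compact_mesh_arrays(g$vertices, tris, sets)
  mesh <- trimesh(cm$vertices, cm$triangles, node_sets = cm$node_sets,
                  thickness = thickness)
  if (max(face_components(mesh)) != 1L)
    stop_gelfrac("meshing_error",
                 "fiber lattice is not a single connected component")
  mesh
}

#' Generate an ellipsoidal cap with a bonded patch region
#'
#' Upper half of an ellipsoid with equatorial radius `R_major` and polar
#' semi-axis `R_minor`, a single-mesh surrogate for a thin device bonded to
#' a curved biological substrate: elements whose centroid lies within the
#' polar cone of half-angle `patch_angle` get `element_region = "hydrogel"`,
#' the remainder `"substrate"` (intended for an Ogden soft-tissue material).
#'
#' Node sets: `"rim"` (the equatorial boundary), `"patch_center"` (apex).
#'
#' @param R_major,R_minor ellipsoid semi-axes.
#' @param patch_angle polar half-angle of the bonded patch, in
#'   `(0, pi/2)`.
#' @param target_h target element size.
#' @param thickness shell thickness (default `0.02 * R_major`).
#' @return a [trimesh()] with two element regions.
#' @export
gen_cap_with_patch <- function(R_major, R_minor, patch_angle, target_h,
                               thickness = NULL) {
  if (!(patch_angle > 0) || !(patch_angle < pi / 2))
    stop_gelfrac("precondition_error", "patch_angle must be in (0, pi/2)")
  if (is.null(thickness)) thickness <- 0.02 * R_major
  k <- max(4L, ceiling((pi / 2) * R_major / target_h))
  ez <- c(0, 0, 1); ex <- c(1, 0, 0); ey <- c(0, 1, 0)
  octs <- list(rbind(ex, ey, ez), rbind(ey, -ex, ez),
               rbind(-ex, -ey, ez), rbind(-ey, ex, ez))
  verts <- NULL; tris <- NULL
  for (oc in octs) {
    p <- octant_patch(oc, k)
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, p$vertices)
    tris <- rbind(tris, p$triangles + off)
  }
  w <- weld_vertices(verts, tris)
  w$triangles <- orient_outward(w$vertices, w$triangles)
  cen <- (w$vertices[w$triangles[, 1], ] + w$vertices[w$triangles[, 2], ] +
            w$vertices[w$triangles[, 3], ]) / 3
  cen <- cen / sqrt(rowSums(cen^2))
  theta <- acos(pmin(1, pmax(-1, cen[, 3])))
  region <- ifelse(theta < patch_angle, "hydrogel", "substrate")
  if (!any(region == "hydrogel") || !any(region == "substrate"))
    stop_gelfrac("meshing_error",
                 "patch_angle leaves one of the regions empty; adjust target_h")
  tol <- 1e-7
  sets <- list(rim = which(abs(w$vertices[, 3]) < tol),
               patch_center = which(abs(w$vertices[, 3] - 1) < tol))
  scaled <- cbind(w$vertices[, 1] * R_major, w$vertices[, 2] * R_major,
                  w$vertices[, 3] * R_minor)
  trimesh(scaled, w$triangles, node_sets = sets,
          element_region = region, thickness = thickness)
}

#' Generate a closed icosphere
#'
#' Subdivided icosahedron with all vertices on the sphere of radius `R`.
#' A closed (boundary-free) mesh used for homogeneous phase-field checks.
#'
#' @param R radius.
#' @param subdiv number of 4-to-1 subdivision passes (>= 0).
#' @return a [trimesh()].
#' @export
gen_icosphere <- function(R = 1, subdiv = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    verts <- v[as.integer(t(f)), , drop = FALSE]     # 3 per face
    mid <- rbind((verts[seq(1, 3 * nf, 3), ] + verts[seq(2, 3 * nf, 3), ]) / 2,
                 (verts[seq(2, 3 * nf, 3), ] + verts[seq(3, 3 * nf, 3), ]) / 2,
                 (verts[seq(3, 3 * nf, 3), ] + verts[seq(1, 3 * nf, 3), ]) / 2)
    allv <- rbind(verts, mid)
    a <- seq(1, 3 * nf, 3); b <- a + 1L; c2 <- a + 2L
    m1 <- 3L * nf + seq_len(nf); m2 <- m1 + nf; m3 <- m2 + nf
    newf <- rbind(cbind(a, m1, m3), cbind(m1, b, m2),
                  cbind(m3, m2, c2), cbind(m1, m2, m3))
    w <- weld_vertices(allv, newf, tol = 1e-12)
    v <- w$vertices / sqrt(rowSums(w$vertices^2))
    f <- w$triangles
  }
  f <- orient_outward(v, f)
  trimesh(v * R, f, thickness = 0.01 * R)
}
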