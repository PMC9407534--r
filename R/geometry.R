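# Discrete differential geometry on the triangle mesh -----------------------
#
# The vertex-based damage equation is discretized with the classical
# cotangent formulation: edge weights w_ij = 1/2 * sum over incident
# triangles of cot(angle opposite the edge), and barycentric vertex areas
# a_i = sum of incident triangle areas / 3. Together they define the graph
# Laplacian L p |_i = (1/a_i) sum_j w_ij (p_i - p_j), the standard
# discretization of the Laplace-Beltrami operator on a surface mesh.

#' Cotangent edge weights and barycentric vertex areas
#'
#' Computes the discrete-geometry operators used by the phase-field
#' assembly: symmetric cotangent edge weights (interior edges sum two
#' cotangents, boundary edges one) and barycentric vertex areas (one third
#' of each incident triangle's area). Weights may be negative on obtuse
#' triangles; they are kept as-is by default, which is standard practice.
#'
#' @param mesh a [trimesh()].
#' @param clamp_weights if `TRUE`, negative edge weights are clamped to 0
#'   (a robustness option for poor-quality meshes; changes the operator).
#' @return an object of class `"graph_operators"`: a list with
#'   `edges` (two-column integer matrix, `i < j`), `weights` (numeric,
#'   per edge), `vertex_areas` (numeric, per vertex) and `n_vertices`.
#' @export
graph_operators <- function(mesh, clamp_weights = FALSE) {
  w <- cotangent_weights(mesh)
  a <- vertex_areas(mesh)
  if (clamp_weights) w$weights <- pmax(w$weights, 0)
  structure(list(edges = w$edges, weights = w$weights,
                 vertex_areas = a, n_vertices = nrow(mesh$vertices)),
            class = "graph_operators")
}

#' Cotangent edge weights
#'
#' For each mesh edge (i, j): `w_ij = 1/2 * sum_T cot(theta_T)` over the one
#' or two triangles T incident to the edge, where `theta_T` is the angle of
#' T at the vertex opposite the edge. An angle within `1e-9` of 0 or pi is a
#' degenerate element and raises an error.
#'
#' @param mesh a [trimesh()].
#' @return list with `edges` (two-column matrix, `i < j`) and `weights`.
#' @export
cotangent_weights <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  # for each triangle corner k (opposite edge), accumulate cot(angle at k)/2
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  corner <- list(c(2L, 3L, 1L), c(3L, 1L, 2L), c(1L, 2L, 3L))
  for (k in 1:3) {
    opp <- tr[, corner[[k]][3]]
    a <- tr[, corner[[k]][1]]
    b <- tr[, corner[[k]][2]]
    u <- v[a, , drop = FALSE] - v[opp, , drop = FALSE]
    w2 <- v[b, , drop = FALSE] - v[opp, , drop = FALSE]
    dt <- rowSums(u * w2)
    cx <- u[, 2] * w2[, 3] - u[, 3] * w2[, 2]
    cy <- u[, 3] * w2[, 1] - u[, 1] * w2[, 3]
    cz <- u[, 1] * w2[, 2] - u[, 2] * w2[, 1]
    crn <- sqrt(cx^2 + cy^2 + cz^2)
    ang <- atan2(crn, dt)
    if (any(ang < 1e-9 | ang > pi - 1e-9))
      stop_gelfrac("geometry_error", sprintf(
        "degenerate angle in triangle %d",
        which(ang < 1e-9 | ang > pi - 1e-9)[1]))
    ii <- c(ii, pmin(a, b)); jj <- c(jj, pmax(a, b))
    ww <- c(ww, 0.5 * dt / crn)          # cot = cos/sin = dot/|cross|
  }
  key <- paste(ii, jj)
  agg <- rowsum(ww, key)
  ij <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  edges <- cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))
  o <- order(edges[, 1], edges[, 2])
  list(edges = edges[o, , drop = FALSE], weights = as.numeric(agg)[o])
}

#' Barycentric vertex areas
#'
#' `a_i = sum over incident triangles of area/3`. Always positive and sums
#' exactly to the total surface area (a partition of unity), unlike Voronoi
#' areas which can go negative on obtuse meshes.
#'
#' @param mesh a [trimesh()].
#' @return numeric vector, one area per vertex.
#' @export
vertex_areas <- function(mesh) {
  ar <- triangle_areas(mesh)
  nv <- nrow(mesh$vertices)
  a <- numeric(nv)
  third <- ar / 3
  for (k in 1:3) {
    acc <- rowsum(third, mesh$triangles[, k])
    ix <- as.integer(rownames(acc))
    a[ix] <- a[ix] + as.numeric(acc)
  }
  a
}

# Graph Laplacian applied to a vertex field f: (Lf)_i = sum_j w_ij (f_i - f_j)
# (unnormalized; divide by vertex areas for the Laplace-Beltrami estimate).
graph_laplacian_apply <- function(ops, f) {
  i <- ops$edges[, 1]; j <- ops$edges[, 2]; w <- ops$weights
  out <- numeric(ops$n_vertices)
  contrib_i <- w * (f[i] - f[j])
  acc <- rowsum(c(contrib_i, -contrib_i), c(i, j))
  out[as.integer(rownames(acc))] <- as.numeric(acc)
  out
}

#' Mesh resolution relative to the phase-field length scale
#'
#' Reports the effective element size `h_ele` (mean edge length, and the
#' maximum edge length within the named critical node set if given) divided
#' by the regularization length `ell`. The diffuse crack profile is only
#' resolved when `h_ele < ell`; a warning is issued when the ratio exceeds 1.
#'
#' @param mesh a [trimesh()].
#' @param ell phase-field length scale.
#' @param critical_set optional node-set name; when given, the ratio is also
#'   evaluated over edges with both endpoints in that set's 1-ring.
#' @return list with `h_mean`, `h_max`, `ratio` (= `h_mean / ell`) and
#'   `ratio_max`.
#' @export
mesh_resolution <- function(mesh, ell, critical_set = NULL) {
  ed <- mesh_edges(mesh)
  v <- mesh$vertices
  len <- sqrt(rowSums((v[ed$i, , drop = FALSE] - v[ed$j, , drop = FALSE])^2))
  h_mean <- mean(len); h_max <- max(len)
  if (!is.null(critical_set)) {
    ix <- mesh$node_sets[[critical_set]]
    if (!is.null(ix)) {
      sel <- ed$i %in% ix | ed$j %in% ix
      if (any(sel)) h_max <- max(len[sel])
    }
  }
  out <- list(h_mean = h_mean, h_max = h_max,
              ratio = h_mean / ell, ratio_max = h_max / ell)
  if (out$ratio > 1)
    warning(sprintf(
      "gelfrac: mesh under-resolves the phase field: h_ele/ell = %.3g > 1",
      out$ratio), call. = FALSE)
  out
}
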