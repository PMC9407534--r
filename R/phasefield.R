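# Vertex-based phase-field (damage) equation --------------------------------
#
# At each vertex i the discrete damage equation reads
#   (4 l (1-K) Wbar+_i / Gc + 1) p_i
#     + 4 l^2 (1/a_i) sum_j w_ij (p_i - p_j) = 1,
# with cotangent edge weights w_ij and barycentric vertex areas a_i. The
# assembled system is symmetrized by multiplying row i through by a_i,
# which leaves the solution unchanged and yields a symmetric (positive
# definite for nonnegative weights) sparse matrix. p = 1 is intact, p = 0
# broken; with Wbar+ = 0 the constant vector p = 1 solves the system
# exactly. Irreversibility is enforced by driving the equation with the
# running maximum H of the tensile energy density per element.

#' Phase-field parameters
#'
#' @param ell regularization length scale (sets the diffuse crack width;
#'   the mesh must resolve it, `h_ele < ell`).
#' @param gc fracture energy per unit area (critical energy release rate).
#' @param k_res residual constant K shared with the degradation function.
#' @return object of class `"phase_params"`.
#' @export
phase_params <- function(ell = 0.1, gc = 1e-3, k_res = 1e-4) {
  stopifnot(ell > 0, gc > 0, k_res > 0, k_res < 1)
  structure(list(ell = ell, gc = gc, k_res = k_res), class = "phase_params")
}

#' Transfer per-element driving energy to vertices
#'
#' Vertex value = area-weighted mean of the incident enabled elements'
#' energies, with barycentric weights (element area / 3). Elements outside
#' phase-field-enabled regions (non-hydrogel materials) do not contribute;
#' vertices with no enabled incident element get 0.
#'
#' @param mesh a [trimesh()].
#' @param elem_W per-element driving energy density (e.g. the history
#'   field).
#' @param enabled logical per-element mask (default all enabled).
#' @return per-vertex driving energy.
#' @export
vertex_driving_energy <- function(mesh, elem_W, enabled = NULL) {
  nt <- nrow(mesh$triangles)
  if (length(elem_W) != nt)
    stop_gelfrac("dimension_error", "elem_W must have one value per element")
  if (is.null(enabled)) enabled <- rep(TRUE, nt)
  ar <- triangle_areas(mesh) / 3
  ar[!enabled] <- 0
  nv <- nrow(mesh$vertices)
  num <- numeric(nv); den <- numeric(nv)
  for (k in 1:3) {
    ix <- mesh$triangles[, k]
    accn <- rowsum(ar * elem_W, ix)
    accd <- rowsum(ar, ix)
    at <- as.integer(rownames(accn))
    num[at] <- num[at] + as.numeric(accn)
    den[at] <- den[at] + as.numeric(accd)
  }
  out <- numeric(nv)
  pos <- den > 0
  out[pos] <- num[pos] / den[pos]
  out
}

#' Assemble the symmetrized phase-field linear system
#'
#' Builds `A p = b` with
#' `A_ii = a_i (4 l (1-K) W_i / Gc + 1) + 4 l^2 sum_j w_ij`,
#' `A_ij = -4 l^2 w_ij`, `b_i = a_i`. A is symmetric; with all `W = 0`,
#' `A 1 = b` holds exactly.
#'
#' @param ops [graph_operators()] of the mesh.
#' @param vertex_W per-vertex driving energy (>= 0).
#' @param params a [phase_params()].
#' @return list with sparse symmetric `A` (dgCMatrix) and `b`.
#' @export
assemble_phase_system <- function(ops, vertex_W, params) {
  nv <- ops$n_vertices
  if (length(vertex_W) != nv)
    stop_gelfrac("dimension_error", "vertex_W must have one value per vertex")
  if (any(!is.finite(vertex_W)))
    stop_gelfrac("assembly_error", sprintf(
      "non-finite driving energy at vertex %d", which(!is.finite(vertex_W))[1]))
  l <- params$ell; gc <- params$gc; K <- params$k_res
  i <- ops$edges[, 1]; j <- ops$edges[, 2]; w <- ops$weights
  wsum <- numeric(nv)
  acc <- rowsum(c(w, w), c(i, j))
  wsum[as.integer(rownames(acc))] <- as.numeric(acc)
  dia <- ops$vertex_areas * (4 * l * (1 - K) * vertex_W / gc + 1) +
    4 * l^2 * wsum
  A <- Matrix::sparseMatrix(i = c(seq_len(nv), i, j),
                            j = c(seq_len(nv), j, i),
                            x = c(dia, rep(-4 * l^2 * w, 2)),
                            dims = c(nv, nv))
  if (any(!is.finite(A@x)))
    stop_gelfrac("assembly_error", "non-finite entry in phase-field matrix")
  list(A = A, b = ops$vertex_areas)
}

#' Solve the phase-field system
#'
#' Sparse direct (Cholesky, falling back to LU when the matrix is
#' indefinite, e.g. with negative cotangent weights on poor meshes), with a
#' residual check `|A p - b| <= 1e-10 |b|`. The solution is clamped into
#' `[0, 1]` afterwards; the number of clamped entries is reported.
#'
#' @param sys list `(A, b)` from [assemble_phase_system()].
#' @return list with `p` (clamped), `p_raw`, `residual`, `n_clamped`.
#' @export
solve_phase <- function(sys) {
  p <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(sys$A)),
                             sys$b)),
    error = function(e)
      as.numeric(Matrix::solve(sys$A, sys$b)))
  res <- sqrt(sum((as.numeric(sys$A %*% p) - sys$b)^2)) /
    sqrt(sum(sys$b^2))
  if (!is.finite(res) || res > 1e-10)
    stop_gelfrac("linear_solve_error", sprintf(
      "phase-field solve residual %.3e exceeds 1e-10", res))
  clamped <- p < -1e-12 | p > 1 + 1e-12   # ignore pure roundoff
  list(p = pmin(pmax(p, 0), 1), p_raw = p, residual = res,
       n_clamped = sum(clamped))
}

#' Update the irreversibility history field
#'
#' `H' = max(H, Wbar+)` per element. The phase-field solve is driven by H,
#' not the instantaneous tensile energy, so damage never heals on
#' unloading.
#'
#' @param H current history field (>= 0), or `NULL` to initialize.
#' @param elem_W_plus instantaneous per-element tensile energy density.
#' @return updated history vector.
#' @export
update_history <- function(H, elem_W_plus) {
  if (is.null(H)) H <- numeric(length(elem_W_plus))
  if (length(H) != length(elem_W_plus))
    stop_gelfrac("dimension_error", "history and energy arrays differ in length")
  pmax(H, elem_W_plus)
}
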