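# Membrane shell kinematics and force assembly ------------------------------
#
# Constant-strain membrane triangle on a curved reference surface. Each
# element carries a reference orthonormal tangent frame (t1, t2, N) and the
# 2x2 reference edge matrix Dm (upper triangular by construction of t1
# along the first edge). For current nodal positions the in-plane map is
#   M = [e1 e2] Dm^{-1}  (3 x 2, reference tangent coords -> 3D),
# whose singular values are the in-plane principal stretches (lambda1,
# lambda2); the through-thickness stretch lambda3 scales the reference
# normal and is closed by the plane-stress condition dW/dlambda3 = 0.
# The element deformation gradient is F = M [t1 t2]' + lambda3 n N'.
#
# Internal forces are the exact gradient of the total degraded energy with
# respect to nodal positions. Because lambda3 sits at its plane-stress
# optimum, the envelope condition removes both the lambda3 sensitivity and
# the current-normal sensitivity (the normal stress component is zero), so
# only the in-plane terms assemble:
#   dE_elem = A t * (B[,1] . de1 + B[,2] . de2),  B = M S2 Dm^{-T},
# with S2 = V diag(g_i / lambda_i) V' computed from the closed-form
# spectral decomposition of C2 = M'M and g_i = dW/dlambda_i.

#' Reference element frames
#'
#' Precomputes, for every triangle, the orthonormal tangent basis, the
#' inverse reference edge matrix, the reference area and normal.
#'
#' @param mesh a [trimesh()].
#' @return object of class `"element_frames"` (list of per-element arrays).
#' @export
element_frames <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  a <- sqrt(rowSums(e1^2))
  t1 <- e1 / a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  N <- cbind(nx, ny, nz) / nn
  t2 <- cbind(N[, 2] * t1[, 3] - N[, 3] * t1[, 2],
              N[, 3] * t1[, 1] - N[, 1] * t1[, 3],
              N[, 1] * t1[, 2] - N[, 2] * t1[, 1])
  b <- rowSums(e2 * t1)
  d <- rowSums(e2 * t2)          # > 0 for non-degenerate, oriented triangles
  structure(list(t1 = t1, t2 = t2, N = N,
                 i11 = 1 / a, i12 = -b / (a * d), i22 = 1 / d,
                 area = 0.5 * nn),
            class = "element_frames")
}

# current in-plane map M = [m1 m2] and its 2x2 metric, vectorized
membrane_map <- function(frames, tr, positions) {
  e1 <- positions[tr[, 2], , drop = FALSE] - positions[tr[, 1], , drop = FALSE]
  e2 <- positions[tr[, 3], , drop = FALSE] - positions[tr[, 1], , drop = FALSE]
  m1 <- e1 * frames$i11
  m2 <- e1 * frames$i12 + e2 * frames$i22
  c11 <- rowSums(m1 * m1); c12 <- rowSums(m1 * m2); c22 <- rowSums(m2 * m2)
  half_diff <- (c11 - c22) / 2
  disc <- sqrt(half_diff^2 + c12^2)
  eig1 <- (c11 + c22) / 2 + disc
  eig2 <- pmax((c11 + c22) / 2 - disc, 0)
  list(e1 = e1, e2 = e2, m1 = m1, m2 = m2,
       c11 = c11, c12 = c12, c22 = c22, eig1 = eig1, eig2 = eig2,
       lambda1 = sqrt(eig1), lambda2 = sqrt(eig2))
}

#' Element deformation gradient of the membrane model
#'
#' Builds the full 3 x 3 deformation gradient of one element from current
#' vertex positions and a given through-thickness stretch: the in-plane map
#' composed with the tangent basis, plus `lambda3` carrying the reference
#' normal onto the current unit normal.
#'
#' @param mesh a [trimesh()].
#' @param element element index.
#' @param positions n x 3 current coordinates.
#' @param lambda3 through-thickness stretch (> 0).
#' @param frames optional precomputed [element_frames()].
#' @return 3 x 3 matrix F with `det F > 0`.
#' @export
element_deformation_gradient <- function(mesh, element, positions, lambda3 = 1,
                                         frames = NULL) {
  if (lambda3 <= 0) stop_gelfrac("precondition_error", "lambda3 must be > 0")
  if (is.null(frames)) frames <- element_frames(mesh)
  tr <- mesh$triangles[element, , drop = FALSE]
  mm <- membrane_map(lapply(frames, function(x)
    if (is.matrix(x)) x[element, , drop = FALSE] else x[element]),
    matrix(tr, 1, 3), positions)
  if (mm$eig2 < 1e-24)
    stop_gelfrac("degenerate_deformation", sprintf(
      "collapsed current triangle in element %d", element))
  Tb <- cbind(frames$t1[element, ], frames$t2[element, ])
  M <- cbind(mm$m1[1, ], mm$m2[1, ])
  ncur <- c(mm$e1[1, 2] * mm$e2[1, 3] - mm$e1[1, 3] * mm$e2[1, 2],
            mm$e1[1, 3] * mm$e2[1, 1] - mm$e1[1, 1] * mm$e2[1, 3],
            mm$e1[1, 1] * mm$e2[1, 2] - mm$e1[1, 2] * mm$e2[1, 1])
  ncur <- ncur / sqrt(sum(ncur^2))
  M %*% t(Tb) + lambda3 * tcrossprod(ncur, frames$N[element, ])
}

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch
gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  k <- seq_len(n - 1L)
  beta <- k / sqrt(4 * k^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(k, k + 1L)] <- beta
  Jm[cbind(k + 1L, k)] <- beta
  e <- eigen(Jm, symmetric = TRUE)
  o <- order(e$values)
  list(x = e$values[o], w = 2 * e$vectors[1, o]^2)
}

#' Through-thickness quadrature rule
#'
#' Gauss-Legendre abscissae and weights on `[-t/2, t/2]`; weights sum to the
#' thickness `t`. In pure-membrane mode every Gauss point sees the same
#' deformation gradient, so the thickness average reduces to the mid-surface
#' value; the rule matters once hinge bending perturbs the through-thickness
#' state in future extensions.
#'
#' @param n_gauss number of points (>= 1; the default 3 follows common
#'   shell practice of using at least three points through the thickness).
#' @param t thickness.
#' @return list with `x` (abscissae) and `w` (weights, `sum(w) = t`).
#' @export
thickness_rule <- function(n_gauss = 3L, t = 1) {
  stopifnot(n_gauss >= 1L, t > 0)
  gl <- gauss_legendre(as.integer(n_gauss))
  list(x = gl$x * t / 2, w = gl$w * t / 2)
}

# degradation function g(p) = (1 - K) p^2 + K
degrade <- function(p, k_res) (1 - k_res) * p^2 + k_res

# --- plane-stress thickness stretch ----------------------------------------

# hydrogel: the degraded energy is convex in lambda3 (each branch piece is
# convex and the split is C1 at the kinks lambda3 = 1 and J = 1), and the
# one-sided derivative at the lower kink is always <= 0 while at the upper
# kink it is always >= 0, so the stationary point lies between the kinks,
# where the stationarity condition is a single quadratic:
#   c0 = lambda1 lambda2 > 1:  lambda3 in [1/c0, 1], branch (compressive mu
#       term, tensile volumetric term): (mu + g chi c0^2) x^2 - g chi c0 x - mu = 0
#   c0 < 1: lambda3 in [1, 1/c0]: (g mu + chi c0^2) x^2 - chi c0 x - g mu = 0
ps_lambda3_hydrogel <- function(lambda1, lambda2, g, mu, chi) {
  c0 <- lambda1 * lambda2
  up <- c0 > 1
  cmu <- g + (1 - g) * up            # g when c0 <= 1 (lambda3 >= 1), else 1
  cchi <- 1 + (g - 1) * up           # g when c0 > 1 (J >= 1), else 1
  A <- cmu * mu + cchi * chi * c0^2
  B <- cchi * chi * c0
  root <- (B + sqrt(B^2 + 4 * A * cmu * mu)) / (2 * A)
  lo <- pmin(1, 1 / c0); hi <- pmax(1, 1 / c0)
  pmin(pmax(root, lo), hi)
}

# Ogden: safeguarded bisection on dW/dlambda3 over [1e-3, 1e3] (log scale)
ps_lambda3_ogden <- function(lambda1, lambda2, mat, lo = 1e-3, hi = 1e3,
                             iters = 80L) {
  a <- mat$alpha; mu <- mat$mu_og; kb <- mat$k_og
  dW <- function(l3) {
    J <- lambda1 * lambda2 * l3
    lb1 <- J^(-1 / 3) * lambda1; lb2 <- J^(-1 / 3) * lambda2
    lb3 <- J^(-1 / 3) * l3
    S <- lb1^a + lb2^a + lb3^a
    (2 * mu / a) * (lb3^a - S / 3) / l3 + kb * (J - 1) * J / l3
  }
  flo <- dW(rep(lo, length(lambda1))); fhi <- dW(rep(hi, length(lambda1)))
  if (any(flo > 0 | fhi < 0))
    stop_gelfrac("root_bracketing_error", sprintf(
      "plane-stress bracket has no sign change (lambda1=%.4g, lambda2=%.4g)",
      lambda1[which(flo > 0 | fhi < 0)[1]], lambda2[which(flo > 0 | fhi < 0)[1]]))
  llo <- rep(log(lo), length(lambda1)); lhi <- rep(log(hi), length(lambda1))
  for (it in seq_len(iters)) {
    mid <- (llo + lhi) / 2
    fm <- dW(exp(mid))
    pos <- fm > 0
    lhi[pos] <- mid[pos]; llo[!pos] <- mid[!pos]
  }
  exp((llo + lhi) / 2)
}

#' Plane-stress through-thickness stretch
#'
#' Returns the `lambda3 > 0` minimizing the (degraded) energy density at
#' fixed in-plane stretches, i.e. the root of `dW/dlambda3 = 0`, at which
#' the through-thickness Cauchy stress vanishes. For the hydrogel split
#' model the stationarity condition is piecewise quadratic and solved in
#' closed form; for the Ogden model a safeguarded bisection on
#' `[1e-3, 1e3]` is used.
#'
#' @param lambda1,lambda2 in-plane principal stretches (> 0); vectorized.
#' @param p_elem phase-field value(s) in `[0, 1]` (ignored by Ogden).
#' @param mat a [hydrogel_material()] or [ogden_material()].
#' @return numeric vector of lambda3 values.
#' @export
plane_stress_lambda3 <- function(lambda1, lambda2, p_elem = 1, mat) {
  stopifnot(all(lambda1 > 0), all(lambda2 > 0))
  n <- max(length(lambda1), length(lambda2))
  lambda1 <- rep_len(lambda1, n); lambda2 <- rep_len(lambda2, n)
  if (inherits(mat, "hydrogel_material")) {
    g <- rep_len(degrade(p_elem, mat$k_res), n)
    ps_lambda3_hydrogel(lambda1, lambda2, g, mat$mu, mat$chi)
  } else if (inherits(mat, "ogden_material")) {
    ps_lambda3_ogden(lambda1, lambda2, mat)
  } else stop_gelfrac("precondition_error", "unknown material type")
}

# --- shell model ------------------------------------------------------------

#' Assemble a shell model
#'
#' Bundles the mesh, per-region materials, phase-field parameters, the
#' discrete-geometry operators and optional hinge-bending stabilization
#' into the object consumed by the solvers. Damage evolves only on regions
#' whose material is a hydrogel; Ogden regions carry p = 1 throughout.
#'
#' @param mesh a [trimesh()].
#' @param materials named list mapping each region label of
#'   `mesh$element_region` to a [hydrogel_material()] or
#'   [ogden_material()].
#' @param pf a [phase_params()].
#' @param bending list `(enabled, stiffness)`: optional discrete-hinge
#'   bending energy `k_b (theta - theta0)^2 |e|^2 / (A1 + A2)` per interior
#'   edge, degraded by the same function as the tensile membrane energy.
#'   Default off; it exists to stabilize compressed curved shells, not to
#'   model solid-shell bending.
#' @param n_gauss through-thickness Gauss points (see [thickness_rule()]).
#' @param clamp_weights passed to [graph_operators()].
#' @return object of class `"shell_model"`.
#' @export
shell_model <- function(mesh, materials, pf = phase_params(),
                        bending = list(enabled = FALSE, stiffness = 0),
                        n_gauss = 3L, clamp_weights = FALSE) {
  regions <- unique(mesh$element_region)
  missing <- setdiff(regions, names(materials))
  if (length(missing))
    stop_gelfrac("config_error", sprintf(
      "no material for region(s): %s", paste(missing, collapse = ", ")))
  frames <- element_frames(mesh)
  nt <- nrow(mesh$triangles)
  is_gel <- vapply(mesh$element_region, function(r)
    inherits(materials[[r]], "hydrogel_material"), logical(1))
  # per-element material parameter arrays (fast path; heterogeneous regions)
  mu <- chi <- kres <- og_mu <- og_k <- og_a <- numeric(nt)
  for (r in regions) {
    ix <- mesh$element_region == r
    m <- materials[[r]]
    if (inherits(m, "hydrogel_material")) {
      mu[ix] <- m$mu; chi[ix] <- m$chi; kres[ix] <- m$k_res
    } else {
      og_mu[ix] <- m$mu_og; og_k[ix] <- m$k_og; og_a[ix] <- m$alpha
    }
  }
  ops <- graph_operators(mesh, clamp_weights = clamp_weights)
  bend <- NULL
  if (isTRUE(bending$enabled) && bending$stiffness > 0) {
    bend <- hinge_structure(mesh, frames)
    bend$stiffness <- bending$stiffness
  }
  structure(list(mesh = mesh, frames = frames, materials = materials,
                 pf = pf, ops = ops, n_gauss = as.integer(n_gauss),
                 is_gel = unname(is_gel),
                 mu = mu, chi = chi, kres = kres,
                 og_mu = og_mu, og_k = og_k, og_a = og_a,
                 bending = bend),
            class = "shell_model")
}

# interior-edge hinge bookkeeping for the optional bending stabilizer
hinge_structure <- function(mesh, frames) {
  ed <- mesh_edges(mesh)
  int <- ed$n_incident == 2L
  if (!any(int)) return(list(n = 0L))
  i0 <- ed$i[int]; i1 <- ed$j[int]
  t1 <- ed$tri1[int]; t2 <- ed$tri2[int]
  opp_of <- function(tri, a, b) {
    tv <- mesh$triangles[tri, , drop = FALSE]
    o <- integer(length(tri))
    for (k in 1:3) {
      cand <- tv[, k]
      sel <- cand != a & cand != b & o == 0L
      o[sel] <- cand[sel]
    }
    o
  }
  i2 <- opp_of(t1, i0, i1); i3 <- opp_of(t2, i0, i1)
  ar <- triangle_areas(mesh)
  v <- mesh$vertices
  len2 <- rowSums((v[i1, , drop = FALSE] - v[i0, , drop = FALSE])^2)
  coef <- len2 / (ar[t1] + ar[t2])
  st <- list(n = length(i0), i0 = i0, i1 = i1, i2 = i2, i3 = i3,
             tri1 = t1, tri2 = t2, coef = coef)
  st$theta0 <- hinge_angles(st, mesh$vertices)$theta
  st
}

# signed dihedral angles and their position gradients for all hinges
hinge_angles <- function(st, pos, with_grad = FALSE) {
  x0 <- pos[st$i0, , drop = FALSE]; x1 <- pos[st$i1, , drop = FALSE]
  x2 <- pos[st$i2, , drop = FALSE]; x3 <- pos[st$i3, , drop = FALSE]
  e <- x1 - x0
  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross3(e, x2 - x0)         # normal of (x0, x1, x2)
  n2 <- cross3(x3 - x0, e)         # normal of (x0, x3, x1)
  elen <- sqrt(rowSums(e^2))
  ehat <- e / elen
  sint <- rowSums(cross3(n1, n2) * ehat)
  cost <- rowSums(n1 * n2)
  theta <- atan2(sint, cost)
  out <- list(theta = theta)
  if (with_grad) {
    n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
    g2 <- -n1 * (elen / n1sq)
    g3 <- -n2 * (elen / n2sq)
    a1 <- rowSums((x1 - x2) * e) / elen
    a2 <- rowSums((x1 - x3) * e) / elen
    b1 <- rowSums((x0 - x2) * e) / elen
    b2 <- rowSums((x0 - x3) * e) / elen
    g0 <- n1 * (a1 / n1sq) + n2 * (a2 / n2sq)
    g1 <- -(n1 * (b1 / n1sq) + n2 * (b2 / n2sq))
    out$g0 <- g0; out$g1 <- g1; out$g2 <- g2; out$g3 <- g3
  }
  out
}

# --- mechanical state: energy, split densities, forces ----------------------

# Evaluate everything at given positions and per-element phase value.
# Returns per-element densities (thickness-averaged; equal to the
# mid-surface value in membrane mode), total energy and, optionally, the
# assembled nodal gradient (internal forces).
mech_state <- function(model, positions, p_elem, want_grad = TRUE,
                       want_stress = FALSE) {
  mesh <- model$mesh; fr <- model$frames
  tr <- mesh$triangles
  mm <- membrane_map(fr, tr, positions)
  if (any(mm$eig2 < 1e-24)) {
    bad <- which(mm$eig2 < 1e-24)[1]
    stop_gelfrac("degenerate_deformation", sprintf(
      "collapsed current triangle in element %d", bad))
  }
  l1 <- mm$lambda1; l2 <- mm$lambda2
  nt <- nrow(tr)
  l3 <- numeric(nt); Wp <- numeric(nt); Wm <- numeric(nt)
  g1 <- numeric(nt); g2v <- numeric(nt)
  gel <- model$is_gel
  gfac <- rep(1, nt)
  if (any(gel)) {
    i <- if (all(gel)) TRUE else which(gel)
    la <- l1[i]; lb <- l2[i]
    mu <- model$mu[i]; chi <- model$chi[i]; kr <- model$kres[i]
    gf <- degrade(p_elem[i], kr)
    gfac[i] <- gf
    l3i <- ps_lambda3_hydrogel(la, lb, gf, mu, chi)
    J <- la * lb * l3i
    wa <- 0.5 * (la^2 - 1) - log(la)
    wb <- 0.5 * (lb^2 - 1) - log(lb)
    wc <- 0.5 * (l3i^2 - 1) - log(l3i)
    ma <- la > 1; mb <- lb > 1; mc <- l3i > 1; mj <- J > 1
    jterm <- 0.5 * chi * (J - 1)^2
    Wp[i] <- mu * (wa * ma + wb * mb + wc * mc) + jterm * mj
    Wm[i] <- mu * (wa * (1 - ma) + wb * (1 - mb) + wc * (1 - mc)) +
      jterm * (1 - mj)
    vol <- chi * (J - 1) * J
    da <- mu * (la - 1 / la); db <- mu * (lb - 1 / lb)
    g1[i] <- gf * (da * ma + vol * mj / la) + da * (1 - ma) +
      vol * (1 - mj) / la
    g2v[i] <- gf * (db * mb + vol * mj / lb) + db * (1 - mb) +
      vol * (1 - mj) / lb
    l3[i] <- l3i
  }
  if (any(!gel)) {
    i <- which(!gel)
    muo <- model$og_mu[i]; ko <- model$og_k[i]; al <- model$og_a[i]
    l3i <- ps_lambda3_ogden_vec(l1[i], l2[i], muo, ko, al)
    J <- l1[i] * l2[i] * l3i
    jb <- J^(-1 / 3)
    S <- (jb * l1[i])^al + (jb * l2[i])^al + (jb * l3i)^al
    W <- 2 * muo / al^2 * (S - 3) + 0.5 * ko * (J - 1)^2
    Wm[i] <- W                      # substrate: never degraded, never driving
    g1[i] <- (2 * muo / al) * ((jb * l1[i])^al - S / 3) / l1[i] +
      ko * (J - 1) * J / l1[i]
    g2v[i] <- (2 * muo / al) * ((jb * l2[i])^al - S / 3) / l2[i] +
      ko * (J - 1) * J / l2[i]
    l3[i] <- l3i
  }
  Wdeg <- gfac * Wp + Wm
  fac <- fr$area * mesh$thickness
  energy <- sum(fac * Wdeg)
  out <- list(W_plus = Wp, W_minus = Wm, W = Wdeg, lambda1 = l1, lambda2 = l2,
              lambda3 = l3, energy = energy,
              E_plus = sum(fac * gfac * Wp), E_minus = sum(fac * Wm),
              E_bend = 0)
  if (want_stress) {
    J3 <- l1 * l2 * l3
    # effective Cauchy stress from principal values sigma_i = g_i lambda_i / J
    # (sigma_3 = 0 by the plane-stress closure)
    sg1 <- g1 * l1 / J3; sg2 <- g2v * l2 / J3
    mean_s <- (sg1 + sg2) / 3
    out$sigma_vm <- sqrt(1.5 * ((sg1 - mean_s)^2 + (sg2 - mean_s)^2 +
                                  (0 - mean_s)^2))
  }
  if (want_grad) {
    h1 <- g1 / l1; h2 <- g2v / l2
    gap <- mm$eig1 - mm$eig2
    sep <- gap > 1e-12 * pmax(mm$eig1, 1)
    hh <- (h1 + h2) / 2
    invgap <- sep / pmax(gap, .Machine$double.xmin)
    p11 <- (mm$c11 - mm$eig2) * invgap
    p12 <- mm$c12 * invgap
    dh <- (h1 - h2) * sep
    nsep <- 1 - sep
    s11 <- sep * (h2 + dh * p11) + nsep * hh
    s22 <- sep * (h2 + dh * (1 - p11)) + nsep * hh
    s12 <- dh * p12
    t11 <- s11 * fr$i11 + s12 * fr$i12
    t12 <- s12 * fr$i22
    t21 <- s12 * fr$i11 + s22 * fr$i12
    t22 <- s22 * fr$i22
    B1 <- mm$m1 * t11 + mm$m2 * t21
    B2 <- mm$m1 * t12 + mm$m2 * t22
    c1 <- B1 * fac; c2 <- B2 * fac
    contrib <- rbind(-(c1 + c2), c1, c2)
    idx <- c(tr[, 1], tr[, 2], tr[, 3])
    grad <- matrix(0, nrow(positions), 3)
    acc <- rowsum(contrib, idx)
    grad[as.integer(rownames(acc)), ] <- acc
    out$grad <- grad
  }
  # optional hinge bending stabilizer
  if (!is.null(model$bending) && model$bending$n > 0L) {
    st <- model$bending
    ha <- hinge_angles(st, positions, with_grad = want_grad)
    pe <- (p_elem[st$tri1] + p_elem[st$tri2]) / 2
    kr_e <- (model$kres[st$tri1] + model$kres[st$tri2]) / 2
    ge <- degrade(pe, ifelse(kr_e > 0, kr_e, 1e-4))
    dth <- ha$theta - st$theta0
    eb <- st$stiffness * ge * st$coef * dth^2
    out$E_bend <- sum(eb)
    out$energy <- out$energy + out$E_bend
    if (want_grad) {
      w <- 2 * st$stiffness * ge * st$coef * dth
      contrib <- rbind(ha$g0 * w, ha$g1 * w, ha$g2 * w, ha$g3 * w)
      idx <- c(st$i0, st$i1, st$i2, st$i3)
      acc <- rowsum(contrib, idx)
      out$grad[as.integer(rownames(acc)), ] <-
        out$grad[as.integer(rownames(acc)), ] + acc
    }
  }
  out
}

ps_lambda3_ogden_vec <- function(lambda1, lambda2, mu, kb, a,
                                 lo = 1e-3, hi = 1e3, iters = 70L) {
  dW <- function(l3) {
    J <- lambda1 * lambda2 * l3
    jb <- J^(-1 / 3)
    S <- (jb * lambda1)^a + (jb * lambda2)^a + (jb * l3)^a
    (2 * mu / a) * ((jb * l3)^a - S / 3) / l3 + kb * (J - 1) * J / l3
  }
  if (any(dW(rep(lo, length(lambda1))) > 0 |
            dW(rep(hi, length(lambda1))) < 0))
    stop_gelfrac("root_bracketing_error",
                 "Ogden plane-stress bracket has no sign change")
  llo <- rep(log(lo), length(lambda1)); lhi <- rep(log(hi), length(lambda1))
  for (it in seq_len(iters)) {
    mid <- (llo + lhi) / 2
    pos <- dW(exp(mid)) > 0
    lhi[pos] <- mid[pos]; llo[!pos] <- mid[!pos]
  }
  exp((llo + lhi) / 2)
}

#' Thickness-averaged split energy of one element
#'
#' Evaluates the tensile/compressive energy densities at each
#' through-thickness Gauss point of the element and returns their
#' arithmetic average `(1/NG) sum_I W_I`. In membrane mode every Gauss
#' point sees the same deformation gradient, so the average equals the
#' single-point value; the function exists to honor the averaging contract
#' explicitly.
#'
#' @param model a [shell_model()].
#' @param element element index.
#' @param positions n x 3 current coordinates.
#' @param p_elem element phase value.
#' @return named vector `c(W_plus = , W_minus = )`.
#' @export
element_avg_energy <- function(model, element, positions, p_elem = 1) {
  ng <- model$n_gauss
  acc <- c(W_plus = 0, W_minus = 0)
  ms <- mech_state_single(model, element, positions, p_elem)
  for (I in seq_len(ng)) acc <- acc + c(ms$W_plus, ms$W_minus)
  acc / ng
}

mech_state_single <- function(model, element, positions, p_elem) {
  p <- rep(1, nrow(model$mesh$triangles))
  p[element] <- p_elem
  st <- mech_state(model, positions, p, want_grad = FALSE)
  list(W_plus = st$W_plus[element], W_minus = st$W_minus[element])
}

#' Assembled internal nodal forces and total energy
#'
#' The internal force vector is the exact gradient of the total energy
#' `sum_e A_e t_e W_e(positions, p)` with respect to nodal positions
#' (3 components per vertex), assembled element-wise from the PK1 stress in
#' the principal frame; the plane-stress envelope condition removes all
#' lambda3 sensitivity terms.
#'
#' @param model a [shell_model()].
#' @param positions n x 3 current coordinates.
#' @param p per-vertex phase field (mapped to elements by the vertex mean),
#'   or `NULL` for intact material.
#' @return list with `forces` (n x 3 matrix, `dE/dx`), `energy`,
#'   `W_plus`, `W_minus` (per-element densities), `lambda3`.
#' @export
internal_forces <- function(model, positions, p = NULL) {
  pe <- element_phase(model, p)
  st <- mech_state(model, positions, pe, want_grad = TRUE)
  list(forces = st$grad, energy = st$energy,
       W_plus = st$W_plus, W_minus = st$W_minus, lambda3 = st$lambda3,
       E_plus = st$E_plus, E_minus = st$E_minus, E_bend = st$E_bend)
}

#' Total energy at given positions and phase field
#'
#' @inheritParams internal_forces
#' @return scalar total energy.
#' @export
total_energy <- function(model, positions, p = NULL) {
  pe <- element_phase(model, p)
  mech_state(model, positions, pe, want_grad = FALSE)$energy
}

# element phase value = mean of its three vertex values; substrate regions
# are pinned at p = 1
element_phase <- function(model, p) {
  nt <- nrow(model$mesh$triangles)
  if (is.null(p)) return(rep(1, nt))
  tr <- model$mesh$triangles
  pe <- (p[tr[, 1]] + p[tr[, 2]] + p[tr[, 3]]) / 3
  pe[!model$is_gel] <- 1
  pe
}
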