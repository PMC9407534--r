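# membrane kinematics, plane-stress closure, force assembly

test_that("element deformation gradient has the expected singular values", {
  m <- flat_strip(1, 1, 0.5)
  fr <- element_frames(m)
  # identity
  F <- element_deformation_gradient(m, 1, m$vertices, 1, frames = fr)
  expect_equal(svd(F)$d, c(1, 1, 1), tolerance = 1e-12)
  expect_gt(det(F), 0)
  # uniform in-plane stretch s with lambda3 = q
  pos <- m$vertices
  pos[, 1:2] <- pos[, 1:2] * 1.3
  F <- element_deformation_gradient(m, 2, pos, 0.85, frames = fr)
  expect_equal(sort(svd(F)$d), sort(c(1.3, 1.3, 0.85)), tolerance = 1e-12)
  # rigid rotation: singular values 1 and zero split energy
  set.seed(31)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  F <- element_deformation_gradient(m, 3, m$vertices %*% t(R), 1, frames = fr)
  expect_equal(svd(F)$d, c(1, 1, 1), tolerance = 1e-10)
  expect_equal(unname(split_energy(stretch_state(F), ref_hydrogel())),
               c(0, 0), tolerance = 1e-12)
  expect_error(element_deformation_gradient(m, 1, m$vertices, 0),
               class = "gelfrac_precondition_error")
})

test_that("plane-stress lambda3: trivial, scan oracle, incompressible limit", {
  mat <- ref_hydrogel()
  expect_equal(plane_stress_lambda3(1, 1, 0.3, mat), 1)
  expect_equal(plane_stress_lambda3(1, 1, 1, mat), 1)

  # brute-force 2000-point scan oracle at random states
  set.seed(32)
  for (k in 1:10) {
    l1 <- runif(1, 0.75, 1.4); l2 <- runif(1, 0.75, 1.4); p <- runif(1)
    l3 <- plane_stress_lambda3(l1, l2, p, mat)
    lo <- min(1, 1 / (l1 * l2)) * 0.8
    hi <- max(1, 1 / (l1 * l2)) * 1.2
    grid <- seq(lo, hi, length.out = 2000)
    W <- vapply(grid, function(x) {
      w <- split_energy(stretch_state(diag(c(l1, l2, x))), mat)
      degraded_energy(w[1], w[2], p, mat)
    }, numeric(1))
    expect_lt(abs(l3 - grid[which.min(W)]), (grid[2] - grid[1]) + 1e-6)
    # stationarity: through-thickness stress vanishes at the solution
    h <- 1e-6
    Wof <- function(x) {
      w <- split_energy(stretch_state(diag(c(l1, l2, x))), mat)
      degraded_energy(w[1], w[2], p, mat)
    }
    expect_lt(abs((Wof(l3 + h) - Wof(l3 - h)) / (2 * h)), 1e-6)
  }

  # chi/mu -> infinity forces the incompressible limit l3 -> 1/(l1 l2)
  stiff <- hydrogel_material(1, 1e4, 1e-4)
  l3 <- plane_stress_lambda3(1.2, 1.0, 1, stiff)
  expect_lt(abs(l3 - 1 / 1.2) / (1 / 1.2), 0.01)

  # Ogden closure agrees with a scan too
  om <- ref_ogden()
  l3 <- plane_stress_lambda3(1.05, 1.02, mat = om)
  grid <- seq(0.8, 1.1, length.out = 2000)
  W <- vapply(grid, function(x)
    ogden_energy(diag(c(1.05, 1.02, x)), om), numeric(1))
  expect_lt(abs(l3 - grid[which.min(W)]), (grid[2] - grid[1]) + 1e-6)
})

test_that("thickness averaging equals the membrane value for any NG", {
  m <- flat_strip(1, 1, 0.5)
  mat <- ref_hydrogel()
  pos <- m$vertices
  pos[, 1:2] <- pos[, 1:2] * 1.1
  for (ng in c(1L, 3L, 5L)) {
    model <- shell_model(m, list(hydrogel = mat), n_gauss = ng)
    w <- element_avg_energy(model, 2, pos, p_elem = 0.8)
    st <- gelfrac:::mech_state(model, pos, rep(0.8, nrow(m$triangles)),
                               want_grad = FALSE)
    expect_equal(unname(w["W_plus"]), st$W_plus[2], tolerance = 1e-14)
    expect_equal(unname(w["W_minus"]), st$W_minus[2], tolerance = 1e-14)
  }
  model <- shell_model(m, list(hydrogel = mat))
  expect_equal(unname(element_avg_energy(model, 1, m$vertices, 1)), c(0, 0))
  # quadrature weights integrate the thickness exactly
  tr <- thickness_rule(4L, t = 0.3)
  expect_equal(sum(tr$w), 0.3, tolerance = 1e-14)
  expect_true(all(abs(tr$x) <= 0.15))
})

test_that("assembled forces are the exact gradient of the total energy", {
  set.seed(33)
  m <- gen_notched_plate(2, 1, 0.5, 0.12)
  mat <- ref_hydrogel()
  model <- shell_model(m, list(hydrogel = mat))
  nv <- nrow(m$vertices)
  pos <- m$vertices + matrix(rnorm(3 * nv, 0, 0.01), nv, 3)
  pos[, 1:2] <- pos[, 1:2] * 1.04
  p <- runif(nv, 0.2, 1)
  fi <- internal_forces(model, pos, p)
  h <- 1e-6
  for (k in 1:15) {
    v <- sample(nv, 1); d <- sample(3, 1)
    pp <- pos; pp[v, d] <- pp[v, d] + h
    pm <- pos; pm[v, d] <- pm[v, d] - h
    fd <- (total_energy(model, pp, p) - total_energy(model, pm, p)) / (2 * h)
    expect_lt(abs(fd - fi$forces[v, d]) / max(abs(fd), 1e-10), 1e-4)
  }
})

test_that("rigid motions are force-free and translations conserved", {
  set.seed(34)
  m <- gen_perforated_sphere_patch(1, 0.05, 0L, "octant", 0.2)
  model <- shell_model(m, list(hydrogel = ref_hydrogel()))
  nv <- nrow(m$vertices)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  pos <- m$vertices %*% t(R) + matrix(c(0.2, -0.1, 0.4), nv, 3, byrow = TRUE)
  fi <- internal_forces(model, pos, NULL)
  expect_lt(max(abs(fi$forces)), 1e-9)
  expect_lt(abs(fi$energy), 1e-12)

  # stretched free-floating mesh: net force zero (translation invariance)
  pos2 <- m$vertices * 1.08
  fi2 <- internal_forces(model, pos2, NULL)
  expect_lt(max(abs(colSums(fi2$forces))), 1e-10)
  expect_gt(fi2$energy, 0)
})

test_that("envelope condition: energy is second order in lambda3 perturbations", {
  m <- flat_strip(1, 1, 0.5)
  mat <- ref_hydrogel()
  model <- shell_model(m, list(hydrogel = mat))
  pos <- m$vertices
  pos[, 1:2] <- pos[, 1:2] * 1.15
  st <- gelfrac:::mech_state(model, pos, rep(0.9, nrow(m$triangles)),
                             want_grad = FALSE)
  e <- 3L
  l3 <- st$lambda3[e]
  g <- gelfrac:::degrade(0.9, mat$k_res)
  Wof <- function(x) {
    w <- split_energy(stretch_state(diag(c(st$lambda1[e], st$lambda2[e], x))),
                      mat)
    degraded_energy(w[1], w[2], 0.9, mat)
  }
  d3 <- vapply(c(1e-3, 1e-4), function(h)
    abs(Wof(l3 + h) - Wof(l3)), numeric(1))
  # quadratic scaling: shrinking the step by 10 shrinks the gap by ~100
  expect_lt(d3[2], d3[1] / 50)
})

test_that("total energy is additive over elements", {
  m <- flat_strip(1.5, 1, 0.25)
  mat <- ref_hydrogel()
  model <- shell_model(m, list(hydrogel = mat))
  pos <- m$vertices
  pos[, 1] <- pos[, 1] * 1.07
  p <- rep(0.85, nrow(m$vertices))
  pe <- gelfrac:::element_phase(model, p)
  st <- gelfrac:::mech_state(model, pos, pe, want_grad = FALSE)
  fac <- model$frames$area * m$thickness
  expect_equal(st$energy, sum(fac * st$W), tolerance = 1e-12)
  expect_equal(total_energy(model, pos, p), st$energy, tolerance = 1e-15)
})

test_that("hinge bending energy is degraded and its gradient is exact", {
  set.seed(35)
  m <- gen_icosphere(1, 1)
  mat <- ref_hydrogel()
  model <- shell_model(m, list(hydrogel = mat),
                       bending = list(enabled = TRUE, stiffness = 1e-3))
  nv <- nrow(m$vertices)
  # reference state: rest angles give zero bending energy
  fi0 <- internal_forces(model, m$vertices, NULL)
  expect_equal(fi0$E_bend, 0, tolerance = 1e-15)
  pos <- m$vertices + matrix(rnorm(3 * nv, 0, 0.02), nv, 3)
  p <- runif(nv, 0.2, 1)
  fi <- internal_forces(model, pos, p)
  expect_gt(fi$E_bend, 0)
  h <- 1e-6
  for (k in 1:8) {
    v <- sample(nv, 1); d <- sample(3, 1)
    pp <- pos; pp[v, d] <- pp[v, d] + h
    pm <- pos; pm[v, d] <- pm[v, d] - h
    fd <- (total_energy(model, pp, p) - total_energy(model, pm, p)) / (2 * h)
    expect_lt(abs(fd - fi$forces[v, d]) / max(abs(fd), 1e-8), 2e-4)
  }
  # damage reduces bending resistance
  E_intact <- total_energy(model, pos, rep(1, nv))
  E_damaged <- total_energy(model, pos, rep(0.2, nv))
  expect_lt(E_damaged, E_intact)
})
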