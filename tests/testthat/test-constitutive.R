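# split neo-Hookean hydrogel model, Ogden model, stresses

test_that("stretch_state extracts principal stretches and invariants", {
  s <- stretch_state(diag(3))
  expect_equal(s$lambdas, c(1, 1, 1))
  expect_equal(s$J, 1)
  expect_equal(s$I1, 3)

  s <- stretch_state(diag(c(1.2, 1.0, 0.8)))
  expect_equal(s$lambdas, c(1.2, 1.0, 0.8))
  expect_equal(s$J, 0.96, tolerance = 1e-12)
  expect_equal(prod(s$lambdas), s$J, tolerance = 1e-10)

  # rotation invariance of the principal decomposition
  set.seed(21)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  s2 <- stretch_state(R %*% diag(c(1.2, 1, 0.8)))
  expect_equal(s2$lambdas, c(1.2, 1, 0.8), tolerance = 1e-10)
  expect_equal(s2$J, 0.96, tolerance = 1e-10)

  expect_error(stretch_state(diag(c(1, 1, -1))),
               class = "gelfrac_inverted_element")
})

test_that("split energy matches independently evaluated closed forms", {
  mat <- ref_hydrogel()
  w0 <- split_energy(stretch_state(diag(3)), mat)
  expect_equal(unname(w0), c(0, 0))

  # frozen values from scalar evaluation of the neo-Hookean form
  # G = mu/2 sum(l^2 - 1 - 2 log l) + chi/2 (J-1)^2 with mu=1, chi=2.17
  w <- split_energy(stretch_state(diag(c(1.2, 1, 1))), mat)
  expect_equal(unname(w[1]), 0.5 * (1.44 - 1 - 2 * log(1.2)) +
                 0.5 * 2.17 * 0.2^2, tolerance = 1e-12)
  expect_equal(unname(w[1]), 0.08108, tolerance = 1e-4)
  expect_equal(unname(w[2]), 0)

  w <- split_energy(stretch_state(diag(c(0.8, 1, 1))), mat)
  expect_equal(unname(w[1]), 0)
  expect_equal(unname(w[2]), 0.08654, tolerance = 1e-4)

  # mixed state: J = 0.96 <= 1, so no volumetric tensile part
  w <- split_energy(stretch_state(diag(c(1.2, 0.8, 1))), mat)
  expect_equal(unname(w[1]), 0.03768, tolerance = 1e-4)
  expect_equal(unname(w[2]),
               0.5 * (0.64 - 1 - 2 * log(0.8)) + 0.5 * 2.17 * (0.96 - 1)^2,
               tolerance = 1e-12)
})

test_that("split is exhaustive, nonnegative and continuous across the kinks", {
  mat <- ref_hydrogel()
  set.seed(22)
  for (k in 1:20) {
    F <- random_F()
    s <- stretch_state(F)
    w <- split_energy(s, mat)
    expect_gte(w[1], 0)
    expect_gte(w[2], 0)
    G <- mat$mu * sum(0.5 * (s$lambdas^2 - 1 - 2 * log(s$lambdas))) +
      0.5 * mat$chi * (s$J - 1)^2
    expect_equal(unname(w[1] + w[2]), G, tolerance = 1e-12)
  }
  # path crossing lambda = 1 and J = 1: W+ + W- continuous, parts continuous
  path <- seq(0.98, 1.02, length.out = 81)
  vals <- vapply(path, function(a)
    split_energy(stretch_state(diag(c(a, 1, 1))), mat), numeric(2))
  expect_lt(max(abs(diff(vals[1, ]))), 1e-3)
  expect_lt(max(abs(diff(vals[2, ]))), 1e-3)
  idx1 <- which.min(abs(path - 1))
  expect_equal(unname(vals[1, idx1]), 0, tolerance = 1e-12)
  expect_equal(unname(vals[2, idx1]), 0, tolerance = 1e-12)
})

test_that("degradation applies to the tensile part only and is monotone in p", {
  mat <- hydrogel_material(1, 2.17, k_res = 1e-4)
  expect_equal(degraded_energy(2, 1, 1, mat), 3)               # full integrity
  expect_equal(degraded_energy(2, 1, 0, mat), 1e-4 * 2 + 1)    # residual
  expect_equal(degraded_energy(2, 1, 0.5, mat),
               (0.9999 * 0.25 + 1e-4) * 2 + 1, tolerance = 1e-12)
  expect_equal(degraded_energy(2, 1, 0.5, mat), 1.50015, tolerance = 1e-12)
  p <- seq(0, 1, 0.05)
  expect_true(all(diff(degraded_energy(2, 1, p, mat)) > 0))
  expect_error(degraded_energy(1, 1, 1.5, mat), class = "gelfrac_domain_error")
})

test_that("hydrogel PK1 matches the undamaged closed form and the FD oracle", {
  mat <- hydrogel_material(1, 2.17, k_res = 1e-12)
  # all stretches > 1 and J > 1 with p = 1, K -> 0: classical neo-Hookean
  F <- diag(c(1.3, 1.2, 1.1)) %*% (diag(3) + 0.05 * matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3))
  s <- stretch_state(F)
  stopifnot(all(s$lambdas > 1), s$J > 1)
  P <- pk1_hydrogel(F, 1, mat)
  Pref <- mat$mu * (F - t(solve(F))) +
    mat$chi * s$J * (s$J - 1) * t(solve(F))
  expect_equal(P, Pref, tolerance = 1e-9)

  # FD oracle over random states and damage levels
  mat <- ref_hydrogel()
  set.seed(23)
  for (k in 1:20) {
    F <- random_F()
    p <- runif(1)
    P <- pk1_hydrogel(F, p, mat)
    fun <- function(FF) {
      w <- split_energy(stretch_state(FF), mat)
      degraded_energy(w[1], w[2], p, mat)
    }
    Pfd <- fd_matrix_grad(fun, F)
    expect_lt(max(abs(P - Pfd)) / max(abs(Pfd), 1e-8), 1e-5)
  }
  expect_equal(pk1_hydrogel(diag(3), 0.5, mat), matrix(0, 3, 3))
})

test_that("frame indifference of energies and stress norms", {
  mat <- ref_hydrogel()
  om <- ref_ogden()
  set.seed(24)
  for (k in 1:10) {
    F <- random_F()
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
    w1 <- split_energy(stretch_state(F), mat)
    w2 <- split_energy(stretch_state(R %*% F), mat)
    expect_equal(w1, w2, tolerance = 1e-10)
    expect_equal(ogden_energy(F, om), ogden_energy(R %*% F, om),
                 tolerance = 1e-10)
    expect_equal(norm(pk1_hydrogel(F, 0.7, mat), "F"),
                 norm(pk1_hydrogel(R %*% F, 0.7, mat), "F"), tolerance = 1e-9)
  }
})

test_that("Ogden energy and stress: reference values, alpha = 2 reduction, FD", {
  om <- ref_ogden()
  expect_equal(ogden_energy(diag(3), om), 0)
  expect_equal(ogden_pk1(diag(3), om), matrix(0, 3, 3), tolerance = 1e-14)

  # isochoric uniaxial state, soft-tissue parameters
  F <- diag(c(1.1, 1.1^-0.5, 1.1^-0.5))
  expect_equal(ogden_energy(F, om),
               2 * 0.1 / 400 * (1.1^(-20) + 2 * 1.1^10 - 3), tolerance = 1e-12)
  expect_equal(ogden_energy(F, om), 1.1681e-3, tolerance = 1e-4)

  # alpha = 2 collapses to deviatoric neo-Hookean + volumetric
  om2 <- ogden_material(0.37, 1.4, alpha = 2)
  set.seed(25)
  for (k in 1:10) {
    F <- random_F(0.15)
    s <- stretch_state(F)
    Wref <- 0.37 / 2 * (s$J^(-2 / 3) * sum(s$lambdas^2) - 3) +
      0.5 * 1.4 * (s$J - 1)^2
    expect_equal(ogden_energy(F, om2), Wref, tolerance = 1e-10)
  }

  # FD oracle for the stress
  set.seed(26)
  for (k in 1:20) {
    F <- random_F(0.1)
    P <- ogden_pk1(F, om)
    Pfd <- fd_matrix_grad(function(FF) ogden_energy(FF, om), F)
    expect_lt(max(abs(P - Pfd)) / max(abs(Pfd)), 1e-5)
  }
})

test_that("effective Cauchy stress: zero, hydrostatic and uniaxial cases", {
  F <- diag(c(1.2, 0.9, 1.05))
  expect_equal(cauchy_effective(matrix(0, 3, 3), F), 0)
  # hydrostatic Cauchy stress: sigma = -q I => P = J sigma F^-T
  J <- det(F)
  P <- J * (-0.37 * diag(3)) %*% t(solve(F))
  expect_equal(cauchy_effective(P, F), 0, tolerance = 1e-12)
  # uniaxial sigma = diag(s, 0, 0) gives von Mises s
  P <- J * diag(c(2.5, 0, 0)) %*% t(solve(F))
  expect_equal(cauchy_effective(P, F), 2.5, tolerance = 1e-12)
})
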