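# Constitutive models --------------------------------------------------------
#
# Hydrogel: compressible neo-Hookean energy in principal stretches,
#   G(lambda, J) = mu/2 * sum(lambda_i^2 - 1 - 2 log lambda_i)
#               + chi/2 * (J - 1)^2,
# split into a tensile part W+ (stretches > 1 and J > 1) and a compressive
# part W- (stretches < 1 and J < 1). Only W+ is degraded by the damage
# function g(p) = (1 - K) p^2 + K (p = 1 intact, p = 0 broken).
#
# Substrate: Ogden model in deviatoric principal stretches,
#   W = 2 muOg / alpha^2 * (lbar1^a + lbar2^a + lbar3^a - 3)
#     + KOg/2 * (J - 1)^2,  lbar_i = J^(-1/3) lambda_i.
#
# Both energies are isotropic functions of the principal stretches, so the
# first Piola-Kirchhoff stress is assembled in the principal (SVD) frame:
# P = U diag(dW/dlambda_i) V' for F = U diag(lambda) V'. This holds for the
# gradient even with repeated singular values (only tangents need the
# divided-difference limit, and gelfrac solves equilibrium by energy
# minimization, so tangents are never assembled).

#' Hydrogel material (split neo-Hookean)
#'
#' @param mu initial shear modulus (> 0); all bundled scenarios use mu = 1
#'   in nondimensional units.
#' @param chi Lame-type volumetric constant (>= 0); default `2.17 * mu`.
#' @param k_res residual stiffness constant K in the degradation function
#'   `(1-K) p^2 + K`, a small value kept for numerical stability.
#' @return object of class `"hydrogel_material"`.
#' @export
hydrogel_material <- function(mu = 1, chi = 2.17 * mu, k_res = 1e-4) {
  stopifnot(mu > 0, chi >= 0, k_res > 0, k_res < 1)
  structure(list(type = "hydrogel", mu = mu, chi = chi, k_res = k_res),
            class = c("hydrogel_material", "gelfrac_material"))
}

#' Ogden material (soft-tissue substrate)
#'
#' @param mu_og shear modulus (> 0).
#' @param k_og bulk modulus (> 0).
#' @param alpha Ogden exponent (nonzero; may be negative — the bundled
#'   soft-tissue parameters use alpha = -20).
#' @return object of class `"ogden_material"`.
#' @export
ogden_material <- function(mu_og = 0.1, k_og = 1.0, alpha = -20) {
  stopifnot(mu_og > 0, k_og > 0, alpha != 0)
  structure(list(type = "ogden", mu_og = mu_og, k_og = k_og, alpha = alpha),
            class = c("ogden_material", "gelfrac_material"))
}

#' Principal-stretch decomposition of a deformation gradient
#'
#' Singular value decomposition of F: principal stretches (descending),
#' Jacobian `J = det F = prod(lambda)`, first invariant `I1 = sum(lambda^2)`
#' and the rotation factors needed to assemble stresses in the principal
#' frame.
#'
#' @param F 3 x 3 deformation gradient with `det F > 0`.
#' @param element optional element id for error reporting.
#' @return object of class `"stretch_state"` with fields `F`, `lambdas`,
#'   `J`, `I1`, `U`, `V`.
#' @export
stretch_state <- function(F, element = NULL) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop_gelfrac("inverted_element", sprintf(
      "det F = %.3e <= 0%s", J,
      if (is.null(element)) "" else sprintf(" in element %d", element)))
  sv <- svd(F)
  structure(list(F = F, lambdas = sv$d, J = J, I1 = sum(sv$d^2),
                 U = sv$u, V = sv$v),
            class = "stretch_state")
}

# scalar neo-Hookean stretch term, zero at lambda = 1, nonnegative
nh_term <- function(lam) 0.5 * (lam^2 - 1 - 2 * log(lam))

#' Tension/compression split of the hydrogel energy
#'
#' `W+ = G(lambda_i^+, J^+)` and `W- = G(lambda_i^-, J^-)` where a stretch
#' enters the tensile branch when `lambda_i > 1` (else it is replaced by 1
#' and contributes nothing) and the volumetric term enters the tensile
#' branch when `J > 1`. Both parts are nonnegative and sum to the undamaged
#' energy `G(lambda_i, J)`.
#'
#' @param s a [stretch_state()].
#' @param mat a [hydrogel_material()].
#' @return named numeric vector `c(W_plus = , W_minus = )`.
#' @export
split_energy <- function(s, mat) {
  lam <- s$lambdas; J <- s$J
  wp <- mat$mu * sum(nh_term(pmax(lam, 1))) +
    0.5 * mat$chi * (max(J, 1) - 1)^2
  wm <- mat$mu * sum(nh_term(pmin(lam, 1))) +
    0.5 * mat$chi * (min(J, 1) - 1)^2
  c(W_plus = wp, W_minus = wm)
}

#' Degraded free energy density
#'
#' `W = [(1 - K) p^2 + K] W+ + W-`: damage degrades only the tensile part,
#' leaving compressive resistance intact.
#'
#' @param W_plus,W_minus the split energies.
#' @param p_elem phase-field value in `[0, 1]` (1 = intact).
#' @param mat a [hydrogel_material()] (supplies K).
#' @return scalar energy density.
#' @export
degraded_energy <- function(W_plus, W_minus, p_elem, mat) {
  if (any(p_elem < 0 | p_elem > 1))
    stop_gelfrac("domain_error", "phase field p must lie in [0, 1]")
  ((1 - mat$k_res) * p_elem^2 + mat$k_res) * W_plus + W_minus
}

# derivative of the split energies with respect to each principal stretch,
# at fixed branch assignment (ties at lambda = 1 / J = 1 are C1, so the
# branch choice does not affect the value)
split_dW_dlam <- function(lam, J, mat) {
  dev_p <- ifelse(lam > 1, mat$mu * (lam - 1 / lam), 0)
  dev_m <- ifelse(lam < 1, mat$mu * (lam - 1 / lam), 0)
  vol_p <- if (J > 1) mat$chi * (J - 1) * J / lam else rep(0, length(lam))
  vol_m <- if (J < 1) mat$chi * (J - 1) * J / lam else rep(0, length(lam))
  list(plus = dev_p + vol_p, minus = dev_m + vol_m)
}

#' First Piola-Kirchhoff stress of the degraded hydrogel model
#'
#' `P = g(p) dW+/dF + dW-/dF` with `g(p) = (1-K) p^2 + K`, assembled in the
#' principal frame through the SVD of F.
#'
#' @param F 3 x 3 deformation gradient (`det F > 0`).
#' @param p_elem phase-field value in `[0, 1]`.
#' @param mat a [hydrogel_material()].
#' @return 3 x 3 PK1 stress matrix.
#' @export
pk1_hydrogel <- function(F, p_elem, mat) {
  if (p_elem < 0 || p_elem > 1)
    stop_gelfrac("domain_error", "phase field p must lie in [0, 1]")
  s <- stretch_state(F)
  d <- split_dW_dlam(s$lambdas, s$J, mat)
  g <- (1 - mat$k_res) * p_elem^2 + mat$k_res
  s$U %*% diag(g * d$plus + d$minus) %*% t(s$V)
}

#' Ogden free energy density
#'
#' @param F 3 x 3 deformation gradient (`det F > 0`).
#' @param mat an [ogden_material()].
#' @return scalar energy density (zero at F = identity).
#' @export
ogden_energy <- function(F, mat) {
  s <- stretch_state(F)
  lbar <- s$J^(-1 / 3) * s$lambdas
  2 * mat$mu_og / mat$alpha^2 * (sum(lbar^mat$alpha) - 3) +
    0.5 * mat$k_og * (s$J - 1)^2
}

#' Ogden first Piola-Kirchhoff stress
#'
#' Principal-frame derivative:
#' `dW/dlambda_i = (2 muOg / alpha) (lbar_i^alpha - mean(lbar^alpha)) / lambda_i
#'  + KOg (J - 1) J / lambda_i`.
#'
#' @inheritParams ogden_energy
#' @return 3 x 3 PK1 stress matrix.
#' @export
ogden_pk1 <- function(F, mat) {
  s <- stretch_state(F)
  lam <- s$lambdas
  lbar <- s$J^(-1 / 3) * lam
  la <- lbar^mat$alpha
  g <- 2 * mat$mu_og / mat$alpha * (la - mean(la)) / lam +
    mat$k_og * (s$J - 1) * s$J / lam
  s$U %*% diag(g) %*% t(s$V)
}

#' Effective (von Mises) Cauchy stress
#'
#' Pushes a PK1 stress forward to the Cauchy stress
#' `sigma = J^-1 P F'` and returns the von Mises equivalent
#' `sqrt(3/2 * dev(sigma) : dev(sigma))`.
#'
#' @param P 3 x 3 PK1 stress.
#' @param F 3 x 3 deformation gradient (`det F > 0`).
#' @return scalar effective stress.
#' @export
cauchy_effective <- function(P, F) {
  J <- det(F)
  if (J <= 0) stop_gelfrac("inverted_element", "det F <= 0")
  sig <- (P %*% t(F)) / J
  dev <- sig - diag(3) * sum(diag(sig)) / 3
  sqrt(1.5 * sum(dev * dev))
}
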