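# Staggered quasi-static solver ---------------------------------------------
#
# At every load step the prescribed displacements are applied, then the two
# sub-problems are alternated until joint convergence:
#   (a) mechanical equilibrium: minimize the total degraded energy over the
#       free nodal positions at fixed damage p (L-BFGS-B with the exact
#       assembled gradient);
#   (b) damage: update the element history field H = max(H, Wbar+) and
#       solve the linear vertex phase-field system at fixed positions.
# Convergence: max |delta p| < tol_p and relative energy change < tol_E.

#' Boundary-condition constraint
#'
#' A named node set, the constrained coordinate directions and the
#' prescribed displacement per unit load factor (0 = pinned at the
#' reference position).
#'
#' @param set node-set name.
#' @param dofs integer vector within 1:3 (x, y, z). Ignored when
#'   `radial = TRUE` (the in-plane dofs 1:2 are constrained).
#' @param value numeric displacement per unit load factor, length 1 or
#'   `length(dofs)`.
#' @param radial if `TRUE`, `value` is an in-plane radial displacement
#'   magnitude: each node moves along its reference `(x, y)` direction
#'   (used e.g. to expand the rim of a cap radially).
#' @return a `"bc_constraint"` list.
#' @export
bc_constraint <- function(set, dofs = 1:3, value = 0, radial = FALSE) {
  stopifnot(all(dofs %in% 1:3), length(value) %in% c(1L, length(dofs)))
  if (radial) dofs <- 1:2
  structure(list(set = set, dofs = as.integer(dofs),
                 value = rep_len(as.numeric(value), length(dofs)),
                 radial = isTRUE(radial)),
            class = "bc_constraint")
}

#' Load schedule
#'
#' @param constraints list of [bc_constraint()]s. The constraint whose
#'   `value` is nonzero drives the load; its displacement is scaled by each
#'   load factor in turn.
#' @param factors numeric load factors, visited in order. Typically a
#'   strictly increasing ramp from just above 0; non-monotone sequences are
#'   allowed for load-unload studies.
#' @param report_set node-set name over which reaction forces are summed
#'   (defaults to the first constrained set with a nonzero value).
#' @return a `"load_schedule"` list.
#' @export
load_schedule <- function(constraints, factors, report_set = NULL) {
  stopifnot(length(constraints) > 0, all(is.finite(factors)))
  if (is.null(report_set)) {
    driven <- vapply(constraints, function(cc) any(cc$value != 0), logical(1))
    report_set <- constraints[[if (any(driven)) which(driven)[1] else 1L]]$set
  }
  structure(list(constraints = constraints, factors = as.numeric(factors),
                 report_set = report_set),
            class = "load_schedule")
}

#' Solver tolerances
#'
#' @param tol_p staggered convergence threshold on `max |delta p|`.
#' @param tol_E staggered convergence threshold on the relative energy
#'   change.
#' @param max_stag_iters staggered iteration cap per step.
#' @param grad_tol projected-gradient tolerance of the displacement solve;
#'   `NULL` picks `1e-8 * mu_ref * total reference area`.
#' @param maxit L-BFGS-B iteration cap.
#' @param on_nonconverged `"continue"` or `"abort"` when a step hits
#'   `max_stag_iters`.
#' @return list of tolerances.
#' @export
solver_tols <- function(tol_p = 1e-4, tol_E = 1e-8, max_stag_iters = 50L,
                        grad_tol = NULL, maxit = 1000L,
                        on_nonconverged = c("continue", "abort")) {
  list(tol_p = tol_p, tol_E = tol_E, max_stag_iters = as.integer(max_stag_iters),
       grad_tol = grad_tol, maxit = as.integer(maxit),
       on_nonconverged = match.arg(on_nonconverged))
}

#' Initial simulation state
#'
#' @param model a [shell_model()].
#' @return a `"sim_state"`: reference positions, p = 1, H = 0, step 0.
#' @export
init_state <- function(model) {
  structure(list(positions = model$mesh$vertices,
                 p = rep(1, nrow(model$mesh$vertices)),
                 H = numeric(nrow(model$mesh$triangles)),
                 step = 0L, load_factor = 0, converged = TRUE,
                 n_stag_iters = 0L, n_clamped = 0L),
            class = "sim_state")
}

default_grad_tol <- function(model) {
  mu_ref <- max(model$mu, model$og_mu)
  1e-8 * max(mu_ref, 1e-12) * sum(model$frames$area)
}

# constrained dof bookkeeping: returns prescribed positions for a factor
# and the logical free-dof mask (n x 3)
apply_constraints <- function(model, positions, constraints, factor) {
  mesh <- model$mesh
  free <- matrix(TRUE, nrow(positions), 3)
  pos <- positions
  for (cc in constraints) {
    ix <- mesh$node_sets[[cc$set]]
    if (is.null(ix))
      stop_gelfrac("config_error", sprintf("unknown node set '%s'", cc$set))
    if (isTRUE(cc$radial)) {
      r <- sqrt(mesh$vertices[ix, 1]^2 + mesh$vertices[ix, 2]^2)
      r[r < 1e-14] <- 1
      rhat <- mesh$vertices[ix, 1:2, drop = FALSE] / r
      pos[ix, 1:2] <- mesh$vertices[ix, 1:2, drop = FALSE] +
        factor * cc$value[1] * rhat
      free[ix, 1:2] <- FALSE
    } else for (k in seq_along(cc$dofs)) {
      d <- cc$dofs[k]
      pos[ix, d] <- mesh$vertices[ix, d] + factor * cc$value[k]
      free[ix, d] <- FALSE
    }
  }
  list(positions = pos, free = free)
}

# displacement sub-solve: energy minimization over free dofs at fixed p
solve_displacement <- function(model, positions, free, p, tols) {
  gtol <- if (is.null(tols$grad_tol)) default_grad_tol(model) else tols$grad_tol
  x0 <- positions[free]
  pe <- element_phase(model, p)
  fn <- function(x) {
    pos <- positions; pos[free] <- x
    mech_state(model, pos, pe, want_grad = FALSE)$energy
  }
  gr <- function(x) {
    pos <- positions; pos[free] <- x
    mech_state(model, pos, pe, want_grad = TRUE)$grad[free]
  }
  res <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = tols$maxit, factr = 10,
                                     pgtol = gtol))
  if (!res$convergence %in% c(0L, 1L) || !is.finite(res$value))
    stop_gelfrac("step_error", sprintf(
      "displacement solve failed (%s); consider a smaller load increment",
      res$message))
  positions[free] <- res$par
  positions
}

# damage sub-solve on vertices incident to phase-field-enabled elements;
# other vertices are held at p = 1
solve_damage <- function(model, H) {
  mesh <- model$mesh
  vW <- vertex_driving_energy(mesh, H, enabled = model$is_gel)
  sys <- assemble_phase_system(model$ops, vW, model$pf)
  gel_v <- sort(unique(as.integer(mesh$triangles[model$is_gel, ])))
  nv <- nrow(mesh$vertices)
  if (length(gel_v) == nv) {
    sol <- solve_phase(sys)
    return(list(p = sol$p, n_clamped = sol$n_clamped))
  }
  other <- setdiff(seq_len(nv), gel_v)
  A <- sys$A
  b <- sys$b[gel_v] - as.numeric(A[gel_v, other, drop = FALSE] %*%
                                   rep(1, length(other)))
  sub <- list(A = A[gel_v, gel_v, drop = FALSE], b = b)
  p <- rep(1, nv)
  psol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::forceSymmetric(sub$A), sub$b)),
    error = function(e) as.numeric(Matrix::solve(sub$A, sub$b)))
  p[gel_v] <- pmin(pmax(psol, 0), 1)
  list(p = p, n_clamped = sum(psol < -1e-12 | psol > 1 + 1e-12))
}

#' One staggered load step
#'
#' Applies the prescribed displacements for load factor `factor`, then
#' alternates the displacement minimization and the damage solve until
#' `max |delta p| < tol_p` and the relative total-energy change is below
#' `tol_E`, or `max_stag_iters` is reached (the state is then flagged
#' non-converged).
#'
#' @param model a [shell_model()].
#' @param state a `"sim_state"` (from [init_state()] or a previous step).
#' @param schedule a [load_schedule()].
#' @param factor load factor for this step.
#' @param tols a [solver_tols()] list.
#' @return updated `"sim_state"`.
#' @export
staggered_step <- function(model, state, schedule, factor,
                           tols = solver_tols()) {
  ac <- apply_constraints(model, state$positions, schedule$constraints, factor)
  pos <- ac$positions
  p <- state$p
  H <- state$H
  E_prev <- total_energy(model, pos, p)
  converged <- FALSE
  n_clamped <- 0L
  for (it in seq_len(tols$max_stag_iters)) {
    pos <- solve_displacement(model, pos, ac$free, p, tols)
    pe <- element_phase(model, p)
    st <- mech_state(model, pos, pe, want_grad = FALSE)
    H <- update_history(H, st$W_plus)
    dmg <- solve_damage(model, H)
    dp <- max(abs(dmg$p - p))
    p <- dmg$p
    n_clamped <- dmg$n_clamped
    E_now <- total_energy(model, pos, p)
    dE <- abs(E_now - E_prev) / max(abs(E_now), .Machine$double.eps)
    E_prev <- E_now
    if (dp < tols$tol_p && dE < tols$tol_E) { converged <- TRUE; break }
  }
  if (!converged && tols$on_nonconverged == "abort")
    stop_gelfrac("step_error", sprintf(
      "staggered iteration did not converge in %d iterations at factor %.6g",
      tols$max_stag_iters, factor))
  structure(list(positions = pos, p = p, H = H,
                 step = state$step + 1L, load_factor = factor,
                 converged = converged, n_stag_iters = it,
                 n_clamped = n_clamped, free = ac$free),
            class = "sim_state")
}

#' Reaction force on a node set
#'
#' Sum of the assembled internal nodal forces (`dE/dx`) over the set: the
#' force transmitted through the constraint (equal and opposite to the
#' force the structure exerts on its support).
#'
#' @param model a [shell_model()].
#' @param state a `"sim_state"`.
#' @param node_set node-set name.
#' @return length-3 numeric vector.
#' @export
reaction_force <- function(model, state, node_set) {
  ix <- model$mesh$node_sets[[node_set]]
  if (is.null(ix))
    stop_gelfrac("config_error", sprintf("unknown node set '%s'", node_set))
  fi <- internal_forces(model, state$positions, state$p)
  colSums(fi$forces[ix, , drop = FALSE])
}

#' Run a full quasi-static simulation
#'
#' Steps through the load schedule, recording one row per converged step
#' (load factor, imposed displacement, reaction force on the report set,
#' energy bookkeeping, minimum p, staggered iteration count) and optionally
#' writing a VTU time series (phase field, displacement, effective Cauchy
#' stress, tensile energy density and region per element).
#'
#' The mesh resolution relative to `ell` is checked up front; a ratio
#' `h_ele/ell > 1` warns that the diffuse crack cannot be resolved.
#'
#' @param model a [shell_model()].
#' @param schedule a [load_schedule()].
#' @param tols a [solver_tols()].
#' @param out_dir output directory for `record.csv` and the VTU series
#'   (`NULL` disables file output).
#' @param write_vtu write per-step VTU files (default `TRUE` when
#'   `out_dir` is given).
#' @param verbose print per-step progress to stderr.
#' @return invisibly, a list with `record` (data.frame), `state` (final),
#'   `states` (list of per-step p fields) and `resolution`.
#' @export
run_simulation <- function(model, schedule, tols = solver_tols(),
                           out_dir = NULL, write_vtu = !is.null(out_dir),
                           verbose = FALSE) {
  resol <- mesh_resolution(model$mesh, model$pf$ell)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  state <- init_state(model)
  # displacement magnitude per unit factor of the driving constraint
  drv <- NULL
  for (cc in schedule$constraints)
    if (any(cc$value != 0)) { drv <- cc; break }
  u_unit <- if (is.null(drv)) 0 else sqrt(sum(drv$value^2))
  rows <- vector("list", length(schedule$factors))
  p_steps <- vector("list", length(schedule$factors))
  series <- if (!is.null(out_dir)) file.path(out_dir, "series") else NULL
  for (s in seq_along(schedule$factors)) {
    f <- schedule$factors[s]
    state <- staggered_step(model, state, schedule, f, tols)
    R <- reaction_force(model, state, schedule$report_set)
    pe <- element_phase(model, state$p)
    st <- mech_state(model, state$positions, pe, want_grad = FALSE,
                     want_stress = TRUE)
    rows[[s]] <- data.frame(
      step = state$step, load_factor = f, u_imposed = f * u_unit,
      Rx = R[1], Ry = R[2], Rz = R[3],
      E_total = st$energy, E_plus = st$E_plus, E_minus = st$E_minus,
      p_min = min(state$p), n_stag_iters = state$n_stag_iters,
      converged = state$converged)
    p_steps[[s]] <- state$p
    if (verbose)
      message(sprintf("step %3d  factor %.5g  |R| %.5g  p_min %.4f  iters %d",
                      s, f, sqrt(sum(R^2)), min(state$p), state$n_stag_iters))
    if (isTRUE(write_vtu) && !is.null(out_dir)) {
      write_vtu(model$mesh, file.path(out_dir, sprintf("step_%04d.vtu", s)),
                point_fields = list(
                  p = state$p,
                  displacement = state$positions - model$mesh$vertices),
                cell_fields = list(
                  effective_stress = st$sigma_vm,
                  W_plus = st$W_plus,
                  region = as.numeric(factor(model$mesh$element_region))),
                positions = state$positions, series = series, time = f)
    }
  }
  record <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(record, file.path(out_dir, "record.csv"),
                     row.names = FALSE)
  invisible(list(record = record, state = state, states = p_steps,
                 resolution = resol))
}
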