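# YAML run configuration ----------------------------------------------------
#
# Fail-loud schema: unknown keys are errors, and validation reports every
# problem at once. All quantities are nondimensional, matching the solver.

CONFIG_SCHEMA_VERSION <- 1L

config_defaults <- function() list(
  schema_version = CONFIG_SCHEMA_VERSION,
  seed = 1L,
  mesh = NULL,
  materials = NULL,
  # ell and gc are required (no default): a run must state its length scale
  # and fracture energy explicitly
  phase_field = list(ell = NULL, gc = NULL, k_res = 1e-4, clamp = TRUE,
                     clamp_weights = FALSE),
  bending = list(enabled = FALSE, stiffness = 0),
  thickness_rule = list(n_gauss = 3L),
  solver = list(tol_p = 1e-4, tol_E = 1e-8, max_stag_iters = 50L,
                grad_tol = NULL, maxit = 1000L, on_nonconverged = "continue"),
  schedule = NULL,
  output = list(dir = NULL, write_vtu = TRUE)
)

known_generators <- c("notched_plate", "perforated_sphere", "fiber_strip",
                      "cap_with_patch", "icosphere")

#' Validate a run configuration
#'
#' Checks the YAML-derived configuration list against the schema: required
#' blocks present, no unknown keys, physical parameters positive where
#' required, referenced generators known. All violations are collected and
#' reported together.
#'
#' @param cfg configuration list (e.g. from [read_config()]).
#' @return the configuration with defaults filled in; stops with a
#'   `gelfrac_config_error` listing every violation otherwise.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  def <- config_defaults()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    add(sprintf("unknown top-level key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(cfg$schema_version))
    add("missing schema_version")
  else if (cfg$schema_version != CONFIG_SCHEMA_VERSION)
    add(sprintf("unsupported schema_version %s", cfg$schema_version))
  # merge defaults (shallow for blocks)
  for (k in names(def)) {
    if (is.null(cfg[[k]])) cfg[k] <- def[k]
    else if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      unk <- setdiff(names(cfg[[k]]), names(def[[k]]))
      if (length(unk) && k %in% c("phase_field", "bending", "thickness_rule",
                                  "solver", "output"))
        add(sprintf("unknown key(s) in %s: %s", k, paste(unk, collapse = ", ")))
      for (kk in names(def[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][kk] <- def[[k]][kk]
    }
  }
  # mesh
  m <- cfg$mesh
  if (is.null(m)) add("missing mesh block")
  else {
    unk <- setdiff(names(m), c("generator", "params", "file", "format"))
    if (length(unk)) add(sprintf("unknown key(s) in mesh: %s",
                                 paste(unk, collapse = ", ")))
    if (is.null(m$generator) && is.null(m$file))
      add("mesh block needs either 'generator' or 'file'")
    if (!is.null(m$generator) && !m$generator %in% known_generators)
      add(sprintf("unknown mesh generator '%s' (known: %s)", m$generator,
                  paste(known_generators, collapse = ", ")))
  }
  # materials
  if (is.null(cfg$materials) || !length(cfg$materials))
    add("missing materials block")
  else for (r in names(cfg$materials)) {
    mb <- cfg$materials[[r]]
    if (is.null(mb$type) || !mb$type %in% c("hydrogel", "ogden")) {
      add(sprintf("material '%s': type must be 'hydrogel' or 'ogden'", r))
    } else if (mb$type == "hydrogel") {
      unk <- setdiff(names(mb), c("type", "mu", "chi", "k_res"))
      if (length(unk)) add(sprintf("material '%s': unknown key(s) %s", r,
                                   paste(unk, collapse = ", ")))
      if (!is.null(mb$mu) && mb$mu <= 0) add(sprintf("material '%s': mu must be > 0", r))
      if (!is.null(mb$chi) && mb$chi < 0) add(sprintf("material '%s': chi must be >= 0", r))
    } else {
      unk <- setdiff(names(mb), c("type", "mu_og", "k_og", "alpha"))
      if (length(unk)) add(sprintf("material '%s': unknown key(s) %s", r,
                                   paste(unk, collapse = ", ")))
      if (!is.null(mb$alpha) && mb$alpha == 0)
        add(sprintf("material '%s': alpha must be nonzero", r))
    }
  }
  # phase field
  pf <- cfg$phase_field
  for (key in c("ell", "gc")) {
    val <- pf[[key]]
    if (is.null(val)) add(sprintf("phase_field: missing '%s'", key))
    else if (!is.numeric(val) || val <= 0)
      add(sprintf("phase_field: '%s' must be a positive number", key))
  }
  if (!is.null(pf$k_res) && (pf$k_res <= 0 || pf$k_res >= 1))
    add("phase_field: k_res must lie in (0, 1)")
  # schedule
  sc <- cfg$schedule
  if (is.null(sc)) add("missing schedule block")
  else {
    unk <- setdiff(names(sc), c("constraints", "factors", "report_set"))
    if (length(unk)) add(sprintf("unknown key(s) in schedule: %s",
                                 paste(unk, collapse = ", ")))
    if (is.null(sc$constraints) || !length(sc$constraints))
      add("schedule: needs at least one constraint")
    else for (ci in seq_along(sc$constraints)) {
      cc <- sc$constraints[[ci]]
      unk <- setdiff(names(cc), c("set", "dofs", "value", "radial"))
      if (length(unk)) add(sprintf("schedule constraint %d: unknown key(s) %s",
                                   ci, paste(unk, collapse = ", ")))
      if (is.null(cc$set)) add(sprintf("schedule constraint %d: missing 'set'", ci))
      if (!is.null(cc$dofs) && !all(unlist(cc$dofs) %in% 1:3))
        add(sprintf("schedule constraint %d: dofs must be within 1:3", ci))
    }
    if (is.null(sc$factors) || !length(unlist(sc$factors)))
      add("schedule: missing 'factors'")
    else if (!all(is.finite(unlist(sc$factors))))
      add("schedule: factors must be finite numbers")
  }
  if (length(errs))
    stop_gelfrac("config_error", paste0(
      "invalid configuration:\n  - ", paste(errs, collapse = "\n  - ")))
  cfg
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file path.
#' @return validated configuration list with defaults resolved.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_gelfrac("config_error", sprintf("config file not found: %s", path))
  validate_config(yaml::read_yaml(path))
}

#' Write a configuration to YAML
#'
#' The effective (defaults-resolved) configuration is written into the
#' output directory by [run_config()], so a run can be reproduced exactly
#' from its own artifacts.
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_config <- function(cfg, path) {
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# instantiate the mesh declared in a config
mesh_from_config <- function(cfg) {
  m <- cfg$mesh
  if (!is.null(m$file))
    return(read_mesh(m$file, fmt = if (is.null(m$format)) "auto" else m$format))
  pr <- if (is.null(m$params)) list() else m$params
  switch(m$generator,
         notched_plate = do.call(gen_notched_plate, pr),
         perforated_sphere = do.call(gen_perforated_sphere_patch, pr),
         fiber_strip = do.call(gen_fiber_strip, pr),
         cap_with_patch = do.call(gen_cap_with_patch, pr),
         icosphere = do.call(gen_icosphere, pr))
}

materials_from_config <- function(cfg) {
  out <- list()
  for (r in names(cfg$materials)) {
    mb <- cfg$materials[[r]]
    out[[r]] <- if (mb$type == "hydrogel")
      hydrogel_material(mu = mb$mu %||% 1, chi = mb$chi %||% 2.17,
                        k_res = mb$k_res %||% cfg$phase_field$k_res %||% 1e-4)
    else
      ogden_material(mu_og = mb$mu_og %||% 0.1, k_og = mb$k_og %||% 1,
                     alpha = mb$alpha %||% -20)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build model and schedule from a validated configuration
#'
#' @param cfg validated configuration list.
#' @return list with `model`, `schedule`, `tols`, `out_dir`, `cfg`.
#' @export
build_from_config <- function(cfg) {
  cfg <- validate_config(cfg)
  set.seed(cfg$seed %||% 1L)
  mesh <- mesh_from_config(cfg)
  mats <- materials_from_config(cfg)
  pf <- phase_params(ell = cfg$phase_field$ell, gc = cfg$phase_field$gc,
                     k_res = cfg$phase_field$k_res %||% 1e-4)
  model <- shell_model(mesh, mats, pf = pf,
                       bending = cfg$bending,
                       n_gauss = cfg$thickness_rule$n_gauss,
                       clamp_weights = isTRUE(cfg$phase_field$clamp_weights))
  cons <- lapply(cfg$schedule$constraints, function(cc)
    bc_constraint(cc$set, dofs = unlist(cc$dofs) %||% 1:3,
                  value = unlist(cc$value) %||% 0,
                  radial = isTRUE(cc$radial)))
  schedule <- load_schedule(cons, unlist(cfg$schedule$factors),
                            report_set = cfg$schedule$report_set)
  s <- cfg$solver
  tols <- solver_tols(tol_p = s$tol_p, tol_E = s$tol_E,
                      max_stag_iters = s$max_stag_iters,
                      grad_tol = s$grad_tol, maxit = s$maxit,
                      on_nonconverged = s$on_nonconverged)
  list(model = model, schedule = schedule, tols = tols,
       out_dir = cfg$output$dir, cfg = cfg)
}

#' Run a simulation from a configuration
#'
#' Validates the configuration, instantiates mesh/model/schedule, writes
#' the effective configuration into the output directory and executes
#' [run_simulation()].
#'
#' @param cfg configuration list or YAML path.
#' @param out_dir optional output directory override.
#' @param verbose passed to [run_simulation()].
#' @return the [run_simulation()] result, invisibly.
#' @export
run_config <- function(cfg, out_dir = NULL, verbose = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  built <- build_from_config(cfg)
  od <- out_dir %||% built$out_dir
  if (!is.null(od)) {
    if (!dir.exists(od)) dir.create(od, recursive = TRUE)
    built$cfg$output$dir <- od
    write_config(built$cfg, file.path(od, "config.yaml"))
  }
  run_simulation(built$model, built$schedule, built$tols, out_dir = od,
                 write_vtu = isTRUE(built$cfg$output$write_vtu) && !is.null(od),
                 verbose = verbose)
}

# Bundled desk-scale demo scenarios ------------------------------------------

#' Bundled demo configurations
#'
#' Desk-scale versions of the benchmark scenarios: `"sent"` (single-edge
#' notched plate in tension), `"sphere-compression"` (perforated sphere
#' octant pressed at the pole), `"sphere-shear"` (quadrant sheared at the
#' pole), `"fiber-strip"` (fibered scaffold pushed out of plane at its
#' center) and `"cap-patch"` (hydrogel patch on an Ogden cap expanded
#' radially at the rim). Hydrogel parameters follow the nondimensional
#' reference set mu = 1, chi/mu = 2.17, K = 1e-4; soft-tissue substrate
#' muOg/mu = 0.1, KOg/mu = 1, alpha = -20.
#'
#' @param name demo name.
#' @param gc override of the fracture energy Gc.
#' @param out_dir output directory stored in the config.
#' @param n_steps override of the number of load steps.
#' @param target_h override of the mesh size.
#' @return configuration list (validated).
#' @export
demo_config <- function(name = c("sent", "sphere-compression", "sphere-shear",
                                 "fiber-strip", "cap-patch"),
                        gc = NULL, out_dir = NULL, n_steps = NULL,
                        target_h = NULL) {
  name <- match.arg(name)
  hydrogel <- list(type = "hydrogel", mu = 1, chi = 2.17, k_res = 1e-4)
  cfg <- switch(
    name,
    "sent" = list(
      mesh = list(generator = "notched_plate",
                  params = list(length = 2, width = 1, notch_length = 0.5,
                                target_h = target_h %||% 0.04,
                                thickness = 0.1)),
      materials = list(hydrogel = hydrogel),
      phase_field = list(ell = 0.08, gc = gc %||% 2e-4, k_res = 1e-4),
      schedule = list(
        constraints = list(
          list(set = "bottom", dofs = 1:3, value = 0),
          list(set = "top", dofs = c(1L, 3L), value = 0),
          list(set = "top", dofs = 2L, value = 1)),
        factors = as.list(seq_len(n_steps %||% 18L) / (n_steps %||% 18L) * 0.036),
        report_set = "top"),
      solver = list(grad_tol = 2e-7)),
    "sphere-compression" = list(
      mesh = list(generator = "perforated_sphere",
                  params = list(R = 1, r_hole = 0.05, n_holes = 3L,
                                symmetry = "octant",
                                target_h = target_h %||% 0.035,
                                thickness = 0.02)),
      materials = list(hydrogel = hydrogel),
      phase_field = list(ell = 0.06, gc = gc %||% 3e-4, k_res = 1e-4),
      bending = list(enabled = TRUE, stiffness = 1e-5),
      schedule = list(
        constraints = list(
          list(set = "equator", dofs = 3L, value = 0),
          list(set = "sym_x0", dofs = 1L, value = 0),
          list(set = "sym_y0", dofs = 2L, value = 0),
          list(set = "pole_cap", dofs = 3L, value = -1)),
        factors = as.list(seq_len(n_steps %||% 12L) / (n_steps %||% 12L) * 0.12),
        report_set = "pole_cap"),
      solver = list(grad_tol = 2e-7)),
    "sphere-shear" = list(
      mesh = list(generator = "perforated_sphere",
                  params = list(R = 1, r_hole = 0.05, n_holes = 3L,
                                symmetry = "quadrant",
                                target_h = target_h %||% 0.045,
                                thickness = 0.02)),
      materials = list(hydrogel = hydrogel),
      phase_field = list(ell = 0.06, gc = gc %||% 3e-4, k_res = 1e-4),
      bending = list(enabled = TRUE, stiffness = 1e-5),
      schedule = list(
        constraints = list(
          list(set = "equator", dofs = 1:3, value = 0),
          list(set = "sym_y0", dofs = 2L, value = 0),
          list(set = "pole_cap", dofs = 1L, value = 1)),
        factors = as.list(seq_len(n_steps %||% 10L) / (n_steps %||% 10L) * 0.08),
        report_set = "pole_cap"),
      solver = list(grad_tol = 2e-7)),
    "fiber-strip" = list(
      mesh = list(generator = "fiber_strip",
                  params = list(length = 4, width = 1, thickness = 0.1,
                                n_fibers = 4L, n_crosslinks = 3L,
                                target_h = target_h %||% 0.04)),
      materials = list(hydrogel = hydrogel),
      phase_field = list(ell = 0.06, gc = gc %||% 3e-4, k_res = 1e-4),
      schedule = list(
        constraints = list(
          list(set = "left", dofs = 1:3, value = 0),
          list(set = "right", dofs = 1:3, value = 0),
          list(set = "center", dofs = 3L, value = 1)),
        factors = as.list(seq_len(n_steps %||% 16L) / (n_steps %||% 16L) * 0.45),
        report_set = "center"),
      solver = list(grad_tol = 2e-7)),
    "cap-patch" = list(
      mesh = list(generator = "cap_with_patch",
                  params = list(R_major = 1, R_minor = 0.8, patch_angle = 0.5,
                                target_h = target_h %||% 0.1,
                                thickness = 0.02)),
      materials = list(
        hydrogel = hydrogel,
        substrate = list(type = "ogden", mu_og = 0.1, k_og = 1, alpha = -20)),
      phase_field = list(ell = 0.12, gc = gc %||% 3e-4, k_res = 1e-4),
      schedule = list(
        constraints = list(
          list(set = "rim", dofs = 3L, value = 0),
          list(set = "rim", value = 1, radial = TRUE),
          list(set = "patch_center", dofs = 1:3, value = 0)),
        factors = as.list(seq_len(n_steps %||% 8L) / (n_steps %||% 8L) * 0.24),
        report_set = "rim"),
      solver = list(grad_tol = 2e-7))
  )
  cfg$schema_version <- CONFIG_SCHEMA_VERSION
  cfg$seed <- 1L
  cfg$output <- list(dir = out_dir, write_vtu = !is.null(out_dir))
  validate_config(cfg)
}
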