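# staggered driver, reaction forces, records

small_sent_model <- function(h = 0.12, ell = 0.1, gc = 2e-4) {
  m <- gen_notched_plate(2, 1, 0.5, h)
  shell_model(m, list(hydrogel = ref_hydrogel()),
              pf = phase_params(ell = ell, gc = gc, k_res = 1e-4))
}

tension_schedule <- function(factors, value = 1) {
  load_schedule(list(bc_constraint("bottom", 1:3, 0),
                     bc_constraint("top", c(1, 3), 0),
                     bc_constraint("top", 2, value)),
                factors = factors, report_set = "top")
}

test_that("zero imposed displacement converges in one staggered iteration", {
  model <- small_sent_model()
  sch <- tension_schedule(0, value = 0)
  st <- staggered_step(model, init_state(model), sch, 0)
  expect_true(st$converged)
  expect_equal(st$n_stag_iters, 1L)
  expect_equal(st$p, rep(1, nrow(model$mesh$vertices)))
  expect_lt(max(abs(internal_forces(model, st$positions, st$p)$forces)), 1e-12)
})

test_that("small stretch below damage onset keeps p near 1", {
  model <- small_sent_model()
  sch <- tension_schedule(5e-4)
  st <- staggered_step(model, init_state(model), sch, 5e-4,
                       solver_tols(grad_tol = 1e-8))
  expect_true(st$converged)
  expect_lte(st$n_stag_iters, 3L)
  expect_gt(min(st$p), 0.99)
})

test_that("reaction forces balance on a free-floating stretched strip", {
  # thin membrane: keeps the L-BFGS rounding plateau of the gradient well
  # below the absolute force tolerance checked here
  m <- gen_notched_plate(2, 1, 0.5, 0.15, thickness = 0.01)
  model <- shell_model(m, list(hydrogel = ref_hydrogel()),
                       pf = phase_params(0.1, 1e-2, 1e-4))
  sch <- load_schedule(list(bc_constraint("left", 1:3, c(-0.005, 0, 0)),
                            bc_constraint("right", 1:3, c(0.005, 0, 0))),
                       factors = 1, report_set = "right")
  st <- staggered_step(model, init_state(model), sch, 1,
                       solver_tols(grad_tol = 1e-11, maxit = 5000L))
  RL <- reaction_force(model, st, "left")
  RR <- reaction_force(model, st, "right")
  expect_lt(max(abs(RL + RR)), 1e-8)
  expect_gt(RR[1], 0)
  expect_error(reaction_force(model, st, "nope"),
               class = "gelfrac_config_error")
  # undeformed state has zero reaction
  expect_equal(reaction_force(model, init_state(model), "left"), rep(0, 3))
})

test_that("reaction grows monotonically before damage", {
  model <- small_sent_model(gc = 1e2)   # effectively undamageable
  sch <- tension_schedule(seq(0.002, 0.01, by = 0.002))
  res <- suppressWarnings(run_simulation(model, sch, solver_tols(grad_tol = 1e-8)))
  expect_true(all(diff(res$record$Ry) > 0))
  expect_true(all(res$record$p_min > 0.999))
})

test_that("staggered p satisfies the assembled system at convergence", {
  model <- small_sent_model()
  sch <- tension_schedule(0.008)
  st <- staggered_step(model, init_state(model), sch, 0.008,
                       solver_tols(tol_p = 1e-6, grad_tol = 1e-9))
  vW <- vertex_driving_energy(model$mesh, st$H, enabled = model$is_gel)
  sys <- assemble_phase_system(model$ops, vW, model$pf)
  r <- as.numeric(sys$A %*% st$p) - sys$b
  expect_lt(sqrt(sum(r^2)) / sqrt(sum(sys$b^2)), 1e-10)
})

test_that("energy bookkeeping is consistent at every recorded step", {
  model <- small_sent_model()
  sch <- tension_schedule(seq(0.004, 0.012, by = 0.004))
  res <- suppressWarnings(run_simulation(model, sch, solver_tols(grad_tol = 2e-8)))
  expect_equal(res$record$E_total, res$record$E_plus + res$record$E_minus,
               tolerance = 1e-10)
  expect_true(all(res$record$converged))
  expect_true(all(diff(res$record$step) == 1L))
})

test_that("load-unload leaves element damage non-increasing in time", {
  model <- small_sent_model(h = 0.1, ell = 0.08)
  sch <- tension_schedule(c(seq(0.003, 0.015, by = 0.003), 0.009, 0.003))
  res <- suppressWarnings(run_simulation(model, sch, solver_tols(grad_tol = 2e-7)))
  pe <- vapply(res$states, function(p) gelfrac:::element_phase(model, p),
               numeric(nrow(model$mesh$triangles)))
  expect_lte(max(diff(t(pe))), 1e-12)
  # some damage actually accumulated, so the check is not vacuous
  expect_lt(min(pe), 0.95)
})

test_that("runs are deterministic: identical configs give identical records", {
  cfg <- demo_config("sent", n_steps = 2L, target_h = 0.15)
  r1 <- suppressWarnings(run_config(cfg, out_dir = NULL))
  r2 <- suppressWarnings(run_config(cfg, out_dir = NULL))
  expect_identical(r1$record, r2$record)
  expect_identical(r1$state$p, r2$state$p)
})

test_that("run_simulation writes CSV and a VTU series", {
  skip_if_not_installed("xml2")
  dir <- withr::local_tempdir()
  model <- small_sent_model(h = 0.15)
  sch <- tension_schedule(c(0.004, 0.008))
  res <- suppressWarnings(run_simulation(model, sch, solver_tols(grad_tol = 1e-7),
                                         out_dir = dir))
  expect_true(file.exists(file.path(dir, "record.csv")))
  rec <- utils::read.csv(file.path(dir, "record.csv"))
  expect_equal(nrow(rec), 2L)
  expect_true(all(c("step", "load_factor", "u_imposed", "Rx", "Ry", "Rz",
                    "E_total", "E_plus", "E_minus", "p_min",
                    "n_stag_iters") %in% names(rec)))
  expect_true(file.exists(file.path(dir, "step_0001.vtu")))
  expect_true(file.exists(file.path(dir, "step_0002.vtu")))
  pvd <- xml2::read_xml(file.path(dir, "series.pvd"))
  expect_length(xml2::xml_find_all(pvd, "//DataSet"), 2L)
})
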