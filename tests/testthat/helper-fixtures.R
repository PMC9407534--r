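# shared fixtures: tiny meshes built in code, reference material parameters,
# and a cache so expensive demo runs are computed once per test session

ref_hydrogel <- function() hydrogel_material(mu = 1, chi = 2.17, k_res = 1e-4)
ref_ogden <- function() ogden_material(mu_og = 0.1, k_og = 1, alpha = -20)

single_triangle <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

unit_square_mesh <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
          rbind(c(1, 2, 3), c(1, 3, 4)))
}

equilateral_pair <- function() {
  h <- sqrt(3) / 2
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, h, 0), c(0.5, -h, 0)),
          rbind(c(1, 2, 3), c(1, 4, 2)))
}

# structured flat rectangle without a notch (valid trimesh)
flat_strip <- function(lx = 2, ly = 1, h = 0.2) {
  g <- gelfrac:::struct_rect(seq(0, lx, by = h), seq(0, ly, by = h))
  trimesh(g$vertices, g$triangles)
}

# random deformation gradient with safely positive determinant
random_F <- function(scale = 0.2) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, 0, scale), 3, 3)
    if (det(F) > 0.1) return(F)
  }
}

# numeric central difference of a scalar function of a matrix entry
fd_matrix_grad <- function(fun, F, h = 1e-6) {
  G <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    G[i, j] <- (fun(Fp) - fun(Fm)) / (2 * h)
  }
  G
}

# session cache for expensive simulation runs (acceptance criteria share
# the baseline SENT run between tests)
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

sent_demo_run <- function(gc = 2e-4) {
  key <- sprintf("sent_%g", gc)
  cached_run(key, {
    cfg <- demo_config("sent", gc = gc)
    suppressWarnings(run_config(cfg, out_dir = NULL))
  })
}

# displacement at which the phase field first drops below `thresh`
first_drop_u <- function(res, thresh = 0.1) {
  for (s in seq_along(res$states))
    if (min(res$states[[s]]) < thresh) return(res$record$u_imposed[s])
  NA_real_
}
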