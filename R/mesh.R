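#' @keywords internal
"_PACKAGE"

# Triangle surface mesh ------------------------------------------------------

#' Construct a triangle surface mesh
#'
#' `trimesh()` builds the reference-configuration data structure used by all
#' solvers in gelfrac: vertex coordinates, triangle connectivity, named node
#' sets (used for boundary conditions and reaction-force reporting), a
#' per-element material region label and a per-element shell thickness.
#' Construction validates the mesh: index ranges, non-degenerate triangles,
#' manifold-with-boundary topology (every edge shared by at most two
#' triangles) and consistent winding orientation across shared edges.
#'
#' @param vertices numeric matrix, one row per vertex, 3 columns (x, y, z).
#'   Meshes are always embedded in 3D; planar generators place them in z = 0.
#' @param triangles integer matrix, one row per triangle, 3 columns of
#'   1-based vertex indices.
#' @param node_sets named list of integer vectors (vertex indices). May be
#'   empty.
#' @param element_region character vector, one region label per triangle.
#'   Defaults to `"hydrogel"`.
#' @param thickness numeric vector of per-element shell thickness (> 0),
#'   recycled from a scalar. Defaults to 1.
#' @return an object of class `"trimesh"`.
#' @export
trimesh <- function(vertices, triangles, node_sets = list(),
                    element_region = NULL, thickness = 1) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) == 2L) vertices <- cbind(vertices, 0)
  if (ncol(vertices) != 3L)
    stop("gelfrac: vertices must be an n x 3 matrix", call. = FALSE)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L)
    stop("gelfrac: triangles must be an m x 3 matrix", call. = FALSE)
  nv <- nrow(vertices); nt <- nrow(triangles)
  if (is.null(element_region)) element_region <- rep("hydrogel", nt)
  element_region <- as.character(rep_len(element_region, nt))
  thickness <- as.numeric(rep_len(thickness, nt))
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         node_sets = node_sets,
                         element_region = element_region,
                         thickness = thickness),
                    class = "trimesh")
  validate_trimesh(mesh)
  mesh
}

#' Validate trimesh invariants
#'
#' Checks every structural invariant of a [trimesh()]: index ranges, three
#' distinct vertices per triangle, triangle areas above `1e-12`, at most two
#' triangles per edge, consistent orientation, positive thickness, and that
#' all node sets reference existing vertices. Called by the constructor;
#' exposed so generators and readers can re-assert validity.
#'
#' @param mesh a `"trimesh"` object (or plain list with the same fields).
#' @return `invisible(TRUE)`; stops with a classed error otherwise.
#' @export
validate_trimesh <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  nv <- nrow(v); nt <- nrow(tr)
  if (!all(is.finite(v))) stop_gelfrac("geometry_error", "non-finite vertex coordinates")
  if (nt < 1L) stop_gelfrac("topology_error", "mesh has no triangles")
  if (min(tr) < 1L || max(tr) > nv)
    stop_gelfrac("topology_error", sprintf(
      "face references vertex index outside 1..%d", nv))
  dup <- tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]
  if (any(dup))
    stop_gelfrac("topology_error", sprintf(
      "triangle %d has repeated vertices", which(dup)[1]))
  ar <- triangle_areas(mesh)
  if (any(ar <= 1e-12))
    stop_gelfrac("geometry_error", sprintf(
      "degenerate triangle %d (area %.3e <= 1e-12)",
      which(ar <= 1e-12)[1], min(ar)))
  ed <- mesh_edges(mesh)
  if (any(ed$n_incident > 2L)) {
    bad <- which(ed$n_incident > 2L)[1]
    stop_gelfrac("topology_error", sprintf(
      "non-manifold edge (%d,%d) shared by %d triangles",
      ed$i[bad], ed$j[bad], ed$n_incident[bad]))
  }
  # winding consistency: an interior edge must be traversed once in each
  # direction by its two incident triangles
  if (any(ed$n_incident == 2L & ed$same_dir))
    stop_gelfrac("topology_error", "inconsistent winding orientation across a shared edge")
  if (any(mesh$thickness <= 0))
    stop_gelfrac("geometry_error", "element thickness must be > 0")
  if (length(mesh$node_sets)) {
    for (nm in names(mesh$node_sets)) {
      ix <- mesh$node_sets[[nm]]
      if (length(ix) && (min(ix) < 1L || max(ix) > nv))
        stop_gelfrac("topology_error", sprintf(
          "node set '%s' references vertices outside the mesh", nm))
    }
  }
  invisible(TRUE)
}

stop_gelfrac <- function(class, msg) {
  stop(structure(class = c(paste0("gelfrac_", class), "error", "condition"),
                 list(message = paste0("gelfrac: ", msg), call = NULL)))
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s (%d)", names(table(x$element_region)),
                            as.integer(table(x$element_region))),
                    collapse = ", ")))
  if (length(x$node_sets))
    cat(sprintf("  node sets: %s\n",
                paste(sprintf("%s (%d)", names(x$node_sets),
                              lengths(x$node_sets)), collapse = ", ")))
  invisible(x)
}

#' Triangle areas of the reference configuration
#'
#' @param mesh a [trimesh()].
#' @param positions optional alternative n x 3 coordinate matrix (defaults to
#'   the reference vertices).
#' @return numeric vector of per-triangle areas.
#' @export
triangle_areas <- function(mesh, positions = NULL) {
  v <- if (is.null(positions)) mesh$vertices else positions
  tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Edge table with incidence counts and winding bookkeeping.
# Returns a data.frame with columns i, j (i < j), n_incident, same_dir
# (TRUE when two incident triangles traverse the edge in the same direction,
# i.e. inconsistent winding), tri1, tri2 (incident triangle ids, NA if none).
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  nt <- nrow(tr)
  a <- c(tr[, 1], tr[, 2], tr[, 3])
  b <- c(tr[, 2], tr[, 3], tr[, 1])
  tri <- rep.int(seq_len(nt), 3L)
  i <- pmin(a, b); j <- pmax(a, b)
  dirfwd <- a < b                       # traversal direction relative to (i,j)
  key <- paste(i, j)
  o <- order(i, j)
  i <- i[o]; j <- j[o]; tri <- tri[o]; dirfwd <- dirfwd[o]
  grp <- cumsum(!duplicated(cbind(i, j)))
  n_incident <- tabulate(grp)
  first <- which(!duplicated(grp))
  res <- data.frame(i = i[first], j = j[first], n_incident = n_incident)
  res$tri1 <- tri[first]
  second <- first + 1L
  has2 <- res$n_incident >= 2L
  res$tri2 <- NA_integer_
  res$tri2[has2] <- tri[second[has2]]
  res$same_dir <- FALSE
  res$same_dir[has2] <- dirfwd[first[has2]] == dirfwd[second[has2]]
  res
}

#' Boundary vertex indices of a mesh
#'
#' Vertices lying on at least one boundary edge (edge with a single incident
#' triangle).
#' @param mesh a [trimesh()].
#' @return integer vector of vertex indices.
#' @export
boundary_vertices <- function(mesh) {
  ed <- mesh_edges(mesh)
  bd <- ed$n_incident == 1L
  sort(unique(c(ed$i[bd], ed$j[bd])))
}

# Number of closed boundary loops (each boundary vertex has exactly two
# boundary edges on a manifold-with-boundary mesh; loops = connected
# components of the boundary edge graph).
boundary_loop_count <- function(mesh) {
  ed <- mesh_edges(mesh)
  bd <- which(ed$n_incident == 1L)
  if (!length(bd)) return(0L)
  verts <- sort(unique(c(ed$i[bd], ed$j[bd])))
  idx <- match(c(ed$i[bd], ed$j[bd]), verts)
  n <- length(verts)
  # union-find over boundary edges
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  m <- length(bd)
  for (k in seq_len(m)) {
    ra <- find(idx[k]); rb <- find(idx[m + k])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Connected components of the face-adjacency graph (faces adjacent when they
# share an edge). Used by generators to assert connectivity and by tests to
# check that a slit topologically separates the two crack flanks locally.
face_components <- function(mesh) {
  ed <- mesh_edges(mesh)
  int <- ed$n_incident == 2L
  nt <- nrow(mesh$triangles)
  parent <- seq_len(nt)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in which(int)) {
    ra <- find(ed$tri1[k]); rb <- find(ed$tri2[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(nt), find, integer(1))
  match(roots, unique(roots))
}

# Connected components of the vertex graph (vertices joined by mesh edges).
vertex_components <- function(mesh) {
  ed <- mesh_edges(mesh)
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(ed))) {
    ra <- find(ed$i[k]); rb <- find(ed$j[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  match(roots, unique(roots))
}

# Mesh readers ---------------------------------------------------------------

#' Read a triangle mesh from OFF or OBJ
#'
#' Supports ASCII OFF and Wavefront OBJ with triangular faces only; any quad
#' or larger polygon is rejected. The returned mesh carries the default
#' region label (`"hydrogel"`), unit thickness and no node sets; generators
#' should be preferred when node sets are needed.
#'
#' @param path file path.
#' @param fmt `"off"`, `"obj"` or `"auto"` (by file extension).
#' @return a [trimesh()].
#' @export
read_mesh <- function(path, fmt = c("auto", "off", "obj")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path))
    stop_gelfrac("format_error", sprintf("mesh file not found: %s", path))
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- switch(ext, off = "off", obj = "obj",
                  stop_gelfrac("format_error", sprintf(
                    "cannot infer mesh format from extension '%s'", ext)))
  }
  if (fmt == "off") read_off(path) else read_obj(path)
}

read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  if (!length(ln) || toupper(ln[1]) != "OFF")
    stop_gelfrac("format_error", "not an OFF file (missing OFF header)")
  toks <- strsplit(paste(ln[-1], collapse = " "), "[[:space:]]+")[[1]]
  num <- suppressWarnings(as.numeric(toks))
  if (anyNA(num)) stop_gelfrac("format_error", "non-numeric token in OFF file")
  if (length(num) < 3) stop_gelfrac("format_error", "truncated OFF header")
  nv <- as.integer(num[1]); nf <- as.integer(num[2])
  pos <- 4L
  need <- 3L * nv
  if (length(num) < pos - 1L + need)
    stop_gelfrac("format_error", "truncated OFF vertex block")
  verts <- matrix(num[pos:(pos - 1L + need)], ncol = 3, byrow = TRUE)
  pos <- pos + need
  faces <- matrix(0L, nf, 3)
  for (f in seq_len(nf)) {
    if (length(num) < pos) stop_gelfrac("format_error", "truncated OFF face block")
    k <- as.integer(num[pos])
    if (k != 3L)
      stop_gelfrac("format_error", sprintf(
        "face %d has %d vertices; only triangles are supported", f, k))
    faces[f, ] <- as.integer(num[(pos + 1L):(pos + 3L)]) + 1L  # OFF is 0-based
    pos <- pos + 1L + k
  }
  trimesh(verts, faces)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  vlines <- grep("^v[[:space:]]", ln, value = TRUE)
  flines <- grep("^f[[:space:]]", ln, value = TRUE)
  if (!length(vlines) || !length(flines))
    stop_gelfrac("format_error", "OBJ file has no vertices or no faces")
  verts <- t(vapply(strsplit(vlines, "[[:space:]]+"), function(tk) {
    xyz <- suppressWarnings(as.numeric(tk[2:4]))
    if (anyNA(xyz)) stop_gelfrac("format_error", "bad OBJ vertex line")
    xyz
  }, numeric(3)))
  faces <- t(vapply(strsplit(flines, "[[:space:]]+"), function(tk) {
    ids <- tk[-1]
    if (length(ids) != 3L)
      stop_gelfrac("format_error", sprintf(
        "OBJ face with %d vertices; only triangles are supported", length(ids)))
    ix <- suppressWarnings(as.integer(sub("/.*$", "", ids)))
    if (anyNA(ix)) stop_gelfrac("format_error", "bad OBJ face line")
    ix
  }, integer(3)))
  trimesh(verts, faces)
}

#' Write a triangle mesh to ASCII OFF
#'
#' @param mesh a [trimesh()].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                     mesh$triangles[, 3] - 1L), con)
  invisible(path)
}
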