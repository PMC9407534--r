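# VTU (VTK XML unstructured grid) output ------------------------------------
#
# Plain ASCII XML, triangle cells (VTK type 5). A companion .pvd collection
# file indexes the time series; write_vtu() maintains it incrementally so a
# partially completed run still has a readable index.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_num <- function(x) sprintf("%.9g", x)

data_array <- function(name, values, ncomp = 1L) {
  c(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
            xml_escape(name), ncomp),
    paste0("          ",
           vapply(split(fmt_num(t(values)),
                        rep(seq_len(NROW(values)), each = ncomp)),
                  paste, collapse = " ", FUN.VALUE = character(1))),
    "        </DataArray>")
}

#' Write a triangle mesh with fields to a VTU file
#'
#' Writes an XML unstructured-grid file with the mesh triangles, optional
#' per-vertex (`point_fields`) and per-element (`cell_fields`) arrays, using
#' the supplied `positions` (deformed coordinates) or the reference
#' configuration. Field names are preserved verbatim. When `series` is
#' given, a ParaView collection file (`<series>.pvd`) indexing all steps
#' written so far is (re)written alongside.
#'
#' @param mesh a [trimesh()].
#' @param path output `.vtu` file path.
#' @param point_fields named list of per-vertex arrays (vectors of length
#'   n_vertices or matrices with n_vertices rows).
#' @param cell_fields named list of per-element arrays.
#' @param positions optional n x 3 matrix of current coordinates.
#' @param series optional series base path (without extension); the file is
#'   registered in `<series>.pvd` at time `time`.
#' @param time time/load value recorded in the series index.
#' @return `invisible(path)`.
#' @export
write_vtu <- function(mesh, path, point_fields = list(), cell_fields = list(),
                      positions = NULL, series = NULL, time = 0) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  pos <- if (is.null(positions)) mesh$vertices else positions
  if (nrow(pos) != nv) stop_gelfrac("dimension_error", "positions length mismatch")
  for (nm in names(point_fields)) {
    if (NROW(point_fields[[nm]]) != nv)
      stop_gelfrac("dimension_error", sprintf(
        "point field '%s' has length %d, expected %d",
        nm, NROW(point_fields[[nm]]), nv))
  }
  for (nm in names(cell_fields)) {
    if (NROW(cell_fields[[nm]]) != nt)
      stop_gelfrac("dimension_error", sprintf(
        "cell field '%s' has length %d, expected %d",
        nm, NROW(cell_fields[[nm]]), nt))
  }
  out <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "  <UnstructuredGrid>",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nt),
    "      <Points>",
    data_array("Points", pos, 3L),
    "      </Points>",
    "      <Cells>",
    '        <DataArray type="Int32" Name="connectivity" format="ascii">',
    paste0("          ", apply(mesh$triangles - 1L, 1, paste, collapse = " ")),
    "        </DataArray>",
    '        <DataArray type="Int32" Name="offsets" format="ascii">',
    paste0("          ", paste(3L * seq_len(nt), collapse = " ")),
    "        </DataArray>",
    '        <DataArray type="UInt8" Name="types" format="ascii">',
    paste0("          ", paste(rep(5L, nt), collapse = " ")),
    "        </DataArray>",
    "      </Cells>")
  if (length(point_fields)) {
    out <- c(out, "      <PointData>")
    for (nm in names(point_fields))
      out <- c(out, data_array(nm, point_fields[[nm]],
                               if (is.matrix(point_fields[[nm]]))
                                 ncol(point_fields[[nm]]) else 1L))
    out <- c(out, "      </PointData>")
  }
  if (length(cell_fields)) {
    out <- c(out, "      <CellData>")
    for (nm in names(cell_fields))
      out <- c(out, data_array(nm, cell_fields[[nm]],
                               if (is.matrix(cell_fields[[nm]]))
                                 ncol(cell_fields[[nm]]) else 1L))
    out <- c(out, "      </CellData>")
  }
  out <- c(out, "    </Piece>", "  </UnstructuredGrid>", "</VTKFile>")
  writeLines(out, path)
  if (!is.null(series)) register_vtu_step(series, path, time)
  invisible(path)
}

# maintain <series>.pvd: a json sidecar keeps (time, file) pairs across calls
register_vtu_step <- function(series, path, time) {
  sidecar <- paste0(series, "_steps.json")
  steps <- if (file.exists(sidecar))
    jsonlite::fromJSON(sidecar, simplifyDataFrame = TRUE)
  else data.frame(time = numeric(0), file = character(0))
  steps <- steps[steps$file != basename(path), , drop = FALSE]
  steps <- rbind(steps, data.frame(time = time, file = basename(path)))
  steps <- steps[order(steps$time), , drop = FALSE]
  jsonlite::write_json(steps, sidecar, digits = NA)
  pvd <- c('<?xml version="1.0"?>',
           '<VTKFile type="Collection" version="0.1" byte_order="LittleEndian">',
           "  <Collection>",
           sprintf('    <DataSet timestep="%s" group="" part="0" file="%s"/>',
                   fmt_num(steps$time), xml_escape(steps$file)),
           "  </Collection>",
           "</VTKFile>")
  writeLines(pvd, paste0(series, ".pvd"))
  invisible(NULL)
}
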