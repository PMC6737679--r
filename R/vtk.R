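#' Write a tetrahedral mesh as legacy ASCII VTK
#'
#' Nodes, tetrahedra, the per-element tissue label as cell data, the fixed
#' flag as point data, and any extra point vectors (e.g. displacements).
#'
#' @param mesh A `tet_mesh`.
#' @param path Output `.vtk` path.
#' @param point_vectors Optional named list of n x 3 matrices written as
#'   point-data VECTORS (e.g. `list(displacement = u)`).
#' @param nodes_mm Node positions to write (defaults to `mesh$nodes`).
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, point_vectors = NULL,
                           nodes_mm = mesh$nodes) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(nodes_mm)
  m <- nrow(mesh$tets)
  cat("# vtk DataFile Version 3.0\n", file = con)
  cat("tet mesh (mm)\nASCII\nDATASET UNSTRUCTURED_GRID\n", file = con)
  cat(sprintf("POINTS %d double\n", n), file = con)
  write(t(nodes_mm), file = con, ncolumns = 3)
  cat(sprintf("CELLS %d %d\n", m, 5 * m), file = con)
  write(t(cbind(4L, mesh$tets - 1L)), file = con, ncolumns = 5)
  cat(sprintf("CELL_TYPES %d\n", m), file = con)
  write(rep(10L, m), file = con, ncolumns = 1)
  cat(sprintf("CELL_DATA %d\nSCALARS tissue_label int 1\nLOOKUP_TABLE default\n",
              m), file = con)
  write(mesh$label, file = con, ncolumns = 1)
  cat(sprintf("POINT_DATA %d\nSCALARS fixed int 1\nLOOKUP_TABLE default\n", n),
      file = con)
  write(as.integer(mesh$fixed), file = con, ncolumns = 1)
  for (nm in names(point_vectors)) {
    cat(sprintf("VECTORS %s double\n", nm), file = con)
    write(t(point_vectors[[nm]]), file = con, ncolumns = 3)
  }
  invisible(path)
}
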