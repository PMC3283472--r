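#' Export a mesh (and optional fields) as a VTK unstructured grid
#'
#' Writes an ASCII .vtu XML file with the hexahedra (VTK cell type 12) and,
#' optionally, beam/spring elements as line cells (type 3). Point data
#' (e.g. displacements) and per-hex cell data (e.g. sigma_n, tau_slip) can
#' be attached; cell data on line cells is padded with NaN.
#'
#' @param mesh a `spine_mesh`.
#' @param path output file path (conventionally .vtu).
#' @param point_data named list of per-node vectors or n x k matrices.
#' @param cell_data named list of per-hex vectors.
#' @param include_lines also write beams and springs as line cells.
#' @return the path, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list(),
                      include_lines = TRUE) {
  n <- nrow(mesh$nodes)
  hx <- mesh$hex_conn
  nhex <- if (is.null(hx)) 0L else nrow(hx)
  lines <- NULL
  if (include_lines) {
    if (!is.null(mesh$beams)) {
      lines <- rbind(lines, cbind(mesh$beams$n1, mesh$beams$n2))
    }
    if (!is.null(mesh$springs)) {
      lines <- rbind(lines, cbind(mesh$springs$n1, mesh$springs$n2))
    }
  }
  nline <- if (is.null(lines)) 0L else nrow(lines)
  ncell <- nhex + nline

  num <- function(x) paste(format(x, digits = 9, trim = TRUE,
                                  scientific = TRUE), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ncell))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w("          ", num(as.vector(t(mesh$nodes))))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  connectivity <- c(if (nhex) as.vector(t(hx)) - 1L,
                    if (nline) as.vector(t(lines)) - 1L)
  offsets <- cumsum(c(rep(8L, nhex), rep(2L, nline)))
  types <- c(rep(12L, nhex), rep(3L, nline))
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  w("          ", paste(connectivity, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  w("          ", paste(offsets, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w("          ", paste(types, collapse = " "))
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      k <- if (is.matrix(v)) ncol(v) else 1L
      w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">', nm, k))
      w("          ", num(if (is.matrix(v)) as.vector(t(v)) else v))
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  if (length(cell_data) && ncell) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      v <- c(cell_data[[nm]], rep(NaN, nline))
      w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm))
      w("          ", num(v))
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
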