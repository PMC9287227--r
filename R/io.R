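# Mesh and field export: VTK XML unstructured grids (VTU) for field
# inspection and Gmsh 2.2 ASCII for mesh exchange. Both are written by hand
# (plain-text formats); the VTU arrays carry documented names.

#' Write a mesh (with optional fields) as a VTU file
#'
#' ASCII VTK XML UnstructuredGrid with hexahedron cells. Point data arrays
#' may be vectors (length n_nodes) or matrices (n_nodes x 3); cell data
#' arrays have one value per element. Standard array names used by the
#' pipeline: "displacement" (mm), "total_deformation" (mm), "von_mises"
#' (MPa), "region_id", "contact_status".
#'
#' @param mesh a `shell_mesh`
#' @param path output path
#' @param point_data,cell_data named lists of arrays
#' @return the path, invisibly
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "shell_mesh"))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(format(x, digits = 9, trim = TRUE,
                                  scientific = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, num), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(num(8L * seq_len(ne)), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(12L, ne), collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  write_arrays <- function(data, n) {
    for (nm in names(data)) {
      x <- data[[nm]]
      if (is.matrix(x)) {
        stopifnot(nrow(x) == n)
        w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
          nm, ncol(x))
        writeLines(apply(x, 1, num), con)
      } else {
        stopifnot(length(x) == n)
        w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
        writeLines(num(as.numeric(x)), con)
      }
      w('        </DataArray>')
    }
  }
  w('      <PointData>')
  write_arrays(point_data, nn)
  w('      </PointData>')
  w('      <CellData>')
  write_arrays(cell_data, ne)
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write / read a mesh in Gmsh 2.2 ASCII format
#'
#' Hexahedra (Gmsh element type 5); the physical tag encodes the region
#' (the tag-name table is written as `$PhysicalNames`). Round-trips through
#' [read_msh()].
#'
#' @param mesh a `shell_mesh`
#' @param path file path
#' @return the path ([write_msh()]) or a `shell_mesh` ([read_msh()]),
#'   region tags and node/element numbering preserved (surface sets are not
#'   stored in the format and are dropped on read)
#' @export
write_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "shell_mesh"))
  regions <- sort(unique(mesh$region))
  rid <- stats::setNames(seq_along(regions), regions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines("$PhysicalNames", con)
  writeLines(as.character(length(regions)), con)
  writeLines(sprintf('3 %d "%s"', rid, regions), con)
  writeLines("$EndPhysicalNames", con)
  writeLines("$Nodes", con)
  writeLines(as.character(nrow(mesh$nodes)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("$EndNodes", con)
  writeLines("$Elements", con)
  writeLines(as.character(nrow(mesh$elems)), con)
  writeLines(paste(seq_len(nrow(mesh$elems)), 5, 2,
                   rid[mesh$region], rid[mesh$region],
                   mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
                   mesh$elems[, 4], mesh$elems[, 5], mesh$elems[, 6],
                   mesh$elems[, 7], mesh$elems[, 8]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname write_msh
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- which(lines == paste0("$", name)) + 1L
    i1 <- which(lines == paste0("$End", name)) - 1L
    if (!length(i0) || !length(i1)) stop(sprintf("missing $%s section", name))
    lines[i0:i1]
  }
  pn <- sec("PhysicalNames")
  n_names <- as.integer(pn[1])
  name_tab <- character(0)
  if (n_names > 0) {
    parts <- regmatches(pn[-1], regexec('^\\d+ (\\d+) "(.*)"$', pn[-1]))
    ids <- vapply(parts, function(p) as.integer(p[2]), 0L)
    name_tab <- stats::setNames(vapply(parts, function(p) p[3], ""), ids)
  }
  nd <- sec("Nodes")
  nn <- as.integer(nd[1])
  ndm <- matrix(as.numeric(unlist(strsplit(nd[-1], " +"))), nn, 4,
                byrow = TRUE)
  el <- sec("Elements")
  ne <- as.integer(el[1])
  elm <- matrix(as.numeric(unlist(strsplit(el[-1], " +"))), ne, byrow = TRUE,
                ncol = length(strsplit(el[2], " +")[[1]]))
  if (any(elm[, 2] != 5)) stop("only hexahedral (type 5) meshes supported")
  ntags <- elm[1, 3]
  conn <- elm[, (4 + ntags):(11 + ntags), drop = FALSE]
  storage.mode(conn) <- "integer"
  region <- as.character(name_tab[as.character(elm[, 4])])
  mesh <- list(nodes = ndm[order(ndm[, 1]), 2:4, drop = FALSE],
               elems = conn, region = region,
               sets = list(), type = "imported", resolution = list())
  class(mesh) <- "shell_mesh"
  mesh
}
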