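#' Write a labelled tet mesh as ASCII VTU
#'
#' Serializes the mesh as a VTK XML UnstructuredGrid: tetrahedra (cell type
#' 10) followed by the interface facet triangles (cell type 5).  Cell data
#' carry `part` (1 = plate, 2 = mucosa, 0 = interface facet), `segment`
#' (-1 where not applicable) and `bonded` (facet cells); point data carry
#' the named node-set membership flags.  Coordinates are written with 17
#' significant digits so a write/read round trip reproduces nodes,
#' connectivity and labels exactly.
#'
#' @param mesh A [tet_mesh()].
#' @param path Output file path (`.vtu`).
#' @param cell_data Optional named list of extra numeric per-tet vectors
#'   (e.g. von Mises stress) appended as cell data (facet cells get NaN).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, cell_data = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  n_nodes <- nrow(mesh$nodes)
  n_tets <- nrow(mesh$tets)
  facets <- mesh$facets
  n_fac <- if (is.null(facets)) 0L else nrow(facets)
  n_cells <- n_tets + n_fac

  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  int <- function(x) paste(format(x, scientific = FALSE, trim = TRUE), collapse = " ")

  conn_tets <- as.vector(t(mesh$tets)) - 1L
  conn <- conn_tets
  offs <- seq_len(n_tets) * 4L
  types <- rep(10L, n_tets)
  if (n_fac > 0) {
    conn <- c(conn, as.vector(t(as.matrix(facets[, c("n1", "n2", "n3")]))) - 1L)
    offs <- c(offs, n_tets * 4L + seq_len(n_fac) * 3L)
    types <- c(types, rep(5L, n_fac))
  }

  part_code <- ifelse(mesh$part == "plate", 1L, 2L)
  seg <- ifelse(is.na(mesh$segment), -1L, mesh$segment)
  cd_part <- c(part_code, rep(0L, n_fac))
  cd_seg <- c(seg, rep(-1L, n_fac))
  cd_bonded <- c(rep(-1L, n_tets), if (n_fac) as.integer(facets$bonded) else integer())

  lines <- c(
    "<?xml version=\"1.0\"?>",
    "<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">",
    "  <UnstructuredGrid>",
    sprintf("    <Piece NumberOfPoints=\"%d\" NumberOfCells=\"%d\">", n_nodes, n_cells),
    "      <Points>",
    "        <DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">",
    paste0("          ", num(as.vector(t(mesh$nodes)))),
    "        </DataArray>",
    "      </Points>",
    "      <Cells>",
    "        <DataArray type=\"Int64\" Name=\"connectivity\" format=\"ascii\">",
    paste0("          ", int(conn)),
    "        </DataArray>",
    "        <DataArray type=\"Int64\" Name=\"offsets\" format=\"ascii\">",
    paste0("          ", int(offs)),
    "        </DataArray>",
    "        <DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">",
    paste0("          ", int(types)),
    "        </DataArray>",
    "      </Cells>"
  )

  cd <- list(part = cd_part, segment = cd_seg, bonded = cd_bonded)
  if (!is.null(cell_data)) {
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      stopifnot(length(v) == n_tets)
      cd[[nm]] <- c(v, rep(NaN, n_fac))
    }
  }
  cd_lines <- c("      <CellData>")
  for (nm in names(cd)) {
    is_int <- nm %in% c("part", "segment", "bonded")
    cd_lines <- c(
      cd_lines,
      sprintf(
        "        <DataArray type=\"%s\" Name=\"%s\" format=\"ascii\">",
        if (is_int) "Int32" else "Float64", nm
      ),
      paste0("          ", if (is_int) int(cd[[nm]]) else num(cd[[nm]])),
      "        </DataArray>"
    )
  }
  cd_lines <- c(cd_lines, "      </CellData>")

  pd_lines <- c("      <PointData>")
  for (nm in names(mesh$node_sets)) {
    flag <- integer(n_nodes)
    flag[mesh$node_sets[[nm]]] <- 1L
    pd_lines <- c(
      pd_lines,
      sprintf(
        "        <DataArray type=\"Int32\" Name=\"nodeset_%s\" format=\"ascii\">",
        nm
      ),
      paste0("          ", int(flag)),
      "        </DataArray>"
    )
  }
  pd_lines <- c(pd_lines, "      </PointData>")

  lines <- c(
    lines, cd_lines, pd_lines,
    "    </Piece>",
    "  </UnstructuredGrid>",
    "</VTKFile>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled tet mesh from ASCII VTU
#'
#' Inverse of [write_mesh()].  Requires the `part` cell-data array; files
#' without part labels are rejected with a format error naming the missing
#' field.  Interface facet geometry (area, footprint centroid) is
#' recomputed from the read coordinates.
#'
#' @param path Path to a `.vtu` file written by [write_mesh()] (or any
#'   ASCII VTU with tet cells and a compatible `part` array).
#' @return A [tet_mesh()].
#' @export
read_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (is.na(xml2::xml_name(piece))) stop("read_mesh: no <Piece> element found")

  get_array <- function(xpath, required = TRUE, what = "numeric") {
    node <- xml2::xml_find_first(doc, xpath)
    if (is.na(xml2::xml_name(node))) {
      if (required) stop(sprintf("read_mesh: missing required array at %s", xpath))
      return(NULL)
    }
    txt <- xml2::xml_text(node)
    v <- scan(text = txt, what = double(), quiet = TRUE)
    if (what == "integer") as.integer(v) else v
  }

  coords <- get_array(".//Points/DataArray")
  nodes <- matrix(coords, ncol = 3L, byrow = TRUE)
  conn <- get_array(".//Cells/DataArray[@Name='connectivity']", what = "integer")
  offs <- get_array(".//Cells/DataArray[@Name='offsets']", what = "integer")
  types <- get_array(".//Cells/DataArray[@Name='types']", what = "integer")

  part_arr <- get_array(".//CellData/DataArray[@Name='part']",
    required = FALSE, what = "integer"
  )
  if (is.null(part_arr)) {
    stop("read_mesh: format error - cell data array 'part' (plate/mucosa labels) is missing")
  }
  seg_arr <- get_array(".//CellData/DataArray[@Name='segment']",
    required = FALSE, what = "integer"
  )
  bonded_arr <- get_array(".//CellData/DataArray[@Name='bonded']",
    required = FALSE, what = "integer"
  )

  starts <- c(0L, offs[-length(offs)]) + 1L
  is_tet <- types == 10L
  is_tri <- types == 5L
  tet_ids <- which(is_tet)
  tets <- t(vapply(tet_ids, function(k) conn[starts[k]:(starts[k] + 3L)], integer(4))) + 1L
  part <- c("facet", "plate", "mucosa")[part_arr[tet_ids] + 1L]
  if (any(!part %in% c("plate", "mucosa"))) {
    stop("read_mesh: format error - tet cells carry invalid 'part' codes")
  }
  segment <- if (is.null(seg_arr)) rep(NA_integer_, length(tet_ids)) else {
    s <- seg_arr[tet_ids]
    s[s < 0L] <- NA_integer_
    s
  }

  node_sets <- list()
  pd <- xml2::xml_find_all(doc, ".//PointData/DataArray")
  for (node in pd) {
    nm <- xml2::xml_attr(node, "Name")
    if (startsWith(nm, "nodeset_")) {
      flag <- as.integer(scan(text = xml2::xml_text(node), what = double(), quiet = TRUE))
      node_sets[[sub("^nodeset_", "", nm)]] <- which(flag == 1L)
    }
  }

  facets <- NULL
  if (any(is_tri)) {
    tri_ids <- which(is_tri)
    tri <- t(vapply(tri_ids, function(k) conn[starts[k]:(starts[k] + 2L)], integer(3))) + 1L
    p1 <- nodes[tri[, 1], , drop = FALSE]
    e1 <- nodes[tri[, 2], , drop = FALSE] - p1
    e2 <- nodes[tri[, 3], , drop = FALSE] - p1
    cr <- cbind(
      e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
      e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
      e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    )
    facets <- data.frame(
      n1 = tri[, 1], n2 = tri[, 2], n3 = tri[, 3],
      cx = (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3,
      cy = (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3,
      area = 0.5 * sqrt(rowSums(cr^2)),
      bonded = if (is.null(bonded_arr)) TRUE else bonded_arr[tri_ids] == 1L
    )
  }

  tet_mesh(nodes, tets, part, segment, node_sets, facets)
}
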