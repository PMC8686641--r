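#' Labelled tetrahedral mesh container
#'
#' A conforming 4-node tetrahedral mesh of the plate-mucosa bilayer (or any
#' labelled tet mesh).  Connectivity is 1-based and positively oriented
#' (strictly positive signed volumes).
#'
#' @param nodes N x 3 numeric matrix of coordinates (mm).
#' @param tets M x 4 integer matrix of node indices.
#' @param part Character vector of length M, each `"plate"` or `"mucosa"`.
#' @param segment Integer vector of length M: segment id (1..14) for mucosa
#'   tets, `NA` for plate tets.
#' @param node_sets Named list of integer node-index vectors; the bilayer
#'   mesher populates `bone_surface`, `plate_oral` and `interface`.
#' @param facets Data frame of interface triangles (columns `n1 n2 n3`,
#'   footprint centroid `cx cy`, `area` in mm^2, `bonded` flag), or `NULL`.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, part, segment = rep(NA_integer_, nrow(tets)),
                     node_sets = list(), facets = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L)
  if (length(part) != nrow(tets)) stop("tet_mesh: one part label per tet required")
  if (!all(part %in% c("plate", "mucosa"))) {
    stop("tet_mesh: part labels must be 'plate' or 'mucosa'")
  }
  if (min(tets) < 1L || max(tets) > nrow(nodes)) {
    stop("tet_mesh: connectivity references nodes outside 1..N")
  }
  vols <- tet_volumes_impl(nodes, tets)
  if (any(vols <= 0)) {
    stop(sprintf("tet_mesh: %d tetrahedra have non-positive volume", sum(vols <= 0)))
  }
  for (nm in names(node_sets)) {
    ns <- node_sets[[nm]]
    if (length(ns) && (min(ns) < 1L || max(ns) > nrow(nodes))) {
      stop(sprintf("tet_mesh: node set '%s' references invalid indices", nm))
    }
  }
  structure(
    list(
      nodes = nodes, tets = tets, part = part,
      segment = as.integer(segment), node_sets = node_sets,
      facets = facets, relief = NULL
    ),
    class = "tet_mesh"
  )
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf(
    "Tetrahedral mesh: %d nodes, %d tets (%d plate, %d mucosa)\n",
    nrow(x$nodes), nrow(x$tets),
    sum(x$part == "plate"), sum(x$part == "mucosa")
  ))
  if (!is.null(x$facets)) {
    cat(sprintf(
      "  interface: %d facets, %.1f mm^2 (%d bonded)\n",
      nrow(x$facets), sum(x$facets$area), sum(x$facets$bonded)
    ))
  }
  if (!is.null(x$relief)) {
    cat(sprintf(
      "  relief: %d facets decoupled, depth %.2f mm\n",
      length(x$relief$facet_ids), x$relief$depth
    ))
  }
  invisible(x)
}

tet_volumes_impl <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  d1 <- nodes[tets[, 2], , drop = FALSE] - a
  d2 <- nodes[tets[, 3], , drop = FALSE] - a
  d3 <- nodes[tets[, 4], , drop = FALSE] - a
  det3 <- d1[, 1] * (d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]) -
    d1[, 2] * (d2[, 1] * d3[, 3] - d2[, 3] * d3[, 1]) +
    d1[, 3] * (d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1])
  det3 / 6
}

#' Signed volumes of all tetrahedra
#'
#' @param mesh A [tet_mesh()].
#' @return Numeric vector of tet volumes (mm^3).
#' @export
tet_volumes <- function(mesh) tet_volumes_impl(mesh$nodes, mesh$tets)

# Kuhn/Freudenthal split of a hexahedral cell into 6 tets.  Each tet follows
# a monotone lattice path from local corner (0,0,0) to (1,1,1); with the
# same main-diagonal direction in every cell the triangulation is globally
# conforming.  Rows: local corner ids (1..8, binary order di + 2 dj + 4 dk)
# of the 4 vertices, ordered for positive volume on a right-handed cell.
kuhn_tets <- function() {
  corner <- function(di, dj, dk) 1L + di + 2L * dj + 4L * dk
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ex <- diag(3)
  out <- matrix(0L, 6, 4)
  for (t in seq_along(perms)) {
    p <- perms[[t]]
    v <- matrix(0, 4, 3)
    v[2, ] <- ex[p[1], ]
    v[3, ] <- ex[p[1], ] + ex[p[2], ]
    v[4, ] <- c(1, 1, 1)
    ids <- corner(v[, 1], v[, 2], v[, 3])
    vol <- det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))
    if (vol < 0) ids <- ids[c(1, 3, 2, 4)]
    out[t, ] <- ids
  }
  out
}

# tets for a structured (nx x ny x nz cells) grid; node id of lattice point
# (i, j, k), i in 1..nx+1 etc., is i + (j-1)(nx+1) + (k-1)(nx+1)(ny+1)
structured_tets <- function(nx, ny, nz) {
  kt <- kuhn_tets()
  node_id <- function(i, j, k) i + (j - 1L) * (nx + 1L) + (k - 1L) * (nx + 1L) * (ny + 1L)
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  # local corners in binary order (di, dj, dk)
  off <- cbind(
    di = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
    dj = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
    dk = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  )
  corners <- matrix(0L, nrow(cells), 8L)
  for (c8 in 1:8) {
    corners[, c8] <- node_id(
      cells$i + off[c8, 1], cells$j + off[c8, 2], cells$k + off[c8, 3]
    )
  }
  tets <- matrix(0L, nrow(cells) * 6L, 4L)
  for (t in 1:6) {
    tets[seq(t, by = 6L, length.out = nrow(cells)), ] <- corners[, kt[t, ], drop = FALSE]
  }
  list(tets = tets, cells = cells, cell_of_tet = rep(seq_len(nrow(cells)), each = 6L))
}

#' Mesh the layered palate geometry
#'
#' Structured mapped-grid mesher: a regular footprint grid with node columns
#' following the three surfaces, layers through each part, and every
#' hexahedral cell split into 6 tetrahedra with a consistent diagonal rule.
#' This guarantees a conforming plate-mucosa interface (shared nodes realize
#' the bonded adhesion condition) without an external mesh generator.
#'
#' Through-thickness layers: `ceil(mean thickness / mesh_edge)` with a
#' minimum of 2 for the mucosa (resolving the stress gradient the relief
#' decision depends on) and `ceil(plate_thickness / mesh_edge)` with a
#' minimum of 1 for the plate.
#'
#' @param geometry A [build_geometry()] result.
#' @param mesh_edge Target in-plane node spacing (mm); defaults to the
#'   configured value.
#' @return A [tet_mesh()] with node sets `bone_surface`, `plate_oral`,
#'   `interface`, per-mucosa-tet segment ids and the interface facet table.
#' @export
mesh_layered <- function(geometry, mesh_edge = geometry$config$mesh_edge) {
  stopifnot(inherits(geometry, "layered_geometry"))
  if (!is.numeric(mesh_edge) || mesh_edge <= 0) {
    stop("mesh_layered: mesh_edge must be positive")
  }
  cfg <- geometry$config
  W <- cfg$arch_half_width
  L <- cfg$arch_length

  nx <- max(2L, as.integer(ceiling(2 * W / mesh_edge)))
  ny <- max(2L, as.integer(ceiling(L / mesh_edge)))
  xg <- seq(-W, W, length.out = nx + 1L)
  yg <- seq(0, L, length.out = ny + 1L)
  gx <- rep(xg, times = ny + 1L)
  gy <- rep(yg, each = nx + 1L)

  t_grid <- geometry$thickness(gx, gy)
  if (any(t_grid <= 0)) stop("mesh_layered: degenerate geometry (non-positive mucosal thickness)")
  n_p <- max(1L, as.integer(ceiling(cfg$plate_thickness / mesh_edge)))
  n_m <- max(2L, as.integer(ceiling(mean(t_grid) / mesh_edge)))

  z_oral <- geometry$z_oral(gx, gy)
  z_int <- geometry$z_interface(gx, gy)
  z_bone <- geometry$z_bone(gx, gy)

  n_sheets <- n_p + n_m + 1L
  npts <- (nx + 1L) * (ny + 1L)
  nodes <- matrix(0, npts * n_sheets, 3L)
  for (k in seq_len(n_sheets)) {
    idx <- (k - 1L) * npts + seq_len(npts)
    if (k <= n_p + 1L) {
      f <- (k - 1L) / n_p
      z <- z_oral + f * (z_int - z_oral)
    } else {
      f <- (k - 1L - n_p) / n_m
      z <- z_int + f * (z_bone - z_int)
    }
    nodes[idx, ] <- cbind(gx, gy, z)
  }

  st <- structured_tets(nx, ny, n_p + n_m)
  tets <- st$tets
  cell_k <- st$cells$k[st$cell_of_tet]
  part <- ifelse(cell_k <= n_p, "plate", "mucosa")

  # per-tet centroid for segment lookup (mucosa only)
  cx <- (nodes[tets[, 1], 1] + nodes[tets[, 2], 1] +
    nodes[tets[, 3], 1] + nodes[tets[, 4], 1]) / 4
  cy <- (nodes[tets[, 1], 2] + nodes[tets[, 2], 2] +
    nodes[tets[, 3], 2] + nodes[tets[, 4], 2]) / 4
  segment <- rep(NA_integer_, nrow(tets))
  is_muc <- part == "mucosa"
  segment[is_muc] <- geometry$segment_at(cx[is_muc], cy[is_muc])

  sheet_nodes <- function(k) (k - 1L) * npts + seq_len(npts)
  node_sets <- list(
    plate_oral = sheet_nodes(1L),
    interface = sheet_nodes(n_p + 1L),
    bone_surface = sheet_nodes(n_sheets)
  )

  facets <- interface_facets(nodes, nx, ny, sheet0 = n_p)
  mesh <- tet_mesh(nodes, tets, part, segment, node_sets, facets)
  mesh$grid <- list(nx = nx, ny = ny, n_plate_layers = n_p, n_mucosa_layers = n_m,
                    mesh_edge = mesh_edge)
  mesh
}

# interface triangles on node sheet (sheet0 + 1), split along the same
# main diagonal (i,j)-(i+1,j+1) the Kuhn rule induces on horizontal faces
interface_facets <- function(nodes, nx, ny, sheet0) {
  npts <- (nx + 1L) * (ny + 1L)
  base <- sheet0 * npts
  node_id <- function(i, j) base + i + (j - 1L) * (nx + 1L)
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  a <- node_id(cells$i, cells$j)
  b <- node_id(cells$i + 1L, cells$j)
  c_ <- node_id(cells$i, cells$j + 1L)
  d <- node_id(cells$i + 1L, cells$j + 1L)
  tri <- rbind(cbind(a, b, d), cbind(a, d, c_))
  colnames(tri) <- c("n1", "n2", "n3")
  p1 <- nodes[tri[, 1], , drop = FALSE]
  e1 <- nodes[tri[, 2], , drop = FALSE] - p1
  e2 <- nodes[tri[, 3], , drop = FALSE] - p1
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  area <- 0.5 * sqrt(rowSums(cr^2))
  cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cy <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  data.frame(
    n1 = tri[, 1], n2 = tri[, 2], n3 = tri[, 3],
    cx = cx, cy = cy, area = area, bonded = TRUE
  )
}

#' Structured tet mesh of an axis-aligned box
#'
#' Verification fixture generator: meshes `[0, lx] x [0, ly] x [0, lz]` with
#' the same hex-to-tet split as the bilayer mesher, a single part label, and
#' face node sets `xmin, xmax, ymin, ymax, zmin, zmax`.
#'
#' @param lx,ly,lz Box edge lengths (mm).
#' @param edge Target element edge (mm).
#' @param part Part label for all tets (`"mucosa"` or `"plate"`).
#' @return A [tet_mesh()].
#' @export
mesh_box <- function(lx, ly, lz, edge, part = "mucosa") {
  stopifnot(lx > 0, ly > 0, lz > 0, edge > 0)
  nx <- max(1L, as.integer(round(lx / edge)))
  ny <- max(1L, as.integer(round(ly / edge)))
  nz <- max(1L, as.integer(round(lz / edge)))
  xg <- seq(0, lx, length.out = nx + 1L)
  yg <- seq(0, ly, length.out = ny + 1L)
  zg <- seq(0, lz, length.out = nz + 1L)
  nodes <- as.matrix(expand.grid(x = xg, y = yg, z = zg))
  st <- structured_tets(nx, ny, nz)
  tol <- 1e-9
  node_sets <- list(
    xmin = which(nodes[, 1] < tol), xmax = which(nodes[, 1] > lx - tol),
    ymin = which(nodes[, 2] < tol), ymax = which(nodes[, 2] > ly - tol),
    zmin = which(nodes[, 3] < tol), zmax = which(nodes[, 3] > lz - tol)
  )
  tet_mesh(nodes, st$tets, rep(part, nrow(st$tets)), node_sets = node_sets)
}

#' Boundary faces and boundary nodes of a tet mesh
#'
#' A face is on the boundary when it belongs to exactly one tetrahedron.
#'
#' @param mesh A [tet_mesh()].
#' @return `boundary_faces()`: integer matrix (one face per row, original
#'   vertex order of the owning tet); `boundary_nodes()`: sorted integer
#'   vector of node indices.
#' @export
boundary_faces <- function(mesh) {
  tt <- mesh$tets
  faces <- rbind(
    tt[, c(1, 3, 2)], tt[, c(1, 2, 4)],
    tt[, c(2, 3, 4)], tt[, c(1, 4, 3)]
  )
  s1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  s3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  s2 <- as.integer(faces[, 1]) + as.integer(faces[, 2]) + as.integer(faces[, 3]) - s1 - s3
  key <- paste(s1, s2, s3)
  cnt <- table(key)
  faces[cnt[key] == 1L, , drop = FALSE]
}

#' @rdname boundary_faces
#' @export
boundary_nodes <- function(mesh) sort(unique(as.vector(boundary_faces(mesh))))
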