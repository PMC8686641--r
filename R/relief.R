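#' Select the relief region for a borderline stress
#'
#' Implements the selective-relief rule: the relief target is the part of
#' the plate-mucosa interface where the no-relief model generates mucosal
#' von Mises stress at the borderline or higher.  Element stress is
#' projected to interface facets conservatively, as the maximum over all
#' mucosa tets touching any node of the facet, so anything in contact with
#' super-threshold stress is relieved.
#'
#' @param stress A `stress_field` computed on the no-relief model.
#' @param mesh The [tet_mesh()] the stress was computed on.
#' @param borderline Threshold stress in MPa; 0 selects the whole
#'   interface.
#' @return Object of class `region_mask`: `facet_ids` (row indices into
#'   `mesh$facets`), `area` (mm^2), `borderline`.
#' @export
select_relief_region <- function(stress, mesh, borderline) {
  stopifnot(inherits(stress, "stress_field"), inherits(mesh, "tet_mesh"))
  if (is.null(mesh$facets)) stop("select_relief_region: mesh has no interface facets")
  fmax <- facet_max_stress(stress, mesh)
  ids <- which(fmax >= borderline)
  region_mask(ids, mesh, borderline = borderline)
}

# per-facet max von Mises over mucosa tets touching any facet node
facet_max_stress <- function(stress, mesh) {
  muc <- which(mesh$part == "mucosa")
  vm <- stress$von_mises[muc]
  tt <- mesh$tets[muc, , drop = FALSE]
  node_max <- rep(-Inf, nrow(mesh$nodes))
  tab <- tapply(rep(vm, 4L), as.vector(tt), max)
  idx <- as.integer(names(tab))
  node_max[idx] <- tab
  fc <- mesh$facets
  pmax(node_max[fc$n1], node_max[fc$n2], node_max[fc$n3])
}

region_mask <- function(facet_ids, mesh, borderline = NULL, width = NULL) {
  facet_ids <- as.integer(facet_ids)
  if (length(facet_ids) &&
    (min(facet_ids) < 1L || max(facet_ids) > nrow(mesh$facets))) {
    stop("region_mask: facet ids outside the mesh's interface facet set")
  }
  structure(
    list(
      facet_ids = facet_ids,
      area = if (length(facet_ids)) sum(mesh$facets$area[facet_ids]) else 0,
      borderline = borderline,
      width = width
    ),
    class = "region_mask"
  )
}

#' Conventional mid-palatal relief region
#'
#' Interface facets whose footprint centroid lies within `width / 2` of the
#' midline (x = 0), over the full arch length.
#'
#' @param mesh A [tet_mesh()] with interface facets.
#' @param width Strip width in mm (default 10); must be smaller than the
#'   footprint width.
#' @return A `region_mask`.
#' @export
build_mid_palatal_region <- function(mesh, width = 10) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.null(mesh$facets)) stop("build_mid_palatal_region: mesh has no interface facets")
  footprint_width <- diff(range(mesh$nodes[, 1]))
  if (width >= footprint_width) {
    stop(sprintf(
      "build_mid_palatal_region: width %g mm exceeds the footprint width %g mm",
      width, footprint_width
    ))
  }
  cx <- mesh$facets$cx
  ids <- which(abs(cx) <= width / 2)
  if (length(ids) == 0L) {
    warning("build_mid_palatal_region: width smaller than one facet; selecting the facet row nearest the midline")
    ids <- which(abs(cx) <= min(abs(cx)) + 1e-9)
  }
  region_mask(ids, mesh, width = width)
}

#' Apply relief by decoupling the bonded interface
#'
#' Relief of a region opens a gap (default 0.25 mm) between the plate's
#' intaglio surface and the mucosa there.  In a linear bonded model with an
#' open gap no force crosses the relieved area, so the relief is realized
#' mechanically by decoupling: every interface node touched by a relieved
#' facet is duplicated, plate tetrahedra are re-wired to the duplicates,
#' and no force transfer remains across the region.  Meshes stay comparable
#' across scenarios (no re-meshing).  Use [check_gap_closure()] after the
#' re-solve to verify the open-gap assumption.
#'
#' @param mesh A [tet_mesh()] with interface facets.
#' @param region A `region_mask` from [select_relief_region()] or
#'   [build_mid_palatal_region()].
#' @param depth Relief gap depth in mm (default 0.25); recorded for the
#'   gap-closure check.
#' @return A new [tet_mesh()] with duplicated interface nodes and the
#'   relief record in `$relief`; the input mesh unchanged (identical
#'   object) when the region is empty.
#' @export
apply_relief <- function(mesh, region, depth = 0.25) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(region, "region_mask"))
  if (depth <= 0) stop("apply_relief: depth must be positive (mm)")
  ids <- region$facet_ids
  if (length(ids) == 0L) {
    return(mesh)
  }
  fc <- mesh$facets[ids, , drop = FALSE]
  relieved_nodes <- sort(unique(c(fc$n1, fc$n2, fc$n3)))
  n0 <- nrow(mesh$nodes)
  dup <- n0 + seq_along(relieved_nodes)
  nodes <- rbind(mesh$nodes, mesh$nodes[relieved_nodes, , drop = FALSE])

  map <- integer(n0)
  map[relieved_nodes] <- dup
  tets <- mesh$tets
  pl <- mesh$part == "plate"
  sub <- tets[pl, , drop = FALSE]
  hit <- map[sub] != 0L
  sub[hit] <- map[sub[hit]]
  tets[pl, ] <- sub

  facets <- mesh$facets
  facets$bonded[ids] <- FALSE

  out <- tet_mesh(nodes, tets, mesh$part, mesh$segment, mesh$node_sets, facets)
  out$grid <- mesh$grid
  out$relief <- list(
    facet_ids = ids,
    depth = depth,
    pairs = data.frame(orig = relieved_nodes, dup = dup)
  )
  out
}

#' Check the open-gap assumption after a relieved solve
#'
#' The decoupling realization of relief assumes the 0.25 mm gap stays open.
#' This check recomputes, at every duplicated interface node pair, the
#' relative normal approach of the plate towards the mucosa
#' (`u_z(plate side) - u_z(mucosa side)`); approach beyond the relief depth
#' means the gap would have closed and contact (not modelled) would carry
#' load.
#'
#' @param mesh A relieved [tet_mesh()] (from [apply_relief()]).
#' @param disp The `displacement_field` solved on that mesh.
#' @return Data frame of node pairs with their `approach` (mm) and a
#'   `closed` flag; attribute `any_closed`.
#' @export
check_gap_closure <- function(mesh, disp) {
  if (is.null(mesh$relief)) {
    return(structure(
      data.frame(orig = integer(), dup = integer(), approach = numeric(), closed = logical()),
      any_closed = FALSE
    ))
  }
  u <- if (inherits(disp, "displacement_field")) disp$u else as.matrix(disp)
  pairs <- mesh$relief$pairs
  approach <- u[pairs$dup, 3] - u[pairs$orig, 3]
  out <- data.frame(
    orig = pairs$orig, dup = pairs$dup,
    approach = approach,
    closed = approach > mesh$relief$depth
  )
  attr(out, "any_closed") <- any(out$closed)
  out
}
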