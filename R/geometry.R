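#' Sample a 14-segment mucosal thickness map
#'
#' Draws one thickness per segment uniformly within the configured
#' per-segment bounds, from a deterministic generator.  Stands in for the
#' per-site thickness measurements of a real subject.
#'
#' @param config A [palate_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Named numeric vector of length 14 (class `thickness_map`),
#'   thickness in mm, names `segment_1` .. `segment_14`.
#' @export
sample_thickness_map <- function(config, seed = config$seed) {
  validate_palate_config(config)
  tb <- config$thickness_bounds
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  thickness <- stats::runif(nrow(tb), min = tb[, 1], max = tb[, 2])
  names(thickness) <- paste0("segment_", seq_len(nrow(tb)))
  class(thickness) <- "thickness_map"
  thickness
}

#' Build the layered palate geometry
#'
#' Combines the footprint, the vault profile and a thickness map into three
#' stacked surfaces over the footprint: bone surface (top), plate-mucosa
#' interface, and plate oral surface (bottom).  At every footprint point the
#' vertical bone-to-interface distance equals the smoothed mucosal thickness
#' and the interface-to-oral distance equals the plate thickness.
#'
#' The bone surface is a cosine arch across the width,
#' `z = dome_height/2 * (1 + cos(pi * x / arch_half_width))`, constant along
#' the arch; `dome_height = 0` gives a flat slab.  Segment-center
#' thicknesses are blended over the footprint by bilinear interpolation on
#' the 2 x n_rows grid of segment centers (constant extrapolation beyond the
#' outermost centers), so the sampled value is recovered exactly at each
#' segment center and the blend is smooth, deterministic and
#' mirror-symmetric whenever the map is.
#'
#' @param config A [palate_config()].
#' @param thickness A `thickness_map` from [sample_thickness_map()], or any
#'   positive numeric vector of length 14.
#' @return An object of class `layered_geometry` exposing vectorized surface
#'   functions `z_bone(x, y)`, `z_interface(x, y)`, `z_oral(x, y)`, the
#'   thickness field `thickness(x, y)` and the `segment_at(x, y)` lookup.
#' @export
build_geometry <- function(config, thickness) {
  validate_palate_config(config)
  thickness <- as.numeric(thickness)
  if (length(thickness) != config$n_segments) {
    stop(sprintf(
      "build_geometry: thickness map must have %d entries, got %d",
      config$n_segments, length(thickness)
    ))
  }
  if (any(!is.finite(thickness)) || any(thickness <= 0)) {
    stop("build_geometry: all thicknesses must be finite and strictly positive")
  }
  tb <- config$thickness_bounds
  out_of_bounds <- thickness < tb[, 1] - 1e-9 | thickness > tb[, 2] + 1e-9
  if (any(out_of_bounds)) {
    stop(sprintf(
      "build_geometry: thickness outside configured bounds for segment(s) %s",
      paste(which(out_of_bounds), collapse = ", ")
    ))
  }

  L <- config$arch_length
  W <- config$arch_half_width
  n_rows <- config$n_rows
  y_centers <- (seq_len(n_rows) - 0.5) / n_rows * L
  t_left <- thickness[2L * seq_len(n_rows) - 1L]
  t_right <- thickness[2L * seq_len(n_rows)]

  thickness_fun <- function(x, y) {
    # column profiles along y (constant extrapolation past outer centers),
    # then linear blend across x between the two column centers at -W/2, W/2
    tl <- stats::approx(y_centers, t_left, xout = y, rule = 2)$y
    tr <- stats::approx(y_centers, t_right, xout = y, rule = 2)$y
    w <- pmin(1, pmax(0, (x + W / 2) / W))
    t <- (1 - w) * tl + w * tr
    # midline raphe groove: narrow thin band that the 2-column segment
    # blend cannot represent; vanishes at the segment centers (|x| = W/2)
    if (config$raphe_thinning > 0) {
      t <- t * (1 - config$raphe_thinning * exp(-x^2 / (2 * config$raphe_width^2)))
    }
    t
  }

  z_bone <- function(x, y) {
    config$dome_height * 0.5 * (1 + cos(pi * pmin(W, pmax(-W, x)) / W)) + 0 * y
  }
  z_interface <- function(x, y) z_bone(x, y) - thickness_fun(x, y)
  z_oral <- function(x, y) z_interface(x, y) - config$plate_thickness

  segment_at <- function(x, y) {
    row <- pmin(n_rows, pmax(1L, ceiling(y / L * n_rows)))
    side <- ifelse(x < 0, 1L, 2L)
    as.integer((row - 1L) * 2L + side)
  }

  geom <- list(
    config = config,
    thickness_map = thickness,
    footprint = list(xlim = c(-W, W), ylim = c(0, L)),
    thickness = thickness_fun,
    z_bone = z_bone,
    z_interface = z_interface,
    z_oral = z_oral,
    segment_at = segment_at
  )
  class(geom) <- "layered_geometry"
  geom
}

#' @export
print.layered_geometry <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Layered palate geometry: footprint %g x %g mm, dome %g mm, plate %g mm\n",
    2 * cfg$arch_half_width, cfg$arch_length, cfg$dome_height, cfg$plate_thickness
  ))
  cat(sprintf(
    "  mucosal thickness %.2f-%.2f mm over %d segments\n",
    min(x$thickness_map), max(x$thickness_map), cfg$n_segments
  ))
  invisible(x)
}
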