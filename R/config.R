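#' Configuration for the synthetic palate model
#'
#' Defines the parametric stand-in for a CT-derived palatal-plate model: a
#' stiff resin plate bonded to the oral surface of a rigid-backed mucosa
#' layer whose thickness varies over 14 segments (7 anterior-posterior rows
#' x left/right).  All lengths are in mm (consistent mm-N-MPa unit system).
#'
#' Coordinate convention: x runs left-right with the midline at x = 0,
#' y runs anterior (0) to posterior (`arch_length`), z points from the oral
#' side (plate, bottom) up towards the bone surface (top, fixed).  The bite
#' load acts in +z, compressing the mucosa against the bone.
#'
#' @param arch_length Anterior-posterior extent of the region of interest
#'   (mm).  Default 45, a typical adult span from mesial of the first molars
#'   to distal of the second molars.
#' @param arch_half_width Half-width of the footprint (mm); the footprint is
#'   `[-arch_half_width, arch_half_width] x [0, arch_length]`.
#' @param dome_height Vault rise of the bone surface at the midline (mm);
#'   0 gives a flat slab (used by solver verification fixtures).
#' @param plate_thickness Resin plate thickness (mm).
#' @param n_rows Number of anterior-posterior segment rows; with the two
#'   left/right columns this must give 14 segments (n_rows = 7).
#' @param thickness_bounds 14 x 2 matrix of per-segment (min, max) mucosal
#'   thickness bounds in mm; rows ordered by segment id (see
#'   [segment_layout()]).  Default bounds are thin in the mid-arch rows and
#'   thicker towards the borders, spanning 1.0-6.0 mm (see
#'   [default_thickness_bounds()]).
#' @param raphe_thinning Fractional thinning of the mucosa at the midline
#'   (0 disables).  The palatine raphe is a narrow band of thin, firmly
#'   bound mucosa along the midline - the anatomical reason conventional
#'   mid-palatal relief exists - which a two-column segment grid cannot
#'   express, so the generator superimposes a Gaussian midline groove on
#'   the segment blend.  Default 0.45.
#' @param raphe_width Gaussian half-width (standard deviation, mm) of the
#'   raphe groove; default 3.
#' @param mesh_edge Target element edge length (mm); default 0.5.  Coarser
#'   values are routinely used for fast exploratory runs.
#' @param seed Integer seed controlling thickness sampling.
#' @return An object of class `palate_config`.
#' @seealso [sample_thickness_map()], [build_geometry()]
#' @export
palate_config <- function(arch_length = 45,
                          arch_half_width = 22,
                          dome_height = 10,
                          plate_thickness = 1.5,
                          n_rows = 7,
                          thickness_bounds = default_thickness_bounds(n_rows),
                          raphe_thinning = 0.45,
                          raphe_width = 3,
                          mesh_edge = 0.5,
                          seed = 1L) {
  cfg <- list(
    arch_length = arch_length,
    arch_half_width = arch_half_width,
    dome_height = dome_height,
    plate_thickness = plate_thickness,
    n_rows = as.integer(n_rows),
    n_segments = 2L * as.integer(n_rows),
    thickness_bounds = as.matrix(thickness_bounds),
    raphe_thinning = raphe_thinning,
    raphe_width = raphe_width,
    mesh_edge = mesh_edge,
    seed = as.integer(seed)
  )
  class(cfg) <- "palate_config"
  validate_palate_config(cfg)
  cfg
}

validate_palate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  for (fld in c("arch_length", "arch_half_width", "plate_thickness", "mesh_edge")) {
    if (!is.numeric(cfg[[fld]]) || length(cfg[[fld]]) != 1L || cfg[[fld]] <= 0) {
      stop(sprintf("palate_config: '%s' must be a single positive length (mm)", fld))
    }
  }
  if (!is.numeric(cfg$dome_height) || cfg$dome_height < 0) {
    stop("palate_config: 'dome_height' must be >= 0")
  }
  if (!is.numeric(cfg$raphe_thinning) || cfg$raphe_thinning < 0 || cfg$raphe_thinning >= 1) {
    stop("palate_config: 'raphe_thinning' must lie in [0, 1)")
  }
  if (!is.numeric(cfg$raphe_width) || cfg$raphe_width <= 0) {
    stop("palate_config: 'raphe_width' must be positive (mm)")
  }
  if (cfg$n_segments != 14L) {
    stop(sprintf(
      "palate_config: segment layout must contain exactly 14 segments, got %d",
      cfg$n_segments
    ))
  }
  tb <- cfg$thickness_bounds
  if (!is.matrix(tb) || nrow(tb) != cfg$n_segments || ncol(tb) != 2L) {
    stop("palate_config: 'thickness_bounds' must be a 14 x 2 matrix of (min, max) mm")
  }
  if (any(tb <= 0)) stop("palate_config: thickness bounds must be strictly positive")
  if (any(tb[, 1] > tb[, 2])) {
    bad <- which(tb[, 1] > tb[, 2])
    stop(sprintf(
      "palate_config: thickness min > max for segment(s) %s",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(cfg)
}

#' Default per-segment mucosal thickness bounds
#'
#' Thin bounds in the mid-arch rows (the mid-palatal region around the
#' raphe, where denture pain typically arises and where conventional relief
#' is placed), thicker towards the anterior and posterior borders, spanning
#' 1.0-6.0 mm overall - a typical palatal-mucosa range.
#'
#' @param n_rows Number of anterior-posterior rows (7).
#' @return A `2 * n_rows` x 2 matrix of (min, max) thickness in mm.
#' @export
default_thickness_bounds <- function(n_rows = 7) {
  # 0 at the central row, 1 at the outermost rows
  frac <- abs(seq_len(n_rows) - (n_rows + 1) / 2) / ((n_rows - 1) / 2)
  lo <- 1.0 + 2.0 * frac
  hi <- 2.5 + 3.5 * frac
  per_row <- cbind(lo, hi)
  bounds <- per_row[rep(seq_len(n_rows), each = 2L), , drop = FALSE]
  dimnames(bounds) <- list(
    paste0("segment_", seq_len(2L * n_rows)),
    c("min", "max")
  )
  bounds
}

#' Segment layout of the mucosal footprint
#'
#' Segment ids 1..14 tile the footprint as `n_rows` anterior-posterior rows
#' times two left/right columns: segment `2*(row-1) + 1` is the left half of
#' row `row`, `2*(row-1) + 2` the right half.
#'
#' @param config A [palate_config()].
#' @return A data.frame with columns `segment`, `row`, `side` and the
#'   footprint coordinates of each segment center (`x_center`, `y_center`).
#' @export
segment_layout <- function(config) {
  n_rows <- config$n_rows
  row <- rep(seq_len(n_rows), each = 2L)
  side <- rep(c("left", "right"), times = n_rows)
  x_center <- ifelse(side == "left", -0.5, 0.5) * config$arch_half_width
  y_center <- (row - 0.5) / n_rows * config$arch_length
  data.frame(
    segment = seq_len(2L * n_rows),
    row = row,
    side = side,
    x_center = x_center,
    y_center = y_center,
    stringsAsFactors = FALSE
  )
}

#' Study configuration for the relief simulation
#'
#' Bundles everything one run of the full study needs: the synthetic palate,
#' the two materials, the bite load, the list of borderline stresses, the
#' report thresholds, and the relief parameters.
#'
#' Defaults follow the study conditions: bite force 111 N applied vertically
#' onto the plate center; borderlines 0.04, 0.06, 0.08, 0.10 and 0.14 MPa,
#' chosen inside the analyzed stress range whose endpoints are 0.02 and
#' 0.20 MPa; relief depth 0.25 mm; mid-palatal relief strip 10 mm wide.
#'
#' @param palate A [palate_config()].
#' @param materials Named list with elements `plate` and `mucosa`, each a
#'   [material()].  Defaults: plate resin E = 2650 MPa, nu = 0.3; mucosa
#'   E = 8 MPa, nu = 0.37.  The mucosal modulus is a free parameter (the
#'   subject's measured value is not public); the default is calibrated once
#'   so that the no-relief model at 111 N generates stresses spanning the
#'   analyzed 0.02-0.20 MPa interval, the condition the study design states
#'   (see the vignette).
#' @param bite_force Total applied load in N (default 111).
#' @param patch_radius Radius (mm) of the load patch on the plate's oral
#'   surface over which the bite force is distributed (default 3).  A finite
#'   patch avoids the point-load singularity that would make threshold
#'   volumes mesh-dependent.
#' @param borderlines Strictly increasing vector of borderline stresses
#'   (MPa), each inside the open interval given by `stress_range`.
#' @param stress_range Endpoints (MPa) of the analyzed stress interval;
#'   default `c(0.02, 0.20)`.
#' @param thresholds Ascending report thresholds (MPa) for the volume
#'   distributions; must include the upper stress-range endpoint 0.20.
#' @param relief_depth Relief gap depth in mm (default 0.25).
#' @param mid_palatal_width Width (mm) of the conventional mid-palatal
#'   relief strip (default 10).
#' @param seed Integer seed for the whole study (overrides `palate$seed`).
#' @return An object of class `study_config`.
#' @export
study_config <- function(palate = palate_config(),
                         materials = list(
                           plate = material(2650, 0.3),
                           mucosa = material(8, 0.37)
                         ),
                         bite_force = 111,
                         patch_radius = 3,
                         borderlines = c(0.04, 0.06, 0.08, 0.10, 0.14),
                         stress_range = c(0.02, 0.20),
                         thresholds = seq(0.02, 0.20, by = 0.02),
                         relief_depth = 0.25,
                         mid_palatal_width = 10,
                         seed = NULL) {
  if (!is.null(seed)) palate$seed <- as.integer(seed)
  cfg <- list(
    palate = palate,
    materials = materials,
    bite_force = bite_force,
    patch_radius = patch_radius,
    borderlines = borderlines,
    stress_range = stress_range,
    thresholds = thresholds,
    relief_depth = relief_depth,
    mid_palatal_width = mid_palatal_width,
    seed = palate$seed
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  validate_palate_config(cfg$palate)
  stopifnot(
    is.list(cfg$materials),
    all(c("plate", "mucosa") %in% names(cfg$materials))
  )
  lapply(cfg$materials, validate_material)
  if (cfg$bite_force <= 0) stop("study_config: bite_force must be positive (N)")
  if (cfg$patch_radius <= 0) stop("study_config: patch_radius must be positive (mm)")
  if (cfg$relief_depth <= 0) stop("study_config: relief_depth must be positive (mm)")
  if (cfg$mid_palatal_width <= 0) stop("study_config: mid_palatal_width must be positive (mm)")
  if (length(cfg$stress_range) != 2L || diff(cfg$stress_range) <= 0) {
    stop("study_config: stress_range must be two increasing endpoints (MPa)")
  }
  b <- cfg$borderlines
  if (length(b) > 0) {
    if (any(diff(b) <= 0)) stop("study_config: borderlines must be strictly increasing")
    if (any(b <= cfg$stress_range[1]) || any(b >= cfg$stress_range[2])) {
      stop(sprintf(
        "study_config: borderlines must lie strictly inside (%g, %g) MPa",
        cfg$stress_range[1], cfg$stress_range[2]
      ))
    }
  }
  th <- cfg$thresholds
  if (is.unsorted(th, strictly = TRUE)) {
    stop("study_config: thresholds must be strictly ascending")
  }
  if (!any(abs(th - cfg$stress_range[2]) < 1e-12)) {
    stop(sprintf(
      "study_config: thresholds must include the upper stress-range endpoint %g MPa",
      cfg$stress_range[2]
    ))
  }
  invisible(cfg)
}

#' Read / write a study configuration as YAML
#'
#' Every field of [palate_config()] and [study_config()] can be given in a
#' structured text file; omitted fields take their defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pal_args <- raw$palate %||% list()
  if (!is.null(pal_args$thickness_bounds)) {
    pal_args$thickness_bounds <- matrix(
      unlist(pal_args$thickness_bounds),
      ncol = 2, byrow = TRUE
    )
  }
  palate <- do.call(palate_config, pal_args)
  mat <- raw$materials
  materials <- if (is.null(mat)) {
    list(plate = material(2650, 0.3), mucosa = material(8, 0.37))
  } else {
    list(
      plate = material(mat$plate$young_modulus, mat$plate$poisson_ratio),
      mucosa = material(mat$mucosa$young_modulus, mat$mucosa$poisson_ratio)
    )
  }
  args <- raw[setdiff(names(raw), c("palate", "materials"))]
  do.call(study_config, c(list(palate = palate, materials = materials), args))
}

#' @rdname read_study_config
#' @param config A `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  out <- list(
    palate = list(
      arch_length = config$palate$arch_length,
      arch_half_width = config$palate$arch_half_width,
      dome_height = config$palate$dome_height,
      plate_thickness = config$palate$plate_thickness,
      n_rows = config$palate$n_rows,
      thickness_bounds = apply(config$palate$thickness_bounds, 1, as.list),
      mesh_edge = config$palate$mesh_edge,
      seed = config$palate$seed
    ),
    materials = lapply(config$materials, function(m) {
      list(young_modulus = m$young_modulus, poisson_ratio = m$poisson_ratio)
    }),
    bite_force = config$bite_force,
    patch_radius = config$patch_radius,
    borderlines = config$borderlines,
    stress_range = config$stress_range,
    thresholds = config$thresholds,
    relief_depth = config$relief_depth,
    mid_palatal_width = config$mid_palatal_width
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
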