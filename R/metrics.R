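#' Stress-volume distribution of the mucosa
#'
#' For each threshold, accumulates the volume of mucosa within which von
#' Mises stress is generated at that threshold or higher (plate elements
#' excluded), from the piecewise-constant per-tet stresses.  Also bins the
#' mucosa volume into the disjoint intervals between consecutive
#' thresholds; both representations are reported since "at a stress value"
#' can be read either way.
#'
#' @param stress A `stress_field` on `mesh`.
#' @param mesh A [tet_mesh()] with a non-empty mucosa part.
#' @param thresholds Strictly ascending stress thresholds (MPa).
#' @return Object of class `volume_distribution`: `thresholds`,
#'   `cumulative` (volume >= each threshold, mm^3), `bin_volumes`
#'   (length `k + 1`, intervals `[0, t1), [t1, t2), ..., [tk, Inf)`),
#'   `total` mucosa volume (mm^3).
#' @export
stress_volume_distribution <- function(stress, mesh, thresholds) {
  stopifnot(inherits(stress, "stress_field"), inherits(mesh, "tet_mesh"))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("stress_volume_distribution: thresholds must be strictly ascending")
  }
  muc <- mesh$part == "mucosa"
  if (!any(muc)) stop("stress_volume_distribution: mesh has no mucosa elements")
  vols <- tet_volumes(mesh)[muc]
  vm <- stress$von_mises[muc]

  cumulative <- vapply(thresholds, function(t) sum(vols[vm >= t]), numeric(1))
  bin_idx <- findInterval(vm, thresholds)  # 0 .. k
  bin_volumes <- vapply(0:length(thresholds), function(j) sum(vols[bin_idx == j]), numeric(1))
  k <- length(thresholds)
  names(bin_volumes) <- c(
    sprintf("[0,%g)", thresholds[1]),
    if (k > 1) sprintf("[%g,%g)", thresholds[-k], thresholds[-1]),
    sprintf("[%g,Inf)", thresholds[k])
  )
  structure(
    list(
      thresholds = thresholds,
      cumulative = cumulative,
      bin_volumes = bin_volumes,
      total = sum(vols)
    ),
    class = "volume_distribution"
  )
}

#' Relief / no-relief distribution-volume ratio
#'
#' The paper-style ratio: the distribution volume at a threshold, as a
#' percentage of the no-relief baseline volume at the same threshold
#' (baseline = 100%).
#'
#' @param d A `volume_distribution` for the relieved model.
#' @param baseline The no-relief `volume_distribution` (same thresholds).
#' @param threshold Threshold stress (MPa); must be one of the
#'   distributions' thresholds.
#' @return Percentage (100 = unchanged).  A zero baseline volume raises an
#'   error of class `palaterelief_zero_baseline` (reported as
#'   not-applicable in tables, never silently 0).
#' @export
volume_ratio <- function(d, baseline, threshold) {
  stopifnot(
    inherits(d, "volume_distribution"),
    inherits(baseline, "volume_distribution")
  )
  i <- which(abs(d$thresholds - threshold) < 1e-9)
  ib <- which(abs(baseline$thresholds - threshold) < 1e-9)
  if (length(i) != 1L || length(ib) != 1L) {
    stop(sprintf("volume_ratio: threshold %g MPa not among the distribution thresholds", threshold))
  }
  b <- baseline$cumulative[ib]
  if (b <= 0) {
    stop(errorCondition(
      sprintf("volume_ratio: baseline volume at %g MPa is zero; ratio undefined", threshold),
      class = c("palaterelief_zero_baseline", "error", "condition")
    ))
  }
  100 * (d$cumulative[i] / b)
}

#' Ratio table across scenarios
#'
#' @param distributions Named list of `volume_distribution`s (must include
#'   the baseline scenario).
#' @param baseline_name Name of the no-relief baseline scenario.
#' @return Data frame: one row per scenario, one `pct_at_<t>` column per
#'   threshold; `NA` where the baseline volume is zero.
#' @export
ratio_table <- function(distributions, baseline_name = "no_relief") {
  baseline <- distributions[[baseline_name]]
  if (is.null(baseline)) stop(sprintf("ratio_table: no scenario named '%s'", baseline_name))
  th <- baseline$thresholds
  rows <- lapply(names(distributions), function(nm) {
    d <- distributions[[nm]]
    pct <- vapply(th, function(t) {
      tryCatch(
        volume_ratio(d, baseline, t),
        palaterelief_zero_baseline = function(e) NA_real_
      )
    }, numeric(1))
    stats::setNames(
      data.frame(scenario = nm, t(pct), stringsAsFactors = FALSE),
      c("scenario", sprintf("pct_at_%.2f", th))
    )
  })
  do.call(rbind, rows)
}
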