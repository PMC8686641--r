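#' Write the study report to disk
#'
#' Emits, under `outdir`: the ratio table (`ratios.csv`), both volume
#' distribution representations (`distributions_cumulative.csv`,
#' `distributions_bins.csv`), one VTU von Mises field map per scenario
#' (`field_<scenario>.vtu`), a distribution plot
#' (`distribution_plot.png`), and the fully resolved study configuration
#' (`study_config.yaml`).  File contents are deterministic given a fixed
#' report.
#'
#' @param report A `study_report` from [run_study()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(report, outdir) {
  stopifnot(inherits(report, "study_report"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, mode = 2L) != 0L) {
    stop(sprintf("render_report: cannot write to '%s'", outdir))
  }
  written <- character()

  path <- file.path(outdir, "ratios.csv")
  utils::write.csv(report$ratios, path, row.names = FALSE)
  written <- c(written, path)

  cum <- do.call(rbind, lapply(names(report$scenarios), function(nm) {
    d <- report$scenarios[[nm]]$distribution
    data.frame(
      scenario = nm, threshold_mpa = d$thresholds,
      volume_mm3 = d$cumulative, total_mucosa_mm3 = d$total,
      stringsAsFactors = FALSE
    )
  }))
  path <- file.path(outdir, "distributions_cumulative.csv")
  utils::write.csv(cum, path, row.names = FALSE)
  written <- c(written, path)

  bins <- do.call(rbind, lapply(names(report$scenarios), function(nm) {
    d <- report$scenarios[[nm]]$distribution
    data.frame(
      scenario = nm, bin = names(d$bin_volumes),
      volume_mm3 = as.numeric(d$bin_volumes), stringsAsFactors = FALSE
    )
  }))
  path <- file.path(outdir, "distributions_bins.csv")
  utils::write.csv(bins, path, row.names = FALSE)
  written <- c(written, path)

  for (nm in names(report$scenarios)) {
    sc <- report$scenarios[[nm]]
    path <- file.path(outdir, sprintf("field_%s.vtu", nm))
    write_mesh(sc$mesh, path, cell_data = list(von_mises = sc$stress$von_mises))
    written <- c(written, path)
  }

  path <- file.path(outdir, "distribution_plot.png")
  grDevices::png(path, width = 1400, height = 900, res = 150)
  print(plot_distributions(report))
  grDevices::dev.off()
  written <- c(written, path)

  path <- file.path(outdir, "study_config.yaml")
  write_study_config(report$config, path)
  written <- c(written, path)

  invisible(written)
}

#' Plot cumulative stress-volume distributions per scenario
#'
#' @param report A `study_report`.
#' @return A ggplot object: mucosa volume with von Mises stress at each
#'   threshold or higher, one line per scenario.
#' @export
plot_distributions <- function(report) {
  df <- do.call(rbind, lapply(names(report$scenarios), function(nm) {
    d <- report$scenarios[[nm]]$distribution
    data.frame(
      scenario = nm, threshold = d$thresholds, volume = d$cumulative,
      stringsAsFactors = FALSE
    )
  }))
  df$scenario <- factor(df$scenario, levels = names(report$scenarios))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$threshold, y = .data$volume, colour = .data$scenario)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "von Mises stress threshold (MPa)",
      y = expression("mucosa volume at threshold or higher (mm"^3 * ")"),
      colour = NULL,
      title = "Stress-volume distributions by relief scenario"
    ) +
    ggplot2::theme_minimal()
}
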