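#' Pipeline run configuration
#'
#' Builds, validates and serializes the configuration of a full analysis
#' run. Every default is echoed into the emitted YAML so a run is fully
#' specified by its config file alone.
#'
#' @param mode one of `"simulate-lines"`, `"simulate-circles"`,
#'   `"simulate-parallel"`, `"real-data"`.
#' @param width,height mask / analysis grid size in pixels.
#' @param n_shapes number of simulated shapes.
#' @param radius_range circle radius range, pixels.
#' @param spacing parallel-line spacing, pixels.
#' @param densities data densities to sweep.
#' @param position_fwhm,outlier_density noise grids (crossed).
#' @param n_replicates samplings per condition.
#' @param seed_base integer base seed.
#' @param scale analysis rescale factor for real data.
#' @param camera_pixel_size_nm camera pixel size, nm.
#' @param input_csv real-data localization table path (`mode = "real-data"`).
#' @param column_map column mapping for [read_localizations()].
#' @param smooth apply accumulator smoothing.
#' @param ... overrides stored verbatim in the config.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(mode = "simulate-lines", width = 640, height = 640,
                       n_shapes = 12, radius_range = c(30, 60), spacing = 20,
                       densities = seq(0.05, 1, by = 0.05),
                       position_fwhm = 0, outlier_density = 0,
                       n_replicates = 100, seed_base = 1, scale = 25,
                       camera_pixel_size_nm = 158, input_csv = NULL,
                       column_map = list(x = "x", y = "y"), smooth = NULL,
                       ...) {
  cfg <- c(as.list(environment()), list(...))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  modes <- c("simulate-lines", "simulate-circles", "simulate-parallel",
             "real-data")
  if (!cfg$mode %in% modes)
    stop("mode must be one of: ", paste(modes, collapse = ", "))
  stopifnot(cfg$width >= 2, cfg$height >= 2,
            all(cfg$densities > 0 & cfg$densities <= 1),
            all(cfg$position_fwhm >= 0),
            all(cfg$outlier_density >= 0 & cfg$outlier_density <= 1),
            cfg$n_replicates >= 1, cfg$scale > 0)
  if (cfg$mode == "real-data" && is.null(cfg$input_csv))
    stop("real-data mode requires input_csv")
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$densities <- as.numeric(cfg$densities)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> detect -> evaluate -> report for a
#' [run_config()]: builds or reads the input, runs the density sweep, and
#' writes all artifacts (effective config, mask PNG + shape JSON, sweep CSV
#' and JSON summary, detections CSV of a representative replicate, score
#' plot, and a log of parameters and timings) into `out_dir`.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the sweep object and the artifact paths.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logln <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...),
                             "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logln("run_pipeline mode=%s seed_base=%d", cfg$mode, cfg$seed_base)
  write_run_config(cfg, file.path(out_dir, "config.yaml"))

  shape <- if (cfg$mode == "simulate-circles") "circle" else "line"
  if (cfg$mode == "real-data") {
    locs <- read_localizations(cfg$input_csv, cfg$column_map,
                               units = "camera-pixel", scale = cfg$scale,
                               camera_pixel_size = cfg$camera_pixel_size_nm)
    locs <- rescale_discretize(locs, cfg$scale)
    dims <- c(max(locs$points$x) + 1, max(locs$points$y) + 1)
    fit_line <- hough_fit(locs, "line", dims = dims)
    fit_circle <- hough_fit(locs, "circle", dims = dims,
                            params = hough_params(
                              "circle",
                              r_range = c(10, 120) * cfg$scale /
                                cfg$camera_pixel_size_nm, r_step = 0.4,
                              nm_per_px = cfg$camera_pixel_size_nm / cfg$scale))
    write_detections_csv(fit_line, file.path(out_dir, "lines.csv"))
    write_detections_csv(fit_circle, file.path(out_dir, "circles.csv"))
    logln("real-data: %d points, %d lines, %d circles", nrow(locs$points),
          nrow(fit_line$detections), nrow(fit_circle$detections))
    return(invisible(list(line = fit_line, circle = fit_circle,
                          out_dir = out_dir)))
  }

  mask <- switch(cfg$mode,
    "simulate-lines" = make_line_mask(cfg$width, cfg$height, cfg$n_shapes,
                                      seed = cfg$seed_base),
    "simulate-circles" = make_circle_mask(cfg$width, cfg$height,
                                          cfg$n_shapes, cfg$radius_range,
                                          seed = cfg$seed_base),
    "simulate-parallel" = make_parallel_line_mask(cfg$width, cfg$height,
                                                  cfg$n_shapes, cfg$spacing,
                                                  seed = cfg$seed_base))
  write_mask_png(mask, file.path(out_dir, "mask.png"))
  noise_cfgs <- list()
  for (pf in cfg$position_fwhm)
    for (od in cfg$outlier_density)
      noise_cfgs[[length(noise_cfgs) + 1]] <-
        list(position_fwhm = pf, outlier_density = od)
  t0 <- Sys.time()
  sweep <- density_sweep(mask, shape, densities = cfg$densities,
                         noise_cfgs = noise_cfgs,
                         n_replicates = cfg$n_replicates,
                         seed_base = cfg$seed_base, smooth = cfg$smooth)
  logln("sweep: %d conditions x %d replicates in %.1f s",
        length(cfg$densities) * length(noise_cfgs), cfg$n_replicates,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  write_sweep(sweep, file.path(out_dir, "sweep.csv"),
              file.path(out_dir, "sweep_summary.json"))
  # representative replicate at the highest density
  locs <- sample_localizations(mask, max(cfg$densities),
                               seed = cfg$seed_base)
  fit <- hough_fit(locs, shape, dims = c(mask$width, mask$height),
                   density = max(cfg$densities), smooth = cfg$smooth)
  write_detections_csv(fit, file.path(out_dir, "detections.csv"))
  grDevices::png(file.path(out_dir, "score_vs_density.png"), 800, 600)
  plot(sweep, main = sprintf("%s reconstruction", shape))
  dev.off()
  logln("artifacts written to %s", out_dir)
  invisible(list(sweep = sweep, mask = mask, fit = fit, out_dir = out_dir))
}
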