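#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the full configuration of a pipeline run:
#' input paths, per-stage parameters, units and seed. Unknown fields are
#' rejected so that typos fail fast.
#'
#' @param input list with either `stack` (multi-page TIFF path) or `tracks`
#'   (tracks CSV path), and optionally `mask` (binary image path).
#' @param outdir output directory for all artifacts.
#' @param track list of tracking parameters (`levels`, plus
#'   [keyhole_params()] fields).
#' @param kinematics list of smoothing parameters (`n_derivatives, q, r,
#'   init_state_cov_scale, min_length, outlier_speed`).
#' @param field list of inference parameters (`fine_grid, fine_spacing,
#'   width_rule, coarse_width, prior_var, noise_var, grid_shape, extent,
#'   display_range`).
#' @param frame_interval frame interval in seconds (default 90).
#' @param pixel_size optional pixel size, um/px.
#' @param z_per_t,projection z handling for TIFF input.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, outdir, track = list(), kinematics = list(),
                            field = list(), frame_interval = 90,
                            pixel_size = NULL, z_per_t = 1L,
                            projection = "max", seed = 1L) {
  if (is.null(input$stack) && is.null(input$tracks)) {
    stop_config("Config needs input$stack or input$tracks.")
  }
  structure(
    list(input = input, outdir = outdir, track = track,
         kinematics = kinematics, field = field,
         frame_interval = frame_interval, pixel_size = pixel_size,
         z_per_t = as.integer(z_per_t), projection = projection,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file with the same fields.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("Config file does not exist: %s", path))
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full inference pipeline
#'
#' Executes tracking (skipped when a tracks CSV is supplied), velocity
#' smoothing, and field inference, writing every intermediate product as a
#' plain file under `config$outdir`: `tracks.csv`, `kinematics.csv`,
#' `field_mean.tif`/`field_mean.csv`, `field_variance.csv`,
#' `posterior.json`, `overlay.png`, `velocity_histograms.png`, a
#' `run_log.txt`, and `manifest.json` recording every parameter and the seed
#' so the run can be reproduced exactly. Field TIFFs are written unit-range
#' normalised (TIFF samples live in [0, 1]); the exact values are in the CSV
#' and the value range in the manifest.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return (invisibly) a list of artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$input$stack, config$input$tracks, config$input$mask)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_config(sprintf("Input path does not exist: %s", p))
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run_log.txt")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stages <- character()
  timings <- list()
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    stages <<- c(stages, stage)
    out
  }
  set.seed(config$seed)
  dt_min <- config$frame_interval / 60
  paths <- list(manifest = file.path(config$outdir, "manifest.json"),
                log = log_path)

  # --- tracking -------------------------------------------------------------
  if (!is.null(config$input$tracks)) {
    tracks <- read_tracks(config$input$tracks)
    stages <- c(stages, "track")
    timings$track <- 0
    say("Loaded %d track points from %s (tracker stage skipped).",
        nrow(tracks), config$input$tracks)
  } else {
    tracks <- timed("track", {
      stack <- read_stack(config$input$stack, z_per_t = config$z_per_t,
                          projection = config$projection)
      say("Read stack %s: %d frames of %d x %d.", config$input$stack,
          dim(stack)[3], dim(stack)[1], dim(stack)[2])
      kp_args <- config$track[setdiff(names(config$track), "levels")]
      track_stack(stack, levels = config$track$levels %||% 1L,
                  params = do.call(keyhole_params, kp_args))
    })
    say("Tracked %d cells (%d points).", length(unique(tracks$track_id)),
        nrow(tracks))
  }
  paths$tracks <- file.path(config$outdir, "tracks.csv")
  write_tracks(tracks, paths$tracks)

  # --- kinematics -----------------------------------------------------------
  kcfg <- config$kinematics
  kin <- timed("velocity", {
    k <- smooth_tracks(
      tracks, dt = dt_min,
      n_derivatives = kcfg$n_derivatives %||% 3L,
      q = kcfg$q %||% 0.5, r = kcfg$r %||% 1,
      init_state_cov_scale = kcfg$init_state_cov_scale %||% 100,
      pixel_size = config$pixel_size
    )
    filter_and_clean(k, min_length = kcfg$min_length %||% 5L,
                     outlier_speed = kcfg$outlier_speed %||% 20)
  })
  say("Smoothed %d tracks; %d usable velocity samples.",
      length(unique(kin$track_id)), sum(kin$usable))
  paths$kinematics <- file.path(config$outdir, "kinematics.csv")
  write_tracks(kin, paths$kinematics)
  paths$velocity_hist <- file.path(config$outdir, "velocity_histograms.png")
  ggplot2::ggsave(paths$velocity_hist, plot_velocity_histograms(kin),
                  width = 6, height = 5, dpi = 120)

  # --- field inference ------------------------------------------------------
  fcfg <- config$field
  ext <- fcfg$extent %||% c(min(kin$x), max(kin$x), min(kin$y), max(kin$y))
  grid_shape <- fcfg$grid_shape %||% c(100L, 100L)
  mask <- NULL
  if (!is.null(config$input$mask)) {
    m <- read_mask(config$input$mask)
    # resample the mask to the prediction grid by nearest neighbour
    ri <- round(seq(1, nrow(m), length.out = grid_shape[1]))
    ci <- round(seq(1, ncol(m), length.out = grid_shape[2]))
    mask <- m[ri, ci]
  }
  field <- timed("infer", {
    basis <- multiscale_basis(
      ext, fine_grid = fcfg$fine_grid %||% c(6, 6),
      fine_spacing = fcfg$fine_spacing %||% (diff(ext[1:2]) / 5),
      width_rule = fcfg$width_rule %||% "half_spacing",
      coarse_width = fcfg$coarse_width
    )
    infer_field(kin, basis, prior_var = fcfg$prior_var %||% 100,
                noise_var = fcfg$noise_var %||% 1,
                grid_shape = grid_shape, extent = ext, mask = mask)
  })
  post <- attr(field, "posterior")
  say("Inferred field from %d regression rows on %d basis functions.",
      post$n_rows, length(post$mean))

  paths$field_tiff <- file.path(config$outdir, "field_mean.tif")
  paths$field_csv <- file.path(config$outdir, "field_mean.csv")
  fr <- write_field(field, paths$field_tiff, paths$field_csv)
  paths$field_variance <- file.path(config$outdir, "field_variance.csv")
  readr::write_csv(
    dplyr::rename(as_tibble(scalar_field(field$variance, field$extent, field$mask)),
                  variance = "value"),
    paths$field_variance, progress = FALSE
  )
  paths$posterior <- file.path(config$outdir, "posterior.json")
  jsonlite::write_json(
    list(mean = post$mean, prior_var = post$prior_var,
         noise_var = post$noise_var, n_rows = post$n_rows,
         basis = as.data.frame(post$basis), extent = ext),
    paths$posterior, digits = NA, auto_unbox = TRUE
  )

  paths$overlay <- file.path(config$outdir, "overlay.png")
  background <- if (!is.null(config$input$stack)) {
    st <- read_stack(config$input$stack, z_per_t = config$z_per_t,
                     projection = config$projection)
    scalar_field(st[, , 1], ext)
  } else {
    scalar_field(matrix(0, grid_shape[1], grid_shape[2]), ext)
  }
  ggplot2::ggsave(
    paths$overlay,
    plot_overlay(field, background, display_range = fcfg$display_range),
    width = 7, height = 6, dpi = 120
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("chemofield")),
    seed = config$seed, frame_interval_s = config$frame_interval,
    pixel_size_um = config$pixel_size,
    input = config$input, stages = stages,
    track_stage_skipped = !is.null(config$input$tracks), timings_s = timings,
    parameters = list(track = config$track, kinematics = config$kinematics,
                      field = config$field),
    extent = ext, field_value_range = fr$value_range,
    artifacts = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(log_lines, log_path)
  say("Wrote %d artifacts to %s.", length(paths), config$outdir)
  invisible(paths)
}

#' Overlay an inferred field on a microscopy frame
#'
#' Renders the field as a semi-transparent pseudocolour layer over the
#' grayscale background image, the standard presentation of an inferred
#' chemoattractant landscape in its anatomical context. A fixed display range
#' clips the colour scale (making panels comparable across runs) without
#' altering the stored values; the colourbar is labelled in arbitrary units
#' because the field scale is not identifiable.
#'
#' @param field a [scalar_field].
#' @param background a [scalar_field] (e.g. a microscopy frame wrapped with
#'   [scalar_field()]) sharing the field's extent.
#' @param display_range optional `c(lo, hi)` colour limits.
#' @param alpha field layer opacity.
#' @return a ggplot object.
#' @export
plot_overlay <- function(field, background, display_range = NULL, alpha = 0.6) {
  if (max(abs(field$extent - background$extent)) > 1e-6) {
    stop_data("Field and background extents differ.")
  }
  bg <- as_tibble(background)
  fg <- as_tibble(field)
  fg$value[!fg$mask] <- NA_real_
  all_masked <- all(!is.finite(fg$value))
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = bg, ggplot2::aes(.data$x, .data$y, fill = .data$value),
                         show.legend = FALSE) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!all_masked) {
    p <- p + ggnewlayer_field(fg, display_range, alpha)
  } else {
    p <- p + ggplot2::labs(subtitle = "field fully masked (a.u.)")
  }
  p
}

# Second fill scale for the field layer without pulling in extra packages:
# draw the field as tiles with per-pixel colours computed here.
ggnewlayer_field <- function(fg, display_range, alpha) {
  rng <- display_range %||% range(fg$value, na.rm = TRUE)
  norm <- (pmin(pmax(fg$value, rng[1]), rng[2]) - rng[1]) / diff(rng)
  pal <- grDevices::hcl.colors(256, "Viridis")
  fg$col <- pal[pmax(1, ceiling(norm * 255 + 1e-9))]
  fg <- fg[is.finite(fg$value), , drop = FALSE]
  list(
    ggplot2::geom_raster(data = fg, ggplot2::aes(.data$x, .data$y),
                         fill = fg$col, alpha = alpha),
    ggplot2::geom_point(
      data = tibble(x = fg$x[1], y = fg$y[1], v = rng),
      ggplot2::aes(.data$x, .data$y, colour = .data$v), size = 0, alpha = 0
    ),
    ggplot2::scale_colour_viridis_c(name = "field (a.u.)", limits = rng),
    ggplot2::guides(colour = ggplot2::guide_colourbar())
  )
}
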