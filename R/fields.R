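#' Scalar fields on a rectangular grid
#'
#' A `scalar_field` stores a 2-D scalar quantity (here: a chemoattractant
#' concentration landscape in arbitrary units) sampled on a regular grid, with
#' a validity mask marking which pixels lie inside the domain of interest.
#' Fields created by [make_field()] additionally carry their closed-form
#' definition so that values and gradients can be evaluated analytically at
#' arbitrary (off-grid) positions; fields produced by [predict_field()] carry a
#' pointwise predictive variance grid.
#'
#' The grid convention follows image coordinates: `values[i, j]` is the pixel
#' at `y = y_coords[i]`, `x = x_coords[j]`, with the origin at the top-left of
#' the image and coordinates in pixels.
#'
#' @param values numeric matrix of field values (rows index y, columns x).
#' @param extent numeric length-4 vector `c(x_min, x_max, y_min, y_max)` in px.
#' @param mask logical matrix of the same shape as `values`; `TRUE` marks
#'   pixels inside the domain. Defaults to all `TRUE`.
#' @param variance optional numeric matrix of pointwise variances.
#' @param kind,params closed-form definition (used internally by
#'   [make_field()]); leave `NULL` for purely gridded fields.
#'
#' @return An object of class `scalar_field`.
#' @seealso [make_field()], [normalize_field()], [predict_field()]
#' @export
scalar_field <- function(values, extent, mask = NULL, variance = NULL,
                         kind = NULL, params = NULL) {
  values <- as.matrix(values)
  extent <- as.numeric(extent)
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop_config("`extent` must be c(x_min, x_max, y_min, y_max) with positive spans.")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  mask <- matrix(as.logical(mask), nrow(values), ncol(values))
  if (!all(dim(mask) == dim(values))) {
    stop_config("`mask` must have the same dimensions as `values`.")
  }
  if (any(!is.finite(values[mask]))) {
    stop_data("Field values must be finite wherever the mask is TRUE.")
  }
  structure(
    list(values = values, extent = extent, mask = mask, variance = variance,
         kind = kind, params = params, display_range = NULL),
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf(
    "<scalar_field> %d x %d grid, extent [%g, %g] x [%g, %g] px\n",
    nrow(x$values), ncol(x$values), x$extent[1], x$extent[2], x$extent[3], x$extent[4]
  ))
  cat(sprintf("  masked-in pixels: %d (%.1f%%); value range %.4g .. %.4g\n",
              sum(x$mask), 100 * mean(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  if (!is.null(x$kind)) cat("  closed form:", x$kind, "\n")
  invisible(x)
}

field_axis_coords <- function(field) {
  list(
    x = seq(field$extent[1], field$extent[2], length.out = ncol(field$values)),
    y = seq(field$extent[3], field$extent[4], length.out = nrow(field$values))
  )
}

#' Construct a ground-truth chemoattractant field
#'
#' Builds the scalar fields used as simulation ground truth: a linear gradient
#' (the microfluidic in-vitro setting, where attractant concentration rises
#' linearly across the chamber), an isotropic Gaussian peak (a wound releasing
#' attractant that decays with distance), or a sum of such components.
#'
#' @param kind one of `"linear"`, `"gaussian_peak"`, `"mixture"`.
#' @param params a named list of per-kind parameters:
#'   * `linear`: `g` (length-2 gradient vector, field units per px) and
#'     `intercept` (scalar, default 0); the field is `g . s + intercept`.
#'   * `gaussian_peak`: `amplitude`, `centre` (length-2, px), `width`
#'     (sd of the peak, px, > 0); the field is
#'     `amplitude * exp(-||s - centre||^2 / (2 width^2))`.
#'   * `mixture`: `components`, a list of `list(kind = , params = )` entries
#'     which are summed.
#' @param extent domain `c(x_min, x_max, y_min, y_max)` in px.
#' @param grid_shape integer `c(rows, cols)` of the sampled grid.
#' @param mask optional logical matrix (`TRUE` = inside domain).
#'
#' @return A [scalar_field] carrying its closed form, so [field_at()] and
#'   [field_gradient()] evaluate it analytically.
#' @examples
#' f <- make_field("linear", list(g = c(1, 0)), extent = c(0, 10, 0, 10),
#'                 grid_shape = c(11, 11))
#' field_at(f, cbind(5, 3)) # 5
#' @export
make_field <- function(kind, params, extent, grid_shape = c(100, 100),
                       mask = NULL) {
  kind <- as.character(kind)
  if (!kind %in% c("linear", "gaussian_peak", "mixture")) {
    stop_config(sprintf("Unknown field kind '%s'.", kind))
  }
  params <- validate_field_params(kind, params)
  grid_shape <- as.integer(grid_shape)
  xs <- seq(extent[1], extent[2], length.out = grid_shape[2])
  ys <- seq(extent[3], extent[4], length.out = grid_shape[1])
  pts <- cbind(rep(xs, each = grid_shape[1]), rep(ys, times = grid_shape[2]))
  vals <- matrix(eval_field_closed_form(kind, params, pts),
                 nrow = grid_shape[1], ncol = grid_shape[2])
  scalar_field(vals, extent, mask = mask, kind = kind, params = params)
}

validate_field_params <- function(kind, params) {
  switch(kind,
    linear = {
      if (is.null(params$g) || length(params$g) != 2) {
        stop_config("linear field needs `g`, a length-2 gradient vector.")
      }
      params$intercept <- params$intercept %||% 0
      params
    },
    gaussian_peak = {
      if (is.null(params$centre) || length(params$centre) != 2) {
        stop_config("gaussian_peak field needs `centre`, a length-2 position.")
      }
      params$amplitude <- params$amplitude %||% 1
      if (is.null(params$width) || params$width <= 0) {
        stop_config("gaussian_peak field needs `width` > 0.")
      }
      params
    },
    mixture = {
      if (is.null(params$components) || !length(params$components)) {
        stop_config("mixture field needs a non-empty `components` list.")
      }
      params$components <- lapply(params$components, function(cc) {
        list(kind = cc$kind, params = validate_field_params(cc$kind, cc$params))
      })
      params
    }
  )
}

eval_field_closed_form <- function(kind, params, pts) {
  switch(kind,
    linear = pts[, 1] * params$g[1] + pts[, 2] * params$g[2] + params$intercept,
    gaussian_peak = {
      d2 <- (pts[, 1] - params$centre[1])^2 + (pts[, 2] - params$centre[2])^2
      params$amplitude * exp(-d2 / (2 * params$width^2))
    },
    mixture = {
      Reduce(`+`, lapply(params$components, function(cc) {
        eval_field_closed_form(cc$kind, cc$params, pts)
      }))
    }
  )
}

eval_field_gradient_closed_form <- function(kind, params, pts) {
  switch(kind,
    linear = cbind(rep(params$g[1], nrow(pts)), rep(params$g[2], nrow(pts))),
    gaussian_peak = {
      dx <- pts[, 1] - params$centre[1]
      dy <- pts[, 2] - params$centre[2]
      f <- params$amplitude * exp(-(dx^2 + dy^2) / (2 * params$width^2))
      cbind(-dx * f / params$width^2, -dy * f / params$width^2)
    },
    mixture = {
      Reduce(`+`, lapply(params$components, function(cc) {
        eval_field_gradient_closed_form(cc$kind, cc$params, pts)
      }))
    }
  )
}

#' Evaluate a field (or its gradient) at arbitrary positions
#'
#' Fields with a closed form ([make_field()]) are evaluated analytically;
#' purely gridded fields are evaluated by bilinear interpolation, with the
#' gradient taken by central differences on the grid.
#'
#' @param field a [scalar_field].
#' @param points numeric matrix with columns (x, y) in px.
#' @return `field_at()`: a numeric vector of field values. `field_gradient()`:
#'   a two-column matrix of (df/dx, df/dy).
#' @export
field_at <- function(field, points) {
  points <- as_points_matrix(points)
  if (!is.null(field$kind)) {
    return(eval_field_closed_form(field$kind, field$params, points))
  }
  ax <- field_axis_coords(field)
  pracma::interp2(ax$x, ax$y, field$values,
                  clamp_to(points[, 1], ax$x), clamp_to(points[, 2], ax$y))
}

#' @rdname field_at
#' @export
field_gradient <- function(field, points) {
  points <- as_points_matrix(points)
  if (!is.null(field$kind)) {
    return(eval_field_gradient_closed_form(field$kind, field$params, points))
  }
  ax <- field_axis_coords(field)
  hx <- diff(ax$x[1:2]); hy <- diff(ax$y[1:2])
  g <- pracma::gradient(field$values, hx, hy)
  # pracma::gradient returns X = d/dcol (x) and Y = d/drow (y)
  cbind(
    pracma::interp2(ax$x, ax$y, g$X, clamp_to(points[, 1], ax$x), clamp_to(points[, 2], ax$y)),
    pracma::interp2(ax$x, ax$y, g$Y, clamp_to(points[, 1], ax$x), clamp_to(points[, 2], ax$y))
  )
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- matrix(as.numeric(points), ncol = 2)
  if (any(!is.finite(points))) stop_data("Points must be finite.")
  points
}

clamp_to <- function(v, coords) pmin(pmax(v, min(coords)), max(coords))

#' Is a position inside the field's masked domain?
#'
#' @inheritParams field_at
#' @return logical vector; `FALSE` outside the extent or on masked-out pixels.
#' @export
field_inside <- function(field, points) {
  points <- as_points_matrix(points)
  ax <- field_axis_coords(field)
  inside <- points[, 1] >= field$extent[1] & points[, 1] <= field$extent[2] &
    points[, 2] >= field$extent[3] & points[, 2] <= field$extent[4]
  i <- pmin(pmax(round(approx_index(ax$y, points[, 2])), 1L), nrow(field$values))
  j <- pmin(pmax(round(approx_index(ax$x, points[, 1])), 1L), ncol(field$values))
  inside & field$mask[cbind(i, j)]
}

approx_index <- function(coords, v) {
  1 + (v - coords[1]) / (coords[length(coords)] - coords[1]) * (length(coords) - 1)
}

#' Normalise or fix the display range of a field
#'
#' `unit_range` affinely rescales the masked pixels to span exactly (0, 1), the
#' convention used to display inferred fields whose absolute scale is not
#' identifiable (the chemotactic proportionality constant is unknown, so the
#' field is defined only up to a positive affine transformation).
#' `fixed_range` leaves the stored values untouched and records a display
#' range; plotting functions clip the colour scale to it, which makes fields
#' from different runs visually comparable.
#'
#' @param field a [scalar_field].
#' @param mode `"unit_range"` or `"fixed_range"`.
#' @param range length-2 numeric display bounds, required for `fixed_range`.
#' @return A [scalar_field].
#' @export
normalize_field <- function(field, mode = c("unit_range", "fixed_range"),
                            range = NULL) {
  mode <- match.arg(mode)
  if (mode == "unit_range") {
    v <- field$values[field$mask]
    if (length(unique(v)) < 2) {
      stop_data("unit_range normalisation needs at least 2 distinct masked values.")
    }
    field$values <- (field$values - min(v)) / (max(v) - min(v))
    field$variance <- NULL
    # closed form no longer matches the rescaled values
    field$kind <- NULL
    field$params <- NULL
  } else {
    if (is.null(range) || length(range) != 2 || range[2] <= range[1]) {
      stop_config("fixed_range needs `range = c(lo, hi)` with hi > lo.")
    }
    field$display_range <- as.numeric(range)
  }
  field
}

#' Values as shown under the field's display range
#'
#' Clips field values to the `fixed_range` display bounds (if any) without
#' modifying the stored values.
#' @param field a [scalar_field].
#' @return numeric matrix of displayed values.
#' @export
field_display_values <- function(field) {
  v <- field$values
  if (!is.null(field$display_range)) {
    v <- pmin(pmax(v, field$display_range[1]), field$display_range[2])
  }
  v
}

#' @export
as_tibble.scalar_field <- function(x, ...) {
  ax <- field_axis_coords(x)
  # column names shadow the argument inside tibble(), so precompute
  xs <- rep(ax$x, each = nrow(x$values))
  ys <- rep(ax$y, times = ncol(x$values))
  vals <- as.vector(x$values)
  msk <- as.vector(x$mask)
  out <- tibble(x = xs, y = ys, value = vals, mask = msk)
  if (!is.null(x$variance)) out$variance <- as.vector(x$variance)
  out
}

#' @export
autoplot.scalar_field <- function(object, ...) {
  df <- as_tibble(object)
  df$value[!df$mask] <- NA_real_
  limits <- object$display_range
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = "field (a.u.)", limits = limits,
      oob = scales::squish, na.value = "transparent"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
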