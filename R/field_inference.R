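#' Multiscale squared-exponential basis
#'
#' Builds the two-scale radial basis used to decompose the chemoattractant
#' field: a coarse 2 x 2 grid of wide functions centred at the four corners of
#' the domain, capturing the domain-wide trend, plus a regular fine grid
#' centred in the domain capturing local detail. Reference configurations:
#' 3 x 3 fine at 320 px spacing with widths equal to the spacing
#' (in-vitro-style, 13 functions total), and 6 x 6 fine at 100 px spacing with
#' widths of half the spacing (whole-larva-style, 40 functions total).
#'
#' @param extent domain `c(x_min, x_max, y_min, y_max)` in px.
#' @param fine_grid integer `c(rows, cols)` of fine centres.
#' @param fine_spacing fine centre spacing, px.
#' @param width_rule `"half_spacing"` (fine width = spacing / 2) or
#'   `"equal_spacing"` (fine width = spacing).
#' @param coarse_width width of the corner functions, px; defaults to half
#'   the larger domain dimension so that the coarse scale spans the domain.
#' @return A tibble of class `basis_set` with columns `x, y, width, scale`
#'   (`scale` is `"coarse"` or `"fine"`) and the extent as an attribute.
#' @export
multiscale_basis <- function(extent, fine_grid = c(6, 6), fine_spacing = 100,
                             width_rule = c("half_spacing", "equal_spacing"),
                             coarse_width = NULL) {
  width_rule <- match.arg(width_rule)
  extent <- as.numeric(extent)
  wx <- extent[2] - extent[1]
  wy <- extent[4] - extent[3]
  if (length(extent) != 4 || wx <= 0 || wy <= 0) {
    stop_config("`extent` must be c(x_min, x_max, y_min, y_max) with positive spans.")
  }
  if (fine_spacing <= 0) stop_config("fine_spacing must be positive.")
  fine_grid <- as.integer(fine_grid)

  span_x <- (fine_grid[2] - 1) * fine_spacing
  span_y <- (fine_grid[1] - 1) * fine_spacing
  if (span_x > wx + 1e-9 || span_y > wy + 1e-9) {
    stop_config("Fine basis grid exceeds the domain extent; reduce grid or spacing.")
  }
  fx <- (extent[1] + extent[2]) / 2 - span_x / 2 + (seq_len(fine_grid[2]) - 1) * fine_spacing
  fy <- (extent[3] + extent[4]) / 2 - span_y / 2 + (seq_len(fine_grid[1]) - 1) * fine_spacing
  fine_width <- if (width_rule == "half_spacing") fine_spacing / 2 else fine_spacing

  coarse_width <- coarse_width %||% (max(wx, wy) / 2)
  coarse <- tibble(
    x = c(extent[1], extent[2], extent[1], extent[2]),
    y = c(extent[3], extent[3], extent[4], extent[4]),
    width = coarse_width, scale = "coarse"
  )
  fine <- tibble(
    x = rep(fx, times = fine_grid[1]),
    y = rep(fy, each = fine_grid[2]),
    width = fine_width, scale = "fine"
  )
  out <- bind_rows(coarse, fine)
  attr(out, "extent") <- extent
  class(out) <- c("basis_set", class(out))
  out
}

#' Evaluate squared-exponential basis functions
#'
#' `phi_i(s) = exp(-||s - c_i||^2 / (2 sigma_i^2))` for each basis centre
#' `c_i` with isotropic width `sigma_i`; values lie in (0, 1].
#'
#' @param basis a [multiscale_basis()] (any tibble with `x, y, width` works).
#' @param points numeric matrix or data frame of (x, y) positions.
#' @return numeric matrix, `nrow(points) x nrow(basis)`.
#' @export
eval_basis <- function(basis, points) {
  points <- as_points_matrix(points)
  d2 <- outer(points[, 1], basis$x, `-`)^2 + outer(points[, 2], basis$y, `-`)^2
  exp(-sweep(d2, 2, 2 * basis$width^2, `/`))
}

#' Assemble the line-integral regression system
#'
#' Under the proportionality assumption (velocity = chi * grad f), the field
#' difference along one track step equals the line integral of the gradient,
#' which for a step short enough that velocity is approximately constant
#' reduces to the inner product of the velocity estimate with the step
#' displacement. Expanding the field on the basis turns this into one linear
#' equation per consecutive sample pair: response
#' `v_hat_k . (s_{k+1} - s_k)` against design row
#' `phi_i(s_{k+1}) - phi_i(s_k)`; the unknown proportionality constant is
#' absorbed into the basis parameters, so the inferred field's scale is
#' arbitrary. Steps touching a sample flagged `usable = FALSE` (velocity
#' outliers) are skipped.
#'
#' @param kin kinematics tibble (`track_id, frame, x, y, vx, vy`, optionally
#'   `usable`), typically from [smooth_tracks()] + [filter_and_clean()].
#' @param basis a [multiscale_basis()].
#' @return list of class `regression_system`: `design` (N x n_basis matrix),
#'   `response` (length N), `row_meta` (tibble `track_id, frame`), `basis`.
#' @export
assemble_regression <- function(kin, basis) {
  if (!"usable" %in% names(kin)) kin$usable <- TRUE
  kin <- arrange(kin, .data$track_id, .data$frame)
  rows <- kin |>
    group_by(.data$track_id) |>
    mutate(
      x2 = dplyr::lead(.data$x), y2 = dplyr::lead(.data$y),
      usable2 = dplyr::lead(.data$usable)
    ) |>
    ungroup() |>
    filter(!is.na(.data$x2), .data$usable, .data$usable2)
  if (!nrow(rows)) stop_data("No usable data: zero regression rows.")

  phi1 <- eval_basis(basis, cbind(rows$x, rows$y))
  phi2 <- eval_basis(basis, cbind(rows$x2, rows$y2))
  design <- phi2 - phi1
  response <- rows$vx * (rows$x2 - rows$x) + rows$vy * (rows$y2 - rows$y)
  if (any(!is.finite(design)) || any(!is.finite(response))) {
    stop_data("Non-finite entries in the regression system.")
  }
  structure(
    list(design = design, response = response,
         row_meta = tibble(track_id = rows$track_id, frame = rows$frame),
         basis = basis),
    class = "regression_system"
  )
}

#' Bayesian posterior over the basis parameters
#'
#' Conjugate linear-Gaussian inference with a zero-mean isotropic Gaussian
#' prior (variance `prior_var`) on the basis parameters and i.i.d. Gaussian
#' response noise (variance `noise_var`): the posterior is Gaussian with
#' covariance `(X'X / noise_var + I / prior_var)^{-1}` and mean
#' `cov X'y / noise_var`. The system is solved by Cholesky factorisation of
#' the regularised normal matrix (never by explicit inversion of an
#' unregularised, possibly ill-conditioned `X'X`). With zero rows the
#' posterior equals the prior. Because the proportionality constant is
#' unknown, the posterior mean field is identified only up to scale; only the
#' ratio `prior_var / noise_var` affects the mean.
#'
#' @param system a [assemble_regression()] result.
#' @param prior_var prior parameter variance (default 100).
#' @param noise_var response noise variance (default 1).
#' @return object of class `field_posterior`: `mean` (vector), `covariance`
#'   (matrix), `prior_var`, `noise_var`, `basis`, `n_rows`.
#' @export
infer_posterior <- function(system, prior_var = 100, noise_var = 1) {
  if (prior_var <= 0 || noise_var <= 0) {
    stop_config("prior_var and noise_var must be positive.")
  }
  X <- system$design
  y <- system$response
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop_data("Non-finite entries in the regression system.")
  }
  B <- ncol(X)
  A <- crossprod(X) / noise_var + diag(1 / prior_var, B)
  R <- chol(A)
  covariance <- chol2inv(R)
  b <- crossprod(X, y) / noise_var
  mean <- backsolve(R, backsolve(R, b, transpose = TRUE))
  structure(
    list(mean = as.numeric(mean), covariance = covariance,
         prior_var = prior_var, noise_var = noise_var,
         basis = system$basis, n_rows = nrow(X)),
    class = "field_posterior"
  )
}

#' @export
print.field_posterior <- function(x, ...) {
  cat(sprintf(
    "<field_posterior> %d basis functions, %d regression rows\n",
    length(x$mean), x$n_rows
  ))
  cat(sprintf("  prior_var = %g, noise_var = %g\n", x$prior_var, x$noise_var))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.field_posterior <- function(x, ...) {
  # the x/y columns would shadow the argument inside tibble(), so precompute
  b <- x$basis
  tibble(
    term = paste0(b$scale, "_", seq_along(x$mean)),
    estimate = x$mean,
    std.error = sqrt(diag(x$covariance)),
    x = b$x, y = b$y, width = b$width, scale = b$scale
  )
}

#' @importFrom generics glance
#' @export
glance.field_posterior <- function(x, ...) {
  tibble(
    n_basis = length(x$mean), n_rows = x$n_rows,
    prior_var = x$prior_var, noise_var = x$noise_var,
    mean_abs_estimate = mean(abs(x$mean))
  )
}

#' Predictive field surface
#'
#' Evaluates the posterior predictive mean `sum_i theta_i phi_i(s*)` and
#' variance `phi(s*)' Cov phi(s*)` of the inferred field on a regular grid,
#' interpolating between observation locations. Grid points outside the mask
#' are marked invalid.
#'
#' @param posterior a [infer_posterior()] result.
#' @param grid_shape integer `c(rows, cols)` of the prediction grid.
#' @param extent prediction extent; defaults to the basis extent.
#' @param mask optional logical matrix (`grid_shape`), `TRUE` = valid.
#' @return a [scalar_field] with `values` = predictive mean and `variance` =
#'   pointwise predictive variance.
#' @export
predict_field <- function(posterior, grid_shape = c(100, 100), extent = NULL,
                          mask = NULL) {
  extent <- extent %||% attr(posterior$basis, "extent")
  grid_shape <- as.integer(grid_shape)
  xs <- seq(extent[1], extent[2], length.out = grid_shape[2])
  ys <- seq(extent[3], extent[4], length.out = grid_shape[1])
  pts <- cbind(rep(xs, each = grid_shape[1]), rep(ys, times = grid_shape[2]))
  phi <- eval_basis(posterior$basis, pts)
  mu <- matrix(phi %*% posterior$mean, grid_shape[1], grid_shape[2])
  vr <- matrix(rowSums((phi %*% posterior$covariance) * phi),
               grid_shape[1], grid_shape[2])
  scalar_field(mu, extent, mask = mask, variance = pmax(vr, 0))
}

#' One-call field inference from kinematics
#'
#' Convenience wrapper: [assemble_regression()] + [infer_posterior()] +
#' [predict_field()].
#'
#' @inheritParams assemble_regression
#' @inheritParams infer_posterior
#' @inheritParams predict_field
#' @return a [scalar_field]; the `field_posterior` is attached as
#'   `attr(, "posterior")`.
#' @export
infer_field <- function(kin, basis, prior_var = 100, noise_var = 1,
                        grid_shape = c(100, 100), extent = NULL, mask = NULL) {
  post <- infer_posterior(assemble_regression(kin, basis), prior_var, noise_var)
  field <- predict_field(post, grid_shape, extent, mask)
  attr(field, "posterior") <- post
  field
}
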