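#' Simulation configuration
#'
#' Collects the parameters of the agent-based chemotaxis simulator. The
#' generative model is the one the inference assumes: each cell's velocity is
#' proportional to the local field gradient (Keller-Segel proportionality)
#' plus Gaussian velocity noise, and its centroid is observed at a fixed frame
#' interval with additive Gaussian position noise.
#'
#' @param chi proportionality constant between field gradient and velocity
#'   (px^2 min^-1 per field unit). Arbitrary-unit fields make this a free
#'   parameter; default 1.
#' @param dt_integrate forward-Euler integration step, minutes; must not
#'   exceed `sample_interval`.
#' @param sample_interval interval between observed frames, minutes
#'   (default 1.5 min = 90 s, the acquisition interval of the motivating
#'   experiments).
#' @param process_noise_sd sd of the Gaussian velocity noise, px/min.
#' @param obs_noise_sd sd of the centroid observation noise, px.
#' @param n_cells number of cells.
#' @param n_frames number of observed frames per cell.
#' @param seed integer seed; a fixed seed makes the output bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chi = 1, dt_integrate = 0.1, sample_interval = 1.5,
                       process_noise_sd = 0.5, obs_noise_sd = 1,
                       n_cells = 50, n_frames = 40, seed = 1L) {
  if (process_noise_sd < 0 || obs_noise_sd < 0) {
    stop_config("Noise standard deviations must be >= 0.")
  }
  if (dt_integrate <= 0 || sample_interval <= 0 || dt_integrate > sample_interval) {
    stop_config("Need 0 < dt_integrate <= sample_interval.")
  }
  if (n_cells < 1 || n_frames < 2) stop_config("Need n_cells >= 1 and n_frames >= 2.")
  structure(
    list(chi = chi, dt_integrate = dt_integrate, sample_interval = sample_interval,
         process_noise_sd = process_noise_sd, obs_noise_sd = obs_noise_sd,
         n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate cell tracks over a chemoattractant field
#'
#' Runs the generative chemotaxis model forward: cells start at uniform random
#' positions inside the field's masked domain (or at `start_positions`), move
#' with velocity `chi * grad f(s)` plus Gaussian velocity noise integrated by
#' forward Euler at `dt_integrate`, and are observed every `sample_interval`
#' with centroid noise. A cell that leaves the masked domain has its track
#' truncated at the exit, mirroring real tracks that end at the image edge.
#'
#' @param field a [scalar_field] (the ground-truth chemoattractant landscape).
#' @param cfg a [sim_config()].
#' @param start_positions optional n x 2 matrix of initial (x, y) positions;
#'   must lie inside the masked domain.
#' @return A tibble with columns `track_id, frame, x, y` (`frame` is 0-based),
#'   observed positions in px. The noise-free truth is attached as
#'   `attr(, "truth")`: a tibble `track_id, frame, x_true, y_true, vx_true,
#'   vy_true` where the true velocity is the deterministic drift
#'   `chi * grad f` at the true position.
#' @examples
#' f <- make_field("linear", list(g = c(0.5, 0)), extent = c(0, 100, 0, 100))
#' trk <- simulate_tracks(f, sim_config(n_cells = 3, n_frames = 5,
#'                                      process_noise_sd = 0, obs_noise_sd = 0))
#' @export
simulate_tracks <- function(field, cfg = sim_config(), start_positions = NULL) {
  stopifnot(inherits(field, "scalar_field"), inherits(cfg, "sim_config"))
  if (!any(field$mask)) stop_data("Field mask is all-FALSE: no domain to simulate in.")
  run <- function() simulate_tracks_impl(field, cfg, start_positions)
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run()) else run()
}

simulate_tracks_impl <- function(field, cfg, start_positions) {
  n <- cfg$n_cells
  if (is.null(start_positions)) {
    start_positions <- sample_positions_in_mask(field, n)
  } else {
    start_positions <- matrix(as.numeric(start_positions), ncol = 2)
    if (nrow(start_positions) != n) {
      stop_config("start_positions must have one row per cell.")
    }
    if (!all(field_inside(field, start_positions))) {
      stop_data("All start positions must lie inside the masked domain.")
    }
  }

  n_sub <- max(1L, round(cfg$sample_interval / cfg$dt_integrate))
  dt <- cfg$sample_interval / n_sub
  pos <- start_positions
  alive <- rep(TRUE, n)

  # per-frame records
  true_pos <- array(NA_real_, c(n, 2, cfg$n_frames))
  true_vel <- array(NA_real_, c(n, 2, cfg$n_frames))
  record <- function(k) {
    g <- field_gradient(field, pos)
    true_pos[, , k] <<- pos
    true_vel[, , k] <<- cfg$chi * g
    true_pos[!alive, , k] <<- NA_real_
    true_vel[!alive, , k] <<- NA_real_
  }
  record(1L)

  for (k in seq_len(cfg$n_frames - 1L)) {
    for (s in seq_len(n_sub)) {
      idx <- which(alive)
      if (!length(idx)) break
      g <- field_gradient(field, pos[idx, , drop = FALSE])
      v <- cfg$chi * g
      if (cfg$process_noise_sd > 0) {
        v <- v + matrix(rnorm(2 * length(idx), sd = cfg$process_noise_sd),
                        ncol = 2)
      }
      pos[idx, ] <- pos[idx, , drop = FALSE] + v * dt
      still_in <- field_inside(field, pos[idx, , drop = FALSE])
      alive[idx[!still_in]] <- FALSE
    }
    record(k + 1L)
  }

  obs <- true_pos
  if (cfg$obs_noise_sd > 0) {
    noise <- array(rnorm(length(obs), sd = cfg$obs_noise_sd), dim = dim(obs))
    obs <- obs + noise
  }

  rows <- purrr::map_dfr(seq_len(n), function(i) {
    keep <- which(!is.na(true_pos[i, 1, ]))
    tibble(
      track_id = i, frame = keep - 1L,
      x = obs[i, 1, keep], y = obs[i, 2, keep],
      x_true = true_pos[i, 1, keep], y_true = true_pos[i, 2, keep],
      vx_true = true_vel[i, 1, keep], vy_true = true_vel[i, 2, keep]
    )
  })
  rows <- dplyr::filter(dplyr::group_by(rows, .data$track_id), dplyr::n() >= 2)
  rows <- dplyr::ungroup(rows)
  out <- dplyr::select(rows, "track_id", "frame", "x", "y")
  attr(out, "truth") <- dplyr::select(
    rows, "track_id", "frame", "x_true", "y_true", "vx_true", "vy_true"
  )
  out
}

sample_positions_in_mask <- function(field, n) {
  out <- matrix(NA_real_, 0, 2)
  guard <- 0L
  while (nrow(out) < n) {
    m <- 4L * (n - nrow(out))
    cand <- cbind(stats::runif(m, field$extent[1], field$extent[2]),
                  stats::runif(m, field$extent[3], field$extent[4]))
    cand <- cand[field_inside(field, cand), , drop = FALSE]
    out <- rbind(out, cand)
    guard <- guard + 1L
    if (guard > 1000L) stop_data("Could not sample start positions inside the mask.")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Ground truth attached to simulated tracks
#'
#' @param tracks output of [simulate_tracks()].
#' @return tibble of true positions and velocities.
#' @export
sim_truth <- function(tracks) {
  truth <- attr(tracks, "truth")
  if (is.null(truth)) stop_data("These tracks carry no simulation truth.")
  truth
}

#' Render synthetic fluorescence frames from tracks
#'
#' Draws each cell as an isotropic Gaussian-profile bright blob (profile sd =
#' `cell_radius / 2`, evaluated out to three radii) on a dark background with
#' optional additive Gaussian noise — a minimal stand-in for fluorescently
#' labelled cells on a confocal background, used to exercise the segmentation
#' and tracking stage against known trajectories.
#'
#' Pixel `[r, c]` of a frame is centred at image coordinates
#' `(x, y) = (c - 1, r - 1)` (0-based, origin top-left), consistent with the
#' centroid coordinates reported by [hysteresis_segment()].
#'
#' @param tracks tibble `track_id, frame, x, y` (0-based frames, px).
#' @param frame_shape integer `c(rows, cols)`.
#' @param cell_radius apparent cell radius, px (> 0).
#' @param peak_intensity blob peak value.
#' @param background_noise_sd sd of additive Gaussian background noise.
#' @param seed optional seed for the background noise.
#' @return numeric array `rows x cols x n_frames` with
#'   `n_frames = max(frame) + 1`.
#' @export
render_frames <- function(tracks, frame_shape = c(256, 256), cell_radius = 5,
                          peak_intensity = 1, background_noise_sd = 0,
                          seed = NULL) {
  if (cell_radius <= 0) stop_config("cell_radius must be positive.")
  frame_shape <- as.integer(frame_shape)
  n_frames <- if (nrow(tracks)) max(tracks$frame) + 1L else 1L
  stack <- array(0, c(frame_shape[1], frame_shape[2], n_frames))
  if (nrow(tracks)) {
    oob <- tracks$x < 0 | tracks$x > frame_shape[2] - 1 |
      tracks$y < 0 | tracks$y > frame_shape[1] - 1
    if (any(oob)) stop_data("Track positions fall outside the frame bounds.")
    sd_blob <- cell_radius / 2
    half <- ceiling(3 * cell_radius)
    for (i in seq_len(nrow(tracks))) {
      cx <- tracks$x[i]; cy <- tracks$y[i]; f <- tracks$frame[i] + 1L
      cols <- max(1L, floor(cx + 1 - half)):min(frame_shape[2], ceiling(cx + 1 + half))
      rws <- max(1L, floor(cy + 1 - half)):min(frame_shape[1], ceiling(cy + 1 + half))
      d2 <- outer((rws - 1 - cy)^2, (cols - 1 - cx)^2, `+`)
      blob <- peak_intensity * exp(-d2 / (2 * sd_blob^2))
      stack[rws, cols, f] <- stack[rws, cols, f] + blob
    }
  }
  if (background_noise_sd > 0) {
    add_noise <- function() {
      stack + array(rnorm(length(stack), sd = background_noise_sd), dim(stack))
    }
    stack <- if (!is.null(seed)) withr::with_seed(seed, add_noise()) else add_noise()
  }
  stack
}
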