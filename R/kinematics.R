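#' Taylor-series state-space model for track smoothing
#'
#' Builds the constant-interval discrete-time state-space model used to
#' estimate signal derivatives from noisy centroid positions. Per spatial
#' axis the state holds the position and its first `n_derivatives - 1`
#' derivatives; the transition matrix is the upper-triangular Taylor matrix
#' `F[i, j] = dt^(j-i) / (j-i)!` (for `j >= i`) and the state-noise block is
#' the integrated-white-noise covariance
#' `Q[i, j] = q * dt^(2n+1-i-j) / ((n-i)! (n-j)! (2n+1-i-j))` (1-based i, j),
#' i.e. white noise of power `q` driving the highest derivative. The two
#' spatial axes are assembled block-diagonally, and the measurement matrix
#' selects the two positions.
#'
#' @param n_derivatives states per axis (position, velocity, ...); >= 1.
#'   The default 3 (position, velocity, acceleration) gives smooth velocity
#'   estimates without lag.
#' @param dt sampling interval in minutes (default 1.5 min = 90 s).
#' @param q state-noise power (px^2 min^-(2n-1) scale); larger values track
#'   the raw signal more closely, smaller values smooth harder.
#' @param r measurement-noise variance, px^2.
#' @return list with `transition`, `measurement`, `state_noise`,
#'   `meas_noise` matrices plus `n`, `dt`, `q`, `r`. `transition` and
#'   `state_noise` are `2n x 2n` (x-axis block then y-axis block);
#'   `measurement` is `2 x 2n`.
#' @export
build_state_space <- function(n_derivatives = 3L, dt = 1.5, q = 0.5, r = 1) {
  n <- as.integer(n_derivatives)
  if (n < 1L) stop_config("n_derivatives must be >= 1.")
  if (dt <= 0 || q <= 0 || r < 0) stop_config("Need dt > 0, q > 0, r >= 0.")
  Fa <- taylor_transition(n, dt)
  Qa <- integrated_noise_cov(n, dt, q)
  Z <- matrix(0, n, n)
  transition <- rbind(cbind(Fa, Z), cbind(Z, Fa))
  state_noise <- rbind(cbind(Qa, Z), cbind(Z, Qa))
  measurement <- matrix(0, 2, 2 * n)
  measurement[1, 1] <- 1
  measurement[2, n + 1] <- 1
  list(transition = transition, measurement = measurement,
       state_noise = state_noise, meas_noise = diag(r, 2),
       n = n, dt = dt, q = q, r = r)
}

taylor_transition <- function(n, dt) {
  Fa <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) Fa[i, j] <- dt^(j - i) / factorial(j - i)
  }
  Fa
}

integrated_noise_cov <- function(n, dt, q) {
  Qa <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- 2 * n + 1 - i - j
    Qa[i, j] <- q * dt^p / (factorial(n - i) * factorial(n - j) * p)
  }
  Qa
}

#' Kalman filter over a centroid track
#'
#' Standard predict/update recursions over a single track. The state is
#' initialised at the first observed position with all derivatives zero and
#' covariance `init_state_cov_scale` times the identity. Frame gaps inside a
#' track are handled exactly by propagating the transition and state noise
#' over the elapsed interval `gap * dt` without a measurement update.
#'
#' @param positions numeric `T x 2` matrix of observed (x, y), px.
#' @param frames integer frame indices (strictly increasing).
#' @param ss model from [build_state_space()].
#' @param init_state_cov_scale initial state covariance scale.
#' @return list with `mean` (`T x 2n` filtered means), `cov` (list of
#'   `2n x 2n` covariances), `pred_mean`, `pred_cov`, `gaps` (per-step frame
#'   gap used), and `ss` — everything [rts_smooth()] needs.
#' @export
kalman_filter <- function(positions, frames, ss, init_state_cov_scale = 100) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  T_ <- nrow(positions)
  if (T_ < 2) stop_data("Track must have at least 2 samples.")
  if (any(diff(frames) <= 0)) stop_data("Frames must be strictly increasing.")
  m <- 2L * ss$n
  H <- ss$measurement
  R <- ss$meas_noise

  mn <- matrix(0, T_, m)
  cv <- vector("list", T_)
  pm <- matrix(NA_real_, T_, m)
  pc <- vector("list", T_)
  gaps <- c(NA_integer_, diff(frames))

  x <- numeric(m)
  x[1] <- positions[1, 1]
  x[ss$n + 1] <- positions[1, 2]
  P <- diag(init_state_cov_scale, m)
  # first measurement update at k = 1
  upd <- kf_update(x, P, positions[1, ], H, R)
  mn[1, ] <- upd$x; cv[[1]] <- upd$P

  for (k in 2:T_) {
    g <- gaps[k]
    Fk <- if (g == 1L) ss$transition else gap_transition(ss, g)$F
    Qk <- if (g == 1L) ss$state_noise else gap_transition(ss, g)$Q
    x <- Fk %*% mn[k - 1, ]
    P <- Fk %*% cv[[k - 1]] %*% t(Fk) + Qk
    P <- (P + t(P)) / 2
    pm[k, ] <- x; pc[[k]] <- P
    upd <- kf_update(as.numeric(x), P, positions[k, ], H, R)
    mn[k, ] <- upd$x; cv[[k]] <- upd$P
  }
  list(mean = mn, cov = cv, pred_mean = pm, pred_cov = pc,
       gaps = gaps, frames = frames, ss = ss,
       init_state_cov_scale = init_state_cov_scale)
}

kf_update <- function(x, P, y, H, R) {
  S <- H %*% P %*% t(H) + R
  ok <- tryCatch({
    cS <- chol(S)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("Singular innovation covariance in Kalman update (r = 0 with degenerate geometry?)")
  K <- P %*% t(H) %*% chol2inv(chol(S))
  x_new <- x + as.numeric(K %*% (y - H %*% x))
  # Joseph form for numerical symmetry/PSD
  A <- diag(length(x)) - K %*% H
  P_new <- A %*% P %*% t(A) + K %*% R %*% t(K)
  list(x = x_new, P = (P_new + t(P_new)) / 2)
}

gap_transition <- function(ss, gap) {
  list(F = {
    Fa <- taylor_transition(ss$n, ss$dt * gap)
    Z <- matrix(0, ss$n, ss$n)
    rbind(cbind(Fa, Z), cbind(Z, Fa))
  }, Q = {
    Qa <- integrated_noise_cov(ss$n, ss$dt * gap, ss$q)
    Z <- matrix(0, ss$n, ss$n)
    rbind(cbind(Qa, Z), cbind(Z, Qa))
  })
}

#' Rauch-Tung-Striebel smoothing of a filtered track
#'
#' Backward recursion conditioning each state on the full observation
#' sequence: the smoother gain is `G_k = P_k F' P_pred(k+1)^{-1}`, the
#' smoothed mean `m_k + G_k (ms_{k+1} - m_pred(k+1))` and covariance
#' `P_k + G_k (Ps_{k+1} - P_pred(k+1)) G_k'`. The smoothed covariance never
#' exceeds the filtered one (as quadratic forms), and the last sample's
#' smoothed state equals its filtered state.
#'
#' @param filt output of [kalman_filter()].
#' @param track_id identifier used in error messages.
#' @return list with `mean` (`T x 2n`), `cov` (list), `positions`
#'   (`T x 2` smoothed), `velocities` (`T x 2`, px/min), `frames`.
#' @export
rts_smooth <- function(filt, track_id = NA) {
  ss <- filt$ss
  T_ <- nrow(filt$mean)
  m <- ncol(filt$mean)
  ms <- filt$mean
  Ps <- filt$cov
  for (k in (T_ - 1):1) {
    g <- filt$gaps[k + 1]
    Fk <- if (g == 1L) ss$transition else gap_transition(ss, g)$F
    Ppred <- filt$pred_cov[[k + 1]]
    Pinv <- tryCatch(chol2inv(chol(Ppred)), error = function(e) {
      stop(sprintf("Non-invertible predicted covariance at sample %d (track %s).",
                   k + 1, as.character(track_id)))
    })
    G <- filt$cov[[k]] %*% t(Fk) %*% Pinv
    ms[k, ] <- filt$mean[k, ] +
      as.numeric(G %*% (ms[k + 1, ] - filt$pred_mean[k + 1, ]))
    Pk <- filt$cov[[k]] + G %*% (Ps[[k + 1]] - Ppred) %*% t(G)
    Ps[[k]] <- (Pk + t(Pk)) / 2
  }
  pos_idx <- c(1L, ss$n + 1L)
  vel_idx <- if (ss$n >= 2) c(2L, ss$n + 2L) else NULL
  list(mean = ms, cov = Ps,
       positions = ms[, pos_idx, drop = FALSE],
       velocities = if (is.null(vel_idx)) NULL else ms[, vel_idx, drop = FALSE],
       frames = filt$frames)
}

#' Smooth centroid tracks and estimate velocities
#'
#' Runs the Kalman filter and RTS smoother over every track in a track table,
#' returning smoothed positions and velocities with per-sample state
#' covariances. Tracks with fewer than 2 samples are dropped with a message.
#'
#' @param tracks tibble `track_id, frame, x, y` (px; 0-based frames).
#' @param dt frame interval in minutes (default 1.5 min = 90 s).
#' @param n_derivatives,q,r,init_state_cov_scale see [build_state_space()]
#'   and [kalman_filter()]. `n_derivatives` must be >= 2 here so that a
#'   velocity state exists.
#' @param pixel_size optional pixel size in um/px; when given, velocities are
#'   reported in um/min instead of px/min (positions stay in px).
#' @return tibble `track_id, frame, x, y, vx, vy, speed` with smoothed
#'   quantities; the per-sample smoothed state covariances are attached as
#'   `attr(, "covariances")` (a list, one `2n x 2n` matrix list per track).
#' @export
smooth_tracks <- function(tracks, dt = 1.5, n_derivatives = 3L, q = 0.5,
                          r = 1, init_state_cov_scale = 100,
                          pixel_size = NULL) {
  if (n_derivatives < 2L) stop_config("smooth_tracks needs n_derivatives >= 2.")
  ss <- build_state_space(n_derivatives, dt, q, r)
  tracks <- arrange(tracks, .data$track_id, .data$frame)
  ids <- unique(tracks$track_id)
  vel_scale <- if (is.null(pixel_size)) 1 else pixel_size
  covs <- list()
  out <- purrr::map_dfr(ids, function(id) {
    d <- tracks[tracks$track_id == id, , drop = FALSE]
    if (nrow(d) < 2) {
      inform(sprintf("smooth_tracks: dropping track %s (fewer than 2 samples).",
                     as.character(id)))
      return(NULL)
    }
    filt <- kalman_filter(cbind(d$x, d$y), d$frame, ss, init_state_cov_scale)
    sm <- rts_smooth(filt, track_id = id)
    covs[[as.character(id)]] <<- sm$cov
    tibble(
      track_id = id, frame = d$frame,
      x = sm$positions[, 1], y = sm$positions[, 2],
      vx = sm$velocities[, 1] * vel_scale, vy = sm$velocities[, 2] * vel_scale
    )
  })
  if (!nrow(out)) stop_data("No track with >= 2 samples to smooth.")
  out <- mutate(out, speed = sqrt(.data$vx^2 + .data$vy^2))
  attr(out, "covariances") <- covs
  out
}

#' Exclude short tracks and velocity outliers
#'
#' Tracks with fewer than `min_length` samples carry too little information
#' for derivative estimation and are dropped. Velocity samples whose
#' magnitude exceeds `outlier_speed` (typically tracker identity-swap
#' artefacts) are flagged unusable for the downstream field regression; the
#' positions are retained. Exclusion counts are reported via [message()].
#'
#' @param kin kinematics tibble from [smooth_tracks()].
#' @param min_length minimum samples per track (default 5).
#' @param outlier_speed speed threshold in the velocity unit of `kin`
#'   (default 20, px/min or um/min).
#' @return the filtered tibble with a logical `usable` column.
#' @export
filter_and_clean <- function(kin, min_length = 5L, outlier_speed = 20) {
  if (min_length <= 0 || outlier_speed <= 0) {
    stop_config("Thresholds must be positive.")
  }
  n0 <- length(unique(kin$track_id))
  kept <- kin |>
    group_by(.data$track_id) |>
    filter(dplyr::n() >= min_length) |>
    ungroup()
  n1 <- length(unique(kept$track_id))
  if (!nrow(kept)) stop_data("No usable data: all tracks shorter than min_length.")
  kept <- mutate(kept, usable = sqrt(.data$vx^2 + .data$vy^2) <= outlier_speed)
  message(sprintf(
    "filter_and_clean: dropped %d/%d short tracks; flagged %d/%d velocity outliers.",
    n0 - n1, n0, sum(!kept$usable), nrow(kept)
  ))
  if (!any(kept$usable)) stop_data("No usable data: every velocity sample is an outlier.")
  kept
}

#' Velocity component histograms
#'
#' Histograms of the per-sample x and y velocity components aggregated over
#' all tracks — the standard sanity check that most velocities sit in a
#' plausible physiological range and cluster around zero.
#'
#' @param kin kinematics tibble from [smooth_tracks()].
#' @param xlim optional symmetric display range for the velocity axis.
#' @return a ggplot object.
#' @export
plot_velocity_histograms <- function(kin, xlim = NULL) {
  df <- tidyr::pivot_longer(kin[, c("vx", "vy")], dplyr::everything(),
                            names_to = "component", values_to = "velocity")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$velocity)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey30") +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::labs(x = "velocity (per min)", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(xlim)) p <- p + ggplot2::coord_cartesian(xlim = xlim)
  p
}
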