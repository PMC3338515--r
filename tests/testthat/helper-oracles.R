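# Independent oracles used across test files. These deliberately take a
# different computational route from the package (dense batch solves, QR on
# augmented systems, reference flood fill) so that agreement is meaningful.

# Batch maximum-a-posteriori state estimate of the linear-Gaussian track model:
# stack all states into one vector and solve the dense normal equations of the
# full joint log-density. The RTS smoother must reproduce these means.
batch_map_states <- function(positions, frames, ss, init_scale = 100) {
  m <- 2L * ss$n
  T_ <- nrow(positions)
  H <- ss$measurement
  Rinv <- solve(ss$meas_noise)
  A <- matrix(0, T_ * m, T_ * m)
  b <- numeric(T_ * m)
  idx <- function(k) ((k - 1) * m + 1):(k * m)
  m0 <- numeric(m)
  m0[1] <- positions[1, 1]
  m0[ss$n + 1] <- positions[1, 2]
  P0inv <- diag(1 / init_scale, m)
  A[idx(1), idx(1)] <- P0inv
  b[idx(1)] <- P0inv %*% m0
  for (k in seq_len(T_)) {
    A[idx(k), idx(k)] <- A[idx(k), idx(k)] + t(H) %*% Rinv %*% H
    b[idx(k)] <- b[idx(k)] + t(H) %*% Rinv %*% positions[k, ]
  }
  gaps <- diff(frames)
  for (k in seq_len(T_ - 1)) {
    FQ <- chemofield:::gap_transition(ss, gaps[k])
    Qi <- solve(FQ$Q)
    Fk <- FQ$F
    A[idx(k), idx(k)] <- A[idx(k), idx(k)] + t(Fk) %*% Qi %*% Fk
    A[idx(k), idx(k + 1)] <- A[idx(k), idx(k + 1)] - t(Fk) %*% Qi
    A[idx(k + 1), idx(k)] <- A[idx(k + 1), idx(k)] - Qi %*% Fk
    A[idx(k + 1), idx(k + 1)] <- A[idx(k + 1), idx(k + 1)] + Qi
  }
  matrix(solve(A, b), T_, m, byrow = TRUE)
}

# Ridge regression via QR on the augmented least-squares system
# [X / sigma_e; I / sigma_theta] beta ~ [y / sigma_e; 0]: an independent route
# to the posterior mean, avoiding the normal equations entirely.
ridge_qr <- function(X, y, prior_var, noise_var) {
  p <- ncol(X)
  Xa <- rbind(X / sqrt(noise_var), diag(1 / sqrt(prior_var), p))
  ya <- c(y / sqrt(noise_var), numeric(p))
  qr.solve(Xa, ya)
}

# Reference 8-connected flood fill from seed pixels over a foreground mask,
# plain BFS — the oracle for hysteresis connectivity.
flood_from_seeds <- function(fg, seeds) {
  visited <- matrix(FALSE, nrow(fg), ncol(fg))
  queue <- which(seeds & fg)
  visited[queue] <- TRUE
  nr <- nrow(fg)
  while (length(queue)) {
    p <- queue[1]
    queue <- queue[-1]
    r <- ((p - 1) %% nr) + 1
    cc <- ((p - 1) %/% nr) + 1
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- r + dr
      c2 <- cc + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= ncol(fg)) {
        p2 <- (c2 - 1) * nr + r2
        if (fg[p2] && !visited[p2]) {
          visited[p2] <- TRUE
          queue <- c(queue, p2)
        }
      }
    }
  }
  visited
}

# Straight-line tracks at constant velocity, a common tracking fixture.
straight_tracks <- function(n, start_x, start_y, vel, n_frames) {
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      track_id = i, frame = 0:(n_frames - 1),
      x = start_x[i] + vel[i, 1] * (0:(n_frames - 1)),
      y = start_y[i] + vel[i, 2] * (0:(n_frames - 1))
    )
  })
}
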