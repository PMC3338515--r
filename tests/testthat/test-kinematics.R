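test_that("state-space matrices take the stated Taylor and noise forms", {
  ss2 <- build_state_space(2, dt = 1, q = 1, r = 1)
  expect_equal(ss2$transition[1:2, 1:2], matrix(c(1, 0, 1, 1), 2, 2))
  expect_equal(ss2$state_noise[1:2, 1:2],
               matrix(c(1 / 3, 1 / 2, 1 / 2, 1), 2, 2))

  ss3 <- build_state_space(3, dt = 0.5, q = 2, r = 1)
  expect_equal(ss3$transition[1, 3], 0.5^2 / 2)
  # axes are assembled block-diagonally and the measurement selects positions
  expect_equal(ss3$transition[1:3, 4:6], matrix(0, 3, 3))
  expect_equal(ss3$measurement[1, ], c(1, 0, 0, 0, 0, 0))
  expect_equal(ss3$measurement[2, ], c(0, 0, 0, 1, 0, 0))

  expect_error(build_state_space(0), "n_derivatives")
})

test_that("state-noise covariance matches the integrated-Wiener-process integral", {
  # oracle: Q = q * int_0^dt F(tau) G G' F(tau)' dtau with G loading white
  # noise on the highest derivative, evaluated by numerical quadrature
  for (n in 2:4) for (dt in c(0.5, 1.5)) {
    q <- 0.7
    num <- matrix(0, n, n)
    taus <- seq(0, dt, length.out = 2001)
    for (i in 1:n) for (j in 1:n) {
      fi <- taus^(n - i) / factorial(n - i)
      fj <- taus^(n - j) / factorial(n - j)
      num[i, j] <- q * pracma::trapz(taus, fi * fj)
    }
    Qa <- build_state_space(n, dt, q, 1)$state_noise[1:n, 1:n]
    expect_equal(Qa, num, tolerance = 1e-6)
  }
})

test_that("the filter matches a hand-computed scalar Kalman recursion", {
  # n = 1: state = position only, F = 1, Q = q dt, H = 1 — the textbook
  # scalar filter. Hand-run two predict/update cycles as the oracle.
  q <- 0.3; r <- 2; dt <- 1; p0 <- 10
  y <- c(1.0, 2.5, 1.7)
  ss <- build_state_space(1, dt, q, r)
  filt <- kalman_filter(cbind(y, 0 * y), frames = 0:2, ss,
                        init_state_cov_scale = p0)

  x <- y[1]; P <- p0
  K <- P / (P + r); x <- x + K * (y[1] - x); P <- (1 - K) * P # update k=1
  expect_equal(filt$mean[1, 1], x, tolerance = 1e-12)
  for (k in 2:3) {
    P <- P + q * dt                                   # predict
    K <- P / (P + r)
    x <- x + K * (y[k] - x)                           # update
    P <- (1 - K) * P
    expect_equal(filt$mean[k, 1], x, tolerance = 1e-12)
    expect_equal(filt$cov[[k]][1, 1], P, tolerance = 1e-12)
  }
})

test_that("a constant-position track filters to zero velocity", {
  ss <- build_state_space(3, 1.5, 0.5, 1)
  pos <- cbind(rep(12, 30), rep(-4, 30))
  filt <- kalman_filter(pos, 0:29, ss)
  expect_equal(filt$mean[30, 1], 12, tolerance = 1e-6)
  expect_equal(filt$mean[30, 2], 0, tolerance = 1e-6)
  expect_equal(filt$mean[30, 4], -4, tolerance = 1e-6)
  # covariance trace settles (Riccati convergence): non-increasing after
  # the transient
  traces <- vapply(filt$cov, function(P) sum(diag(P)), numeric(1))
  expect_true(all(diff(traces[10:30]) <= 1e-9))
})

test_that("RTS smoothing matches the batch MAP solution and its invariants", {
  set.seed(5)
  ss <- build_state_space(3, 1.5, 0.5, 1)
  for (rep in 1:5) {
    pos <- cbind(cumsum(rnorm(25, 1)), cumsum(rnorm(25, -0.5))) +
      matrix(rnorm(50), ncol = 2)
    frames <- if (rep == 3) c(0:10, 13:26) else 0:24 # one run with a gap
    filt <- kalman_filter(pos, frames, ss)
    sm <- rts_smooth(filt)
    map <- batch_map_states(pos, frames, ss)
    expect_lt(max(abs(sm$mean - map)) / max(abs(map)), 1e-8)
    # last smoothed state equals last filtered state
    expect_equal(sm$mean[nrow(pos), ], filt$mean[nrow(pos), ])
    # smoothing never inflates uncertainty
    for (k in seq_len(nrow(pos))) {
      expect_lte(sum(diag(sm$cov[[k]])), sum(diag(filt$cov[[k]])) + 1e-10)
    }
  }
})

test_that("a noise-free constant-velocity track yields the exact velocity", {
  v <- c(2, -1)
  pos <- cbind(5 + v[1] * 1.5 * (0:29), 7 + v[2] * 1.5 * (0:29))
  kin <- smooth_tracks(
    tibble::tibble(track_id = 1L, frame = 0:29, x = pos[, 1], y = pos[, 2]),
    dt = 1.5, r = 1e-4
  )
  interior <- 5:25
  expect_equal(kin$vx[interior], rep(v[1], length(interior)), tolerance = 1e-4)
  expect_equal(kin$vy[interior], rep(v[2], length(interior)), tolerance = 1e-4)
})

test_that("axes decouple and velocities transform correctly under isometries", {
  set.seed(17)
  pos <- cbind(cumsum(rnorm(20, 2)), cumsum(rnorm(20, 1))) + rnorm(40)
  tr <- tibble::tibble(track_id = 1L, frame = 0:19, x = pos[, 1], y = pos[, 2])
  kin <- smooth_tracks(tr)

  # swapping the axes swaps the outputs exactly
  kin_swapped <- smooth_tracks(dplyr::mutate(tr, tmp = x, x = y, y = tmp))
  expect_equal(kin_swapped$x, kin$y)
  expect_equal(kin_swapped$vx, kin$vy)

  # translation invariance of velocity
  kin_shift <- smooth_tracks(dplyr::mutate(tr, x = x + 100, y = y - 50))
  expect_equal(kin_shift$vx, kin$vx, tolerance = 1e-10)
  expect_equal(kin_shift$x, kin$x + 100, tolerance = 1e-8)

  # rotation equivariance
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rotated <- cbind(tr$x, tr$y) %*% t(R)
  kin_rot <- smooth_tracks(dplyr::mutate(tr, x = rotated[, 1], y = rotated[, 2]))
  vrot <- cbind(kin$vx, kin$vy) %*% t(R)
  expect_equal(kin_rot$vx, vrot[, 1], tolerance = 1e-8)
  expect_equal(kin_rot$vy, vrot[, 2], tolerance = 1e-8)
})

test_that("velocities convert to um/min when a pixel size is supplied", {
  pos <- cbind(2 * 1.5 * (0:9), rep(0, 10))
  tr <- tibble::tibble(track_id = 1L, frame = 0:9, x = pos[, 1], y = pos[, 2])
  px <- smooth_tracks(tr, r = 1e-4)
  um <- smooth_tracks(tr, r = 1e-4, pixel_size = 0.65)
  expect_equal(um$vx, px$vx * 0.65)
  expect_equal(um$x, px$x) # positions stay in px
})

test_that("short tracks are dropped and fast samples flagged, with hand counts", {
  kin <- dplyr::bind_rows(
    tibble::tibble(track_id = 1L, frame = 0:2, x = 0, y = 0, vx = 1, vy = 0),
    tibble::tibble(track_id = 2L, frame = 0:6, x = 0, y = 0,
                   vx = c(1, 2, 30, 3, 1, 25, 2), vy = 0)
  )
  kin$speed <- sqrt(kin$vx^2 + kin$vy^2)
  out <- suppressMessages(filter_and_clean(kin, min_length = 5, outlier_speed = 20))
  expect_equal(unique(out$track_id), 2L) # 3-sample track dropped
  expect_equal(sum(out$usable), 5)      # 30 and 25 exceed the threshold
  expect_equal(nrow(out), 7)            # positions retained

  ok <- suppressMessages(filter_and_clean(kin[kin$track_id == 2, ],
                                          min_length = 5, outlier_speed = 100))
  expect_true(all(ok$usable))
  expect_error(
    suppressMessages(filter_and_clean(kin, min_length = 50)),
    "No usable data"
  )
})
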