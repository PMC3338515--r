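ext500 <- c(0, 500, 0, 500)

test_that("multiscale basis has the reference layouts and widths", {
  larva <- multiscale_basis(ext500, fine_grid = c(6, 6), fine_spacing = 100,
                            width_rule = "half_spacing")
  expect_equal(nrow(larva), 40)             # 4 coarse + 36 fine
  expect_equal(sum(larva$scale == "coarse"), 4)
  expect_equal(unique(larva$width[larva$scale == "fine"]), 50)
  # coarse functions sit at the four domain corners
  corners <- larva[larva$scale == "coarse", c("x", "y")]
  expect_setequal(paste(corners$x, corners$y),
                  c("0 0", "500 0", "0 500", "500 500"))

  vitro <- multiscale_basis(c(0, 640, 0, 640), fine_grid = c(3, 3),
                            fine_spacing = 320, width_rule = "equal_spacing")
  expect_equal(nrow(vitro), 13)             # 4 coarse + 9 fine
  expect_equal(unique(vitro$width[vitro$scale == "fine"]), 320)

  expect_error(
    multiscale_basis(c(0, 100, 0, 100), fine_grid = c(6, 6), fine_spacing = 100),
    "exceeds"
  )
})

test_that("squared-exponential basis evaluates with the 1/(2 sigma^2) convention", {
  b <- multiscale_basis(ext500, c(2, 2), 100)
  centre <- c(b$x[5], b$y[5])
  expect_equal(eval_basis(b, rbind(centre))[1, 5], 1)

  # half value at distance sigma * sqrt(2 ln 2)
  d <- b$width[5] * sqrt(2 * log(2))
  expect_equal(eval_basis(b, rbind(centre + c(d, 0)))[1, 5], 0.5,
               tolerance = 1e-12)

  # ten widths away the response is numerically dead
  far <- eval_basis(b, rbind(centre + c(10 * b$width[5], 0)))[1, 5]
  expect_lt(far, 1e-10)
  phi <- eval_basis(b, cbind(runif(20, 0, 500), runif(20, 0, 500)))
  expect_true(all(phi > 0 & phi <= 1))
})

test_that("regression rows encode the line-integral difference model", {
  b <- multiscale_basis(ext500, c(2, 2), 100)
  kin <- tibble::tibble(
    track_id = 1L, frame = 0:2,
    x = c(100, 101, 101), y = c(200, 200, 200),
    vx = c(1, 0.5, 0), vy = c(0, 0, 0)
  )
  sys <- assemble_regression(kin, b)
  expect_equal(dim(sys$design), c(2, nrow(b)))
  # response = v . delta_s
  expect_equal(sys$response[1], 1) # (1,0).(1,0)
  # stationary step: zero row, zero response
  expect_equal(sys$response[2], 0)
  expect_equal(max(abs(sys$design[2, ])), 0)
  # design = phi(s2) - phi(s1), checked against direct evaluation
  expect_equal(sys$design[1, ],
               eval_basis(b, cbind(101, 200))[1, ] -
                 eval_basis(b, cbind(100, 200))[1, ])

  # constructed single-basis system with phi values 0.8 and 0.3
  b1 <- tibble::tibble(x = 0, y = 0, width = 10, scale = "fine")
  p1 <- sqrt(-2 * 100 * log(0.8)) # distance where phi = 0.8
  p2 <- sqrt(-2 * 100 * log(0.3))
  kin1 <- tibble::tibble(track_id = 1L, frame = 0:1, x = c(p1, p2), y = 0,
                         vx = 1, vy = 0)
  sys1 <- assemble_regression(kin1, b1)
  expect_equal(sys1$design[1, 1], -0.5, tolerance = 1e-12)

  # steps touching an outlier-flagged sample are skipped
  kin4 <- tibble::tibble(
    track_id = 1L, frame = 0:3, x = c(100, 105, 110, 115), y = 200,
    vx = 1, vy = 0, usable = c(TRUE, TRUE, FALSE, TRUE)
  )
  expect_equal(nrow(assemble_regression(kin4, b)$design), 1)
  kin4$usable <- c(FALSE, FALSE, FALSE, FALSE)
  expect_error(assemble_regression(kin4, b), "No usable data")
})

test_that("posterior matches the conjugate closed form and the OLS limit", {
  # 1-D conjugate case: design [1], response [1]
  sys <- structure(list(design = matrix(1), response = 1,
                        row_meta = tibble::tibble(track_id = 1, frame = 0),
                        basis = tibble::tibble(x = 0, y = 0, width = 1,
                                               scale = "fine")),
                   class = "regression_system")
  post <- infer_posterior(sys, prior_var = 1, noise_var = 1)
  expect_equal(post$mean, 0.5)
  expect_equal(post$covariance[1, 1], 0.5)

  # no rows: posterior equals the prior
  sys0 <- sys
  sys0$design <- matrix(numeric(), 0, 3)
  sys0$response <- numeric()
  post0 <- infer_posterior(sys0, prior_var = 7, noise_var = 1)
  expect_equal(post0$mean, rep(0, 3))
  expect_equal(post0$covariance, diag(7, 3))

  # diffuse-prior limit recovers ordinary least squares
  set.seed(2)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- X %*% rnorm(5) + rnorm(200, sd = 0.1)
  sysX <- structure(list(design = X, response = as.numeric(y)),
                    class = "regression_system")
  post_inf <- infer_posterior(sysX, prior_var = 1e10, noise_var = 1)
  ols <- qr.solve(X, y)
  expect_equal(post_inf$mean, as.numeric(ols), tolerance = 1e-6)

  sys_bad <- sysX
  sys_bad$response[3] <- NaN
  expect_error(infer_posterior(sys_bad), "finite")
})

test_that("posterior agrees with an augmented-QR ridge oracle on random systems", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    p <- sample(2:30, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    pv <- stats::runif(1, 0.1, 50)
    nv <- stats::runif(1, 0.1, 5)
    sys <- structure(list(design = X, response = y),
                     class = "regression_system")
    post <- infer_posterior(sys, pv, nv)
    oracle <- ridge_qr(X, y, pv, nv)
    expect_lt(max(abs(post$mean - oracle)) / max(abs(oracle)), 1e-8)
  }
})

test_that("duplicating rows is equivalent to halving their noise variance", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  s1 <- structure(list(design = rbind(X, X), response = c(y, y)),
                  class = "regression_system")
  s2 <- structure(list(design = X, response = y), class = "regression_system")
  p1 <- infer_posterior(s1, prior_var = 10, noise_var = 1)
  p2 <- infer_posterior(s2, prior_var = 10, noise_var = 0.5)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-10)
  expect_equal(p1$covariance, p2$covariance, tolerance = 1e-10)
})

test_that("field prediction evaluates the posterior and respects the prior bound", {
  b <- multiscale_basis(ext500, c(3, 3), 100)
  # zero posterior mean -> zero field
  post0 <- structure(list(mean = rep(0, nrow(b)), covariance = diag(nrow(b)),
                          prior_var = 1, noise_var = 1, basis = b, n_rows = 0),
                     class = "field_posterior")
  f0 <- predict_field(post0, grid_shape = c(20, 20))
  expect_true(all(f0$values == 0))

  # single basis, theta = 2: mean at the centre is 2
  b1 <- tibble::tibble(x = 250, y = 250, width = 50, scale = "fine")
  attr(b1, "extent") <- ext500
  post1 <- structure(list(mean = 2, covariance = matrix(0.1), prior_var = 1,
                          noise_var = 1, basis = b1, n_rows = 5),
                     class = "field_posterior")
  f1 <- predict_field(post1, grid_shape = c(21, 21))
  expect_equal(f1$values[11, 11], 2)

  # in the no-data limit variance(s) = prior_var * sum phi_i(s)^2 exactly,
  # and predictive variance is never negative
  pv <- 3.5
  sys0 <- structure(list(design = matrix(numeric(), 0, nrow(b)),
                         response = numeric(), basis = b),
                    class = "regression_system")
  fprior <- predict_field(infer_posterior(sys0, prior_var = pv), c(15, 15))
  phi <- eval_basis(b, tibble::as_tibble(fprior)[, c("x", "y")])
  expect_equal(as.vector(fprior$variance), pv * rowSums(phi^2),
               tolerance = 1e-10)
  expect_true(all(fprior$variance >= 0))
})

test_that("normalisation maps masked values as stated and clipping is display-only", {
  f <- scalar_field(matrix(c(2, 4, 6, 100), 2, 2), c(0, 1, 0, 1),
                    mask = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  n <- normalize_field(f, "unit_range")
  expect_equal(sort(n$values[n$mask]), c(0, 0.5, 1))

  already <- scalar_field(matrix(seq(0, 1, length.out = 9), 3, 3), c(0, 1, 0, 1))
  expect_equal(normalize_field(already, "unit_range")$values, already$values)

  fr <- normalize_field(scalar_field(matrix(c(-30, 0, 55, 20), 2, 2),
                                     c(0, 1, 0, 1)),
                        "fixed_range", range = c(-20, 40))
  disp <- field_display_values(fr)
  expect_equal(disp[1, 2], 40)  # 55 displayed clipped
  expect_equal(fr$values[1, 2], 55) # stored value unchanged
  expect_equal(disp[1, 1], -20)

  const <- scalar_field(matrix(1, 3, 3), c(0, 1, 0, 1))
  expect_error(normalize_field(const, "unit_range"), "distinct")
})

test_that("tidy and glance summarise the posterior per basis function", {
  b <- multiscale_basis(ext500, c(2, 2), 100)
  set.seed(3)
  kin <- tibble::tibble(track_id = 1L, frame = 0:9,
                        x = seq(50, 450, length.out = 10),
                        y = seq(50, 450, length.out = 10),
                        vx = 1, vy = 1)
  post <- infer_posterior(assemble_regression(kin, b))
  td <- tidy(post)
  expect_equal(nrow(td), nrow(b))
  expect_true(all(c("term", "estimate", "std.error", "scale") %in% names(td)))
  expect_true(all(td$std.error > 0))
  gl <- glance(post)
  expect_equal(gl$n_basis, nrow(b))
  expect_equal(gl$n_rows, 9)
})
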