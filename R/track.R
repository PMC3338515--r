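#' Pyramid reduction of an image
#'
#' Each level averages every 2 x 2 block of contiguous pixels into one pixel,
#' halving the number of rows and columns. One level takes a 1000 x 1000
#' frame to 500 x 500, cutting segmentation cost fourfold per level while
#' also suppressing pixel noise. Odd dimensions are padded by edge
#' replication before averaging (reported via a message).
#'
#' @param image numeric matrix.
#' @param levels integer >= 0; number of halvings.
#' @return numeric matrix of size `dim(image) / 2^levels` (up to padding).
#' @export
pyramid_reduce <- function(image, levels = 1L) {
  levels <- as.integer(levels)
  if (levels < 0) stop_config("`levels` must be >= 0.")
  x <- as.matrix(image)
  for (l in seq_len(levels)) {
    if (nrow(x) %% 2L == 1L) {
      inform("pyramid_reduce: padding odd row dimension by edge replication.")
      x <- rbind(x, x[nrow(x), , drop = FALSE])
    }
    if (ncol(x) %% 2L == 1L) {
      inform("pyramid_reduce: padding odd column dimension by edge replication.")
      x <- cbind(x, x[, ncol(x), drop = FALSE])
    }
    ri <- seq(1L, nrow(x), by = 2L)
    ci <- seq(1L, ncol(x), by = 2L)
    x <- (x[ri, ci, drop = FALSE] + x[ri + 1L, ci, drop = FALSE] +
            x[ri, ci + 1L, drop = FALSE] + x[ri + 1L, ci + 1L, drop = FALSE]) / 4
  }
  x
}

#' Hysteresis segmentation with Otsu thresholds
#'
#' Two-threshold segmentation of fluorescent cells: pixels at or above the
#' high threshold are foreground seeds; pixels between the low and high
#' thresholds are foreground only if 8-connected to a seed. The high threshold
#' is Otsu's threshold on the intensity data and the low threshold is Otsu's
#' threshold computed on `log(image + 1)` (mapped back to intensity), which
#' places it below the high threshold on typical bright-cell/dark-background
#' frames. Connected foreground components are labelled and summarised as
#' detections with intensity-unweighted centroids.
#'
#' @param image numeric matrix (a single frame). A constant image yields zero
#'   detections rather than an error.
#' @param frame 0-based frame index recorded in the detections.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `detections`, a tibble `frame, x, y, area, label` with centroids in
#'   0-based pixel coordinates (x = column, y = row, origin top-left).
#' @export
hysteresis_segment <- function(image, frame = 0L) {
  image <- as.matrix(image)
  empty <- list(
    labels = matrix(0L, nrow(image), ncol(image)),
    detections = tibble(frame = integer(), x = numeric(), y = numeric(),
                        area = numeric(), label = integer())
  )
  rng <- range(image)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(empty)

  high <- EBImage::otsu(image, range = rng, levels = 256)
  logim <- log1p(image - rng[1])
  lrng <- range(logim)
  low <- if (diff(lrng) > 0) {
    expm1(EBImage::otsu(logim, range = lrng, levels = 256)) + rng[1]
  } else {
    high
  }
  low <- min(low, high)

  seeds <- image >= high
  fg <- image >= low
  if (!any(seeds)) return(empty)

  labels <- label_components_8(fg)
  keep <- sort(unique(labels[seeds]))
  keep <- keep[keep > 0L]
  labels[!(labels %in% keep)] <- 0L
  # relabel 1..K in raster order for determinism
  relab <- match(labels, c(0L, keep)) - 1L
  labels <- matrix(as.integer(relab), nrow(image), ncol(image))

  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[idx]
  det <- tibble(row = idx[, 1], col = idx[, 2], label = lab) |>
    group_by(.data$label) |>
    summarise(
      x = mean(.data$col) - 1, y = mean(.data$row) - 1, area = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(frame = as.integer(frame)) |>
    select("frame", "x", "y", "area", "label")
  list(labels = labels, detections = det)
}

# 8-connected component labelling of a logical matrix via igraph.
label_components_8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  ids <- which(fg)
  out <- matrix(0L, nr, nc)
  if (!length(ids)) return(out)
  pos <- matrix(0L, nr * nc, 1)
  pos[ids] <- seq_along(ids)
  r <- ((ids - 1L) %% nr) + 1L
  cc <- ((ids - 1L) %/% nr) + 1L
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    r2 <- r + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    has <- fg[nb]
    edges[[length(edges) + 1L]] <- cbind(pos[ids[ok][has]], pos[nb[has]])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    if (is.null(e) || !nrow(e)) matrix(integer(), 0, 2) else e,
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out[ids] <- as.integer(comp)
  out
}

#' Keyhole linking parameters
#'
#' The keyhole model predicts a cell's most probable landing position by
#' linear extrapolation from its two preceding positions. A candidate
#' detection continues the track if it falls inside a narrow wedge (default
#' 60 degrees) oriented towards the prediction — encoding persistent motion —
#' or inside the complementary truncated circle (default 300 degrees) around
#' the last position, which admits direction changes at moderate speed.
#'
#' @param wedge_angle full wedge opening angle, degrees.
#' @param circle_angle complementary circle angle, degrees; must sum to 360
#'   with `wedge_angle`.
#' @param wedge_length_factor wedge length as a multiple of the predicted
#'   displacement.
#' @param circle_radius truncated-circle radius, px.
#' @param min_area single-detection tracks with area below this (px^2) are
#'   discarded as noise during [backward_repair()].
#' @return list of class `keyhole_params`.
#' @export
keyhole_params <- function(wedge_angle = 60, circle_angle = 300,
                           wedge_length_factor = 3, circle_radius = 20,
                           min_area = 2) {
  if (abs(wedge_angle + circle_angle - 360) > 1e-8) {
    stop_config("wedge_angle + circle_angle must equal 360 degrees.")
  }
  if (wedge_length_factor <= 0 || circle_radius <= 0) {
    stop_config("Keyhole lengths must be positive.")
  }
  structure(
    list(wedge_angle = wedge_angle, circle_angle = circle_angle,
         wedge_length_factor = wedge_length_factor,
         circle_radius = circle_radius, min_area = min_area),
    class = "keyhole_params"
  )
}

# Score one candidate against a track history (last, and prev if available).
# Returns c(class, dist): class 0 = wedge (beats circle), 1 = circle,
# Inf = reject; dist = distance to prediction (wedge) or to last point
# (circle). The wedge encodes the most probable landing position.
keyhole_score <- function(last, prev, cand, params) {
  vec <- cand - last
  r <- sqrt(sum(vec^2))
  if (!is.null(prev)) {
    pred_disp <- last - prev
    plen <- sqrt(sum(pred_disp^2))
    if (plen > 1e-9) {
      pred <- last + pred_disp
      cosang <- sum(vec * pred_disp) / (r * plen)
      ang <- if (r < 1e-12) 0 else acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang <= params$wedge_angle / 2 &&
          r <= params$wedge_length_factor * plen) {
        return(c(0, sqrt(sum((cand - pred)^2))))
      }
    }
  }
  if (r <= params$circle_radius) return(c(1, r))
  c(Inf, Inf)
}

#' Link detections across frames with the keyhole model
#'
#' Builds centroid tracks frame by frame. For each track active at the
#' previous frame, candidate detections are scored against the keyhole
#' (see [keyhole_params()]); wedge matches beat circle matches and ties are
#' broken by distance, so linking is invariant to the ordering of detections
#' within a frame. Each detection joins at most one track; unlinked
#' detections start new tracks. Tracks with a single point so far accept the
#' nearest detection within the circle radius.
#'
#' @param detections tibble `frame, x, y` (optionally `area`), 0-based frames.
#' @param params a [keyhole_params()].
#' @return tibble `track_id, frame, x, y, area` ordered by track then frame.
#' @export
keyhole_link <- function(detections, params = keyhole_params()) {
  empty <- tibble(track_id = integer(), frame = integer(), x = numeric(),
                  y = numeric(), area = numeric())
  if (is.null(detections) || !nrow(detections)) return(empty)
  if (!"area" %in% names(detections)) detections$area <- NA_real_
  detections <- arrange(detections, .data$frame, .data$x, .data$y)

  tracks <- list()   # each: list(frames=, x=, y=, area=)
  active <- integer() # indices of tracks extendable at the previous frame
  frames <- sort(unique(detections$frame))

  for (f in frames) {
    dets <- detections[detections$frame == f, , drop = FALSE]
    nd <- nrow(dets)
    # score all (active track, detection) pairs
    cand <- NULL
    if (length(active) && nd) {
      cand <- purrr::map_dfr(seq_along(active), function(ti) {
        tr <- tracks[[active[ti]]]
        npt <- length(tr$frames)
        last <- c(tr$x[npt], tr$y[npt])
        prev <- if (npt >= 2) c(tr$x[npt - 1], tr$y[npt - 1]) else NULL
        sc <- t(vapply(seq_len(nd), function(di) {
          keyhole_score(last, prev, c(dets$x[di], dets$y[di]), params)
        }, numeric(2)))
        tibble(ti = ti, di = seq_len(nd), class = sc[, 1], dist = sc[, 2])
      })
      cand <- cand[is.finite(cand$dist), , drop = FALSE]
      cand <- cand[order(cand$class, cand$dist, cand$ti, cand$di), , drop = FALSE]
    }
    used_t <- logical(length(active)); used_d <- logical(nd)
    if (!is.null(cand) && nrow(cand)) {
      for (i in seq_len(nrow(cand))) {
        ti <- cand$ti[i]; di <- cand$di[i]
        if (used_t[ti] || used_d[di]) next
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        k <- active[ti]
        tracks[[k]]$frames <- c(tracks[[k]]$frames, f)
        tracks[[k]]$x <- c(tracks[[k]]$x, dets$x[di])
        tracks[[k]]$y <- c(tracks[[k]]$y, dets$y[di])
        tracks[[k]]$area <- c(tracks[[k]]$area, dets$area[di])
      }
    }
    new_active <- active[used_t]
    for (di in which(!used_d)) {
      tracks[[length(tracks) + 1L]] <- list(
        frames = f, x = dets$x[di], y = dets$y[di], area = dets$area[di]
      )
      new_active <- c(new_active, length(tracks))
    }
    active <- new_active
  }
  tracks_to_tibble(tracks)
}

tracks_to_tibble <- function(tracks) {
  if (!length(tracks)) {
    return(tibble(track_id = integer(), frame = integer(), x = numeric(),
                  y = numeric(), area = numeric()))
  }
  purrr::map_dfr(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    tibble(track_id = i, frame = as.integer(tr$frames),
           x = tr$x, y = tr$y, area = tr$area)
  })
}

tibble_to_tracks <- function(tb) {
  tb <- arrange(tb, .data$track_id, .data$frame)
  if (!"area" %in% names(tb)) tb$area <- NA_real_
  lapply(split(tb, tb$track_id), function(d) {
    list(frames = d$frame, x = d$x, y = d$y, area = d$area)
  })
}

#' Backward-pass track repair
#'
#' Runs the keyhole model in the backwards time direction to join track
#' sections split in error: a track ending at frame `k` is merged with one
#' starting at frame `k + 1` when the time-reversed keyhole prediction from
#' the start of the later track accepts the end of the earlier one. After
#' merging, single-point tracks whose detection area falls below
#' `params$min_area` are discarded as segmentation noise. The pass is
#' idempotent on an already-consistent track set.
#'
#' @param tracks tibble `track_id, frame, x, y[, area]`.
#' @param params a [keyhole_params()].
#' @return repaired tracks tibble with renumbered `track_id`.
#' @export
backward_repair <- function(tracks, params = keyhole_params()) {
  trl <- tibble_to_tracks(tracks)
  if (!length(trl)) return(tracks_to_tibble(trl))

  repeat {
    merged <- FALSE
    ends <- vapply(trl, function(t) t$frames[length(t$frames)], numeric(1))
    starts <- vapply(trl, function(t) t$frames[1], numeric(1))
    # candidate junctions: A ends at f, B starts at f + 1
    best <- NULL
    for (bi in seq_along(trl)) {
      ai_all <- which(ends == starts[bi] - 1L)
      if (!length(ai_all)) next
      B <- trl[[bi]]
      last <- c(B$x[1], B$y[1])
      prev <- if (length(B$frames) >= 2) c(B$x[2], B$y[2]) else NULL
      for (ai in ai_all) {
        if (ai == bi) next
        A <- trl[[ai]]
        na <- length(A$frames)
        sc <- keyhole_score(last, prev, c(A$x[na], A$y[na]), params)
        if (is.finite(sc[2]) &&
            (is.null(best) || sc[1] < best$class ||
             (sc[1] == best$class && sc[2] < best$dist))) {
          best <- list(ai = ai, bi = bi, class = sc[1], dist = sc[2])
        }
      }
    }
    if (is.null(best)) break
    A <- trl[[best$ai]]; B <- trl[[best$bi]]
    trl[[best$ai]] <- list(frames = c(A$frames, B$frames),
                           x = c(A$x, B$x), y = c(A$y, B$y),
                           area = c(A$area, B$area))
    trl[[best$bi]] <- NULL
    merged <- TRUE
    if (!merged) break
  }

  keep <- vapply(trl, function(t) {
    length(t$frames) > 1L || is.na(t$area[1]) || t$area[1] >= params$min_area
  }, logical(1))
  tracks_to_tibble(trl[keep])
}

#' Segment and track a fluorescence stack
#'
#' Full tracking stage: optional z-projection, pyramid reduction, hysteresis
#' Otsu segmentation per frame, keyhole linking, and backward repair.
#' Centroids found on the reduced grid are rescaled by `2^levels` back to
#' original-image pixels (areas by `4^levels`).
#'
#' @param stack numeric array `rows x cols x frames`, or a list of matrices.
#' @param levels pyramid levels (default 1: e.g. 1000 x 1000 -> 500 x 500).
#' @param params a [keyhole_params()] interpreted on the reduced grid.
#' @param verbose log per-frame detection counts via [message()].
#' @return tracks tibble `track_id, frame, x, y, area` in original-image px.
#' @export
track_stack <- function(stack, levels = 1L, params = keyhole_params(),
                        verbose = FALSE) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) != 3) stop_data("`stack` must be rows x cols x frames.")
  nf <- dim(stack)[3]
  dets <- purrr::map_dfr(seq_len(nf), function(f) {
    red <- pyramid_reduce(stack[, , f], levels)
    d <- hysteresis_segment(red, frame = f - 1L)$detections
    if (verbose) message(sprintf("frame %d: %d detections", f - 1L, nrow(d)))
    d
  })
  tr <- keyhole_link(dets, params)
  tr <- backward_repair(tr, params)
  scale <- 2^levels
  mutate(tr, x = .data$x * scale, y = .data$y * scale,
         area = .data$area * scale^2)
}

#' Maximum- or mean-intensity projection of a z-stack over time
#'
#' Collapses a `rows x cols x z x t` array (or a `rows x cols x (z*t)` array
#' with `z_per_t` slices per time point, pages ordered z-fastest) to a
#' `rows x cols x t` stack.
#'
#' @param stack 4-D array, or 3-D array with `z_per_t` > 1.
#' @param projection `"max"` or `"mean"`.
#' @param z_per_t slices per time point for 3-D input.
#' @return 3-D array `rows x cols x t`.
#' @export
project_stack <- function(stack, projection = c("max", "mean"), z_per_t = 1L) {
  projection <- match.arg(projection)
  fun <- if (projection == "max") max else mean
  d <- dim(stack)
  if (length(d) == 4) {
    t_idx <- seq_len(d[4])
    out <- array(0, c(d[1], d[2], d[4]))
    for (t in t_idx) out[, , t] <- apply(stack[, , , t, drop = FALSE], c(1, 2), fun)
    return(out)
  }
  if (length(d) != 3) stop_data("`stack` must be 3-D or 4-D.")
  z_per_t <- as.integer(z_per_t)
  if (z_per_t <= 1L) return(stack)
  if (d[3] %% z_per_t != 0L) stop_data("Number of pages not divisible by z_per_t.")
  nt <- d[3] %/% z_per_t
  out <- array(0, c(d[1], d[2], nt))
  for (t in seq_len(nt)) {
    sl <- stack[, , ((t - 1L) * z_per_t + 1L):(t * z_per_t), drop = FALSE]
    out[, , t] <- apply(sl, c(1, 2), fun)
  }
  out
}
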