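#' Read and write centroid track tables
#'
#' Tracks are exchanged as CSV with header `track_id,frame,x,y` (x = column,
#' y = row, pixel units, origin top-left, 0-based frames). Extra columns
#' (e.g. `area`, `vx`, `vy`) are preserved.
#'
#' @param path file path.
#' @param tracks a tracks or kinematics tibble.
#' @return `read_tracks()`: a tibble. `write_tracks()`: `path`, invisibly.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("Input path does not exist: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(out))) {
    stop_data(sprintf("Track CSV must have columns %s.", paste(need, collapse = ", ")))
  }
  mutate(out, track_id = as.integer(.data$track_id), frame = as.integer(.data$frame))
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tracks, path, progress = FALSE)
  invisible(path)
}

#' Read and write multi-page TIFF stacks
#'
#' `read_stack()` loads a multi-page TIFF as a `rows x cols x pages` array
#' (an optional z dimension is collapsed with [project_stack()]).
#' `write_stack()` writes one page per frame; TIFF sample values must lie in
#' [0, 1], so frames are clipped to that range (with a warning if clipping
#' changed anything).
#'
#' @param path TIFF file path.
#' @param z_per_t z-slices per time point (pages ordered z-fastest).
#' @param projection how to collapse z, `"max"` or `"mean"`.
#' @param stack numeric array `rows x cols x frames`.
#' @param bits_per_sample TIFF bit depth (8 or 16).
#' @return `read_stack()`: a 3-D array. `write_stack()`: `path`, invisibly.
#' @export
read_stack <- function(path, z_per_t = 1L, projection = "max") {
  if (!file.exists(path)) stop_config(sprintf("Input path does not exist: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  stack <- simplify2array(pages)
  project_stack(stack, projection = projection, z_per_t = z_per_t)
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path, bits_per_sample = 16L) {
  if (is.list(stack)) stack <- simplify2array(stack)
  clipped <- pmin(pmax(stack, 0), 1)
  if (max(abs(clipped - stack)) > 0) {
    warn("write_stack: values outside [0, 1] were clipped for TIFF output.")
  }
  frames <- lapply(seq_len(dim(clipped)[3]), function(k) clipped[, , k])
  tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

#' Write a field as TIFF (unit-range) and exact CSV
#'
#' The TIFF holds the unit-range-normalised field (TIFF samples must lie in
#' [0, 1]); the exact values go to a flat CSV `x,y,value,mask[,variance]` and
#' the true value range is returned so callers can record it.
#'
#' @param field a [scalar_field].
#' @param tiff_path,csv_path output paths (either may be `NULL` to skip).
#' @return list with the written paths and the field `value_range`.
#' @export
write_field <- function(field, tiff_path = NULL, csv_path = NULL) {
  rng <- range(field$values[field$mask])
  if (!is.null(tiff_path)) {
    v <- if (diff(rng) > 0) (field$values - rng[1]) / diff(rng) else field$values * 0
    v[!field$mask] <- 0
    tiff::writeTIFF(pmin(pmax(v, 0), 1), tiff_path, bits.per.sample = 16L)
  }
  if (!is.null(csv_path)) {
    readr::write_csv(as_tibble(field), csv_path, progress = FALSE)
  }
  list(tiff = tiff_path, csv = csv_path, value_range = rng)
}

#' Read a binary mask image
#'
#' Reads a PNG or TIFF and thresholds it at half its maximum to a logical
#' mask (`TRUE` = inside domain).
#'
#' @param path image path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("Input path does not exist: %s", path))
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > max(img) / 2
}
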