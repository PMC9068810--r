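#' Render event logs into a TIRF-like two-half-field image stack
#'
#' Each bound fluorophore is drawn as a 2D Gaussian of s.d. `psf_sigma`
#' whose total (infinite-plane) integral equals `unit_intensity`, centred at
#' the molecule's Cy3 position (left half-field) or at its
#' `channel_transform`-mapped Cy5 position (right half-field).  Per-pixel
#' background is `background_pre` on the Cy3 half and steps from
#' `background_pre` to `background_post` on the Cy5 half at `flow_frame`;
#' Gaussian noise of s.d. `noise_sd` is added per pixel.  Excitation and
#' bleaching follow [render_traces()]: the same occupancy realisation is used
#' for both, so AOI-integrated movie intensities match the corresponding
#' traces up to PSF truncation (backgrounds scale with the box area).
#'
#' @param logs List of `event_log` objects.
#' @param acq An [acquisition_params()] object.
#' @param positions Numeric matrix (n x 2) of Cy3 spot centres `(x, y)`,
#'   0-based pixel coordinates, inside the left half-field.
#' @param rng_seed Optional integer seed.
#' @return 3D numeric array `[frame, row, col]` of intensities (a.u.), with
#'   attributes `acq`, `positions`, `positions_cy5`.
#' @export
render_movie <- function(logs, acq, positions, rng_seed = NULL) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  h <- acq$field_size[1]; w <- acq$field_size[2]
  half_w <- w / 2
  if (length(logs)) {
    positions <- matrix(positions, ncol = 2)
    if (nrow(positions) != length(logs))
      stop("need one (x, y) position per event log")
    if (any(positions[, 1] < 0) || any(positions[, 1] >= half_w) ||
        any(positions[, 2] < 0) || any(positions[, 2] >= h))
      stop("positions must lie inside the Cy3 (left) half-field")
  } else positions <- matrix(numeric(0), ncol = 2)
  tr <- acq$channel_transform
  pos_cy5 <- if (nrow(positions))
    t(tr$A %*% t(positions) + tr$b) else positions
  if (nrow(positions) &&
      (any(pos_cy5[, 1] < 0) || any(pos_cy5[, 1] >= w) ||
       any(pos_cy5[, 2] < 0) || any(pos_cy5[, 2] >= h)))
    stop("channel_transform maps a position outside the field")

  n <- acq$n_frames
  mask <- excitation_mask(acq)
  dt <- acq$frame_interval
  mid <- (seq_len(n) - 0.5) * dt

  # per-molecule per-frame fluorophore counts (bleaching included), reusing
  # the trace renderer so trace/movie realisations agree
  occ3 <- matrix(0L, n, max(1L, length(logs)))
  occ5 <- matrix(0L, n, max(1L, length(logs)))
  for (m in seq_along(logs)) {
    trm <- render_traces(logs[[m]], within_acq_noise_free(acq))
    u <- acq$unit_intensity
    occ3[, m] <- as.integer(round((trm$cy3$intensity - attr(trm$cy3, "baseline")) / u))
    occ5[, m] <- as.integer(round((trm$cy5$intensity - attr(trm$cy5, "baseline")) / u))
  }

  # precompute integer-grid Gaussian patches per molecule and channel
  patch_r <- max(3L, ceiling(4 * acq$psf_sigma))
  mk_patch <- function(cx, cy) {
    xs <- (floor(cx) - patch_r):(floor(cx) + patch_r)
    ys <- (floor(cy) - patch_r):(floor(cy) + patch_r)
    gx <- exp(-((xs - cx)^2) / (2 * acq$psf_sigma^2))
    gy <- exp(-((ys - cy)^2) / (2 * acq$psf_sigma^2))
    g <- outer(gy, gx) / (2 * pi * acq$psf_sigma^2)   # rows = y, cols = x
    keep_y <- ys >= 0 & ys < h; keep_x <- xs >= 0 & xs < w
    list(rows = ys[keep_y] + 1L, cols = xs[keep_x] + 1L,
         g = g[keep_y, keep_x, drop = FALSE])
  }
  patches3 <- lapply(seq_len(nrow(positions)), function(m)
    mk_patch(positions[m, 1], positions[m, 2]))
  patches5 <- lapply(seq_len(nrow(positions)), function(m)
    mk_patch(pos_cy5[m, 1], pos_cy5[m, 2]))

  cols_cy3 <- seq_len(half_w)
  bg5 <- ifelse(seq_len(n) - 1L >= acq$flow_frame,
                acq$background_post, acq$background_pre)
  stack <- array(0, dim = c(n, h, w))
  u <- acq$unit_intensity
  for (f in seq_len(n)) {
    frame <- matrix(acq$background_pre, h, w)
    frame[, -cols_cy3] <- bg5[f]
    for (m in seq_along(logs)) {
      if (mask[f, "cy3"] && occ3[f, m] > 0) {
        p <- patches3[[m]]
        frame[p$rows, p$cols] <- frame[p$rows, p$cols] + u * occ3[f, m] * p$g
      }
      if (mask[f, "cy5"] && occ5[f, m] > 0) {
        p <- patches5[[m]]
        frame[p$rows, p$cols] <- frame[p$rows, p$cols] + u * occ5[f, m] * p$g
      }
    }
    if (acq$noise_sd > 0)
      frame <- frame + matrix(stats::rnorm(h * w, 0, acq$noise_sd), h, w)
    stack[f, , ] <- frame
  }
  structure(stack, acq = acq, positions = positions, positions_cy5 = pos_cy5)
}

# same acquisition without per-sample noise/bleach randomness is handled by
# render_traces itself; the movie renderer only needs noise off in the
# per-molecule occupancy pass
within_acq_noise_free <- function(acq) { acq$noise_sd <- 0; acq }

#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' Intensities are linearly scaled by `scale` (a.u. per full 16-bit range),
#' clipped to `[0, 1]`, and written uncompressed.
#'
#' @param stack 3D array `[frame, row, col]` from [render_movie()].
#' @param file Output TIFF path.
#' @param scale Full-scale intensity in a.u.; defaults to slightly above the
#'   stack maximum.
#' @return `file` invisibly, with the scale stored in attribute `"scale"`.
#' @export
write_movie_tiff <- function(stack, file, scale = NULL) {
  if (is.null(scale)) scale <- max(stack) * 1.05
  n <- dim(stack)[1]
  pages <- lapply(seq_len(n), function(f)
    pmin(pmax(stack[f, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, file, bits.per.sample = 16L, compression = "none")
  attr(file, "scale") <- scale
  invisible(file)
}

#' Read a multi-page TIFF back into an image stack
#'
#' @param file TIFF path written by [write_movie_tiff()].
#' @param scale Full-scale intensity in a.u. used when writing.
#' @return 3D numeric array `[frame, row, col]` in a.u.
#' @export
read_movie_tiff <- function(file, scale = 1) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  n <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  stack <- array(0, dim = c(n, h, w))
  for (f in seq_len(n)) stack[f, , ] <- pages[[f]] * scale
  stack
}
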