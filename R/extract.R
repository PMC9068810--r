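#' Detect single-molecule spots in a reference image
#'
#' Finds local maxima above `background mean + detection_threshold x SD`
#' (background statistics estimated robustly via median/MAD) and refines each
#' to a subpixel centroid over the surrounding box.  Coordinates are 0-based
#' `(x, y) = (column, row)`.
#'
#' @param reference_image 2D numeric matrix, typically the mean of the first
#'   both-excited frames of a movie (see [reference_image()]).
#' @param detection_threshold Threshold in multiples of the background SD.
#' @param box_halfwidth Halfwidth of the centroid box in pixels.
#' @return Numeric matrix (n x 2) of `(x, y)` centres; zero rows if nothing
#'   is detected.  A warning is logged if >= 1% of pixels sit at the image
#'   maximum (saturation).
#' @export
detect_spots <- function(reference_image, detection_threshold = 5,
                         box_halfwidth = 2) {
  img <- reference_image
  stopifnot(is.matrix(img))
  if (mean(img == max(img)) >= 0.01)
    warning("reference image looks saturated (>= 1% of pixels at maximum)")
  bg_mean <- stats::median(img)
  bg_sd <- stats::mad(img)
  if (bg_sd == 0) bg_sd <- stats::sd(img)
  thr <- bg_mean + detection_threshold * bg_sd
  h <- nrow(img); w <- ncol(img)
  # 3x3 local maxima above threshold (strict against already-found maxima is
  # handled by >= plus coincidence merging below)
  cand <- which(img > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rs <- max(1, r - 1):min(h, r + 1)
    cs <- max(1, c - 1):min(w, c + 1)
    keep[i] <- img[r, c] == max(img[rs, cs])
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))))
  # subpixel centroid over the box, background-subtracted
  hw <- box_halfwidth
  centres <- t(apply(cand, 1, function(rc) {
    r <- rc[1]; c <- rc[2]
    rs <- max(1, r - hw):min(h, r + hw)
    cs <- max(1, c - hw):min(w, c + hw)
    patch <- pmax(img[rs, cs, drop = FALSE] - bg_mean, 0)
    tot <- sum(patch)
    if (tot == 0) return(c(c - 1, r - 1))
    cx <- sum(t(patch) * (cs - 1)) / tot       # columns -> x (0-based)
    cy <- sum(patch * (rs - 1)) / tot          # rows -> y
    c(cx, cy)
  }))
  colnames(centres) <- c("x", "y")
  # merge coincident maxima (plateaus / same-pixel duplicates)
  if (nrow(centres) > 1) {
    d <- as.matrix(stats::dist(centres))
    drop <- logical(nrow(centres))
    for (i in seq_len(nrow(centres) - 1))
      if (!drop[i])
        drop[which(d[i, ] < 1 & seq_len(nrow(centres)) > i)] <- TRUE
    centres <- centres[!drop, , drop = FALSE]
  }
  centres
}

#' Mean of the first both-excited frames of a stack
#'
#' @param stack 3D array `[frame, row, col]`.
#' @param n_frames Number of leading frames to average (default 10, the
#'   both-on head of the movie).
#' @return 2D matrix.
#' @export
reference_image <- function(stack, n_frames = 10) {
  n <- min(n_frames, dim(stack)[1])
  m <- stack[1, , ]
  if (n > 1) for (f in 2:n) m <- m + stack[f, , ]
  m / n
}

#' Discard AOIs closer than a minimum separation
#'
#' Every member of any pair closer than `min_separation` is discarded (the
#' experimental rule: AOIs that may contain two or more Hfq are excluded, so
#' neither member of a close pair can be kept).  The result is independent of
#' input ordering.
#'
#' @param centers Numeric matrix (n x 2) of `(x, y)` centres.
#' @param min_separation Minimum pairwise distance in pixels.
#' @return The retained rows of `centers`.
#' @export
filter_aois <- function(centers, min_separation = 5) {
  centers <- matrix(centers, ncol = 2)
  if (nrow(centers) < 2) return(centers)
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  keep <- apply(d, 1, min) > min_separation
  centers[keep, , drop = FALSE]
}

#' Map Cy3 AOI centres into the Cy5 half-field
#'
#' Applies the affine channel transform to each Cy3 centre and builds the AOI
#' table.  AOIs whose Cy3 or mapped Cy5 box would leave the field are dropped
#' and counted.
#'
#' @param centers Numeric matrix (n x 2) of Cy3 `(x, y)` centres.
#' @param transform Affine map `list(A = 2x2, b = length-2)`; must be
#'   invertible.
#' @param field_size `c(height, width)` in pixels.
#' @param box_halfwidth AOI box halfwidth (box side `2*halfwidth + 1`).
#' @return Data frame with columns `id`, `x_cy3`, `y_cy3`, `x_cy5`, `y_cy5`,
#'   `box_halfwidth`; attribute `n_dropped` counts out-of-field AOIs.
#' @export
map_channels <- function(centers, transform, field_size,
                         box_halfwidth = 2) {
  centers <- matrix(centers, ncol = 2)
  if (abs(det(transform$A)) < 1e-12)
    stop("channel transform is singular")
  mapped <- if (nrow(centers))
    t(transform$A %*% t(centers) + transform$b)
  else centers
  h <- field_size[1]; w <- field_size[2]; hw <- box_halfwidth
  inside <- function(p) {
    round(p[, 1]) - hw >= 0 & round(p[, 1]) + hw <= w - 1 &
      round(p[, 2]) - hw >= 0 & round(p[, 2]) + hw <= h - 1
  }
  ok <- if (nrow(centers)) inside(centers) & inside(mapped) else logical(0)
  aois <- data.frame(id = sprintf("aoi_%d", seq_len(sum(ok))),
                     x_cy3 = centers[ok, 1], y_cy3 = centers[ok, 2],
                     x_cy5 = mapped[ok, 1], y_cy5 = mapped[ok, 2],
                     box_halfwidth = hw, stringsAsFactors = FALSE)
  attr(aois, "n_dropped") <- sum(!ok)
  aois
}

#' Integrate an AOI over an image stack
#'
#' Sums intensity per frame over the `(2*halfwidth + 1)^2` box centred at the
#' rounded AOI centre of the requested channel, and estimates a per-frame
#' local baseline from the median of an annulus two to four pixels outside
#' the box (scaled to the box area).
#'
#' @param stack 3D array `[frame, row, col]` with an `acq` attribute (as
#'   returned by [render_movie()]), or any stack plus an explicit `acq`.
#' @param aoi One row of the [map_channels()] table.
#' @param channel `"cy3"` or `"cy5"`.
#' @param acq [acquisition_params()] describing the stack (defaults to the
#'   stack's own attribute).
#' @return An `intensity_trace` data frame (`frame`, `time_s`, `intensity`,
#'   `excited`) with the annulus baseline in attribute `baseline`.
#' @export
integrate_aoi <- function(stack, aoi, channel = c("cy3", "cy5"), acq = NULL) {
  channel <- match.arg(channel)
  if (is.null(acq)) acq <- attr(stack, "acq")
  if (is.null(acq)) stop("no acquisition metadata supplied for the stack")
  cx <- round(aoi[[paste0("x_", channel)]])
  cy <- round(aoi[[paste0("y_", channel)]])
  hw <- aoi$box_halfwidth
  h <- dim(stack)[2]; w <- dim(stack)[3]
  if (cx - hw < 0 || cx + hw > w - 1 || cy - hw < 0 || cy + hw > h - 1)
    stop(sprintf("AOI %s box out of bounds on channel %s",
                 as.character(aoi$id), channel))
  rows <- (cy - hw):(cy + hw) + 1L
  cols <- (cx - hw):(cx + hw) + 1L
  n <- dim(stack)[1]
  box_area <- length(rows) * length(cols)
  intensity <- apply(stack[, rows, cols, drop = FALSE], 1, sum)

  ro <- (max(0, cy - hw - 4)):(min(h - 1, cy + hw + 4)) + 1L
  co <- (max(0, cx - hw - 4)):(min(w - 1, cx + hw + 4)) + 1L
  # annulus = outer window minus an inner guard of box + 1 px
  guard_rows <- (max(0, cy - hw - 1)):(min(h - 1, cy + hw + 1)) + 1L
  guard_cols <- (max(0, cx - hw - 1)):(min(w - 1, cx + hw + 1)) + 1L
  inner <- matrix(FALSE, length(ro), length(co))
  inner[match(intersect(ro, guard_rows), ro),
        match(intersect(co, guard_cols), co)] <- TRUE
  baseline <- vapply(seq_len(n), function(f)
    stats::median(stack[f, ro, co][!inner]) * box_area, numeric(1))
  # the background varies only at the flow step: a running median keeps the
  # step sharp while suppressing per-frame estimation noise
  if (n >= 25) baseline <- stats::runmed(baseline, 25)

  mask <- excitation_mask(acq)
  dt <- acq$frame_interval
  structure(
    data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) * dt,
               intensity = intensity, excited = mask[seq_len(n), channel]),
    channel = channel, frame_interval = dt, baseline = baseline,
    molecule_id = as.character(aoi$id),
    class = c("intensity_trace", "data.frame"))
}

#' Full trace-extraction pass over a movie
#'
#' Detect spots on the reference image, filter close pairs, map channels,
#' and integrate both channels for every retained AOI.
#'
#' @param stack 3D array from [render_movie()] or [read_movie_tiff()].
#' @param acq [acquisition_params()] for the stack.
#' @param detection_threshold,min_separation,box_halfwidth Tuning knobs, see
#'   the individual stage functions.
#' @return List with `aois` (data frame) and `traces` (per-AOI named list of
#'   `list(cy3 =, cy5 =)` traces).
#' @export
extract_traces <- function(stack, acq = attr(stack, "acq"),
                           detection_threshold = 5, min_separation = 5,
                           box_halfwidth = 2) {
  ref <- reference_image(stack, acq$both_on_head)
  # detect on the Cy3 (left) half-field only
  half_w <- acq$field_size[2] / 2
  centres <- detect_spots(ref[, seq_len(half_w), drop = FALSE],
                          detection_threshold, box_halfwidth)
  centres <- filter_aois(centres, min_separation)
  aois <- map_channels(centres, acq$channel_transform, acq$field_size,
                       box_halfwidth)
  traces <- lapply(seq_len(nrow(aois)), function(i) {
    aoi <- aois[i, , drop = FALSE]
    list(cy3 = integrate_aoi(stack, aoi, "cy3", acq),
         cy5 = integrate_aoi(stack, aoi, "cy5", acq))
  })
  names(traces) <- aois$id
  list(aois = aois, traces = traces)
}
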