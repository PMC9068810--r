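#' Detect the competitor flow time from the Cy5 background step
#'
#' The arrival of the competitor solution raises the Cy5 background.  The
#' Cy5-excited samples are median-filtered (window `runmed_k`) to suppress
#' binding events, and the change point minimizing the two-segment squared
#' error of the filtered background is located.  The flow time is reported on
#' the global clock as the end time of the last pre-step Cy5 sample.
#'
#' Because competitor binding events also raise the Cy5 signal, the change
#' point is taken as the *earliest* significant upward step: after locating
#' the best two-segment split, the search recurses into the left segment as
#' long as a further significant positive step is found there (the flow step
#' always precedes binding steps).
#'
#' @param trace A Cy5 `intensity_trace`.
#' @param runmed_k Odd window width (samples) for the running median.
#' @param min_improvement Minimum fractional reduction of the one-segment
#'   squared error; below this the step is deemed undetectable and an error
#'   is raised (supply the flow time manually in that case).
#' @return Flow time in seconds.
#' @export
detect_flow_time <- function(trace, runmed_k = 51, min_improvement = 0.05) {
  exc <- trace[trace$excited, , drop = FALSE]
  n <- nrow(exc)
  if (n < 10) stop("trace has fewer than 10 excited frames")
  k <- min(runmed_k, if (n %% 2L) n else n - 1L)
  x <- stats::runmed(exc$intensity, k)
  min_step <- 3 * robust_noise_sd(exc$intensity)

  best_split <- function(seg) {
    m <- length(seg)
    if (m < 6L) return(NULL)
    sse1 <- sum((seg - mean(seg))^2)
    cs <- cumsum(seg); cs2 <- cumsum(seg^2)
    i <- seq_len(m - 1L)
    sse_l <- cs2[i] - cs[i]^2 / i
    sse_r <- (cs2[m] - cs2[i]) - (cs[m] - cs[i])^2 / (m - i)
    sse2 <- sse_l + sse_r
    b <- which.min(sse2)
    improvement <- if (sse1 > 0) (sse1 - sse2[b]) / sse1 else 0
    step <- (cs[m] - cs[b]) / (m - b) - cs[b] / b
    if (improvement < min_improvement || step <= 0 || step < min_step)
      return(NULL)
    b
  }

  split <- best_split(x)
  if (is.null(split))
    stop("no detectable Cy5 background step; supply flow_time manually")
  repeat {
    earlier <- best_split(x[seq_len(split)])
    if (is.null(earlier)) break
    split <- earlier
  }
  dt <- attr(trace, "frame_interval")
  exc$time_s[split] + dt   # end of last pre-step sample, global clock
}

# noise SD from first differences: insensitive to plateaus and steps; a
# noise-free trace correctly yields 0
robust_noise_sd <- function(x) {
  s <- stats::median(abs(diff(x))) * 1.4826 / sqrt(2)
  if (is.na(s)) s <- 0
  s
}

#' Segment a trace into bound intervals
#'
#' Works on the channel's own excited-frame timebase (0.2 s effective
#' resolution during alternating excitation).  Hysteresis thresholding:
#' runs of at least `min_frames` frames with
#' `intensity > baseline + threshold_k * sigma` seed intervals, which are
#' then extended outward through contiguous frames above
#' `baseline + sigma` (so single-frame noise dips inside a bound stretch do
#' not split it); remaining dark gaps of up to `gap_frames` excited frames
#' (fluorophore blinking) are bridged.  Intervals touching the first or
#' last excited frame are flagged censored.
#'
#' @param trace An `intensity_trace`.
#' @param baseline Per-frame (full-trace length) or scalar baseline in a.u.;
#'   defaults to the trace's `baseline` attribute.
#' @param sigma Noise s.d. in a.u.; estimated from first differences of the
#'   excited samples when `NULL`.
#' @param threshold_k Threshold in noise SDs above baseline.
#' @param min_frames Minimum run length (excited frames).
#' @param gap_frames Maximum bridged gap (excited frames).
#' @return Data frame of class `bound_intervals`: `channel`, `t_start`,
#'   `t_end` (half-open, seconds, global clock), `stoichiometry` (1 here;
#'   see [quantize_stoichiometry()]), `left_censored`, `right_censored`.
#' @export
segment_trace <- function(trace, baseline = NULL, sigma = NULL,
                          threshold_k = 3, min_frames = 2, gap_frames = 1) {
  exc_idx <- which(trace$excited)
  if (length(exc_idx) < 10) stop("trace has fewer than 10 excited frames")
  x <- trace$intensity[exc_idx]
  if (is.null(baseline)) baseline <- attr(trace, "baseline")
  if (is.null(baseline)) stop("no baseline available for segmentation")
  b <- if (length(baseline) == 1L) rep(baseline, length(exc_idx))
       else baseline[exc_idx]
  if (is.null(sigma)) sigma <- robust_noise_sd(x - b)
  on_high <- x > b + threshold_k * sigma
  on_low <- x > b + sigma

  # seed with min_frames-long high runs, extend edges through low frames
  r <- rle(on_high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- logical(length(x))
  for (j in which(r$values & r$lengths >= min_frames)) {
    i0 <- starts[j]; i1 <- ends[j]
    # extend at most one frame per edge: enough to merge across a
    # two-frame noise dip without inflating boundary errors
    if (i0 > 1L && on_low[i0 - 1L]) i0 <- i0 - 1L
    if (i1 < length(x) && on_low[i1 + 1L]) i1 <- i1 + 1L
    on[i0:i1] <- TRUE
  }

  # bridge short dark gaps between on-runs
  if (gap_frames > 0 && any(on)) {
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values))
      if (!r$values[j] && r$lengths[j] <= gap_frames &&
          j > 1L && j < length(r$values))
        on[starts[j]:ends[j]] <- TRUE
  }

  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  ch <- attr(trace, "channel")
  dt <- attr(trace, "frame_interval")
  t_all <- trace$time_s[exc_idx]
  n_exc <- length(exc_idx)
  # end of an interval = start time of the excited sample after its last
  # on-sample (or last frame end for a censored interval)
  sample_end <- c(t_all[-1], t_all[n_exc] + dt)

  out <- data.frame(
    channel = character(0), t_start = numeric(0), t_end = numeric(0),
    stoichiometry = integer(0), left_censored = logical(0),
    right_censored = logical(0), stringsAsFactors = FALSE)
  for (j in which(keep)) {
    out <- rbind(out, data.frame(
      channel = ch, t_start = t_all[starts[j]], t_end = sample_end[ends[j]],
      stoichiometry = 1L,
      left_censored = starts[j] == 1L,
      right_censored = ends[j] == n_exc, stringsAsFactors = FALSE))
  }
  class(out) <- c("bound_intervals", "data.frame")
  attr(out, "molecule_id") <- attr(trace, "molecule_id")
  attr(out, "sigma") <- sigma
  out
}

#' Estimate the per-fluorophore unit intensity
#'
#' Takes the background-subtracted plateau (mean on-intensity) of each
#' interval and returns the median plateau of the lowest mode of the plateau
#' distribution, i.e. the single-fluorophore brightness even when multi-
#' fluorophore intervals are present.
#'
#' @param traces List of `intensity_trace` objects (any channel mix).
#' @param intervals Optional list of matching `bound_intervals`; segmented
#'   with defaults when `NULL`.
#' @param min_intervals Minimum number of usable intervals (default 20).
#' @return Unit intensity in a.u.
#' @export
estimate_unit_intensity <- function(traces, intervals = NULL,
                                    min_intervals = 20) {
  if (is.null(intervals)) intervals <- lapply(traces, segment_trace)
  plateaus <- numeric(0)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]; iv <- intervals[[i]]
    if (!nrow(iv)) next
    b <- attr(tr, "baseline")
    bvec <- if (length(b) == 1L) rep(b, nrow(tr)) else b
    exc <- tr$excited
    for (j in seq_len(nrow(iv))) {
      sel <- which(exc & tr$time_s >= iv$t_start[j] &
                     tr$time_s < iv$t_end[j])
      # drop the first and last on-sample: partially-occupied edge frames
      # depress the plateau of short intervals
      if (length(sel) >= 4) sel <- sel[-c(1, length(sel))]
      if (length(sel) >= 2)
        plateaus <- c(plateaus, mean(tr$intensity[sel] - bvec[sel]))
    }
  }
  if (length(plateaus) < min_intervals)
    stop(sprintf("need >= %d intervals to estimate unit intensity (got %d)",
                 min_intervals, length(plateaus)))
  if (stats::sd(plateaus) == 0) return(plateaus[1])
  # lowest density mode identifies the single-fluorophore brightness
  d <- tryCatch(stats::density(plateaus, bw = "SJ"),
                error = function(e) stats::density(plateaus))
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (!length(peaks)) return(stats::median(plateaus))
  lowest <- d$x[peaks[1]]
  members <- plateaus[abs(plateaus - lowest) < lowest / 2]
  if (!length(members)) members <- plateaus
  stats::median(members)
}

#' Quantize the stoichiometry of a bound interval
#'
#' Rounds each excited sample's background-subtracted intensity to a
#' fluorophore count (`round(y / unit)`), applies a median-of-3 filter so
#' that single-sample excursions (below the resolvable step size) are
#' discarded while runs of two or more samples survive, and run-length
#' encodes the result into constant-count segments (counts clamped to >= 1
#' with a warning).  The interval's stoichiometry is the maximum segment
#' count.
#'
#' @param interval One row of a `bound_intervals` data frame.
#' @param trace The matching `intensity_trace`.
#' @param unit Unit intensity in a.u. (> 0), e.g. from
#'   [estimate_unit_intensity()].
#' @return List with `counts` (per-segment fluorophore counts), `t_breaks`
#'   (segment boundary times, including interval ends) and `stoichiometry`
#'   (max count).
#' @export
quantize_stoichiometry <- function(interval, trace, unit) {
  stopifnot(unit > 0)
  sel <- which(trace$excited & trace$time_s >= interval$t_start &
                 trace$time_s < interval$t_end)
  b <- attr(trace, "baseline")
  bvec <- if (length(b) == 1L) rep(b, nrow(trace)) else b
  y <- trace$intensity[sel] - bvec[sel]
  tt <- trace$time_s[sel]

  z <- as.integer(round(y / unit))
  if (length(z) >= 3L) z <- as.integer(stats::runmed(z, 3L))
  r <- rle(z)
  ends <- cumsum(r$lengths)
  counts <- r$values
  if (any(counts < 1L)) {
    warning("segment intensity rounds to 0 fluorophores; clamped to 1")
    counts <- pmax(counts, 1L)
    # re-merge segments that became equal after clamping
    r2 <- rle(counts)
    ends <- ends[cumsum(r2$lengths)]
    counts <- r2$values
  }
  breaks <- ends[-length(ends)]            # last sample index per segment
  t_breaks <- c(interval$t_start, tt[breaks + 1L], interval$t_end)
  list(counts = as.integer(counts), t_breaks = t_breaks,
       stoichiometry = max(counts))
}

#' Segment both channels of a molecule and attach stoichiometry
#'
#' Convenience wrapper used by the pipeline: segments the Cy3 and Cy5 traces
#' and, when `unit` is given, quantizes Cy5 stoichiometry (the Cy3 resident
#' is a single fluorophore by construction).
#'
#' @param traces `list(cy3 =, cy5 =)` of `intensity_trace` objects.
#' @param unit Optional unit intensity for Cy5 step counting.
#' @param ... Passed to [segment_trace()].
#' @return `list(cy3 =, cy5 =)` of `bound_intervals`; Cy5 rows gain a
#'   `segments` attribute (list of quantization results, one per interval).
#' @export
segment_molecule <- function(traces, unit = NULL, ...) {
  iv3 <- segment_trace(traces$cy3, ...)
  iv5 <- segment_trace(traces$cy5, ...)
  if (!is.null(unit) && nrow(iv5)) {
    segs <- lapply(seq_len(nrow(iv5)), function(j)
      quantize_stoichiometry(iv5[j, , drop = FALSE], traces$cy5, unit))
    iv5$stoichiometry <- vapply(segs, `[[`, integer(1), "stoichiometry")
    attr(iv5, "segments") <- segs
  }
  list(cy3 = iv3, cy5 = iv5)
}
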