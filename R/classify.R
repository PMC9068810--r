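#' Pair resident and competitor intervals into an occupancy timeline
#'
#' Builds the piecewise-constant state `(resident_bound, competitor_count)`
#' over the movie from the two channels' interval lists.  The competitor
#' count sums the per-segment stoichiometry of all overlapping Cy5 intervals
#' (falling back to 1 per interval when no quantization is attached), so a
#' stepwise Cy5 intensity increase appears as a count step.
#'
#' @param cy3,cy5 `bound_intervals` for one molecule (Cy5 optionally with a
#'   `segments` attribute from [segment_molecule()]).
#' @param t_max Movie end time (seconds); defaults to the largest interval
#'   end.
#' @return Data frame of class `occupancy_timeline`: `t_start`, `t_end`
#'   (half-open), `resident_bound`, `competitor_count`.
#' @export
pair_intervals <- function(cy3, cy5, t_max = NULL) {
  for (iv in list(cy3, cy5)) {
    if (nrow(iv) > 1) {
      o <- order(iv$t_start)
      if (any(iv$t_start[o][-1] < iv$t_end[o][-nrow(iv)] - 1e-9))
        stop("overlapping intervals within one channel")
    }
  }
  if (is.null(t_max))
    t_max <- max(c(cy3$t_end, cy5$t_end, 0))

  # competitor count as a step function: +/- stoichiometry at segment edges
  step_t <- numeric(0); step_d <- numeric(0)
  segs <- attr(cy5, "segments")
  if (nrow(cy5)) for (j in seq_len(nrow(cy5))) {
    if (!is.null(segs)) {
      s <- segs[[j]]
      for (k in seq_along(s$counts)) {
        step_t <- c(step_t, s$t_breaks[k], s$t_breaks[k + 1L])
        step_d <- c(step_d, s$counts[k], -s$counts[k])
      }
    } else {
      step_t <- c(step_t, cy5$t_start[j], cy5$t_end[j])
      step_d <- c(step_d, cy5$stoichiometry[j], -cy5$stoichiometry[j])
    }
  }

  brk <- sort(unique(c(0, t_max, cy3$t_start, cy3$t_end, step_t)))
  brk <- brk[brk <= t_max + 1e-12]
  t0 <- brk[-length(brk)]; t1 <- brk[-1]
  res <- vapply(t0, function(t) any(cy3$t_start <= t + 1e-12 &
                                      cy3$t_end > t + 1e-12), logical(1))
  cnt <- vapply(t0, function(t)
    sum(step_d[step_t <= t + 1e-12]), numeric(1))
  out <- data.frame(t_start = t0, t_end = t1,
                    resident_bound = res,
                    competitor_count = as.integer(round(cnt)))
  # merge consecutive identical states
  same <- c(FALSE, out$resident_bound[-1] == out$resident_bound[-nrow(out)] &
              out$competitor_count[-1] == out$competitor_count[-nrow(out)])
  grp <- cumsum(!same)
  out <- do.call(rbind, lapply(split(out, grp), function(g)
    data.frame(t_start = g$t_start[1], t_end = g$t_end[nrow(g)],
               resident_bound = g$resident_bound[1],
               competitor_count = g$competitor_count[1])))
  rownames(out) <- NULL
  structure(out, t_max = t_max,
            resident_right_censored = any(cy3$right_censored),
            class = c("occupancy_timeline", "data.frame"))
}

#' Competitor association times
#'
#' `t_bind` is the time from the flow event to the start of the first
#' competitor interval that colocalizes with the resident; `t_bind_diss` is
#' the same quantity restricted to the colocalization episode after which the
#' resident departs.  Molecules where no competitor ever colocalizes get an
#' absent (`NA`) `t_bind` with a right-censoring time of `t_max - t_flow`.
#'
#' @param timeline An `occupancy_timeline`.
#' @param t_flow Flow time in seconds.
#' @return List with `t_bind`, `t_bind_censored`, `t_bind_diss`.
#' @export
extract_tbind <- function(timeline, t_flow) {
  tl <- timeline
  t_max <- attr(tl, "t_max")
  coloc <- tl$resident_bound & tl$competitor_count >= 1
  t_bind <- NA_real_; t_bind_diss <- NA_real_
  if (any(coloc))
    t_bind <- tl$t_start[which(coloc)[1]] - t_flow
  ep <- coloc_episodes(tl)
  if (nrow(ep)) {
    disp <- ep[ep$outcome == "resident_left", , drop = FALSE]
    if (nrow(disp))
      t_bind_diss <- disp$t_start[1] - t_flow
  }
  list(t_bind = t_bind,
       t_bind_censored = if (is.na(t_bind)) t_max - t_flow else NA_real_,
       t_bind_diss = t_bind_diss)
}

# maximal episodes with resident bound and competitor_count >= 1, with the
# outcome that ended each episode
coloc_episodes <- function(tl) {
  t_max <- attr(tl, "t_max")
  coloc <- tl$resident_bound & tl$competitor_count >= 1
  out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    outcome = character(0), max_count = integer(0),
                    stringsAsFactors = FALSE)
  if (!any(coloc)) return(out)
  r <- rle(coloc)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    t0 <- tl$t_start[i0]; t1 <- tl$t_end[i1]
    outcome <- if (i1 == nrow(tl) && abs(t1 - t_max) < 1e-9 &&
                   isTRUE(attr(tl, "resident_right_censored"))) {
      "censored"
    } else if (i1 < nrow(tl) && !tl$resident_bound[i1 + 1L]) {
      "resident_left"
    } else if (i1 == nrow(tl) && abs(t1 - t_max) < 1e-9) {
      "censored"
    } else "competitor_left"
    out <- rbind(out, data.frame(
      t_start = t0, t_end = t1, outcome = outcome,
      max_count = max(tl$competitor_count[i0:i1]),
      stringsAsFactors = FALSE))
  }
  out
}

#' Displacement times
#'
#' For each resident departure that occurs while at least one competitor is
#' bound and is followed by continued competitor occupancy, returns
#' `t_diss` = departure time minus the start of the colocalization episode
#' (the moment the competitor count first rose from 0 while the resident was
#' bound).
#'
#' @param timeline An `occupancy_timeline`.
#' @return Numeric vector of displacement times (seconds), possibly empty.
#' @export
extract_tdiss <- function(timeline) {
  ep <- coloc_episodes(timeline)
  ep <- ep[ep$outcome == "resident_left", , drop = FALSE]
  if (!nrow(ep)) return(numeric(0))
  # require continued competitor occupancy immediately after the departure
  keep <- vapply(seq_len(nrow(ep)), function(j) {
    after <- timeline$t_start >= ep$t_end[j] - 1e-9
    k <- which(after)[1]
    !is.na(k) && timeline$competitor_count[k] >= 1
  }, logical(1))
  ep <- ep[keep, , drop = FALSE]
  ep$t_end - ep$t_start
}

#' Coexistence dwells and their outcomes
#'
#' Each maximal episode with the resident bound and at least one competitor
#' bound yields a coexistence time `t_co` (episode duration) and the outcome
#' that ended it: `resident_left`, `competitor_left`, or `censored` at the
#' movie end.
#'
#' @param timeline An `occupancy_timeline`.
#' @return Data frame: `t_co`, `outcome`, `max_count`.
#' @export
extract_tco <- function(timeline) {
  ep <- coloc_episodes(timeline)
  data.frame(t_co = ep$t_end - ep$t_start, outcome = ep$outcome,
             max_count = ep$max_count, stringsAsFactors = FALSE)
}

#' Build the per-molecule competition record
#'
#' Derives all per-molecule observables from the paired interval lists: the
#' association times, displacement times, coexistence dwells, competitor
#' counts and concurrent-occupancy maximum.
#'
#' @param cy3,cy5 `bound_intervals` for one molecule.
#' @param t_flow Flow time (seconds).
#' @param t_max Movie end time (seconds).
#' @param stable_threshold Stable-coexistence threshold (seconds).
#' @param molecule_id Identifier.
#' @return A `competition_record` (list) with fields `molecule_id`,
#'   `t_flow`, `t_bind`, `t_bind_censored`, `t_bind_diss`, `t_diss`,
#'   `t_co` (data frame), `n_competitors_at_displacement`,
#'   `max_concurrent_srnas`, `modes`.
#' @export
competition_record <- function(cy3, cy5, t_flow, t_max = NULL,
                               stable_threshold = 20,
                               molecule_id = attr(cy3, "molecule_id")) {
  tl <- pair_intervals(cy3, cy5, t_max = t_max)
  tb <- extract_tbind(tl, t_flow)
  td <- extract_tdiss(tl)
  tc <- extract_tco(tl)
  ep <- coloc_episodes(tl)
  n_at_disp <- NA_integer_
  disp <- which(ep$outcome == "resident_left")
  if (length(disp)) n_at_disp <- ep$max_count[disp[1]]
  max_conc <- max(c(0L, tl$competitor_count +
                      as.integer(tl$resident_bound)))
  rec <- list(molecule_id = molecule_id, t_flow = t_flow,
              t_bind = tb$t_bind, t_bind_censored = tb$t_bind_censored,
              t_bind_diss = tb$t_bind_diss,
              t_diss = td, t_co = tc,
              n_competitors_at_displacement = n_at_disp,
              max_concurrent_srnas = max_conc,
              timeline = tl)
  rec$modes <- classify_molecule(rec, stable_threshold)
  class(rec) <- "competition_record"
  rec
}

#' Classify a molecule's competition modes
#'
#' * `passive`: the resident departed (uncensored) without any competitor
#'   having colocalized at any time before that departure.
#' * `active`: at least one displacement time exists.
#' * `stable_coexistence`: at least one coexistence dwell exceeds
#'   `stable_threshold` (a censored episode already longer than the
#'   threshold qualifies, since its true dwell can only be longer).
#' * `none`: no qualifying event.
#'
#' `active` and `stable_coexistence` may co-occur; `passive` excludes
#' `active` for the same departure.
#'
#' @param record A `competition_record` (or compatible list).
#' @param stable_threshold Seconds; default 20.
#' @return Character vector of mode flags.
#' @export
classify_molecule <- function(record, stable_threshold = 20) {
  tl <- record$timeline
  modes <- character(0)
  if (length(record$t_diss)) modes <- c(modes, "active")
  if (nrow(record$t_co) && any(record$t_co$t_co > stable_threshold))
    modes <- c(modes, "stable_coexistence")
  # passive: resident departure with no prior colocalization
  dep <- which(!tl$resident_bound)
  if (length(dep) && !isTRUE(attr(tl, "resident_right_censored"))) {
    t_dep <- tl$t_start[dep[1]]
    coloc_before <- any(tl$resident_bound & tl$competitor_count >= 1 &
                          tl$t_start < t_dep)
    if (!coloc_before && !"active" %in% modes) modes <- c(modes, "passive")
  }
  if (!length(modes)) modes <- "none"
  modes
}

#' Number of competitors bound before a displacement
#'
#' Counts the distinct competitor binding steps (arrival events, i.e.
#' increments of the competitor count) during the colocalization episode
#' that ended in the resident's displacement.
#'
#' @param timeline An `occupancy_timeline` containing a displacement.
#' @return Integer count (the peak competitor count reached during the
#'   displacing episode), or `NA` if no displacement exists.
#' @export
count_competitors_before_displacement <- function(timeline) {
  ep <- coloc_episodes(timeline)
  disp <- which(ep$outcome == "resident_left")
  if (!length(disp)) return(NA_integer_)
  ep$max_count[disp[1]]
}

#' Resident survival curve
#'
#' Percentage of molecules whose resident is still bound, sampled every
#' `bin` seconds, relative to the number bound at movie start.
#'
#' @param records List of `competition_record` objects.
#' @param bin Sampling interval in seconds (default 1).
#' @param t_max End of the sampled range; defaults to the records' movie end.
#' @return Data frame `time_s`, `percent_remaining`, `n_bound`.
#' @export
resident_survival_curve <- function(records, bin = 1, t_max = NULL) {
  stopifnot(length(records) >= 1)
  if (is.null(t_max))
    t_max <- max(vapply(records, function(r) attr(r$timeline, "t_max"),
                        numeric(1)))
  times <- seq(0, t_max, by = bin)
  bound_at <- function(tl, t) {
    i <- which(tl$t_start <= t + 1e-12 & tl$t_end > t + 1e-12)
    if (!length(i)) {
      # beyond last state row: resident gone unless censored-bound
      return(t >= attr(tl, "t_max") &&
               isTRUE(attr(tl, "resident_right_censored")))
    }
    tl$resident_bound[i[1]]
  }
  n0 <- sum(vapply(records, function(r) bound_at(r$timeline, 0), logical(1)))
  if (n0 == 0) stop("no resident bound at movie start")
  nb <- vapply(times, function(t)
    sum(vapply(records, function(r) bound_at(r$timeline, t), logical(1))),
    numeric(1))
  data.frame(time_s = times, percent_remaining = 100 * nb / n0, n_bound = nb)
}

#' Endpoint percent-remaining across fields of view
#'
#' Per-FOV percentage of resident molecules remaining relative to the mean
#' pre-competition count, with the mean and SD across FOVs.
#'
#' @param before_counts Per-FOV molecule counts before competitor addition.
#' @param after_counts Per-FOV counts 5 minutes after addition.
#' @return List with `percent` (per FOV), `mean`, `sd`.
#' @export
percent_remaining_endpoint <- function(before_counts, after_counts) {
  if (length(after_counts) < 2) stop("need >= 2 fields of view")
  before_mean <- mean(before_counts)
  if (before_mean <= 0) stop("before-competition count is zero")
  pct <- 100 * after_counts / before_mean
  list(percent = pct, mean = mean(pct), sd = stats::sd(pct))
}

#' Photobleaching quality control
#'
#' Compares the number of bound fluorophores at the end of the long movie
#' with the mean count over short movies in separate fields of view; the
#' movie passes when the two differ by less than 15%.
#'
#' @param end_of_movie_count Count at the end of the long movie.
#' @param fov_mean_count Mean count over short-movie FOVs (> 0).
#' @param max_percent Pass threshold in percent (default 15).
#' @return List with `percent_difference` and `pass`.
#' @export
photobleaching_qc <- function(end_of_movie_count, fov_mean_count,
                              max_percent = 15) {
  stopifnot(fov_mean_count > 0)
  pd <- 100 * abs(end_of_movie_count - fov_mean_count) / fov_mean_count
  list(percent_difference = pd, pass = pd < max_percent)
}

#' Ground-truth competition record straight from an event log
#'
#' Bypasses rendering and segmentation: converts the simulator's exact event
#' times into intervals and classifies them, providing the oracle labels the
#' trace pipeline is checked against.  With `acq` supplied, the exact
#' intervals are first discretized to each channel's excited-frame timebase
#' (by direct event-time arithmetic, independent of the rendering and
#' thresholding path), mirroring what any trace analysis at that sampling
#' can possibly resolve: events shorter than the per-channel sampling
#' interval are genuinely invisible at the 0.2 s resolution of alternating
#' excitation.
#'
#' @param log An `event_log`.
#' @param stable_threshold Seconds; default 20.
#' @param acq Optional [acquisition_params()]; discretize to its timebase.
#' @param min_frames,gap_frames Discretization counterparts of the
#'   [segment_trace()] arguments (used only with `acq`).
#' @return A `competition_record`.
#' @export
truth_record <- function(log, stable_threshold = 20, acq = NULL,
                         min_frames = 2, gap_frames = 1) {
  if (!is.null(acq)) {
    d <- discretize_log(log, acq, min_frames, gap_frames)
    return(competition_record(d$cy3, d$cy5, t_flow = attr(log, "flow_time"),
                              t_max = attr(log, "duration"),
                              stable_threshold = stable_threshold,
                              molecule_id = attr(log, "molecule_id")))
  }
  ivs <- event_log_intervals(log)
  duration <- attr(log, "duration")
  mk <- function(ch) {
    sub <- ivs[ivs$channel == ch, , drop = FALSE]
    out <- data.frame(channel = rep(ch, nrow(sub)),
                      t_start = sub$t_start, t_end = sub$t_end,
                      stoichiometry = rep(1L, nrow(sub)),
                      left_censored = sub$t_start <= 0,
                      right_censored = sub$right_censored,
                      stringsAsFactors = FALSE)
    out <- out[order(out$t_start), , drop = FALSE]
    class(out) <- c("bound_intervals", "data.frame")
    attr(out, "molecule_id") <- attr(log, "molecule_id")
    out
  }
  cy3 <- mk("cy3")
  cy5raw <- ivs[ivs$channel == "cy5", , drop = FALSE]
  # ground-truth competitor intervals may overlap (multiple competitors);
  # convert to a stoichiometry step function via the segments mechanism
  cy5 <- flatten_overlaps(cy5raw, attr(log, "molecule_id"))
  competition_record(cy3, cy5, t_flow = attr(log, "flow_time"),
                     t_max = duration, stable_threshold = stable_threshold,
                     molecule_id = attr(log, "molecule_id"))
}

#' Discretize an event log to the acquisition timebase
#'
#' For each channel, an excited frame is "on" when its midpoint falls inside
#' a bound interval of that channel's species; runs of on-frames are turned
#' into intervals with the same run-length, gap-bridging and censoring
#' conventions as [segment_trace()], and Cy5 per-frame competitor counts
#' become the stoichiometry step function.
#'
#' @param log An `event_log`.
#' @param acq An [acquisition_params()] object.
#' @param min_frames,gap_frames As in [segment_trace()].
#' @return `list(cy3 =, cy5 =)` of `bound_intervals`.
#' @export
discretize_log <- function(log, acq, min_frames = 2, gap_frames = 1) {
  ivs <- event_log_intervals(log)
  mask <- excitation_mask(acq)
  dt <- acq$frame_interval
  n <- acq$n_frames
  mid <- (seq_len(n) - 0.5) * dt
  mol <- attr(log, "molecule_id")

  channel_intervals <- function(ch) {
    exc_idx <- which(mask[, ch])
    t_all <- (exc_idx - 1L) * dt
    m <- mid[exc_idx]
    sub <- ivs[ivs$channel == ch, , drop = FALSE]
    cnt <- integer(length(exc_idx))
    for (j in seq_len(nrow(sub)))
      cnt <- cnt + as.integer(m >= sub$t_start[j] & m < sub$t_end[j])
    on <- cnt > 0L
    if (gap_frames > 0 && any(on)) {
      r <- rle(on)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (j in seq_along(r$values))
        if (!r$values[j] && r$lengths[j] <= gap_frames &&
            j > 1L && j < length(r$values))
          on[starts[j]:ends[j]] <- TRUE
    }
    r <- rle(on)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_frames
    n_exc <- length(exc_idx)
    sample_end <- c(t_all[-1], t_all[n_exc] + dt)
    rows <- list(); segs <- list()
    for (j in which(keep)) {
      i0 <- starts[j]; i1 <- ends[j]
      cc <- pmax(cnt[i0:i1], 1L)   # bridged gap frames count as 1
      rr <- rle(cc)
      # single-sample count spikes are below the resolvable step size
      resolvable <- rr$values[rr$lengths >= min(2L, length(cc))]
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, t_start = t_all[i0], t_end = sample_end[i1],
        stoichiometry = max(1L, resolvable),
        left_censored = i0 == 1L, right_censored = i1 == n_exc,
        stringsAsFactors = FALSE)
      ee <- cumsum(rr$lengths); ss <- ee - rr$lengths + 1L
      brk_t <- c(t_all[i0], t_all[i0 - 1L + ss[-1]], sample_end[i1])
      segs[[length(segs) + 1L]] <- list(
        counts = as.integer(rr$values), t_breaks = brk_t,
        stoichiometry = as.integer(max(rr$values)))
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(channel = character(0), t_start = numeric(0),
                 t_end = numeric(0), stoichiometry = integer(0),
                 left_censored = logical(0), right_censored = logical(0),
                 stringsAsFactors = FALSE)
    class(out) <- c("bound_intervals", "data.frame")
    attr(out, "molecule_id") <- mol
    if (ch == "cy5" && length(segs)) attr(out, "segments") <- segs
    out
  }
  list(cy3 = channel_intervals("cy3"), cy5 = channel_intervals("cy5"))
}

# collapse possibly-overlapping same-channel intervals into non-overlapping
# intervals carrying a per-segment count step function
flatten_overlaps <- function(ivs, molecule_id) {
  if (!nrow(ivs)) {
    out <- data.frame(channel = character(0), t_start = numeric(0),
                      t_end = numeric(0), stoichiometry = integer(0),
                      left_censored = logical(0), right_censored = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("bound_intervals", "data.frame")
    attr(out, "molecule_id") <- molecule_id
    return(out)
  }
  brk <- sort(unique(c(ivs$t_start, ivs$t_end)))
  t0 <- brk[-length(brk)]; t1 <- brk[-1]
  cnt <- vapply(t0, function(t)
    sum(ivs$t_start <= t + 1e-12 & ivs$t_end > t + 1e-12), numeric(1))
  on <- cnt > 0
  r <- rle(on)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rows <- list(); segs <- list()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    seg_idx <- i0:i1
    rows[[length(rows) + 1L]] <- data.frame(
      channel = "cy5", t_start = t0[i0], t_end = t1[i1],
      stoichiometry = as.integer(max(cnt[seg_idx])),
      left_censored = t0[i0] <= 0,
      right_censored = any(ivs$right_censored &
                             abs(ivs$t_end - t1[i1]) < 1e-12),
      stringsAsFactors = FALSE)
    # merge equal-count consecutive segments
    rr <- rle(cnt[seg_idx])
    ee <- cumsum(rr$lengths); ss <- ee - rr$lengths + 1L
    segs[[length(segs) + 1L]] <- list(
      counts = as.integer(rr$values),
      t_breaks = c(t0[seg_idx[ss]], t1[seg_idx[length(seg_idx)]]),
      stoichiometry = as.integer(max(rr$values)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bound_intervals", "data.frame")
  attr(out, "molecule_id") <- molecule_id
  attr(out, "segments") <- segs
  out
}

#' Flatten records into the dwells table
#'
#' One row per observation: `molecule_id`, `type`
#' (`t_bind`/`t_bind_diss`/`t_diss`/`t_co`), `value_s`, `censored`,
#' `outcome`.
#'
#' @param records List of `competition_record` objects.
#' @return Data frame.
#' @export
dwells_table <- function(records) {
  rows <- lapply(records, function(r) {
    out <- list()
    if (!is.na(r$t_bind))
      out[[length(out) + 1L]] <- data.frame(
        molecule_id = r$molecule_id, type = "t_bind", value_s = r$t_bind,
        censored = FALSE, outcome = NA_character_)
    else if (!is.na(r$t_bind_censored))
      out[[length(out) + 1L]] <- data.frame(
        molecule_id = r$molecule_id, type = "t_bind",
        value_s = r$t_bind_censored, censored = TRUE,
        outcome = NA_character_)
    if (!is.na(r$t_bind_diss))
      out[[length(out) + 1L]] <- data.frame(
        molecule_id = r$molecule_id, type = "t_bind_diss",
        value_s = r$t_bind_diss, censored = FALSE, outcome = NA_character_)
    for (v in r$t_diss)
      out[[length(out) + 1L]] <- data.frame(
        molecule_id = r$molecule_id, type = "t_diss", value_s = v,
        censored = FALSE, outcome = NA_character_)
    if (nrow(r$t_co))
      out[[length(out) + 1L]] <- data.frame(
        molecule_id = r$molecule_id, type = "t_co", value_s = r$t_co$t_co,
        censored = r$t_co$outcome == "censored", outcome = r$t_co$outcome)
    if (length(out)) do.call(rbind, out) else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(molecule_id = character(0), type = character(0),
                      value_s = numeric(0), censored = logical(0),
                      outcome = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flatten records into the per-molecule records table
#'
#' @param records List of `competition_record` objects.
#' @return Data frame, one row per molecule.
#' @export
records_table <- function(records) {
  out <- do.call(rbind, lapply(records, function(r) data.frame(
    molecule_id = r$molecule_id, t_flow = r$t_flow,
    t_bind = r$t_bind, t_bind_diss = r$t_bind_diss,
    n_t_diss = length(r$t_diss), n_t_co = nrow(r$t_co),
    n_competitors_at_displacement = r$n_competitors_at_displacement,
    max_concurrent_srnas = r$max_concurrent_srnas,
    passive = "passive" %in% r$modes,
    active = "active" %in% r$modes,
    stable_coexistence = "stable_coexistence" %in% r$modes,
    none = identical(r$modes, "none"),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
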