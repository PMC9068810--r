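#' Simulate one immobilized Hfq molecule's competition timeline
#'
#' Event-driven (Gillespie-style, with scheduled non-Markovian delays)
#' simulation of sRNA exchange on a single immobilized Hfq hexamer.  The
#' resident is bound at time zero.  Competitors arrive as a Poisson process
#' at rate `k_arrival` from `flow_time` onward, while fewer than
#' `max_competitors` are bound.  Each arrival is a transient probe with
#' probability `p_probe` (dwell exponential with mean `tau_probe`);
#' otherwise it binds stably and, if the resident is present, either triggers
#' displacement (probability `p_displace`; resident departure delayed by a
#' draw from `diss_mixture`) or coexists (joint dwell drawn from
#' `co_mixture`, ended by the resident with probability
#' `p_resident_leaves_first`, else by the competitor).  An RNA bound alone
#' dissociates spontaneously at rate `k_passive`.  Event times are exact;
#' discretization happens only at rendering.
#'
#' @param params A [competition_params()] object.
#' @param duration Movie duration in seconds.
#' @param flow_time Time (seconds) of competitor addition; `0 <= flow_time <
#'   duration`.
#' @param rng_seed Optional integer seed (set for reproducibility; if `NULL`
#'   the current RNG stream is used).
#' @param molecule_id Identifier stored on the event log.
#'
#' @return An `event_log`: a data frame with columns `time_s`, `species`
#'   (`"resident"` or `"competitor_<i>"`), `action` (`"bind"`,
#'   `"dissociate"`) plus attributes `molecule_id`, `duration`, `flow_time`.
#'   Species still bound at `duration` are right-censored (no dissociate
#'   event).
#' @export
simulate_molecule <- function(params, duration, flow_time, rng_seed = NULL,
                              molecule_id = "mol_1") {
  stopifnot(inherits(params, "competition_params"), duration > 0,
            flow_time >= 0, flow_time < duration)
  validate_competition_params(params)
  if (!is.null(rng_seed)) set.seed(rng_seed)

  diss_m <- do.call(rbind, params$diss_mixture)
  co_m <- do.call(rbind, params$co_mixture)
  draw_mix <- function(m) {
    j <- sample.int(nrow(m), 1L, prob = m[, 1])
    stats::rexp(1L, rate = 1 / max(m[j, 2], .Machine$double.xmin))
  }

  ev_time <- numeric(0); ev_species <- character(0); ev_action <- character(0)
  log_ev <- function(t, sp, ac) {
    ev_time <<- c(ev_time, t); ev_species <<- c(ev_species, sp)
    ev_action <<- c(ev_action, ac)
  }

  res_bound <- TRUE
  log_ev(0, "resident", "bind")
  # scheduled departures: named vector time by competitor species
  comp_departs <- numeric(0)       # departure time per bound competitor
  comp_next_id <- 1L
  pending_diss <- Inf              # scheduled resident displacement time
  t <- 0

  repeat {
    n_comp <- length(comp_departs)
    t_arr <- if (n_comp < params$max_competitors && params$k_arrival > 0)
      max(t, flow_time) + stats::rexp(1L, params$k_arrival) else Inf
    t_pass <- if (res_bound && n_comp == 0L && params$k_passive > 0)
      t + stats::rexp(1L, params$k_passive) else Inf
    t_comp <- if (n_comp) min(comp_departs) else Inf
    t_next <- min(t_arr, t_pass, t_comp, pending_diss)
    if (t_next >= duration) break
    t <- t_next

    if (t == pending_diss) {                      # active displacement lands
      log_ev(t, "resident", "dissociate")
      res_bound <- FALSE
      pending_diss <- Inf
    } else if (n_comp && t == t_comp) {           # a competitor departs
      j <- which.min(comp_departs)
      sp <- names(comp_departs)[j]
      out <- attr(comp_departs, "outcome")[j]
      if (identical(out, "resident_left")) {
        # coexistence ends by resident departure; competitor stays on
        if (res_bound) {
          log_ev(t, "resident", "dissociate")
          res_bound <- FALSE
          pending_diss <- Inf
        }
        oc <- attr(comp_departs, "outcome")
        comp_departs[j] <- if (params$k_passive > 0)
          t + stats::rexp(1L, params$k_passive) else Inf
        oc[j] <- "occupant"
        attr(comp_departs, "outcome") <- oc
      } else {
        log_ev(t, sp, "dissociate")
        oc <- attr(comp_departs, "outcome")[-j]
        comp_departs <- comp_departs[-j]
        attr(comp_departs, "outcome") <- oc
      }
    } else if (t == t_pass) {                     # passive resident departure
      log_ev(t, "resident", "dissociate")
      res_bound <- FALSE
      pending_diss <- Inf
    } else {                                      # competitor arrival
      sp <- paste0("competitor_", comp_next_id)
      comp_next_id <- comp_next_id + 1L
      log_ev(t, sp, "bind")
      oc <- attr(comp_departs, "outcome")
      if (stats::runif(1L) < params$p_probe) {    # transient probe
        dep <- t + stats::rexp(1L, 1 / max(params$tau_probe, .Machine$double.xmin))
        if (params$probe_can_displace && res_bound &&
            stats::runif(1L) < params$p_displace && !is.finite(pending_diss))
          pending_diss <- t + draw_mix(diss_m)
        comp_departs <- c(comp_departs, stats::setNames(dep, sp))
        attr(comp_departs, "outcome") <- c(oc, "probe")
      } else if (res_bound && stats::runif(1L) < params$p_displace) {
        # displacement branch: resident leaves after a diss_mixture delay,
        # competitor remains as the new occupant
        pending_diss <- min(pending_diss, t + draw_mix(diss_m))
        dep <- if (params$k_passive > 0)
          t + stats::rexp(1L, params$k_passive) else Inf
        comp_departs <- c(comp_departs, stats::setNames(dep, sp))
        attr(comp_departs, "outcome") <- c(oc, "occupant")
      } else if (res_bound) {
        # coexistence branch: joint dwell, ended by one of the two RNAs
        dwell <- draw_mix(co_m)
        out <- if (stats::runif(1L) < params$p_resident_leaves_first)
          "resident_left" else "competitor_left"
        comp_departs <- c(comp_departs, stats::setNames(t + dwell, sp))
        attr(comp_departs, "outcome") <- c(oc, out)
      } else {
        # resident already gone: plain occupancy with passive off-rate
        dep <- if (params$k_passive > 0)
          t + stats::rexp(1L, params$k_passive) else Inf
        comp_departs <- c(comp_departs, stats::setNames(dep, sp))
        attr(comp_departs, "outcome") <- c(oc, "occupant")
      }
    }
  }

  log <- data.frame(time_s = ev_time, species = ev_species, action = ev_action,
                    stringsAsFactors = FALSE)
  log <- log[order(log$time_s, seq_len(nrow(log))), , drop = FALSE]
  rownames(log) <- NULL
  structure(log, molecule_id = molecule_id, duration = duration,
            flow_time = flow_time, params = params,
            class = c("event_log", "data.frame"))
}

#' Simulate a whole field of molecules
#'
#' @param params A [competition_params()] object.
#' @param n_molecules Number of immobilized Hfq molecules.
#' @param duration,flow_time Passed to [simulate_molecule()].
#' @param rng_seed Integer seed for the whole experiment.
#' @return List of `event_log` objects named by molecule id.
#' @export
simulate_experiment <- function(params, n_molecules, duration = 300,
                                flow_time = 10, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  out <- vector("list", n_molecules)
  for (i in seq_len(n_molecules))
    out[[i]] <- simulate_molecule(params, duration, flow_time,
                                  molecule_id = sprintf("mol_%d", i))
  names(out) <- vapply(out, attr, "", "molecule_id")
  out
}

#' Ground-truth bound intervals from an event log
#'
#' Converts exact bind/dissociate/bleach events into half-open per-species
#' intervals on the continuous timebase; species bound at the end of the
#' movie are right-censored at `duration`.
#'
#' @param log An `event_log`.
#' @return Data frame: `species`, `channel` (`cy3` for the resident, `cy5`
#'   otherwise), `t_start`, `t_end`, `right_censored`.
#' @export
event_log_intervals <- function(log) {
  duration <- attr(log, "duration")
  sp <- unique(log$species)
  res <- lapply(sp, function(s) {
    e <- log[log$species == s, , drop = FALSE]
    starts <- e$time_s[e$action == "bind"]
    ends <- e$time_s[e$action %in% c("dissociate", "bleach")]
    cens <- length(ends) < length(starts)
    if (cens) ends <- c(ends, duration)
    data.frame(species = s,
               channel = if (s == "resident") "cy3" else "cy5",
               t_start = starts, t_end = ends,
               right_censored = c(rep(FALSE, length(starts) - cens),
                                  rep(TRUE, cens)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$t_start), , drop = FALSE]
}

#' Render an event log into two-channel intensity traces
#'
#' Per-frame intensity = background + `unit_intensity` x (number of unbleached
#' bound fluorophores of that channel) x excitation + Gaussian noise.  The
#' Cy5 background steps from `background_pre` to `background_post` at
#' `flow_frame`; the Cy3 background stays at `background_pre`.  Occupancy is
#' sampled at frame midpoints.  If `params$k_bleach > 0`, each bound
#' fluorophore bleaches independently on each of its excited frames with
#' probability `1 - exp(-k_bleach * frame_interval)`; bleach events are
#' appended to the returned log (attribute `"log"`).
#'
#' @param log An `event_log` from [simulate_molecule()].
#' @param acq An [acquisition_params()] object.
#' @param rng_seed Optional integer seed.
#' @return A named list `list(cy3 =, cy5 =)` of `intensity_trace` data frames
#'   with columns `frame` (0-based), `time_s` (frame start), `intensity`,
#'   `excited`; attributes `channel`, `frame_interval`, `baseline` (per-frame
#'   true background), `flow_time`, `molecule_id`.  The possibly
#'   bleach-augmented event log is attached as attribute `"log"`.
#' @export
render_traces <- function(log, acq, rng_seed = NULL) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  params <- attr(log, "params")
  k_bleach <- if (is.null(params)) 0 else params$k_bleach

  n <- acq$n_frames
  dt <- acq$frame_interval
  mid <- (seq_len(n) - 0.5) * dt
  mask <- excitation_mask(acq)
  ivs <- event_log_intervals(log)

  occ <- list(cy3 = integer(n), cy5 = integer(n))
  bleach_events <- NULL
  for (i in seq_len(nrow(ivs))) {
    ch <- ivs$channel[i]
    on <- mid >= ivs$t_start[i] & mid < ivs$t_end[i]
    if (k_bleach > 0 && any(on)) {
      p_bleach <- 1 - exp(-k_bleach * dt)
      exc_on <- which(on & mask[, ch])
      if (length(exc_on)) {
        hit <- which(stats::runif(length(exc_on)) < p_bleach)
        if (length(hit)) {
          bf <- exc_on[min(hit)]            # first excited frame that bleaches
          on[seq_len(n) > bf] <- FALSE      # dark from the next frame on
          bleach_events <- rbind(bleach_events,
            data.frame(time_s = bf * dt, species = ivs$species[i],
                       action = "bleach", stringsAsFactors = FALSE))
        }
      }
    }
    occ[[ch]] <- occ[[ch]] + as.integer(on)
  }

  flow_time <- attr(log, "flow_time")
  bg <- list(
    cy3 = rep(acq$background_pre, n),
    cy5 = ifelse(seq_len(n) - 1L >= acq$flow_frame,
                 acq$background_post, acq$background_pre))

  mk <- function(ch) {
    y <- bg[[ch]] + acq$unit_intensity * occ[[ch]] * as.numeric(mask[, ch])
    if (acq$noise_sd > 0) y <- y + stats::rnorm(n, 0, acq$noise_sd)
    structure(
      data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) * dt,
                 intensity = y, excited = mask[, ch]),
      channel = ch, frame_interval = dt, baseline = bg[[ch]],
      noise_sd = acq$noise_sd, flow_time = flow_time,
      molecule_id = attr(log, "molecule_id"),
      class = c("intensity_trace", "data.frame"))
  }
  out <- list(cy3 = mk("cy3"), cy5 = mk("cy5"))
  if (!is.null(bleach_events)) {
    aug <- rbind(as.data.frame(log), bleach_events)
    aug <- aug[order(aug$time_s), ]
    rownames(aug) <- NULL
    attributes(aug)[c("molecule_id", "duration", "flow_time", "params")] <-
      attributes(log)[c("molecule_id", "duration", "flow_time", "params")]
    class(aug) <- c("event_log", "data.frame")
    attr(out, "log") <- aug
  } else attr(out, "log") <- log
  out
}

#' Write an event log (or list of logs) to CSV
#'
#' @param logs An `event_log` or list of them.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_event_log <- function(logs, file) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  rows <- lapply(logs, function(l)
    cbind(molecule_id = attr(l, "molecule_id"), as.data.frame(l)))
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
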