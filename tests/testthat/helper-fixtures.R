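# Shared fixture builders for the test suite.  Everything is generated in
# code; no stored data.

# hand-written event log with exact times
make_log <- function(events, duration = 300, flow_time = 10,
                     molecule_id = "mol_1", params = NULL) {
  log <- data.frame(time_s = vapply(events, `[[`, 0, 1),
                    species = vapply(events, `[[`, "", 2),
                    action = vapply(events, `[[`, "", 3),
                    stringsAsFactors = FALSE)
  structure(log, molecule_id = molecule_id, duration = duration,
            flow_time = flow_time, params = params,
            class = c("event_log", "data.frame"))
}

# a bound_intervals table from plain vectors
make_intervals <- function(channel, t_start, t_end,
                           stoichiometry = rep(1L, length(t_start)),
                           left_censored = rep(FALSE, length(t_start)),
                           right_censored = rep(FALSE, length(t_start)),
                           molecule_id = "mol_1") {
  out <- data.frame(channel = rep(channel, length(t_start)),
                    t_start = t_start, t_end = t_end,
                    stoichiometry = as.integer(stoichiometry),
                    left_censored = left_censored,
                    right_censored = right_censored,
                    stringsAsFactors = FALSE)
  class(out) <- c("bound_intervals", "data.frame")
  attr(out, "molecule_id") <- molecule_id
  out
}

# a bare intensity trace on a continuous (all-excited) timebase
make_trace <- function(intensity, channel = "cy5", dt = 0.1, baseline = 0,
                       excited = rep(TRUE, length(intensity))) {
  n <- length(intensity)
  structure(
    data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) * dt,
               intensity = intensity, excited = excited),
    channel = channel, frame_interval = dt,
    baseline = if (length(baseline) == 1L) rep(baseline, n) else baseline,
    molecule_id = "mol_1",
    class = c("intensity_trace", "data.frame"))
}

# minimal competition_record stand-in for summary-level tests
fake_record <- function(modes, molecule_id = "m") {
  structure(list(molecule_id = molecule_id, t_flow = 10,
                 t_bind = NA_real_, t_bind_censored = NA_real_,
                 t_bind_diss = NA_real_, t_diss = numeric(0),
                 t_co = data.frame(t_co = numeric(0), outcome = character(0),
                                   max_count = integer(0)),
                 n_competitors_at_displacement = NA_integer_,
                 max_concurrent_srnas = 1L, modes = modes,
                 timeline = NULL),
            class = "competition_record")
}

# quiet wrapper: stoichiometry clamp warnings are expected under heavy noise
segment_quietly <- function(...) suppressWarnings(segment_molecule(...))
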