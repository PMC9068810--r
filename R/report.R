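#' Summarize competition modes for one resident/competitor pair
#'
#' Computes per-replicate percentages of molecules flagged passive, stable
#' coexistence and active, then the mean and s.e.m. across replicates.
#'
#' @param records List of `competition_record` objects.
#' @param replicate_ids Vector (one entry per record) assigning each molecule
#'   to an independent replicate.
#' @param resident_label,competitor_label Identifiers for the pair.
#' @return A `pair_summary` list: labels, `percent_passive`,
#'   `percent_coexistence`, `percent_active` (each `c(mean, sem)`),
#'   `n_molecules`, `per_replicate` data frame.
#' @export
summarize_pair <- function(records, replicate_ids = NULL,
                           resident_label = "resident",
                           competitor_label = "competitor") {
  stopifnot(length(records) >= 1)
  if (is.null(replicate_ids)) replicate_ids <- rep(1L, length(records))
  stopifnot(length(replicate_ids) == length(records))
  tab <- records_table(records)
  reps <- split(seq_along(records), replicate_ids)
  if (any(!lengths(reps))) stop("empty replicate")
  per_rep <- do.call(rbind, lapply(names(reps), function(r) {
    i <- reps[[r]]
    data.frame(replicate = r, n = length(i),
               percent_passive = 100 * mean(tab$passive[i]),
               percent_coexistence = 100 * mean(tab$stable_coexistence[i]),
               percent_active = 100 * mean(tab$active[i]))
  }))
  msem <- function(x) {
    m <- mean(x)
    s <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    c(mean = m, sem = s)
  }
  structure(list(resident_label = resident_label,
                 competitor_label = competitor_label,
                 percent_passive = msem(per_rep$percent_passive),
                 percent_coexistence = msem(per_rep$percent_coexistence),
                 percent_active = msem(per_rep$percent_active),
                 n_molecules = length(records),
                 per_replicate = per_rep),
            class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  cat(sprintf("%s resident vs %s competitor (n = %d molecules, %d replicates)\n",
              x$resident_label, x$competitor_label, x$n_molecules,
              nrow(x$per_replicate)))
  for (m in c("percent_passive", "percent_coexistence", "percent_active"))
    cat(sprintf("  %-20s %5.1f%% +/- %.1f\n",
                sub("percent_", "", m), x[[m]]["mean"], x[[m]]["sem"]))
  invisible(x)
}

#' Competition-mode heat maps across pairs
#'
#' Arranges pair summaries into three resident x competitor percentage
#' matrices (passive, stable coexistence, active).
#'
#' @param summaries List of `pair_summary` objects.
#' @return Named list of three matrices (rows = residents, cols =
#'   competitors); values in `[0, 100]`, `NA` for untested pairs.
#' @export
mode_heatmaps <- function(summaries) {
  res <- unique(vapply(summaries, `[[`, "", "resident_label"))
  comp <- unique(vapply(summaries, `[[`, "", "competitor_label"))
  mk <- function(field) {
    m <- matrix(NA_real_, length(res), length(comp),
                dimnames = list(res, comp))
    for (s in summaries)
      m[s$resident_label, s$competitor_label] <- s[[field]]["mean"]
    m
  }
  list(passive = mk("percent_passive"),
       coexistence = mk("percent_coexistence"),
       active = mk("percent_active"))
}

default_config <- function() {
  list(mode = "traces",                # or "movie"
       pair = "H-DA_vs_CX",
       params = NULL,                  # overrides competition_preset(pair)
       n_molecules = 100,
       duration = 300,
       flow_time = 10,
       n_replicates = 2,
       stable_threshold = 20,
       acquisition = list(),           # overrides acquisition_params()
       fit = list(k_max = 3, resolution = 0.2, n_boot = 200),
       detect_flow = TRUE,
       seed = 1)
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  required <- c("mode", "n_molecules", "duration", "flow_time", "seed")
  for (f in required)
    if (is.null(cfg[[f]])) stop(sprintf("config field '%s' is missing", f))
  if (!cfg$mode %in% c("traces", "movie"))
    stop("config 'mode' must be 'traces' or 'movie'")
  if (!is.null(cfg$acquisition$frame_interval) &&
      cfg$acquisition$frame_interval <= 0)
    stop("config field 'frame_interval' must be > 0")
  cfg
}

pipeline_stage <- function(name, expr, verbose = TRUE) {
  if (verbose) message(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full simulate-and-analyze pipeline
#'
#' Executes simulate -> (render movie -> extract | render traces) ->
#' segment -> classify -> dwell-time fits -> summaries, and writes all
#' artifacts (intervals/dwells/records/summary CSVs, fit JSON, survival
#' curve and heat-map CSV + PDF, and a machine-readable run manifest) to
#' `out_dir`.
#'
#' @param config Configuration list or path to a JSON file.  Recognised
#'   fields (with defaults): `mode` ("traces" or "movie"), `pair` (preset
#'   name), `params` (overrides of [competition_params()]), `n_molecules`,
#'   `duration`, `flow_time`, `n_replicates`, `stable_threshold`,
#'   `acquisition` (overrides of [acquisition_params()]), `fit`
#'   (`k_max`, `resolution`, `n_boot`), `detect_flow`, `seed`.
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param verbose Emit stage progress messages.
#' @return Invisible list: `records`, `dwells`, `intervals`, `fits`,
#'   `summary`, `survival`, `manifest`, `counts` (molecules in/out per
#'   stage).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- pipeline_stage("config", validate_config(config), verbose)
  set.seed(cfg$seed)
  params <- if (!is.null(cfg$params))
    do.call(competition_params, cfg$params)
  else competition_preset(cfg$pair)
  acq_args <- utils::modifyList(
    list(flow_frame = round(cfg$flow_time /
                              (cfg$acquisition$frame_interval %||% 0.1)),
         n_frames = round(cfg$duration /
                            (cfg$acquisition$frame_interval %||% 0.1))),
    cfg$acquisition)
  acq <- do.call(acquisition_params, acq_args)
  counts <- list()

  logs <- pipeline_stage("simulate",
    simulate_experiment(params, cfg$n_molecules, cfg$duration,
                        cfg$flow_time), verbose)
  counts$simulated <- length(logs)

  if (cfg$mode == "movie") {
    traces <- pipeline_stage("extract", {
      hw <- 2
      half_w <- acq$field_size[2] / 2
      pos <- spot_grid(length(logs), half_w, acq$field_size[1],
                       margin = hw + 5, min_sep = 8)
      stack <- render_movie(logs, acq, pos)
      ex <- extract_traces(stack, acq)
      ex$traces
    }, verbose)
  } else {
    traces <- pipeline_stage("render",
      lapply(logs, render_traces, acq = acq), verbose)
  }
  counts$traces <- length(traces)

  t_flow <- cfg$flow_time
  if (isTRUE(cfg$detect_flow) && length(traces)) {
    t_flow <- pipeline_stage("flow", {
      # per-frame lower quartile across AOIs: the synchronized background
      # step survives while unsynchronized binding events are rejected
      cy5s <- lapply(traces, `[[`, "cy5")
      m <- vapply(cy5s, `[[`, numeric(nrow(cy5s[[1]])), "intensity")
      agg <- cy5s[[1]]
      agg$intensity <- apply(m, 1, stats::quantile, probs = 0.25)
      tryCatch(detect_flow_time(agg), error = function(e) cfg$flow_time)
    }, verbose)
  }

  seg <- pipeline_stage("segment", {
    unit <- tryCatch(
      estimate_unit_intensity(lapply(traces, `[[`, "cy5")),
      error = function(e) acq$unit_intensity)
    lapply(traces, segment_molecule, unit = unit)
  }, verbose)

  records <- pipeline_stage("classify", {
    out <- lapply(seq_along(seg), function(i)
      competition_record(seg[[i]]$cy3, seg[[i]]$cy5, t_flow = t_flow,
                         t_max = cfg$duration,
                         stable_threshold = cfg$stable_threshold,
                         molecule_id = names(seg)[i] %||%
                           sprintf("mol_%d", i)))
    names(out) <- vapply(out, `[[`, "", "molecule_id")
    out
  }, verbose)
  counts$classified <- length(records)

  dwells <- dwells_table(records)
  intervals <- do.call(rbind, lapply(seq_along(seg), function(i) {
    iv <- rbind(as.data.frame(seg[[i]]$cy3), as.data.frame(seg[[i]]$cy5))
    if (nrow(iv)) cbind(molecule_id = names(seg)[i], iv) else NULL
  }))

  fits <- pipeline_stage("fit", {
    out <- list()
    for (type in c("t_diss", "t_co")) {
      d <- dwells[dwells$type == type, , drop = FALSE]
      if (nrow(d) >= 25) {
        ks <- seq_len(cfg$fit$k_max %||% 3)
        fl <- lapply(ks, function(k)
          tryCatch(fit_mle_mixture(d$value_s, d$censored, k = k,
                                   resolution = cfg$fit$resolution %||% 0.2),
                   error = function(e) NULL))
        fl <- fl[!vapply(fl, is.null, logical(1))]
        if (length(fl)) {
          sel <- tryCatch(select_model(fl), error = function(e)
            list(k = fl[[length(fl)]]$n_components))
          best <- fl[[which(vapply(fl, `[[`, integer(1), "n_components")
                            == sel$k)[1]]]
          nb <- cfg$fit$n_boot %||% 200
          if (nb > 0)
            best <- tryCatch(
              bootstrap_errors(d$value_s, d$censored, best, n_boot = nb,
                               rng_seed = cfg$seed),
              error = function(e) best)
          out[[type]] <- list(fit = best, selection = sel)
        }
      }
    }
    out
  }, verbose)

  summary <- pipeline_stage("summarize", {
    rep_ids <- rep(seq_len(max(1, cfg$n_replicates)),
                   length.out = length(records))
    summarize_pair(records, rep_ids,
                   resident_label = strsplit(cfg$pair, "_vs_")[[1]][1],
                   competitor_label = strsplit(cfg$pair, "_vs_")[[1]][2])
  }, verbose)

  survival <- resident_survival_curve(records, bin = 1, t_max = cfg$duration)

  manifest <- list(
    package = "hfqcompete",
    version = as.character(utils::packageVersion("hfqcompete")),
    config = cfg, t_flow_used = t_flow,
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(out_dir)) pipeline_stage("write", {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(dwells, file.path(out_dir, "dwells.csv"),
                     row.names = FALSE)
    utils::write.csv(records_table(records),
                     file.path(out_dir, "records.csv"), row.names = FALSE)
    if (!is.null(intervals))
      utils::write.csv(intervals, file.path(out_dir, "intervals.csv"),
                       row.names = FALSE)
    utils::write.csv(survival, file.path(out_dir, "survival.csv"),
                     row.names = FALSE)
    utils::write.csv(summary$per_replicate,
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    fit_json <- lapply(fits, function(f) list(
      k = f$fit$n_components, lifetimes_s = f$fit$lifetimes,
      fractions = f$fit$fractions, loglik = f$fit$loglik,
      ci_lower = f$fit$ci_lower, ci_upper = f$fit$ci_upper,
      n = f$fit$n_observations, n_censored = f$fit$n_censored,
      method = f$fit$method))
    jsonlite::write_json(fit_json, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    hm <- mode_heatmaps(list(summary))
    for (nm in names(hm))
      utils::write.csv(hm[[nm]],
                       file.path(out_dir, sprintf("heatmap_%s.csv", nm)))
    grDevices::pdf(file.path(out_dir, "survival_curve.pdf"), 6, 4)
    graphics::plot(survival$time_s, survival$percent_remaining, type = "l",
                   xlab = "time (s)", ylab = "% resident remaining",
                   ylim = c(0, 100))
    grDevices::dev.off()
  }, verbose)

  invisible(list(records = records, dwells = dwells, intervals = intervals,
                 fits = fits, summary = summary, survival = survival,
                 manifest = manifest, counts = counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic well-separated spot layout for simulated movies
spot_grid <- function(n, half_w, h, margin = 8, min_sep = 8) {
  nx <- max(1L, floor((half_w - 2 * margin) / min_sep))
  ny <- max(1L, floor((h - 2 * margin) / min_sep))
  if (nx * ny < n) stop("field too small for the requested molecule count")
  g <- expand.grid(x = margin + min_sep * (seq_len(nx) - 1L),
                   y = margin + min_sep * (seq_len(ny) - 1L))
  as.matrix(g[seq_len(n), , drop = FALSE])
}
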