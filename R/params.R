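#' Kinetic parameters of a competition experiment
#'
#' Bundles the phenomenological kinetic scheme for sRNA exchange on a single
#' immobilized Hfq hexamer: a resident sRNA is bound at time zero, and after
#' the competitor flow event Cy5-labelled competitors arrive as a Poisson
#' process.  Each arrival is either a short nonproductive "probe" or a stable
#' binder; a stable binder either triggers displacement of the resident (with
#' a delay drawn from an exponential mixture) or coexists with it for a dwell
#' drawn from a second mixture, ended by the departure of one of the two RNAs.
#'
#' @param k_arrival Per-second pseudo-first-order competitor arrival rate
#'   (association rate constant times competitor concentration).  Arrivals are
#'   suppressed while `max_competitors` RNAs are already bound.
#' @param p_probe Probability that an arrival is a transient probe rather than
#'   a stable binder.
#' @param tau_probe Mean dwell (seconds) of a probing event.
#' @param p_displace Probability that a stable arrival (while the resident is
#'   bound) triggers active displacement rather than coexistence.
#' @param diss_mixture Exponential mixture for the displacement delay
#'   \eqn{t_{diss}}: a list of `c(fraction, tau_seconds)` pairs, fractions
#'   summing to 1.
#' @param co_mixture Exponential mixture for the joint coexistence dwell
#'   \eqn{t_{co}}, same format.
#' @param p_resident_leaves_first Probability that a coexistence episode ends
#'   with the resident (rather than the competitor) departing.
#' @param k_passive Per-second spontaneous off-rate of a lone bound RNA
#'   (the passive-competition channel).
#' @param max_competitors Maximum number of simultaneously bound competitors.
#' @param k_bleach Per-second per-fluorophore photobleaching rate under
#'   excitation; applied by the renderers on excited frames only.
#' @param probe_can_displace Whether probing events may trigger displacement
#'   of the resident (default `FALSE`: probes are nonproductive).
#'
#' @return An object of class `competition_params` (a validated list).
#' @seealso [competition_preset()], [simulate_molecule()]
#' @export
competition_params <- function(k_arrival = 0.05,
                               p_probe = 0.4,
                               tau_probe = 1,
                               p_displace = 0.7,
                               diss_mixture = list(c(0.45, 0.3), c(0.35, 8), c(0.20, 90)),
                               co_mixture = list(c(0.7, 6), c(0.3, 60)),
                               p_resident_leaves_first = 0.5,
                               k_passive = 3e-4,
                               max_competitors = 3,
                               k_bleach = 0,
                               probe_can_displace = FALSE) {
  p <- list(k_arrival = k_arrival, p_probe = p_probe, tau_probe = tau_probe,
            p_displace = p_displace, diss_mixture = diss_mixture,
            co_mixture = co_mixture,
            p_resident_leaves_first = p_resident_leaves_first,
            k_passive = k_passive, max_competitors = max_competitors,
            k_bleach = k_bleach, probe_can_displace = probe_can_displace)
  validate_competition_params(p)
  class(p) <- "competition_params"
  p
}

validate_mixture <- function(mix, name) {
  if (!is.list(mix) || !length(mix))
    stop(sprintf("'%s' must be a non-empty list of c(fraction, tau) pairs", name))
  m <- do.call(rbind, mix)
  if (ncol(m) != 2L)
    stop(sprintf("'%s' entries must be c(fraction, tau) pairs", name))
  if (any(m[, 1] < 0) || any(m[, 2] < 0))
    stop(sprintf("'%s' fractions and lifetimes must be >= 0", name))
  if (abs(sum(m[, 1]) - 1) > 1e-9)
    stop(sprintf("'%s' fractions must sum to 1 (got %.12g)", name, sum(m[, 1])))
  invisible(m)
}

validate_competition_params <- function(p) {
  stopifnot(p$k_arrival >= 0, p$k_passive >= 0, p$k_bleach >= 0,
            p$tau_probe >= 0, p$max_competitors >= 1)
  for (pr in c("p_probe", "p_displace", "p_resident_leaves_first"))
    if (p[[pr]] < 0 || p[[pr]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", pr))
  validate_mixture(p$diss_mixture, "diss_mixture")
  validate_mixture(p$co_mixture, "co_mixture")
  invisible(p)
}

#' @export
print.competition_params <- function(x, ...) {
  cat("Competition kinetics\n")
  cat(sprintf("  arrival rate      : %.4g /s (probes: %.0f%%, tau %.3g s)\n",
              x$k_arrival, 100 * x$p_probe, x$tau_probe))
  cat(sprintf("  P(displacement)   : %.2f\n", x$p_displace))
  fmt_mix <- function(m) paste(vapply(m, function(cc)
    sprintf("%.0f%% @ %.3g s", 100 * cc[1], cc[2]), ""), collapse = ", ")
  cat(sprintf("  t_diss mixture    : %s\n", fmt_mix(x$diss_mixture)))
  cat(sprintf("  t_co mixture      : %s\n", fmt_mix(x$co_mixture)))
  cat(sprintf("  passive off-rate  : %.4g /s; max competitors %d\n",
              x$k_passive, x$max_competitors))
  invisible(x)
}

#' Acquisition parameters for trace and movie rendering
#'
#' Describes the smTIRF movie: 3,000 frames of 100 ms by default, both
#' channels excited during the first and last second of the movie and
#' alternating excitation in between (Cy3 on even frames, Cy5 on odd frames)
#' to limit photobleaching, and a Cy5 background step at the competitor flow
#' frame.  The camera is a two-half-field layout: Cy3 on the left half, Cy5
#' on the right half, related by `channel_transform`.
#'
#' @param frame_interval Seconds per frame.
#' @param n_frames Number of frames in the movie.
#' @param flow_frame 0-based frame index of competitor addition (Cy5
#'   background step).
#' @param unit_intensity Integrated intensity (a.u.) contributed by one
#'   fluorophore on an excited frame.
#' @param background_pre,background_post Cy5 per-AOI background (a.u.) before
#'   and after the flow event; the Cy3 background equals `background_pre`
#'   throughout.
#' @param noise_sd Gaussian noise s.d. (a.u.) added per frame (per pixel for
#'   movies, per trace sample for traces).
#' @param field_size `c(height, width)` of the full camera field in pixels
#'   (width spans both half-fields).
#' @param psf_sigma Gaussian point-spread-function s.d. in pixels.
#' @param channel_transform Affine map from Cy3 to Cy5 coordinates:
#'   `list(A = 2x2 matrix, b = length-2 offset)` acting on `(x, y)` column
#'   vectors.  Default translates by half the field width.
#' @param both_on_head,both_on_tail Number of leading/trailing frames with
#'   both lasers on.
#'
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(frame_interval = 0.1,
                               n_frames = 3000,
                               flow_frame = 100,
                               unit_intensity = 300,
                               background_pre = 100,
                               background_post = 160,
                               noise_sd = 0,
                               field_size = c(128, 256),
                               psf_sigma = 1.1,
                               channel_transform = NULL,
                               both_on_head = 10,
                               both_on_tail = 10) {
  stopifnot(frame_interval > 0, n_frames >= 1,
            flow_frame >= 0, flow_frame < n_frames)
  if (background_post < background_pre)
    stop("background_post must be >= background_pre")
  if (is.null(channel_transform))
    channel_transform <- list(A = diag(2), b = c(field_size[2] / 2, 0))
  if (is.null(channel_transform$A) || is.null(channel_transform$b) ||
      !all(dim(channel_transform$A) == c(2, 2)))
    stop("channel_transform must be list(A = 2x2 matrix, b = length-2 vector)")
  acq <- list(frame_interval = frame_interval, n_frames = n_frames,
              flow_frame = flow_frame, unit_intensity = unit_intensity,
              background_pre = background_pre, background_post = background_post,
              noise_sd = noise_sd, field_size = field_size,
              psf_sigma = psf_sigma, channel_transform = channel_transform,
              both_on_head = both_on_head, both_on_tail = both_on_tail)
  class(acq) <- "acquisition_params"
  acq
}

#' Per-frame excitation mask
#'
#' Both lasers are on for the first `both_on_head` and last `both_on_tail`
#' frames; in between, excitation alternates with Cy3 on even (0-based) frame
#' indices and Cy5 on odd ones.
#'
#' @param acq An [acquisition_params()] object.
#' @return Logical matrix with `n_frames` rows and columns `cy3`, `cy5`.
#' @export
excitation_mask <- function(acq) {
  i <- seq_len(acq$n_frames) - 1L
  both <- i < acq$both_on_head | i >= acq$n_frames - acq$both_on_tail
  cy3 <- both | (i %% 2L == 0L)
  cy5 <- both | (i %% 2L == 1L)
  cbind(cy3 = cy3, cy5 = cy5)
}

#' Named kinetic presets for the four resident/competitor pairs
#'
#' Regime-faithful parameter sets for the four core sRNA pairs: resident
#' DsrA or ChiX on Hfq ("H-DA", "H-CX") challenged by DsrA or ChiX ("DA",
#' "CX").  Values are chosen inside the experimentally reported ranges (for
#' example displacement lifetimes of roughly 0-0.5, 4-13 and 58-133 s with a
#' 13-22% slow fraction, stable coexistence more frequent for heterotypic
#' pairs, passive exchange rare) and are meant as realistic fixtures for the
#' simulator, not as refits of any particular dataset.
#'
#' @param pair One of `"H-DA_vs_DA"`, `"H-DA_vs_CX"`, `"H-CX_vs_DA"`,
#'   `"H-CX_vs_CX"`.
#' @return A [competition_params()] object.
#' @export
competition_preset <- function(pair = c("H-DA_vs_DA", "H-DA_vs_CX",
                                        "H-CX_vs_DA", "H-CX_vs_CX")) {
  pair <- match.arg(pair)
  switch(pair,
    # homotypic: clash on the same face -> sub-resolution tau_diss1,
    # stable coexistence infrequent (~16-17% of coexistence events),
    # intermediate resident removal over a 5 min movie
    "H-DA_vs_DA" = competition_params(
      k_arrival = 0.030, p_probe = 0.70, tau_probe = 1.2, p_displace = 0.25,
      diss_mixture = list(c(0.45, 0.1), c(0.37, 8), c(0.18, 90)),
      co_mixture = list(c(0.80, 6), c(0.20, 70)),
      p_resident_leaves_first = 0.10, k_passive = 3e-4),
    "H-CX_vs_CX" = competition_params(
      k_arrival = 0.035, p_probe = 0.72, tau_probe = 1.0, p_displace = 0.25,
      diss_mixture = list(c(0.40, 0.1), c(0.42, 10), c(0.18, 100)),
      co_mixture = list(c(0.80, 6), c(0.20, 70)),
      p_resident_leaves_first = 0.10, k_passive = 3e-4),
    # class II challenger on class I resident: fast access (many probes
    # before a stable binder), strong displacement, few residents survive
    "H-DA_vs_CX" = competition_params(
      k_arrival = 0.070, p_probe = 0.90, tau_probe = 0.8, p_displace = 0.75,
      diss_mixture = list(c(0.43, 0.4), c(0.42, 6), c(0.15, 80)),
      co_mixture = list(c(0.50, 5), c(0.50, 60)),
      p_resident_leaves_first = 0.50, k_passive = 3e-4),
    # class I challenger on class II resident: slow access, little
    # displacement, frequent stable coexistence, most residents survive
    "H-CX_vs_DA" = competition_params(
      k_arrival = 0.012, p_probe = 0.65, tau_probe = 1.5, p_displace = 0.06,
      diss_mixture = list(c(0.30, 0.5), c(0.50, 13), c(0.20, 110)),
      co_mixture = list(c(0.50, 5), c(0.50, 60)),
      p_resident_leaves_first = 0.10, k_passive = 3e-4))
}
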