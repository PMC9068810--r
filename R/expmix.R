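#' Empirical CDF of uncensored dwell times
#'
#' Thin wrapper around [stats::ecdf()] restricted to the observed
#' (uncensored) dwells, used for the cumulative-fraction binding plots.
#'
#' @param times Numeric vector of dwell times.
#' @param censored Optional logical flags; censored observations are
#'   excluded.
#' @return A right-continuous step function of class `ecdf`.
#' @export
empirical_cdf <- function(times, censored = NULL) {
  if (!is.null(censored)) times <- times[!censored]
  if (!length(times)) stop("no uncensored observations")
  stats::ecdf(times)
}

# mixture parameter transforms: theta = (log tau_1..k, alpha_1..k-1) with
# fractions = softmax(c(alpha, 0))
theta_to_par <- function(theta, k) {
  taus <- exp(theta[seq_len(k)])
  if (k == 1L) return(list(taus = taus, fracs = 1))
  a <- c(theta[(k + 1L):(2L * k - 1L)], 0)
  e <- exp(a - max(a))
  list(taus = taus, fracs = e / sum(e))
}

par_to_theta <- function(taus, fracs) {
  k <- length(taus)
  if (k == 1L) return(log(taus))
  c(log(taus), log(fracs[-k] / fracs[k]))
}

sort_components <- function(taus, fracs) {
  o <- order(taus)
  list(taus = taus[o], fracs = fracs[o])
}

#' Least-squares exponential-mixture fit to the empirical CDF
#'
#' Fits \eqn{F(t) = \sum_j A_j (1 - e^{-t/\tau_j})} with \eqn{\sum_j A_j = 1}
#' to the ECDF evaluated at the observed times, by multi-start quasi-Newton
#' least squares (lifetimes on log scale, fractions via softmax).
#'
#' @param times Uncensored dwell times (>= 10 observations).
#' @param k Number of exponential components (1-3).
#' @param n_starts Number of random multi-starts (>= 5).
#' @param rng_seed Optional seed for the start dispersion.
#' @return An object of class `expmix` with `method = "cdf_ls"`.
#' @export
fit_cdf_exponentials <- function(times, k, n_starts = 5, rng_seed = NULL) {
  stopifnot(k >= 1, k <= 3)
  if (length(times) < 10) stop("need >= 10 uncensored observations")
  if (stats::sd(times) == 0)
    stop("degenerate input: all dwell times identical")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tt <- sort(times)
  Fhat <- seq_along(tt) / length(tt)
  loss <- function(theta) {
    p <- theta_to_par(theta, k)
    Fm <- colSums(p$fracs * (1 - exp(-outer(1 / p$taus, tt))))
    sum((Fm - Fhat)^2)
  }
  best <- NULL
  qs <- stats::quantile(tt, probs = seq(0.15, 0.85, length.out = k))
  for (s in seq_len(max(n_starts, 5))) {
    taus0 <- pmax(as.numeric(qs) * exp(stats::rnorm(k, 0, 0.8)), 1e-6)
    theta0 <- par_to_theta(taus0, rep(1 / k, k))
    fit <- tryCatch(stats::optim(theta0, loss, method = "BFGS",
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("CDF exponential fit failed to converge in all starts")
  p <- theta_to_par(best$par, k)
  p <- sort_components(p$taus, p$fracs)
  new_expmix(k, p$taus, p$fracs, loglik = NA_real_, method = "cdf_ls",
             n = length(times), n_censored = 0L, resolution = 0,
             loss = best$value)
}

expmix_loglik <- function(theta, k, t_obs, t_cens, n_sub, resolution) {
  p <- theta_to_par(theta, k)
  taus <- p$taus; fracs <- p$fracs
  ll <- 0
  if (length(t_obs)) {
    dens <- exp(-outer(t_obs, 1 / taus)) %*% (fracs / taus)
    ll <- ll + sum(log(pmax(dens, 1e-300)))
  }
  if (length(t_cens)) {
    surv <- exp(-outer(t_cens, 1 / taus)) %*% fracs
    ll <- ll + sum(log(pmax(surv, 1e-300)))
  }
  if (n_sub > 0) {
    pint <- sum(fracs * (1 - exp(-resolution / taus)))
    ll <- ll + n_sub * log(max(pint, 1e-300))
  }
  ll
}

#' Censored maximum-likelihood exponential-mixture fit
#'
#' The dwell-time estimator at the heart of the analysis.  Maximizes
#' \deqn{\sum_{uncens} \log \sum_j \frac{a_j}{\tau_j} e^{-t_i/\tau_j}
#'   + \sum_{cens} \log \sum_j a_j e^{-t_i/\tau_j}}
#' with observations below the acquisition `resolution` contributing the
#' interval likelihood \eqn{\sum_j a_j (1 - e^{-res/\tau_j})}.  Lifetimes are
#' optimized on the log scale (positivity) and fractions through a softmax;
#' components are reported sorted by ascending lifetime.  A fitted component
#' whose lifetime falls below the resolution is reported with lifetime 0
#' (sub-resolution), matching the convention that displacement faster than
#' the 0.2 s sampling of alternating excitation is indistinguishable from
#' instantaneous.
#'
#' @param times Dwell times in seconds (>= 20 observations for k >= 2).
#' @param censored Logical right-censoring flags (default none).
#' @param k Number of components (1-3).
#' @param resolution Acquisition time resolution in seconds (> 0); 0.2 s
#'   during alternating excitation.
#' @param n_starts Multi-start count.
#' @param rng_seed Optional seed for start dispersion.
#' @return An object of class `expmix`: lifetimes (`lifetimes`, with
#'   sub-resolution components reported as 0 and the raw optimum kept in
#'   `lifetimes_raw`), `fractions`, `loglik`, `n`, `n_censored`, `method`.
#' @export
fit_mle_mixture <- function(times, censored = NULL, k = 2, resolution = 0.2,
                            n_starts = 5, rng_seed = NULL) {
  if (k > 3) stop("at most 3 exponential components are supported")
  stopifnot(k >= 1, resolution > 0)
  if (is.null(censored)) censored <- rep(FALSE, length(times))
  stopifnot(length(censored) == length(times))
  if (length(times) < max(2 * k, if (k >= 2) 20 else 2))
    stop("too few observations for the requested number of components")
  if (!is.null(rng_seed)) set.seed(rng_seed)

  sub <- !censored & times < resolution
  t_obs <- times[!censored & !sub]
  t_cens <- times[censored]
  n_sub <- sum(sub)

  if (k == 1L && n_sub == 0L) {
    # closed-form censored-exponential MLE
    tau <- sum(times) / max(length(t_obs), 1L)
    ll <- expmix_loglik(log(tau), 1L, t_obs, t_cens, 0L, resolution)
    return(new_expmix(1L, tau, 1, loglik = ll, method = "mle",
                      n = length(times), n_censored = sum(censored),
                      resolution = resolution))
  }

  nll <- function(theta) -expmix_loglik(theta, k, t_obs, t_cens, n_sub,
                                        resolution)
  pos <- times[!censored]
  if (!length(pos)) pos <- times
  qs <- as.numeric(stats::quantile(pmax(pos, resolution / 2),
                                   probs = seq(0.1, 0.9, length.out = k)))
  best <- NULL
  for (s in seq_len(max(n_starts, 1))) {
    jitter <- if (s == 1L) rep(1, k) else exp(stats::rnorm(k, 0, 0.8))
    taus0 <- pmax(qs * jitter, resolution / 10)
    theta0 <- par_to_theta(taus0, rep(1 / k, k))
    fit <- tryCatch(stats::optim(theta0, nll, method = "BFGS",
                                 control = list(maxit = 1000)),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("mixture MLE failed to converge in all starts")
  p <- theta_to_par(best$par, k)
  p <- sort_components(p$taus, p$fracs)
  new_expmix(k, p$taus, p$fracs, loglik = -best$value, method = "mle",
             n = length(times), n_censored = sum(censored),
             resolution = resolution)
}

new_expmix <- function(k, taus, fracs, loglik, method, n, n_censored,
                       resolution, loss = NULL) {
  lifetimes <- taus
  if (resolution > 0) lifetimes[lifetimes < resolution] <- 0
  structure(list(n_components = as.integer(k),
                 lifetimes = lifetimes, lifetimes_raw = taus,
                 fractions = fracs, loglik = loglik, method = method,
                 n_observations = as.integer(n),
                 n_censored = as.integer(n_censored),
                 resolution = resolution, loss = loss,
                 ci_lower = NULL, ci_upper = NULL),
            class = "expmix")
}

#' @export
print.expmix <- function(x, ...) {
  cat(sprintf("Exponential mixture (%d component%s, %s)\n",
              x$n_components, if (x$n_components > 1) "s" else "",
              if (x$method == "mle") "censored MLE" else "CDF least squares"))
  for (j in seq_len(x$n_components)) {
    lt <- if (x$lifetimes[j] == 0)
      sprintf("< %.3g (sub-resolution)", x$resolution)
    else sprintf("%.4g", x$lifetimes[j])
    ci <- ""
    if (!is.null(x$ci_lower))
      ci <- sprintf("  [%.3g, %.3g]", x$ci_lower[j], x$ci_upper[j])
    cat(sprintf("  tau%d = %s s  (fraction %.3f)%s\n", j, lt,
                x$fractions[j], ci))
  }
  cat(sprintf("  n = %d (%d censored)", x$n_observations, x$n_censored))
  if (is.finite(x$loglik)) cat(sprintf(", logLik = %.2f", x$loglik))
  cat("\n")
  invisible(x)
}

#' @export
coef.expmix <- function(object, ...) {
  k <- object$n_components
  stats::setNames(c(object$lifetimes, object$fractions),
                  c(paste0("tau", seq_len(k)), paste0("A", seq_len(k))))
}

#' @export
logLik.expmix <- function(object, ...) {
  structure(object$loglik, df = 2L * object$n_components - 1L,
            nobs = object$n_observations, class = "logLik")
}

#' @export
summary.expmix <- function(object, ...) {
  print(object)
  cat(sprintf("  BIC = %.2f\n", bic_expmix(object)))
  invisible(object)
}

bic_expmix <- function(fit) {
  df <- 2L * fit$n_components - 1L
  -2 * fit$loglik + df * log(fit$n_observations)
}

#' Simulate dwell times from a fitted mixture
#'
#' @param object An `expmix` fit.
#' @param nsim Number of dwells to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Numeric vector of simulated dwell times.
#' @export
simulate.expmix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$n_components, nsim, replace = TRUE,
                     prob = object$fractions)
  stats::rexp(nsim, rate = 1 / pmax(object$lifetimes_raw[comp], 1e-12))
}

#' Plot a fitted mixture against the dwell-time data
#'
#' Draws the probability-density histogram of the dwells (with binomial
#' error bars) and overlays the fitted mixture density.
#'
#' @param x An `expmix` fit.
#' @param times The dwell times the model was fitted to.
#' @param bin_edges Histogram bin edges (default: 20 bins to the data max).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.expmix <- function(x, times, bin_edges = NULL, ...) {
  if (is.null(bin_edges))
    bin_edges <- seq(0, max(times) * 1.001, length.out = 21)
  h <- density_histogram(times, bin_edges)
  mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  graphics::plot(mids, h$density, type = "h", lwd = 3, col = "grey60",
                 xlab = "dwell time (s)", ylab = "probability density", ...)
  graphics::arrows(mids, pmax(h$density - h$error, 0),
                   mids, h$density + h$error,
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  tt <- seq(min(bin_edges), max(bin_edges), length.out = 400)
  dens <- colSums(x$fractions / pmax(x$lifetimes_raw, 1e-12) *
                    exp(-outer(1 / pmax(x$lifetimes_raw, 1e-12), tt)))
  graphics::lines(tt, dens, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Select the number of exponential components
#'
#' Chooses the smallest `k` that is not rejected against `k + 1` by a
#' likelihood-ratio test at `alpha` (2 degrees of freedom per added
#' component); BIC values are reported alongside for transparency.
#'
#' @param fits List of `expmix` MLE fits of nested `k` on identical data,
#'   ordered by increasing `k`.
#' @param alpha LRT significance level.
#' @return List: `k` (chosen), `lrt` (data frame of tests), `bic` (per fit).
#' @export
select_model <- function(fits, alpha = 0.05) {
  ks <- vapply(fits, `[[`, integer(1), "n_components")
  ns <- vapply(fits, `[[`, integer(1), "n_observations")
  if (any(diff(ks) != 1L) || length(unique(ns)) != 1L)
    stop("fits must be nested (consecutive k on identical data)")
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  lrt <- NULL
  chosen <- ks[length(ks)]
  for (i in seq_len(length(fits) - 1L)) {
    stat <- max(0, 2 * (lls[i + 1L] - lls[i]))
    pval <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
    lrt <- rbind(lrt, data.frame(k_null = ks[i], k_alt = ks[i + 1L],
                                 statistic = stat, p_value = pval))
    if (pval >= alpha) { chosen <- ks[i]; break }
  }
  list(k = chosen, lrt = lrt,
       bic = stats::setNames(vapply(fits, bic_expmix, numeric(1)),
                             paste0("k", ks)))
}

#' Bootstrap confidence intervals for a mixture fit
#'
#' Case resampling with replacement: each replicate refits the mixture
#' starting from the point estimate; percentile 68% and 95% intervals are
#' returned per parameter, with label switching resolved by sorting
#' lifetimes ascending.
#'
#' @param times,censored The data the fit was obtained from.
#' @param fit A converged `expmix` MLE fit.
#' @param n_boot Number of replicates (default 1000, > 0).
#' @param rng_seed Integer seed.
#' @param max_fail Maximum tolerated fraction of non-converged replicates.
#' @return The `fit` with `ci_lower`/`ci_upper` (95%, lifetimes then
#'   fractions), plus a `bootstrap` element holding the replicate matrix and
#'   the 68% intervals.
#' @export
bootstrap_errors <- function(times, censored = NULL, fit, n_boot = 1000,
                             rng_seed = 1, max_fail = 0.1) {
  if (n_boot <= 0) stop("n_boot must be positive")
  if (is.null(censored)) censored <- rep(FALSE, length(times))
  set.seed(rng_seed)
  k <- fit$n_components
  n <- length(times)
  theta_hat <- par_to_theta(fit$lifetimes_raw, fit$fractions)
  reps <- matrix(NA_real_, n_boot, 2L * k)
  fails <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    tb <- times[idx]; cb <- censored[idx]
    est <- tryCatch({
      sub <- !cb & tb < fit$resolution
      t_obs <- tb[!cb & !sub]; t_cens <- tb[cb]; n_sub <- sum(sub)
      if (k == 1L && n_sub == 0L) {
        tau <- sum(tb) / max(length(t_obs), 1L)
        list(taus = tau, fracs = 1)
      } else {
        nll <- function(th) -expmix_loglik(th, k, t_obs, t_cens, n_sub,
                                           fit$resolution)
        o <- stats::optim(theta_hat, nll, method = "BFGS",
                          control = list(maxit = 500))
        p <- theta_to_par(o$par, k)
        sort_components(p$taus, p$fracs)
      }
    }, error = function(e) NULL)
    if (is.null(est)) { fails <- fails + 1L; next }
    reps[b, ] <- c(est$taus, est$fracs)
  }
  if (fails / n_boot > max_fail)
    stop(sprintf("bootstrap: %d/%d replicates failed to converge",
                 fails, n_boot))
  qs95 <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
  qs68 <- apply(reps, 2, stats::quantile, probs = c(0.16, 0.84),
                na.rm = TRUE)
  fit$ci_lower <- qs95[1, ]
  fit$ci_upper <- qs95[2, ]
  fit$bootstrap <- list(replicates = reps, n_failed = fails,
                        ci68_lower = qs68[1, ], ci68_upper = qs68[2, ],
                        seed = rng_seed)
  fit
}

#' Probability-density histogram with binomial error bars
#'
#' Density per bin \eqn{d_i = n_i / (N w_i)} with error
#' \eqn{\sqrt{p_i(1-p_i)/N} / w_i}, \eqn{p_i = n_i/N} — the binomial
#' variance of the bin occupancy.
#'
#' @param times Dwell times.
#' @param bin_edges Strictly increasing bin edges.
#' @return Data frame: `bin_lo`, `bin_hi`, `count`, `density`, `error`.
#' @export
density_histogram <- function(times, bin_edges) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be increasing")
  if (!length(times)) stop("no observations")
  n_i <- graphics::hist(times, breaks = bin_edges, plot = FALSE,
                        right = FALSE, include.lowest = TRUE)$counts
  N <- length(times)
  w <- diff(bin_edges)
  p <- n_i / N
  data.frame(bin_lo = bin_edges[-length(bin_edges)], bin_hi = bin_edges[-1],
             count = n_i, density = p / w,
             error = sqrt(p * (1 - p) / N) / w)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D = sup |F_x - F_y| with the asymptotic p-value, via [stats::ks.test()].
#'
#' @param x,y Dwell-time samples.
#' @return List with `D` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Cellular access-time bound for the stable-coexistence threshold
#'
#' Converts a cellular mRNA copy-number range and cell volume into a
#' concentration range, and with the apparent association rate constant into
#' the time an RNA needs to access Hfq: concentration = copies / (volume x
#' Avogadro), access time = 1 / (k_on x concentration).  With 10-60 copies
#' in 0.5 um^3 and k_on = 2e5 /M/s this reproduces the ~30-200 nM and
#' ~25-150 s ranges that justify the 20 s threshold.
#'
#' @param copies Length-2 (or scalar) copy-number range.
#' @param volume_um3 Cell volume in cubic micrometres.
#' @param k_on Association rate constant in /M/s.
#' @return Data frame: `copies`, `concentration_nM`, `access_time_s`.
#' @export
access_time_bound <- function(copies = c(10, 60), volume_um3 = 0.5,
                              k_on = 2e5) {
  stopifnot(all(copies > 0), volume_um3 > 0, k_on > 0)
  avogadro <- 6.02214076e23
  litres <- volume_um3 * 1e-15
  conc_M <- copies / (litres * avogadro)
  data.frame(copies = copies,
             concentration_nM = conc_M * 1e9,
             access_time_s = 1 / (k_on * conc_M))
}
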