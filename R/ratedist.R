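#' Firing-rate histogram on a log10 axis
#'
#' Bins the firing rates of active electrodes on a log10(events/s) axis with a
#' fixed grid (default bin width 0.1 over [-1.5, 1.1], covering the active
#' range 0.05-10 ev/s), density-normalized so heights times bin widths sum
#' to 1. A fixed grid keeps fits comparable across developmental time points.
#'
#' @param x a [spike_train_set()] or a numeric vector of rates (events/s).
#' @param config an [analysis_config()]; rates outside the active bounds are
#'   excluded (zero-rate electrodes are inactive by definition).
#' @param bin_width bin width in log10 units.
#' @param range log10 range of the grid.
#' @return object of class `rate_histogram`: list with `breaks`, `mids`,
#'   `density`, `counts`, `n` (electrodes retained).
#' @export
rate_histogram <- function(x, config = analysis_config(), bin_width = 0.1,
                           range = c(-1.5, 1.1)) {
  rates <- if (inherits(x, "spike_train_set")) electrode_rates(x) else
    as.numeric(x)
  rates <- rates[rates >= config$active_rate_bounds[1L] &
                   rates <= config$active_rate_bounds[2L]]
  if (length(rates) < 10L)
    stop("fewer than 10 active electrodes; record longer or more activity")
  breaks <- seq(range[1L], range[2L] + 1e-9, by = bin_width)
  lr <- log10(rates)
  lr <- lr[lr >= breaks[1L] & lr <= breaks[length(breaks)]]
  h <- graphics::hist(lr, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, density = h$density,
                 counts = h$counts, n = length(lr)),
            class = "rate_histogram")
}

#' Fit a Gaussian to the log-rate histogram
#'
#' Least-squares Gaussian fit `A * exp(-(x - mu)^2 / (2 sigma^2))` to the
#' density-normalized histogram on the log10 axis — the standard way of
#' quantifying a lognormal-like firing-rate distribution. Parameter standard
#' errors come from the fit covariance; the goodness of fit is the R-squared
#' of the fitted curve against the histogram, flagged poor below `gof_min`.
#'
#' @param h a [rate_histogram()], with at least 5 occupied bins.
#' @param gof_min R-squared below which the fit is flagged.
#' @return object of class `lognormal_fit`: list with `mu`, `sigma`,
#'   `amplitude`, `se` (named vector), `ci` (95\% intervals), `gof`,
#'   `poor_fit`, `fitted`, `h`.
#' @export
fit_lognormal <- function(h, gof_min = 0.8) {
  stopifnot(inherits(h, "rate_histogram"))
  if (sum(h$counts > 0) < 5L)
    stop("fewer than 5 occupied bins; cannot fit")
  d <- h$density; m <- h$mids
  w <- d / sum(d)
  mu0 <- sum(w * m)
  s0 <- max(sqrt(sum(w * (m - mu0)^2)), 0.05)
  A0 <- max(d)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ A * exp(-(m - mu)^2 / (2 * s^2)),
                      start = list(A = A0, mu = mu0, s = s0),
                      lower = c(0, min(m), 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("Gaussian fit failed (%s); starts A=%.3g mu=%.3g s=%.3g on %d bins",
                   conditionMessage(e), A0, mu0, s0, sum(h$counts > 0)))
  )
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  pred <- stats::predict(fit)
  ss_res <- sum((d - pred)^2)
  ss_tot <- sum((d - mean(d))^2)
  gof <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  names(se) <- c("amplitude", "mu", "sigma")
  structure(list(
    mu = unname(cf["mu"]), sigma = unname(abs(cf["s"])),
    amplitude = unname(cf["A"]), se = se,
    ci = rbind(mu = cf["mu"] + c(-1.96, 1.96) * se["mu"],
               sigma = abs(cf["s"]) + c(-1.96, 1.96) * se["sigma"]),
    gof = gof, poor_fit = is.na(gof) || gof < gof_min,
    fitted = pred, h = h
  ), class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> mu = %.3f, sigma = %.3f log10(ev/s), R^2 = %.3f%s\n",
              x$mu, x$sigma, x$gof, if (x$poor_fit) " (poor fit)" else ""))
  invisible(x)
}

#' Compare two log-rate distribution fits
#'
#' Quantifies the shift between two fitted firing-rate distributions as a
#' fold change `10^(mu_a - mu_b)`, with the convention that `fit_a` is the
#' earlier time point: a fold > 1 means the distribution shifted toward low
#' firing rates. The peak-height ratio is `amplitude_b / amplitude_a`.
#'
#' @param fit_a,fit_b converged [fit_lognormal()] objects (earlier, later).
#' @return list with `fold_shift`, `peak_ratio`, `direction`.
#' @export
compare_fits <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "lognormal_fit"), inherits(fit_b, "lognormal_fit"))
  if (fit_a$poor_fit || fit_b$poor_fit)
    warning("comparing fits flagged as poor")
  fold <- 10^(fit_a$mu - fit_b$mu)
  list(
    fold_shift = fold,
    peak_ratio = fit_b$amplitude / fit_a$amplitude,
    direction = if (fold > 1) "toward low firing rates"
      else if (fold < 1) "toward high firing rates" else "no shift"
  )
}
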