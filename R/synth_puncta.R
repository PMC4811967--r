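#' Generate a synthetic fluorescence puncta image with ground truth
#'
#' Renders diffraction-limited synaptic puncta as Gaussian-profile ellipses on
#' a smooth heterogeneous background (a low plateau plus a few broad Gaussian
#' blobs) with additive pixel noise, emulating a single-channel confocal
#' micrograph of immunostained puncta. Puncta centres are placed by rejection
#' sampling so that no two objects overlap; the ground truth lists every
#' centre, major axis and peak intensity.
#'
#' The Gaussian major-axis SD is `major_axis / 2.9`, calibrated so that the
#' major axis of the above-threshold region measured by [count_puncta()]
#' approximates the programmed axis for typical filtered-intensity thresholds.
#'
#' @param n_puncta number of puncta.
#' @param axis_range range (um) the major axes are drawn from, uniformly.
#' @param scale image scale (um/pixel).
#' @param size image side length (pixels).
#' @param background list with `level` (plateau), `amplitude` and `n_blobs`
#'   (broad background blobs), `blob_sd_um` (their SD in um).
#' @param noise_sd pixel noise SD (intensity units).
#' @param peak_range punctum peak intensity range.
#' @param seed random seed.
#' @return list with `image` (a [puncta_image()]) and `truth` (data frame of
#'   `x_um`, `y_um`, `major_axis_um`, `peak`).
#' @export
gen_puncta_image <- function(n_puncta = 50L, axis_range = c(0.5, 1.0),
                             scale = 0.077, size = 512L,
                             background = list(level = 0.08, amplitude = 0.05,
                                               n_blobs = 4L, blob_sd_um = 8),
                             noise_sd = 0.02, peak_range = c(0.5, 0.9),
                             seed = 1L) {
  if (scale <= 0) stop("`scale` must be positive (um/pixel)")
  if (axis_range[1L] / scale < 2)
    stop("puncta would span fewer than 2 pixels at this scale")
  set.seed(seed)
  size <- as.integer(size)
  field_um <- size * scale
  px <- matrix(background$level, size, size)
  xg <- (seq_len(size) - 0.5) * scale
  # smooth heterogeneous background
  if (background$n_blobs > 0) {
    for (b in seq_len(background$n_blobs)) {
      cx <- stats::runif(1, 0, field_um); cy <- stats::runif(1, 0, field_um)
      s <- background$blob_sd_um
      px <- px + background$amplitude *
        exp(-0.5 * outer((xg - cy)^2, (xg - cx)^2, "+") / s^2)
    }
  }
  # non-overlapping punctum placement
  axes <- stats::runif(n_puncta, axis_range[1L], axis_range[2L])
  peaks <- stats::runif(n_puncta, peak_range[1L], peak_range[2L])
  margin <- if (n_puncta > 0) max(axes) + 2 * scale else 0
  centres <- matrix(NA_real_, n_puncta, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < n_puncta) {
    tries <- tries + 1L
    if (tries > 200L * n_puncta)
      stop("requested puncta density too high to place without overlap")
    cand <- stats::runif(2, margin, field_um - margin)
    if (placed > 0L) {
      dmin <- axes[placed + 1L] + axes[seq_len(placed)] + 4 * scale
      dd <- sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) - cand)^2))
      if (any(dd < dmin)) next
    }
    placed <- placed + 1L
    centres[placed, ] <- cand
  }
  for (i in seq_len(n_puncta)) {
    s_maj <- axes[i] / 2.9
    s_min <- s_maj * stats::runif(1, 0.6, 1)
    th <- stats::runif(1, 0, pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L)
    # pixels within 4 sigma of the centre
    r_px <- ceiling(4 * s_maj / scale)
    ci <- round(centres[i, ] / scale)
    rows <- max(1L, ci[2L] - r_px):min(size, ci[2L] + r_px)
    cols <- max(1L, ci[1L] - r_px):min(size, ci[1L] + r_px)
    dy <- xg[rows] - centres[i, 2L]
    dx <- xg[cols] - centres[i, 1L]
    g <- expand.grid(dy = dy, dx = dx)
    u <- as.matrix(g) %*% R
    q <- (u[, 1L] / s_min)^2 + (u[, 2L] / s_maj)^2
    px[rows, cols] <- px[rows, cols] +
      peaks[i] * matrix(exp(-0.5 * q), length(rows), length(cols))
  }
  px <- px + matrix(stats::rnorm(size * size, 0, noise_sd), size, size)
  px <- pmin(pmax(px, 0), 1)
  list(
    image = puncta_image(px, scale = scale, channel = "synthetic"),
    truth = data.frame(x_um = centres[, 1L], y_um = centres[, 2L],
                       major_axis_um = axes, peak = peaks)
  )
}
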