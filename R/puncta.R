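#' Fluorescence puncta image
#'
#' A single-channel greyscale micrograph with a physical scale. Intensities
#' are normalized to [0, 1] (dividing by the maximum when needed).
#'
#' @param pixels numeric matrix of intensities.
#' @param scale micrometres per pixel.
#' @param channel optional channel label (e.g. `"PSD-95"`, `"V-GLUT"`).
#' @return object of class `puncta_image`.
#' @export
puncta_image <- function(pixels, scale, channel = NA_character_) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("pixel intensities must be finite")
  if (scale <= 0) stop("`scale` must be positive (um/pixel)")
  mx <- max(pixels)
  if (mx > 1) pixels <- pixels / mx
  if (min(pixels) < 0) stop("pixel intensities must be non-negative")
  structure(list(pixels = pixels, scale = scale, channel = channel),
            class = "puncta_image")
}

#' @export
print.puncta_image <- function(x, ...) {
  cat(sprintf("<puncta_image> %d x %d px at %g um/px (%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$scale, x$channel))
  invisible(x)
}

#' Read a greyscale image as a puncta image
#'
#' Reads a TIFF or PNG micrograph (averaging channels if needed).
#'
#' @param path image file.
#' @param scale micrometres per pixel.
#' @param channel optional channel label.
#' @return a [puncta_image()].
#' @export
read_puncta_image <- function(path, scale, channel = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package `tiff` is required to read TIFF images")
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package `png` is required to read PNG images")
      png::readPNG(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(px)) == 3L) px <- apply(px, c(1L, 2L), mean)
  puncta_image(px, scale, channel)
}

#' Granulometric filtering of a puncta image
#'
#' Size-selective isolation of small bright objects: the smooth heterogeneous
#' background is estimated by grayscale morphological opening with a disc
#' structuring element slightly larger than the maximum punctum diameter
#' (derived from the upper major-axis bound and the image scale), and
#' subtracted (white top-hat). The filtered intensities are binarized at
#' `max(threshold, offset)`: the threshold defaults to Otsu's method on the
#' filtered image, and the offset (default 0.07) is the floor above which
#' puncta are picked; along any cross-section the reported punctum locations
#' are exactly the runs where the filtered intensity exceeds the offset.
#'
#' @param image a [puncta_image()].
#' @param threshold binarization threshold in [0, 1], or `NULL` for Otsu.
#' @param offset intensity offset (floor) in [0, 1).
#' @param config an [analysis_config()] (axis bounds for the disc size).
#' @return object of class `granulo_filter`: list with `filtered` (matrix),
#'   `mask` (logical matrix), `threshold` (the applied cutoff), `se_diameter`
#'   (px), `scale`.
#' @export
granulometric_filter <- function(image, threshold = NULL,
                                 offset = NULL, config = analysis_config()) {
  stopifnot(inherits(image, "puncta_image"))
  if (is.null(offset)) offset <- config$puncta_offset
  if (offset < 0 || offset >= 1) stop("`offset` must lie in [0, 1)")
  if (!is.null(threshold) && (threshold < 0 || threshold > 1))
    stop("`threshold` must lie in [0, 1]")
  px <- image$pixels
  r_px <- ceiling(config$puncta_axis_bounds[2L] / image$scale / 2) + 2L
  d <- 2L * r_px + 1L
  brush <- EBImage::makeBrush(d, shape = "disc")
  # smooth before opening so the background estimate is not biased low by
  # pixel noise (the opening of raw noise sits ~2.5 SD below its mean)
  smoothed <- EBImage::gblur(EBImage::Image(px), sigma = 2)
  bg <- EBImage::opening(smoothed, brush)
  filtered <- pmax(px - as.matrix(bg@.Data), 0)
  if (is.null(threshold)) {
    threshold <- tryCatch(EBImage::otsu(EBImage::Image(filtered)),
                          error = function(e) offset)
  }
  cut <- max(threshold, offset)
  structure(list(filtered = filtered, mask = filtered > cut,
                 threshold = cut, se_diameter = d, scale = image$scale),
            class = "granulo_filter")
}

#' Above-offset runs along a cross-section
#'
#' @param gf a [granulometric_filter()] result.
#' @param row image row of the cross-section.
#' @param offset intensity offset; defaults to the filter's applied cutoff.
#' @return data frame with `start_um`, `end_um` of each above-offset run.
#' @export
cross_section_runs <- function(gf, row, offset = gf$threshold) {
  profile <- gf$filtered[row, ]
  above <- profile > offset
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_um = (starts[keep] - 1) * gf$scale,
             end_um = ends[keep] * gf$scale)
}

#' Count and measure puncta
#'
#' Labels connected components of the granulometric mask, measures each
#' component's centroid and major axis via the best-fit (second-moment)
#' ellipse, discards components whose major axis falls outside the configured
#' bounds (0.3-1.3 um) and reports the density per square micrometre of the
#' field.
#'
#' @param gf a [granulometric_filter()] result.
#' @param config an [analysis_config()] (axis bounds).
#' @return object of class `puncta_set`: list with `puncta` (data frame
#'   `x_um`, `y_um`, `major_axis_um`, `integrated_intensity`), `n`,
#'   `field_area_um2`, `density`, `n_rejected`.
#' @export
count_puncta <- function(gf, config = analysis_config()) {
  stopifnot(inherits(gf, "granulo_filter"))
  if (is.null(gf$scale) || gf$scale <= 0) stop("image scale is missing")
  field_area <- prod(dim(gf$mask)) * gf$scale^2
  lab <- EBImage::bwlabel(EBImage::Image(gf$mask * 1))
  n_obj <- max(lab)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      major_axis_um = numeric(0),
                      integrated_intensity = numeric(0))
  if (n_obj == 0)
    return(structure(list(puncta = empty, n = 0L,
                          field_area_um2 = field_area, density = 0,
                          n_rejected = 0L), class = "puncta_set"))
  mom <- EBImage::computeFeatures.moment(lab)
  mom <- matrix(mom, ncol = ncol(mom), dimnames = dimnames(mom))
  lab_m <- as.matrix(lab@.Data)
  intens <- as.numeric(tapply(gf$filtered[lab_m > 0], lab_m[lab_m > 0], sum))
  major_um <- mom[, "m.majoraxis"] * gf$scale
  b <- config$puncta_axis_bounds
  keep <- major_um >= b[1L] & major_um <= b[2L]
  # computeFeatures.moment: m.cx runs along matrix rows, m.cy along columns
  puncta <- data.frame(
    x_um = (mom[keep, "m.cy"] - 0.5) * gf$scale,
    y_um = (mom[keep, "m.cx"] - 0.5) * gf$scale,
    major_axis_um = major_um[keep],
    integrated_intensity = intens[keep]
  )
  structure(list(puncta = puncta, n = sum(keep),
                 field_area_um2 = field_area,
                 density = sum(keep) / field_area,
                 n_rejected = sum(!keep)),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d puncta over %.0f um^2 (%.4g /um^2)\n",
              x$n, x$field_area_um2, x$density))
  invisible(x)
}

#' Compare puncta densities between two conditions
#'
#' Fold change `mean(a) / mean(b)` of per-field densities, with SEM by
#' first-order error propagation and a two-sided Wilcoxon rank-sum p-value.
#'
#' @param densities_a,densities_b numeric per-field densities (puncta/um^2);
#'   at least 3 fields per condition.
#' @return list with `fold`, `fold_sem`, `p_value`, `n_a`, `n_b`.
#' @export
condition_comparison <- function(densities_a, densities_b) {
  if (length(densities_a) < 3L || length(densities_b) < 3L)
    stop("at least 3 fields per condition are required")
  ma <- mean(densities_a); mb <- mean(densities_b)
  if (mb == 0) stop("zero mean density in the denominator condition")
  sa <- stats::sd(densities_a) / sqrt(length(densities_a))
  sb <- stats::sd(densities_b) / sqrt(length(densities_b))
  fold <- ma / mb
  list(
    fold = fold,
    fold_sem = fold * sqrt((sa / ma)^2 + (sb / mb)^2),
    p_value = suppressWarnings(
      stats::wilcox.test(densities_a, densities_b)$p.value),
    n_a = length(densities_a), n_b = length(densities_b)
  )
}

#' Excitatory/inhibitory puncta-count ratio
#'
#' Per-field ratio of V-GLUT to V-GAT puncta counts (paired channels from the
#' same fields), summarized as mean +/- SEM over fields. Fields with zero
#' V-GAT counts are excluded with a warning; with a single usable field the
#' SEM is `NA` and flagged.
#'
#' @param vglut,vgat paired per-field puncta counts (numeric vectors or lists
#'   of [count_puncta()] results).
#' @return list with `ratio`, `sem`, `per_field`, `n_fields`, `sem_defined`.
#' @export
glut_gat_ratio <- function(vglut, vgat) {
  as_counts <- function(x)
    if (is.list(x)) vapply(x, function(p) p$n, numeric(1)) else as.numeric(x)
  g <- as_counts(vglut); a <- as_counts(vgat)
  if (length(g) != length(a))
    stop("V-GLUT and V-GAT must be paired per field")
  zero <- a == 0
  if (any(zero)) {
    warning(sprintf("%d field(s) with zero V-GAT count excluded", sum(zero)))
    g <- g[!zero]; a <- a[!zero]
  }
  if (!length(g)) stop("no usable fields")
  ratios <- g / a
  list(
    ratio = mean(ratios),
    sem = if (length(ratios) > 1L) stats::sd(ratios) / sqrt(length(ratios))
      else NA_real_,
    per_field = ratios,
    n_fields = length(ratios),
    sem_defined = length(ratios) > 1L
  )
}
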