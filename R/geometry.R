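#' Electrode array geometry
#'
#' Describes the electrode grid of a CMOS multielectrode array: a regular
#' `n_rows` x `n_cols` lattice of square electrodes at a fixed pitch, with an
#' optional set of dedicated stimulation sites. The default corresponds to a
#' 64 x 64 array of 4096 recording electrodes (21 x 21 um electrodes, 42 um
#' pitch). All distance computations in the package derive from this object;
#' distances are expressed in pitch units (i.e. "electrodes") unless stated
#' otherwise.
#'
#' @param n_rows,n_cols grid dimensions (default 64 x 64).
#' @param pitch centre-to-centre electrode spacing in micrometres.
#' @param electrode_size electrode side length in micrometres.
#' @param stim_sites optional integer matrix (or 2-column data frame) of
#'   stimulation-site grid positions, one `(row, col)` pair per row, 1-based.
#'   At most 16 sites.
#' @return an object of class `array_geometry`.
#' @examples
#' geom <- array_geometry()
#' n_electrodes(geom)
#' @export
array_geometry <- function(n_rows = 64L, n_cols = 64L, pitch = 42,
                           electrode_size = 21, stim_sites = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) || pitch <= 0)
    stop("`pitch` must be a single positive number (um)")
  if (!is.null(stim_sites)) {
    stim_sites <- as.matrix(stim_sites)
    storage.mode(stim_sites) <- "integer"
    if (ncol(stim_sites) != 2L)
      stop("`stim_sites` must have two columns (row, col)")
    if (nrow(stim_sites) > 16L)
      stop("at most 16 stimulation sites are supported")
    bad <- stim_sites[, 1L] < 1L | stim_sites[, 1L] > n_rows |
      stim_sites[, 2L] < 1L | stim_sites[, 2L] > n_cols
    if (any(bad))
      stop("stimulation sites must lie inside the electrode grid")
    colnames(stim_sites) <- c("row", "col")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
         electrode_size = electrode_size, stim_sites = stim_sites),
    class = "array_geometry"
  )
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> %d x %d electrodes, pitch %g um, %d stim sites\n",
              x$n_rows, x$n_cols, x$pitch,
              if (is.null(x$stim_sites)) 0L else nrow(x$stim_sites)))
  invisible(x)
}

#' Number of electrodes in a geometry
#' @param geometry an [array_geometry()].
#' @return integer electrode count (`n_rows * n_cols`).
#' @export
n_electrodes <- function(geometry) geometry$n_rows * geometry$n_cols

#' Electrode grid coordinates
#'
#' Electrodes are indexed 1..n in row-major order; this returns their
#' `(row, col)` grid coordinates.
#'
#' @param geometry an [array_geometry()].
#' @return a matrix with columns `row`, `col`, one row per electrode.
#' @export
electrode_coords <- function(geometry) {
  n <- n_electrodes(geometry)
  idx <- seq_len(n) - 1L
  cbind(row = idx %/% geometry$n_cols + 1L,
        col = idx %% geometry$n_cols + 1L)
}

#' Electrode-to-site distances in pitch units
#'
#' Euclidean distance on the grid between every electrode and a stimulation
#' site, in pitch units ("electrode distances"). Multiply by `geometry$pitch`
#' for micrometres.
#'
#' @param geometry an [array_geometry()].
#' @param site either an index into `geometry$stim_sites` or a length-2
#'   `(row, col)` position.
#' @return numeric vector, one distance per electrode.
#' @export
electrode_distances <- function(geometry, site) {
  pos <- resolve_site(geometry, site)
  xy <- electrode_coords(geometry)
  sqrt((xy[, "row"] - pos[1L])^2 + (xy[, "col"] - pos[2L])^2)
}

resolve_site <- function(geometry, site) {
  if (length(site) == 1L) {
    if (is.null(geometry$stim_sites))
      stop("geometry has no stimulation sites; pass a (row, col) position")
    site <- as.integer(site)
    if (site < 1L || site > nrow(geometry$stim_sites))
      stop("stimulation-site index out of range")
    return(as.numeric(geometry$stim_sites[site, ]))
  }
  pos <- as.numeric(site)
  if (length(pos) != 2L) stop("`site` must be an index or a (row, col) pair")
  if (pos[1L] < 1 || pos[1L] > geometry$n_rows ||
      pos[2L] < 1 || pos[2L] > geometry$n_cols)
    stop("stimulation site lies off the electrode grid")
  pos
}

#' Concentric ring specification around a stimulation site
#'
#' Builds the circular regions used for latency-versus-distance analysis: an
#' innermost disc of radius `radii[1]` and annuli between consecutive radii,
#' all in pitch units. The default radii run from 4 to 30 electrodes in steps
#' of 2. The rings partition the disc of the largest radius.
#'
#' @param radii increasing numeric radii in pitch units.
#' @return an object of class `ring_spec` with elements `radii` and `area`
#'   (disc areas `pi * r^2` in squared pitch units).
#' @export
ring_spec <- function(radii = seq(4, 30, by = 2)) {
  radii <- as.numeric(radii)
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("`radii` must be positive and strictly increasing")
  structure(list(radii = radii, area = ring_area(radii)), class = "ring_spec")
}

#' Disc area for a ring radius
#'
#' Area of the circular region of radius `r` in pitch units, `pi * r^2`
#' (squared pitch units). For the default geometry these reproduce the region
#' sizes quoted with the ring radii (r = 4 -> ~50, r = 30 -> ~2827).
#'
#' @param r radius in pitch units (vectorized).
#' @return `pi * r^2`.
#' @export
ring_area <- function(r) pi * r^2

#' Assign electrodes to rings
#'
#' @param geometry an [array_geometry()].
#' @param site stimulation site (index or `(row, col)`).
#' @param rings a [ring_spec()].
#' @return integer vector, one entry per electrode: the ring index
#'   (1 = innermost disc), or `NA` for electrodes beyond the largest radius.
#' @export
ring_membership <- function(geometry, site, rings = ring_spec()) {
  d <- electrode_distances(geometry, site)
  # innermost disc is [0, r1]; annuli are (r_{k-1}, r_k]
  idx <- findInterval(d, c(0, rings$radii), left.open = TRUE)
  idx[d == 0] <- 1L
  idx[idx > length(rings$radii)] <- NA_integer_
  as.integer(idx)
}

#' Default stimulation-site layout
#'
#' A regular 4 x 4 layout of 16 stimulation sites interleaved in the array,
#' mimicking a stimulation-capable chip.
#'
#' @param n_rows,n_cols grid dimensions of the host array.
#' @return integer matrix of 16 `(row, col)` positions.
#' @export
default_stim_sites <- function(n_rows = 64L, n_cols = 64L) {
  r <- round(seq(n_rows / 8, n_rows * 7 / 8, length.out = 4))
  c <- round(seq(n_cols / 8, n_cols * 7 / 8, length.out = 4))
  as.matrix(expand.grid(row = as.integer(r), col = as.integer(c)))
}
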