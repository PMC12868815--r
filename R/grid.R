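#' Capture-array geometry description
#'
#' Physical geometry of a Visium-style capture array: circular spots of
#' 55 um diameter packed hexagonally at 100 um center-to-center spacing,
#' leaving a 45 um interstitial gap between capture areas.
#'
#' @param spot_diameter_um Spot (capture area) diameter in microns.
#' @param center_spacing_um Center-to-center spacing of adjacent spots in
#'   microns; must exceed `spot_diameter_um`.
#' @param microns_per_pixel Image scale of the full-resolution image, in
#'   microns per pixel.
#' @param n_rows,n_cols Array dimensions in lattice rows/columns.
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(n_rows = 4, n_cols = 6)
#' interstitial_gap(g)  # 45
#' @export
grid_geometry <- function(spot_diameter_um = 55, center_spacing_um = 100,
                          microns_per_pixel = 10 / 3,
                          n_rows = 64L, n_cols = 64L) {
  if (!is.numeric(spot_diameter_um) || spot_diameter_um <= 0 ||
      !is.numeric(center_spacing_um) || center_spacing_um <= 0 ||
      !is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("spot diameter, spacing and scale must be positive", call. = FALSE)
  if (spot_diameter_um >= center_spacing_um)
    stop("spot_diameter_um must be smaller than center_spacing_um",
         call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  structure(list(spot_diameter_um = spot_diameter_um,
                 center_spacing_um = center_spacing_um,
                 microns_per_pixel = microns_per_pixel,
                 n_rows = n_rows, n_cols = n_cols),
            class = "grid_geometry")
}

#' @rdname grid_geometry
#' @param geometry A `grid_geometry` object.
#' @export
interstitial_gap <- function(geometry) {
  geometry$center_spacing_um - geometry$spot_diameter_um
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "capture-array geometry: %g um spots @ %g um spacing (gap %g um), %d x %d, %.4g um/px\n",
    x$spot_diameter_um, x$center_spacing_um, interstitial_gap(x),
    x$n_rows, x$n_cols, x$microns_per_pixel))
  invisible(x)
}

# Parity-lattice neighbour offsets: (0, +-2) and (+-1, +-1).
.hex_offsets <- cbind(dr = c(0L, 0L, -1L, -1L, 1L, 1L),
                      dc = c(-2L, 2L, -1L, 1L, -1L, 1L))

#' Hexagonal-lattice neighbours of an array position
#'
#' Visium arrays use a parity convention: a spot exists at `(row, col)` only
#' when `row + col` is even, and its six neighbours sit at `(row, col +- 2)`
#' and `(row +- 1, col +- 1)`. Positions outside the array are dropped.
#'
#' @param array_row,array_col Integer lattice coordinates with even parity.
#' @param n_rows,n_cols Optional array bounds (rows `0..n_rows-1`, columns
#'   `0..n_cols-1`); `NULL` leaves the lattice unbounded.
#' @return Integer matrix with columns `array_row`, `array_col`.
#' @export
hex_neighbors <- function(array_row, array_col, n_rows = NULL, n_cols = NULL) {
  if ((array_row + array_col) %% 2L != 0L)
    stop("(array_row + array_col) must be even on the parity lattice",
         call. = FALSE)
  nb <- cbind(array_row = array_row + .hex_offsets[, "dr"],
              array_col = array_col + .hex_offsets[, "dc"])
  keep <- nb[, 1L] >= 0L & nb[, 2L] >= 0L
  if (!is.null(n_rows)) keep <- keep & nb[, 1L] < n_rows
  if (!is.null(n_cols)) keep <- keep & nb[, 2L] < n_cols
  nb[keep, , drop = FALSE]
}

#' Build a hexagonal capture lattice
#'
#' Lays out spots on the parity lattice: row `r` carries spots at the
#' columns of matching parity, so every interior spot has six neighbours at
#' exactly `center_spacing_um`. Micron coordinates place columns at half the
#' spacing and rows at `sqrt(3)/2` times the spacing; pixel coordinates are
#' the micron centers divided by `microns_per_pixel` and rounded to the
#' nearest pixel.
#'
#' @param geometry A [grid_geometry()].
#' @return A `data.frame` of class `spot_grid` with columns `spot_id`,
#'   `array_row`, `array_col`, `um_x`, `um_y`, `px_row`, `px_col`,
#'   `in_tissue`, and the geometry attached as attribute `"geometry"`.
#' @export
make_hex_grid <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  rows <- seq_len(geometry$n_rows) - 1L
  spots <- do.call(rbind, lapply(rows, function(r) {
    cols <- seq.int(r %% 2L, by = 2L, length.out = ceiling(geometry$n_cols / 2))
    cbind(array_row = rep.int(r, length(cols)), array_col = cols)
  }))
  s <- geometry$center_spacing_um
  um_x <- spots[, "array_col"] * s / 2
  um_y <- spots[, "array_row"] * s * sqrt(3) / 2
  grid <- data.frame(
    spot_id = sprintf("spot_%03d_%03d", spots[, "array_row"],
                      spots[, "array_col"]),
    array_row = spots[, "array_row"],
    array_col = spots[, "array_col"],
    um_x = um_x, um_y = um_y,
    px_row = round(um_y / geometry$microns_per_pixel),
    px_col = round(um_x / geometry$microns_per_pixel),
    in_tissue = 1L,
    stringsAsFactors = FALSE)
  attr(grid, "geometry") <- geometry
  class(grid) <- c("spot_grid", "data.frame")
  grid
}

#' Full-resolution image scale from a scale-factors record
#'
#' The microns-per-pixel scale of a sample is taken as the mean of the two
#' available physical/pixel diameter ratios: spot (55 um by default) and
#' fiducial (85 um vendor constant by default). A warning is emitted when
#' the two channels disagree by more than 1% relative.
#'
#' @param scalefactors List or data.frame with `spot_diameter_fullres` and
#'   `fiducial_diameter_fullres` (pixels).
#' @param spot_diameter_um,fiducial_diameter_um Physical diameters in
#'   microns.
#' @return Scale in microns per full-resolution pixel.
#' @export
microns_per_pixel <- function(scalefactors, spot_diameter_um = 55,
                              fiducial_diameter_um = 85) {
  sp <- scalefactors$spot_diameter_fullres
  fd <- scalefactors$fiducial_diameter_fullres
  if (is.null(sp) || is.null(fd) || sp <= 0 || fd <= 0)
    stop("scalefactors must carry positive spot and fiducial diameters",
         call. = FALSE)
  r1 <- spot_diameter_um / sp
  r2 <- fiducial_diameter_um / fd
  if (abs(r1 - r2) > 0.01 * max(r1, r2))
    warning(sprintf(
      "discordant scale estimates: spot %.4g vs fiducial %.4g um/px; using the mean",
      r1, r2), call. = FALSE)
  mean(c(r1, r2))
}
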