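#' Convert an RGB image to optical density
#'
#' Beer-Lambert conversion: `OD_c = -log10((I_c + eps) / I0)`, clipped at
#' zero below. The one-intensity-unit guard avoids `log(0)` at fully
#' absorbing pixels and sits below 8-bit quantization noise; it also makes
#' OD exactly zero wherever the pixel equals the background intensity.
#'
#' @param image Numeric `H x W x 3` array (or `H x W` matrix) of channel
#'   intensities in `[0, I0]`.
#' @param I0 Background (incident) intensity, default 255.
#' @param eps Guard added to intensities before the log.
#' @return Array of the same shape holding per-channel optical densities.
#' @export
rgb_to_od <- function(image, I0 = 255, eps = 1) {
  if (I0 <= 0) stop("I0 must be positive", call. = FALSE)
  od <- -log10((image + eps) / I0)
  od[od < 0] <- 0
  od
}

# Pixel transparency mask: mean-channel OD at or below beta.
.transparent <- function(od, beta) {
  h <- dim(od)[1L]; w <- dim(od)[2L]
  mean_od <- rowMeans(matrix(od, h * w, dim(od)[3L]))
  matrix(mean_od <= beta, h, w)
}

#' Estimate the dominant (eosin) stain vector from an OD image
#'
#' Filters out transparent pixels (mean-channel OD at or below `beta`),
#' computes the covariance of the remaining OD triplets and returns the
#' unit eigenvector of the largest eigenvalue, sign-fixed so the mean OD
#' projection onto it is positive. For eosin-only or eosin-dominated
#' sections this is the eosin signal direction.
#'
#' @param od `H x W x 3` optical-density array (see [rgb_to_od()]).
#' @param beta Transparency threshold in OD units (default 0.15).
#' @return List of class `stain_basis` with `eosin_vector` (unit 3-vector),
#'   `beta`, and the fraction of OD variance the vector explains.
#' @export
estimate_eosin_vector <- function(od, beta = 0.15) {
  h <- dim(od)[1L]; w <- dim(od)[2L]
  pix <- matrix(od, h * w, 3L)
  keep <- rowMeans(pix) > beta
  if (sum(keep) < 3L)
    stop("fewer than 3 non-transparent pixels", call. = FALSE)
  pix <- pix[keep, , drop = FALSE]
  cv <- stats::cov(pix)
  if (!all(is.finite(cv)) || sum(abs(cv)) == 0)
    stop("degenerate OD covariance (constant image?)", call. = FALSE)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1L] <= 1e-12)
    stop("degenerate OD covariance (constant image?)", call. = FALSE)
  v <- eg$vectors[, 1L]
  if (sum(pix %*% v) < 0) v <- -v
  structure(list(eosin_vector = v, beta = beta,
                 explained = eg$values[1L] / sum(pmax(eg$values, 0))),
            class = "stain_basis")
}

#' Project onto the eosin direction and normalize to a reference value
#'
#' Projects each pixel's OD triplet onto the eosin vector and rescales the
#' single-channel result so the `reference_quantile` of the non-transparent
#' projections equals `reference_value`. Global intensity scale therefore
#' cancels between samples (uneven staining correction).
#'
#' @param od `H x W x 3` optical-density array.
#' @param basis A `stain_basis` from [estimate_eosin_vector()].
#' @param reference_value Target value of the reference quantile.
#' @param reference_quantile Quantile of non-transparent projections used
#'   as the reference pixel value.
#' @return `H x W` matrix: the normalized grayscale eosin-OD image.
#' @export
normalize_eosin <- function(od, basis, reference_value = 1,
                            reference_quantile = 0.99) {
  if (reference_value <= 0) stop("reference_value must be positive",
                                 call. = FALSE)
  h <- dim(od)[1L]; w <- dim(od)[2L]
  pix <- matrix(od, h * w, 3L)
  proj <- as.vector(pix %*% basis$eosin_vector)
  keep <- rowMeans(pix) > basis$beta
  if (!any(keep)) stop("no non-transparent pixels to normalize against",
                       call. = FALSE)
  ref <- stats::quantile(proj[keep], reference_quantile, names = FALSE,
                         type = 7)
  if (!is.finite(ref) || ref <= 0 || stats::sd(proj[keep]) == 0)
    stop("zero projection spread; cannot normalize", call. = FALSE)
  matrix(proj * (reference_value / ref), h, w)
}

#' Per-spot quantile of a grayscale image over the capture disks
#'
#' For each spot, takes the `q`-quantile (linear interpolation between
#' order statistics, R type 7) of the pixel values inside the disk of
#' `radius_px` around the spot center. Spots whose disk contains no pixels
#' get `NA` and a warning.
#'
#' @param gray `H x W` numeric matrix (e.g. normalized eosin OD).
#' @param grid A `spot_grid` or data.frame with `px_row`, `px_col`
#'   (1-based full-resolution pixel centers) and `spot_id`.
#' @param radius_px Disk radius in pixels.
#' @param q Quantile in (0, 1]; default 0.90.
#' @return Named numeric vector of per-spot quantile values.
#' @export
spot_od_quantile <- function(gray, grid, radius_px, q = 0.90) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]", call. = FALSE)
  if (radius_px <= 0) stop("radius_px must be positive", call. = FALSE)
  h <- nrow(gray); w <- ncol(gray)
  ir <- ceiling(radius_px)
  out <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pr <- grid$px_row[i]; pc <- grid$px_col[i]
    rows <- max(1L, pr - ir):min(h, pr + ir)
    cols <- max(1L, pc - ir):min(w, pc + ir)
    if (length(rows) < 1L || length(cols) < 1L || pr + ir < 1 || pc + ir < 1 ||
        pr - ir > h || pc - ir > w) next
    dd <- outer((rows - pr)^2, (cols - pc)^2, "+")
    vals <- gray[rows, cols, drop = FALSE][dd <= radius_px^2]
    if (length(vals) == 0L) next
    out[i] <- stats::quantile(vals, q, names = FALSE, type = 7)
  }
  if (anyNA(out))
    warning(sum(is.na(out)), " spot(s) had no pixels within the disk",
            call. = FALSE)
  names(out) <- grid$spot_id
  out
}

#' Otsu threshold of a numeric vector
#'
#' Histogram-based split (256 bins) maximizing the between-class variance;
#' used as the default cut between tissue-covered and tissue-sparse spot
#' OD quantiles when no explicit threshold is configured.
#'
#' @param x Numeric vector.
#' @param n_bins Number of histogram bins.
#' @return The threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0)
    stop("cannot threshold a constant vector", call. = FALSE)
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  hcount <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- hcount / sum(hcount)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  # bimodal data with an empty gap yields a plateau of maximal
  # between-class variance; split at its middle, not its first bin
  at_max <- which(sigma_b >= max(sigma_b) - 1e-12 * max(sigma_b))
  mean(mids[range(at_max)])
}

#' Flag tissue-sparse spots by their OD quantile
#'
#' A spot is tissue-sparse iff its 90th-quantile OD falls below the
#' threshold; sparse spots are treated as background by all downstream
#' geometry. The default threshold is the Otsu split of the quantile
#' distribution.
#'
#' @param qvals Per-spot quantile values (see [spot_od_quantile()]).
#' @param threshold Numeric cut, or `"otsu"` (default).
#' @return Logical vector (`NA` quantiles flag as sparse).
#' @export
flag_sparse_spots <- function(qvals, threshold = "otsu") {
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(qvals)
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  flag <- qvals < threshold
  flag[is.na(flag)] <- TRUE
  flag
}

#' Label tissue-edge spots on the hexagonal lattice
#'
#' A retained tissue spot is an edge spot iff at least one of its (up to
#' six) hex neighbours is background or lies off the array. `background`
#' must cover every array position in `grid`; any lattice position absent
#' from `grid` is treated as background.
#'
#' @param grid Data frame with `array_row`, `array_col` (all array
#'   positions of the sample).
#' @param background Logical per-row flags: `TRUE` for background
#'   (not-in-tissue, tissue-sparse, or otherwise removed) spots.
#' @return Logical per-row edge flags (`FALSE` for background rows).
#' @export
label_edge_spots <- function(grid, background) {
  stopifnot(length(background) == nrow(grid))
  key <- function(r, c) paste(r, c, sep = ",")
  bg_lookup <- new.env(parent = emptyenv(), size = nrow(grid))
  for (i in seq_len(nrow(grid)))
    assign(key(grid$array_row[i], grid$array_col[i]), background[i],
           envir = bg_lookup)
  edge <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (background[i]) next
    nr <- grid$array_row[i] + .hex_offsets[, "dr"]
    nc <- grid$array_col[i] + .hex_offsets[, "dc"]
    for (j in seq_len(6L)) {
      v <- mget(key(nr[j], nc[j]), envir = bg_lookup,
                ifnotfound = list(TRUE))[[1L]]
      if (isTRUE(v)) { edge[i] <- TRUE; break }
    }
  }
  edge
}

#' Filter spots by minimum RNA molecule count
#'
#' Retains spots whose column total is at least `min_total` (default 200
#' molecules), preserving column order.
#'
#' @param counts Genes x spots matrix (dense or `Matrix` sparse).
#' @param min_total Minimum total count for retention.
#' @return Logical vector over columns: `TRUE` for retained spots.
#' @export
filter_min_counts <- function(counts, min_total = 200L) {
  if (min_total < 0) stop("min_total must be >= 0", call. = FALSE)
  Matrix::colSums(counts) >= min_total
}

#' Run the full image + count spot QC for one sample
#'
#' Sequence: 10x in-tissue flag, then the 90th-quantile eosin-OD
#' tissue-sparse filter, then the minimum-count filter; edge labels are
#' computed on the final retained set (everything else, including sparse
#' and low-count spots, counts as background).
#'
#' @param image `H x W x 3` RGB intensity array (0-255 scale).
#' @param grid All array positions with `px_row`/`px_col` pointing into
#'   `image` and an `in_tissue` column.
#' @param counts Genes x spots matrix over the in-tissue spots, columns
#'   named by `spot_id`.
#' @param beta Transparency threshold (OD) for stain estimation.
#' @param q Spot quantile (default 0.90).
#' @param sparse_threshold Numeric or `"otsu"`.
#' @param min_total Minimum molecule count (default 200).
#' @param radius_px Spot disk radius; default half the spot diameter from
#'   the grid's attached geometry.
#' @return Data frame of class `spot_qc`: `spot_id`, `in_tissue`,
#'   `q90_od`, `sparse_flag`, `total_counts`, `min_count_pass`, `retained`,
#'   `edge_flag`; the estimated `stain_basis` is attached as an attribute.
#' @export
spot_qc <- function(image, grid, counts, beta = 0.15, q = 0.90,
                    sparse_threshold = "otsu", min_total = 200L,
                    radius_px = NULL) {
  geom <- attr(grid, "geometry")
  if (is.null(radius_px)) {
    if (is.null(geom))
      stop("radius_px is required when the grid has no geometry attribute",
           call. = FALSE)
    radius_px <- geom$spot_diameter_um / 2 / geom$microns_per_pixel
  }
  od <- rgb_to_od(image)
  basis <- estimate_eosin_vector(od, beta = beta)
  gray <- normalize_eosin(od, basis)
  qv <- suppressWarnings(spot_od_quantile(gray, grid, radius_px, q = q))
  in_tissue <- grid$in_tissue == 1L
  sparse <- rep(NA, nrow(grid))
  sparse[in_tissue] <- flag_sparse_spots(qv[in_tissue],
                                         threshold = sparse_threshold)
  totals <- rep(NA_real_, nrow(grid))
  idx <- match(colnames(counts), grid$spot_id)
  totals[idx] <- Matrix::colSums(counts)
  pass <- !is.na(totals) & totals >= min_total
  retained <- in_tissue & !is.na(sparse) & !sparse & pass
  edge <- label_edge_spots(grid, background = !retained)
  qc <- data.frame(spot_id = grid$spot_id, in_tissue = in_tissue,
                   q90_od = qv, sparse_flag = sparse,
                   total_counts = totals, min_count_pass = pass,
                   retained = retained, edge_flag = edge,
                   row.names = NULL, stringsAsFactors = FALSE)
  attr(qc, "stain_basis") <- basis
  class(qc) <- c("spot_qc", "data.frame")
  qc
}
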