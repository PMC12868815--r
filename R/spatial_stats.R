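#' Observation window and radius grid for point-pattern statistics
#'
#' The window area defaults to the bounding box of the retained spot
#' centers (convex hull optional); the radius grid defaults to 50 equally
#' spaced radii from 0 to half the window's shorter side, spanning local to
#' whole-sample scales.
#'
#' @param coords Numeric `n x 2` matrix of spot centers (pixels), columns
#'   x, y.
#' @param mode `"bbox"` (default) or `"hull"`.
#' @param n_radii Number of radii.
#' @param r Optional explicit radius grid (strictly increasing, `>= 0`).
#' @return List of class `ripley_window` with `area`, `r`, `mode`.
#' @export
make_window <- function(coords, mode = c("bbox", "hull"), n_radii = 50L,
                        r = NULL) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  xr <- range(coords[, 1L]); yr <- range(coords[, 2L])
  if (mode == "bbox") {
    area <- diff(xr) * diff(yr)
  } else {
    hull <- grDevices::chull(coords)
    hx <- coords[hull, 1L]; hy <- coords[hull, 2L]
    area <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
  }
  if (area <= 0) stop("window area must be positive", call. = FALSE)
  if (is.null(r))
    r <- seq(0, min(diff(xr), diff(yr)) / 2, length.out = n_radii)
  if (any(diff(r) <= 0) || r[1L] < 0)
    stop("radii must be strictly increasing and non-negative", call. = FALSE)
  structure(list(area = area, r = r, mode = mode), class = "ripley_window")
}

# Pair-count helper: number of ordered pairs with distance <= r, for each
# radius, from the vector of unordered pairwise distances.
.pair_counts <- function(dvec, r) {
  2 * findInterval(r, sort(dvec))
}

#' Ripley's K and variance-stabilized L for one point pattern
#'
#' Uncorrected estimator `K(r) = |A| / (n (n - 1)) * sum_{i != j}
#' 1(d_ij <= r)` and `L(r) = sqrt(K(r) / pi)`. No edge correction is
#' applied by default (the null used downstream conditions on the same
#' lattice, so the edge bias cancels); a translation correction for the
#' bounding-box window is available.
#'
#' @param points `n x 2` coordinate matrix of the spots of one type.
#' @param window A [make_window()] (its `r` grid is used).
#' @param correction `"none"` (default) or `"translation"`.
#' @return Data frame of class `ripley_curve`: `r`, `K`, `L`, with
#'   `n_points` as an attribute.
#' @export
ripley_l <- function(points, window, correction = c("none", "translation")) {
  correction <- match.arg(correction)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("Ripley's L is undefined for fewer than 2 points",
                   call. = FALSE)
  r <- window$r
  if (correction == "none") {
    d <- stats::dist(points)
    K <- window$area / (n * (n - 1)) * .pair_counts(as.vector(d), r)
  } else {
    a <- diff(range(points[, 1L])); b <- diff(range(points[, 2L]))
    dx <- abs(outer(points[, 1L], points[, 1L], "-"))
    dy <- abs(outer(points[, 2L], points[, 2L], "-"))
    wgt <- 1 / ((1 - dx / max(a, 1e-12)) * (1 - dy / max(b, 1e-12)))
    dmat <- sqrt(dx^2 + dy^2)
    off <- upper.tri(dmat)
    dv <- dmat[off]; wv <- wgt[off]
    o <- order(dv)
    cumw <- c(0, cumsum(wv[o]))
    K <- window$area / (n * (n - 1)) *
      2 * cumw[findInterval(r, dv[o]) + 1L]
  }
  out <- data.frame(r = r, K = K, L = sqrt(K / pi))
  attr(out, "n_points") <- n
  class(out) <- c("ripley_curve", "data.frame")
  out
}

#' Per-type Ripley curves for one sample
#'
#' Computes [ripley_l()] for every spot type with at least `min_points`
#' spots; types below that are skipped with a message.
#'
#' @param coords `n x 2` matrix of retained spot centers.
#' @param labels Per-spot type labels.
#' @param window Optional [make_window()]; defaults to the bounding box of
#'   `coords`.
#' @param min_points Minimum points per type (default 2).
#' @param correction Passed to [ripley_l()].
#' @return Long data frame: `spot_type`, `r`, `K`, `L`, `n_points`.
#' @export
sample_ripley_curves <- function(coords, labels, window = NULL,
                                 min_points = 2L,
                                 correction = "none") {
  coords <- as.matrix(coords)
  if (is.null(window)) window <- make_window(coords)
  out <- list()
  for (ty in sort(unique(labels))) {
    idx <- which(labels == ty)
    if (length(idx) < min_points) {
      message("skipping type '", ty, "': fewer than ", min_points, " spots")
      next
    }
    cv <- ripley_l(coords[idx, , drop = FALSE], window,
                   correction = correction)
    out[[ty]] <- data.frame(spot_type = ty, cv,
                            n_points = length(idx),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Random-labeling envelope for per-type Ripley curves
#'
#' Null model conditioning on the observed retained-spot lattice: type
#' labels are reassigned uniformly at random without replacement over the
#' retained positions, `L` is recomputed per simulation, and pointwise
#' percentile bands are returned per type. Types with fewer than 2 spots
#' are skipped.
#'
#' @param coords `n x 2` matrix of retained spot centers.
#' @param type_counts Named integer vector of per-type spot counts
#'   (`sum <= nrow(coords)`).
#' @param window A [make_window()].
#' @param n_sim Number of label permutations (default 99; must be >= 39).
#' @param seed Integer seed; bands are deterministic given it.
#' @param probs Envelope percentiles (default 2.5/97.5).
#' @return Named list per type: data frame `r`, `lo`, `hi`.
#' @export
random_label_envelope <- function(coords, type_counts, window, n_sim = 99L,
                                  seed = 1L, probs = c(0.025, 0.975)) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (sum(type_counts) > n)
    stop("type counts exceed the number of retained spots", call. = FALSE)
  if (n_sim < 39L) stop("n_sim must be at least 39", call. = FALSE)
  keep <- type_counts >= 2L
  if (!all(keep))
    message("skipping type(s) with fewer than 2 spots: ",
            paste(names(type_counts)[!keep], collapse = ", "))
  type_counts <- type_counts[keep]
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  r <- window$r
  sims <- lapply(names(type_counts), function(ty)
    matrix(NA_real_, n_sim, length(r)))
  names(sims) <- names(type_counts)
  for (s in seq_len(n_sim)) {
    perm <- sample.int(n)
    offset <- 0L
    for (ty in names(type_counts)) {
      m <- type_counts[[ty]]
      idx <- perm[offset + seq_len(m)]
      offset <- offset + m
      d <- stats::dist(coords[idx, , drop = FALSE])
      K <- window$area / (m * (m - 1)) * .pair_counts(as.vector(d), r)
      sims[[ty]][s, ] <- sqrt(K / pi)
    }
  }
  lapply(sims, function(mat) {
    qs <- apply(mat, 2L, stats::quantile, probs = probs, names = FALSE,
                type = 7)
    data.frame(r = r, lo = qs[1L, ], hi = qs[2L, ])
  })
}

#' Local polynomial (loess-type) smoother
#'
#' Tricube-weighted local linear fit: at each query point the
#' `ceiling(span * n)` nearest observations get weights
#' `(1 - (d/h)^3)^3` with `h` the span-neighbourhood radius, and a
#' degree-1 weighted least squares fit is evaluated. Query points whose
#' window holds fewer than two positive-weight observations yield `NA`.
#'
#' @param x,y Observations.
#' @param span Fraction of points in each local window, in (0, 1].
#' @param degree Local polynomial degree; only 1 is implemented.
#' @param xout Query points (default `x`).
#' @return Numeric vector of fitted values at `xout`.
#' @export
loess_smooth <- function(x, y, span = 0.75, degree = 1L, xout = x) {
  stopifnot(length(x) == length(y))
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  if (degree != 1L) stop("only degree 1 is implemented", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(unique(x)) < 2L)
    stop("need at least 2 distinct x values", call. = FALSE)
  k <- max(2L, ceiling(span * n))
  vapply(xout, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = k)[k]
    if (h == 0) {
      # duplicated x at the query point: fall back to their mean
      return(mean(y[d == 0]))
    }
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    if (sum(use) < 2L || length(unique(x[use])) < 2L) {
      if (sum(use) >= 1L) return(stats::weighted.mean(y[use], w[use]))
      return(NA_real_)
    }
    sw <- sum(w)
    mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    sxx <- sum(w * (x - mx)^2)
    if (sxx == 0) return(my)
    b <- sum(w * (x - mx) * (y - my)) / sxx
    my + b * (x0 - mx)
  }, numeric(1))
}

#' Aggregate per-sample Ripley curves into stage-level curves
#'
#' Pools the `(r, L)` points of all samples in each (stage, spot type)
#' cell and smooths them onto a common radius grid with the local
#' polynomial smoother. Cells with no curve are omitted with a warning.
#'
#' @param curves Long data frame with columns `sample`, `spot_type`, `r`,
#'   `L` (radii should be comparable across samples, e.g. in microns).
#' @param stages Named character vector mapping sample -> stage.
#' @param span Smoother span.
#' @param r_out Common radius grid; defaults to 50 points spanning the
#'   pooled radii.
#' @return Data frame of class `stage_aggregate`: `stage`, `spot_type`,
#'   `r`, `L_smooth`, `n_samples`.
#' @export
aggregate_stage_curves <- function(curves, stages, span = 0.75,
                                   r_out = NULL) {
  stopifnot(all(c("sample", "spot_type", "r", "L") %in% names(curves)))
  curves$stage <- stages[curves$sample]
  if (anyNA(curves$stage))
    stop("samples without a stage label: ",
         paste(unique(curves$sample[is.na(curves$stage)]), collapse = ", "),
         call. = FALSE)
  if (is.null(r_out))
    r_out <- seq(min(curves$r), max(curves$r), length.out = 50L)
  cells <- unique(curves[, c("stage", "spot_type")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- curves$stage == cells$stage[i] &
      curves$spot_type == cells$spot_type[i]
    cell <- curves[sel, ]
    if (nrow(cell) == 0L) {
      warning("empty cell: ", cells$stage[i], " / ", cells$spot_type[i],
              call. = FALSE)
      next
    }
    fit <- loess_smooth(cell$r, cell$L, span = span, xout = r_out)
    out[[i]] <- data.frame(stage = cells$stage[i],
                           spot_type = cells$spot_type[i],
                           r = r_out, L_smooth = fit,
                           n_samples = length(unique(cell$sample)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("stage_aggregate", "data.frame")
  res
}

#' Plot stage-aggregated Ripley curves
#'
#' One panel per spot type, one curve per stage; `L(r) > r` (dashed
#' reference) indicates clustering.
#'
#' @param x A `stage_aggregate`.
#' @param types Spot types to draw (default: all, up to 4).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.stage_aggregate <- function(x, types = NULL, ...) {
  if (is.null(types)) types <- utils::head(unique(x$spot_type), 4L)
  op <- graphics::par(mfrow = c(1, length(types)))
  on.exit(graphics::par(op), add = TRUE)
  for (ty in types) {
    sub <- x[x$spot_type == ty, ]
    wide <- stats::reshape(sub[, c("stage", "r", "L_smooth")],
                           idvar = "r", timevar = "stage",
                           direction = "wide")
    graphics::matplot(wide$r, wide[, -1L, drop = FALSE], type = "l",
                      lty = 1, xlab = "r", ylab = "L(r)", main = ty, ...)
    graphics::abline(0, 1, lty = 2, col = "grey")
  }
  invisible(x)
}
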