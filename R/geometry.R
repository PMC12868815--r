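#' Peripheral-region parameters
#'
#' The peripheral region comprises tissue spots whose radial distance to
#' the nearest tissue-border spot is at most ~500 microns (equivalently
#' 150 full-resolution pixels at 10/3 um/px). Both micron and fixed-pixel
#' threshold modes are supported.
#'
#' @param threshold_um Micron threshold (default 500).
#' @param fallback_threshold_px Pixel threshold used in `"px"` mode
#'   (default 150).
#' @param spot_diameter_um,fiducial_diameter_um Physical diameters used to
#'   derive the image scale (fiducial 85 um is a vendor constant).
#' @return List of class `periphery_params`.
#' @export
periphery_params <- function(threshold_um = 500, fallback_threshold_px = 150,
                             spot_diameter_um = 55,
                             fiducial_diameter_um = 85) {
  if (threshold_um < 0 || fallback_threshold_px <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(threshold_um = threshold_um,
                 fallback_threshold_px = fallback_threshold_px,
                 spot_diameter_um = spot_diameter_um,
                 fiducial_diameter_um = fiducial_diameter_um),
            class = "periphery_params")
}

# Connected components of tissue spots under hex adjacency (BFS on keys).
.tissue_components <- function(grid, tissue) {
  key <- paste(grid$array_row, grid$array_col, sep = ",")
  idx_of <- new.env(parent = emptyenv(), size = nrow(grid))
  for (i in which(tissue)) assign(key[i], i, envir = idx_of)
  comp <- rep(NA_integer_, nrow(grid))
  cur <- 0L
  for (s in which(tissue)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      nr <- grid$array_row[i] + .hex_offsets[, "dr"]
      nc <- grid$array_col[i] + .hex_offsets[, "dc"]
      for (j in seq_len(6L)) {
        ni <- mget(paste(nr[j], nc[j], sep = ","), envir = idx_of,
                   ifnotfound = list(NA_integer_))[[1L]]
        if (!is.na(ni) && is.na(comp[ni])) {
          comp[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
  }
  comp
}

# Background cells connected to the off-array exterior (flood fill over
# background positions; any background cell with an off-array neighbour
# seeds the fill).
.exterior_background <- function(grid, tissue) {
  key <- paste(grid$array_row, grid$array_col, sep = ",")
  on_array <- new.env(parent = emptyenv(), size = nrow(grid))
  for (i in seq_len(nrow(grid))) assign(key[i], i, envir = on_array)
  bg <- which(!tissue)
  exterior <- rep(FALSE, nrow(grid))
  seeds <- integer(0)
  neigh_idx <- function(i) {
    nr <- grid$array_row[i] + .hex_offsets[, "dr"]
    nc <- grid$array_col[i] + .hex_offsets[, "dc"]
    vapply(seq_len(6L), function(j)
      mget(paste(nr[j], nc[j], sep = ","), envir = on_array,
           ifnotfound = list(NA_integer_))[[1L]], integer(1))
  }
  for (i in bg) if (anyNA(neigh_idx(i))) seeds <- c(seeds, i)
  exterior[seeds] <- TRUE
  queue <- seeds
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    for (ni in neigh_idx(i)) {
      if (!is.na(ni) && !tissue[ni] && !exterior[ni]) {
        exterior[ni] <- TRUE
        queue <- c(queue, ni)
      }
    }
  }
  exterior
}

#' Select tissue-border spots
#'
#' The faithful mode reads a manual selection (the border spots that
#' resemble the pleural surface, chosen by eye): a text file with one spot
#' barcode per line, `#` comments allowed. Every listed id must be an edge
#' spot. The automated fallback returns the edge spots of the largest
#' connected tissue component that touch the exterior background (the
#' outer boundary, excluding interior holes).
#'
#' @param grid All array positions (`array_row`, `array_col`, `spot_id`).
#' @param edge_flags Logical per-row edge labels (see
#'   [label_edge_spots()]).
#' @param background Logical per-row background flags used for edge
#'   labelling; needed by the automated mode.
#' @param manual_file Optional path to the manual border list.
#' @return Character vector of border spot ids, with attribute
#'   `"provenance"` set to `"manual-file"` or `"automated"`.
#' @export
select_border_spots <- function(grid, edge_flags, background = NULL,
                                manual_file = NULL) {
  if (!is.null(manual_file)) {
    ids <- readLines(manual_file)
    ids <- trimws(sub("#.*$", "", ids))
    ids <- ids[nzchar(ids)]
    bad <- setdiff(ids, grid$spot_id[edge_flags])
    if (length(bad))
      stop("manual border ids are not edge spots: ",
           paste(bad, collapse = ", "), call. = FALSE)
    return(structure(ids, provenance = "manual-file"))
  }
  if (is.null(background))
    stop("automated border selection needs the background flags",
         call. = FALSE)
  tissue <- !background
  comp <- .tissue_components(grid, tissue)
  main <- which.max(tabulate(comp))
  exterior <- .exterior_background(grid, tissue)
  # a spot is on the outer boundary iff some neighbour is exterior
  # background or off-array
  key <- paste(grid$array_row, grid$array_col, sep = ",")
  status <- new.env(parent = emptyenv(), size = nrow(grid))
  for (i in seq_len(nrow(grid)))
    assign(key[i], if (tissue[i]) FALSE else exterior[i], envir = status)
  border <- vapply(seq_len(nrow(grid)), function(i) {
    if (!tissue[i] || is.na(comp[i]) || comp[i] != main || !edge_flags[i])
      return(FALSE)
    nr <- grid$array_row[i] + .hex_offsets[, "dr"]
    nc <- grid$array_col[i] + .hex_offsets[, "dc"]
    for (j in seq_len(6L)) {
      v <- mget(paste(nr[j], nc[j], sep = ","), envir = status,
                ifnotfound = list(TRUE))[[1L]]
      if (isTRUE(v)) return(TRUE)
    }
    FALSE
  }, logical(1))
  structure(grid$spot_id[border], provenance = "automated")
}

#' Radial distance of each tissue spot to the nearest border spot
#'
#' Euclidean center-to-center distance in full-resolution pixels; border
#' spots get zero.
#'
#' @param spots Data frame with `spot_id`, `px_row`, `px_col` (the spots to
#'   measure, typically the retained tissue spots).
#' @param border Character vector of border spot ids (must appear in
#'   `spots`).
#' @return Named numeric vector of pixel distances.
#' @export
distance_to_border <- function(spots, border) {
  if (length(border) == 0L) stop("border set is empty", call. = FALSE)
  bidx <- match(border, spots$spot_id)
  if (anyNA(bidx))
    stop("border ids missing from the spot table: ",
         paste(border[is.na(bidx)], collapse = ", "), call. = FALSE)
  dx <- outer(spots$px_col, spots$px_col[bidx], "-")
  dy <- outer(spots$px_row, spots$px_row[bidx], "-")
  d <- sqrt(dx^2 + dy^2)
  out <- apply(d, 1L, min)
  names(out) <- spots$spot_id
  out
}

#' Flag peripheral spots by border distance
#'
#' Peripheral iff `distance_px * scale <= threshold_um` (micron mode,
#' inclusive boundary: "not greater than"), or
#' `distance_px <= fallback_threshold_px` in pixel mode.
#'
#' @param distances_px Per-spot pixel distances (see
#'   [distance_to_border()]).
#' @param scale Microns per full-resolution pixel.
#' @param params A [periphery_params()].
#' @param mode `"um"` (default) or `"px"`.
#' @return Logical peripheral flags.
#' @export
flag_peripheral <- function(distances_px, scale,
                            params = periphery_params(),
                            mode = c("um", "px")) {
  mode <- match.arg(mode)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  # relative epsilon keeps the inclusive boundary exact under floating
  # point (e.g. 150 px * 10/3 um/px must count as 500 um)
  if (mode == "um") {
    eps <- 1e-9 * max(1, params$threshold_um)
    distances_px * scale <= params$threshold_um + eps
  } else {
    distances_px <= params$fallback_threshold_px + 1e-9
  }
}
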