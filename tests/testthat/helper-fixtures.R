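# Shared fixtures and independent oracles used across the suite.

small_grid <- function(n_rows = 20L, n_cols = 20L) {
  make_hex_grid(grid_geometry(n_rows = n_rows, n_cols = n_cols))
}

# O(n * 6) brute-force edge labelling: a tissue spot is an edge spot iff
# any of its six lattice neighbours is background or absent.
brute_force_edges <- function(grid, background) {
  key <- paste(grid$array_row, grid$array_col, sep = ",")
  vapply(seq_len(nrow(grid)), function(i) {
    if (background[i]) return(FALSE)
    for (j in 1:6) {
      nk <- paste(grid$array_row[i] + c(0, 0, -1, -1, 1, 1)[j],
                  grid$array_col[i] + c(-2, 2, -1, 1, -1, 1)[j], sep = ",")
      m <- match(nk, key)
      if (is.na(m) || background[m]) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# O(n^2 * B) brute-force Ripley K estimator (uncorrected).
brute_force_k <- function(points, area, r) {
  n <- nrow(points)
  counts <- numeric(length(r))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((points[i, ] - points[j, ])^2))
    counts <- counts + (d <= r)
  }
  area / (n * (n - 1)) * counts
}

# Two-stain OD image with a controlled eosin-dominant variance structure.
two_stain_image <- function(seed, h = 120L, w = 120L,
                            eosin_sd = 0.15, hema_max = 0.10) {
  set.seed(seed)
  eo <- matrix(pmax(0, 0.8 + stats::rnorm(h * w, 0, eosin_sd)), h, w)
  he <- matrix(stats::runif(h * w, 0, hema_max), h, w)
  ev <- c(0.092789, 0.954111, 0.283111); ev <- ev / sqrt(sum(ev^2))
  hv <- c(0.644211, 0.716556, 0.266844); hv <- hv / sqrt(sum(hv^2))
  img <- render_stain_image(array(c(eo, he), c(h, w, 2L)), rbind(ev, hv))
  list(image = img, eosin = ev, hema = hv, conc = list(eo = eo, he = he))
}

# Per-sample label fields for a two-stage study design (no disk I/O).
simulate_stage_labels <- function(grid, rep_seed,
                                  config = study_config(),
                                  n_per_stage = 6L) {
  stages <- rep(names(config$stage_composition), each = n_per_stage)
  lapply(seq_along(stages), function(i)
    simulate_type_field(grid, config$stage_composition[[stages[i]]],
                        config$clustering_dispersion[[stages[i]]],
                        seed = rep_seed * 1000 + i))
}
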