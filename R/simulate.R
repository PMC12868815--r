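#' Male sex-signature genes
#'
#' Y-linked (and Y-homologous) genes used for rank-based sex calling of
#' samples: RPS4Y1, UTY, KDM5D, DDX3Y, USP9Y, VCX, VCY.
#' @export
male_signature_genes <- c("RPS4Y1", "UTY", "KDM5D", "DDX3Y", "USP9Y",
                          "VCX", "VCY")

#' Default spot-type vocabulary
#'
#' The ten tissue niches the generator emulates, named after the
#' compartments seen in mid-gestation lung sections.
#' @export
spot_type_names <- c("distal_parenchyma", "mesenchyme_parenchyma",
                     "distal_airway", "proximal_airway",
                     "mesenchyme_vessel_adjacent", "pulmonary_vessels",
                     "pulmonary_vessels_small", "megakaryocyte_parenchyma",
                     "lymphatic", "cartilage")

.default_composition <- function() {
  pg <- c(0.30, 0.20, 0.08, 0.05, 0.15, 0.07, 0.05, 0.04, 0.03, 0.03)
  cn <- c(0.45, 0.08, 0.10, 0.05, 0.12, 0.08, 0.04, 0.05, 0.02, 0.01)
  names(pg) <- names(cn) <- spot_type_names
  list(pseudoglandular = pg, canalicular = cn)
}

#' Configuration for a synthetic two-stage Visium study
#'
#' Defaults emulate the study design the package targets: 12 samples, six
#' pseudoglandular (13-16 weeks) and six canalicular (17-20 weeks), ten
#' spatially clustered spot types, a +0.15 upward shift in
#' `distal_parenchyma` (and compensating mesenchymal decrease) between
#' stages, tighter spatial clustering in the canalicular stage, and a small
#' fraction of tissue-sparse spots whose RNA totals fall below the minimum
#' count threshold.
#'
#' @param n_samples_per_stage Samples per developmental stage.
#' @param stage_composition Named list (one entry per stage) of
#'   length-10 type-proportion vectors, each summing to 1.
#' @param clustering_dispersion Named numeric per stage: positional-noise
#'   scale of the type field in microns; smaller means tighter type domains.
#' @param nb_mean,nb_dispersion Baseline negative-binomial mean per gene and
#'   dispersion (size) parameter.
#' @param marker_fold Mean fold-elevation of a type's marker genes in spots
#'   of that type.
#' @param markers_per_type Marker genes per spot type.
#' @param n_background_genes Genes with type-independent expression.
#' @param sex_assignments Character vector (length `2 * n_samples_per_stage`)
#'   of `"male"`/`"female"`; the default mirrors a 5M/7F design.
#' @param condition_assignments Character vector of per-sample conditions;
#'   the default places two `"trisomy21"` samples in each stage.
#' @param sparse_spot_fraction Fraction of in-tissue spots rendered and
#'   counted as tissue-sparse.
#' @param sparse_scale Multiplier applied to NB means of sparse spots.
#' @param n_type_centers Total number of type centers drawn per sample.
#' @param geometry A [grid_geometry()]; the default (44 x 44) yields about
#'   970 spots per sample of which most lie in tissue.
#' @param random_seed Integer study seed; per-sample sub-seeds are derived
#'   from it by fixed arithmetic.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_samples_per_stage = 6L,
                         stage_composition = .default_composition(),
                         clustering_dispersion = c(pseudoglandular = 600,
                                                   canalicular = 150),
                         nb_mean = 4, nb_dispersion = 2,
                         marker_fold = 5, markers_per_type = 10L,
                         n_background_genes = 400L,
                         sex_assignments = NULL,
                         condition_assignments = NULL,
                         sparse_spot_fraction = 0.05,
                         sparse_scale = 0.02,
                         n_type_centers = 40L,
                         geometry = grid_geometry(n_rows = 44L, n_cols = 44L),
                         random_seed = 20260101L) {
  stages <- names(stage_composition)
  if (length(stages) < 1L)
    stop("stage_composition must be a named list", call. = FALSE)
  for (st in stages) {
    p <- stage_composition[[st]]
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("each stage composition must be a non-negative vector summing to 1",
           call. = FALSE)
  }
  if (any(clustering_dispersion <= 0))
    stop("clustering_dispersion values must be positive", call. = FALSE)
  if (nb_mean < 0 || nb_dispersion <= 0)
    stop("invalid negative-binomial parameters", call. = FALSE)
  if (sparse_spot_fraction < 0 || sparse_spot_fraction > 1)
    stop("sparse_spot_fraction must be in [0, 1]", call. = FALSE)
  n_total <- as.integer(n_samples_per_stage) * length(stages)
  if (is.null(sex_assignments))
    sex_assignments <- rep(c("female", "male", "male", "female", "female",
                             "male", "female", "female", "female", "female",
                             "male", "male"), length.out = n_total)
  if (is.null(condition_assignments)) {
    # two affected samples per stage, mirroring the 4-of-12 trisomy design
    condition_assignments <- rep("control", n_total)
    per <- as.integer(n_samples_per_stage)
    for (k in seq_along(stages)) {
      n_t21 <- min(2L, max(0L, per - 1L))
      idx <- (k - 1L) * per + utils::tail(seq_len(per), n_t21)
      condition_assignments[idx] <- "trisomy21"
    }
  }
  structure(list(
    n_samples_per_stage = as.integer(n_samples_per_stage),
    stages = stages,
    stage_composition = stage_composition,
    clustering_dispersion = clustering_dispersion,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    marker_fold = marker_fold,
    markers_per_type = as.integer(markers_per_type),
    n_background_genes = as.integer(n_background_genes),
    sex_assignments = sex_assignments,
    condition_assignments = condition_assignments,
    sparse_spot_fraction = sparse_spot_fraction,
    sparse_scale = sparse_scale,
    n_type_centers = as.integer(n_type_centers),
    geometry = geometry,
    random_seed = as.integer(random_seed)), class = "study_config")
}

# Deterministic sub-seed arithmetic: keeps sample-level streams independent
# of each other while the whole study is reproducible from one integer.
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483629)
}

#' Simulate a spatially clustered categorical type field
#'
#' Draws type "centers" on the lattice bounding box (the number of centers
#' per type proportional to its target proportion) and assigns each spot a
#' type by sampling from Gaussian-kernel mixture weights
#' `P(k | s) \propto (p_k / m_k) * sum_j exp(-d(s, c_jk)^2 / (2 sigma^2))`.
#' As `dispersion` shrinks this reduces to labelling by the nearest center
#' (tight clustered domains); as it grows the label distribution converges
#' exactly to the configured proportions.
#'
#' @param grid A `spot_grid` (or any data.frame with `um_x`, `um_y`).
#' @param proportions Non-negative type proportions summing to 1; names are
#'   used as type labels when present.
#' @param dispersion Positional-noise scale sigma, in the same units as the
#'   grid coordinates (microns).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param n_centers Total number of type centers.
#' @return Character (or factor-level) vector of per-spot type labels.
#' @export
simulate_type_field <- function(grid, proportions, dispersion, seed,
                                n_centers = 40L) {
  if (nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0))
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  labels <- names(proportions)
  if (is.null(labels)) labels <- paste0("type_", seq_along(proportions))
  active <- which(proportions > 0)
  if (length(active) == 1L)
    return(rep(labels[active], nrow(grid)))

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  # centers per active type, proportional to proportion, at least one each
  m <- pmax(1L, round(proportions[active] * n_centers))
  xr <- range(grid$um_x); yr <- range(grid$um_y)
  ctr_type <- rep(seq_along(active), m)
  cx <- stats::runif(sum(m), xr[1], xr[2])
  cy <- stats::runif(sum(m), yr[1], yr[2])
  # log-weights per spot x center, stabilized per spot
  d2 <- outer(grid$um_x, cx, "-")^2 + outer(grid$um_y, cy, "-")^2
  lw <- sweep(-d2 / (2 * dispersion^2), 2,
              log(proportions[active][ctr_type] / m[ctr_type]), "+")
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  # per-spot type probabilities: sum center weights within type
  probs <- t(rowsum(t(w), group = ctr_type))
  probs <- probs / rowSums(probs)
  cum <- t(apply(probs, 1, cumsum))
  u <- stats::runif(nrow(grid))
  pick <- rowSums(u > cum) + 1L
  labels[active][pick]
}

# Seed guard: set the RNG deterministically and return a restorer.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483629))
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate negative-binomial spot counts with planted structure
#'
#' Gene universe: `markers_per_type` marker genes per spot type (elevated
#' `marker_fold`-fold in spots of their type), the seven male-signature
#' genes (expressed only when `sex = "male"`), and background genes.
#' Tissue-sparse spots have all gene means multiplied by `sparse_scale`, so
#' their totals fall below the minimum-count QC threshold.
#'
#' @param labels Per-spot type labels.
#' @param config A [study_config()].
#' @param sex `"male"` or `"female"`.
#' @param seed Integer seed.
#' @param sparse_spots Logical per-spot vector of tissue-sparse spots.
#' @return List with `counts` (a `dgCMatrix`, genes x spots) and `gene_map`
#'   (data.frame: gene, class, type).
#' @export
simulate_counts <- function(labels, config, sex = "female", seed,
                            sparse_spots = rep(FALSE, length(labels))) {
  n_spots <- length(labels)
  if (n_spots < 1L) stop("need at least one spot", call. = FALSE)
  if (config$markers_per_type < 1L)
    stop("markers_per_type must be >= 1", call. = FALSE)
  if (config$nb_mean < 0 || config$nb_dispersion <= 0)
    stop("invalid negative-binomial parameters", call. = FALSE)
  types <- names(config$stage_composition[[1L]])
  gene_map <- rbind(
    data.frame(gene = paste0(rep(types, each = config$markers_per_type),
                             "_marker_",
                             rep(seq_len(config$markers_per_type),
                                 length(types))),
               class = "marker",
               type = rep(types, each = config$markers_per_type),
               stringsAsFactors = FALSE),
    data.frame(gene = male_signature_genes, class = "sex", type = NA,
               stringsAsFactors = FALSE),
    data.frame(gene = paste0("BG_", seq_len(config$n_background_genes)),
               class = "background", type = NA, stringsAsFactors = FALSE))

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  mu_base <- config$nb_mean
  type_idx <- match(labels, types)
  spot_scale <- ifelse(sparse_spots, config$sparse_scale, 1)
  n_genes <- nrow(gene_map)
  mat <- matrix(0L, n_genes, n_spots,
                dimnames = list(gene_map$gene, NULL))
  for (g in seq_len(n_genes)) {
    mu <- rep(mu_base, n_spots)
    if (gene_map$class[g] == "marker") {
      mu[labels == gene_map$type[g]] <- mu_base * config$marker_fold
    } else if (gene_map$class[g] == "sex") {
      mu <- if (identical(sex, "male")) rep(mu_base * 3, n_spots) else
        rep(0, n_spots)
    }
    mu <- mu * spot_scale
    if (all(mu == 0)) next
    mat[g, ] <- stats::rnbinom(n_spots, size = config$nb_dispersion, mu = mu)
  }
  list(counts = Matrix::Matrix(mat, sparse = TRUE), gene_map = gene_map)
}

#' Render a stained-tissue RGB image by the Beer-Lambert forward model
#'
#' Per channel `c`, transmitted intensity is
#' `I_c = I0 * 10^(-sum_s C_s * S_sc)`, quantized to 8 bits (floor).
#' Pixels with zero concentration in every stain render exactly at the
#' background intensity `I0` (a transparent background).
#'
#' @param concentrations Numeric `H x W` matrix (single stain) or
#'   `H x W x S` array of non-negative stain concentrations.
#' @param basis `S x 3` matrix of unit-norm, non-negative stain OD vectors
#'   (rows), or a length-3 vector for a single stain.
#' @param background_intensity Incident intensity `I0` (default 255).
#' @return Integer `H x W x 3` array of 8-bit channel intensities.
#' @export
render_stain_image <- function(concentrations, basis,
                               background_intensity = 255) {
  if (is.matrix(concentrations))
    concentrations <- array(concentrations, c(dim(concentrations), 1L))
  if (is.null(dim(basis))) basis <- matrix(basis, nrow = 1L)
  if (dim(concentrations)[3L] != nrow(basis))
    stop("number of stains in concentrations and basis differ", call. = FALSE)
  if (any(concentrations < 0) || any(basis < 0))
    stop("concentrations and basis must be non-negative", call. = FALSE)
  h <- dim(concentrations)[1L]; w <- dim(concentrations)[2L]
  cmat <- matrix(concentrations, h * w, dim(concentrations)[3L])
  od <- cmat %*% basis              # (H*W) x 3 optical densities
  img <- floor(background_intensity * 10^(-od))
  array(as.integer(pmax(0, pmin(255, img))), c(h, w, 3L))
}

# Standard eosin / hematoxylin OD direction vectors (unit norm).
.eosin_vector <- function() {
  v <- c(0.092789, 0.954111, 0.283111); v / sqrt(sum(v^2))
}
.hematoxylin_vector <- function() {
  v <- c(0.644211, 0.716556, 0.266844); v / sqrt(sum(v^2))
}

# Paint per-spot stain levels as filled disks onto pixel concentration maps.
.paint_spots <- function(h, w, px_row, px_col, radius_px, levels) {
  conc <- matrix(0, h, w)
  r2 <- radius_px^2
  ir <- ceiling(radius_px)
  for (i in seq_along(px_row)) {
    rows <- max(1L, px_row[i] - ir):min(h, px_row[i] + ir)
    cols <- max(1L, px_col[i] - ir):min(w, px_col[i] + ir)
    dd <- outer((rows - px_row[i])^2, (cols - px_col[i])^2, "+")
    sel <- dd <= r2
    block <- conc[rows, cols, drop = FALSE]
    block[sel] <- pmax(block[sel], levels[i])
    conc[rows, cols] <- block
  }
  conc
}

# Simulate one sample: tissue mask, sparse flags, type field, counts, image.
.simulate_sample <- function(config, stage, sample_index, sex) {
  seed <- sub_seed(config$random_seed, sample_index)
  grid <- make_hex_grid(config$geometry)
  geom <- config$geometry

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  # tissue mask: ellipse around the lattice center with a wavy boundary
  cx <- mean(range(grid$um_x)); cy <- mean(range(grid$um_y))
  rx <- diff(range(grid$um_x)) / 2 * 0.88
  ry <- diff(range(grid$um_y)) / 2 * 0.88
  ang <- atan2(grid$um_y - cy, grid$um_x - cx)
  phase <- stats::runif(1, 0, 2 * pi)
  wav <- 1 + 0.08 * sin(3 * ang + phase)
  grid$in_tissue <- as.integer(((grid$um_x - cx) / rx)^2 +
                                 ((grid$um_y - cy) / ry)^2 <= wav^2)
  tissue <- which(grid$in_tissue == 1L)
  sparse <- rep(FALSE, nrow(grid))
  n_sparse <- round(config$sparse_spot_fraction * length(tissue))
  if (n_sparse > 0)
    sparse[sample(tissue, n_sparse)] <- TRUE

  labels <- rep(NA_character_, nrow(grid))
  labels[tissue] <- simulate_type_field(
    grid[tissue, ], config$stage_composition[[stage]],
    dispersion = config$clustering_dispersion[[stage]],
    seed = sub_seed(seed, 1L), n_centers = config$n_type_centers)

  sim <- simulate_counts(labels[tissue], config, sex = sex,
                         seed = sub_seed(seed, 2L),
                         sparse_spots = sparse[tissue])

  # image: eosin level per spot (uneven staining), faint hematoxylin
  mpp <- geom$microns_per_pixel
  margin_px <- ceiling(geom$center_spacing_um / mpp)
  h <- max(grid$px_row) + 2L * margin_px
  w <- max(grid$px_col) + 2L * margin_px
  px_row <- grid$px_row + margin_px
  px_col <- grid$px_col + margin_px
  radius_px <- geom$spot_diameter_um / 2 / mpp
  eo_level <- rep(0, nrow(grid))
  eo_level[tissue] <- 0.9 + stats::rnorm(length(tissue), 0, 0.08)
  eo_level[sparse] <- 0.02
  eo_level <- pmax(eo_level, 0)
  he_level <- rep(0, nrow(grid))
  he_level[tissue] <- stats::runif(length(tissue), 0, 0.08)
  he_level[sparse] <- 0
  conc <- array(0, c(h, w, 2L))
  conc[, , 1L] <- .paint_spots(h, w, px_row, px_col, radius_px, eo_level)
  conc[, , 2L] <- .paint_spots(h, w, px_row, px_col, radius_px, he_level)
  basis <- rbind(.eosin_vector(), .hematoxylin_vector())
  img <- render_stain_image(conc, basis)

  positions <- data.frame(
    barcode = grid$spot_id, in_tissue = grid$in_tissue,
    array_row = grid$array_row, array_col = grid$array_col,
    pxl_row_in_fullres = px_row, pxl_col_in_fullres = px_col,
    stringsAsFactors = FALSE)
  scalefactors <- list(
    spot_diameter_fullres = geom$spot_diameter_um / mpp,
    fiducial_diameter_fullres = 85 / mpp,
    tissue_hires_scalef = 1.0)
  list(grid = grid, positions = positions, scalefactors = scalefactors,
       image = img, counts = sim$counts, gene_map = sim$gene_map,
       labels = labels, sparse = sparse, tissue_idx = tissue,
       stain_basis = basis)
}

.sample_frame <- function(config) {
  per <- config$n_samples_per_stage
  stages <- rep(config$stages, each = per)
  weeks <- unlist(lapply(seq_along(config$stages), function(k) {
    base <- if (k == 1L) 13 else 17
    base + (seq_len(per) - 1L) %% 4L
  }))
  data.frame(
    sample = sprintf("%s_%02d", substr(stages, 1, 2), seq_along(stages)),
    gestational_week = weeks, stage = stages,
    condition = config$condition_assignments,
    sex = config$sex_assignments, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic multi-sample study on disk
#'
#' Writes one Space Ranger-style bundle per sample:
#' `tissue_positions_list.csv` (headerless: barcode, in_tissue, array_row,
#' array_col, pxl_row_in_fullres, pxl_col_in_fullres),
#' `scalefactors_json.json`, `image_hires.png`, `matrix.mtx` +
#' `features.tsv` + `barcodes.tsv` (in-tissue spots), and
#' `spot_types.tsv` (the ground-truth per-spot annotations a real analysis
#' would obtain by clustering); plus a study-level `samples.tsv`.
#' Byte-identical across runs at a fixed `config$random_seed`.
#'
#' @param config A [study_config()].
#' @param out_dir Destination directory (created if missing).
#' @return Invisibly, the ground truth: the sample table plus per-sample
#'   true labels, sparse flags, gene maps and stain basis.
#' @export
generate_study <- function(config, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  samples <- .sample_frame(config)
  truth <- vector("list", nrow(samples))
  names(truth) <- samples$sample
  for (i in seq_len(nrow(samples))) {
    sm <- .simulate_sample(config, samples$stage[i], i, samples$sex[i])
    sdir <- file.path(out_dir, samples$sample[i])
    dir.create(sdir, showWarnings = FALSE)
    utils::write.table(sm$positions,
                       file.path(sdir, "tissue_positions_list.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(sm$scalefactors,
                         file.path(sdir, "scalefactors_json.json"),
                         auto_unbox = TRUE, digits = NA)
    png::writePNG(sm$image / 255, file.path(sdir, "image_hires.png"))
    counts <- sm$counts
    colnames(counts) <- sm$grid$spot_id[sm$tissue_idx]
    Matrix::writeMM(counts, file.path(sdir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(sdir, "features.tsv"))
    writeLines(colnames(counts), file.path(sdir, "barcodes.tsv"))
    ann <- data.frame(spot_id = sm$grid$spot_id[sm$tissue_idx],
                      spot_type = sm$labels[sm$tissue_idx],
                      stringsAsFactors = FALSE)
    utils::write.table(ann, file.path(sdir, "spot_types.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    truth[[i]] <- list(labels = sm$labels, sparse = sm$sparse,
                       tissue_idx = sm$tissue_idx, gene_map = sm$gene_map,
                       stain_basis = sm$stain_basis)
  }
  utils::write.table(samples, file.path(out_dir, "samples.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(samples = samples, per_sample = truth, config = config))
}
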