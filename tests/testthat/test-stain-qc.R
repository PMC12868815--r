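test_that("optical-density conversion has the right fixed points and range", {
  expect_equal(as.vector(rgb_to_od(array(255, c(1, 1, 3)))), c(0, 0, 0))
  expect_equal(as.vector(rgb_to_od(array(24.5, c(1, 1, 3)))), rep(1, 3),
               tolerance = 1e-12)
  od <- rgb_to_od(array(rep(0:255, each = 3), c(3, 1, 256)))
  expect_true(all(is.finite(od)) && all(od >= 0))
  expect_error(rgb_to_od(array(1, c(1, 1, 3)), I0 = 0), "positive")
})

test_that("single-stain images recover the stain vector almost exactly", {
  set.seed(1)
  conc <- matrix(pmax(0, 0.7 + rnorm(2500, 0, 0.2)), 50, 50)
  v <- c(0.092789, 0.954111, 0.283111); v <- v / sqrt(sum(v^2))
  img <- render_stain_image(conc, v)
  est <- estimate_eosin_vector(rgb_to_od(img))
  expect_gte(abs(sum(est$eosin_vector * v)), 0.999)
})

test_that("eosin vector is within 5 degrees when eosin dominates", {
  angles <- vapply(1:20, function(s) {
    fx <- two_stain_image(s)
    est <- estimate_eosin_vector(rgb_to_od(fx$image))
    acos(min(1, abs(sum(est$eosin_vector * fx$eosin)))) * 180 / pi
  }, numeric(1))
  expect_lt(max(angles), 5)
})

test_that("eosin estimate is invariant to pixel order and OD scale", {
  fx <- two_stain_image(3)
  od <- rgb_to_od(fx$image)
  v0 <- estimate_eosin_vector(od)$eosin_vector
  # permute pixels
  set.seed(9)
  perm <- sample(prod(dim(od)[1:2]))
  odp <- array(apply(matrix(od, ncol = 3), 2, function(ch) ch[perm]),
               dim(od))
  expect_equal(abs(sum(estimate_eosin_vector(odp)$eosin_vector * v0)), 1,
               tolerance = 1e-9)
  # global OD scaling (threshold scaled too, to keep the same pixel set)
  est2 <- estimate_eosin_vector(od * 2, beta = 0.3)
  expect_equal(abs(sum(est2$eosin_vector * v0)), 1, tolerance = 1e-9)
})

test_that("degenerate images fail stain estimation", {
  expect_error(estimate_eosin_vector(array(0.5, c(4, 4, 3))), "degenerate")
  expect_error(estimate_eosin_vector(array(0, c(4, 4, 3))),
               "non-transparent")
})

test_that("eosin normalization is a fixed point at the reference and scale-free", {
  # OD field with every pixel clearly non-transparent, so the mask is
  # stable under rescaling
  set.seed(5)
  v <- c(0.092789, 0.954111, 0.283111); v <- v / sqrt(sum(v^2))
  conc <- matrix(runif(1600, 0.5, 1.2), 40, 40)
  basis <- structure(list(eosin_vector = v, beta = 0.15),
                     class = "stain_basis")
  make_od <- function(cc) array(outer(as.vector(cc), v), c(40, 40, 3))
  # fixed point: a field whose 0.99 projection quantile is already 1
  conc_fixed <- conc / stats::quantile(conc, 0.99, names = FALSE)
  g_fixed <- normalize_eosin(make_od(conc_fixed), basis)
  expect_equal(g_fixed, conc_fixed, tolerance = 1e-12, ignore_attr = TRUE)
  # global scale invariance
  g1 <- normalize_eosin(make_od(conc), basis)
  g2 <- normalize_eosin(make_od(conc) * 3.7, basis)
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("two exposures of the same stain field normalize identically", {
  set.seed(6)
  conc <- matrix(pmax(0, 0.7 + rnorm(2500, 0, 0.15)), 50, 50)
  v <- c(0.092789, 0.954111, 0.283111); v <- v / sqrt(sum(v^2))
  img_a <- render_stain_image(conc, v, background_intensity = 255)
  img_b <- render_stain_image(conc, v, background_intensity = 200)
  od_a <- rgb_to_od(img_a, I0 = 255)
  od_b <- rgb_to_od(img_b, I0 = 200)
  ba <- estimate_eosin_vector(od_a)
  expect_equal(normalize_eosin(od_a, ba), normalize_eosin(od_b, ba),
               tolerance = 0.05)
})

test_that("spot quantiles follow the linear-interpolation definition", {
  # disk holding exactly the values 1..10
  gray <- matrix(1:10, 1, 10)
  grid <- data.frame(spot_id = "s1", px_row = 1, px_col = 5)
  q <- spot_od_quantile(gray, grid, radius_px = 20, q = 0.9)
  expect_equal(unname(q), 9.1)  # sorted x: x9 + 0.1 (x10 - x9)
  expect_equal(unname(spot_od_quantile(gray, grid, radius_px = 20, q = 1)),
               10)
  # constant image returns the constant for any q
  gray_c <- matrix(0.42, 30, 30)
  grid2 <- data.frame(spot_id = c("a", "b"), px_row = c(10, 20),
                      px_col = c(10, 20))
  for (qq in c(0.25, 0.9, 1))
    expect_equal(unname(spot_od_quantile(gray_c, grid2, 4, q = qq)),
                 c(0.42, 0.42))
  # empty disk -> NA with warning
  grid3 <- data.frame(spot_id = "off", px_row = -50, px_col = -50)
  expect_warning(qn <- spot_od_quantile(gray_c, grid3, 2), "no pixels")
  expect_true(is.na(qn))
})

test_that("sparse flagging respects thresholds and recovers planted spots", {
  qv <- c(a = 0.9, b = 1.1, c = 0.02, d = 0.95)
  expect_equal(unname(flag_sparse_spots(qv, threshold = 0)),
               rep(FALSE, 4))
  expect_equal(unname(flag_sparse_spots(qv, threshold = 2)),
               rep(TRUE, 4))
  # Otsu split separates a well-separated mixture exactly
  set.seed(2)
  qv2 <- c(rnorm(95, 1, 0.05), rnorm(5, 0.05, 0.01))
  flags <- flag_sparse_spots(qv2)
  expect_equal(unname(flags), rep(c(FALSE, TRUE), c(95, 5)))
})

test_that("edge labelling equals brute-force adjacency on random masks", {
  grid <- small_grid(12L, 12L)
  set.seed(31)
  for (i in 1:100) {
    bg <- runif(nrow(grid)) < runif(1, 0.1, 0.9)
    expect_identical(label_edge_spots(grid, bg),
                     brute_force_edges(grid, bg))
  }
})

test_that("edge labelling handles solid and degenerate masks", {
  grid <- small_grid(10L, 10L)
  # solid block of tissue: edges are exactly the spots with an off-array
  # neighbour
  bg <- rep(FALSE, nrow(grid))
  edges <- label_edge_spots(grid, bg)
  n_nb <- vapply(seq_len(nrow(grid)), function(i)
    nrow(hex_neighbors(grid$array_row[i], grid$array_col[i],
                       n_rows = 10L, n_cols = 10L)), integer(1))
  expect_identical(edges, n_nb < 6L)
  # isolated single tissue spot is an edge spot
  bg2 <- rep(TRUE, nrow(grid)); bg2[25] <- FALSE
  expect_identical(which(label_edge_spots(grid, bg2)), 25L)
})

test_that("minimum-count filter keeps the documented boundary", {
  counts <- matrix(0, 3, 5)
  counts[1, ] <- c(0, 150, 200, 201, 1000)
  expect_equal(unname(filter_min_counts(counts, 200)),
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(all(filter_min_counts(counts, 0)))
  # 199 removed, 200 retained
  expect_equal(unname(filter_min_counts(matrix(c(199, 200), 1), 200)),
               c(FALSE, TRUE))
  expect_error(filter_min_counts(counts, -1), ">= 0")
})

test_that("the QC filter pipeline is idempotent on the retained set", {
  cfg <- study_config(geometry = grid_geometry(n_rows = 16L, n_cols = 16L),
                      random_seed = 8L)
  td <- file.path(tempdir(), "study_idem")
  generate_study(cfg, td)
  b <- read_sample_bundle(file.path(td, "ps_01"))
  grid <- data.frame(spot_id = b$positions$barcode,
                     array_row = b$positions$array_row,
                     array_col = b$positions$array_col,
                     px_row = b$positions$pxl_row_in_fullres,
                     px_col = b$positions$pxl_col_in_fullres,
                     in_tissue = b$positions$in_tissue)
  qc <- spot_qc(b$image, grid, b$counts,
                radius_px = b$scalefactors$spot_diameter_fullres / 2)
  kept <- b$counts[, colnames(b$counts) %in% qc$spot_id[qc$retained]]
  expect_true(all(filter_min_counts(kept, 200)))
  unlink(td, recursive = TRUE)
})
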