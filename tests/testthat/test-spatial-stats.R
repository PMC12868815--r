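test_that("Ripley estimator matches its closed forms", {
  pts <- rbind(c(0, 0), c(3, 4))  # distance 5
  win <- make_window(pts, r = c(1, 4.9, 5, 10))
  win$area <- 100
  cv <- ripley_l(pts, win)
  expect_equal(cv$K, c(0, 0, 100, 100))
  expect_equal(cv$L, c(0, 0, sqrt(100 / pi), sqrt(100 / pi)))
  expect_error(ripley_l(rbind(c(0, 0)), win), "fewer than 2")
})

test_that("Ripley estimator equals O(n^2) brute force", {
  set.seed(23)
  for (n in c(10, 120, 300)) {
    pts <- cbind(runif(n, 0, 50), runif(n, 0, 80))
    win <- make_window(pts, n_radii = 30L)
    cv <- ripley_l(pts, win)
    expect_equal(cv$K, brute_force_k(pts, win$area, win$r),
                 tolerance = 1e-12)
    # K is monotone non-decreasing in r
    expect_true(all(diff(cv$K) >= 0))
  }
})

test_that("Ripley estimator is invariant to order and rigid translation", {
  set.seed(8)
  pts <- cbind(runif(60), runif(60))
  win <- make_window(pts, n_radii = 20L)
  cv <- ripley_l(pts, win)
  cv_perm <- ripley_l(pts[sample(60), ], win)
  expect_equal(cv$K, cv_perm$K)
  shifted <- sweep(pts, 2, c(13.7, -2.4), "+")
  cv_shift <- ripley_l(shifted, win)
  expect_equal(cv$K, cv_shift$K)
})

test_that("random labeling on a dense lattice gives L close to r", {
  # the translation-corrected estimator recovers the CSR reference; the
  # uncorrected default carries the (cancelling) edge deficit instead
  grid <- small_grid(50L, 50L)
  coords <- as.matrix(grid[, c("um_x", "um_y")])
  win <- make_window(coords)
  set.seed(12)
  l_mat <- replicate(30, {
    idx <- sample(nrow(coords), 400)
    ripley_l(coords[idx, ], win, correction = "translation")$L
  })
  l_bar <- rowMeans(l_mat)
  # spacing (100 um) << r << window size (min side 2450 um); below ~5
  # spacings the lattice ring structure dominates the estimate
  mid <- win$r >= 500 & win$r <= 1200
  expect_true(all(abs(l_bar[mid] - win$r[mid]) <= 0.05 * win$r[mid]))
})

test_that("random-label envelopes are deterministic and detect clustering", {
  grid <- small_grid(24L, 24L)
  coords <- as.matrix(grid[, c("um_x", "um_y")])
  win <- make_window(coords)
  counts <- c(a = 100L, b = nrow(grid) - 100L)
  e1 <- random_label_envelope(coords, counts, win, n_sim = 49, seed = 99)
  e2 <- random_label_envelope(coords, counts, win, n_sim = 49, seed = 99)
  expect_identical(e1, e2)
  # a tightly clustered field escapes the upper band at mid radii
  lab <- simulate_type_field(grid, c(a = 0.3, b = 0.7), 50, seed = 2)
  obs <- ripley_l(coords[lab == "a", ], win)
  env <- random_label_envelope(coords, table(lab)[c("a", "b")], win,
                               n_sim = 99, seed = 5)
  mid <- win$r > 200 & win$r < 800
  expect_gt(mean(obs$L[mid] > env$a$hi[mid]), 0.8)
  # a type with fewer than 2 spots is skipped
  expect_message(
    e3 <- random_label_envelope(coords, c(a = 50L, b = 1L), win,
                                n_sim = 39, seed = 1),
    "fewer than 2")
  expect_named(e3, "a")
})

test_that("the local polynomial smoother reproduces constants and lines", {
  x <- seq(0, 10, length.out = 40)
  expect_equal(loess_smooth(x, rep(3.3, 40), span = 0.5), rep(3.3, 40))
  y <- 2 - 0.7 * x
  expect_equal(loess_smooth(x, y, span = 0.4), y, tolerance = 1e-9)
  expect_error(loess_smooth(c(1, 1), c(1, 2)), "distinct")
})

test_that("the smoother solves tricube weighted least squares at a query", {
  set.seed(77)
  x <- sort(runif(30, 0, 1))
  y <- sin(4 * x) + rnorm(30, 0, 0.1)
  x0 <- 0.42
  span <- 0.6
  fit <- loess_smooth(x, y, span = span, xout = x0)
  # independent WLS oracle
  k <- ceiling(span * 30)
  d <- abs(x - x0)
  h <- sort(d)[k]
  w <- pmax(0, (1 - pmin(d / h, 1)^3)^3)
  co <- stats::lm.wfit(cbind(1, x - x0), y, w)$coefficients
  expect_equal(fit, unname(co[1]), tolerance = 1e-9)
})

test_that("stage aggregation pools curves and a single sample is its own smooth", {
  r <- seq(0, 10, length.out = 25)
  curves <- data.frame(sample = "s1", spot_type = "a", r = r,
                       L = r + sin(r))
  agg <- aggregate_stage_curves(curves, c(s1 = "early"), span = 0.5,
                                r_out = r)
  expect_equal(agg$L_smooth, loess_smooth(r, r + sin(r), span = 0.5,
                                          xout = r))
  expect_equal(unique(agg$n_samples), 1L)
  expect_error(aggregate_stage_curves(curves, c(zz = "early")),
               "without a stage")
})

test_that("permuting stage labels removes the stage contrast", {
  grid <- small_grid(24L, 24L)
  coords <- as.matrix(grid[, c("um_x", "um_y")])
  win <- make_window(coords)
  cfg <- study_config()
  truth <- rep(c("pseudoglandular", "canalicular"), each = 4)
  # fixed per-sample curves, simulated once under the true stages
  curves <- do.call(rbind, lapply(1:8, function(i) {
    lab <- simulate_type_field(grid, cfg$stage_composition[[truth[i]]],
                               cfg$clustering_dispersion[[truth[i]]],
                               seed = 400 + i)
    cv <- ripley_l(coords[lab == "distal_parenchyma", ], win)
    data.frame(sample = paste0("s", i), spot_type = "distal_parenchyma",
               r = cv$r, L = cv$L)
  }))
  mean_gap <- function(stages) {
    names(stages) <- paste0("s", 1:8)
    agg <- aggregate_stage_curves(curves, stages, span = 0.75)
    a <- agg$L_smooth[agg$stage == "pseudoglandular"]
    b <- agg$L_smooth[agg$stage == "canalicular"]
    mean(abs(a - b), na.rm = TRUE)
  }
  observed <- mean_gap(truth)
  set.seed(61)
  permuted <- vapply(1:8, function(i) mean_gap(sample(truth)), numeric(1))
  expect_gt(observed, mean(permuted))
})
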