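test_that("composition tables normalize per sample and reject bad labels", {
  ann <- data.frame(sample = "s1",
                    spot_type = c("a", "a", "a", "b"))
  ct <- composition_table(ann)
  expect_equal(ct$freq, c(0.75, 0.25))
  # zero-completion and row sums over several samples
  ann2 <- data.frame(sample = rep(c("s1", "s2"), c(4, 3)),
                     spot_type = c("a", "a", "b", "c", "a", "a", "a"))
  ct2 <- composition_table(ann2)
  sums <- tapply(ct2$freq, ct2$sample, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
  expect_equal(nrow(ct2), 6L)  # full vocabulary in both samples
  expect_error(composition_table(ann, types = c("a")), "unknown spot type")
})

test_that("generated compositions match the configured proportions", {
  grid <- small_grid(63L, 63L)  # ~2000 spots
  cfg <- study_config()
  p <- cfg$stage_composition$pseudoglandular
  lab <- simulate_type_field(grid, p, dispersion = 1e6, seed = 21)
  ct <- composition_table(data.frame(sample = "s", spot_type = lab),
                          types = names(p))
  n <- nrow(grid)
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(ct$freq[match(names(p), ct$spot_type)] - p)
                  <= 3 * se))
})

test_that("Wilcoxon exact enumeration reproduces the small-sample oracle", {
  t1 <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(t1$p.value, 1 / 3)
  expect_equal(t1$statistic, 3)
  # identical multisets are maximally non-significant
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2))$p.value, 1)
  expect_warning(t_deg <- wilcoxon_rank_sum(c(2, 2), c(2, 2)), "identical")
  expect_equal(t_deg$p.value, 1)
  # tie-free 6 vs 6: stats::wilcox.test exact as the independent oracle
  set.seed(10)
  for (i in 1:5) {
    v <- sample(1000, 12)  # 12 distinct values: no ties anywhere
    x <- v[1:6]; y <- v[7:12]
    ours <- wilcoxon_rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
  # tied 6 vs 6: full 924-arrangement enumeration oracle
  x <- c(1, 2, 2, 3, 5, 5); y <- c(2, 3, 3, 4, 5, 6)
  rk <- rank(c(x, y))
  combos <- utils::combn(12, 6)
  w_all <- colSums(matrix(rk[combos], nrow = 6))
  w_obs <- sum(rk[1:6])
  p_oracle <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(wilcoxon_rank_sum(x, y)$p.value, p_oracle)
})

test_that("the large-sample path matches the tie-corrected normal test", {
  set.seed(3)
  x <- round(rnorm(15, 0, 2), 1)
  y <- round(rnorm(12, 0.5, 2), 1)
  ours <- wilcoxon_rank_sum(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  expect_match(ours$method, "normal approximation")
})

test_that("stage composition tests adjust across types", {
  cfg <- study_config(geometry = grid_geometry(n_rows = 24L, n_cols = 24L))
  grid <- make_hex_grid(cfg$geometry)
  ann <- do.call(rbind, lapply(1:12, function(i) {
    st <- if (i <= 6) "pseudoglandular" else "canalicular"
    lab <- simulate_type_field(grid, cfg$stage_composition[[st]],
                               cfg$clustering_dispersion[[st]],
                               seed = 500 + i)
    data.frame(sample = sprintf("s%02d", i), spot_type = lab, stage = st)
  }))
  comp <- composition_table(ann[, 1:2],
                            sample_meta = unique(ann[, c("sample", "stage")]))
  res <- stage_composition_test(comp)
  expect_equal(sort(res$spot_type), sort(spot_type_names))
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  # the configured +0.15 shift is the strongest signal
  expect_lt(res$p_raw[res$spot_type == "distal_parenchyma"], 0.05)
})

test_that("peripheral t-test matches the closed-form oracle", {
  # symmetric mean-zero differences
  x <- c(2, 1, 2, 1); y <- c(1, 2, 1, 2)
  tt <- student_t_peripheral(x, y)
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)
  # identical vectors: zero variance of differences is an error
  expect_error(student_t_peripheral(c(1, 2, 3), c(1, 2, 3)),
               "zero variance")
  # fixed 6-sample vectors against the textbook formula
  a <- c(0.31, 0.42, 0.28, 0.36, 0.40, 0.33)
  b <- c(0.22, 0.30, 0.25, 0.28, 0.31, 0.27)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(6))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), 5)
  tt2 <- student_t_peripheral(a, b)
  expect_equal(unname(tt2$statistic), t_oracle, tolerance = 1e-12)
  expect_equal(tt2$p.value, p_oracle, tolerance = 1e-12)
  # unpaired mode uses the pooled-variance form
  tt3 <- student_t_peripheral(a, b, paired = FALSE)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tt3$p.value, ref$p.value)
})

test_that("permutation test matches exhaustive enumeration and edge cases", {
  set.seed(14)
  freq <- matrix(stats::rgamma(12 * 4, 2), 12, 4)
  freq <- freq / rowSums(freq)
  cond <- rep(c("a", "b"), c(4, 8))
  res <- permutation_composition_test(freq, cond, n_perm = 495)
  # brute-force oracle over all 495 splits
  combos <- utils::combn(12, 4)
  t_all <- apply(combos, 2, function(idx) {
    g1 <- seq_len(12) %in% idx
    sum((colMeans(freq[g1, ]) - colMeans(freq[!g1, ]))^2)
  })
  obs <- sum((colMeans(freq[1:4, ]) - colMeans(freq[5:12, ]))^2)
  expect_equal(res$statistic, obs)
  expect_equal(res$p.value, mean(t_all >= obs - 1e-12))
  expect_match(res$method, "exhaustive")
  # identical samples: zero statistic, p = 1
  freq0 <- matrix(rep(c(0.6, 0.4), each = 8), 8, 2)
  res0 <- permutation_composition_test(freq0, rep(c("a", "b"), 4),
                                       n_perm = 999)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  expect_error(permutation_composition_test(freq, rep("a", 12)),
               "two conditions")
  # Monte-Carlo mode is deterministic given the seed
  freq_big <- matrix(stats::rgamma(18 * 3, 2), 18, 3)
  freq_big <- freq_big / rowSums(freq_big)
  cond_big <- rep(c("a", "b"), 9)
  m1 <- permutation_composition_test(freq_big, cond_big, n_perm = 999,
                                     seed = 5)
  m2 <- permutation_composition_test(freq_big, cond_big, n_perm = 999,
                                     seed = 5)
  expect_equal(m1$p.value, m2$p.value)
  expect_match(m1$method, "Monte-Carlo")
})

test_that("pseudobulk aggregation conserves counts and matches group sums", {
  set.seed(19)
  counts <- matrix(rpois(50 * 200, 2), 50, 200)
  samples <- sample(paste0("s", 1:3), 200, replace = TRUE)
  clusters <- sample(paste0("c", 1:4), 200, replace = TRUE)
  pb <- pseudobulk_aggregate(counts, samples, clusters)
  expect_equal(sum(pb$counts), sum(counts))
  # brute-force group-sum oracle
  for (j in seq_len(ncol(pb$counts))) {
    sel <- samples == pb$col_data$sample[j] &
      clusters == pb$col_data$cluster[j]
    expect_equal(as.numeric(pb$counts[, j]), rowSums(counts[, sel,
                                                            drop = FALSE]))
  }
  # single sample, single cluster: row sums
  pb1 <- pseudobulk_aggregate(counts, rep("s", 200), rep("c", 200))
  expect_equal(as.numeric(pb1$counts[, 1]), rowSums(counts))
  expect_error(pseudobulk_aggregate(counts, samples[-1], clusters),
               "cover")
  expect_error(pseudobulk_aggregate(counts, replace(samples, 3, NA),
                                    clusters), "without")
})

test_that("signature scoring follows the rank formula at its extremes", {
  n <- 2000L
  expr <- stats::setNames(seq(n, 1), paste0("g", seq_len(n)))
  # signature at the very top: score 1
  top <- paste0("g", 1:7)
  expect_equal(signature_score(expr, top, r_max = 1500), 1)
  # all 7 genes beyond the rank cutoff: (7 - 1) / (2 * 1500)
  bottom <- paste0("g", (n - 6):n)
  expect_equal(signature_score(expr, bottom, r_max = 1500),
               (7 - 1) / (2 * 1500))
  # single gene exactly at rank r_max: 1 - (r_max - 1) / r_max
  one <- paste0("g", 1500)
  expect_equal(signature_score(expr, one, r_max = 1500), 1 / 1500)
  expect_error(signature_score(expr, "absent_gene", r_max = 1500),
               "no signature gene")
  expect_error(signature_score(expr[1:100], top, r_max = 1500), "r_max")
})

test_that("signature scores are invariant to monotone transforms", {
  set.seed(25)
  expr <- stats::setNames(stats::rgamma(3000, 1), paste0("g", 1:3000))
  sig <- sample(names(expr), 7)
  s0 <- signature_score(expr, sig)
  expect_equal(signature_score(log1p(expr), sig), s0)
  expect_equal(signature_score(expr^3, sig), s0)
  expect_equal(signature_score(rank(expr), sig), s0)
})

test_that("sex calling separates male and female count profiles", {
  cfg <- study_config(n_background_genes = 300L)
  labels <- rep(spot_type_names[1], 120)
  calls <- vapply(1:6, function(s) {
    sex <- if (s %% 2 == 0) "male" else "female"
    sim <- simulate_counts(labels, cfg, sex = sex, seed = 900 + s)
    totals <- Matrix::rowSums(sim$counts)
    sc <- signature_score(totals, r_max = length(totals) - 1L)
    call_sex(stats::setNames(sc, "s"))$sex == sex
  }, logical(1))
  expect_true(all(calls))
  # degenerate thresholds
  expect_equal(call_sex(c(s1 = 0.9), threshold = 1.1)$sex, "female")
  set.seed(26)
  expr <- stats::setNames(stats::rgamma(2000, 1) + 0.1, paste0("g", 1:2000))
  expr[male_signature_genes] <- 0  # signature silent -> bottom ranks
  expect_equal(call_sex(c(s = signature_score(expr, r_max = 1500)))$sex,
               "female")
})
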