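#' Per-sample spot-type composition table
#'
#' Counts and normalized frequencies per (sample, spot type), completed
#' with zero rows for types absent from a sample so every sample carries
#' the full type vocabulary, ordered by sample then type. Sample metadata
#' (stage, condition, sex) is joined when provided.
#'
#' @param annotations Data frame with one row per spot: `sample`,
#'   `spot_type`.
#' @param types Type vocabulary; defaults to the observed types. Any
#'   annotation outside it is an error.
#' @param sample_meta Optional data.frame keyed by `sample` with metadata
#'   columns (e.g. `stage`, `condition`, `sex`).
#' @return Data frame of class `composition_table`: `sample`, `spot_type`,
#'   `n_spots`, `freq`, plus metadata columns.
#' @export
composition_table <- function(annotations, types = NULL,
                              sample_meta = NULL) {
  stopifnot(all(c("sample", "spot_type") %in% names(annotations)))
  if (is.null(types)) types <- sort(unique(annotations$spot_type))
  bad <- setdiff(unique(annotations$spot_type), types)
  if (length(bad))
    stop("unknown spot type label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  samples <- sort(unique(annotations$sample))
  tab <- table(factor(annotations$sample, levels = samples),
               factor(annotations$spot_type, levels = types))
  out <- data.frame(
    sample = rep(samples, each = length(types)),
    spot_type = rep(types, length(samples)),
    n_spots = as.integer(t(tab)),
    stringsAsFactors = FALSE)
  totals <- stats::ave(out$n_spots, out$sample, FUN = sum)
  out$freq <- ifelse(totals > 0, out$n_spots / totals, 0)
  if (!is.null(sample_meta)) {
    idx <- match(out$sample, sample_meta$sample)
    for (cl in setdiff(names(sample_meta), "sample"))
      out[[cl]] <- sample_meta[[cl]][idx]
  }
  class(out) <- c("composition_table", "data.frame")
  out
}

# Exact rank-sum tail by enumeration of all group-A assignments with
# mid-ranks kept as observed (handles ties exactly).
.wilcox_exact_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(nx)])
  combos <- utils::combn(n, nx)
  w_all <- colSums(matrix(rk[combos], nrow = nx))
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  list(W = w_obs, p_one = min(p_le, p_ge),
       p_two = min(1, 2 * min(p_le, p_ge)))
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' For combined sample size at most `exact_limit` (default 12, the study
#' scale), the two-sided p-value is computed by full enumeration of all
#' `choose(n, n_x)` group assignments of the observed mid-ranks, so ties
#' are handled exactly. Larger samples use the normal approximation with
#' tie correction (and continuity correction).
#'
#' @param x,y Numeric samples.
#' @param exact_limit Combined-size bound for the exact path.
#' @return List of class `lungspatial_test`: `statistic` (rank sum of
#'   `x`), `p.value` (two-sided), `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12L) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups need at least one value", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups; p = 1", call. = FALSE)
    return(structure(list(statistic = sum(rank(c(x, y))[seq_along(x)]),
                          p.value = 1, method = "degenerate"),
                     class = "lungspatial_test"))
  }
  n <- length(x) + length(y)
  if (n <= exact_limit) {
    ex <- .wilcox_exact_p(x, y)
    return(structure(list(statistic = ex$W, p.value = ex$p_two,
                          method = "exact enumeration"),
                     class = "lungspatial_test"))
  }
  nx <- length(x); ny <- length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ties <- table(rk)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  structure(list(statistic = W,
                 p.value = min(1, 2 * stats::pnorm(-abs(z))),
                 method = "normal approximation with tie correction"),
            class = "lungspatial_test")
}

#' @export
print.lungspatial_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g\n",
              x$method, x$statistic, x$p.value))
  invisible(x)
}

#' Per-type stage comparison of spot-type frequencies
#'
#' Applies [wilcoxon_rank_sum()] to each spot type's per-sample
#' frequencies between two stages, with Benjamini-Hochberg adjustment
#' across types (raw p-values are kept alongside).
#'
#' @param comp A [composition_table()] carrying a `stage` column.
#' @param stages The two stage labels to compare (default: the two present).
#' @return Data frame: `spot_type`, `statistic`, `p_raw`, `p_adj`,
#'   `method`.
#' @export
stage_composition_test <- function(comp, stages = NULL) {
  if (is.null(comp$stage)) stop("composition table lacks a stage column",
                                call. = FALSE)
  if (is.null(stages)) stages <- unique(comp$stage)
  if (length(stages) != 2L) stop("need exactly two stages", call. = FALSE)
  types <- unique(comp$spot_type)
  rows <- lapply(types, function(ty) {
    x <- comp$freq[comp$spot_type == ty & comp$stage == stages[1L]]
    y <- comp$freq[comp$spot_type == ty & comp$stage == stages[2L]]
    tt <- suppressWarnings(wilcoxon_rank_sum(x, y))
    data.frame(spot_type = ty, statistic = tt$statistic,
               p_raw = tt$p.value, method = tt$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out[, c("spot_type", "statistic", "p_raw", "p_adj", "method")]
}

#' Compare a type's frequency between peripheral and non-peripheral spots
#'
#' Student's t-test over samples: paired by default (each sample
#' contributes a peripheral and a non-peripheral frequency), or the
#' two-sample pooled-variance form.
#'
#' @param peripheral,non_peripheral Per-sample frequencies of the target
#'   type within the peripheral / non-peripheral region.
#' @param paired Use the paired test (default).
#' @return The `htest` from [stats::t.test()] (pooled variance when
#'   unpaired).
#' @export
student_t_peripheral <- function(peripheral, non_peripheral,
                                 paired = TRUE) {
  if (length(peripheral) < 2L || length(non_peripheral) < 2L)
    stop("need at least 2 samples", call. = FALSE)
  if (paired && length(peripheral) != length(non_peripheral))
    stop("paired mode requires equal lengths", call. = FALSE)
  if (paired && stats::sd(peripheral - non_peripheral) == 0)
    stop("zero variance of differences; t is undefined", call. = FALSE)
  stats::t.test(peripheral, non_peripheral, paired = paired,
                var.equal = !paired)
}

# Omnibus statistic: sum over types of squared mean-frequency differences.
.composition_stat <- function(freq_mat, grp1) {
  m1 <- colMeans(freq_mat[grp1, , drop = FALSE])
  m2 <- colMeans(freq_mat[!grp1, , drop = FALSE])
  sum((m1 - m2)^2)
}

#' Permutation test for composition differences between conditions
#'
#' Statistic: `T = sum_types (mean freq in condition 1 - mean freq in
#' condition 2)^2`. Condition labels are permuted over samples. When all
#' `choose(n, n1)` distinct splits number at most `n_perm` the test is
#' exhaustive (`p = #\{T_perm >= T_obs\} / n_splits`, the observed split
#' included); otherwise `n_perm` random permutations are drawn and
#' `p = (1 + #\{T_perm >= T_obs\}) / (n_perm + 1)`.
#'
#' @param comp A [composition_table()] carrying a `condition` column, or a
#'   samples x types frequency matrix.
#' @param condition Per-sample condition labels (two levels); taken from
#'   `comp` when omitted.
#' @param n_perm Number of permutations (>= 999 recommended).
#' @param seed Integer seed (Monte-Carlo mode only).
#' @return List of class `lungspatial_test`: `statistic`, `p.value`,
#'   `method`, `n_perm_used`.
#' @export
permutation_composition_test <- function(comp, condition = NULL,
                                         n_perm = 999L, seed = 1L) {
  if (inherits(comp, "composition_table")) {
    if (is.null(condition)) {
      meta <- unique(comp[, c("sample", "condition")])
      condition <- meta$condition[order(meta$sample)]
    }
    samples <- sort(unique(comp$sample))
    types <- unique(comp$spot_type)
    freq_mat <- matrix(comp$freq[order(match(comp$sample, samples),
                                       match(comp$spot_type, types))],
                       nrow = length(samples), byrow = TRUE,
                       dimnames = list(samples, types))
  } else {
    freq_mat <- as.matrix(comp)
    if (is.null(condition)) stop("condition labels required", call. = FALSE)
  }
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("need exactly two conditions", call. = FALSE)
  if (min(table(condition)) < 2L)
    stop("need at least 2 samples per condition", call. = FALSE)
  n <- nrow(freq_mat)
  n1 <- sum(condition == levels(condition)[1L])
  obs <- .composition_stat(freq_mat, condition == levels(condition)[1L])
  n_splits <- choose(n, n1)
  eps <- 1e-12
  if (n_splits <= n_perm) {
    combos <- utils::combn(n, n1)
    # T for every split via one matrix product: with z = +-1 indicator,
    # mean difference per type is t(F) z scaled by 1/n1, 1/n2
    z <- matrix(-1 / (n - n1), n, ncol(combos))
    z[cbind(as.vector(combos),
            rep(seq_len(ncol(combos)), each = n1))] <- 1 / n1
    t_all <- colSums((t(freq_mat) %*% z)^2)
    p <- mean(t_all >= obs - eps)
    method <- "exhaustive permutation"
    used <- n_splits
  } else {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    t_perm <- replicate(n_perm, {
      idx <- sample.int(n, n1)
      .composition_stat(freq_mat, seq_len(n) %in% idx)
    })
    p <- (1 + sum(t_perm >= obs - eps)) / (n_perm + 1)
    method <- "Monte-Carlo permutation"
    used <- n_perm
  }
  structure(list(statistic = obs, p.value = p, method = method,
                 n_perm_used = used), class = "lungspatial_test")
}

#' Pseudobulk aggregation of spot counts
#'
#' Sums counts per gene within each (sample, cluster) group; the grand
#' total is conserved exactly.
#'
#' @param counts Genes x spots matrix (dense or sparse).
#' @param sample_ids,cluster_labels Per-spot grouping vectors covering all
#'   columns; any `NA` is an error.
#' @return List of class `pseudobulk`: `counts` (genes x groups sparse
#'   matrix with `sample:cluster` column names) and `col_data`
#'   (data.frame: `sample`, `cluster`).
#' @export
pseudobulk_aggregate <- function(counts, sample_ids, cluster_labels) {
  if (length(sample_ids) != ncol(counts) ||
      length(cluster_labels) != ncol(counts))
    stop("grouping vectors must cover all spots", call. = FALSE)
  if (anyNA(sample_ids) || anyNA(cluster_labels))
    stop("spots without a sample or cluster label", call. = FALSE)
  grp <- interaction(sample_ids, cluster_labels, sep = ":", drop = TRUE)
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp),
                              x = 1, dims = c(length(grp), nlevels(grp)))
  agg <- counts %*% ind
  colnames(agg) <- levels(grp)
  parts <- strsplit(levels(grp), ":", fixed = TRUE)
  col_data <- data.frame(sample = vapply(parts, `[`, "", 1L),
                         cluster = vapply(parts, `[`, "", 2L),
                         stringsAsFactors = FALSE)
  structure(list(counts = agg, col_data = col_data), class = "pseudobulk")
}

#' Rank-based gene-signature score
#'
#' Mann-Whitney-style score: genes are ranked by decreasing expression
#' (mid-ranks for ties; ranks beyond `r_max` clamped to `r_max + 1`), then
#' `U' = sum(ranks of signature genes) - n_sig (n_sig + 1) / 2` and
#' `score = 1 - U' / (n_sig * r_max)`, clipped to `[0, 1]`. The score is
#' invariant to any monotone transform of the expression vector.
#'
#' @param expr Named expression vector, or genes x samples matrix with
#'   rownames.
#' @param signature Character vector of signature genes (unique,
#'   non-empty).
#' @param r_max Rank cutoff (default 1500; must be smaller than the number
#'   of genes).
#' @return Numeric score in `[0, 1]` (vector over columns for a matrix).
#' @export
signature_score <- function(expr, signature = male_signature_genes,
                            r_max = 1500L) {
  signature <- unique(signature)
  if (length(signature) == 0L) stop("empty signature", call. = FALSE)
  if (is.matrix(expr) || inherits(expr, "Matrix")) {
    return(vapply(seq_len(ncol(expr)), function(j) {
      v <- expr[, j]
      names(v) <- rownames(expr)
      signature_score(v, signature, r_max)
    }, numeric(1)))
  }
  if (r_max >= length(expr))
    stop("r_max must be smaller than the number of genes", call. = FALSE)
  present <- intersect(signature, names(expr))
  if (length(present) == 0L)
    stop("no signature gene present in the expression vector",
         call. = FALSE)
  rk <- rank(-as.numeric(expr), ties.method = "average")
  names(rk) <- names(expr)
  rk[rk > r_max] <- r_max + 1
  ns <- length(present)
  u <- sum(rk[present]) - ns * (ns + 1) / 2
  min(1, max(0, 1 - u / (ns * r_max)))
}

#' Call sample sex from male-signature scores
#'
#' @param scores Named per-sample signature scores.
#' @param threshold Score above which a sample is called male
#'   (default 0.2).
#' @return Data frame: `sample`, `score`, `sex`.
#' @export
call_sex <- function(scores, threshold = 0.2) {
  if (length(scores) < 1L) stop("need at least one sample", call. = FALSE)
  data.frame(sample = if (is.null(names(scores)))
    as.character(seq_along(scores)) else names(scores),
    score = as.numeric(scores),
    sex = ifelse(scores > threshold, "male", "female"),
    row.names = NULL, stringsAsFactors = FALSE)
}
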