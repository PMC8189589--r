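# minimal hand-built probe table: `expr` is probes x samples
make_probes <- function(expr, gene_id, background, donor, coords) {
  structure(list(probe_id = sprintf("P%03d", seq_len(nrow(expr))),
                 gene_id = gene_id, expr = expr,
                 background_exceeded = background,
                 sample_donor = donor, sample_coords = coords),
            class = "cm_probes")
}

test_that("probe filtering keeps the at-threshold probe", {
  n_samp <- 100L
  expr <- matrix(rnorm(3 * n_samp), 3, n_samp)
  bg <- rbind(rep(TRUE, n_samp),                       # always exceeds
              c(rep(TRUE, 49), rep(FALSE, 51)),        # 49% -> removed
              c(rep(TRUE, 50), rep(FALSE, 50)))        # exactly 50% -> kept
  pr <- make_probes(expr, c("G1", "G2", "G3"), bg,
                    rep("D1", n_samp), matrix(0, n_samp, 3))
  kept <- filter_probes(pr)
  expect_setequal(kept$gene_id, c("G1", "G3"))
  bg_none <- matrix(FALSE, 3, n_samp)
  pr2 <- make_probes(expr, c("G1", "G2", "G3"), bg_none,
                     rep("D1", n_samp), matrix(0, n_samp, 3))
  expect_warning(filter_probes(pr2), "no probes")
})

test_that("differential stability matches an explicit donor-pair loop", {
  set.seed(1)
  n_loc <- 12L
  donors <- rep(c("D1", "D2", "D3"), each = n_loc)
  location <- rep(seq_len(n_loc), 3)
  base <- rnorm(n_loc)
  # probe 1: identical spatial profile in every donor -> DS = 1
  # probe 2: noisy replicate; probe 3: unrelated across donors
  expr <- rbind(rep(base, 3),
                rep(base, 3) + rnorm(3 * n_loc, sd = 0.8),
                rnorm(3 * n_loc))
  pr <- make_probes(expr, c("G1", "G1", "G1"),
                    matrix(TRUE, 3, 3 * n_loc), donors,
                    matrix(0, 3 * n_loc, 3))
  sel <- select_probe_by_differential_stability(pr, location)
  expect_equal(sel$selected$probe_id, "P001")
  expect_equal(sel$selected$ds, 1, tolerance = 1e-12)
  # oracle: explicit loop over the three donor pairs for probe 2
  ds2 <- crossmode:::.probe_ds(expr[2, ], donors, location)
  pair_cors <- c()
  for (pr_idx in list(c("D1", "D2"), c("D1", "D3"), c("D2", "D3"))) {
    v1 <- expr[2, donors == pr_idx[1]]
    v2 <- expr[2, donors == pr_idx[2]]
    pair_cors <- c(pair_cors, cor(v1, v2))
  }
  expect_equal(ds2, mean(pair_cors), tolerance = 1e-12)
})

test_that("tied probes are resolved by probe id order", {
  n_loc <- 8L
  donors <- rep(c("D1", "D2"), each = n_loc)
  location <- rep(seq_len(n_loc), 2)
  base <- rnorm(n_loc)
  expr <- rbind(rep(base, 2), rep(base, 2))  # identical probes
  pr <- make_probes(expr, c("G1", "G1"), matrix(TRUE, 2, 2 * n_loc),
                    donors, matrix(0, 2 * n_loc, 3))
  sel <- select_probe_by_differential_stability(pr, location)
  expect_equal(sel$selected$probe_id, "P001")
})

test_that("sample matching respects the 3 mm radius", {
  mask <- make_lattice(27, 2)
  samples <- rbind(mask[5, ],                 # exactly at a voxel center
                   mask[10, ] + c(1.4, 0, 0), # within 3 mm
                   mask[1, ] - c(5, 5, 5))    # > 3 mm away from everything
  m <- match_samples_to_voxels(samples, mask)
  expect_equal(m$voxel[1], 5)
  expect_equal(m$distance[1], 0)
  expect_true(m$matched[2])
  expect_false(m$matched[3])
  expect_true(is.na(m$voxel[3]))
})

test_that("scaled robust sigmoid matches its closed form and edge cases", {
  set.seed(2)
  x <- rnorm(41, mean = 3, sd = 2)  # odd length: the median is a data point
  got <- scaled_robust_sigmoid(x)
  s <- 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))
  expect_equal(got, (s - min(s)) / (max(s) - min(s)), tolerance = 1e-12)
  expect_equal(min(got), 0)
  expect_equal(max(got), 1)
  expect_true(all(diff(got[order(x)]) >= 0))             # monotone
  expect_equal(s[x == median(x)], 0.5, tolerance = 1e-12)  # sigmoid(0)
  expect_equal(scaled_robust_sigmoid(rep(2, 5)), rep(0.5, 5))
  expect_error(scaled_robust_sigmoid(1), "2 values")
})

test_that("normalization never mixes donors", {
  set.seed(3)
  vals <- matrix(rnorm(60), 20, 3)
  donor <- rep(c("D1", "D2"), each = 10)
  n1 <- normalize_expression(vals, donor)
  vals2 <- vals
  vals2[donor == "D2", ] <- vals2[donor == "D2", ] * 100 + 7
  n2 <- normalize_expression(vals2, donor)
  expect_equal(n1[donor == "D1", ], n2[donor == "D1", ], tolerance = 1e-12)
})

test_that("NIPALS weights match the cross-covariance oracle", {
  set.seed(4)
  X <- matrix(rnorm(50), 10, 5)
  colnames(X) <- sprintf("G%d", 1:5)
  y <- rnorm(10)
  fit <- fit_pls(X, y, n_components = 2)
  # first weight vector is the normalized cross-covariance of scaled X, y
  Xs <- scale(X)
  w_oracle <- crossprod(Xs, y - mean(y))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(sum(fit$W[, 1] * w_oracle)), 1, tolerance = 1e-10)
  # y proportional to one gene: that gene dominates the first weight
  y2 <- 3 * X[, 4] + rnorm(10, sd = 1e-6)
  fit2 <- fit_pls(X, y2, n_components = 1)
  expect_equal(which.max(abs(fit2$W[, 1])), 4L, ignore_attr = TRUE)
})

test_that("in-sample fit improves with components and predicts exactly at full rank", {
  set.seed(5)
  X <- matrix(rnorm(20 * 8), 20, 8)
  colnames(X) <- sprintf("G%d", 1:8)
  y <- X %*% rnorm(8) + rnorm(20, sd = 0.1)
  r2 <- vapply(1:5, function(k) {
    fit <- fit_pls(X, y, k)
    cor(predict(fit, X, ncomp = k), y)^2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-9))
  expect_error(fit_pls(X, y, 25), "exceeds")
})

test_that("PLS predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(6)
  X <- matrix(rnorm(30 * 12), 30, 12)
  colnames(X) <- sprintf("G%d", 1:12)
  y <- X %*% rnorm(12) + rnorm(30)
  ours <- fit_pls(X, y, n_components = 3)
  theirs <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                          scale = TRUE)
  pred_theirs <- predict(theirs, X)$predict[, 1, 3]
  expect_gt(cor(predict(ours, X, ncomp = 3), pred_theirs), 0.999)
})

test_that("VIP reduces to |w| for one component and matches the formula", {
  set.seed(7)
  X <- matrix(rnorm(40), 10, 4)
  colnames(X) <- sprintf("G%d", 1:4)
  y <- rnorm(10)
  f1 <- fit_pls(X, y, 1)
  v1 <- vip_scores(f1)
  # with one unit-norm weight vector the formula reduces to sqrt(p) * |w|
  expect_equal(as.numeric(v1), sqrt(4) * abs(f1$W[, 1]), tolerance = 1e-10)
  # two-component literal formula evaluation
  f2 <- fit_pls(X, y, 2)
  v2 <- vip_scores(f2)
  p <- 4
  oracle <- sqrt(p * (f2$W^2 %*% f2$SS) / sum(f2$SS))
  expect_equal(as.numeric(v2), as.numeric(oracle), tolerance = 1e-10)
})

test_that("cross-validated accuracy recovers planted expression signal", {
  fx <- tiny_expression(seed = 8, effect_beta = 1.5, noise_sd = 0.3)
  y <- expression_response(fx)
  X <- fx$ex$expression$values
  set.seed(9)
  cv <- cv_pls_accuracy(X, y, components = 2:5, folds = 5, repeats = 2)
  expect_gt(cv$overall, 0.5)
  # pure-noise response: accuracy near zero
  set.seed(10)
  null_r <- vapply(1:5, function(i) {
    cv_pls_accuracy(X, rnorm(length(y)), components = 2:3, folds = 5,
                    repeats = 1)$overall
  }, numeric(1))
  expect_lt(abs(mean(null_r)), 0.15)
  expect_error(cv_pls_accuracy(X[1:3, ], y[1:3], folds = 5), "folds")
})

test_that("fold assignments partition samples exactly once", {
  set.seed(11)
  ids <- crossmode:::.fold_ids(23, 5)
  expect_equal(length(ids), 23L)
  expect_setequal(unique(ids), 1:5)
  expect_true(all(table(ids) %in% c(4, 5)))
})

test_that("permutation significance is bounded and detects planted signal", {
  fx <- tiny_expression(seed = 12, effect_beta = 1.5, noise_sd = 0.3)
  y <- expression_response(fx)
  set.seed(13)
  sig <- pls_significance(fx$ex$expression$values, y, n_perm = 50,
                          components = 2:3, folds = 5, repeats = 1)
  expect_lte(sig$p_perm, 0.05)
  expect_gte(sig$p_perm, 1 / 51)
  expect_true(is.na(sig$p_surrogate))
})

test_that("bootstrap VIP ranking is deterministic about ties and ranks", {
  set.seed(14)
  X <- matrix(rnorm(30 * 6), 30, 6)
  X[, 2] <- X[, 5]  # identical columns
  colnames(X) <- sprintf("G%d", 1:6)
  y <- X[, 1] + rnorm(30, sd = 0.5)
  set.seed(15)
  rk <- bootstrap_vip_ranking(X, y, n_components = 2, n_boot = 50)
  expect_setequal(rk$rank, 1:6)
  r2 <- rk$rank[rk$gene == "G2"]
  r5 <- rk$rank[rk$gene == "G5"]
  expect_equal(abs(r2 - r5), 1L)   # adjacent
  expect_lt(r2, r5)                # tie broken by gene id
  expect_error(bootstrap_vip_ranking(X, y, n_boot = 1), ">= 2")
})

test_that("the full preparation chain matches samples and normalizes per donor", {
  fx <- tiny_expression(seed = 16)
  prep <- prepare_expression(fx$ex$probes, fx$coords)
  expect_equal(ncol(prep$X), 150L)
  expect_true(all(prep$voxel >= 1 & prep$voxel <= nrow(fx$coords)))
  expect_true(all(prep$X >= 0 & prep$X <= 1))
  expect_equal(nrow(prep$X) + prep$dropped, 100L)
})
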