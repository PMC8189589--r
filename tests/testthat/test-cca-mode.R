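# dense generalized-eigenproblem oracle for the first canonical correlation
cca_eigen_oracle <- function(P, C) {
  P <- scale(P, scale = FALSE)
  C <- scale(C, scale = FALSE)
  Spp <- crossprod(P)
  Scc <- crossprod(C)
  Spc <- crossprod(P, C)
  M <- solve(Spp) %*% Spc %*% solve(Scc) %*% t(Spc)
  sqrt(max(Re(eigen(M)$values)))
}

test_that("identical blocks give canonical correlation one", {
  set.seed(1)
  P <- matrix(rnorm(24), 8, 3)
  mode <- fit_cca(P, P)
  expect_equal(mode$canonical_r, 1, tolerance = 1e-10)
})

test_that("first canonical correlation matches the eigenproblem oracle", {
  set.seed(2)
  for (i in 1:5) {
    P <- matrix(rnorm(8 * 3), 8, 3)
    C <- matrix(rnorm(8 * 4), 8, 4)
    mode <- fit_cca(P, C)
    expect_equal(mode$canonical_r, cca_eigen_oracle(P, C), tolerance = 1e-10)
    # and against the base-R implementation as an independent route
    expect_equal(mode$canonical_r, stats::cancor(P, C)$cor[1],
                 tolerance = 1e-8)
  }
})

test_that("canonical correlation is invariant to invertible mixing", {
  set.seed(3)
  P <- matrix(rnorm(30), 10, 3)
  C <- matrix(rnorm(30), 10, 3)
  A <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0.2, 0, -0.7, 1), 3, 3)
  r1 <- fit_cca(P, C)$canonical_r
  r2 <- fit_cca(P, C %*% A)$canonical_r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("rank-deficient input is rejected with a clear message", {
  set.seed(4)
  P <- matrix(rnorm(24), 8, 3)
  C <- cbind(P[, 1], P[, 1], rnorm(8))
  expect_error(fit_cca(P, C), "rank-deficient")
  expect_error(fit_cca(P[1:3, ], P[1:3, ]), "more scans")
})

test_that("scoring training rows reproduces the stored variates", {
  sim <- tiny_cohort(seed = 5)
  m <- cohort_matrices(sim$cohort)
  mode <- fit_cca_mode(m$P, m$C, K = 4)
  sc <- score_scans(mode, m$P, m$C)
  expect_equal(sc$striatal, unname(mode$variates[, "striatal"]),
               tolerance = 1e-10)
  expect_equal(sc$cbf, unname(mode$variates[, "cbf"]), tolerance = 1e-10)
  # duplicated row scores identically
  dup <- score_scans(mode, m$P[c(1, 1), ], m$C[c(1, 1), ])
  expect_equal(dup$striatal[1], dup$striatal[2])
  expect_error(score_scans(mode, m$P[, 1:10], m$C), "does not match")
})

test_that("held-out scores track the planted latent variable", {
  sim <- tiny_cohort(seed = 6, rho = 0.8)
  m <- cohort_matrices(sim$cohort)
  test_idx <- 1:6
  train_idx <- setdiff(seq_len(nrow(m$P)), test_idx)
  mode <- fit_cca_mode(m$P[train_idx, ], m$C[train_idx, ], K = 4)
  sc <- score_scans(mode, m$P[test_idx, ], m$C[test_idx, ])
  z <- sim$truth$latent_scores[test_idx]
  expect_gt(max(abs(cor(sc$striatal, z)), abs(cor(sc$cbf, z))), 0.5)
})

test_that("block permutation respects exchangeability structure", {
  subj <- c("A", "A", "B", "B", "C", "C", "D", "E")  # 3 paired + 2 single
  scheme <- permutation_scheme(subj, "block")
  set.seed(7)
  draws <- replicate(600, paste(block_permutation(scheme), collapse = ","))
  expect_equal(length(unique(draws)), 12L)  # 3! * 2!
  # a paired subject's two scans always travel together, order preserved
  for (d in unique(draws)) {
    pm <- as.integer(strsplit(d, ",")[[1]])
    for (b in list(c(1, 2), c(3, 4), c(5, 6))) {
      expect_true(pm[b[1]] %in% c(1, 3, 5))
      expect_equal(pm[b[2]], pm[b[1]] + 1L)
    }
    expect_true(all(pm[7:8] %in% 7:8))
  }
})

test_that("free permutation reaches every ordering", {
  scheme <- permutation_scheme(c("A", "B", "C"), "free")
  set.seed(8)
  draws <- replicate(200, paste(block_permutation(scheme), collapse = ","))
  expect_equal(length(unique(draws)), 6L)
})

test_that("pair-preserving splits never separate a subject's scans", {
  sim <- tiny_cohort(seed = 9)
  scans <- sim$cohort$scans
  set.seed(10)
  for (i in 1:50) {
    sp <- crossmode:::.draw_split(scans, 0.8, pair_preserving = TRUE)
    subj_train <- scans$subject_id[sp$train]
    subj_test <- scans$subject_id[sp$test]
    expect_equal(length(intersect(subj_train, subj_test)), 0L)
  }
})

test_that("compiled and reference engines compute the identical statistic", {
  sim <- tiny_cohort(seed = 11, rho = 0.5)
  m <- cohort_matrices(sim$cohort)
  a <- cross_validated_mode_test(m$P, m$C, sim$cohort$scans, K_set = 2:4,
                                 n_splits = 8, n_perm = 10, seed = 12,
                                 engine = "cpp")
  b <- cross_validated_mode_test(m$P, m$C, sim$cohort$scans, K_set = 2:4,
                                 n_splits = 8, n_perm = 10, seed = 12,
                                 engine = "r")
  expect_equal(a$mean_oos_r, b$mean_oos_r, tolerance = 1e-12)
  expect_equal(a$null_distribution, b$null_distribution, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$mean_oos_r, mean(a$per_K_r))
})

test_that("in-sample canonical correlation bounds the out-of-sample mean", {
  sim <- tiny_cohort(seed = 13, rho = 0.6)
  m <- cohort_matrices(sim$cohort)
  mt <- cross_validated_mode_test(m$P, m$C, sim$cohort$scans, K_set = 4,
                                  n_splits = 15, n_perm = 5, seed = 14)
  in_sample <- fit_cca_mode(m$P, m$C, K = 4)$canonical_r
  expect_gte(in_sample, mt$mean_oos_r)
})

test_that("covariation influence matches a per-voxel correlation loop", {
  set.seed(15)
  x <- matrix(rnorm(50), 5, 10)
  v <- rnorm(5)
  infl <- covariation_influence(x, v)
  oracle <- vapply(1:10, function(j) cor(x[, j], v), numeric(1))
  expect_equal(infl, oracle, tolerance = 1e-12)
  expect_true(all(infl >= -1 & infl <= 1))
  # a voxel equal to the variate has influence 1; constant voxels get 0
  x2 <- cbind(v, rep(2, 5), x)
  infl2 <- covariation_influence(x2, v)
  expect_equal(infl2[1], 1)
  expect_equal(infl2[2], 0)
  # negating the variate flips the whole map
  expect_equal(covariation_influence(x, -v), -infl, tolerance = 1e-12)
  expect_error(covariation_influence(x[1:2, ], v[1:2]), "3 scans")
  expect_error(covariation_influence(x, v[1:3]), "one entry per scan")
})

test_that("matching counts tied scores as failures", {
  # scans 1 and 2 are exact duplicates: any round drawing them must tie in
  # both modalities and be scored as a failure
  set.seed(99)
  P <- matrix(rnorm(6 * 12), 6, 12)
  C <- matrix(rnorm(6 * 15), 6, 15)
  P[2, ] <- P[1, ]
  C[2, ] <- C[1, ]
  scans <- data.frame(subject_id = sprintf("S%d", 1:6),
                      condition = rep(c("placebo", "drug"), 3))
  n_rounds <- 40L
  res <- matching_accuracy_test(P, C, scans, K = 2, n_rounds = n_rounds,
                                seed = 16)
  # replay the round draws to count rounds holding out the duplicated pair
  set.seed(16)
  rounds <- lapply(seq_len(n_rounds), function(i) sample.int(6, 2))
  n_tied <- sum(vapply(rounds, function(r) setequal(r, c(1, 2)), logical(1)))
  expect_gt(n_tied, 0)
  expect_lte(res$accuracy, 1 - n_tied / n_rounds + 1e-12)
})
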