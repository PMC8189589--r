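test_that("smooth field with zero correlation length is standardized white noise", {
  coords <- make_lattice(50, 2)
  set.seed(42)
  f <- generate_smooth_field(coords, 0)
  set.seed(42)
  z <- rnorm(50)
  expect_equal(f, as.numeric(scale(z)), tolerance = 1e-12)
  expect_equal(mean(f), 0, tolerance = 1e-12)
  expect_equal(sd(f), 1, tolerance = 1e-12)
})

test_that("smoothing lowers the short-lag variogram relative to white noise", {
  coords <- make_lattice(1000, 2)
  set.seed(7)
  smooth <- generate_smooth_field(coords, 12)
  set.seed(7)
  white <- generate_smooth_field(coords, 0)
  vg_s <- empirical_variogram(smooth, coords)
  vg_w <- empirical_variogram(white, coords)
  expect_lt(vg_s$semivariance[1], vg_w$semivariance[1])
  expect_lt(vg_s$semivariance[2], vg_w$semivariance[2])
})

test_that("field generation is reproducible and rejects empty coords", {
  coords <- make_lattice(30, 2)
  set.seed(3)
  a <- generate_smooth_field(coords, 5)
  set.seed(3)
  b <- generate_smooth_field(coords, 5)
  expect_identical(a, b)
  expect_error(generate_smooth_field(coords[0, , drop = FALSE], 5),
               "at least one voxel")
  expect_error(generate_smooth_field(coords, -1), ">= 0")
})

test_that("default cohort reproduces the 51-scan, 28-subject design", {
  sim <- generate_paired_cohort(seed = 1)
  scans <- sim$cohort$scans
  expect_equal(nrow(scans), 51L)
  expect_equal(length(unique(scans$subject_id)), 28L)
  tab <- table(scans$subject_id)
  expect_equal(sum(tab == 2L), 23L)
  expect_equal(sum(tab == 1L), 5L)
  for (s in names(tab[tab == 2L])) {
    expect_setequal(scans$condition[scans$subject_id == s],
                    c("placebo", "drug"))
  }
  expect_true(all(sim$cohort$roi > 0))
  expect_true(all(sim$cohort$brain > 0))
  expect_equal(length(sim$truth$latent_scores), 51L)
  expect_equal(sum(sim$truth$striatal_loading^2), 1, tolerance = 1e-10)
  expect_equal(sum(sim$truth$brain_loading^2), 1, tolerance = 1e-10)
})

test_that("degenerate planted correlation is rejected", {
  expect_error(generate_paired_cohort(planted_rho = 1, seed = 1), "degenerate")
  expect_error(generate_paired_cohort(planted_rho = -0.1, seed = 1))
})

test_that("cohort generation is bit-reproducible given a seed", {
  a <- generate_paired_cohort(n_paired = 5, n_unpaired = 2, n_roi_vox = 30,
                              n_brain_vox = 40, seed = 9)
  b <- generate_paired_cohort(n_paired = 5, n_unpaired = 2, n_roi_vox = 30,
                              n_brain_vox = 40, seed = 9)
  expect_identical(a$cohort$roi, b$cohort$roi)
  expect_identical(a$cohort$brain, b$cohort$brain)
  expect_identical(a$truth$latent_scores, b$truth$latent_scores)
})

test_that("planted rho = 0 leaves modal projections uncorrelated on average", {
  rs <- vapply(1:50, function(s) {
    sim <- tiny_cohort(seed = s, rho = 0)
    p_proj <- log(sim$cohort$roi) %*% sim$truth$striatal_loading
    c_proj <- log(sim$cohort$brain) %*% sim$truth$brain_loading
    cor(p_proj, c_proj)
  }, numeric(1))
  n <- 25L
  expect_lt(abs(mean(rs)), 3 / sqrt(50 * n))
})

test_that("no drug shift means no systematic latent difference", {
  zm <- vapply(1:20, function(s) {
    sim <- tiny_cohort(seed = s, drug_shift = 0)
    z <- sim$truth$latent_scores
    drug <- sim$cohort$scans$condition == "drug"
    mean(z[drug]) - mean(z[!drug])
  }, numeric(1))
  expect_lt(abs(mean(zm)), 3 * sd(zm) / sqrt(20))
})

test_that("expression generator plants signal genes and a probe table", {
  fx <- tiny_expression(seed = 2, effect_beta = 3, noise_sd = 0.1)
  ex <- fx$ex
  expect_equal(nrow(ex$expression$values), 100L)
  expect_equal(length(ex$signal_genes), 15L)
  expect_true(all(ex$signal_genes %in% ex$expression$genes))
  y <- expression_response(fx)
  cors <- abs(cor(ex$expression$values, y))
  top_gene <- ex$expression$genes[which.max(cors)]
  expect_true(top_gene %in% ex$signal_genes)
  # probe table covers every gene at least once
  expect_setequal(unique(ex$probes$gene_id), ex$expression$genes)
  expect_equal(dim(ex$probes$background_exceeded), dim(ex$probes$expr))
})

test_that("null expression (beta = 0) shows no influence tracking", {
  fx <- tiny_expression(seed = 3, effect_beta = 0)
  y <- expression_response(fx)
  cors <- as.numeric(cor(fx$ex$expression$values, y))
  expect_lt(abs(mean(cors)), 0.03)
  expect_lt(max(abs(cors)), 0.45)
})

test_that("expression generator validates sample capacity", {
  coords <- make_lattice(10, 2)
  loading <- rnorm(10)
  expect_error(generate_expression(loading, coords, n_samples = 1000,
                                   n_donors = 2, seed = 1), "exceeds")
  expect_error(generate_expression(loading, coords, n_genes = 5,
                                   n_signal = 10, seed = 1), "n_signal")
})

test_that("gene-set generator controls overlap with signal genes", {
  all_genes <- sprintf("G%04d", 1:200)
  signal <- all_genes[1:40]
  full <- generate_gene_sets(signal, all_genes, overlap_frac = 1,
                             set_size = 30, seed = 1)
  expect_true(all(full$planted %in% signal))
  # zero overlap: planted set drawn from non-signal genes only
  none <- generate_gene_sets(signal, all_genes, overlap_frac = 0,
                             set_size = 30, seed = 1)
  expect_equal(length(intersect(none$planted, signal)), 0L)
  # random sets hit signal at the hypergeometric expectation on average
  ov <- vapply(1:40, function(s)
    length(intersect(generate_gene_sets(signal, all_genes, set_size = 30,
                                        seed = s)$random01, signal)),
    numeric(1))
  expected <- 30 * 40 / 200
  expect_lt(abs(mean(ov) - expected), 3 * sd(ov) / sqrt(40))
  a <- generate_gene_sets(signal, all_genes, set_size = 30, seed = 1)
  b <- generate_gene_sets(signal, all_genes, set_size = 30, seed = 2)
  expect_false(identical(a$random01, b$random01))
  expect_error(generate_gene_sets(signal, all_genes, set_size = 500, seed = 1),
               "exceeds")
})

test_that("parcellation covers all voxels with the requested networks", {
  coords <- make_lattice(200, 2)
  expect_equal(generate_parcellation(coords, n_networks = 1, seed = 1),
               rep(1L, 200))
  lab <- generate_parcellation(coords, n_networks = 5, seed = 1)
  expect_equal(length(lab), 200L)
  expect_setequal(unique(lab), 1:5)
})

test_that("subjective scale has 10 bounded items shifted by the drug", {
  sim <- tiny_cohort(seed = 4, drug_shift = 2)
  sc <- generate_subjective_scale(sim$truth, sim$cohort$scans, slope = 1,
                                  noise_sd = 0.5, seed = 5)
  expect_equal(ncol(sc), 10L)
  expect_true(all(sc >= 1 & sc <= 5))
  drug <- sim$cohort$scans$condition == "drug"
  expect_gt(mean(sc[drug, ]), mean(sc[!drug, ]))
  # slope 0: no condition effect beyond noise
  sc0 <- generate_subjective_scale(sim$truth, sim$cohort$scans, slope = 0,
                                   noise_sd = 0.5, seed = 5)
  expect_lt(abs(mean(sc0[drug, ]) - mean(sc0[!drug, ])), 0.2)
})
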