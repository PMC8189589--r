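#' Regular voxel lattice
#'
#' Builds a compact cubic lattice of voxel center coordinates, used as the
#' geometry for synthetic ROI (striatal) and whole-brain masks.
#'
#' @param n Number of voxels.
#' @param spacing Lattice spacing in mm.
#' @return An `n x 3` numeric matrix of coordinates in mm.
#' @export
make_lattice <- function(n, spacing = 2) {
  .assert_scalar(n, "n", positive = TRUE)
  side <- ceiling(n^(1 / 3))
  g <- seq_len(side) * spacing
  coords <- as.matrix(expand.grid(x = g, y = g, z = g))
  coords[seq_len(n), , drop = FALSE]
}

# row-stochastic smoothing operator: weights exp(-d/L) within the kernel
# support (distances beyond 4L contribute negligibly and are zeroed)
.smoothing_operator <- function(coords, correlation_length) {
  d <- as.matrix(stats::dist(coords))
  w <- exp(-d / correlation_length)
  w[d > 4 * correlation_length] <- 0
  w / rowSums(w)
}

#' Spatially autocorrelated Gaussian field
#'
#' Draws white noise at the voxel coordinates, smooths it with an isotropic
#' exponentially decaying kernel of the given correlation length, and
#' re-standardizes each field to zero mean and unit variance.  With
#' `correlation_length = 0` the field is standardized white noise.  Uses the
#' current RNG state; call [set.seed()] for reproducibility.
#'
#' @param coords `n x 3` matrix of voxel coordinates in mm.
#' @param correlation_length Kernel length scale in mm (`>= 0`).
#' @param n_fields Number of independent fields to draw.
#' @return A length-`n` vector (`n_fields = 1`) or an `n x n_fields` matrix.
#' @export
generate_smooth_field <- function(coords, correlation_length, n_fields = 1L) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("`coords` must contain at least one voxel")
  if (correlation_length < 0) stop("`correlation_length` must be >= 0")
  z <- matrix(rnorm(nrow(coords) * n_fields), nrow(coords), n_fields)
  if (correlation_length > 0) {
    z <- .smoothing_operator(coords, correlation_length) %*% z
  }
  z <- scale(z)
  attributes(z) <- list(dim = dim(z))
  if (n_fields == 1L) drop(z) else z
}

# smooth unit-norm loading vector over a mask
.planted_loading <- function(coords, correlation_length) {
  a <- generate_smooth_field(coords, correlation_length)
  a / sqrt(sum(a^2))
}

#' Generate a paired placebo/drug imaging cohort with a planted cross-modal mode
#'
#' Emulates a simultaneous PET-ASL study: each scan carries a latent score
#' `z` (standard normal, shifted by `drug_shift` for drug-condition scans).
#' Each modality expresses a side-specific score
#' `s = sqrt(rho) z + sqrt(1 - rho) eta` along a smooth unit-norm loading
#' map, plus spatially smooth noise orthogonalized against the loading so
#' that the population correlation of the two modal projections is exactly
#' `planted_rho`.  Log-space fields are exponentiated (`exp(c * field)`,
#' `c = 0.1`) so all map values are strictly positive, as binding potential
#' and blood flow are.
#'
#' Paired subjects contribute one placebo and one drug scan; unpaired
#' subjects are randomly assigned a single condition.
#'
#' @param n_paired Subjects scanned under both conditions (default 23).
#' @param n_unpaired Subjects with a single scan (default 5); defaults give
#'   the 51-scan, 28-subject design.
#' @param n_roi_vox,n_brain_vox Mask sizes for the ROI and brain maps.
#' @param planted_rho Target canonical correlation in `[0, 1)`.
#' @param drug_shift Latent-score shift added for drug scans.
#' @param noise_sd Amplitude of the smooth voxel noise (log scale).
#' @param noise_corr_length,loading_corr_length Kernel lengths (mm) for the
#'   noise fields and the planted loading maps.
#' @param spacing Lattice spacing in mm.
#' @param seed Integer seed; all outputs are bit-reproducible given it.
#' @return A list with elements `cohort` (class `cm_cohort`: scan manifest,
#'   `roi`/`brain` scan-by-voxel matrices, coordinates, parcellation,
#'   subjective-scale scores) and `truth` (class `cm_truth`: latent scores,
#'   loadings, planted parameters).
#' @export
generate_paired_cohort <- function(n_paired = 23L, n_unpaired = 5L,
                                   n_roi_vox = 150L, n_brain_vox = 400L,
                                   planted_rho = 0.8, drug_shift = 1,
                                   noise_sd = 0.2,
                                   noise_corr_length = 6,
                                   loading_corr_length = 8,
                                   spacing = 2, seed = 1L) {
  if (planted_rho < 0 || planted_rho >= 1)
    stop("`planted_rho` must lie in [0, 1); rho = 1 is degenerate")
  set.seed(seed)
  n_scans <- 2L * n_paired + n_unpaired

  subject_id <- c(rep(sprintf("S%02d", seq_len(n_paired)), each = 2L),
                  sprintf("S%02d", n_paired + seq_len(n_unpaired)))
  condition <- c(rep(c("placebo", "drug"), n_paired),
                 sample(c("placebo", "drug"), n_unpaired, replace = TRUE))
  scans <- data.frame(scan_id = sprintf("scan%03d", seq_len(n_scans)),
                      subject_id = subject_id, condition = condition,
                      stringsAsFactors = FALSE)

  roi_coords <- make_lattice(n_roi_vox, spacing)
  brain_coords <- make_lattice(n_brain_vox, spacing)

  a <- .planted_loading(roi_coords, loading_corr_length)
  b <- .planted_loading(brain_coords, loading_corr_length)

  z <- rnorm(n_scans) + ifelse(condition == "drug", drug_shift, 0)
  # side-specific noise is scaled to the population variance of z (which the
  # drug shift inflates) so that cor(s_roi, s_brain) is exactly planted_rho
  f_drug <- mean(condition == "drug")
  v_z <- 1 + drug_shift^2 * f_drug * (1 - f_drug)
  s_roi <- sqrt(planted_rho) * z +
    sqrt((1 - planted_rho) * v_z) * rnorm(n_scans)
  s_brain <- sqrt(planted_rho) * z +
    sqrt((1 - planted_rho) * v_z) * rnorm(n_scans)

  # smooth noise, orthogonalized against the loading so the modal projection
  # carries exactly the side score
  noise_block <- function(coords, loading) {
    e <- generate_smooth_field(coords, noise_corr_length, n_fields = n_scans)
    e <- e - outer(loading, as.numeric(crossprod(e, loading)))
    e
  }
  log_roi <- outer(a, s_roi) + noise_sd * noise_block(roi_coords, a)
  log_brain <- outer(b, s_brain) + noise_sd * noise_block(brain_coords, b)

  cscale <- 0.1  # keeps exp() near-linear while guaranteeing positivity
  roi <- t(exp(cscale * log_roi))
  brain <- t(exp(cscale * log_brain))
  rownames(roi) <- rownames(brain) <- scans$scan_id

  parcellation <- generate_parcellation(brain_coords, n_networks = 7L,
                                        seed = .child_seed(seed, "parcellation"))

  truth <- structure(list(latent_scores = z,
                          side_scores = cbind(roi = s_roi, brain = s_brain),
                          striatal_loading = a, brain_loading = b,
                          planted_rho = planted_rho, drug_shift = drug_shift,
                          noise_sd = noise_sd,
                          signal_genes = character(0),
                          enriched_sets = character(0)),
                     class = "cm_truth")

  cohort <- structure(list(scans = scans, roi = roi, brain = brain,
                           roi_coords = roi_coords, brain_coords = brain_coords,
                           spacing = spacing,
                           parcellation = parcellation,
                           expression = NULL, probes = NULL,
                           gene_sets = NULL, subjective = NULL),
                      class = "cm_cohort")
  cohort$subjective <- generate_subjective_scale(
    truth, scans, slope = 0.8, noise_sd = 1,
    seed = .child_seed(seed, "subjective"))

  list(cohort = cohort, truth = truth)
}

#' @export
print.cm_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d scans (%d subjects), %d ROI voxels, %d brain voxels\n",
              nrow(x$scans), length(unique(x$scans$subject_id)),
              ncol(x$roi), ncol(x$brain)))
  invisible(x)
}

#' Generate striatal expression samples tracking a planted influence map
#'
#' Places tissue samples at ROI voxel centers (a fraction jittered by up to
#' `jitter_mm`, exercising nearest-voxel matching), assigns them to donors,
#' and builds gene expression in which `n_signal` signal genes track the
#' planted loading at the sampled voxel (`effect_beta * loading + noise`)
#' while the remaining genes are pure noise.  Also emits a probe-level table
#' with one to three probes per gene, background-exceedance flags (a random
#' subset of probes is flagged low-quality), and donor labels, so the probe
#' filtering / representative-probe selection steps can be exercised.
#'
#' @param striatal_loading Unit-norm loading vector over ROI voxels.
#' @param roi_coords ROI voxel coordinates (mm).
#' @param n_samples Number of tissue samples (default 153).
#' @param n_genes,n_signal Total genes and planted signal genes.
#' @param effect_beta Signal-gene slope on the (scaled) loading.
#' @param noise_sd Expression noise SD.
#' @param n_donors Number of donors (default 6).
#' @param jitter_mm Maximum coordinate jitter in mm.
#' @param jitter_frac Fraction of samples jittered.
#' @param seed Integer seed.
#' @return A list: `expression` (class `cm_expression`: samples x genes
#'   values, coords, donor, source voxel), `probes` (class `cm_probes`),
#'   `signal_genes` (character).
#' @export
generate_expression <- function(striatal_loading, roi_coords,
                                n_samples = 153L, n_genes = 400L,
                                n_signal = 40L, effect_beta = 1,
                                noise_sd = 0.3, n_donors = 6L,
                                jitter_mm = 2, jitter_frac = 0.2,
                                seed = 1L) {
  if (n_signal > n_genes) stop("`n_signal` must be <= `n_genes`")
  n_vox <- nrow(roi_coords)
  if (n_samples > n_vox * n_donors)
    stop(sprintf("n_samples = %d exceeds the %d available donor-voxel slots",
                 n_samples, n_vox * n_donors))
  set.seed(seed)

  donor <- sprintf("D%d", rep_len(seq_len(n_donors), n_samples))
  # draw (donor, voxel) pairs without duplicates; voxels recur across donors
  voxel <- integer(n_samples)
  for (d in unique(donor)) {
    idx <- which(donor == d)
    voxel[idx] <- sample.int(n_vox, length(idx))
  }
  coords <- roi_coords[voxel, , drop = FALSE]
  jit <- runif(n_samples) < jitter_frac
  if (any(jit)) {
    dir <- matrix(rnorm(3 * sum(jit)), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    coords[jit, ] <- coords[jit, ] + dir * runif(sum(jit), 0, jitter_mm)
  }

  # scale the loading so the signal has unit variance across voxels
  infl <- striatal_loading / sd(striatal_loading)
  genes <- sprintf("G%04d", seq_len(n_genes))
  signal_genes <- genes[seq_len(n_signal)]
  vals <- matrix(rnorm(n_samples * n_genes, sd = noise_sd),
                 n_samples, n_genes, dimnames = list(NULL, genes))
  vals[, seq_len(n_signal)] <- vals[, seq_len(n_signal)] +
    effect_beta * infl[voxel]

  expression <- structure(list(values = vals, coords = coords, donor = donor,
                               source_voxel = voxel,
                               matched_voxel = rep(NA_integer_, n_samples),
                               genes = genes),
                          class = "cm_expression")

  # probe table: probe 1 faithful, extra probes noisier; ~10% of probes get
  # low background exceedance so intensity filtering has something to remove
  n_probes_per_gene <- sample(1:3, n_genes, replace = TRUE)
  probe_gene <- rep(genes, n_probes_per_gene)
  n_probes <- length(probe_gene)
  probe_id <- sprintf("P%05d", seq_len(n_probes))
  first_probe <- !duplicated(probe_gene)
  probe_sd <- ifelse(first_probe, 0.05, 0.6)
  expr <- t(vals[, probe_gene, drop = FALSE]) +
    matrix(rnorm(n_probes * n_samples, sd = probe_sd), n_probes, n_samples)
  low_quality <- !first_probe & runif(n_probes) < 0.15
  p_exceed <- ifelse(low_quality, 0.3, 0.95)
  background <- matrix(runif(n_probes * n_samples) <
                         rep(p_exceed, n_samples), n_probes, n_samples)
  probes <- structure(list(probe_id = probe_id, gene_id = probe_gene,
                           expr = expr, background_exceeded = background,
                           sample_donor = donor, sample_coords = coords),
                      class = "cm_probes")

  list(expression = expression, probes = probes, signal_genes = signal_genes)
}

#' Generate gene sets for enrichment fixtures
#'
#' Builds one "planted" set drawing `overlap_frac` of its members from the
#' signal genes (remainder random), plus `n_sets - 1` fully random sets.
#'
#' @param signal_genes Character vector of signal gene ids.
#' @param all_genes Universe of gene ids.
#' @param n_sets Total number of sets.
#' @param overlap_frac Fraction of the planted set drawn from `signal_genes`.
#' @param set_size Members per set.
#' @param seed Integer seed.
#' @return Named list of character vectors; the enriched set is named
#'   `"planted"`.
#' @export
generate_gene_sets <- function(signal_genes, all_genes, n_sets = 10L,
                               overlap_frac = 0.6, set_size = 40L, seed = 1L) {
  if (overlap_frac < 0 || overlap_frac > 1) stop("`overlap_frac` must be in [0, 1]")
  if (set_size > length(all_genes)) stop("`set_size` exceeds the gene universe")
  set.seed(seed)
  n_from_signal <- min(round(overlap_frac * set_size), length(signal_genes))
  planted <- c(sample(signal_genes, n_from_signal),
               sample(setdiff(all_genes, signal_genes), set_size - n_from_signal))
  sets <- c(list(planted = sample(planted)),
            lapply(seq_len(n_sets - 1L), function(i)
              sample(all_genes, set_size)))
  names(sets) <- c("planted", sprintf("random%02d", seq_len(n_sets - 1L)))
  sets
}

#' Generate a synthetic parcellation of contiguous networks
#'
#' Labels every voxel with one of `n_networks` spatially contiguous blobs
#' (k-means on coordinates), emulating canonical resting-state network
#' parcellations.
#'
#' @param brain_coords Voxel coordinates (mm).
#' @param n_networks Number of networks.
#' @param seed Integer seed.
#' @return Integer label vector over voxels (values `1..n_networks`).
#' @export
generate_parcellation <- function(brain_coords, n_networks = 7L, seed = 1L) {
  set.seed(seed)
  if (n_networks == 1L) return(rep(1L, nrow(brain_coords)))
  km <- kmeans(brain_coords, centers = n_networks, nstart = 3L)
  as.integer(km$cluster)
}

#' Generate subjective drug-effect scale scores
#'
#' Ten items per scan on a 1-5 scale; drug-condition scans are shifted by
#' `slope * drug_shift` before rounding and clamping.
#'
#' @param truth A `cm_truth` object (provides `drug_shift`).
#' @param scans Scan manifest data frame with a `condition` column.
#' @param slope Effect of the drug shift on the items.
#' @param noise_sd Item noise SD.
#' @param seed Integer seed.
#' @return An `n_scans x 10` integer matrix with values in 1..5.
#' @export
generate_subjective_scale <- function(truth, scans, slope = 0.8, noise_sd = 1,
                                      seed = 1L) {
  set.seed(seed)
  n <- nrow(scans)
  shift <- slope * truth$drug_shift * (scans$condition == "drug")
  items <- matrix(rnorm(n * 10L, mean = 3, sd = noise_sd), n, 10L) + shift
  items <- round(items)
  items[items < 1L] <- 1L
  items[items > 5L] <- 5L
  storage.mode(items) <- "integer"
  items
}

#' Attach synthetic expression and gene sets to a cohort
#'
#' Convenience wrapper running [generate_expression()] and
#' [generate_gene_sets()] against a cohort's planted truth and recording the
#' planted signal genes and enriched set names in the truth object.
#'
#' @param sim Output of [generate_paired_cohort()].
#' @param ... Passed to [generate_expression()].
#' @param n_sets,overlap_frac,set_size Passed to [generate_gene_sets()].
#' @param seed Integer seed.
#' @return The input list with `cohort$expression`, `cohort$probes`,
#'   `cohort$gene_sets` and updated `truth`.
#' @export
add_synthetic_expression <- function(sim, ..., n_sets = 10L,
                                     overlap_frac = 0.6, set_size = 40L,
                                     seed = 1L) {
  ex <- generate_expression(sim$truth$striatal_loading,
                            sim$cohort$roi_coords, ..., seed = seed)
  sim$cohort$expression <- ex$expression
  sim$cohort$probes <- ex$probes
  sim$cohort$gene_sets <- generate_gene_sets(
    ex$signal_genes, ex$expression$genes, n_sets = n_sets,
    overlap_frac = overlap_frac, set_size = set_size,
    seed = .child_seed(seed, "gene_sets"))
  sim$truth$signal_genes <- ex$signal_genes
  sim$truth$enriched_sets <- "planted"
  sim
}
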