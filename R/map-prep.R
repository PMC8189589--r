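#' CBF quantification parameters
#'
#' Constants of the pseudo-continuous ASL quantification model.  Defaults
#' are typical 3 T values: blood-tissue partition coefficient
#' `lambda_partition = 0.9`, blood T1 `t1_blood = 1.6` s, gray-matter tissue
#' T1 `t1_tissue = 1.2` s, labeling efficiency `epsilon_efficiency = 0.6`,
#' post-label delay `post_label_delay = 2.025` s, label duration
#' `label_duration = 1.45` s.  The saturation time and the
#' perfusion-weighted scaling factor / number of excitations are
#' sequence-dependent; defaults of 2 s, 1 and 1 are placeholders to be set
#' from the acquisition protocol.
#'
#' @param lambda_partition Partition coefficient (unitless, `<= 1`).
#' @param t1_blood,t1_tissue Longitudinal relaxation times in seconds.
#' @param epsilon_efficiency Labeling efficiency (unitless).
#' @param post_label_delay,label_duration,saturation_time Timings in seconds.
#' @param scale_factor_pw,nex_pw Scanner scaling factor and number of
#'   excitations of the perfusion-weighted image.
#' @return A list of class `cbf_params`.
#' @export
cbf_params <- function(lambda_partition = 0.9, t1_blood = 1.6,
                       t1_tissue = 1.2, epsilon_efficiency = 0.6,
                       post_label_delay = 2.025, label_duration = 1.45,
                       saturation_time = 2, scale_factor_pw = 1, nex_pw = 1) {
  p <- list(lambda_partition = lambda_partition, t1_blood = t1_blood,
            t1_tissue = t1_tissue, epsilon_efficiency = epsilon_efficiency,
            post_label_delay = post_label_delay,
            label_duration = label_duration,
            saturation_time = saturation_time,
            scale_factor_pw = scale_factor_pw, nex_pw = nex_pw)
  for (nm in names(p)) .assert_scalar(p[[nm]], nm, positive = TRUE)
  if (lambda_partition > 1) stop("`lambda_partition` must be <= 1")
  structure(p, class = "cbf_params")
}

#' Quantify cerebral blood flow from a perfusion-weighted image
#'
#' Converts a perfusion-weighted difference image `pw` and a proton-density
#' image `pd` into CBF in ml/100g/min:
#' \deqn{CBF = 6000\,\lambda\;
#'   \frac{\exp(PLD/T_{1b})}{2\,T_{1b}\,(1 - e^{-LT/T_{1b}})\,\varepsilon}\;
#'   \frac{1}{1 - e^{-ST/T_{1t}}}\;
#'   NEX_{PW}\,\frac{PW}{SF_{PW}\,PD}}
#' i.e. the perfusion-weighted ratio corrected multiplicatively for label
#' decay during the post-label delay, finite labeling duration and
#' efficiency, and partial saturation of the proton-density image.
#'
#' @param pw,pd Numeric vectors over the mask voxels (same length); `pd`
#'   must be strictly positive.
#' @param params A [cbf_params()] object.
#' @return Numeric vector of CBF values (ml/100g/min).
#' @export
quantify_cbf <- function(pw, pd, params = cbf_params()) {
  stopifnot(inherits(params, "cbf_params"))
  if (length(pw) != length(pd)) stop("`pw` and `pd` must have equal length")
  bad <- which(pd <= 0)
  if (length(bad))
    stop(sprintf("proton-density image is nonpositive at voxel %d", bad[1]))
  with(params, {
    decay <- exp(post_label_delay / t1_blood) /
      (2 * t1_blood * (1 - exp(-label_duration / t1_blood)) * epsilon_efficiency)
    saturation <- 1 / (1 - exp(-saturation_time / t1_tissue))
    6000 * lambda_partition * decay * saturation * nex_pw *
      pw / (scale_factor_pw * pd)
  })
}

#' Global-mean normalization of a masked map
#'
#' Divides every voxel by the within-mask mean, so the output has mean
#' exactly 1 (the standard correction for global drug effects and
#' between-subject perfusion differences).  `method = "subtract"` instead
#' removes the mean, giving mean 0.
#'
#' @param values Numeric vector of within-mask voxel values.
#' @param method `"divide"` (default) or `"subtract"`.
#' @return Normalized vector of the same length.
#' @export
make_relative_map <- function(values, method = c("divide", "subtract")) {
  method <- match.arg(method)
  m <- mean(values)
  if (method == "divide") {
    if (m == 0) stop("mask mean is zero; relative map undefined")
    values / m
  } else {
    values - m
  }
}

#' Masked map container
#'
#' Pairs one scan's within-mask voxel values with its mask and scan
#' metadata.
#'
#' @param values Numeric vector over mask voxels.
#' @param mask A mask object from [cm_mask()].
#' @param subject_id,condition Scan metadata.
#' @return An object of class `masked_map`.
#' @export
masked_map <- function(values, mask, subject_id = NA_character_,
                       condition = NA_character_) {
  stopifnot(inherits(mask, "cm_mask"))
  if (length(values) != nrow(mask$coords))
    stop("`values` length must equal the mask voxel count")
  if (any(!is.finite(values))) stop("`values` must be finite")
  structure(list(values = as.numeric(values), mask = mask,
                 subject_id = subject_id, condition = condition),
            class = "masked_map")
}

#' Voxel mask
#'
#' @param coords `n x 3` matrix of voxel center coordinates in mm.
#' @param spacing Voxel spacing in mm.
#' @param space_tag Free-text space label.
#' @return An object of class `cm_mask`.
#' @export
cm_mask <- function(coords, spacing = 2, space_tag = "synthetic") {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("mask coordinates must be finite")
  if (anyDuplicated(coords)) stop("mask voxels must be unique")
  structure(list(coords = coords, spacing = spacing, space_tag = space_tag),
            class = "cm_mask")
}

#' Stack masked maps into a scans-by-voxels matrix
#'
#' @param maps List of [masked_map()] objects sharing one mask.
#' @return A list with `matrix` (scans x voxels, rows in input order) and
#'   `manifest` (data frame of subject_id/condition per row).
#' @export
stack_cohort <- function(maps) {
  stopifnot(length(maps) > 0L)
  ref <- maps[[1]]$mask
  for (m in maps) {
    if (!isTRUE(all.equal(m$mask$coords, ref$coords)))
      stop("all maps must share a single mask")
  }
  mat <- do.call(rbind, lapply(maps, `[[`, "values"))
  manifest <- data.frame(subject_id = vapply(maps, `[[`, "", "subject_id"),
                         condition = vapply(maps, `[[`, "", "condition"),
                         stringsAsFactors = FALSE)
  list(matrix = mat, manifest = manifest, mask = ref)
}

#' Column standardization with train-only parameters
#'
#' Computes per-column mean and SD on `fit_rows` only and applies them to
#' all rows, so held-out rows are transformed with training parameters.
#' Columns constant on the fit rows keep SD treated as 1 (fit rows map to
#' 0).
#'
#' @param x Numeric matrix.
#' @param fit_rows Row indices used to estimate the parameters.
#' @return List with `matrix` (standardized), `mean`, `sd`.
#' @export
standardize_columns <- function(x, fit_rows = seq_len(nrow(x))) {
  if (length(fit_rows) < 2L) stop("need at least 2 fit rows")
  std <- .col_standardizer(x, fit_rows)
  list(matrix = .apply_standardizer(x, std), mean = std$mean, sd = std$sd)
}

#' Fit a PCA basis on (standardized) map data
#'
#' Standardizes columns internally (mean/SD of the supplied rows), then
#' takes the top-`K` right singular vectors of the standardized matrix.
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive, for reproducibility.
#'
#' @param x Raw data matrix (rows = scans used for fitting).
#' @param K Number of components, `K <= min(dim(x))`.
#' @return An object of class `pca_basis`: `loadings` (K x voxels,
#'   orthonormal rows), `mean`, `sd`, `K`, `explained_variance_fraction`.
#' @export
fit_pca <- function(x, K) {
  if (K > min(dim(x))) stop(sprintf("K = %d exceeds min(dim(x)) = %d",
                                    K, min(dim(x))))
  std <- .col_standardizer(x, seq_len(nrow(x)))
  xs <- .apply_standardizer(x, std)
  sv <- svd(xs, nu = 0, nv = K)
  load <- t(sv$v)
  flip <- apply(load, 1L, function(r) sign(r[which.max(abs(r))]))
  load <- load * flip
  structure(list(loadings = load, mean = std$mean, sd = std$sd, K = K,
                 explained_variance_fraction = (sv$d^2 / sum(sv$d^2))[seq_len(K)]),
            class = "pca_basis")
}

#' Project rows onto a fitted PCA basis
#'
#' Applies the basis's stored standardization, then the component loadings.
#'
#' @param basis A [fit_pca()] object.
#' @param x Raw rows (scans x voxels) in the basis's voxel space.
#' @return A rows-by-K score matrix.
#' @export
project_pca <- function(basis, x) {
  stopifnot(inherits(basis, "pca_basis"))
  if (ncol(x) != length(basis$mean))
    stop("column count does not match the PCA basis")
  .apply_standardizer(x, list(mean = basis$mean, sd = basis$sd)) %*%
    t(basis$loadings)
}

#' Relative scans-by-voxels matrices for a cohort
#'
#' Applies [make_relative_map()] row-wise to both modalities of a synthetic
#' cohort.
#'
#' @param cohort A `cm_cohort`.
#' @param method Passed to [make_relative_map()].
#' @return List with `P` (ROI) and `C` (brain) matrices.
#' @export
cohort_matrices <- function(cohort, method = "divide") {
  rel <- function(m) t(apply(m, 1L, make_relative_map, method = method))
  list(P = rel(cohort$roi), C = rel(cohort$brain))
}
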