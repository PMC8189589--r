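#' Intensity-based probe filtering
#'
#' Keeps probes whose expression exceeds background noise in at least
#' `min_frac` of samples (probes at exactly the threshold are kept).
#'
#' @param probes A `cm_probes` object (probe-by-sample expression plus
#'   logical background-exceedance flags).
#' @param min_frac Minimum fraction of samples exceeding background.
#' @return The filtered `cm_probes` object.
#' @export
filter_probes <- function(probes, min_frac = 0.5) {
  stopifnot(inherits(probes, "cm_probes"))
  frac <- rowMeans(probes$background_exceeded)
  keep <- frac >= min_frac
  if (!any(keep)) warning("no probes survive background filtering")
  probes$probe_id <- probes$probe_id[keep]
  probes$gene_id <- probes$gene_id[keep]
  probes$expr <- probes$expr[keep, , drop = FALSE]
  probes$background_exceeded <- probes$background_exceeded[keep, , drop = FALSE]
  probes
}

# differential stability of one probe: mean over donor pairs of the
# correlation of its expression profile across locations sampled by both
# donors (donor-pair profiles are matched by location key)
.probe_ds <- function(expr_row, donor, location) {
  donors <- unique(donor)
  if (length(donors) < 2L) stop("differential stability needs >= 2 donors")
  pairs <- utils::combn(donors, 2L, simplify = FALSE)
  cors <- vapply(pairs, function(pr) {
    i1 <- donor == pr[1L]; i2 <- donor == pr[2L]
    common <- intersect(location[i1], location[i2])
    if (length(common) < 3L) return(NA_real_)
    v1 <- expr_row[i1][match(common, location[i1])]
    v2 <- expr_row[i2][match(common, location[i2])]
    if (sd(v1) == 0 || sd(v2) == 0) return(NA_real_)
    cor(v1, v2)
  }, numeric(1))
  mean(cors, na.rm = TRUE)
}

#' Representative probe selection by differential stability
#'
#' For genes indexed by several probes, keeps the probe with the highest
#' differential stability: the mean over donor pairs of the correlation of
#' the probe's expression profile across locations sampled by both donors.
#' Ties are broken by probe id order; single-probe genes are kept trivially.
#'
#' @param probes A `cm_probes` object.
#' @param location Per-sample location key (e.g. nearest mask voxel id)
#'   used to match samples across donors; defaults to the nearest-voxel
#'   match stored by [match_samples_to_voxels()] workflows, and must be
#'   supplied otherwise.
#' @return A list: `expression` (samples x genes matrix of the selected
#'   probes), `selected` (data frame gene/probe/ds).
#' @export
select_probe_by_differential_stability <- function(probes, location) {
  stopifnot(inherits(probes, "cm_probes"))
  ds <- vapply(seq_along(probes$probe_id), function(i)
    .probe_ds(probes$expr[i, ], probes$sample_donor, location), numeric(1))
  ord <- order(probes$gene_id, -ds, probes$probe_id)
  first <- ord[!duplicated(probes$gene_id[ord])]
  first <- first[order(probes$gene_id[first])]
  sel <- data.frame(gene_id = probes$gene_id[first],
                    probe_id = probes$probe_id[first], ds = ds[first],
                    stringsAsFactors = FALSE)
  expr <- t(probes$expr[first, , drop = FALSE])
  colnames(expr) <- sel$gene_id
  list(expression = expr, selected = sel)
}

#' Match tissue samples to mask voxels
#'
#' Each sample is assigned the nearest mask voxel (Euclidean distance to
#' voxel centers); samples farther than `max_dist_mm` from every mask voxel
#' are dropped.
#'
#' @param sample_coords `n x 3` sample coordinates (mm).
#' @param mask_coords Mask voxel center coordinates (mm).
#' @param max_dist_mm Match radius (default 3 mm).
#' @return Data frame with `voxel` (index into the mask), `distance`, and
#'   `matched` (logical); dropped samples have `voxel = NA`.
#' @export
match_samples_to_voxels <- function(sample_coords, mask_coords,
                                    max_dist_mm = 3) {
  sample_coords <- as.matrix(sample_coords)
  mask_coords <- as.matrix(mask_coords)
  res <- t(apply(sample_coords, 1L, function(p) {
    d2 <- colSums((t(mask_coords) - p)^2)
    j <- which.min(d2)
    c(j, sqrt(d2[j]))
  }))
  matched <- res[, 2L] <= max_dist_mm
  data.frame(voxel = ifelse(matched, res[, 1L], NA_integer_),
             distance = res[, 2L], matched = matched)
}

#' Scaled robust sigmoid normalization
#'
#' `s(x) = 1 / (1 + exp(-(x - median) / (IQR / 1.35)))`, rescaled min-max
#' to `[0, 1]`.  The 1.35 constant makes the IQR-based scale consistent
#' with the SD under normality.  Zero-IQR input falls back to all 0.5.
#'
#' @param x Numeric vector.
#' @return Normalized vector in `[0, 1]`.
#' @export
scaled_robust_sigmoid <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  iqr <- stats::IQR(x)
  if (iqr == 0) return(rep(0.5, length(x)))
  s <- 1 / (1 + exp(-(x - median(x)) / (iqr / 1.35)))
  (s - min(s)) / (max(s) - min(s))
}

#' Donor-wise expression normalization
#'
#' Applies [scaled_robust_sigmoid()] within each donor, never mixing
#' donors.  The default axis normalizes each gene across that donor's
#' samples (making genes comparable across donors before aggregation); the
#' alternative normalizes each sample across genes.
#'
#' @param values Samples x genes matrix.
#' @param donor Per-sample donor labels.
#' @param axis `"gene"` (default, within-gene across samples) or
#'   `"sample"` (within-sample across genes).
#' @return Normalized matrix of the same shape.
#' @export
normalize_expression <- function(values, donor, axis = c("gene", "sample")) {
  axis <- match.arg(axis)
  out <- values
  for (d in unique(donor)) {
    idx <- which(donor == d)
    block <- values[idx, , drop = FALSE]
    if (axis == "gene") {
      if (length(idx) >= 2L)
        out[idx, ] <- apply(block, 2L, scaled_robust_sigmoid)
    } else {
      out[idx, ] <- t(apply(block, 1L, scaled_robust_sigmoid))
    }
  }
  out
}

#' Prepare an expression matrix for the influence-map PLS
#'
#' Runs the standard spatial-transcriptomics preparation chain on a
#' probe-level table: intensity-based probe filtering, representative-probe
#' selection by differential stability, sample-to-voxel matching (3 mm
#' radius), and donor-wise scaled-robust-sigmoid normalization.
#'
#' @param probes A `cm_probes` object.
#' @param mask_coords ROI voxel coordinates.
#' @param min_frac,max_dist_mm,axis Passed to the respective steps.
#' @return List: `X` (matched samples x genes normalized matrix), `voxel`
#'   (matched voxel per retained sample), `donor`, `dropped` (count),
#'   `selected` (probe selection table).
#' @export
prepare_expression <- function(probes, mask_coords, min_frac = 0.5,
                               max_dist_mm = 3, axis = "gene") {
  probes <- filter_probes(probes, min_frac)
  m <- match_samples_to_voxels(probes$sample_coords, mask_coords, max_dist_mm)
  loc_key <- match_samples_to_voxels(probes$sample_coords, mask_coords,
                                     max_dist_mm = Inf)$voxel
  sel <- select_probe_by_differential_stability(probes, loc_key)
  keep <- which(m$matched)
  X <- normalize_expression(sel$expression[keep, , drop = FALSE],
                            probes$sample_donor[keep], axis = axis)
  list(X = X, voxel = m$voxel[keep], donor = probes$sample_donor[keep],
       dropped = sum(!m$matched), selected = sel$selected)
}
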