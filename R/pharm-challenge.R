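# Spearman correlation with two-sided p; errors on degenerate input
.spearman <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined: an input is constant")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Within-subject drug-minus-placebo score deltas
#'
#' @param scores Data frame with per-scan `striatal` and `cbf` scores (from
#'   [score_scans()] or a mode's variates), rows aligned with `scans`.
#' @param scans Scan manifest (`subject_id`, `condition`).
#' @return Data frame (`subject_id`, `d_striatal`, `d_cbf`) with one row
#'   per subject scanned under both conditions.
#' @export
delta_scores <- function(scores, scans) {
  stopifnot(nrow(scores) == nrow(scans))
  paired <- names(which(table(scans$subject_id) == 2L))
  rows <- lapply(paired, function(s) {
    i_drug <- which(scans$subject_id == s & scans$condition == "drug")
    i_plac <- which(scans$subject_id == s & scans$condition == "placebo")
    if (length(i_drug) != 1L || length(i_plac) != 1L) return(NULL)
    data.frame(subject_id = s,
               d_striatal = scores$striatal[i_drug] - scores$striatal[i_plac],
               d_cbf = scores$cbf[i_drug] - scores$cbf[i_plac])
  })
  do.call(rbind, rows)
}

#' Correlation of drug-induced changes in the two canonical scores
#'
#' Spearman rank correlation (average ranks for ties, two-sided p) between
#' the within-subject drug-minus-placebo change in the striatal canonical
#' score and the change in the CBF canonical score.
#'
#' @inheritParams delta_scores
#' @return List: `rho`, `p`, `deltas` (the per-subject records).
#' @export
delta_score_correlation <- function(scores, scans) {
  d <- delta_scores(scores, scans)
  if (is.null(d) || nrow(d) < 3L) stop("need at least 3 paired subjects")
  s <- .spearman(d$d_striatal, d$d_cbf)
  list(rho = s$rho, p = s$p, deltas = d)
}

#' Scores from a mode fit on placebo scans only
#'
#' Fits standardization, PCA and CCA exclusively on placebo-condition rows
#' and scores every scan with those frozen parameters, avoiding circularity
#' when relating scores to the drug challenge.
#'
#' @param P,C Raw scans-by-voxels matrices.
#' @param scans Scan manifest.
#' @param K PCA dimensionality.
#' @return List: `scores` (all scans), `mode` (the placebo-trained mode),
#'   `placebo_rows`.
#' @export
placebo_trained_scores <- function(P, C, scans, K = 8L) {
  idx <- which(scans$condition == "placebo")
  if (length(idx) < K + 1L)
    stop(sprintf("need at least %d placebo scans for K = %d", K + 1L, K))
  mode <- fit_cca_mode(P[idx, , drop = FALSE], C[idx, , drop = FALSE], K)
  list(scores = score_scans(mode, P, C), mode = mode, placebo_rows = idx)
}

#' Correlation of mean canonical scores with subjective drug effects
#'
#' Spearman correlation between each scan's mean canonical score (mean of
#' the striatal and CBF scores) and its subjective-effects scale total,
#' over all scans or drug-condition scans only.
#'
#' @param scores Per-scan score data frame (`striatal`, `cbf`).
#' @param scale_totals Per-scan subjective scale totals (e.g.
#'   `rowSums(cohort$subjective)`).
#' @param scans Scan manifest.
#' @param subset `"all"` or `"drug_only"`.
#' @return List: `rho`, `p`, `n`.
#' @export
subjective_effect_correlation <- function(scores, scale_totals, scans,
                                          subset = c("all", "drug_only")) {
  subset <- match.arg(subset)
  stopifnot(length(scale_totals) == nrow(scores))
  idx <- if (subset == "drug_only") which(scans$condition == "drug")
         else seq_len(nrow(scores))
  if (!length(idx)) stop("selected subset contains no scans")
  mean_score <- rowMeans(cbind(scores$striatal, scores$cbf))[idx]
  s <- .spearman(mean_score, scale_totals[idx])
  list(rho = s$rho, p = s$p, n = length(idx))
}
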