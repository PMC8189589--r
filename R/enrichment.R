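#' Subset a ranked gene list to expressed genes
#'
#' Filters a VIP ranking to genes in `expressed_genes` and recomputes ranks
#' `1..n` preserving the original order (used to restrict enrichment to
#' brain-expressed genes).
#'
#' @param ranking A `gene_ranking` data frame (see
#'   [bootstrap_vip_ranking()]).
#' @param expressed_genes Character vector of gene ids to keep.
#' @return The filtered ranking with recomputed `rank`.
#' @export
subset_to_expressed <- function(ranking, expressed_genes) {
  if (!length(expressed_genes)) stop("`expressed_genes` is empty")
  keep <- ranking$gene %in% expressed_genes
  if (!any(keep)) stop("no ranked genes are in the expressed set")
  out <- ranking[keep, , drop = FALSE]
  out <- out[order(out$rank), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Median-rank gene-set enrichment test
#'
#' The statistic is the absolute distance of the gene set's median rank
#' from the center of the ranked list, `|median(rank) - (n + 1)/2|` (the
#' midpoint convention is used for even counts).  The null compares this to
#' the same statistic for `n_random` random same-size gene draws from the
#' ranked list (without replacement); `p` is the add-one fraction of null
#' distances at least as large.  Set members absent from the list are
#' ignored.
#'
#' @param ranking A `gene_ranking` data frame.
#' @param gene_set Character vector of member gene ids.
#' @param set_name Label used in errors and output.
#' @param n_random Number of random sets.
#' @return List of class `enrichment_result`: `set_name`, `n_in_list`,
#'   `observed_median_rank`, `center_distance`, `null_distances`, `p`.
#' @export
median_rank_test <- function(ranking, gene_set, set_name = "set",
                             n_random = 10000L) {
  ranks <- ranking$rank[ranking$gene %in% unique(gene_set)]
  if (!length(ranks))
    stop(sprintf("gene set '%s' has no members in the ranked list", set_name))
  n <- nrow(ranking)
  center <- (n + 1) / 2
  observed <- median(ranks)
  dist_obs <- abs(observed - center)
  k <- length(ranks)
  null <- vapply(seq_len(n_random), function(i)
    abs(median(sample.int(n, k)) - center), numeric(1))
  structure(list(set_name = set_name, n_in_list = k,
                 observed_median_rank = observed,
                 center_distance = dist_obs, null_distances = null,
                 p = .perm_p(null, dist_obs)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: %d genes in list, median rank %.1f (distance %.1f from center), p = %.4g\n",
              x$set_name, x$n_in_list, x$observed_median_rank,
              x$center_distance, x$p))
  invisible(x)
}

#' Median-rank enrichment over a collection of gene sets
#'
#' @param ranking A `gene_ranking` data frame.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param n_random Random sets per test.
#' @return Data frame with one row per set (`set`, `n_in_list`,
#'   `median_rank`, `center_distance`, `p`).
#' @export
enrichment_table <- function(ranking, gene_sets, n_random = 10000L) {
  rows <- lapply(names(gene_sets), function(nm) {
    r <- median_rank_test(ranking, gene_sets[[nm]], nm, n_random)
    data.frame(set = nm, n_in_list = r$n_in_list,
               median_rank = r$observed_median_rank,
               center_distance = r$center_distance, p = r$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
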