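# first canonical pair of two centered score matrices, via Cholesky
# whitening and SVD; returns unit-norm weights and the canonical correlation
.cca_first <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  Sa <- crossprod(A)
  Sb <- crossprod(B)
  Sab <- crossprod(A, B)
  Ra <- tryCatch(chol(Sa), error = function(e) NULL)
  Rb <- tryCatch(chol(Sb), error = function(e) NULL)
  if (is.null(Ra) || is.null(Rb))
    stop("rank-deficient input: a modality's score matrix has collinear columns")
  tmp <- backsolve(Ra, Sab, transpose = TRUE)          # Ra^{-T} Sab
  M <- t(backsolve(Rb, t(tmp), transpose = TRUE))      # ... Rb^{-1}
  sv <- svd(M, nu = 1L, nv = 1L)
  u <- backsolve(Ra, sv$u[, 1L])
  v <- backsolve(Rb, sv$v[, 1L])
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  r <- .safe_cor(as.numeric(A %*% u), as.numeric(B %*% v))
  if (r < 0) {
    v <- -v
    r <- -r
  }
  list(u = u, v = v, r = sv$d[1L], weights_r = r)
}

#' Fit the first canonical mode between two score matrices
#'
#' Finds unit-norm weight vectors `U`, `V` maximizing the Pearson
#' correlation between the canonical variates `PU` and `CV`.  The sign of
#' `V` is fixed so the canonical correlation is nonnegative.
#'
#' @param P,C Numeric `N x K` matrices (e.g. PCA scores of the two
#'   modalities), `N > K`.
#' @return An object of class `cca_mode`: `U`, `V`, `variates` (N x 2),
#'   `canonical_r`, `K`.
#' @export
fit_cca <- function(P, C) {
  P <- as.matrix(P); C <- as.matrix(C)
  if (nrow(P) != nrow(C)) stop("`P` and `C` must have the same number of rows")
  if (nrow(P) <= max(ncol(P), ncol(C)))
    stop("need more scans than score columns to fit CCA")
  f <- .cca_first(P, C)
  structure(list(U = f$u, V = f$v,
                 variates = cbind(striatal = as.numeric(P %*% f$u),
                                  cbf = as.numeric(C %*% f$v)),
                 canonical_r = f$weights_r, K = ncol(P), bases = NULL),
            class = "cca_mode")
}

#' @export
print.cca_mode <- function(x, ...) {
  cat(sprintf("canonical mode: K = %d, first canonical r = %.3f\n",
              x$K, x$canonical_r))
  invisible(x)
}

#' Standardize + PCA + CCA on raw voxel matrices
#'
#' The full in-sample modelling stack: per-modality column standardization
#' and `K`-component PCA (both fit on the supplied rows), then the first
#' canonical pair on the PCA scores.  The returned mode stores both PCA
#' bases so new scans can be scored with frozen parameters.
#'
#' @param P_raw,C_raw Raw scans-by-voxels matrices (relative maps).
#' @param K PCA dimensionality used for both modalities.
#' @return A `cca_mode` with `bases = list(P = ..., C = ...)`.
#' @export
fit_cca_mode <- function(P_raw, C_raw, K = 8L) {
  bp <- fit_pca(P_raw, K)
  bc <- fit_pca(C_raw, K)
  mode <- fit_cca(project_pca(bp, P_raw), project_pca(bc, C_raw))
  mode$bases <- list(P = bp, C = bc)
  mode
}

#' Score scans with a fitted mode
#'
#' Applies the mode's stored standardization and PCA bases to new raw rows
#' and projects onto the canonical weights.
#'
#' @param mode A `cca_mode` with stored bases (from [fit_cca_mode()]).
#' @param P_rows,C_rows Raw voxel rows in the training voxel spaces.
#' @return Data frame with per-scan `striatal` and `cbf` scores.
#' @export
score_scans <- function(mode, P_rows, C_rows) {
  if (is.null(mode$bases)) stop("mode has no stored PCA bases; use fit_cca_mode()")
  sp <- project_pca(mode$bases$P, P_rows) %*% mode$U
  sc <- project_pca(mode$bases$C, C_rows) %*% mode$V
  data.frame(striatal = as.numeric(sp), cbf = as.numeric(sc))
}

#' Exchangeability-block permutation scheme
#'
#' Groups scans by subject: paired subjects (two scans) form size-2 blocks
#' that may only exchange with each other, preserving within-block scan
#' order; single-scan subjects exchange among themselves.  `kind = "free"`
#' permutes scans unrestricted.
#'
#' @param subject_id Character vector, one entry per scan.
#' @param kind `"block"` or `"free"`.
#' @return An object of class `perm_scheme`.
#' @export
permutation_scheme <- function(subject_id, kind = c("block", "free")) {
  kind <- match.arg(kind)
  blocks <- split(seq_along(subject_id), subject_id)
  sizes <- lengths(blocks)
  if (kind == "block" && any(!sizes %in% c(1L, 2L)))
    stop("block scheme supports subjects with 1 or 2 scans only")
  if (kind == "block") {
    for (s in unique(sizes)) {
      if (sum(sizes == s) < 1L) stop("unexchangeable block size")
    }
  }
  structure(list(kind = kind, blocks = unname(blocks), n = length(subject_id)),
            class = "perm_scheme")
}

#' Draw one scan-index permutation under a scheme
#'
#' For the block scheme, blocks of equal size are exchanged as units with
#' within-block order preserved (a paired subject's placebo scan maps to
#' another paired subject's placebo slot).  Uses the current RNG state.
#'
#' @param scheme A [permutation_scheme()].
#' @return Integer permutation `perm` such that `C[perm, ]` realigns the
#'   second modality under the null.
#' @export
block_permutation <- function(scheme) {
  stopifnot(inherits(scheme, "perm_scheme"))
  if (scheme$kind == "free") return(sample.int(scheme$n))
  perm <- integer(scheme$n)
  sizes <- lengths(scheme$blocks)
  for (s in unique(sizes)) {
    grp <- which(sizes == s)
    shuffled <- grp[sample.int(length(grp))]
    for (i in seq_along(grp)) {
      perm[scheme$blocks[[grp[i]]]] <- scheme$blocks[[shuffled[i]]]
    }
  }
  perm
}

# train/test split over scans; if pair_preserving, subjects (with all their
# scans) are assigned to one side so paired scans never straddle the split
.draw_split <- function(scans, train_frac, pair_preserving) {
  n <- nrow(scans)
  n_train <- round(train_frac * n)
  if (!pair_preserving) {
    train <- sort(sample.int(n, n_train))
  } else {
    subj <- unique(scans$subject_id)
    subj <- subj[sample.int(length(subj))]
    train <- integer(0)
    for (s in subj) {
      idx <- which(scans$subject_id == s)
      if (length(train) + length(idx) <= n_train || length(train) == 0L)
        train <- c(train, idx)
      if (length(train) >= n_train) break
    }
    train <- sort(train)
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

# PCA machinery for one modality and one split, via the Gram matrix of the
# standardized training rows (cheap when n_train << n_voxels); returns train
# and test score matrices with Kmax columns
.split_pc_scores <- function(X, train, test, Kmax) {
  std <- .col_standardizer(X, train)
  Xtr <- .apply_standardizer(X[train, , drop = FALSE], std)
  Xte <- .apply_standardizer(X[test, , drop = FALSE], std)
  e <- eigen(tcrossprod(Xtr), symmetric = TRUE)
  keep <- seq_len(Kmax)
  d <- sqrt(pmax(e$values[keep], .Machine$double.eps))
  U <- e$vectors[, keep, drop = FALSE]
  list(train = U * rep(d, each = nrow(U)),
       test = (Xte %*% crossprod(Xtr, U)) / rep(d, each = length(test)))
}

# out-of-sample first-canonical correlation for each K in K_set, given
# precomputed per-split scores of both modalities
.split_oos_r <- function(ps, cs, K_set) {
  vapply(K_set, function(K) {
    f <- .cca_first(ps$train[, seq_len(K), drop = FALSE],
                    cs$train[, seq_len(K), drop = FALSE])
    r <- .safe_cor(as.numeric(ps$test[, seq_len(K), drop = FALSE] %*% f$u),
                   as.numeric(cs$test[, seq_len(K), drop = FALSE] %*% f$v))
    # orientation: align test-set sign with the training-set correlation
    r
  }, numeric(1))
}

#' Cross-validated mode-of-covariation test with permutation inference
#'
#' For each PCA dimensionality `K` in `K_set`, the scans are split
#' `n_splits` times into training (`train_frac`) and test sets;
#' standardization, PCA and CCA are fit on the training rows only and the
#' correlation of the first canonical variate pair is evaluated on the test
#' rows.  The test statistic is the mean over splits and then over `K`.  A
#' null distribution is built by rerunning the identical procedure (same
#' splits) after permuting the second modality's scan assignment under the
#' given scheme; `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param P,C Raw scans-by-voxels matrices (relative maps) of the two
#'   modalities.
#' @param scans Scan manifest (`subject_id`, `condition`), rows aligned.
#' @param K_set PCA dimensionalities to average over (default `2:10`).
#' @param n_splits Train/test splits per `K` (default 100).
#' @param train_frac Training fraction (default 0.8).
#' @param n_perm Number of permutations (default 100).
#' @param scheme_kind `"block"` (dependency-preserving) or `"free"`.
#' @param pair_preserving_split Keep both scans of a paired subject on the
#'   same side of every split.
#' @param seed Integer seed.
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (reference
#'   implementation); both compute the identical statistic.
#' @return An object of class `mode_test`: `mean_oos_r`, `per_K_r`,
#'   `null_distribution`, `p_value`, `n_splits`, `n_perms`.
#' @export
cross_validated_mode_test <- function(P, C, scans, K_set = 2:10,
                                      n_splits = 100L, train_frac = 0.8,
                                      n_perm = 100L,
                                      scheme_kind = c("block", "free"),
                                      pair_preserving_split = FALSE,
                                      seed = 1L, engine = c("cpp", "r")) {
  scheme_kind <- match.arg(scheme_kind)
  engine <- match.arg(engine)
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  n <- nrow(P)
  Kmax <- max(K_set)
  if (round(train_frac * n) <= Kmax + 1L)
    stop("not enough scans for the requested split and K range")
  set.seed(seed)

  splits <- lapply(seq_len(n_splits), function(i)
    .draw_split(scans, train_frac, pair_preserving_split))
  scheme <- permutation_scheme(scans$subject_id, scheme_kind)
  perms <- lapply(seq_len(n_perm), function(i) block_permutation(scheme))

  if (engine == "cpp") {
    train_list <- lapply(splits, `[[`, "train")
    test_list <- lapply(splits, `[[`, "test")
    stat_for <- function(Cmat) {
      colMeans(.mode_oos_matrix_cpp(P, Cmat, train_list, test_list,
                                    as.integer(K_set)))
    }
  } else {
    # P-side scores depend on the split only; cache them
    p_scores <- lapply(splits, function(sp)
      .split_pc_scores(P, sp$train, sp$test, Kmax))
    stat_for <- function(Cmat) {
      rs <- matrix(NA_real_, n_splits, length(K_set))
      for (i in seq_len(n_splits)) {
        cs <- .split_pc_scores(Cmat, splits[[i]]$train, splits[[i]]$test, Kmax)
        rs[i, ] <- .split_oos_r(p_scores[[i]], cs, K_set)
      }
      colMeans(rs)
    }
  }

  per_K <- stat_for(C)
  observed <- mean(per_K)
  null <- vapply(perms, function(pm) mean(stat_for(C[pm, , drop = FALSE])),
                 numeric(1))
  structure(list(mean_oos_r = observed,
                 per_K_r = stats::setNames(per_K, paste0("K", K_set)),
                 null_distribution = null,
                 p_value = .perm_p(null, observed),
                 n_splits = n_splits, n_perms = n_perm,
                 scheme = scheme_kind,
                 pair_preserving_split = pair_preserving_split),
            class = "mode_test")
}

#' @export
print.mode_test <- function(x, ...) {
  cat(sprintf(
    "cross-validated mode test: mean out-of-sample r = %.3f, p = %.4g (%d splits, %d %s permutations)\n",
    x$mean_oos_r, x$p_value, x$n_splits, x$n_perms, x$scheme))
  invisible(x)
}

#' Leave-two-out matching accuracy test
#'
#' Per round, two scans are left out, the mode is fit on the rest, and the
#' two held-out scans are scored in both modalities.  The round is a success
#' iff the rank order of the two striatal scores equals that of the two CBF
#' scores; ties count as failure.  With no cross-modal information the
#' chance level is 50%.  Optionally a permutation null (scan assignment of
#' the second modality permuted under `scheme_kind`, same rounds) yields a
#' p-value.
#'
#' @param P,C Raw scans-by-voxels matrices.
#' @param scans Scan manifest.
#' @param K PCA dimensionality of the fitted mode (default 8).
#' @param n_rounds Leave-two-out rounds (default 100).
#' @param n_perm Permutations for the null (0 = no null).
#' @param scheme_kind Permutation scheme for the null.
#' @param seed Integer seed.
#' @return List: `accuracy`, `null_accuracy` (vector), `null_mean`,
#'   `null_sd`, `p_value` (NA if `n_perm = 0`), `n_rounds`.
#' @export
matching_accuracy_test <- function(P, C, scans, K = 8L, n_rounds = 100L,
                                   n_perm = 0L,
                                   scheme_kind = c("block", "free"),
                                   seed = 1L) {
  scheme_kind <- match.arg(scheme_kind)
  n <- nrow(P)
  if (n < 4L) stop("need at least 4 scans")
  set.seed(seed)
  rounds <- lapply(seq_len(n_rounds), function(i) sample.int(n, 2L))

  run_acc <- function(Cmat) {
    ok <- logical(n_rounds)
    for (i in seq_len(n_rounds)) {
      out <- rounds[[i]]
      keep <- setdiff(seq_len(n), out)
      mode <- fit_cca_mode(P[keep, , drop = FALSE], Cmat[keep, , drop = FALSE], K)
      sc <- score_scans(mode, P[out, , drop = FALSE], Cmat[out, , drop = FALSE])
      d1 <- sc$striatal[1L] - sc$striatal[2L]
      d2 <- sc$cbf[1L] - sc$cbf[2L]
      ok[i] <- d1 != 0 && d2 != 0 && sign(d1) == sign(d2)
    }
    mean(ok)
  }

  accuracy <- run_acc(C)
  null_acc <- numeric(0)
  p <- NA_real_
  if (n_perm > 0L) {
    scheme <- permutation_scheme(scans$subject_id, scheme_kind)
    null_acc <- vapply(seq_len(n_perm), function(i)
      run_acc(C[block_permutation(scheme), , drop = FALSE]), numeric(1))
    p <- .perm_p(null_acc, accuracy)
  }
  list(accuracy = accuracy, null_accuracy = null_acc,
       null_mean = if (length(null_acc)) mean(null_acc) else NA_real_,
       null_sd = if (length(null_acc)) sd(null_acc) else NA_real_,
       p_value = p, n_rounds = n_rounds)
}

#' Covariation influence map
#'
#' Correlates each voxel's data with a canonical variate across scans.  The
#' resulting per-voxel Pearson correlation quantifies how strongly each
#' voxel participates in the mode of covariation.  Constant voxels get
#' influence 0.
#'
#' @param data_matrix Scans-by-voxels matrix.
#' @param variate Canonical variate, one entry per scan.
#' @return Numeric vector of per-voxel correlations in `[-1, 1]`.
#' @export
covariation_influence <- function(data_matrix, variate) {
  if (nrow(data_matrix) != length(variate))
    stop("`variate` must have one entry per scan row")
  if (nrow(data_matrix) < 3L) stop("need at least 3 scans")
  if (sd(variate) == 0) stop("variate is constant")
  r <- suppressWarnings(as.numeric(cor(data_matrix, variate)))
  r[is.na(r)] <- 0
  r
}
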