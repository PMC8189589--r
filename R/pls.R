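#' Partial least squares regression (NIPALS) for a univariate response
#'
#' Iteratively extracts components maximizing covariance between the
#' predictor block and the response, deflating the predictors after each
#' component.  Predictor columns are z-scored (training parameters stored);
#' the response is centered.  For a univariate response the NIPALS inner
#' loop converges in one pass.
#'
#' @param X Samples x genes predictor matrix.
#' @param y Response vector (covariation influence at matched voxels).
#' @param n_components Number of latent components,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @param scale Z-score the predictor columns (default TRUE).
#' @return An object of class `pls_model`: unit-norm weight matrix `W`
#'   (genes x K), loadings `P`, regression scalars `c`, scores `Tmat`,
#'   y-variance explained per component `SS`, per-component cumulative
#'   coefficient matrix `B` (genes x K), and standardization parameters.
#' @export
fit_pls <- function(X, y, n_components, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`y` must have one entry per sample")
  if (n_components > min(n - 1L, p))
    stop("`n_components` exceeds min(samples - 1, genes)")
  mu <- colMeans(X)
  s <- if (scale) {
    s0 <- apply(X, 2L, sd)
    s0[s0 == 0] <- 1
    s0
  } else rep(1, p)
  Xc <- .apply_standardizer(X, list(mean = mu, sd = s))
  y_mean <- mean(y)
  yc <- y - y_mean

  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  cvec <- SS <- numeric(n_components)
  Xd <- Xc; yd <- yc
  for (k in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps)
      stop(sprintf("NIPALS failed at component %d: zero covariance", k))
    w <- w / nw
    t_k <- as.numeric(Xd %*% w)
    tt <- sum(t_k^2)
    p_k <- crossprod(Xd, t_k) / tt
    c_k <- sum(yd * t_k) / tt
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- t_k; cvec[k] <- c_k
    SS[k] <- c_k^2 * tt
    Xd <- Xd - tcrossprod(t_k, p_k)
    yd <- yd - c_k * t_k
  }
  # cumulative regression coefficients for every component count
  B <- matrix(0, p, n_components)
  for (k in seq_len(n_components)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    R <- Wk %*% solve(crossprod(Pk, Wk))
    B[, k] <- R %*% cvec[seq_len(k)]
  }
  structure(list(W = W, P = P, c = cvec, Tmat = Tm, SS = SS, B = B,
                 n_components = n_components,
                 x_mean = mu, x_sd = s, y_mean = y_mean,
                 genes = colnames(X)),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param object A [fit_pls()] model.
#' @param newdata Samples x genes matrix.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$n_components, ...) {
  Xs <- .apply_standardizer(as.matrix(newdata),
                            list(mean = object$x_mean, sd = object$x_sd))
  as.numeric(Xs %*% object$B[, ncomp]) + object$y_mean
}

#' Variable importance in the projection
#'
#' `VIP_j = sqrt(p * sum_k SS_k w_jk^2 / sum_k SS_k)` with unit-norm weight
#' vectors and `SS_k` the response variance explained by component `k`.
#' The squared VIPs average to 1 over genes by construction.
#'
#' @param model A [fit_pls()] model.
#' @return Named numeric vector of per-gene VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (all(model$SS == 0)) stop("model explains no response variance")
  p <- nrow(model$W)
  w2 <- model$W^2  # columns already unit norm
  vip <- sqrt(p * as.numeric(w2 %*% model$SS) / sum(model$SS))
  names(vip) <- model$genes
  vip
}

# fold assignment: a permutation of 1..folds labels covering all samples
.fold_ids <- function(n, folds) {
  sample(rep_len(seq_len(folds), n))
}

#' Cross-validated PLS prediction accuracy
#'
#' For each component count, out-of-fold predictions are assembled over
#' `folds`-fold cross-validation and correlated (Pearson) with the observed
#' response; accuracies are averaged over `repeats` independent fold
#' assignments.  The overall statistic is the mean over component counts.
#'
#' @param X,y Predictors and response.
#' @param components Component counts to evaluate (default `2:10`).
#' @param folds,repeats Cross-validation settings (defaults 5 and 5).
#' @return List: `per_component` (named mean r), `overall` (mean over
#'   components), `best_n_components`.
#' @export
cv_pls_accuracy <- function(X, y, components = 2:10, folds = 5L,
                            repeats = 5L) {
  n <- nrow(X)
  if (n < folds) stop("more folds than samples")
  kmax <- max(components)
  acc <- matrix(NA_real_, repeats, length(components))
  for (r in seq_len(repeats)) {
    ids <- .fold_ids(n, folds)
    pred <- matrix(NA_real_, n, length(components))
    for (f in seq_len(folds)) {
      te <- which(ids == f); tr <- which(ids != f)
      if (length(te) < 2L || length(tr) <= kmax)
        stop("a fold has too few samples for the requested components")
      fit <- fit_pls(X[tr, , drop = FALSE], y[tr], kmax)
      for (ci in seq_along(components)) {
        pred[te, ci] <- predict(fit, X[te, , drop = FALSE],
                                ncomp = components[ci])
      }
    }
    acc[r, ] <- apply(pred, 2L, .safe_cor, y = y)
  }
  per_component <- colMeans(acc)
  names(per_component) <- paste0("ncomp", components)
  list(per_component = per_component, overall = mean(per_component),
       best_n_components = components[which.max(per_component)])
}

#' Permutation and surrogate significance of the PLS accuracy
#'
#' The observed statistic is the overall cross-validated accuracy from
#' [cv_pls_accuracy()].  The permutation null recomputes it with the
#' response values randomly permuted; the surrogate null replaces the
#' response with each row of an autocorrelation-preserving surrogate set
#' (values taken at the same matched voxels).  Add-one p-values.
#'
#' @param X,y Predictors and response.
#' @param n_perm Number of random permutations.
#' @param surrogate_y Optional matrix (`n_null x length(y)`) of surrogate
#'   response vectors, e.g. surrogate influence values at matched voxels.
#' @param components,folds,repeats Passed to [cv_pls_accuracy()].
#' @return List: `observed`, `p_perm`, `p_surrogate` (NA when no
#'   surrogates), `null_perm`, `null_surrogate`.
#' @export
pls_significance <- function(X, y, n_perm = 100L, surrogate_y = NULL,
                             components = 2:10, folds = 5L, repeats = 1L) {
  observed <- cv_pls_accuracy(X, y, components, folds, repeats)$overall
  null_perm <- vapply(seq_len(n_perm), function(i)
    cv_pls_accuracy(X, sample(y), components, folds, repeats)$overall,
    numeric(1))
  p_perm <- .perm_p(null_perm, observed)
  null_surr <- numeric(0)
  p_surr <- NA_real_
  if (!is.null(surrogate_y)) {
    if (ncol(surrogate_y) != length(y))
      stop("surrogate responses must align with `y`")
    null_surr <- vapply(seq_len(nrow(surrogate_y)), function(i)
      cv_pls_accuracy(X, surrogate_y[i, ], components, folds,
                      repeats)$overall, numeric(1))
    p_surr <- .perm_p(null_surr, observed)
  }
  list(observed = observed, p_perm = p_perm, p_surrogate = p_surr,
       null_perm = null_perm, null_surrogate = null_surr)
}

#' Bootstrap VIP gene ranking
#'
#' Refits the PLS model on `n_boot` bootstrap resamples of the samples
#' (resampling with replacement), records each gene's VIP, and ranks genes
#' by `z = mean bootstrap VIP / bootstrap SE`, descending.  Resamples with
#' a constant response are redrawn.
#'
#' @param X,y Predictors and response.
#' @param n_components Components of the refitted models (default 6, the
#'   out-of-sample optimum reported for this analysis family).
#' @param n_boot Number of bootstrap resamples.
#' @return Data frame of class `gene_ranking`: `gene`, `vip` (bootstrap
#'   mean), `vip_se`, `z`, `rank` (1 = most influential; ties broken by
#'   gene id).
#' @export
bootstrap_vip_ranking <- function(X, y, n_components = 6L, n_boot = 1000L) {
  if (n_boot < 2L) stop("`n_boot` must be >= 2")
  n <- nrow(X)
  p <- ncol(X)
  vips <- matrix(NA_real_, n_boot, p)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(y[idx]) > 0) break
      redraws <- redraws + 1L
    }
    vips[b, ] <- vip_scores(fit_pls(X[idx, , drop = FALSE], y[idx],
                                    n_components))
  }
  if (redraws > 0L)
    message(sprintf("redrew %d degenerate bootstrap resamples", redraws))
  vbar <- colMeans(vips)
  se <- apply(vips, 2L, sd)
  z <- vbar / se
  genes <- colnames(X)
  ord <- order(-z, genes)
  out <- data.frame(gene = genes, vip = vbar, vip_se = se, z = z,
                    stringsAsFactors = FALSE)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(p)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}
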