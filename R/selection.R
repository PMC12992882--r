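#' Min-max scaling fitted on training rows only
#'
#' `fit_minmax()` learns per-feature minima and maxima from the training
#' matrix; `apply_minmax()` maps any table with the same columns through
#' the *training* parameters: train columns land in `[0, 1]`, test values
#' outside the training range are deliberately left unclipped (they map
#' below 0 / above 1), so no test information ever enters the scaler.
#' Constant training columns map to 0, with a warning.
#'
#' @param X Numeric matrix (rows = cases) or a feature table from
#'   [extract_table()] (metadata columns are ignored).
#' @return `fit_minmax()`: a `scaler_params` object; `apply_minmax()`: a
#'   matrix of the same shape as its input.
#' @export
fit_minmax <- function(X) {
  if (is.data.frame(X)) X <- table_xy(X)$X
  if (nrow(X) < 2) stop("fit_minmax needs at least 2 training rows")
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  if (any(hi == lo)) {
    warning(sum(hi == lo), " constant training column(s) will be scaled to 0")
  }
  structure(list(min = lo, max = hi), class = "scaler_params")
}

#' @rdname fit_minmax
#' @param params A `scaler_params` from `fit_minmax()`.
#' @export
apply_minmax <- function(X, params) {
  if (is.data.frame(X)) X <- table_xy(X)$X
  stopifnot(inherits(params, "scaler_params"))
  if (!identical(colnames(X), names(params$min))) {
    X <- X[, names(params$min), drop = FALSE] # align by name; errors if missing
  }
  rng <- params$max - params$min
  rng[rng == 0] <- Inf # constant train column -> 0 everywhere
  sweep(sweep(X, 2, params$min), 2, rng, `/`)
}

# stratified fold assignment; reduces the fold count with a warning when the
# rarer class has fewer members than folds
make_folds <- function(y, k, seed) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (min(n1, n0) < 2) stop("both classes need at least 2 members for CV")
  if (min(n1, n0) < k) {
    warning("reducing fold count from ", k, " to ", min(n1, n0),
            " (smallest class has ", min(n1, n0), " members)")
    k <- min(n1, n0)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# L2(ridge)-regularized logistic regression; C is the inverse regularization
# strength (sklearn convention), lambda = 1 / (n * C) in glmnet terms
ridge_logistic <- function(X, y, C = 1) {
  p <- ncol(X)
  if (p == 1) {
    fit <- suppressWarnings(stats::glm(y ~ X[, 1], family = stats::binomial()))
    return(list(coef = stats::setNames(stats::coef(fit)[2], colnames(X)),
                intercept = stats::coef(fit)[1]))
  }
  lam <- 1 / (nrow(X) * C)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lam * c(64, 16, 4, 1), standardize = FALSE)
  cf <- as.numeric(stats::coef(fit, s = lam))
  list(coef = stats::setNames(cf[-1], colnames(X)), intercept = cf[1])
}

ridge_scores <- function(model, X) {
  as.numeric(X[, names(model$coef), drop = FALSE] %*% model$coef + model$intercept)
}

#' Cross-validated feature importance via L2 logistic regression
#'
#' Fits a ridge-penalized logistic regression on the training part of each
#' stratified CV fold (default 10-fold) and scores every feature by the
#' mean absolute coefficient across folds, on min-max-scaled inputs.
#'
#' @param X Scaled feature matrix (training rows).
#' @param y 0/1 labels (1 = sufficient).
#' @param seed Seed controlling the fold assignment.
#' @param k_folds Number of stratified folds.
#' @param C Inverse L2 strength.
#' @return An `importance_ranking`: tibble (`feature`, `importance`) in
#'   decreasing importance order, with the CV setup in attributes.
#' @export
cv_importance <- function(X, y, seed = 1L, k_folds = 10L, C = 1) {
  fold <- make_folds(y, k_folds, derive_seed(seed, "cv-importance"))
  k <- max(fold)
  co <- matrix(0, k, ncol(X), dimnames = list(NULL, colnames(X)))
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- ridge_logistic(X[tr, , drop = FALSE], y[tr], C)
    co[f, names(m$coef)] <- m$coef
  }
  imp <- colMeans(abs(co))
  ord <- order(-imp, colnames(X)) # ties broken by name for determinism
  structure(
    tibble::tibble(feature = colnames(X)[ord], importance = unname(imp[ord])),
    class = c("importance_ranking", class(tibble::tibble())),
    k_folds = k, seed = seed, C = C
  )
}

#' Correlation-guided feature pruning
#'
#' For every feature pair whose training-set Pearson correlation exceeds
#' the threshold (strictly), the less important member is discarded.
#' Pairs are processed in order of descending absolute correlation, then
#' lexicographic name, and an importance tie within a pair drops the
#' lexicographically later name, so the result is deterministic and
#' invariant to column order. Surviving features are pairwise
#' `|r| <= threshold`. Constant columns (undefined correlation) are
#' retained with a warning.
#'
#' @param X Scaled training feature matrix.
#' @param ranking An `importance_ranking` covering all columns of `X`.
#' @param threshold Correlation threshold (pairs with `|r| > threshold` are
#'   pruned; exactly-at-threshold pairs are kept).
#' @return Character vector of surviving feature names, in ranking order.
#' @export
prune_correlated <- function(X, ranking, threshold = 0.9) {
  feats <- colnames(X)
  if (!all(feats %in% ranking$feature)) {
    stop("ranking does not cover all features")
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant column(s): correlation undefined, retained")
  }
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  # strict inequality with an epsilon so a pair at exactly the threshold
  # (up to float rounding of the correlation) is kept
  hit <- which(abs(cm) > threshold + 1e-10 & upper.tri(cm), arr.ind = TRUE)
  imp <- stats::setNames(ranking$importance, ranking$feature)[feats]
  if (nrow(hit) > 0) {
    pair_a <- feats[hit[, 1]]; pair_b <- feats[hit[, 2]]
    r <- abs(cm[hit])
    nm1 <- pmin(pair_a, pair_b); nm2 <- pmax(pair_a, pair_b)
    ordp <- order(-r, nm1, nm2)
    dropped <- character(0)
    for (k in ordp) {
      a <- pair_a[k]; b <- pair_b[k]
      if (a %in% dropped || b %in% dropped) next
      loser <- if (imp[a] > imp[b]) b
      else if (imp[b] > imp[a]) a
      else max(a, b) # tie: lexicographically later name goes
      dropped <- c(dropped, loser)
    }
    feats <- setdiff(feats, dropped)
  }
  ranking$feature[ranking$feature %in% feats]
}

cv_auroc_ridge <- function(X, y, fold, C = 1) {
  k <- max(fold)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- ridge_logistic(X[tr, , drop = FALSE], y[tr], C)
    aucs[f] <- auroc(ridge_scores(m, X[!tr, , drop = FALSE]), y[!tr])
  }
  mean(aucs)
}

#' Incremental top-k subset search maximizing CV AUROC
#'
#' Evaluates the nested subsets top-5, top-6, ..., top-K of the pruned,
#' importance-ranked feature list by mean stratified 10-fold CV AUROC of a
#' ridge logistic regression (same folds for every k), and returns the
#' arg-max subset; AUROC ties resolve to the smallest k. With fewer than 5
#' candidates a single evaluation using all of them is returned.
#'
#' @param X Scaled training feature matrix (columns at least the candidates).
#' @param y 0/1 labels.
#' @param candidates Pruned feature names in ranking order.
#' @param seed Fold-assignment seed.
#' @param k_folds CV folds.
#' @param C Inverse L2 strength.
#' @param k_min Smallest subset size evaluated (default 5).
#' @return A `selection_result`: list with `features` (chosen subset),
#'   `k`, `trace` (tibble k / cv_auroc), `candidates`, `seed`.
#' @export
incremental_search <- function(X, y, candidates, seed = 1L, k_folds = 10L,
                               C = 1, k_min = 5L) {
  stopifnot(length(candidates) >= 1)
  fold <- make_folds(y, k_folds, derive_seed(seed, "incremental"))
  K <- length(candidates)
  ks <- if (K < k_min) K else seq.int(k_min, K)
  tr <- vapply(ks, function(k) {
    cv_auroc_ridge(X[, candidates[seq_len(k)], drop = FALSE], y, fold, C)
  }, 0)
  best <- ks[which.max(tr)] # which.max takes the first maximum -> smallest k
  structure(list(
    features = candidates[seq_len(best)],
    k = best,
    trace = tibble::tibble(k = ks, cv_auroc = tr),
    candidates = candidates,
    seed = seed
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d candidates -> chose k = %d (CV AUROC %.3f)\n",
              length(x$candidates), x$k, max(x$trace$cv_auroc)))
  invisible(x)
}

#' Run the full selection pipeline on a training table
#'
#' Convenience wrapper: scale (train-fitted min-max), rank by CV
#' importance, prune correlated pairs, run the incremental search.
#'
#' @param train_tbl Feature table ([extract_table()]) of training rows.
#' @param seed Seed for fold assignments.
#' @param cor_threshold Correlation pruning threshold.
#' @param k_folds CV folds for importance and search.
#' @return List: `selection` (`selection_result`), `ranking`, `scaler`,
#'   `pruned` (surviving candidates).
#' @export
select_features <- function(train_tbl, seed = 1L, cor_threshold = 0.9,
                            k_folds = 10L) {
  xy <- table_xy(train_tbl)
  scaler <- fit_minmax(xy$X)
  Xs <- apply_minmax(xy$X, scaler)
  ranking <- cv_importance(Xs, xy$y, seed = seed, k_folds = k_folds)
  pruned <- prune_correlated(Xs, ranking, cor_threshold)
  sel <- incremental_search(Xs, xy$y, pruned, seed = seed, k_folds = k_folds)
  list(selection = sel, ranking = ranking, scaler = scaler, pruned = pruned)
}

#' Serialize a selection result to JSON
#'
#' Stable field order and number formatting so identical runs produce
#' byte-identical files.
#'
#' @param sel A `selection_result`.
#' @param path Output path.
#' @param extra Optional named list merged into the JSON (e.g. config hash).
#' @export
write_selection_json <- function(sel, path, extra = NULL) {
  obj <- c(list(
    features = sel$features,
    k = sel$k,
    trace = list(k = sel$trace$k, cv_auroc = sel$trace$cv_auroc),
    candidates = sel$candidates,
    seed = sel$seed
  ), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
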