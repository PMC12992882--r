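# Random-forest collateral classifier: sequential model-based (TPE-style)
# hyperparameter search maximizing stratified-CV AUROC, then a 1000-tree
# final fit validated with 4-fold CV.

# declared search space (modest, suited to <= ~100 selected features):
# max_depth 3..20 or unlimited, min.node.size 1..10, mtry fraction
# 0.2..1.0, class weights none/balanced
forest_space <- function() {
  list(
    max_depth = list(type = "int", lo = 3L, hi = 21L), # 21 encodes unlimited
    min_node = list(type = "int", lo = 1L, hi = 10L),
    mtry_frac = list(type = "num", lo = 0.2, hi = 1.0),
    class_weight = list(type = "cat", values = c("none", "balanced"))
  )
}

y_factor <- function(y) {
  factor(ifelse(y == 1, "sufficient", "non-sufficient"),
         levels = c("non-sufficient", "sufficient"))
}

fit_ranger <- function(X, y, params, num_trees, seed) {
  yf <- y_factor(y)
  cw <- if (identical(params$class_weight, "balanced")) {
    n <- length(yf)
    tab <- table(yf)
    stats::setNames(n / (2 * as.numeric(tab)), names(tab))
  } else NULL
  ranger::ranger(
    x = as.data.frame(X), y = yf,
    num.trees = num_trees,
    mtry = max(1L, floor(params$mtry_frac * ncol(X))),
    min.node.size = params$min_node,
    max.depth = if (params$max_depth >= 21L) 0L else params$max_depth,
    class.weights = cw,
    probability = TRUE,
    seed = seed,
    num.threads = 1L,
    verbose = FALSE
  )
}

ranger_prob <- function(rf, X) {
  stats::predict(rf, data = as.data.frame(X), num.threads = 1L,
                 verbose = FALSE)$predictions[, "sufficient"]
}

cv_auroc_forest <- function(X, y, params, num_trees, fold, seed) {
  k <- max(fold)
  mean(vapply(seq_len(k), function(f) {
    tr <- fold != f
    rf <- fit_ranger(X[tr, , drop = FALSE], y[tr], params, num_trees,
                     seed + f)
    auroc(ranger_prob(rf, X[!tr, , drop = FALSE]), y[!tr])
  }, 0))
}

# --- TPE-style sequential sampler ---------------------------------------

sample_param <- function(sp, rng_good = NULL) {
  if (sp$type == "cat") {
    if (is.null(rng_good) || length(rng_good) == 0) {
      return(sample(sp$values, 1))
    }
    w <- table(factor(rng_good, levels = sp$values)) + 1 # add-one smoothing
    return(sample(sp$values, 1, prob = as.numeric(w)))
  }
  lo <- sp$lo; hi <- sp$hi
  if (is.null(rng_good) || length(rng_good) == 0) {
    v <- stats::runif(1, lo, hi)
  } else {
    centre <- sample(rng_good, 1)
    v <- stats::rnorm(1, as.numeric(centre), 0.2 * (hi - lo))
    v <- min(max(v, lo), hi)
  }
  if (sp$type == "int") as.integer(round(v)) else v
}

param_density <- function(sp, value, obs) {
  if (length(obs) == 0) return(1)
  if (sp$type == "cat") {
    w <- (sum(obs == value) + 1) / (length(obs) + length(sp$values))
    return(w)
  }
  bw <- 0.2 * (sp$hi - sp$lo)
  mean(stats::dnorm(as.numeric(value), as.numeric(obs), bw)) + 1e-12
}

#' Sequential model-based hyperparameter tuning for the forest
#'
#' Tree-structured-Parzen-style optimization over the declared search space
#' (depth bound, minimum node size, feature-subsample fraction, class
#' weighting): 10 random startup trials, then candidates sampled from a
#' kernel density of the best quartile of past trials and scored by the
#' good/bad density ratio. The objective is mean stratified-CV AUROC of a
#' 300-tree forest (the final model alone uses 1000 trees); exactly
#' `n_trials` objective evaluations are performed. Deterministic per seed.
#'
#' @param X Feature matrix restricted to the selected features.
#' @param y 0/1 labels (both classes required).
#' @param n_trials Objective evaluations (default 50).
#' @param seed Seed.
#' @param k_folds CV folds inside the objective (default 5).
#' @param num_trees Trees per tuning forest (default 300).
#' @return List of best hyperparameters (`max_depth`, `min_node`,
#'   `mtry_frac`, `class_weight`) with the trial history in
#'   `attr(, "trials")`.
#' @export
bayes_tune <- function(X, y, n_trials = 50L, seed = 1L, k_folds = 5L,
                       num_trees = 300L) {
  if (length(unique(y)) < 2) stop("bayes_tune needs both classes in y")
  space <- forest_space()
  fold <- make_folds(y, k_folds, derive_seed(seed, "tune-folds"))
  n_startup <- min(10L, n_trials)
  gamma <- 0.25
  trials <- list()
  with_seed(derive_seed(seed, "tpe"), {
    for (t in seq_len(n_trials)) {
      if (t <= n_startup) {
        cand <- lapply(space, sample_param)
      } else {
        vals <- vapply(trials, `[[`, 0, "value")
        n_good <- max(1L, ceiling(gamma * length(vals)))
        good_idx <- order(-vals)[seq_len(n_good)]
        getp <- function(nm, idx) lapply(trials[idx], function(tr) tr$params[[nm]])
        best_score <- -Inf; cand <- NULL
        for (j in 1:24) {
          cj <- lapply(names(space), function(nm) {
            sample_param(space[[nm]], unlist(getp(nm, good_idx)))
          })
          names(cj) <- names(space)
          score <- 0
          for (nm in names(space)) {
            lg <- param_density(space[[nm]], cj[[nm]], unlist(getp(nm, good_idx)))
            gb <- param_density(space[[nm]], cj[[nm]],
                                unlist(getp(nm, setdiff(seq_along(vals), good_idx))))
            score <- score + log(lg) - log(gb)
          }
          if (score > best_score) {
            best_score <- score; cand <- cj
          }
        }
      }
      names(cand) <- names(space)
      val <- cv_auroc_forest(X, y, cand, num_trees, fold,
                             derive_seed(seed, paste0("trial-", t)))
      trials[[t]] <- list(params = cand, value = val)
    }
  })
  vals <- vapply(trials, `[[`, 0, "value")
  best <- trials[[which.max(vals)]]$params
  attr(best, "trials") <- tibble::tibble(
    trial = seq_along(vals), value = vals,
    max_depth = vapply(trials, function(tr) tr$params$max_depth, 1L),
    min_node = vapply(trials, function(tr) tr$params$min_node, 1L),
    mtry_frac = vapply(trials, function(tr) tr$params$mtry_frac, 1),
    class_weight = vapply(trials, function(tr) tr$params$class_weight, "")
  )
  attr(best, "best_value") <- max(vals)
  best
}

#' Default forest hyperparameters (untuned reference)
#' @export
default_params <- function() {
  list(max_depth = 21L, min_node = 1L, mtry_frac = 1 / 3, class_weight = "none")
}

#' Fit the final 1000-tree random forest with a 4-fold CV report
#'
#' @param X Feature matrix (training rows, selected features only).
#' @param y 0/1 labels; needs at least 8 cases (4 stratifiable folds).
#' @param params Hyperparameters from [bayes_tune()] or [default_params()].
#' @param seed Seed.
#' @param num_trees Ensemble size of the final model (default 1000).
#' @return A `collrad_forest`: fitted ensemble, locked feature names,
#'   params, seed, config hash, and `cv_report` (4 per-fold AUROCs).
#' @export
fit_final <- function(X, y, params = default_params(), seed = 1L,
                      num_trees = 1000L) {
  if (length(y) < 8 || min(table(y)) < 4) {
    stop("fit_final needs >= 8 cases with >= 4 per class (4-fold stratified CV)")
  }
  fold <- make_folds(y, 4L, derive_seed(seed, "final-cv"))
  cv_aucs <- vapply(1:4, function(f) {
    tr <- fold != f
    rf <- fit_ranger(X[tr, , drop = FALSE], y[tr], params, num_trees,
                     derive_seed(seed, paste0("final-fold-", f)))
    auroc(ranger_prob(rf, X[!tr, , drop = FALSE]), y[!tr])
  }, 0)
  rf <- fit_ranger(X, y, params, num_trees, derive_seed(seed, "final-fit"))
  rf$call <- NULL # drop the call so serialized artifacts are reproducible
  structure(list(
    forest = rf,
    features = colnames(X),
    params = params[c("max_depth", "min_node", "mtry_frac", "class_weight")],
    seed = as.integer(seed),
    num_trees = num_trees,
    config_hash = config_hash(list(params[c("max_depth", "min_node", "mtry_frac",
                                            "class_weight")],
                                   colnames(X), seed, num_trees)),
    cv_report = cv_aucs
  ), class = "collrad_forest")
}

#' Predicted probability of sufficient collaterals
#'
#' Columns are aligned to the model's locked feature list by name; missing
#' or extra columns raise an error listing the mismatch.
#'
#' @param model A `collrad_forest`.
#' @param X Feature matrix or data frame.
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(model, X) {
  UseMethod("predict_prob")
}

#' @export
predict_prob.collrad_forest <- function(model, X) {
  have <- colnames(X)
  missing_f <- setdiff(model$features, have)
  extra_f <- setdiff(have, model$features)
  if (length(missing_f) || length(extra_f)) {
    stop("feature schema mismatch; missing: [",
         paste(missing_f, collapse = ", "), "], extra: [",
         paste(extra_f, collapse = ", "), "]")
  }
  ranger_prob(model$forest, X[, model$features, drop = FALSE])
}

#' @export
predict.collrad_forest <- function(object, newdata, threshold = 0.5, ...) {
  p <- predict_prob(object, newdata)
  tibble::tibble(
    prob_sufficient = p,
    label = factor(ifelse(p >= threshold, "sufficient", "non-sufficient"),
                   levels = c("non-sufficient", "sufficient"))
  )
}

#' @export
print.collrad_forest <- function(x, ...) {
  cat(sprintf("<collrad_forest> %d trees, %d features, 4-fold CV AUROC %.3f (config %s)\n",
              x$num_trees, length(x$features), mean(x$cv_report), x$config_hash))
  invisible(x)
}

#' Persist / restore a trained forest with its feature schema
#'
#' The archive embeds the feature list and config hash;
#' [predict_prob()] refuses to score under a mismatched schema.
#'
#' @param model A `collrad_forest`.
#' @param path File path (`.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "collrad_forest")) stop("not a collrad_forest archive")
  m
}
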