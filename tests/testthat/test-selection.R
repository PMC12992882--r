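test_that("min-max scaling is train-fitted and never re-fitted on test rows", {
  Xtr <- matrix(c(2, 4, 10, 20), 2, 2, dimnames = list(NULL, c("a", "b")))
  sc <- fit_minmax(Xtr)
  expect_equal(unname(apply_minmax(Xtr, sc)[, "a"]), c(0, 1))
  # out-of-range test value maps past 1 (no clipping)
  Xte <- matrix(c(5, 15), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(apply_minmax(Xte, sc)[1, "a"]), 1.5)
  # leakage detector: fitting on train+test shifts the transform
  sc_leaky <- fit_minmax(rbind(Xtr, Xte))
  expect_false(isTRUE(all.equal(apply_minmax(Xte, sc), apply_minmax(Xte, sc_leaky))))
  # constant column warns and maps to 0
  Xc <- matrix(c(1, 2, 7, 7), 2, 2, dimnames = list(NULL, c("a", "k")))
  expect_warning(scc <- fit_minmax(Xc), "constant")
  expect_equal(unname(apply_minmax(Xc, scc)[, "k"]), c(0, 0))
  expect_error(fit_minmax(Xc[1, , drop = FALSE]), "2 training rows")
})

test_that("cross-validated importance is symmetric, signal-seeking and deterministic", {
  tbl <- signal_table(n = 200, p = 21, n_signal = 1, d = 3, seed = 2)
  xy <- collrad:::table_xy(tbl)
  Xs <- apply_minmax(xy$X, fit_minmax(xy$X))
  # duplicate the signal column: ridge splits the weight equally
  Xdup <- cbind(Xs, f01_copy = Xs[, "f01"])
  rk <- cv_importance(Xdup, xy$y, seed = 4)
  imp <- stats::setNames(rk$importance, rk$feature)
  expect_equal(unname(imp["f01"]), unname(imp["f01_copy"]), tolerance = 1e-4)
  # the separating feature ranks first
  rk2 <- cv_importance(Xs, xy$y, seed = 4)
  expect_identical(rk2$feature[1], "f01")
  # deterministic per seed
  rk3 <- cv_importance(Xs, xy$y, seed = 4)
  expect_identical(rk2, rk3)
  # undersized classes reduce the fold count with a warning
  small <- Xs[c(1:6, 101:112), ]
  expect_warning(cv_importance(small, xy$y[c(1:6, 101:112)], seed = 1),
                 "reducing fold count")
})

test_that("correlation pruning drops the less important of each flagged pair", {
  withr::with_seed(6, {
    n <- 80
    base <- rnorm(n)
    X <- cbind(a = base, b = base, c = rnorm(n)) # a and b identical
  })
  rk <- structure(tibble::tibble(feature = c("a", "c", "b"),
                                 importance = c(0.8, 0.5, 0.3)),
                  class = c("importance_ranking", class(tibble::tibble())))
  kept <- prune_correlated(X, rk, 0.9)
  expect_identical(kept, c("a", "c"))
  # surviving features are pairwise |r| <= threshold
  cm <- abs(stats::cor(X[, kept])); diag(cm) <- 0
  expect_lte(max(cm), 0.9)

  # a pair with r exactly at the threshold is kept (strict inequality):
  # mix the standardized feature with an orthogonal unit-variance residual
  x1 <- c(1, 2, 3, 4, 5)
  y2 <- 0.9 * scale(x1)[, 1] + sqrt(1 - 0.81) * scale(c(1, -2, 0, 2, -1))[, 1]
  Xe <- cbind(p = x1, q = y2)
  stopifnot(abs(abs(cor(Xe)[1, 2]) - 0.9) < 1e-12)
  rke <- structure(tibble::tibble(feature = c("p", "q"),
                                  importance = c(1, 0.5)),
                   class = c("importance_ranking", class(tibble::tibble())))
  expect_identical(prune_correlated(Xe, rke, 0.9), c("p", "q"))

  # nothing above threshold: identity
  expect_identical(prune_correlated(X[, c("a", "c")],
                                    rk[rk$feature %in% c("a", "c"), ], 0.9),
                   c("a", "c"))

  # invariance to column order given fixed importances
  kept2 <- prune_correlated(X[, c("c", "b", "a")], rk, 0.9)
  expect_setequal(kept2, kept)

  # constant column: retained with a warning
  Xc <- cbind(X, z = rep(1, nrow(X)))
  rkc <- structure(tibble::tibble(feature = c("a", "c", "b", "z"),
                                  importance = c(0.8, 0.5, 0.3, 0.1)),
                   class = c("importance_ranking", class(tibble::tibble())))
  expect_warning(keptc <- prune_correlated(Xc, rkc, 0.9), "constant")
  expect_true("z" %in% keptc)
})

test_that("incremental search traces nested subsets and returns the arg-max", {
  tbl <- signal_table(n = 200, p = 12, n_signal = 3, d = 2.5, seed = 9)
  xy <- collrad:::table_xy(tbl)
  Xs <- apply_minmax(xy$X, fit_minmax(xy$X))
  rk <- cv_importance(Xs, xy$y, seed = 3)
  sel <- incremental_search(Xs, xy$y, rk$feature, seed = 3)
  # trace covers k = 5..K
  expect_identical(sel$trace$k, 5:12)
  expect_identical(length(sel$features), sel$k)
  # arg-max property: chosen subset beats (or ties) the top-5 subset
  expect_gte(max(sel$trace$cv_auroc), sel$trace$cv_auroc[1])
  expect_identical(max(sel$trace$cv_auroc), sel$trace$cv_auroc[sel$trace$k == sel$k])
  # fewer than 5 candidates: single evaluation using all
  sel3 <- incremental_search(Xs[, 1:3], xy$y, colnames(Xs)[1:3], seed = 3)
  expect_identical(sel3$k, 3L)
  expect_identical(nrow(sel3$trace), 1L)
})

test_that("the full selection recovers planted signal at a plausible subset size", {
  ks <- integer(5); hits <- integer(5)
  for (s in seq_len(5)) {
    tbl <- signal_table(n = 300, p = 50, n_signal = 5, d = 2, seed = 100 + s)
    res <- select_features(tbl, seed = s)
    ks[s] <- res$selection$k
    hits[s] <- sum(sprintf("f%02d", 1:5) %in% res$selection$features)
    # post-pruning candidates are pairwise |r| <= 0.9
    xy <- collrad:::table_xy(tbl)
    Xs <- apply_minmax(xy$X, res$scaler)
    cm <- abs(stats::cor(Xs[, res$pruned])); diag(cm) <- 0
    expect_lte(max(cm), 0.9)
  }
  expect_gte(stats::median(ks), 5)
  expect_lte(stats::median(ks), 10)
  expect_true(all(hits >= 4))
})

test_that("selection JSON serialization is byte-stable", {
  tbl <- signal_table(n = 120, p = 10, seed = 3)
  r1 <- select_features(tbl, seed = 5)
  r2 <- select_features(tbl, seed = 5)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_selection_json(r1$selection, f1)
  write_selection_json(r2$selection, f2)
  expect_identical(readLines(f1), readLines(f2))
})
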