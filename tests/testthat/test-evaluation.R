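test_that("AUROC equals exhaustive pair counting, with tie handling", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               auroc_bruteforce(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  withr::with_seed(2, {
    s <- sample(1:5, 40, replace = TRUE) # heavy ties
    y <- rep(c(0, 1), 20)
  })
  expect_equal(auroc(s, y), auroc_bruteforce(s, y))
  # complement identity (exact with midrank tie handling)
  expect_equal(auroc(-s, y), 1 - auroc(s, y))
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("confusion metrics reproduce hand ratios and flag undefined rates", {
  cm <- confusion_metrics(tp = 43, fp = 7, tn = 16, fn = 3)
  expect_equal(round_half_up(cm$sensitivity), 0.935)
  expect_equal(round_half_up(cm$specificity), 0.696)
  expect_equal(round_half_up(cm$ppv), 0.860)
  expect_equal(round_half_up(cm$npv), 0.842)
  allc <- confusion_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(unlist(allc[c("sensitivity", "specificity", "ppv", "npv")],
                      use.names = FALSE), rep(1, 4))
  # no predicted negatives: NPV undefined, not zero
  nd <- confusion_metrics(tp = 5, fp = 5, tn = 0, fn = 0)
  expect_true(is.na(nd$npv))
  expect_error(confusion_metrics(0, 0, 0, 0), "sum")
})

test_that("bootstrap CIs are deterministic, contain the point, and narrow with n", {
  gen <- function(n, seed) {
    withr::with_seed(seed, {
      y <- rep(c(0, 1), each = n / 2)
      list(s = rnorm(n) + 1.2 * y, y = y)
    })
  }
  d <- gen(100, 1)
  ci <- bootstrap_ci(d$s, d$y, B = 500, seed = 3)
  expect_identical(ci, bootstrap_ci(d$s, d$y, B = 500, seed = 3))
  a <- auroc(d$s, d$y)
  expect_lte(ci["lower"], a); expect_gte(ci["upper"], a)
  widths <- vapply(1:10, function(s) {
    w100 <- diff(bootstrap_ci(gen(100, s)$s, gen(100, s)$y, B = 400, seed = s))
    w400 <- diff(bootstrap_ci(gen(400, s)$s, gen(400, s)$y, B = 400, seed = s))
    w400 < w100
  }, TRUE)
  expect_gte(stats::median(widths), 1) # majority (here: all counted as logical)
})

test_that("DeLong variance components match the O(n^2) double-loop oracle", {
  withr::with_seed(4, {
    y <- rep(c(0, 1), each = 10)
    sa <- rnorm(20) + y
    sb <- rnorm(20) + 0.5 * y
  })
  mine <- delong_test(sa, sb, y)
  oracle <- delong_bruteforce(sa, sb, y)
  expect_lt(abs(mine$var_diff - oracle$var_diff), 1e-10)
  expect_lt(abs(mine$auc_a - oracle$auc_a), 1e-12)
  # self-comparison convention
  self <- delong_test(sa, sa, y)
  expect_identical(self$z, 0); expect_identical(self$p, 1)
  # antisymmetry
  ba <- delong_test(sb, sa, y)
  expect_equal(ba$z, -mine$z)
  expect_equal(ba$p, mine$p)
  # strongly separated vs random scorer: decisive at n = 500
  withr::with_seed(5, {
    y5 <- rep(c(0, 1), each = 250)
    good <- rnorm(500) + 3 * y5
    rand <- rnorm(500)
  })
  expect_lt(delong_test(good, rand, y5)$p, 0.001)
})

test_that("AUROC and DeLong agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    y <- rep(c(0, 1), each = 40)
    sa <- rnorm(80) + 1.3 * y
    sb <- rnorm(80) + 0.7 * y
  })
  ra <- pROC::roc(y, sa, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, sb, quiet = TRUE, direction = "<")
  expect_equal(auroc(sa, y), as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  ref <- pROC::roc.test(ra, rb, method = "delong")
  mine <- delong_test(sa, sb, y)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(mine$z), abs(unname(ref$statistic)), tolerance = 1e-10)
})

test_that("permutation attribution separates used from null features", {
  tbl <- signal_table(n = 150, p = 5, n_signal = 2, d = 2, seed = 21)
  xy <- collrad:::table_xy(tbl)
  Xs <- apply_minmax(xy$X, fit_minmax(xy$X))
  colnames(Xs)[5] <- "null_feature"
  Xs[, "null_feature"] <- withr::with_seed(1, rnorm(nrow(Xs))) # label-independent
  m <- fit_final(Xs, xy$y, seed = 4, num_trees = 300)
  att <- attribution(m, Xs, xy$y, seed = 7)
  expect_identical(att, attribution(m, Xs, xy$y, seed = 7))
  nf <- att[att$feature == "null_feature", ]
  # within the shuffle noise band of zero (tiny absolute slack because a
  # forest may split on the null feature at a negligible rate)
  expect_lt(abs(nf$importance), 2 * nf$sd + 1e-3)
  expect_true(all(att$importance[att$feature %in% c("f01", "f02")] >
                    nf$importance))
})

test_that("permutation ranking's top feature matches exact Shapley on a toy forest", {
  withr::with_seed(31, {
    n <- 80
    y <- rep(c(0L, 1L), each = n / 2)
    X <- cbind(strong = rnorm(n) + 1.8 * y,
               weak = rnorm(n) + 0.4 * y,
               noise1 = rnorm(n),
               noise2 = rnorm(n))
  })
  m <- fit_final(X, y, seed = 6, num_trees = 200)
  att <- attribution(m, X, y, seed = 6)
  phi <- shapley_exact(X, y, seed = 6)
  expect_identical(att$feature[1], names(which.max(phi)))
})

test_that("eval reports carry coherent intervals and tidy output", {
  withr::with_seed(8, {
    y <- rep(c(0, 1), each = 30)
    s <- pmin(pmax(rnorm(60, 0.35 + 0.3 * y, 0.2), 0), 1)
  })
  r <- eval_report(s, y, seed = 2, B = 300)
  td <- generics::tidy(r)
  expect_identical(td$metric, c("auroc", "sensitivity", "specificity", "ppv", "npv"))
  expect_true(all(td$conf_low <= td$estimate + 1e-12 &
                    td$estimate <= td$conf_high + 1e-12, na.rm = TRUE))
  expect_identical(generics::glance(r)$n, 60L)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})
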