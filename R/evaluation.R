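#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Equals the probability that a random positive case outscores a random
#' negative one, ties counted one half; computed from midranks in
#' O(n log n).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or two-level factor/logical) labels; 1 = positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2) stop("auroc needs both classes present")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix rates
#'
#' Sensitivity, specificity, PPV and NPV from confusion counts; the
#' positive class is *sufficient collaterals*. Rates with a zero
#' denominator are reported as `NA` (undefined), never 0. Reporting
#' convention: round to 3 decimals with [round_half_up()].
#'
#' @param tp,fp,tn,fn Non-negative integer counts (at least one positive).
#' @return Named list: `sensitivity`, `specificity`, `ppv`, `npv`, plus the
#'   counts and `n`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("confusion counts must be non-negative and sum to > 0")
  }
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp),
       ppv = safe(tp, tp + fp),
       npv = safe(tn, tn + fn),
       counts = as.list(counts), n = sum(counts))
}

#' Round half away from zero (reporting convention)
#'
#' @param x Numeric.
#' @param digits Decimal places (default 3).
#' @export
round_half_up <- function(x, digits = 3) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Stratified percentile bootstrap confidence interval for a ROC metric
#'
#' Resamples positives and negatives separately (so every replicate
#' contains both classes), recomputes `metric(scores, labels)` B times and
#' returns the percentile interval.
#'
#' @param scores,labels As in [auroc()]; `n >= 10`.
#' @param metric Function `(scores, labels) -> scalar` (default [auroc()]).
#' @param B Bootstrap replicates.
#' @param seed Seed (deterministic interval per seed).
#' @param conf Coverage (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = auroc, B = 2000L,
                         seed = 1L, conf = 0.95) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(y) < 10) stop("bootstrap_ci needs n >= 10")
  ip <- which(y == 1); im <- which(y == 0)
  stats_b <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(im, length(im), replace = TRUE))
      metric(scores[idx], y[idx])
    }, 0)
  })
  a <- (1 - conf) / 2
  q <- stats::quantile(stats_b, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

# midrank structural components: V10 (per positive), V01 (per negative)
delong_components <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = auc, v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUROCs
#'
#' Fast structural-components (midrank) estimator of
#' `var(AUROC_a - AUROC_b)` for two models scored on the same cases, with a
#' two-sided normal p-value. Identical score vectors (zero variance of the
#' difference) return `z = 0`, `p = 1` by convention.
#'
#' @param scores_a,scores_b Paired scores on identical cases.
#' @param labels 0/1 labels (1 = positive).
#' @return List: `auc_a`, `auc_b`, `z`, `p`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2) stop("delong_test needs both classes")
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= 0 || (d == 0 && var_diff < 1e-300)) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p = p, var_diff = var_diff)
}

#' Permutation feature attribution for a trained classifier
#'
#' Model-agnostic importance: the mean AUROC drop when one feature column
#' is shuffled (20 shuffles per feature by default), with the spread of the
#' shuffled replicates. Features the model ignores score within noise of 0.
#'
#' @param model A fitted model with a [predict_prob()] method (e.g.
#'   [fit_final()]'s forest).
#' @param X Feature matrix (evaluation rows).
#' @param y 0/1 labels.
#' @param n_shuffles Shuffles per feature.
#' @param seed Seed.
#' @return Tibble: `feature`, `importance` (mean AUROC drop), `sd`
#'   (across shuffles), sorted by decreasing importance.
#' @export
attribution <- function(model, X, y, n_shuffles = 20L, seed = 1L) {
  base <- auroc(predict_prob(model, X), y)
  feats <- colnames(X)
  res <- with_seed(derive_seed(seed, "attribution"), {
    lapply(feats, function(f) {
      drops <- vapply(seq_len(n_shuffles), function(s) {
        Xp <- X
        Xp[, f] <- sample(Xp[, f])
        base - auroc(predict_prob(model, Xp), y)
      }, 0)
      c(mean(drops), stats::sd(drops))
    })
  })
  m <- do.call(rbind, res)
  out <- tibble::tibble(feature = feats, importance = m[, 1], sd = m[, 2])
  dplyr::arrange(out, dplyr::desc(.data$importance))
}
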