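# broom-style tidiers and ggplot2 autoplot methods for the fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the incremental-search trace
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return Tibble `k`, `cv_auroc`, `chosen`.
#' @export
tidy.selection_result <- function(x, ...) {
  dplyr::mutate(x$trace, chosen = .data$k == x$k)
}

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(n_candidates = length(x$candidates), k = x$k,
                 cv_auroc = max(x$trace$cv_auroc), seed = x$seed)
}

#' Tidy a fitted forest (per-feature rows)
#'
#' @param x A `collrad_forest`.
#' @param ... Unused.
#' @export
tidy.collrad_forest <- function(x, ...) {
  tibble::tibble(feature = x$features)
}

#' @rdname tidy.collrad_forest
#' @export
glance.collrad_forest <- function(x, ...) {
  tibble::tibble(num_trees = x$num_trees, n_features = length(x$features),
                 cv_auroc = mean(x$cv_report),
                 max_depth = x$params$max_depth,
                 min_node = x$params$min_node,
                 mtry_frac = x$params$mtry_frac,
                 class_weight = x$params$class_weight,
                 config_hash = x$config_hash)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One row per metric with point estimate and 95% CI.
#' @export
tidy.eval_report <- function(x, ...) {
  ms <- c("auroc", "sensitivity", "specificity", "ppv", "npv")
  tibble::tibble(
    metric = ms,
    estimate = vapply(ms, function(m) x[[m]], 0),
    conf_low = vapply(ms, function(m) unname(x[[paste0(m, "_ci")]][1]), 0),
    conf_high = vapply(ms, function(m) unname(x[[paste0(m, "_ci")]][2]), 0)
  )
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, n = x$n,
                 tp = x$counts$tp, fp = x$counts$fp,
                 tn = x$counts$tn, fn = x$counts$fn)
}

#' ROC curve coordinates
#'
#' @param scores,labels As in [auroc()].
#' @return Tibble `threshold`, `fpr`, `tpr` (thresholds descending).
#' @export
roc_points <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  ord <- order(-scores)
  tp <- cumsum(y[ord] == 1)
  fp <- cumsum(y[ord] == 0)
  tibble::tibble(threshold = scores[ord],
                 fpr = fp / sum(y == 0), tpr = tp / sum(y == 1)) |>
    dplyr::bind_rows(tibble::tibble(threshold = Inf, fpr = 0, tpr = 0)) |>
    dplyr::arrange(.data$fpr, .data$tpr)
}

#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tidy.selection_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$cv_auroc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "top-k features", y = "mean CV AUROC",
                  title = "Incremental feature-subset search") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eval_report <- function(object, ...) {
  df <- roc_points(object$scores, object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUROC %.3f, n = %d)",
                                  object$auroc, object$n)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.importance_ranking <- function(object, top_n = 20, ...) {
  df <- utils::head(object, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |coefficient| across CV folds", y = NULL,
                  title = "Cross-validated feature importance") +
    ggplot2::theme_minimal()
}

#' Axial slice plot of a phantom case
#'
#' @param case A `phantom_case`.
#' @param z Slice index (defaults to the mid-axial slice of the CoW).
#' @return A ggplot object (image greyscale + vessel mask outline overlay).
#' @export
plot_case_slice <- function(case, z = NULL) {
  dims <- dim(case$image$data)
  if (is.null(z)) z <- round(0.37 * dims[3])
  img <- case$image$data[, , z]
  msk <- case$vessel_mask$data[, , z]
  df <- tidyr::expand_grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  df$hu <- as.vector(img)
  df$vessel <- as.vector(msk) != 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hu)) +
    ggplot2::geom_point(data = df[df$vessel, ], colour = "red", size = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (Tan %d, %s, fill %.2f), z = %d",
                                  case$case_id %||% "case", case$tan_score,
                                  case$label, case$fill_fraction, z),
                  fill = "HU") +
    ggplot2::theme_void()
}
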