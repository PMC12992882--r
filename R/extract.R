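#' Radiomics extraction configuration
#'
#' Controls which feature classes, filtered images and discretization are
#' used by [extract_table()]. Defaults: fixed bin count B = 32 on z-scored
#' intensities, GLCM distance 1, LoG sigmas 1-3 mm, one wavelet level.
#'
#' @param feature_classes Subset of `shape`, `firstorder`, `glcm`, `glrlm`.
#' @param filters Subset of `original`, `wavelet-coif1`, `log` (intensity
#'   classes only; shape is always computed on the original-geometry mask).
#' @param log_sigmas LoG scales in mm.
#' @param n_bins Gray levels for discretization (>= 2).
#' @param glcm_distance Co-occurrence distance, voxels.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(feature_classes = c("shape", "firstorder", "glcm", "glrlm"),
                              filters = c("original", "wavelet-coif1", "log"),
                              log_sigmas = c(1, 2, 3),
                              n_bins = 32L,
                              glcm_distance = 1L) {
  feature_classes <- match.arg(feature_classes, several.ok = TRUE)
  filters <- match.arg(filters, several.ok = TRUE)
  stopifnot(n_bins >= 2, all(log_sigmas > 0))
  structure(list(feature_classes = feature_classes, filters = filters,
                 log_sigmas = as.numeric(log_sigmas), n_bins = as.integer(n_bins),
                 glcm_distance = as.integer(glcm_distance)),
            class = "extraction_config")
}

# build the named list of images (original + filtered) for intensity classes
filtered_images <- function(image, config) {
  imgs <- list()
  if ("original" %in% config$filters) imgs[["original"]] <- image
  if ("wavelet-coif1" %in% config$filters) {
    wb <- wavelet_bands(image)
    names(wb) <- paste0("wavelet-", names(wb))
    imgs <- c(imgs, wb)
  }
  if ("log" %in% config$filters) {
    for (s in config$log_sigmas) {
      imgs[[sprintf("log-sigma-%g", s)]] <- log_filter(image, s)
    }
  }
  imgs
}

# features for one case under one ROI set; returns a named numeric vector
extract_case <- function(case, roi_set, config) {
  shape_variant <- roi_set$variant %in% c("A", "C")
  out <- numeric(0)
  if (shape_variant && "shape" %in% config$feature_classes) {
    for (nm in names(roi_set$rois)) {
      roi <- roi_set$rois[[nm]]
      stop_if_incompatible(case$image, roi, paste("image and ROI", nm))
      sf <- shape_features(roi)
      names(sf) <- paste(nm, "original", "shape", names(sf), sep = "|")
      out <- c(out, sf)
    }
    return(out)
  }
  # intensity variant (model B): preprocess once, filter once, then sample
  # every filtered image under each ROI
  norm <- clip_znorm(case$image)
  imgs <- filtered_images(norm, config)
  classes <- intersect(config$feature_classes, c("firstorder", "glcm", "glrlm"))
  for (nm in names(roi_set$rois)) {
    roi <- roi_set$rois[[nm]]
    stop_if_incompatible(case$image, roi, paste("image and ROI", nm))
    if (sum(roi$data != 0L) == 0) {
      stop("empty ROI '", nm, "' for case ", case$case_id %||% "<unnamed>")
    }
    for (fi in names(imgs)) {
      img <- imgs[[fi]]
      disc <- NULL
      for (cl in classes) {
        vals <- switch(cl,
          firstorder = firstorder_features(img, roi, config$n_bins),
          glcm = {
            if (is.null(disc)) disc <- discretize(img, roi, config$n_bins)
            glcm_features(disc, roi, config$glcm_distance, config$n_bins)
          },
          glrlm = {
            if (is.null(disc)) disc <- discretize(img, roi, config$n_bins)
            glrlm_features(disc, roi, config$n_bins)
          })
        names(vals) <- paste(nm, fi, cl, names(vals), sep = "|")
        out <- c(out, vals)
      }
    }
  }
  out
}

#' Extract a feature table from a cohort
#'
#' Runs the per-variant radiomics protocol over a list of cases: shape
#' features of each vessel-derived ROI for variants A and C; first-order +
#' texture features of each territory ROI over the original and
#' filter-derived images for variant B. Column names encode provenance as
#' `"{roi}|{filter}|{class}|{feature}"`; the label column is the
#' dichotomized Tan score (sufficient = 1).
#'
#' Cases whose ROI sets cannot be extracted (e.g. an empty ROI) are dropped
#' with a warning naming the case.
#'
#' @param cases List of `phantom_case` (or compatible) objects.
#' @param variant ROI scheme, `"A"`, `"B"` or `"C"`.
#' @param config An [extraction_config()].
#' @param verbose Print per-case progress.
#' @return A tibble: `case_id`, `label` (factor sufficient/non-sufficient),
#'   `y` (integer, sufficient = 1), then one numeric column per feature.
#' @export
extract_table <- function(cases, variant = c("A", "B", "C"),
                          config = extraction_config(), verbose = FALSE) {
  variant <- match.arg(variant)
  rows <- list()
  keep <- logical(length(cases))
  t0 <- as.numeric(Sys.time())
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    rs <- assemble_rois(case, variant)
    row <- tryCatch(extract_case(case, rs, config), error = function(e) e)
    if (inherits(row, "error")) {
      warning("dropping case ", case$case_id %||% i, ": ",
              conditionMessage(row))
      next
    }
    keep[i] <- TRUE
    rows[[length(rows) + 1L]] <- row
    log_stage(verbose, "extract", case = case$case_id %||% i,
              n_features = length(row), t0 = t0)
  }
  if (length(rows) == 0) stop("no cases could be extracted")
  nm1 <- names(rows[[1]])
  bad <- vapply(rows, function(r) !identical(names(r), nm1), TRUE)
  if (any(bad)) stop("inconsistent feature sets across cases")
  mat <- do.call(rbind, rows)
  kept <- cases[keep]
  lab <- vapply(kept, function(cc) cc$label, "")
  tibble::tibble(
    case_id = vapply(seq_along(kept),
                     function(i) kept[[i]]$case_id %||% sprintf("case_%03d", i), ""),
    label = factor(lab, levels = c("non-sufficient", "sufficient")),
    y = as.integer(lab == "sufficient"),
    tibble::as_tibble(mat)
  )
}

# split a feature table into X matrix and y vector
table_xy <- function(tbl) {
  meta <- intersect(c("case_id", "label", "y"), names(tbl))
  X <- as.matrix(tbl[, setdiff(names(tbl), meta), drop = FALSE])
  rownames(X) <- tbl$case_id
  list(X = X, y = tbl$y)
}

#' Write a feature table as CSV with a JSON config sidecar
#'
#' @param tbl Feature table from [extract_table()].
#' @param path CSV path; the sidecar is written as `<path>.json`.
#' @param config The [extraction_config()] used (stored in the sidecar).
#' @export
write_feature_table <- function(tbl, path, config = NULL) {
  utils::write.csv(tbl, path, row.names = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
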