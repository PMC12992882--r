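#' Evaluation report for a scored test set
#'
#' AUROC with a stratified percentile-bootstrap 95% CI, confusion counts at
#' the 0.5 probability threshold, and sensitivity/specificity/PPV/NPV each
#' with bootstrap CIs. Positive class = sufficient collaterals.
#'
#' @param scores Predicted probability of sufficient collaterals.
#' @param labels 0/1 or factor labels (sufficient = positive).
#' @param seed Bootstrap seed.
#' @param B Bootstrap replicates.
#' @param threshold Decision threshold for the hard label.
#' @return An `eval_report` list.
#' @export
eval_report <- function(scores, labels, seed = 1L, B = 2000L, threshold = 0.5) {
  y <- as.integer(as.factor(labels)) - 1L
  pred <- as.integer(scores >= threshold)
  cm <- confusion_metrics(tp = sum(pred == 1 & y == 1),
                          fp = sum(pred == 1 & y == 0),
                          tn = sum(pred == 0 & y == 0),
                          fn = sum(pred == 0 & y == 1))
  metric_fns <- list(
    auroc = auroc,
    sensitivity = function(s, yy) {
      p <- as.integer(s >= threshold)
      if (sum(yy == 1) == 0) NA_real_ else sum(p == 1 & yy == 1) / sum(yy == 1)
    },
    specificity = function(s, yy) {
      p <- as.integer(s >= threshold)
      if (sum(yy == 0) == 0) NA_real_ else sum(p == 0 & yy == 0) / sum(yy == 0)
    },
    ppv = function(s, yy) {
      p <- as.integer(s >= threshold)
      if (sum(p == 1) == 0) NA_real_ else sum(p == 1 & yy == 1) / sum(p == 1)
    },
    npv = function(s, yy) {
      p <- as.integer(s >= threshold)
      if (sum(p == 0) == 0) NA_real_ else sum(p == 0 & yy == 0) / sum(p == 0)
    }
  )
  cis <- lapply(names(metric_fns), function(nm) {
    bootstrap_ci(scores, y, metric_fns[[nm]], B = B,
                 seed = derive_seed(seed, paste0("ci-", nm)))
  })
  names(cis) <- names(metric_fns)
  structure(list(
    auroc = auroc(scores, y), auroc_ci = cis$auroc,
    sensitivity = cm$sensitivity, sensitivity_ci = cis$sensitivity,
    specificity = cm$specificity, specificity_ci = cis$specificity,
    ppv = cm$ppv, ppv_ci = cis$ppv,
    npv = cm$npv, npv_ci = cis$npv,
    counts = cm$counts, n = cm$n, seed = as.integer(seed),
    threshold = threshold,
    scores = scores, y = y
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%.3f (%.3f-%.3f)", round_half_up(v),
                                 round_half_up(ci[1]), round_half_up(ci[2]))
  cat("<eval_report> n =", x$n, "\n")
  cat("  AUROC       ", fmt(x$auroc, x$auroc_ci), "\n")
  cat("  Sensitivity ", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  Specificity ", fmt(x$specificity, x$specificity_ci), "\n")
  cat("  PPV         ", fmt(x$ppv, x$ppv_ci), "\n")
  cat("  NPV         ", fmt(x$npv, x$npv_ci), "\n")
  cat(sprintf("  counts: tp=%d fp=%d tn=%d fn=%d\n", x$counts$tp, x$counts$fp,
              x$counts$tn, x$counts$fn))
  invisible(x)
}

#' Run configuration for a full training run
#'
#' @param variant ROI scheme (`"A"`, `"B"`, `"C"`).
#' @param phantom A [phantom_config()] (cases generated on the fly) or
#'   `NULL` when `cases` are supplied to [run_train()] directly.
#' @param extraction An [extraction_config()].
#' @param train_ids,test_ids Disjoint case-id character vectors.
#' @param n_trials Tuning budget.
#' @param seed Master seed; every random stage derives its own stream.
#' @param out_dir Output directory root (a `run-<hash>` subdirectory is
#'   created so re-runs with a changed config never overwrite).
#' @return A `run_config` list.
#' @export
run_config <- function(variant, phantom = NULL,
                       extraction = extraction_config(),
                       train_ids, test_ids, n_trials = 50L, seed = 1L,
                       out_dir = NULL) {
  if (anyDuplicated(c(train_ids, test_ids))) {
    overlap <- intersect(train_ids, test_ids)
    dup <- unique(c(train_ids[duplicated(train_ids)],
                    test_ids[duplicated(test_ids)], overlap))
    stop("train/test case ids must be unique and disjoint; offending ids: ",
         paste(dup, collapse = ", "))
  }
  structure(list(variant = match.arg(variant, c("A", "B", "C")),
                 phantom = phantom, extraction = extraction,
                 train_ids = train_ids, test_ids = test_ids,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Seeded stratified train/test split of a cohort manifest
#'
#' @param manifest Cohort manifest (needs `case_id`, `label`).
#' @param test_fraction Fraction of each class assigned to the test set.
#' @param seed Seed.
#' @return List with `train_ids`, `test_ids`.
#' @export
stratified_split <- function(manifest, test_fraction = 0.25, seed = 1L) {
  with_seed(derive_seed(seed, "split"), {
    test <- unlist(lapply(split(manifest$case_id, manifest$label), function(ids) {
      sample(ids, round(length(ids) * test_fraction))
    }))
  })
  list(train_ids = setdiff(manifest$case_id, test),
       test_ids = sort(unname(test)))
}

#' Train a collateral classifier end-to-end
#'
#' Executes the full protocol on a cohort: feature extraction for the
#' configured ROI variant, train-fitted min-max scaling, cross-validated
#' importance ranking, correlation pruning, incremental subset search,
#' sequential hyperparameter tuning, the 1000-tree final fit, and held-out
#' evaluation. Every random stage is seeded from the master seed; stage
#' logs report input/output sizes.
#'
#' @param config A [run_config()].
#' @param cases Optional pre-generated case list (otherwise generated from
#'   `config$phantom`).
#' @param feature_table Optional pre-extracted feature table (skips
#'   extraction; must contain all train/test ids).
#' @param verbose Print stage logs.
#' @return A `collrad_run`: `model`, `selection`, `ranking`, `scaler`,
#'   `params`, `report` (held-out [eval_report()]), `train_report`
#'   (4-fold CV AUROCs), `config`, `config_hash`, `test_scores`.
#' @export
run_train <- function(config, cases = NULL, feature_table = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  seed <- config$seed
  if (is.null(feature_table)) {
    if (is.null(cases)) {
      if (is.null(config$phantom)) stop("run_train needs cases, a feature table or a phantom config")
      cohort <- generate_cohort(config$phantom)
      cases <- cohort$cases
      log_stage(verbose, "phantom", n = length(cases), t0 = t0)
    }
    ids <- vapply(cases, function(cc) cc$case_id, "")
    wanted <- c(config$train_ids, config$test_ids)
    missing_ids <- setdiff(wanted, ids)
    if (length(missing_ids)) {
      stop("case ids not found in cohort: ", paste(missing_ids, collapse = ", "))
    }
    feature_table <- extract_table(cases[ids %in% wanted], config$variant,
                                   config$extraction, verbose = verbose)
    log_stage(verbose, "extract", rows = nrow(feature_table),
              cols = ncol(feature_table) - 3L, t0 = t0)
  }
  tr_tbl <- feature_table[feature_table$case_id %in% config$train_ids, ]
  te_tbl <- feature_table[feature_table$case_id %in% config$test_ids, ]
  if (nrow(tr_tbl) == 0) stop("no training rows after id filtering")

  sel <- select_features(tr_tbl, seed = derive_seed(seed, "selection"))
  log_stage(verbose, "selection", candidates = length(sel$pruned),
            chosen = sel$selection$k, t0 = t0)

  xy_tr <- table_xy(tr_tbl)
  X_tr <- apply_minmax(xy_tr$X, sel$scaler)[, sel$selection$features, drop = FALSE]
  params <- bayes_tune(X_tr, xy_tr$y, n_trials = config$n_trials,
                       seed = derive_seed(seed, "tuning"))
  log_stage(verbose, "tuning", trials = config$n_trials,
            cv_auroc = round(attr(params, "best_value"), 3), t0 = t0)

  model <- fit_final(X_tr, xy_tr$y, params, seed = derive_seed(seed, "final"))
  log_stage(verbose, "final-fit", trees = model$num_trees,
            cv4 = round(mean(model$cv_report), 3), t0 = t0)

  report <- NULL
  test_scores <- NULL
  if (nrow(te_tbl) > 0) {
    xy_te <- table_xy(te_tbl)
    X_te <- apply_minmax(xy_te$X, sel$scaler)[, sel$selection$features, drop = FALSE]
    test_scores <- tibble::tibble(case_id = te_tbl$case_id,
                                  y = xy_te$y,
                                  prob_sufficient = predict_prob(model, X_te))
    report <- eval_report(test_scores$prob_sufficient, xy_te$y,
                          seed = derive_seed(seed, "bootstrap"))
    log_stage(verbose, "evaluate", n_test = nrow(te_tbl),
              auroc = round(report$auroc, 3), t0 = t0)
  }

  chash <- config_hash(list(config$variant, unclass(config$extraction),
                            config$train_ids, config$test_ids,
                            config$n_trials, seed))
  run <- structure(list(model = model, selection = sel$selection,
                        ranking = sel$ranking, scaler = sel$scaler,
                        params = params, report = report,
                        train_report = model$cv_report,
                        test_scores = test_scores,
                        config = config, config_hash = chash),
                   class = "collrad_run")
  if (!is.null(config$out_dir)) persist_run(run, config$out_dir)
  run
}

persist_run <- function(run, out_dir) {
  dir <- file.path(out_dir, paste0("run-", run$config_hash))
  if (dir.exists(dir)) {
    stop("output directory ", dir, " already exists; refusing to overwrite a prior run")
  }
  dir.create(dir, recursive = TRUE)
  write_selection_json(run$selection, file.path(dir, "selection.json"),
                       extra = list(config_hash = run$config_hash))
  save_model(run$model, file.path(dir, "model.rds"))
  slim <- run[c("model", "selection", "scaler", "params", "config",
                "config_hash")]
  class(slim) <- "collrad_run"
  saveRDS(slim, file.path(dir, "run.rds"), version = 2)
  if (!is.null(run$report)) {
    r <- run$report
    jsonlite::write_json(list(
      auroc = r$auroc, auroc_ci = unname(r$auroc_ci),
      sensitivity = r$sensitivity, specificity = r$specificity,
      ppv = r$ppv, npv = r$npv, counts = r$counts, n = r$n,
      config_hash = run$config_hash
    ), file.path(dir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @export
print.collrad_run <- function(x, ...) {
  cat(sprintf("<collrad_run> variant %s, %d features selected, config %s\n",
              x$config$variant, x$selection$k, x$config_hash))
  if (!is.null(x$report)) {
    cat(sprintf("  held-out AUROC %.3f (n = %d)\n", x$report$auroc, x$report$n))
  }
  invisible(x)
}

#' Score new cases with a persisted model
#'
#' Extracts the model's ROI variant features from each case, applies the
#' stored scaler and feature schema, and returns per-case probabilities and
#' dichotomized calls. An empty case list yields an empty (but well-formed)
#' tibble.
#'
#' @param run A `collrad_run` (or list with `model`, `scaler`, `selection`,
#'   `config`).
#' @param cases List of cases (as from [generate_cohort()] or
#'   [read_cohort()]).
#' @return Tibble: `case_id`, `prob_sufficient`, `label`.
#' @export
run_score <- function(run, cases) {
  if (length(cases) == 0) {
    return(tibble::tibble(case_id = character(), prob_sufficient = numeric(),
                          label = factor(character(),
                                         levels = c("non-sufficient", "sufficient"))))
  }
  tbl <- extract_table(cases, run$config$variant, run$config$extraction)
  xy <- table_xy(tbl)
  X <- apply_minmax(xy$X, run$scaler)[, run$selection$features, drop = FALSE]
  pred <- stats::predict(run$model, X)
  tibble::tibble(case_id = tbl$case_id, pred)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir Directory with `<id>_*.nii.gz` volumes and `manifest.csv`.
#' @return List with `cases` and `manifest`, mirroring [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(utils::read.csv(file.path(dir, "manifest.csv"),
                                                stringsAsFactors = FALSE))
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$case_id[i]
    base <- file.path(dir, id)
    atlas <- read_volume(paste0(base, "_territory.nii.gz"), labels = TRUE,
                         label_map = territory_label_map())
    comp <- build_mca_composite(atlas)
    dims <- dim(comp$mca_terr_L$data)
    mca_comp <- array(0L, dims)
    mca_comp[comp$mca_terr_L$data != 0L] <- 1L
    mca_comp[comp$mca_terr_R$data != 0L] <- 2L
    structure(list(
      case_id = id,
      image = read_volume(paste0(base, "_cta.nii.gz")),
      vessel_mask = read_volume(paste0(base, "_vessels.nii.gz"), labels = TRUE,
                                label_map = c(vessel = 1L)),
      cow_mask = read_volume(paste0(base, "_cow.nii.gz"), labels = TRUE,
                             label_map = cow_label_map()),
      territory_atlas = atlas,
      mca_territory = label_volume(mca_comp, spacing = atlas$spacing,
                                   affine = atlas$affine,
                                   label_map = c("mca_terr_L" = 1L,
                                                 "mca_terr_R" = 2L)),
      tan_score = manifest$tan_score[i],
      label = manifest$label[i],
      occluded_side = manifest$occluded_side[i],
      fill_fraction = manifest$fill_fraction[i],
      seed = manifest$seed[i]
    ), class = "phantom_case")
  })
  list(cases = cases, manifest = manifest)
}

#' DeLong comparison record for two models scored on the same cases
#'
#' @param scores_a,scores_b Paired probability scores.
#' @param labels Shared 0/1 labels.
#' @param alpha Significance level (default 0.05).
#' @param names Length-2 model names for the record.
#' @return Tibble with both AUROCs, `z`, `p` and `significant`.
#' @export
compare_models <- function(scores_a, scores_b, labels, alpha = 0.05,
                           names = c("model_a", "model_b")) {
  dl <- delong_test(scores_a, scores_b, labels)
  tibble::tibble(
    model_a = names[1], model_b = names[2],
    auroc_a = dl$auc_a, auroc_b = dl$auc_b,
    z = dl$z, p = dl$p, significant = dl$p < alpha
  )
}
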