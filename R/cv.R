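#' Cross-validation plan
#'
#' `"jackknife"` is leave-one-out: every record is tested once by a model
#' trained on all the others. `"kfold"` is stratified k-fold with
#' seed-controlled shuffling. `tuning` decides where the (C, gamma) grid
#' search runs: `"global"` tunes once on the full dataset before the CV loop
#' (the cheaper protocol usual in this literature; the test records leak into
#' hyperparameter selection, and the report says so), `"per_fold"` re-tunes
#' inside each training split (leakage-free, slower).
#'
#' @param scheme `"jackknife"` or `"kfold"`.
#' @param k number of folds (kfold only).
#' @param seed integer seed for fold construction and tuning.
#' @param tuning `"global"` or `"per_fold"`.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(scheme = c("jackknife", "kfold"), k = 5L, seed = 1L,
                    tuning = c("global", "per_fold")) {
  scheme <- match.arg(scheme)
  tuning <- match.arg(tuning)
  k <- as.integer(k)
  if (scheme == "kfold" && k < 2) stopf("kfold needs k >= 2")
  out <- list(scheme = scheme, k = k, seed = as.integer(seed), tuning = tuning)
  class(out) <- "cv_plan"
  out
}

#' Cross-validated evaluation of the full pipeline
#'
#' Encodes the dataset, then for each fold fits the min-max scaler and the
#' RBF-SVM on the training split only and predicts the held-out records, so
#' every record is predicted exactly once by a model that never saw it.
#' Pooled predictions give the confusion counts and the Sn/Sp/Qa/MCC report.
#'
#' @param x a labelled [peptide_set()] with both classes present.
#' @param parts,alphabet,normalization,scale,lambda,atoms,form encoder
#'   configuration, see [encode_features()].
#' @param c_grid,gamma_grid hyperparameter grids, see [grid_search()];
#'   singleton grids fix (C, gamma) without searching.
#' @param grid_folds folds used inside the tuning grid search.
#' @param plan a [cv_plan()].
#' @return An object of class `acp_cv`: list with `metrics` (a
#'   [compute_metrics()] report), `predictions` (data frame: id, truth,
#'   predicted, decision, fold), `plan`, `tuning` (chosen (C, gamma), global
#'   mode) or `fold_tuning` (per-fold choices), `folds` (per-fold test ids
#'   and scaler ranges), and the encoder `meta`.
#' @export
run_cv <- function(x, parts = c("aac", "raac", "acacs"),
                   alphabet = raac_alphabet(), normalization = "L",
                   scale = default_shift_scale(), lambda = 5L,
                   atoms = colnames(scale$values), form = "sqdiff",
                   c_grid = default_c_grid(), gamma_grid = default_gamma_grid(),
                   grid_folds = 5L, plan = cv_plan()) {
  stopifnot(inherits(x, "peptide_set"), inherits(plan, "cv_plan"))
  labels <- x$label
  if (anyNA(labels)) stopf("run_cv requires every record to be labelled")
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  m <- encode_features(x, parts = parts, alphabet = alphabet,
                       normalization = normalization, scale = scale,
                       lambda = lambda, atoms = atoms, form = form)
  meta <- attr(m, "meta")
  m <- unclass(m); attr(m, "meta") <- NULL

  fold_id <- if (plan$scheme == "jackknife") seq_len(nrow(x))
             else stratified_folds(labels, plan$k, plan$seed)

  tuned <- NULL
  if (plan$tuning == "global") {
    tuned <- if (length(c_grid) == 1 && length(gamma_grid) == 1)
      list(C = c_grid, gamma = gamma_grid, accuracy = NA_real_)
    else grid_search(m, labels, c_grid, gamma_grid, folds = grid_folds,
                     seed = plan$seed)
  }

  n <- nrow(x)
  pred <- character(n); dec <- numeric(n)
  fold_info <- list()
  fold_tuning <- list()
  for (f in sort(unique(fold_id))) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    if (plan$tuning == "per_fold") {
      ft <- if (length(c_grid) == 1 && length(gamma_grid) == 1)
        list(C = c_grid, gamma = gamma_grid)
      else grid_search(m[tr, , drop = FALSE], labels[tr], c_grid, gamma_grid,
                       folds = grid_folds, seed = plan$seed)
      C <- ft$C; gamma <- ft$gamma
      fold_tuning[[length(fold_tuning) + 1L]] <- list(fold = f, C = C, gamma = gamma)
    } else {
      C <- tuned$C; gamma <- tuned$gamma
    }
    scaler <- fit_scaler(m[tr, , drop = FALSE])
    model <- svm_train(m[tr, , drop = FALSE], labels[tr], C = C, gamma = gamma,
                       scaler = scaler)
    p <- predict(model, m[te, , drop = FALSE], type = "both")
    pred[te] <- p$label
    dec[te] <- p$decision
    fold_info[[length(fold_info) + 1L]] <-
      list(fold = f, test_ids = x$id[te],
           scaler_min = scaler$min, scaler_max = scaler$max)
  }

  predictions <- data.frame(id = x$id, truth = labels, predicted = pred,
                            decision = dec, fold = fold_id,
                            stringsAsFactors = FALSE)
  metrics <- compute_metrics(tally_confusion(labels, pred))
  out <- list(metrics = metrics, predictions = predictions, plan = plan,
              tuning = tuned, fold_tuning = if (length(fold_tuning)) fold_tuning,
              folds = fold_info, meta = meta, n = n)
  class(out) <- "acp_cv"
  out
}

#' @export
print.acp_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation (%s tuning) on %d records\n",
              if (x$plan$scheme == "jackknife") "jackknife"
              else sprintf("%d-fold stratified", x$plan$k),
              x$plan$tuning, x$n))
  if (!is.null(x$tuning))
    cat(sprintf("  selected C = %g, gamma = %g%s\n", x$tuning$C, x$tuning$gamma,
                if (x$plan$tuning == "global")
                  " (tuned on the full data; test records leak into selection)"
                else ""))
  print(x$metrics)
  invisible(x)
}

#' Write a CV report to JSON and per-record predictions to TSV
#'
#' The JSON carries rounded and unrounded metrics, confusion counts, the CV
#' plan, tuning mode and chosen hyperparameters; the TSV has one row per
#' record (id, true label, predicted label, decision value, fold index).
#'
#' @param cv an `acp_cv` from [run_cv()].
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the report list written as JSON.
#' @export
write_cv_report <- function(cv, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(cv, "acp_cv"))
  mt <- cv$metrics
  report <- list(
    scheme = cv$plan$scheme,
    k = if (cv$plan$scheme == "kfold") cv$plan$k,
    seed = cv$plan$seed,
    tuning_mode = cv$plan$tuning,
    leakage_note = if (cv$plan$tuning == "global")
      "hyperparameters tuned on the full dataset before CV; test records leak into selection",
    selected = if (!is.null(cv$tuning)) list(C = cv$tuning$C, gamma = cv$tuning$gamma),
    counts = unclass(mt$counts),
    metrics = list(sn = mt$sn, sp = mt$sp, qa = mt$qa, mcc = mt$mcc),
    metrics_rounded = mt$rounded,
    encoder = cv$meta)
  report <- report[!vapply(report, is.null, logical(1))]
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(tsv_path))
    utils::write.table(cv$predictions, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(report)
}
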