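#' Min-max feature scaling fit on training data
#'
#' Records per-feature minima and maxima from the supplied rows only; applying
#' maps x to (x - min)/(max - min). Constant features map to 0; values outside
#' the training range extrapolate beyond [0, 1] (no clipping).
#'
#' @param x numeric feature matrix with column names.
#' @return An `acp_scaler`: list with `min`, `max`, `feature_names`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stopf("cannot fit a scaler on an empty matrix")
  if (is.null(colnames(x))) stopf("feature matrix must have column names")
  out <- list(min = apply(x, 2, min), max = apply(x, 2, max),
              feature_names = colnames(x))
  class(out) <- "acp_scaler"
  out
}

#' @rdname fit_scaler
#' @param scaler an `acp_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "acp_scaler"))
  x <- as.matrix(x)
  check_feature_names(colnames(x), scaler$feature_names)
  rng <- scaler$max - scaler$min
  scaled <- sweep(x, 2, scaler$min)
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  scaled
}

check_feature_names <- function(got, want) {
  if (is.null(got)) stopf("feature matrix must have column names")
  if (length(got) != length(want) || any(got != want)) {
    bad <- which(got[seq_len(min(length(got), length(want)))] !=
                 want[seq_len(min(length(got), length(want)))])
    if (length(bad) > 0)
      stopf("feature mismatch at column %d: got '%s', expected '%s'",
            bad[1], got[bad[1]], want[bad[1]])
    stopf("feature count mismatch: got %d, expected %d",
          length(got), length(want))
  }
  invisible(TRUE)
}

as_pm1 <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stopf("labels contain NA")
  if (!all(labels %in% c("positive", "negative")))
    stopf("labels must be 'positive' or 'negative'")
  ifelse(labels == "positive", 1L, -1L)
}

#' Train an RBF-kernel support-vector classifier
#'
#' Binary C-SVC with kernel exp(-gamma * ||x - x'||^2), trained by sequential
#' minimal optimization. Features are min-max scaled with parameters fit on
#' the training rows (pass a pre-fit `scaler` to reuse one). The positive
#' class is "anticancer"; a decision value of exactly 0 classifies as
#' positive.
#'
#' @param x numeric feature matrix (rows = samples, named columns).
#' @param labels character/factor vector of `"positive"`/`"negative"`, one per
#'   row; both classes must be present.
#' @param C regularization parameter (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param scaler optional pre-fit [fit_scaler()] result; default fits on `x`.
#' @param tol SMO stopping tolerance on the violating-pair gap.
#' @return An `acp_svm` model object.
#' @seealso [grid_search()], [predict.acp_svm()]
#' @export
svm_train <- function(x, labels, C, gamma, scaler = NULL, tol = 1e-3) {
  x <- as.matrix(x)
  y <- as_pm1(labels)
  if (length(y) != nrow(x)) stopf("one label per row required")
  if (length(unique(y)) < 2) stopf("training data must contain both classes")
  if (C <= 0 || gamma <= 0) stopf("C and gamma must be positive")
  if (is.null(scaler)) scaler <- fit_scaler(x)
  check_feature_names(colnames(x), scaler$feature_names)
  xs <- apply_scaler(scaler, x)
  fit <- smo_train_cpp(xs, y, C, gamma, tol)
  out <- list(alpha = fit$alpha, b = fit$b, y = y, X = xs,
              n_sv = fit$n_sv, iter = fit$iter,
              C = C, gamma = gamma, scaler = scaler,
              feature_names = scaler$feature_names,
              format = "acpep-model-v1")
  class(out) <- "acp_svm"
  out
}

#' @export
print.acp_svm <- function(x, ...) {
  cat(sprintf("RBF-SVM: C = %g, gamma = %g, %d/%d support vectors\n",
              x$C, x$gamma, x$n_sv, length(x$alpha)))
  invisible(x)
}

#' Predict with a trained SVM
#'
#' @param object an `acp_svm` from [svm_train()].
#' @param newdata feature matrix whose columns match training exactly (order
#'   and names); may have zero rows.
#' @param type `"class"` for labels, `"decision"` for raw decision values,
#'   `"both"` for a data frame of label and decision value.
#' @param ... unused.
#' @return Per `type`: character vector of labels (decision >= 0 is
#'   positive), numeric decision values, or a data frame with both.
#' @export
predict.acp_svm <- function(object, newdata, type = c("class", "decision", "both"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  check_feature_names(colnames(newdata), object$feature_names)
  if (nrow(newdata) == 0) {
    dec <- numeric(0)
  } else {
    xs <- apply_scaler(object$scaler, newdata)
    dec <- smo_decision_cpp(object$X, object$y, object$alpha, object$b,
                            object$gamma, xs)
  }
  lab <- ifelse(dec >= 0, "positive", "negative")
  switch(type,
         class = stats::setNames(lab, rownames(newdata)),
         decision = stats::setNames(dec, rownames(newdata)),
         both = data.frame(id = rownames(newdata) %||% seq_along(dec),
                           label = lab, decision = dec,
                           stringsAsFactors = FALSE, row.names = NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default hyperparameter grids
#'
#' The conventional exponential grids for RBF-SVM model selection:
#' C in 2^(-5), 2^(-3), ..., 2^15 and gamma in 2^(-15), 2^(-13), ..., 2^3.
#'
#' @return numeric vector of grid values.
#' @export
default_c_grid <- function() 2^seq(-5, 15, by = 2)

#' @rdname default_c_grid
#' @export
default_gamma_grid <- function() 2^seq(-15, 3, by = 2)

#' Grid search for (C, gamma) by k-fold cross-validated accuracy
#'
#' Evaluates every pair on the same seed-determined stratified folds (the
#' scaler is re-fit inside each training split) and returns the pair with the
#' highest mean fold accuracy. Ties break to the smallest C, then the
#' smallest gamma. Deterministic given `seed`.
#'
#' @param x numeric feature matrix.
#' @param labels `"positive"`/`"negative"` per row; both classes required.
#' @param c_grid,gamma_grid candidate values (sorted internally).
#' @param folds number of CV folds (k >= 2).
#' @param seed integer seed controlling fold assignment.
#' @return list with `C`, `gamma`, `accuracy` (mean fold accuracy of the
#'   winner) and `table` (accuracy for every pair).
#' @export
grid_search <- function(x, labels, c_grid = default_c_grid(),
                        gamma_grid = default_gamma_grid(), folds = 5L,
                        seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  y <- as_pm1(labels)
  if (length(unique(y)) < 2) stopf("grid search needs both classes")
  if (folds < 2) stopf("folds must be >= 2")
  c_grid <- sort(unique(c_grid))
  gamma_grid <- sort(unique(gamma_grid))
  fold_id <- stratified_folds(labels, folds, seed)
  grid <- expand.grid(gamma = gamma_grid, C = c_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      model <- svm_train(x[tr, , drop = FALSE], labels[tr],
                         C = grid$C[g], gamma = grid$gamma[g])
      pred <- predict(model, x[!tr, , drop = FALSE], type = "class")
      correct <- correct + sum(pred == labels[!tr])
    }
    acc[g] <- correct / length(labels)
  }
  # ascending (C, gamma) iteration + strict ">" keeps the smallest tie-winner
  best <- 1L
  for (g in seq_len(nrow(grid))) if (acc[g] > acc[best]) best <- g
  list(C = grid$C[best], gamma = grid$gamma[best], accuracy = acc[best],
       table = cbind(grid, accuracy = acc))
}

# Stratified fold ids: within each class, a seed-shuffled round-robin
# assignment to folds 1..k. Errors if k exceeds a class size.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  n <- length(labels)
  fold_id <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (k > length(idx))
        stopf("k = %d exceeds the size of class '%s' (%d)", k, cl, length(idx))
      fold_id[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold_id
}

#' Save / load a trained model
#'
#' Single-file persistence with a format tag checked on load.
#'
#' @param model an `acp_svm` or `acp_model`.
#' @param path file path.
#' @return `path` (save) or the model object (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("acp_svm", "acp_model")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: '%s'", path)
  model <- readRDS(path)
  fmt <- if (inherits(model, "acp_model")) model$svm$format else model$format
  if (!identical(fmt, "acpep-model-v1"))
    stopf("'%s' is not a recognized acpep model file", path)
  model
}
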