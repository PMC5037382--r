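#' Fit an anticancer-peptide classifier
#'
#' The front-door fitting function: encodes a labelled peptide set with the
#' selected hybrid composition features (AAC, reduced-alphabet dipeptides,
#' chemical-shift auto-covariance), grid-searches the RBF-SVM
#' hyperparameters (C, gamma) by stratified k-fold accuracy, and trains the
#' final model on all records with min-max scaling fit on the same records.
#'
#' @param x a labelled [peptide_set()] containing both classes.
#' @param parts ordered subset of `"aac"`, `"raac"`, `"acacs"`.
#' @param alphabet,normalization,scale,lambda,atoms,form encoder parameters,
#'   see [encode_features()].
#' @param c_grid,gamma_grid hyperparameter candidates; singleton grids skip
#'   the search.
#' @param grid_folds folds for the tuning search.
#' @param seed integer seed (fold construction in the search).
#' @return An object of class `acp_model` with components `svm` (the trained
#'   [svm_train()] object), `tuning`, `meta` (encoder config), `levels`,
#'   `call`, and `training` (fitted labels/decision values on the training
#'   records).
#' @examples
#' set <- simulate_peptides(synthetic_spec(30, 30, effect = 0.3, seed = 1))
#' fit <- acp_fit(set, parts = "aac", c_grid = 2, gamma_grid = 0.5)
#' fit
#' @export
acp_fit <- function(x, parts = c("aac", "raac", "acacs"),
                    alphabet = raac_alphabet(), normalization = "L",
                    scale = default_shift_scale(), lambda = 5L,
                    atoms = colnames(scale$values), form = "sqdiff",
                    c_grid = default_c_grid(), gamma_grid = default_gamma_grid(),
                    grid_folds = 5L, seed = 1L) {
  stopifnot(inherits(x, "peptide_set"))
  if (anyNA(x$label)) stopf("every record must be labelled to fit a model")
  m <- encode_features(x, parts = parts, alphabet = alphabet,
                       normalization = normalization, scale = scale,
                       lambda = lambda, atoms = atoms, form = form)
  meta <- attr(m, "meta")
  m <- unclass(m); attr(m, "meta") <- NULL
  tuning <- if (length(c_grid) == 1 && length(gamma_grid) == 1)
    list(C = c_grid, gamma = gamma_grid, accuracy = NA_real_)
  else grid_search(m, x$label, c_grid, gamma_grid, folds = grid_folds,
                   seed = seed)
  svm <- svm_train(m, x$label, C = tuning$C, gamma = tuning$gamma)
  fitted <- predict(svm, m, type = "both")
  fitted$truth <- x$label
  out <- list(svm = svm, tuning = tuning, meta = meta,
              encoder_args = list(alphabet = alphabet,
                                  normalization = normalization, scale = scale,
                                  lambda = lambda,
                                  atoms = meta$atoms %||% NULL, form = form),
              seed = as.integer(seed), training = fitted, call = match.call())
  class(out) <- "acp_model"
  out
}

# encode new peptides with the configuration stored in a fitted model
encode_like <- function(object, newdata) {
  ea <- object$encoder_args
  m <- encode_features(newdata, parts = object$meta$parts,
                       alphabet = ea$alphabet, normalization = ea$normalization %||% "L",
                       scale = ea$scale, lambda = ea$lambda %||% 5L,
                       atoms = ea$atoms %||% colnames(ea$scale$values),
                       form = ea$form %||% "sqdiff")
  unclass(m)
}

#' @export
print.acp_model <- function(x, ...) {
  cat("Anticancer-peptide classifier (RBF-SVM over hybrid compositions)\n")
  cat(sprintf("  features: %s (%d columns)\n",
              paste(x$meta$parts, collapse = " + "),
              length(x$svm$feature_names)))
  cat(sprintf("  C = %g, gamma = %g; %d/%d support vectors\n",
              x$svm$C, x$svm$gamma, x$svm$n_sv, length(x$svm$alpha)))
  invisible(x)
}

#' @export
summary.acp_model <- function(object, ...) {
  tr <- object$training
  metrics <- compute_metrics(tally_confusion(tr$truth, tr$label))
  out <- list(model = object, training_metrics = metrics,
              n = nrow(tr), n_pos = sum(tr$truth == "positive"),
              n_neg = sum(tr$truth == "negative"))
  class(out) <- "summary.acp_model"
  out
}

#' @export
print.summary.acp_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  trained on %d records (%d positive, %d negative)\n",
              x$n, x$n_pos, x$n_neg))
  if (!is.null(x$model$tuning) && is.finite(x$model$tuning$accuracy %||% NA))
    cat(sprintf("  grid-search CV accuracy: %.4f\n", x$model$tuning$accuracy))
  cat("  training-set (resubstitution) performance:\n  ")
  print(x$training_metrics)
  invisible(x)
}

#' Predict anticancer activity for new peptides
#'
#' @param object an `acp_model` from [acp_fit()].
#' @param newdata a [peptide_set()] (encoded with the model's stored feature
#'   configuration) or a feature matrix whose columns match training.
#' @param type `"class"`, `"decision"` or `"both"`; see [predict.acp_svm()].
#' @param ... unused.
#' @return See [predict.acp_svm()]; decision value >= 0 means "anticancer".
#' @export
predict.acp_model <- function(object, newdata, type = c("class", "decision", "both"),
                              ...) {
  type <- match.arg(type)
  m <- if (inherits(newdata, "peptide_set")) {
    if (nrow(newdata) == 0)
      matrix(numeric(0), 0, length(object$svm$feature_names),
             dimnames = list(NULL, object$svm$feature_names))
    else encode_like(object, newdata)
  } else as.matrix(newdata)
  predict(object$svm, m, type = type)
}

#' Decision-value plot for a fitted classifier
#'
#' Strip chart of training decision values by true class, with the decision
#' boundary at 0. A well-separated fit shows the classes on opposite sides.
#'
#' @param x an `acp_model`.
#' @param ... passed to [graphics::stripchart()].
#' @return `x`, invisibly.
#' @export
plot.acp_model <- function(x, ...) {
  tr <- x$training
  graphics::stripchart(decision ~ factor(truth, c("negative", "positive")),
                       data = tr, vertical = TRUE, method = "jitter",
                       pch = 16, col = c("grey40", "firebrick"),
                       ylab = "SVM decision value", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
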