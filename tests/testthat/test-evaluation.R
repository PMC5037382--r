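test_that("metrics reproduce published-table arithmetic from counts", {
  # combined-feature jackknife row: Sn 89.86, Sp 96.12, MCC 0.867
  m <- compute_metrics(confusion_counts(tp = 124, fn = 14, fp = 8, tn = 198))
  expect_equal(m$rounded$sn, 89.86)
  expect_equal(m$rounded$sp, 96.12)
  expect_equal(m$rounded$mcc, 0.867)

  # acACS-only row: Qa 82.56, MCC 0.633
  m2 <- compute_metrics(confusion_counts(tp = 98, fn = 40, fp = 20, tn = 186))
  expect_equal(m2$rounded$qa, 82.56)
  expect_equal(m2$rounded$mcc, 0.633)

  perfect <- compute_metrics(confusion_counts(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(perfect$sn, 100)
  expect_equal(perfect$sp, 100)
  expect_equal(perfect$qa, 100)
  expect_equal(perfect$mcc, 1)

  expect_error(confusion_counts(-1, 0, 0, 5), "non-negative")
  expect_error(compute_metrics(confusion_counts(0, 0, 1, 1)), "at least one")
})

test_that("an all-one-class prediction yields MCC 0 with a warning flag", {
  expect_warning(m <- compute_metrics(confusion_counts(tp = 5, fn = 0,
                                                       fp = 5, tn = 0)),
                 "MCC")
  expect_equal(m$mcc, 0)
  expect_true(m$mcc_undefined)
})

test_that("confusion counts are recoverable from printed Sn/Sp", {
  cc <- recover_confusion(89.86, 96.12, 138, 206)
  expect_equal(cc$TP, 124)
  expect_equal(cc$TN, 198)
  expect_true(attr(cc, "consistent"))

  cc2 <- recover_confusion(87.68, 94.66, 138, 206)
  expect_equal(cc2$TP, 121)
  expect_equal(cc2$TN, 195)

  cc3 <- recover_confusion(100, 100, 17, 23)
  expect_equal(cc3$TP, 17)
  expect_equal(cc3$TN, 23)
  expect_equal(cc3$FN + cc3$FP, 0)

  expect_error(recover_confusion(101, 50, 10, 10), "\\[0, 100\\]")
  expect_warning(recover_confusion(50, 50, 3, 3), "do not reproduce")
})

test_that("metrics agree with a brute-force tally oracle on random predictions", {
  set.seed(201)
  for (i in 1:1000) {
    n <- sample(4:60, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    pred <- sample(c("positive", "negative"), n, replace = TRUE)
    # independent per-record tally
    tp <- 0; fn <- 0; fp <- 0; tn <- 0
    for (j in seq_len(n)) {
      if (truth[j] == "positive") {
        if (pred[j] == "positive") tp <- tp + 1 else fn <- fn + 1
      } else {
        if (pred[j] == "positive") fp <- fp + 1 else tn <- tn + 1
      }
    }
    m <- suppressWarnings(
      compute_metrics(tally_confusion(truth, pred)))
    expect_equal(m$counts$TP, tp)
    expect_equal(m$counts$TN, tn)
    expect_equal(m$sn, 100 * tp / (tp + fn))
    expect_equal(m$sp, 100 * tn / (tn + fp))
    expect_equal(m$qa, 100 * (tp + tn) / n)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})

test_that("Qa is the prevalence-weighted mean of Sn and Sp", {
  set.seed(202)
  for (i in 1:50) {
    cc <- confusion_counts(tp = sample(0:40, 1), fn = sample(1:40, 1),
                           fp = sample(1:40, 1), tn = sample(0:40, 1))
    m <- suppressWarnings(compute_metrics(cc))
    n_pos <- cc$TP + cc$FN
    n_neg <- cc$TN + cc$FP
    expect_equal(m$qa, (n_pos * m$sn + n_neg * m$sp) / (n_pos + n_neg),
                 tolerance = 1e-12)
  }
})

test_that("MCC is bounded and behaves under class and prediction swaps", {
  set.seed(203)
  for (i in 1:50) {
    cc <- confusion_counts(tp = sample(1:40, 1), fn = sample(1:40, 1),
                           fp = sample(1:40, 1), tn = sample(1:40, 1))
    m <- compute_metrics(cc)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    # renaming the classes (truth and predictions together) swaps Sn and Sp
    # and leaves the symmetric MCC unchanged
    swapped <- compute_metrics(confusion_counts(tp = cc$TN, fn = cc$FP,
                                                fp = cc$FN, tn = cc$TP))
    expect_equal(swapped$mcc, m$mcc)
    expect_equal(swapped$sn, m$sp)
    expect_equal(swapped$sp, m$sn)
    # inverting every prediction negates MCC
    flipped <- compute_metrics(confusion_counts(tp = cc$FN, fn = cc$TP,
                                                fp = cc$TN, tn = cc$FP))
    expect_equal(flipped$mcc, -m$mcc)
  }
})

test_that("class-mean composition averages per-peptide AAC vectors", {
  d <- peptide_set(c("a", "b"), c("AA", "CC"), c("positive", "positive"))
  d <- peptide_set(c(d$id, "n1"), c(d$sequence, "GG"),
                   c(d$label, "negative"))
  cm <- class_mean_composition(d)
  expect_equal(unname(cm["positive", c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(cm["negative", "G"]), 1)

  d2 <- peptide_set(c("p", "q", "n"), c("AAAA", "AC", "GG"),
                    c("positive", "positive", "negative"))
  cm2 <- class_mean_composition(d2)
  expect_equal(unname(cm2["positive", "A"]), 0.75)
  expect_equal(unname(cm2["positive", "C"]), 0.25)
  expect_equal(unname(rowSums(cm2)), c(1, 1))

  single <- peptide_set(c("p", "n"), c("GLF", "KK"), c("positive", "negative"))
  expect_equal(class_mean_composition(single)["positive", ],
               encode_aac("GLF")[1, ])

  unlabelled <- peptide_set("x", "GG")
  expect_error(class_mean_composition(unlabelled), "empty")
})

test_that("jackknife CV tests every record exactly once", {
  set.seed(204)
  d <- simulate_peptides(synthetic_spec(3, 2, effect = 0, seed = 5))
  cv <- run_cv(d, parts = "aac", c_grid = 2, gamma_grid = 0.5,
               plan = cv_plan("jackknife"))
  expect_equal(nrow(cv$predictions), 5)
  expect_setequal(cv$predictions$id, d$id)
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
  expect_length(cv$folds, 5)                       # one model per record
  expect_true(all(vapply(cv$folds, function(f) length(f$test_ids), 1L) == 1))
  # pooled counts partition the classes
  cc <- cv$metrics$counts
  expect_equal(cc$TP + cc$FN, 3)
  expect_equal(cc$TN + cc$FP, 2)
})

test_that("fold scalers never see the held-out rows", {
  set.seed(205)
  d <- simulate_peptides(synthetic_spec(8, 8, effect = 0.2, seed = 9))
  cv <- run_cv(d, parts = "aac", c_grid = 2, gamma_grid = 0.5,
               plan = cv_plan("kfold", k = 4, seed = 2))
  m <- encode_features(d, parts = "aac")
  for (f in cv$folds) {
    tr_rows <- unclass(m)[setdiff(d$id, f$test_ids), , drop = FALSE]
    expect_equal(f$scaler_min, apply(tr_rows, 2, min))
    expect_equal(f$scaler_max, apply(tr_rows, 2, max))
  }
})

test_that("stratified k-fold validates k against class sizes", {
  d <- simulate_peptides(synthetic_spec(3, 10, effect = 0, seed = 1))
  expect_error(run_cv(d, parts = "aac", c_grid = 2, gamma_grid = 0.5,
                      plan = cv_plan("kfold", k = 5)),
               "exceeds")
})

test_that("strong compositional signal yields high k-fold accuracy", {
  d <- simulate_peptides(synthetic_spec(30, 30, effect = 0.3, seed = 11))
  cv <- run_cv(d, parts = "aac", c_grid = 2^c(0, 3, 6),
               gamma_grid = 2^c(-5, -3, -1),
               plan = cv_plan("kfold", k = 5, seed = 1))
  expect_gte(cv$metrics$qa, 85)
})

test_that("per-fold tuning records a hyperparameter choice per fold", {
  d <- simulate_peptides(synthetic_spec(6, 6, effect = 0.3, seed = 12))
  cv <- run_cv(d, parts = "aac", c_grid = c(1, 8), gamma_grid = 0.25,
               grid_folds = 2,
               plan = cv_plan("kfold", k = 3, seed = 4, tuning = "per_fold"))
  expect_length(cv$fold_tuning, 3)
  expect_null(cv$tuning)
  expect_true(all(vapply(cv$fold_tuning, function(t) t$C %in% c(1, 8), TRUE)))
})

test_that("CV reports serialize to JSON and TSV", {
  d <- simulate_peptides(synthetic_spec(5, 5, effect = 0, seed = 3))
  cv <- run_cv(d, parts = "aac", c_grid = 2, gamma_grid = 0.5,
               plan = cv_plan("jackknife"))
  js <- tempfile(fileext = ".json")
  tsv <- tempfile(fileext = ".tsv")
  write_cv_report(cv, js, tsv)
  rep <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(rep$counts$TP + rep$counts$FN + rep$counts$FP + rep$counts$TN, 10)
  expect_equal(rep$tuning_mode, "global")
  expect_match(rep$leakage_note, "leak")
  preds <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(preds), 10)
  expect_named(preds, c("id", "truth", "predicted", "decision", "fold"))
})
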