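test_that("baseline specs carry the tuned default hyperparameters", {
  lr <- baseline_spec("lr")
  expect_identical(lr$kind, "logistic-regression")
  expect_equal(lr$hyperparameters$C, 2.21)
  expect_identical(lr$hyperparameters$penalty, "l2")
  svm <- baseline_spec("support-vector-machine")
  expect_equal(svm$hyperparameters$gamma, 0.1)
  expect_equal(svm$hyperparameters$C, 10)
  xgb <- baseline_spec("xgb")
  expect_equal(xgb$hyperparameters$max_depth, 10)
  expect_equal(xgb$hyperparameters$gamma, 1.625)
  expect_equal(xgb$hyperparameters$min_child_weight, 1.0)
  expect_equal(xgb$hyperparameters$subsample, 1.0)
  expect_equal(xgb$hyperparameters$colsample_bytree, 1.0)
  rf <- baseline_spec("random-forest")
  expect_equal(rf$hyperparameters$n_estimators, 200)
  expect_equal(rf$hyperparameters$min_samples_leaf, 2)
  ert <- baseline_spec("ert")
  expect_equal(ert$hyperparameters$n_estimators, 1000)
  expect_equal(ert$hyperparameters$min_samples_leaf, 2)
  expect_error(baseline_spec("neural-net"), "unknown baseline kind")
  expect_error(baseline_spec("lr", ntree = 5), "unknown hyperparameter")
  # overrides are accepted
  expect_equal(baseline_spec("rf", n_estimators = 50)$
                 hyperparameters$n_estimators, 50)
})

test_that("baselines consume the same flattened features as the CNN input", {
  st <- tiny_study()
  dt <- merge(st$curated, st$sim$features, by = c("peptide", "allele"))[1:8, ]
  pairs <- encode_pairs(dt, st$sim$pseudo_table)
  norm <- list(ba = fit_minmax(c(0, 5)), tap = fit_minmax(c(-1, 1)))
  X <- neoimm:::baseline_features(pairs, norm)
  expect_identical(ncol(X), ncol(pairs$pep) + ncol(pairs$mhc) + 2L)
  expect_identical(unname(X[, seq_len(ncol(pairs$pep))]), pairs$pep)
  expect_identical(unname(X[, ncol(pairs$pep) + seq_len(ncol(pairs$mhc))]),
                   pairs$mhc)
  expect_equal(unname(X[, "ba_norm"]), apply_minmax(pairs$ic50, norm$ba))
})

test_that("every baseline trains, predicts in range and fills the report", {
  st <- tiny_study()
  models <- list()
  for (k in c("lr", "svm", "xgb", "rf")) {
    b <- train_baseline(k, st$curated, st$sim$features,
                        st$sim$pseudo_table,
                        seed = 3L)
    expect_true(b$trained)
    models[[k]] <- b
  }
  # smaller forest for speed; the default 1000 trees is exercised via spec
  models$ert <- train_baseline(
    build_baseline(baseline_spec("ert", n_estimators = 100)),
    st$curated, st$sim$features, st$sim$pseudo_table, seed = 3L)
  dt <- merge(st$curated, st$sim$features, by = c("peptide", "allele"))
  te <- dt[dt$split == "test"]
  for (k in setdiff(names(models), "svm")) {
    p <- predict(models[[k]], te, type = "prob")
    expect_true(all(p >= 0 & p <= 1), label = k)
    cls <- predict(models[[k]], te, type = "class")
    expect_true(all(cls %in% c(0L, 1L)), label = k)
  }
  # SVM: decision-function sign for the class, no probabilities by default
  expect_error(predict(models$svm, te, type = "prob"), "probability")
  expect_true(all(predict(models$svm, te, type = "class") %in% c(0L, 1L)))
  tab <- compare_models(models, st$curated, st$sim$features,
                        st$sim$pseudo_table)
  expect_identical(nrow(tab), 5L)
  expect_true(all(c("model", "accuracy", "precision", "recall") %in%
                    names(tab)))
  expect_false(anyNA(tab$accuracy))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
})

test_that("untrained baselines refuse to predict or be compared", {
  b <- build_baseline("lr")
  expect_error(predict(b, data.frame()), "untrained")
  st <- tiny_study()
  expect_error(compare_models(list(lr = b), st$curated, st$sim$features,
                              st$sim$pseudo_table), "untrained")
})
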