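# Classical ML baselines trained on the same representation as the CNN:
# the flattened one-hot peptide + MHC matrices concatenated with the
# normalized binding-affinity and TAP scalars.

baseline_kinds <- function() {
  c("logistic-regression", "support-vector-machine",
    "gradient-boosted-trees", "random-forest", "extremely-randomized-trees")
}

baseline_aliases <- c(
  lr = "logistic-regression", logreg = "logistic-regression",
  svm = "support-vector-machine",
  xgb = "gradient-boosted-trees", xgboost = "gradient-boosted-trees",
  gbt = "gradient-boosted-trees",
  rf = "random-forest",
  ert = "extremely-randomized-trees", extratrees = "extremely-randomized-trees"
)

# Tuned hyperparameter defaults per kind (10-fold CV optima on curated
# class I T-cell assay data); anything untuned falls back to the
# libraries' defaults.
baseline_defaults <- function(kind) {
  switch(kind,
    "logistic-regression" = list(penalty = "l2", C = 2.21),
    "support-vector-machine" = list(kernel = "rbf", gamma = 0.1, C = 10,
                                    probability = FALSE),
    "gradient-boosted-trees" = list(max_depth = 10, min_child_weight = 1.0,
                                    gamma = 1.625, subsample = 1.0,
                                    colsample_bytree = 1.0,
                                    nrounds = 100, eta = 0.3),
    "random-forest" = list(n_estimators = 200, min_samples_leaf = 2),
    "extremely-randomized-trees" = list(n_estimators = 1000,
                                        min_samples_leaf = 2)
  )
}

#' Specify a baseline classifier
#'
#' The five classical immunogenicity baselines with their tuned default
#' hyperparameters: logistic regression (L2, C = 2.21), RBF-kernel SVM
#' (gamma = 0.1, C = 10), gradient-boosted trees (max depth 10, min child
#' weight 1, gamma 1.625, subsample 1, column subsample 1), random forest
#' (200 trees, min leaf 2) and extremely randomized trees (1000 trees, min
#' leaf 2).
#'
#' @param kind One of `r paste(baseline_kinds(), collapse = ", ")` or a
#'   short alias (`lr`, `svm`, `xgb`, `rf`, `ert`).
#' @param ... Hyperparameter overrides (must name known hyperparameters).
#' @return A `neoimm_baseline_spec`.
#' @export
baseline_spec <- function(kind, ...) {
  if (kind %in% names(baseline_aliases)) kind <- baseline_aliases[[kind]]
  if (!kind %in% baseline_kinds()) {
    stop("unknown baseline kind '", kind, "'; expected one of: ",
         paste(baseline_kinds(), collapse = ", "), call. = FALSE)
  }
  hp <- baseline_defaults(kind)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(hp))
  if (length(bad) > 0L) {
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hp[names(overrides)] <- overrides
  structure(list(kind = kind, hyperparameters = hp),
            class = "neoimm_baseline_spec")
}

#' Build an untrained baseline classifier
#'
#' @param spec A [baseline_spec()] (or a kind string).
#' @return An untrained `neoimm_baseline`.
#' @export
build_baseline <- function(spec) {
  if (is.character(spec)) spec <- baseline_spec(spec)
  stopifnot(inherits(spec, "neoimm_baseline_spec"))
  structure(list(spec = spec, fit = NULL, trained = FALSE,
                 norm = NULL, hash = NULL, pseudo_table = NULL),
            class = "neoimm_baseline")
}

#' @export
print.neoimm_baseline <- function(x, ...) {
  hp <- x$spec$hyperparameters
  cat("Baseline classifier: ", x$spec$kind,
      if (isTRUE(x$trained)) " (trained)" else " (untrained)", "\n",
      "hyperparameters: ",
      paste(names(hp), unlist(hp), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Flattened feature matrix shared by all baselines: identical to the CNN's
# input after flattening, i.e. [pep one-hot | mhc one-hot | ba_norm | tap_norm].
baseline_features <- function(pairs, norm, ic50_scale = "raw") {
  ic50 <- pairs$ic50
  if (ic50_scale == "log") ic50 <- log10(pmax(ic50, 1e-12))
  X <- cbind(pairs$pep, pairs$mhc,
             apply_minmax(ic50, norm$ba),
             apply_minmax(pairs$tap, norm$tap))
  colnames(X) <- c(paste0("pep", seq_len(ncol(pairs$pep))),
                   paste0("mhc", seq_len(ncol(pairs$mhc))),
                   "ba_norm", "tap_norm")
  X
}

#' Train a baseline classifier
#'
#' Fits the classifier on the training split, using the same encoded
#' features and the same min-max normalization protocol as [train_cnn()].
#' Where the algorithm supports them, the `class_weights()` weights are
#' applied (toggle with `use_class_weights`).
#'
#' @param classifier An untrained `neoimm_baseline` from [build_baseline()].
#' @param curated Curated dataset with a `split` column.
#' @param features Feature table with `ic50_nm` and `tap`.
#' @param pseudo_table Pseudo-sequence table.
#' @param alphabet Encoding alphabet.
#' @param use_class_weights Apply class weights as sample weights.
#' @param seed Seed for the fit.
#' @param pad Peptide padding placement.
#' @return A trained `neoimm_baseline`.
#' @export
train_baseline <- function(classifier, curated, features, pseudo_table,
                           alphabet = aa_alphabet(), use_class_weights = TRUE,
                           seed = 42L, pad = "right") {
  if (is.character(classifier) || inherits(classifier, "neoimm_baseline_spec")) {
    classifier <- build_baseline(classifier)
  }
  stopifnot(inherits(classifier, "neoimm_baseline"))
  if (!"split" %in% names(curated)) {
    stop("dataset has no split column; call assign_splits() first",
         call. = FALSE)
  }
  dt <- merge(data.table::as.data.table(curated),
              data.table::as.data.table(features)[
                , c("peptide", "allele", "ic50_nm", "tap"), with = FALSE],
              by = c("peptide", "allele"))
  dt <- dt[dt$split == "train"]
  y <- as.numeric(dt$label)
  if (length(unique(y)) < 2L) {
    stop("empty class: training split must contain both labels",
         call. = FALSE)
  }
  ic50 <- dt$ic50_nm
  norm <- list(ba = fit_minmax(ic50), tap = fit_minmax(dt$tap))
  pairs <- encode_pairs(dt, pseudo_table, alphabet, pad = pad)
  X <- baseline_features(pairs, norm)
  w <- if (use_class_weights) {
    cw <- class_weights(sum(y == 1), sum(y == 0))
    ifelse(y == 1, cw$w_pos, cw$w_neg)
  } else rep(1, length(y))

  hp <- classifier$spec$hyperparameters
  fit <- with_seed(seed, switch(classifier$spec$kind,
    "logistic-regression" = {
      # sklearn-style C maps to lambda = 1 / (n * C) for the ridge penalty
      glmnet::glmnet(X, y, family = "binomial",
                     alpha = if (hp$penalty == "l2") 0 else 1,
                     lambda = 1 / (nrow(X) * hp$C), weights = w,
                     standardize = FALSE)
    },
    "support-vector-machine" = {
      cwts <- c("0" = 1, "1" = 1)
      if (use_class_weights) {
        cw <- class_weights(sum(y == 1), sum(y == 0))
        cwts <- c("0" = cw$w_neg, "1" = cw$w_pos)
      }
      e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                 gamma = hp$gamma, cost = hp$C,
                 probability = isTRUE(hp$probability),
                 class.weights = cwts, scale = FALSE)
    },
    "gradient-boosted-trees" = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth,
                      min_child_weight = hp$min_child_weight,
                      gamma = hp$gamma, subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      eta = hp$eta, nthread = 1L),
        data = dtrain, nrounds = hp$nrounds, verbose = 0
      )
    },
    "random-forest" = {
      randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                 ntree = hp$n_estimators,
                                 nodesize = hp$min_samples_leaf)
    },
    "extremely-randomized-trees" = {
      ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                     num.trees = hp$n_estimators,
                     min.node.size = hp$min_samples_leaf,
                     splitrule = "extratrees", probability = TRUE,
                     case.weights = w, num.threads = 1L,
                     seed = seed)
    }
  ))
  classifier$fit <- fit
  classifier$trained <- TRUE
  classifier$norm <- norm
  classifier$hash <- pairs$hash
  classifier$pseudo_table <- pseudo_table
  classifier$pad <- pad
  classifier
}

#' Predict with a trained baseline
#'
#' @param object A trained `neoimm_baseline`.
#' @param newdata Data.frame with `peptide`, `allele`, `ic50_nm`, `tap`, or
#'   a `neoimm_pairs` object.
#' @param type `"prob"` for a probability in \[0, 1\] (unavailable for the
#'   SVM unless built with `probability = TRUE`), `"score"` for a continuous
#'   ranking score (the SVM's decision value), `"class"` for the 0/1 call
#'   (threshold 0.5 on probability; decision-function sign for the SVM).
#' @param ... Unused.
#' @return Numeric vector (prob/score) or integer 0/1 vector (class).
#' @export
predict.neoimm_baseline <- function(object, newdata,
                                    type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) {
    stop("baseline classifier is untrained", call. = FALSE)
  }
  if (inherits(newdata, "neoimm_pairs")) {
    pairs <- newdata
  } else {
    pairs <- encode_pairs(newdata, object$pseudo_table,
                          pad = if (is.null(object$pad)) "right" else object$pad)
  }
  if (!is.null(object$hash) && !identical(pairs$hash, object$hash)) {
    stop("incompatible model: encoding checksum mismatch", call. = FALSE)
  }
  X <- baseline_features(pairs, object$norm)
  kind <- object$spec$kind
  if (kind == "support-vector-machine") {
    if (type == "prob") {
      if (!isTRUE(object$spec$hyperparameters$probability)) {
        stop("SVM was built without probability calibration; ",
             "use type = 'score' or 'class', or build with probability = TRUE",
             call. = FALSE)
      }
      pr <- stats::predict(object$fit, X, probability = TRUE)
      return(unname(attr(pr, "probabilities")[, "1"]))
    }
    pr <- stats::predict(object$fit, X, decision.values = TRUE)
    dv <- as.vector(attr(pr, "decision.values"))
    # e1071 orients the decision value towards the first factor level seen
    # in training; flip so larger = more likely positive
    if (colnames(attr(pr, "decision.values"))[1] == "0/1") dv <- -dv
    if (type == "score") return(dv)
    return(as.integer(dv > 0))
  }
  prob <- switch(kind,
    "logistic-regression" =
      as.vector(stats::predict(object$fit, X, type = "response")),
    "gradient-boosted-trees" =
      stats::predict(object$fit, xgboost::xgb.DMatrix(X)),
    "random-forest" =
      unname(stats::predict(object$fit, X, type = "prob")[, "1"]),
    "extremely-randomized-trees" =
      unname(stats::predict(object$fit, data = X,
                            num.threads = 1L)$predictions[, "1"])
  )
  switch(type, prob = prob, score = prob, class = as.integer(prob > 0.5))
}

#' Compare trained models on the test split
#'
#' Computes accuracy, precision and recall (score threshold 0.5; the SVM
#' uses its decision-function sign) for each trained model on the held-out
#' test split.
#'
#' @param models Named list of trained `neoimm_cnn` / `neoimm_baseline`
#'   models.
#' @param curated Curated dataset with a `split` column containing `"test"`.
#' @param features Feature table.
#' @param pseudo_table Pseudo-sequence table (used to encode once for all
#'   models).
#' @return A `data.table` with columns `model`, `accuracy`, `precision`,
#'   `recall`.
#' @export
compare_models <- function(models, curated, features, pseudo_table) {
  stopifnot(length(models) > 0L)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- paste0("model", seq_along(models))
  }
  dt <- merge(data.table::as.data.table(curated),
              data.table::as.data.table(features)[
                , c("peptide", "allele", "ic50_nm", "tap"), with = FALSE],
              by = c("peptide", "allele"))
  dt <- dt[dt$split == "test"]
  if (nrow(dt) == 0L) stop("no test-split rows", call. = FALSE)
  actual <- dt$label == 1L
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    cls <- if (inherits(m, "neoimm_cnn")) {
      if (!isTRUE(m$trained)) stop("model '", nm, "' is untrained",
                                   call. = FALSE)
      as.integer(stats::predict(m, dt) > 0.5)
    } else if (inherits(m, "neoimm_baseline")) {
      stats::predict(m, dt, type = "class")
    } else {
      stop("unsupported model class for '", nm, "'", call. = FALSE)
    }
    met <- binary_metrics(cls == 1L, actual)
    data.table::data.table(model = nm, accuracy = met$accuracy,
                           precision = met$precision, recall = met$recall)
  })
  data.table::rbindlist(rows)
}
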