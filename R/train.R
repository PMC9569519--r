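# Dataset encoding and the CNN training loop.

# One-hot encode a character vector of equal-length padded sequences into a
# sample-major n x (P * 21) binary matrix, columns position-major.
onehot_matrix <- function(seqs, P, alphabet) {
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
  idx <- matrix(residue_indices(as.vector(chars), alphabet), nrow = n)
  C <- length(alphabet$symbols)
  X <- matrix(0, n, P * C)
  rows <- rep(seq_len(n), P)
  cols <- as.vector((rep(seq_len(P), each = n) - 1L) * C + idx)
  X[cbind(rows, cols)] <- 1
  X
}

pad_peptides <- function(peptides, max_len, pad_symbol, pad = "right") {
  L <- nchar(peptides)
  if (any(L < 8L | L > max_len)) {
    bad <- peptides[L < 8L | L > max_len][1]
    stop("peptide '", bad, "' has length outside 8-", max_len, call. = FALSE)
  }
  n_pad <- max_len - L
  if (pad == "right") {
    paste0(peptides, strrep(pad_symbol, n_pad))
  } else {
    left <- n_pad %/% 2L
    paste0(strrep(pad_symbol, left), peptides,
           strrep(pad_symbol, n_pad - left))
  }
}

#' Encode peptide-MHC pairs for the CNN
#'
#' Builds the one-hot peptide and MHC pseudo-sequence matrices plus the raw
#' IC50 and TAP scalars for a set of candidate pairs. Scalars are normalized
#' later against a model's stored training-set constants.
#'
#' @param data A data.frame with columns `peptide`, `allele`, `ic50_nm`,
#'   `tap`.
#' @param pseudo_table A pseudo-sequence table.
#' @param alphabet The encoding alphabet.
#' @param pad Padding placement for peptides shorter than `max_len`.
#' @param max_len Padded peptide length.
#' @return A `neoimm_pairs` object (list of matrices and scalar vectors)
#'   carrying the encoding checksum used for model-compatibility checks.
#' @export
encode_pairs <- function(data, pseudo_table, alphabet = aa_alphabet(),
                         pad = "right", max_len = 11L) {
  need <- c("peptide", "allele", "ic50_nm", "tap")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  peptides <- toupper(trimws(data$peptide))
  padded <- pad_peptides(peptides, max_len, alphabet$pad_symbol, pad)
  alleles <- normalize_allele_name(data$allele)
  pseq <- unclass(pseudo_table)[alleles]
  if (anyNA(pseq)) {
    stop("allele(s) not in pseudo-sequence table: ",
         paste(unique(alleles[is.na(pseq)]), collapse = ", "), call. = FALSE)
  }
  mhc_len <- attr(pseudo_table, "pseudo_length")
  structure(list(
    pep = onehot_matrix(padded, max_len, alphabet),
    mhc = onehot_matrix(pseq, mhc_len, alphabet),
    ic50 = as.numeric(data$ic50_nm),
    tap = as.numeric(data$tap),
    n = nrow(data),
    n_channels = length(alphabet$symbols),
    pep_len = max_len, mhc_len = mhc_len,
    hash = encoding_hash(alphabet, pseudo_table)
  ), class = "neoimm_pairs")
}

# Assemble the forward-pass input for a row subset, normalizing scalars.
pairs_batch <- function(pairs, rows, norm, ic50_scale) {
  ic50 <- pairs$ic50[rows]
  if (ic50_scale == "log") ic50 <- log10(pmax(ic50, 1e-12))
  list(pep = pairs$pep[rows, , drop = FALSE],
       mhc = pairs$mhc[rows, , drop = FALSE],
       ba = apply_minmax(ic50, norm$ba),
       tap = apply_minmax(pairs$tap[rows], norm$tap),
       n_channels = pairs$n_channels)
}

#' Train the immunogenicity CNN
#'
#' Joins a curated, split dataset with its feature table, fits min-max
#' normalization constants on the training split, and trains the two-branch
#' CNN by minimizing class-weighted binary cross-entropy with Adam.
#' Training stops when the training loss has not improved for
#' `patience_train_loss` epochs, the validation loss has not improved for
#' `patience_val_loss` epochs, or `max_epochs` is reached -- whichever comes
#' first -- and the weights of the best validation-loss epoch are restored.
#' The run is deterministic given `config$seed` (CPU execution).
#'
#' @param curated A curated dataset with a `split` column containing at
#'   least `"train"` and `"validation"`.
#' @param features Feature table with `peptide`, `allele`, `ic50_nm`, `tap`.
#' @param pseudo_table Pseudo-sequence table covering all alleles.
#' @param config A [cnn_config()].
#' @param alphabet Encoding alphabet.
#' @param verbose Print per-epoch losses.
#' @return A trained `neoimm_cnn` with `history` (per-epoch train/validation
#'   loss), stored normalization constants, pseudo-table and encoding hash.
#' @export
train_cnn <- function(curated, features, pseudo_table,
                      config = cnn_config(), alphabet = aa_alphabet(),
                      verbose = FALSE) {
  if (!"split" %in% names(curated)) {
    stop("dataset has no split column; call assign_splits() first",
         call. = FALSE)
  }
  if (!all(c("train", "validation") %in% curated$split)) {
    stop("dataset must contain train and validation splits", call. = FALSE)
  }
  dt <- merge(data.table::as.data.table(curated),
              data.table::as.data.table(features)[
                , c("peptide", "allele", "ic50_nm", "tap"), with = FALSE],
              by = c("peptide", "allele"))
  if (nrow(dt) < nrow(curated)) {
    stop(nrow(curated) - nrow(dt),
         " curated records have no feature-table entry", call. = FALSE)
  }
  y <- as.numeric(dt$label)
  is_train <- dt$split == "train"
  is_val <- dt$split == "validation"
  if (length(unique(y[is_train])) < 2L) {
    stop("empty class: training split must contain both labels",
         call. = FALSE)
  }
  ic50 <- dt$ic50_nm
  if (config$ic50_scale == "log") ic50 <- log10(pmax(ic50, 1e-12))
  norm <- list(ba = fit_minmax(ic50[is_train]),
               tap = fit_minmax(dt$tap[is_train]))
  pairs <- encode_pairs(dt, pseudo_table, alphabet, pad = config$pad)

  model <- build_cnn(config, pep_len = pairs$pep_len,
                     mhc_len = pairs$mhc_len, n_channels = pairs$n_channels)
  model$norm <- norm
  model$hash <- pairs$hash
  model$pseudo_table <- pseudo_table

  if (config$use_class_weights) {
    cw <- class_weights(sum(y[is_train] == 1), sum(y[is_train] == 0))
    w <- ifelse(y == 1, cw$w_pos, cw$w_neg)
  } else {
    w <- rep(1, length(y))
  }

  idx_train <- which(is_train)
  idx_val <- which(is_val)
  val_batch <- pairs_batch(pairs, idx_val, norm, config$ic50_scale)
  y_val <- y[idx_val]

  params <- model$params
  bn_state <- model$bn_state
  fit <- with_seed(config$seed + 1L, {
    opt <- adam_init(params)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best_val <- Inf; best_train <- Inf
    wait_val <- 0L; wait_train <- 0L
    best_params <- params; best_bn <- bn_state
    n_train <- length(idx_train)
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample(idx_train)
      starts <- seq(1L, n_train, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        rows <- perm[s:min(s + config$batch_size - 1L, n_train)]
        batch <- pairs_batch(pairs, rows, norm, config$ic50_scale)
        fw <- cnn_forward(params, bn_state, batch, config, training = TRUE)
        bn_state <- fw$bn_state
        lo <- bce_from_logits(as.vector(fw$z), y[rows], w[rows])
        epoch_loss <- epoch_loss + lo$loss * length(rows)
        grads <- cnn_backward(params, fw$cache,
                              matrix(lo$dz, ncol = 1L), config)
        st <- adam_step(params, grads, opt, config$learning_rate)
        params <- st$params
        opt <- st$opt
      }
      train_loss <- epoch_loss / n_train
      vf <- cnn_forward(params, bn_state, val_batch, config, training = FALSE)
      val_loss <- bce_from_logits(as.vector(vf$z), y_val,
                                  rep(1, length(y_val)))$loss
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss,
                                           val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f",
                        epoch, train_loss, val_loss))
      }
      if (val_loss < best_val) {
        best_val <- val_loss; wait_val <- 0L
        best_params <- params; best_bn <- bn_state
      } else wait_val <- wait_val + 1L
      if (train_loss < best_train) {
        best_train <- train_loss; wait_train <- 0L
      } else wait_train <- wait_train + 1L
      if (wait_train >= config$patience_train_loss ||
          wait_val >= config$patience_val_loss) break
    }
    list(params = best_params, bn_state = best_bn, history = history)
  })
  model$params <- fit$params
  model$bn_state <- fit$bn_state
  model$history <- fit$history
  model$trained <- TRUE
  model
}

#' Predict immunogenicity scores
#'
#' Scores peptide-MHC pairs with a trained CNN. Scalars are normalized with
#' the model's stored training-set constants (out-of-range values clamped);
#' batch normalization uses running statistics, so scores are independent of
#' how predictions are batched, and output order follows input order.
#'
#' @param object A trained `neoimm_cnn`.
#' @param newdata A data.frame with `peptide`, `allele`, `ic50_nm`, `tap`,
#'   or a `neoimm_pairs` object from [encode_pairs()].
#' @param ... Unused.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict.neoimm_cnn <- function(object, newdata, ...) {
  fw <- model_forward(object, newdata)
  as.vector(sigmoid(fw$z))
}

#' Flattened branch outputs of the CNN
#'
#' Runs the forward pass and returns the peptide and MHC branch vectors
#' (each `flattened_dim`-dimensional per input pair) -- the representation
#' concatenated with the two feature scalars before the fusion layers.
#'
#' @param object A `neoimm_cnn` (trained, or untrained for architecture
#'   probing; untrained models fall back to unit normalization).
#' @param data A data.frame with `peptide`, `allele`, `ic50_nm`, `tap`, or
#'   a `neoimm_pairs` object.
#' @return List with matrices `pep` and `mhc`, one row per input pair.
#' @export
branch_outputs <- function(object, data) {
  fw <- model_forward(object, data)
  list(pep = fw$branch_pep, mhc = fw$branch_mhc)
}

model_forward <- function(object, newdata) {
  stopifnot(inherits(object, "neoimm_cnn"))
  if (inherits(newdata, "neoimm_pairs")) {
    pairs <- newdata
  } else {
    if (is.null(object$pseudo_table)) {
      stop("model carries no pseudo-sequence table; pass encoded pairs",
           call. = FALSE)
    }
    pairs <- encode_pairs(newdata, object$pseudo_table)
  }
  if (!is.null(object$hash) && !identical(pairs$hash, object$hash)) {
    stop("incompatible model: encoding checksum mismatch (alphabet or ",
         "pseudo-sequence table differs from training)", call. = FALSE)
  }
  norm <- object$norm
  if (is.null(norm)) {
    norm <- list(ba = structure(list(x_min = 0, x_max = 1),
                                class = "neoimm_minmax"),
                 tap = structure(list(x_min = 0, x_max = 1),
                                 class = "neoimm_minmax"))
  }
  scale <- if (is.null(object$config$ic50_scale)) "raw"
           else object$config$ic50_scale
  batch <- pairs_batch(pairs, seq_len(pairs$n), norm, scale)
  cnn_forward(object$params, object$bn_state, batch, object$config,
              training = FALSE)
}

#' Save / load a trained model
#'
#' Persists the model as a single JSON bundle: weights, batch-norm state,
#' configuration, normalization constants, pseudo-sequence table, encoding
#' hash, training history and a weight checksum verified on load.
#'
#' @param model A `neoimm_cnn`.
#' @param path Output path.
#' @param timestamp Record the creation time in the bundle. The pipeline
#'   writes without a timestamp so that reruns produce byte-identical
#'   artifacts.
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path, timestamp = TRUE) {
  stopifnot(inherits(model, "neoimm_cnn"))
  bundle <- list(
    format = "neoimm_cnn_json_v1",
    created = if (timestamp) format(Sys.time(), tz = "UTC") else NULL,
    config = unclass(model$config),
    dims = model$dims,
    norm = lapply(model$norm, unclass),
    hash = model$hash,
    pseudo = as.list(unclass(model$pseudo_table)),
    pseudo_length = attr(model$pseudo_table, "pseudo_length"),
    history = model$history,
    trained = model$trained,
    params = lapply(model$params, function(p) {
      list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.vector(p))
    }),
    bn_state = model$bn_state,
    checksum = weight_checksum(model$params)
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

weight_checksum <- function(params) {
  s <- sum(vapply(params, function(p) sum(abs(as.vector(p))), numeric(1)))
  signif(s, 12)
}

#' @rdname save_model
#' @param alphabet Alphabet expected by the caller; loading fails if it does
#'   not match the alphabet the model was trained with.
#' @export
load_model <- function(path, alphabet = aa_alphabet()) {
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(bundle$format, "neoimm_cnn_json_v1")) {
    stop("not a recognized model bundle: ", path, call. = FALSE)
  }
  params <- lapply(bundle$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  chk <- weight_checksum(params)
  if (!isTRUE(all.equal(chk, bundle$checksum, tolerance = 1e-9))) {
    stop("corrupt model file: weight checksum ", chk,
         " does not match stored ", bundle$checksum, call. = FALSE)
  }
  cfg <- bundle$config
  config <- cnn_config(
    conv_filters = cfg$conv_filters, kernel_size = cfg$kernel_size,
    dense_units = cfg$dense_units, flattened_dim = cfg$flattened_dim,
    fusion_units = cfg$fusion_units, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, learning_rate = cfg$learning_rate,
    patience_train_loss = cfg$patience_train_loss,
    patience_val_loss = cfg$patience_val_loss,
    use_batch_norm = cfg$use_batch_norm, dropout_rate = cfg$dropout_rate,
    use_class_weights = cfg$use_class_weights, ic50_scale = cfg$ic50_scale,
    pad = cfg$pad, seed = cfg$seed
  )
  pseudo <- pseudo_table(unlist(bundle$pseudo), alphabet = alphabet)
  norm <- lapply(bundle$norm, function(x) {
    structure(list(x_min = x$x_min, x_max = x$x_max),
              class = "neoimm_minmax")
  })
  model <- structure(list(
    params = params,
    bn_state = lapply(bundle$bn_state, function(s) {
      list(mean = as.numeric(s$mean), var = as.numeric(s$var))
    }),
    config = config,
    dims = bundle$dims,
    norm = norm,
    hash = bundle$hash,
    pseudo_table = pseudo,
    history = bundle$history,
    trained = isTRUE(bundle$trained)
  ), class = "neoimm_cnn")
  expect_hash <- encoding_hash(alphabet, pseudo)
  if (!identical(expect_hash, model$hash)) {
    stop("incompatible model: stored encoding hash ", model$hash,
         " does not match alphabet/pseudo-table hash ", expect_hash,
         call. = FALSE)
  }
  model
}
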