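#' Configuration of the immunogenicity CNN
#'
#' Architecture and training protocol of the two-branch convolutional
#' network. The printed protocol constants are the defaults: batch size 64,
#' at most 200 epochs, Adam learning rate 0.001, early-stopping patience 15
#' on training loss and 20 on validation loss, 70/20/10 splits handled
#' upstream, class-weighted binary cross-entropy, batch normalization and
#' dropout. Each branch applies two consecutive convolutional layers and
#' three dense layers and flattens to a 256-dimensional vector; the two
#' branch vectors are concatenated with the normalized binding-affinity and
#' TAP scalars and passed through two fusion dense layers to a single
#' sigmoid output.
#'
#' Hyperparameters without a printed value are package defaults: 16 then 32
#' convolution filters, kernel size 3 (the first kernel spans the full
#' 21-column one-hot width by construction), branch dense widths 32/32/256
#' (a narrow bottleneck, then expansion to the printed 256-dimensional
#' flattened vector -- the bottleneck curbs memorization of one-hot inputs
#' at moderate training-set sizes), fusion widths 64/32, dropout 0.5,
#' batch normalization on the convolutional stacks.
#'
#' @param conv_filters Integer pair: filters of the two conv layers.
#' @param kernel_size Kernel extent along the sequence axis.
#' @param dense_units Integer triple: branch dense widths; the last equals
#'   `flattened_dim`.
#' @param flattened_dim Dimension of each branch's flattened output (256).
#' @param fusion_units Integer pair: fusion dense widths.
#' @param batch_size,max_epochs,learning_rate Training protocol constants.
#' @param patience_train_loss,patience_val_loss Early-stopping patiences.
#' @param use_batch_norm,dropout_rate Regularization settings.
#' @param bn_scope Where batch normalization is applied when
#'   `use_batch_norm` is on: `"conv"` (default; the convolutional stacks
#'   only, dense layers regularized by dropout alone) or `"all"` (every
#'   hidden layer).
#' @param use_class_weights Weight the loss by `class_weights()` (default on).
#' @param ic50_scale `"raw"` (min-max on nM values, the default) or `"log"`
#'   (min-max after log10).
#' @param pad Peptide padding placement, `"right"` or `"center"`.
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @return A `neoimm_cnn_config` list.
#' @export
cnn_config <- function(conv_filters = c(16L, 32L),
                       kernel_size = 3L,
                       dense_units = c(32L, 32L, 256L),
                       flattened_dim = 256L,
                       fusion_units = c(64L, 32L),
                       batch_size = 64L,
                       max_epochs = 200L,
                       learning_rate = 0.001,
                       patience_train_loss = 15L,
                       patience_val_loss = 20L,
                       use_batch_norm = TRUE,
                       bn_scope = c("conv", "all"),
                       dropout_rate = 0.5,
                       use_class_weights = TRUE,
                       ic50_scale = c("raw", "log"),
                       pad = c("right", "center"),
                       seed = 42L) {
  bn_scope <- match.arg(bn_scope)
  ic50_scale <- match.arg(ic50_scale)
  pad <- match.arg(pad)
  stopifnot(length(conv_filters) == 2L, all(conv_filters > 0L),
            kernel_size >= 1L,
            length(dense_units) == 3L, all(dense_units > 0L),
            length(fusion_units) == 2L, all(fusion_units > 0L),
            batch_size > 0L, max_epochs > 0L, learning_rate > 0,
            patience_train_loss > 0L, patience_val_loss > 0L,
            dropout_rate >= 0, dropout_rate < 1)
  if (dense_units[3L] != flattened_dim) {
    stop("last branch dense width (", dense_units[3L],
         ") must equal flattened_dim (", flattened_dim, ")", call. = FALSE)
  }
  structure(list(
    conv_filters = as.integer(conv_filters),
    kernel_size = as.integer(kernel_size),
    dense_units = as.integer(dense_units),
    flattened_dim = as.integer(flattened_dim),
    fusion_units = as.integer(fusion_units),
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    learning_rate = learning_rate,
    patience_train_loss = as.integer(patience_train_loss),
    patience_val_loss = as.integer(patience_val_loss),
    use_batch_norm = isTRUE(use_batch_norm),
    bn_scope = bn_scope,
    dropout_rate = dropout_rate,
    use_class_weights = isTRUE(use_class_weights),
    ic50_scale = ic50_scale,
    pad = pad,
    seed = as.integer(seed)
  ), class = "neoimm_cnn_config")
}

# conv output length along the sequence axis after the two conv layers
conv_out_len <- function(p, k) p - 2L * (k - 1L)

# is batch norm active for this layer class ("conv" or "dense")?
bn_on <- function(config, layer) {
  if (!config$use_batch_norm) return(FALSE)
  scope <- if (is.null(config$bn_scope)) "all" else config$bn_scope
  scope == "all" || layer == "conv"
}

# Initialize all parameters (and batch-norm state) for given input shapes.
cnn_init <- function(config, pep_len, mhc_len, n_channels) {
  k <- config$kernel_size
  f <- config$conv_filters
  d <- config$dense_units
  fu <- config$fusion_units
  if (conv_out_len(pep_len, k) < 1L || conv_out_len(mhc_len, k) < 1L) {
    stop("input shapes too short for kernel size ", k, call. = FALSE)
  }
  params <- list()
  bn_state <- list()
  add_bn <- function(nm, dim) {
    params[[paste0(nm, "_g")]] <<- rep(1, dim)
    params[[paste0(nm, "_be")]] <<- rep(0, dim)
    bn_state[[nm]] <<- list(mean = rep(0, dim), var = rep(1, dim))
  }
  for (br in c("p", "m")) {
    plen <- if (br == "p") pep_len else mhc_len
    flat <- conv_out_len(plen, k) * f[2L]
    params[[paste0(br, "_c1_W")]] <- init_weight(k * n_channels, f[1L])
    params[[paste0(br, "_c1_b")]] <- rep(0, f[1L])
    if (bn_on(config, "conv")) add_bn(paste0(br, "_c1"), f[1L])
    params[[paste0(br, "_c2_W")]] <- init_weight(k * f[1L], f[2L])
    params[[paste0(br, "_c2_b")]] <- rep(0, f[2L])
    if (bn_on(config, "conv")) add_bn(paste0(br, "_c2"), f[2L])
    widths <- c(flat, d)
    for (i in 1:3) {
      nm <- paste0(br, "_d", i)
      params[[paste0(nm, "_W")]] <- init_weight(widths[i], widths[i + 1L])
      params[[paste0(nm, "_b")]] <- rep(0, widths[i + 1L])
      if (bn_on(config, "dense")) add_bn(nm, widths[i + 1L])
    }
  }
  fin <- 2L * config$flattened_dim + 2L
  widths <- c(fin, fu)
  for (i in 1:2) {
    nm <- paste0("f", i)
    params[[paste0(nm, "_W")]] <- init_weight(widths[i], widths[i + 1L])
    params[[paste0(nm, "_b")]] <- rep(0, widths[i + 1L])
    if (bn_on(config, "dense")) add_bn(nm, widths[i + 1L])
  }
  params$out_W <- init_weight(fu[2L], 1L)
  params$out_b <- 0
  list(params = params, bn_state = bn_state)
}

#' Build an untrained immunogenicity CNN
#'
#' Initializes the two-branch architecture for 11 x 21 peptide and
#' (pseudo-length) x 21 MHC one-hot inputs. Initialization is deterministic
#' given `config$seed`.
#'
#' @param config A [cnn_config()].
#' @param pep_len Padded peptide length (rows of the peptide input).
#' @param mhc_len Pseudo-sequence length (rows of the MHC input).
#' @param n_channels Alphabet size (columns of both inputs).
#' @return An untrained `neoimm_cnn` model.
#' @export
build_cnn <- function(config = cnn_config(), pep_len = 11L, mhc_len = 33L,
                      n_channels = 21L) {
  init <- with_seed(config$seed,
                    cnn_init(config, pep_len, mhc_len, n_channels))
  structure(list(
    params = init$params,
    bn_state = init$bn_state,
    config = config,
    dims = list(pep_len = pep_len, mhc_len = mhc_len,
                n_channels = n_channels),
    norm = NULL, hash = NULL, pseudo_table = NULL,
    history = NULL, trained = FALSE
  ), class = "neoimm_cnn")
}

#' @export
print.neoimm_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat("Immunogenicity CNN (", if (isTRUE(x$trained)) "trained" else "untrained",
      "): peptide ", x$dims$pep_len, "x", x$dims$n_channels,
      " + MHC ", x$dims$mhc_len, "x", x$dims$n_channels,
      " -> 2x", x$config$flattened_dim, " + 2 scalars -> sigmoid; ",
      format(n_par, big.mark = ","), " parameters\n", sep = "")
  if (!is.null(x$history)) {
    cat("trained ", nrow(x$history), " epochs; best val loss ",
        signif(min(x$history$val_loss), 4), " at epoch ",
        which.min(x$history$val_loss), "\n", sep = "")
  }
  invisible(x)
}

# One branch: conv -> [bn] -> relu -> conv -> [bn] -> relu -> flatten ->
# 3 x (dense -> [bn] -> relu) -> dropout. X is sample-major B x (P*C).
branch_fwd <- function(br, X, n_channels, params, bn_state, config, training) {
  B <- nrow(X)
  cache <- list(B = B)
  h <- to_blocked(X, n_channels)
  use_bn_conv <- bn_on(config, "conv")
  use_bn_dense <- bn_on(config, "dense")
  for (ci in 1:2) {
    nm <- paste0(br, "_c", ci)
    cv <- conv_fwd(h, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]],
                   B, config$kernel_size)
    cache[[paste0("conv", ci)]] <- cv
    h <- cv$out
    if (use_bn_conv) {
      bn <- bn_fwd(h, params[[paste0(nm, "_g")]], params[[paste0(nm, "_be")]],
                   bn_state[[nm]], training)
      bn_state[[nm]] <- bn$state
      cache[[paste0("bn_c", ci)]] <- bn
      h <- bn$out
    }
    rl <- relu_fwd(h)
    cache[[paste0("relu_c", ci)]] <- rl
    h <- rl$out
  }
  h <- matrix(h, nrow = B)  # flatten: (B*P) x C -> B x (P*C)
  cache$flat_cols <- ncol(h)
  for (di in 1:3) {
    nm <- paste0(br, "_d", di)
    ln <- linear_fwd(h, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]])
    cache[[paste0("lin", di)]] <- ln
    h <- ln$out
    if (use_bn_dense) {
      bn <- bn_fwd(h, params[[paste0(nm, "_g")]], params[[paste0(nm, "_be")]],
                   bn_state[[nm]], training)
      bn_state[[nm]] <- bn$state
      cache[[paste0("bn_d", di)]] <- bn
      h <- bn$out
    }
    rl <- relu_fwd(h)
    cache[[paste0("relu_d", di)]] <- rl
    h <- rl$out
    dp <- dropout_fwd(h, config$dropout_rate, training)
    cache[[paste0("drop_d", di)]] <- dp
    h <- dp$out
  }
  list(out = h, cache = cache, bn_state = bn_state)
}

branch_bwd <- function(br, dout, cache, params, config) {
  use_bn_conv <- bn_on(config, "conv")
  use_bn_dense <- bn_on(config, "dense")
  grads <- list()
  d <- dout
  for (di in 3:1) {
    nm <- paste0(br, "_d", di)
    d <- dropout_bwd(d, cache[[paste0("drop_d", di)]])
    d <- relu_bwd(d, cache[[paste0("relu_d", di)]])
    if (use_bn_dense) {
      bb <- bn_bwd(d, cache[[paste0("bn_d", di)]])
      grads[[paste0(nm, "_g")]] <- bb$dgamma
      grads[[paste0(nm, "_be")]] <- bb$dbeta
      d <- bb$dX
    }
    lb <- linear_bwd(d, cache[[paste0("lin", di)]], params[[paste0(nm, "_W")]])
    grads[[paste0(nm, "_W")]] <- lb$dW
    grads[[paste0(nm, "_b")]] <- lb$db
    d <- lb$dX
  }
  # unflatten B x (P*C) -> (B*P) x C (column-major reshape is self-inverse)
  d <- matrix(d, nrow = nrow(cache$relu_c2$out))
  for (ci in 2:1) {
    nm <- paste0(br, "_c", ci)
    d <- relu_bwd(d, cache[[paste0("relu_c", ci)]])
    if (use_bn_conv) {
      bb <- bn_bwd(d, cache[[paste0("bn_c", ci)]])
      grads[[paste0(nm, "_g")]] <- bb$dgamma
      grads[[paste0(nm, "_be")]] <- bb$dbeta
      d <- bb$dX
    }
    cb <- conv_bwd(d, cache[[paste0("conv", ci)]], params[[paste0(nm, "_W")]])
    grads[[paste0(nm, "_W")]] <- cb$dW
    grads[[paste0(nm, "_b")]] <- cb$db
    d <- cb$dA
  }
  grads
}

# Full forward pass. batch: list(pep, mhc, ba, tap) with sample-major
# matrices carrying attr n_channels. Returns logits, caches, bn state and
# the two branch outputs.
cnn_forward <- function(params, bn_state, batch, config, training) {
  nc <- batch$n_channels
  pb <- branch_fwd("p", batch$pep, nc, params, bn_state, config, training)
  mb <- branch_fwd("m", batch$mhc, nc, params, pb$bn_state, config, training)
  bn_state <- mb$bn_state
  Z <- cbind(pb$out, mb$out, batch$ba, batch$tap)
  cache <- list(p = pb$cache, m = mb$cache,
                p_dim = ncol(pb$out), m_dim = ncol(mb$out))
  h <- Z
  use_bn <- bn_on(config, "dense")
  for (fi in 1:2) {
    nm <- paste0("f", fi)
    ln <- linear_fwd(h, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]])
    cache[[paste0("lin_f", fi)]] <- ln
    h <- ln$out
    if (use_bn) {
      bn <- bn_fwd(h, params[[paste0(nm, "_g")]], params[[paste0(nm, "_be")]],
                   bn_state[[nm]], training)
      bn_state[[nm]] <- bn$state
      cache[[paste0("bn_f", fi)]] <- bn
      h <- bn$out
    }
    rl <- relu_fwd(h)
    cache[[paste0("relu_f", fi)]] <- rl
    h <- rl$out
    if (fi == 1L) {
      dp <- dropout_fwd(h, config$dropout_rate, training)
      cache$drop_f1 <- dp
      h <- dp$out
    }
  }
  ln <- linear_fwd(h, params$out_W, params$out_b)
  cache$lin_out <- ln
  list(z = ln$out, cache = cache, bn_state = bn_state,
       branch_pep = pb$out, branch_mhc = mb$out)
}

cnn_backward <- function(params, cache, dz, config) {
  use_bn <- bn_on(config, "dense")
  grads <- list()
  lb <- linear_bwd(dz, cache$lin_out, params$out_W)
  grads$out_W <- lb$dW
  grads$out_b <- lb$db
  d <- lb$dX
  for (fi in 2:1) {
    nm <- paste0("f", fi)
    if (fi == 1L) d <- dropout_bwd(d, cache$drop_f1)
    d <- relu_bwd(d, cache[[paste0("relu_f", fi)]])
    if (use_bn) {
      bb <- bn_bwd(d, cache[[paste0("bn_f", fi)]])
      grads[[paste0(nm, "_g")]] <- bb$dgamma
      grads[[paste0(nm, "_be")]] <- bb$dbeta
      d <- bb$dX
    }
    lb <- linear_bwd(d, cache[[paste0("lin_f", fi)]],
                     params[[paste0(nm, "_W")]])
    grads[[paste0(nm, "_W")]] <- lb$dW
    grads[[paste0(nm, "_b")]] <- lb$db
    d <- lb$dX
  }
  dp <- d[, seq_len(cache$p_dim), drop = FALSE]
  dm <- d[, cache$p_dim + seq_len(cache$m_dim), drop = FALSE]
  grads <- c(grads,
             branch_bwd("p", dp, cache$p, params, config),
             branch_bwd("m", dm, cache$m, params, config))
  grads
}
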