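ns <- asNamespace("neoimm")

test_that("building a model is deterministic given the seed", {
  cfg <- tiny_cnn_config()
  m1 <- build_cnn(cfg)
  m2 <- build_cnn(cfg)
  expect_identical(m1$params, m2$params)
  cfg2 <- tiny_cnn_config(seed = 6L)
  m3 <- build_cnn(cfg2)
  expect_false(identical(m1$params$p_c1_W, m3$params$p_c1_W))
})

test_that("config validation catches inconsistent architecture", {
  expect_error(cnn_config(dense_units = c(32L, 32L, 128L),
                          flattened_dim = 256L), "flattened_dim")
  expect_error(cnn_config(dropout_rate = 1))
  expect_error(tiny_cnn_config(kernel_size = 7L) |>
                 build_cnn(pep_len = 11L, mhc_len = 12L), "too short")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- cnn_config(conv_filters = c(3L, 4L), dense_units = c(6L, 6L, 8L),
                    flattened_dim = 8L, fusion_units = c(5L, 4L),
                    bn_scope = "all", dropout_rate = 0, seed = 11L)
  m <- build_cnn(cfg, pep_len = 11L, mhc_len = 7L)
  set.seed(2)
  B <- 5L
  batch <- list(pep = matrix(runif(B * 11 * 21), B),
                mhc = matrix(runif(B * 7 * 21), B),
                ba = runif(B), tap = runif(B), n_channels = 21L)
  y <- c(1, 0, 1, 1, 0); w <- rep(1, B)
  lossfun <- function(params) {
    fw <- ns$cnn_forward(params, m$bn_state, batch, cfg, training = TRUE)
    ns$bce_from_logits(as.vector(fw$z), y, w)$loss
  }
  fw <- ns$cnn_forward(m$params, m$bn_state, batch, cfg, training = TRUE)
  lo <- ns$bce_from_logits(as.vector(fw$z), y, w)
  gr <- ns$cnn_backward(m$params, fw$cache, matrix(lo$dz, ncol = 1), cfg)
  eps <- 1e-6
  set.seed(3)
  for (nm in names(m$params)) {
    for (i in sample(seq_along(m$params[[nm]]),
                     min(3, length(m$params[[nm]])))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("branch outputs have the configured flattened dimension", {
  st <- tiny_study()
  cfg <- tiny_cnn_config()
  m <- build_cnn(cfg, mhc_len = 33L)
  m$pseudo_table <- st$sim$pseudo_table
  dt <- merge(st$curated, st$sim$features, by = c("peptide", "allele"))[1:6, ]
  bo <- branch_outputs(m, dt)
  expect_identical(dim(bo$pep), c(6L, 16L))
  expect_identical(dim(bo$mhc), c(6L, 16L))
})

test_that("training returns scores in [0,1], records history and is seeded", {
  st <- tiny_study()
  cfg <- tiny_cnn_config()
  m1 <- train_cnn(st$curated, st$sim$features, st$sim$pseudo_table, cfg)
  m2 <- train_cnn(st$curated, st$sim$features, st$sim$pseudo_table, cfg)
  expect_identical(m1$history, m2$history)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(m1$history)))
  expect_lte(nrow(m1$history), cfg$max_epochs)
  dt <- merge(st$curated, st$sim$features, by = c("peptide", "allele"))
  s1 <- predict(m1, dt)
  expect_length(s1, nrow(dt))
  expect_true(all(s1 >= 0 & s1 <= 1))
  s2 <- predict(m2, dt)
  expect_identical(s1, s2)
})

test_that("prediction is order-equivariant and batching-invariant", {
  st <- tiny_study()
  m <- train_cnn(st$curated, st$sim$features, st$sim$pseudo_table,
                 tiny_cnn_config())
  dt <- merge(st$curated, st$sim$features, by = c("peptide", "allele"))[1:20, ]
  s <- predict(m, dt)
  perm <- sample(20)
  expect_equal(predict(m, dt[perm, ]), s[perm], tolerance = 1e-12)
  singles <- vapply(seq_len(10), function(i) predict(m, dt[i, ]), numeric(1))
  expect_equal(singles, s[1:10], tolerance = 1e-5)
})

test_that("models round-trip through the JSON bundle", {
  st <- tiny_study()
  m <- train_cnn(st$curated, st$sim$features, st$sim$pseudo_table,
                 tiny_cnn_config())
  dt <- merge(st$curated, st$sim$features, by = c("peptide", "allele"))[1:30, ]
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_lte(max(abs(predict(m2, dt) - predict(m, dt))), 1e-6)
  expect_identical(m2$hash, m$hash)
  # corrupting a stored weight trips the checksum
  bundle <- jsonlite::read_json(f, simplifyVector = TRUE)
  bundle$params$out_W$data <- bundle$params$out_W$data + 1
  jsonlite::write_json(bundle, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(f), "checksum")
})

test_that("encoder mismatches are rejected at prediction time", {
  st <- tiny_study()
  m <- train_cnn(st$curated, st$sim$features, st$sim$pseudo_table,
                 tiny_cnn_config())
  dt <- merge(st$curated, st$sim$features, by = c("peptide", "allele"))[1:5, ]
  # same alleles, one pseudo-sequence residue altered -> different hash
  seqs <- unclass(st$sim$pseudo_table)
  first <- substr(seqs, 1, 1)
  other <- pseudo_table(stats::setNames(
    paste0(ifelse(first == "Y", "W", "Y"), substring(seqs, 2)),
    names(st$sim$pseudo_table)))
  pairs <- encode_pairs(dt, other)
  expect_error(predict(m, pairs), "incompatible model")
})

test_that("training validates splits and class presence", {
  st <- tiny_study()
  no_split <- st$curated[, c("peptide", "allele", "label"), with = FALSE]
  expect_error(train_cnn(no_split, st$sim$features, st$sim$pseudo_table,
                         tiny_cnn_config()), "split")
  one_class <- data.table::copy(st$curated)
  one_class$label <- 1L
  expect_error(train_cnn(one_class, st$sim$features, st$sim$pseudo_table,
                         tiny_cnn_config()), "empty class")
})
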