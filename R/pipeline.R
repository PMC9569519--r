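#' Pipeline configuration
#'
#' Bundles the file paths and settings for the end-to-end run:
#' curate -> split -> normalize -> train -> predict -> filter -> rank.
#' One global seed drives split assignment and model training.
#'
#' @param assays Path to the raw assay table.
#' @param features Path to the feature table (`ic50_nm`, `tap`, `tpm`).
#' @param pseudo Path to the pseudo-sequence table.
#' @param out_dir Output directory (created if absent).
#' @param split_fractions Train/test/validation fractions.
#' @param cnn A [cnn_config()]; its seed is overridden by `seed`.
#' @param seed Global seed.
#' @return A `neoimm_pipeline_config`.
#' @export
pipeline_config <- function(assays, features, pseudo, out_dir,
                            split_fractions = c(0.7, 0.2, 0.1),
                            cnn = cnn_config(), seed = 42L) {
  for (p in c(assays, features, pseudo)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  if (length(split_fractions) != 3L ||
      abs(sum(split_fractions) - 1) > 1e-9) {
    stop("split fractions must be a triple summing to 1", call. = FALSE)
  }
  cnn$seed <- as.integer(seed)
  structure(list(assays = assays, features = features, pseudo = pseudo,
                 out_dir = out_dir, split_fractions = split_fractions,
                 cnn = cnn, seed = as.integer(seed)),
            class = "neoimm_pipeline_config")
}

#' Run the full prediction pipeline
#'
#' Executes, in order: (1) curation of the raw assay table; (2) split
#' assignment; (3) normalization-constant fitting; (4) CNN training;
#' (5) scoring of the held-out test split; (6) candidate filtering;
#' (7) ranking. Every stage writes its output under `config$out_dir` and a
#' `manifest.json` records each output file with its MD5 hash, the seed and
#' the package version, so two runs with the same config and seed produce
#' identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the trained model, the ranked candidate
#'   table and the manifest.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "neoimm_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (verbose) message(...)
  stages <- list()
  note <- function(stage, files) {
    stages[[length(stages) + 1L]] <<- list(
      stage = stage, outputs = as.list(basename(files)),
      md5 = as.list(unname(tools::md5sum(files))))
  }

  say("stage 1/7: curate")
  assays <- read_assay_table(config$assays)
  curated <- curate(assays)
  write_curated(curated, out("curated.tsv"))
  note("curate", c(out("curated.tsv"), out("curated.tsv.provenance.json")))

  say("stage 2/7: split")
  curated <- assign_splits(curated, config$split_fractions, config$seed)
  data.table::fwrite(curated, out("curated_split.tsv"), sep = "\t")
  note("split", out("curated_split.tsv"))

  say("stage 3/7: features + normalization")
  features <- read_feature_table(config$features)
  pseudo <- read_pseudo_table(config$pseudo)
  merged <- merge(curated, features, by = c("peptide", "allele"))
  train_rows <- merged[merged$split == "train"]
  norm <- list(ba = fit_minmax(train_rows$ic50_nm),
               tap = fit_minmax(train_rows$tap))
  jsonlite::write_json(lapply(norm, unclass), out("normalization.json"),
                       auto_unbox = TRUE, digits = NA)
  note("normalize", out("normalization.json"))

  say("stage 4/7: train CNN")
  model <- train_cnn(curated, features, pseudo, config$cnn)
  save_model(model, out("model.json"), timestamp = FALSE)
  note("train", out("model.json"))

  say("stage 5/7: score test split")
  test_rows <- merged[merged$split == "test"]
  test_rows$immunogenicity <- stats::predict(model, test_rows)
  write_candidates(test_rows, out("scored.tsv"))
  note("predict", out("scored.tsv"))

  say("stage 6/7: filter candidates")
  kept <- filter_candidates(test_rows, rejects_path = out("rejects.tsv"))
  write_candidates(kept, out("filtered.tsv"))
  note("filter", c(out("filtered.tsv"), out("rejects.tsv")))

  say("stage 7/7: rank candidates")
  ranked <- rank_candidates(kept)
  write_candidates(ranked, out("ranked.tsv"))
  note("rank", out("ranked.tsv"))

  manifest <- list(
    package = "neoimm",
    version = as.character(utils::packageVersion("neoimm")),
    seed = config$seed,
    inputs = as.list(tools::md5sum(c(config$assays, config$features,
                                     config$pseudo))),
    stages = stages
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(model = model, ranked = ranked, manifest = manifest,
                 out_dir = config$out_dir))
}
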