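# Shared fixtures, all built in code.

# deterministic 4-allele pseudo-sequence table (33 residues each)
tiny_pseudo_table <- function() {
  pseudo_table(c(
    "HLA-A*02:01" = "YFAMYGEKVAHTHVDTLYVRYHYYTWAVLAYTW",
    "HLA-B*07:02" = "YYSEYRNICTNTYESNLYLRYDSYTWAEWAYLW",
    "HLA-C*07:01" = "YDSGYREKYRQADVSNLYLWYDSYTWAELAYTW",
    "HLA-A*01:01" = "YSAMYEEKVAHTDENIAYIMYRDYTWVARVYRG"
  ))
}

# small, fast CNN configuration for unit tests
tiny_cnn_config <- function(seed = 5L, ...) {
  cnn_config(conv_filters = c(4L, 6L), dense_units = c(8L, 8L, 16L),
             flattened_dim = 16L, fusion_units = c(8L, 4L),
             max_epochs = 8L, batch_size = 32L, seed = seed,
             ic50_scale = "log", ...)
}

# small simulated study shared across tests (computed once per test file)
tiny_study <- local({
  cache <- NULL
  function(n = 400L, seed = 11L) {
    key <- paste(n, seed)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      sim <- simulate_assays(simulation_config(n_records = n, seed = seed))
      cur <- assign_splits(curate(sim$assays), seed = seed)
      out <- list(sim = sim, curated = cur)
      attr(out, "key") <- key
      cache <<- out
    }
    cache
  }
})

# hand-built toy assay table exercising every curation filter
toy_assay_table <- function() {
  data.frame(
    peptide = c("SIINFEKLV", "AADDEEFFK", "LLLLLLLLLLLL", "KVAELVHFL",
                "RRYYKKTTWW", "MMNNPPQQR"),
    allele = c("HLA-A*02:01", "HLA-A*02:01", "HLA-B*07:02", "HLA-A2",
               "HLA-B*07:02", "HLA-C*07:01"),
    assay = c("IFNg ELISPOT", "ELISA", "ICS", "multimer/tetramer",
              "51 Chromium release", "proliferation assay"),
    outcome = c("Positive", "Negative", "Positive", "Positive",
                "Negative", "Positive"),
    n_subjects_tested = c(10L, 2L, 8L, 6L, 5L, 9L),
    n_subjects_responded = c(4L, 0L, 3L, 2L, 0L, 5L),
    stringsAsFactors = FALSE
  )
}
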