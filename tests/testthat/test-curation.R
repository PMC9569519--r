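test_that("the toy assay table is filtered exactly as the rules dictate", {
  toy <- toy_assay_table()
  cur <- curate(toy)
  # survivors: the ELISPOT positive 9-mer and the 51 Chromium negative
  # 10-mer with 5 subjects; dropped: thin negative (n=2), 12-mer,
  # 2-digit allele, disallowed assay
  expect_identical(nrow(cur), 2L)
  expect_setequal(cur$peptide, c("SIINFEKLV", "RRYYKKTTWW"))
  expect_identical(cur$label[cur$peptide == "SIINFEKLV"], 1L)
  expect_identical(cur$label[cur$peptide == "RRYYKKTTWW"], 0L)
  prov <- attr(cur, "provenance")
  expect_identical(unname(prov["assay_filter"]), 1L)
  expect_identical(unname(prov["allele_filter"]), 1L)
  expect_identical(unname(prov["length_filter"]), 1L)
  expect_identical(unname(prov["thin_negatives"]), 1L)
  expect_identical(sum(prov), nrow(toy) - nrow(cur))
})

test_that("nothing is filtered from a fully clean table", {
  clean <- data.frame(
    peptide = c("AAAAAAAAK", "CCCCCCCCR"),
    allele = "HLA-A*02:01",
    assay = "ELISPOT",
    outcome = c("Positive", "Positive")
  )
  expect_identical(nrow(curate(clean)), 2L)
})

test_that("duplicates collapse and conflicting labels keep the positive", {
  rec <- data.frame(
    peptide = rep("AAAAAAAAK", 3),
    allele = "HLA-A*02:01",
    assay = c("ELISPOT", "ELISPOT", "ICS"),
    outcome = c("Positive", "Positive", "Negative"),
    n_subjects_tested = c(10L, 10L, 10L)
  )
  cur <- curate(rec)
  expect_identical(nrow(cur), 1L)
  expect_identical(cur$label, 1L)
  prov <- attr(cur, "provenance")
  expect_identical(unname(prov["exact_duplicates"]), 1L)
  expect_identical(unname(prov["pair_collapse"]), 1L)
})

test_that("empty input gives an empty dataset with zeroed provenance", {
  cur <- curate(data.frame(peptide = character(), allele = character(),
                           assay = character(), outcome = character()))
  expect_identical(nrow(cur), 0L)
  expect_true(all(attr(cur, "provenance") == 0L))
})

test_that("curation is idempotent on simulated contaminated tables", {
  for (seed in c(3L, 4L)) {
    sim <- simulate_assays(simulation_config(
      n_records = 300L, seed = seed,
      contamination = c(bad_assay = 0.1, two_digit_allele = 0.05,
                        wrong_length = 0.05, thin_negatives = 0.1,
                        duplicates = 0.1)))
    c1 <- curate(sim$assays)
    c2 <- curate(as_assay_records(c1))
    expect_identical(c2$peptide, c1$peptide)
    expect_identical(c2$allele, c1$allele)
    expect_identical(c2$label, c1$label)
    # provenance removals account exactly for the size difference
    expect_identical(sum(attr(c1, "provenance")),
                     nrow(sim$assays) - nrow(c1))
  }
})

test_that("splits are exact, deterministic and partition the data", {
  d <- data.frame(peptide = sprintf("PEP%06d", 1:1000), allele = "x",
                  label = 0L)
  s1 <- assign_splits(d, c(0.7, 0.2, 0.1), seed = 9L)
  expect_identical(
    as.integer(table(s1$split)[c("train", "test", "validation")]),
    c(700L, 200L, 100L))
  s2 <- assign_splits(d, c(0.7, 0.2, 0.1), seed = 9L)
  expect_identical(s1$split, s2$split)
  s3 <- assign_splits(d, c(0.7, 0.2, 0.1), seed = 10L)
  expect_false(identical(s1$split, s3$split))
  # all-train degenerate fractions
  s4 <- assign_splits(d[1:10, ], c(1, 0, 0), seed = 1L)
  expect_true(all(s4$split == "train"))
  expect_error(assign_splits(d, c(0.5, 0.2, 0.2), seed = 1L), "summing to 1")
})

test_that("curated datasets round-trip through TSV with provenance", {
  cur <- curate(toy_assay_table())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_curated(cur, f)
  back <- read_curated(f)
  expect_identical(back$peptide, cur$peptide)
  expect_identical(back$label, cur$label)
  expect_identical(sum(attr(back, "provenance")), sum(attr(cur, "provenance")))
})
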