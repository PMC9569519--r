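`%+%` <- function(a, b) paste0(a, b)

test_that("alphabet has 21 unique symbols with X as pad and A first", {
  ab <- aa_alphabet()
  expect_length(ab$symbols, 21L)
  expect_false(anyDuplicated(ab$symbols) > 0)
  expect_identical(ab$symbols[1], "A")
  expect_identical(ab$pad_symbol, "X")
  expect_true(ab$pad_symbol %in% ab$symbols)
})

test_that("residue encoding is one-hot at the alphabet index", {
  v <- encode_residue("A")
  expect_identical(v, c(1L, rep(0L, 20L)))
  x <- encode_residue("X")
  expect_equal(which(x == 1L), 21L)
  expect_warning(b <- encode_residue("B"), "unknown residue")
  expect_identical(b, x)
  expect_error(encode_residue(""), "invalid residue")
  expect_error(encode_residue("AB"), "invalid residue")
})

test_that("peptide encoding pads to a constant 11 x 21 shape", {
  m <- encode_peptide("AAAAAAAA")
  expect_identical(dim(m), c(11L, 21L))
  a <- encode_residue("A"); x <- encode_residue("X")
  for (i in 1:8) expect_equal(unname(m[i, ]), a)
  for (i in 9:11) expect_equal(unname(m[i, ]), x)
  m11 <- encode_peptide("SIINFEKLMLV")
  expect_false(any(m11[, 21] == 1))  # no padding rows for an 11-mer
  expect_error(encode_peptide("AAAA"), "length")
  expect_error(encode_peptide("AAAAAAAAAAAA"), "length")
  # center padding places pads at both termini
  mc <- encode_peptide("AAAAAAAA", pad = "center")
  expect_equal(unname(mc[1, ]), x)
  expect_equal(unname(mc[11, ]), x)
})

test_that("encoded matrices are one-hot and decodable (fuzz)", {
  set.seed(42)
  res <- setdiff(aa_alphabet()$symbols, "X")
  for (i in 1:25) {
    L <- sample(8:11, 1)
    pep <- paste(sample(res, L, replace = TRUE), collapse = "")
    m <- encode_peptide(pep)
    expect_equal(unname(rowSums(m)), rep(1, 11))
    expect_identical(decode_peptide(m), pep)
  }
})

test_that("peptide encoding is injective on equal-length peptides", {
  set.seed(1)
  res <- setdiff(aa_alphabet()$symbols, "X")
  peps <- unique(replicate(40, paste(sample(res, 9, TRUE), collapse = "")))
  encs <- lapply(peps, encode_peptide)
  keys <- vapply(encs, function(m) paste(which(t(m) == 1), collapse = ","),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("allele names normalize to 4-digit resolution", {
  expect_identical(normalize_allele_name("HLA-A*02:01:01"), "HLA-A*02:01")
  expect_identical(normalize_allele_name("HLA-A*02:01"), "HLA-A*02:01")
  expect_identical(normalize_allele_name("A0201"), "HLA-A*02:01")
  expect_identical(normalize_allele_name("HLA-A02:01"), "HLA-A*02:01")
  expect_identical(normalize_allele_name("hla-b*57:01"), "HLA-B*57:01")
  # idempotence
  expect_identical(normalize_allele_name(normalize_allele_name("A0201")),
                   "HLA-A*02:01")
  expect_error(normalize_allele_name("HLA-A2"), "cannot parse")
  expect_error(normalize_allele_name(""), "empty")
})

test_that("allele encoding uses the pseudo-sequence and normalizes names", {
  tab <- pseudo_table(c("HLA-A*02:01" = strrep("A", 33)))
  m <- encode_allele("HLA-A*02:01", tab)
  expect_identical(dim(m), c(33L, 21L))
  expect_true(all(m[, 1] == 1L))
  m2 <- encode_allele("HLA-A02:01", tab)
  m3 <- encode_allele("A0201", tab)
  expect_equal(unname(m), unname(m2))
  expect_equal(unname(m), unname(m3))
  expect_error(encode_allele("HLA-Z*99:99", tab), "not in pseudo-sequence")
})

test_that("pseudo-sequence tables read from file, skipping comments", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# comment line", "HLA-A*02:01 " %+% strrep("A", 33),
               "HLA-B*07:02\t" %+% strrep("C", 33)), f)
  tab <- read_pseudo_table(f)
  expect_length(tab, 2L)
  expect_identical(attr(tab, "pseudo_length"), 33L)
  expect_identical(attr(tab, "positions"), pseudo_positions())
  f2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("HLA-A*02:01 AAAA", "HLA-B*07:02 AA"), f2)
  expect_error(read_pseudo_table(f2), "inconsistent lengths")
})
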