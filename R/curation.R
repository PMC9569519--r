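#' @importFrom data.table fread fwrite as.data.table data.table setDT :=
NULL

# Canonical names of the five T-cell assay classes accepted as direct
# evidence of (non-)immunogenicity. Matching is case-insensitive substring
# matching, so dialect strings like "IFNg ELISPOT" pass.
allowed_assays <- function() {
  c("elispot", "51 chromium", "ics", "multimer", "tetramer", "elisa")
}

assay_allowed <- function(assay) {
  a <- tolower(trimws(assay))
  pats <- allowed_assays()
  Reduce(`|`, lapply(pats, function(p) grepl(p, a, fixed = TRUE)))
}

#' Read a raw immunogenicity assay table
#'
#' Reads a TSV/CSV of T-cell assay records. Column names are mapped onto the
#' canonical schema `peptide`, `allele`, `assay`, `outcome`,
#' `n_subjects_tested`, `n_subjects_responded`; override the defaults via
#' `columns` when reading database exports with different headers.
#'
#' @param path Path to the table (delimiter inferred).
#' @param columns Named character vector mapping canonical names to the
#'   file's column names; only names present are remapped.
#' @return A `data.table` of assay records.
#' @export
read_assay_table <- function(path, columns = NULL) {
  dt <- data.table::fread(path, sep = "auto", colClasses = NULL,
                          na.strings = c("", "NA"))
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      if (columns[[canon]] %in% names(dt)) {
        data.table::setnames(dt, columns[[canon]], canon)
      }
    }
  }
  need <- c("peptide", "allele", "assay", "outcome")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stop("assay table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("n_subjects_tested", "n_subjects_responded")) {
    if (!col %in% names(dt)) dt[[col]] <- NA_integer_
  }
  dt
}

# Coerce an outcome column (logical, 0/1, or positive/negative strings)
# to integer 0/1.
coerce_outcome <- function(outcome) {
  if (is.logical(outcome)) return(as.integer(outcome))
  if (is.numeric(outcome)) {
    if (!all(outcome %in% c(0, 1))) {
      stop("numeric outcome must be 0/1", call. = FALSE)
    }
    return(as.integer(outcome))
  }
  o <- tolower(trimws(as.character(outcome)))
  lab <- ifelse(grepl("^pos", o), 1L, ifelse(grepl("^neg", o), 0L, NA_integer_))
  if (anyNA(lab)) {
    stop("unrecognized outcome value(s): ",
         paste(unique(outcome[is.na(lab)]), collapse = ", "), call. = FALSE)
  }
  lab
}

#' Curate raw assay records into a labelled peptide-allele dataset
#'
#' Applies, in order: (1) keep only records validated by the five accepted
#' T-cell assay classes (ELISPOT, 51 Chromium release, ICS,
#' multimer/tetramer staining, ELISA); (2) drop records whose MHC allele
#' does not resolve to 4-digit (protein-level) resolution; (3) drop exact
#' duplicate (peptide, allele, outcome) records; (4) keep peptides of length
#' 8--11; (5) drop negative records with missing subject counts or fewer
#' than four tested subjects; (6) collapse residual (peptide, allele)
#' duplicates, keeping the positive label when outcomes conflict (any
#' validated T-cell response is taken as evidence of immunogenicity).
#'
#' @param records A data.frame/data.table of assay records with columns
#'   `peptide`, `allele`, `assay`, `outcome` and optionally
#'   `n_subjects_tested` (see [read_assay_table()]).
#' @return A `neoimm_curated` object: a `data.table` with columns `peptide`,
#'   `allele` (normalized), `label` (0/1) and attribute `provenance`, a named
#'   vector of records removed per filter stage.
#' @examples
#' recs <- data.frame(
#'   peptide = c("SIINFEKLV", "AAAAAAAAA"),
#'   allele = c("HLA-A*02:01", "HLA-A*02:01"),
#'   assay = c("IFNg ELISPOT", "proliferation"),
#'   outcome = c("Positive", "Positive")
#' )
#' curate(recs)  # one survivor
#' @export
curate <- function(records) {
  dt <- data.table::as.data.table(records)
  stages <- c(assay_filter = 0L, allele_filter = 0L, exact_duplicates = 0L,
              length_filter = 0L, thin_negatives = 0L, pair_collapse = 0L)
  if (nrow(dt) == 0L) {
    out <- data.table::data.table(peptide = character(),
                                  allele = character(), label = integer())
    return(new_curated(out, stages))
  }
  if (!"n_subjects_tested" %in% names(dt)) dt$n_subjects_tested <- NA_integer_
  dt$outcome <- coerce_outcome(dt$outcome)
  dt$peptide <- toupper(trimws(dt$peptide))

  n0 <- nrow(dt)
  dt <- dt[assay_allowed(dt$assay)]
  stages["assay_filter"] <- n0 - nrow(dt)

  n0 <- nrow(dt)
  dt <- dt[allele_resolvable(dt$allele)]
  stages["allele_filter"] <- n0 - nrow(dt)
  if (nrow(dt) > 0L) dt$allele <- normalize_allele_name(dt$allele)

  n0 <- nrow(dt)
  dt <- dt[!duplicated(dt[, c("peptide", "allele", "outcome")])]
  stages["exact_duplicates"] <- n0 - nrow(dt)

  n0 <- nrow(dt)
  len <- nchar(dt$peptide)
  dt <- dt[len >= 8L & len <= 11L]
  stages["length_filter"] <- n0 - nrow(dt)

  n0 <- nrow(dt)
  thin <- dt$outcome == 0L &
    (is.na(dt$n_subjects_tested) | dt$n_subjects_tested < 4L)
  dt <- dt[!thin]
  stages["thin_negatives"] <- n0 - nrow(dt)

  # conflict rule: a (peptide, allele) pair with both outcomes keeps the
  # positive record
  n0 <- nrow(dt)
  dt <- dt[order(dt$peptide, dt$allele, -dt$outcome)]
  dt <- dt[!duplicated(dt[, c("peptide", "allele")])]
  stages["pair_collapse"] <- n0 - nrow(dt)

  out <- dt[, c("peptide", "allele", "outcome"), with = FALSE]
  data.table::setnames(out, "outcome", "label")
  new_curated(out, stages)
}

new_curated <- function(dt, provenance) {
  data.table::setattr(dt, "provenance", provenance)
  data.table::setattr(dt, "class", c("neoimm_curated", class(dt)))
  dt
}

#' @export
print.neoimm_curated <- function(x, ...) {
  cat("Curated immunogenicity dataset: ", nrow(x), " (peptide, allele) pairs, ",
      sum(x$label == 1L), " positive / ", sum(x$label == 0L), " negative\n",
      sep = "")
  prov <- attr(x, "provenance")
  cat("records removed per stage: ",
      paste(names(prov), prov, sep = "=", collapse = ", "), "\n", sep = "")
  if ("split" %in% names(x)) {
    cat("splits: ", paste(names(table(x$split)), table(x$split),
                          sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Convert a curated dataset back to well-formed assay records
#'
#' Useful for re-curation round trips; every emitted record passes all
#' curation filters by construction.
#'
#' @param curated A `neoimm_curated` dataset.
#' @return A `data.table` of assay records.
#' @export
as_assay_records <- function(curated) {
  data.table::data.table(
    peptide = curated$peptide,
    allele = curated$allele,
    assay = "ELISPOT",
    outcome = ifelse(curated$label == 1L, "Positive", "Negative"),
    n_subjects_tested = 10L,
    n_subjects_responded = ifelse(curated$label == 1L, 5L, 0L)
  )
}

#' Assign train/test/validation splits
#'
#' Splits rows uniformly at random (seeded, unstratified) into training,
#' testing and validation sets. Counts are floor-based with the remainder
#' assigned to training, so n = 1000 under the default 70/20/10 split gives
#' exactly 700/200/100.
#'
#' @param dataset A `neoimm_curated` dataset (or any data.frame).
#' @param fractions Numeric triple (train, test, validation) summing to 1.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return The dataset with a `split` column added.
#' @export
assign_splits <- function(dataset, fractions = c(0.7, 0.2, 0.1), seed = 42L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must be a triple summing to 1", call. = FALSE)
  }
  n <- nrow(dataset)
  n_test <- floor(fractions[2] * n)
  n_val <- floor(fractions[3] * n)
  n_train <- n - n_test - n_val
  split <- rep(c("train", "test", "validation"), c(n_train, n_test, n_val))
  perm <- with_seed(seed, sample.int(n))
  dataset$split <- split[order(perm)]
  dataset
}

# Evaluate expr with a temporary RNG state seeded by `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Write / read a curated dataset
#'
#' TSV with columns `peptide`, `allele`, `label` and, when present, `split`;
#' provenance counts go to a JSON sidecar `<path>.provenance.json`.
#'
#' @param curated A `neoimm_curated` dataset.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_curated <- function(curated, path) {
  data.table::fwrite(curated, path, sep = "\t")
  prov <- attr(curated, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(as.list(prov), paste0(path, ".provenance.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_curated
#' @export
read_curated <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  prov_path <- paste0(path, ".provenance.json")
  prov <- if (file.exists(prov_path)) {
    unlist(jsonlite::read_json(prov_path))
  } else NULL
  new_curated(dt, prov)
}
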