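#' Filter candidate neoepitopes by the selection criteria
#'
#' Keeps candidates satisfying all four criteria: TAP score > 0 (strict),
#' IC50 <= 500 nM (inclusive), TPM > 0 (strict) and predicted immunogenicity
#' > 0.5 (strict). Input order is preserved; an empty result is allowed.
#'
#' @param candidates A data.frame with numeric columns `tap`, `ic50_nm`
#'   (or `ic50`), `tpm`, `immunogenicity`.
#' @param rejects_path Optional path; when given, rejected rows are written
#'   there as TSV with a `failed_criterion` column naming the first
#'   criterion (in the order above) each row failed.
#' @return The surviving rows, original order and columns.
#' @export
filter_candidates <- function(candidates, rejects_path = NULL) {
  dt <- data.table::as.data.table(candidates)
  ic50 <- candidate_ic50(dt)
  need <- c("tap", "tpm", "immunogenicity")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stop("candidate table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- dt$tap > 0 & ic50 <= 500 & dt$tpm > 0 & dt$immunogenicity > 0.5
  if (!is.null(rejects_path)) {
    rej <- dt[!keep]
    if (nrow(rej) > 0L) {
      ric <- ic50[!keep]
      rej$failed_criterion <- ifelse(!(rej$tap > 0), "tap",
                              ifelse(!(ric <= 500), "ic50",
                              ifelse(!(rej$tpm > 0), "tpm", "immunogenicity")))
    } else {
      rej$failed_criterion <- character(0)
    }
    data.table::fwrite(rej, rejects_path, sep = "\t")
  }
  dt[keep]
}

candidate_ic50 <- function(dt) {
  if ("ic50_nm" %in% names(dt)) return(dt$ic50_nm)
  if ("ic50" %in% names(dt)) return(dt$ic50)
  stop("candidate table missing column(s): ic50_nm", call. = FALSE)
}

#' Rank candidate neoepitopes
#'
#' Orders candidates by descending predicted immunogenicity. Ties are broken
#' by ascending IC50 (stronger binder first), then descending TAP score,
#' then lexicographic peptide -- making the ranking a deterministic total
#' order for any input permutation. Adds 1-based `rank` and
#' `rank_percentage` = rank / total * 100.
#'
#' @param candidates A (typically filtered) candidate table with columns
#'   `peptide`, `immunogenicity`, `ic50_nm` (or `ic50`), `tap`.
#' @return The reordered table with `rank` and `rank_percentage` columns.
#' @export
rank_candidates <- function(candidates) {
  dt <- data.table::as.data.table(candidates)
  if (nrow(dt) == 0L) {
    dt$rank <- integer(0)
    dt$rank_percentage <- numeric(0)
    return(dt)
  }
  ic50 <- candidate_ic50(dt)
  ord <- order(-dt$immunogenicity, ic50, -dt$tap, dt$peptide,
               method = "radix")
  dt <- dt[ord]
  dt$rank <- seq_len(nrow(dt))
  dt$rank_percentage <- dt$rank / nrow(dt) * 100
  dt
}

#' Read / write a candidate neoepitope table
#'
#' TSV/CSV with columns `peptide`, `allele`, `ic50_nm`, `tap`, `tpm` and,
#' once scored, `immunogenicity`; extra columns (e.g. `source_variant`) are
#' passed through.
#'
#' @param path File path.
#' @return A `data.table`.
#' @export
read_candidates <- function(path) {
  dt <- data.table::fread(path, sep = "auto", na.strings = c("", "NA"))
  need <- c("peptide", "allele")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stop("candidate table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt
}

#' @rdname read_candidates
#' @param candidates Table to write.
#' @export
write_candidates <- function(candidates, path) {
  data.table::fwrite(candidates, path, sep = "\t")
  invisible(path)
}
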