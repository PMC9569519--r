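# Seeded generator of synthetic immunogenicity assay tables with a planted,
# learnable rule. It emulates the statistical structure the model assumes:
# per-allele anchor-residue preferences at the canonical class I anchor
# positions (position 2 and the C-terminus), a heavy-tailed IC50 scale, and
# a monotone relationship between binding strength / TAP transport and the
# probability of a positive T-cell assay.

#' Synthetic assay simulation settings
#'
#' Defaults define the reference study conditions: the positive fraction
#' targets the roughly 40% positive rate of curated class I T-cell assay
#' collections, IC50 is drawn log-uniformly on 1--50,000 nM, the TAP score
#' is standard normal, and the planted rule is
#' `p_true = sigmoid(b0 + beta_anchor * anchor_matches +
#' beta_ba * (1 - ba_norm) + beta_tap * tap_norm + noise)`,
#' so stronger binders and efficiently transported peptides trend
#' immunogenic and the anchor preference gives the sequence branches a
#' positional signal. `b0` is calibrated so the mean of `p_true` hits
#' `positive_fraction_target`.
#'
#' @param n_records Number of clean assay records.
#' @param n_alleles Number of synthetic 4-digit alleles.
#' @param peptide_length_range Inclusive bounds within 8--11.
#' @param positive_fraction_target Target mean of the latent probability.
#' @param rule_coefficients Named numeric: `beta_anchor` (per matched anchor
#'   residue), `beta_ba`, `beta_tap`.
#' @param anchor_rate Probability that each anchor position carries the
#'   allele's preferred residue.
#' @param noise_sd SD of the Gaussian noise added to the linear predictor.
#' @param contamination Named fractions (of `n_records`) of records made to
#'   violate each curation filter: `bad_assay`, `two_digit_allele`,
#'   `wrong_length`, `thin_negatives`, `duplicates`.
#' @param seed Integer seed; output tables are byte-identical across runs.
#' @return A `neoimm_sim_config` list.
#' @export
simulation_config <- function(n_records = 2000L,
                              n_alleles = 12L,
                              peptide_length_range = c(8L, 11L),
                              positive_fraction_target = 0.4,
                              rule_coefficients = c(beta_anchor = 2,
                                                    beta_ba = 14,
                                                    beta_tap = 4),
                              anchor_rate = 0.4,
                              noise_sd = 0.4,
                              contamination = c(bad_assay = 0,
                                                two_digit_allele = 0,
                                                wrong_length = 0,
                                                thin_negatives = 0,
                                                duplicates = 0),
                              seed = 7L) {
  stopifnot(n_records > 0L, n_alleles > 0L,
            peptide_length_range[1] >= 8L, peptide_length_range[2] <= 11L,
            positive_fraction_target > 0, positive_fraction_target < 1,
            noise_sd >= 0, anchor_rate >= 0, anchor_rate <= 1)
  cont <- c(bad_assay = 0, two_digit_allele = 0, wrong_length = 0,
            thin_negatives = 0, duplicates = 0)
  if (length(contamination) > 0L) {
    bad <- setdiff(names(contamination), names(cont))
    if (length(bad) > 0L) {
      stop("unknown contamination type(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cont[names(contamination)] <- contamination
  }
  if (any(cont < 0) || any(cont > 1)) {
    stop("contamination fractions must lie in [0, 1]", call. = FALSE)
  }
  # in-place corruptions must leave room in the clean table
  if (sum(cont[c("bad_assay", "two_digit_allele", "wrong_length",
                 "thin_negatives")]) > 1) {
    stop("in-place contamination fractions sum to more than 1",
         call. = FALSE)
  }
  rc <- c(beta_anchor = 2, beta_ba = 14, beta_tap = 4)
  rc[names(rule_coefficients)] <- rule_coefficients
  structure(list(
    n_records = as.integer(n_records), n_alleles = as.integer(n_alleles),
    peptide_length_range = as.integer(peptide_length_range),
    positive_fraction_target = positive_fraction_target,
    rule_coefficients = rc, anchor_rate = anchor_rate,
    noise_sd = noise_sd, contamination = cont, seed = as.integer(seed)
  ), class = "neoimm_sim_config")
}

standard_residues <- function() setdiff(aa_alphabet()$symbols, "X")

# pseudo-sequence positions whose residues define the planted anchor
# preferences (indices into the pseudo-sequence string)
anchor_pseudo_positions <- function() c(5L, 20L)

# random unique 4-digit allele names on loci A/B/C
random_allele_names <- function(n) {
  pool <- expand.grid(locus = c("A", "B", "C"),
                      group = sprintf("%02d", 1:99),
                      protein = sprintf("%02d", 1:20),
                      stringsAsFactors = FALSE)
  pick <- pool[sample.int(nrow(pool), n), ]
  sprintf("HLA-%s*%s:%s", pick$locus, pick$group, pick$protein)
}

random_peptides <- function(n, len_range) {
  res <- standard_residues()
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  peps <- vapply(lens, function(L) {
    paste(sample(res, L, replace = TRUE), collapse = "")
  }, character(1))
  # regenerate collisions so (peptide, allele) pairs stay unique
  while (anyDuplicated(peps) > 0L) {
    dup <- which(duplicated(peps))
    peps[dup] <- vapply(lens[dup], function(L) {
      paste(sample(res, L, replace = TRUE), collapse = "")
    }, character(1))
  }
  peps
}

#' Simulate an assay table with a planted immunogenicity rule
#'
#' Generates alleles with random pseudo-sequences and planted anchor
#' preferences, peptides with anchor residues planted at position 2 and the
#' C-terminus at rate `anchor_rate`, per-record features, latent
#' probabilities under the planted rule and Bernoulli labels; then injects
#' curation-filter violations per `config$contamination`. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `assays` (raw assay table), `features` (per-pair
#'   feature table with `ic50_nm`, `tap`, `tpm`), `pseudo_table`, and
#'   `truth` (a `neoimm_truth` holding each clean record's latent
#'   probability, the planted anchors and the intercept).
#' @export
simulate_assays <- function(config = simulation_config()) {
  stopifnot(inherits(config, "neoimm_sim_config"))
  with_seed(config$seed, simulate_assays_impl(config))
}

simulate_assays_impl <- function(config) {
  n <- config$n_records
  res <- standard_residues()
  alleles <- random_allele_names(config$n_alleles)
  pseudo_seqs <- vapply(seq_len(config$n_alleles), function(i) {
    paste(sample(res, length(pseudo_positions()), replace = TRUE),
          collapse = "")
  }, character(1))
  ptab <- pseudo_table(stats::setNames(pseudo_seqs, alleles))
  # anchor preferences are read off fixed pocket positions of the
  # pseudo-sequence (B pocket ~ position 5, F pocket ~ position 20), the way
  # real anchor motifs are determined by the peptide-contact residues --
  # so the planted rule is a relation between peptide and pseudo-sequence
  # that generalizes across alleles
  anchors <- data.frame(
    allele = alleles,
    anchor_p2 = substr(pseudo_seqs, anchor_pseudo_positions()[1],
                       anchor_pseudo_positions()[1]),
    anchor_ct = substr(pseudo_seqs, anchor_pseudo_positions()[2],
                       anchor_pseudo_positions()[2])
  )

  peptide <- random_peptides(n, config$peptide_length_range)
  allele <- alleles[sample.int(config$n_alleles, n, replace = TRUE)]
  ai <- match(allele, anchors$allele)
  # plant anchors at rate anchor_rate
  set_p2 <- stats::runif(n) < config$anchor_rate
  set_ct <- stats::runif(n) < config$anchor_rate
  peptide <- ifelse(set_p2,
                    paste0(substr(peptide, 1, 1), anchors$anchor_p2[ai],
                           substr(peptide, 3, nchar(peptide))),
                    peptide)
  L <- nchar(peptide)
  peptide <- ifelse(set_ct,
                    paste0(substr(peptide, 1, L - 1), anchors$anchor_ct[ai]),
                    peptide)
  anchor_matches <- (substr(peptide, 2, 2) == anchors$anchor_p2[ai]) +
    (substr(peptide, nchar(peptide), nchar(peptide)) == anchors$anchor_ct[ai])

  ic50 <- exp(stats::runif(n, log(1), log(50000)))
  tap <- stats::rnorm(n)
  tpm <- ifelse(stats::runif(n) < 0.1, 0, stats::rlnorm(n, 1.5, 1.2))
  ba_norm <- log(ic50) / log(50000)
  tap_norm <- pmin(1, pmax(0, (tap + 3) / 6))

  rc <- config$rule_coefficients
  eta0 <- rc[["beta_anchor"]] * anchor_matches +
    rc[["beta_ba"]] * (1 - ba_norm) +
    rc[["beta_tap"]] * tap_norm +
    stats::rnorm(n, 0, config$noise_sd)
  # calibrate the intercept so mean(p_true) hits the target fraction
  b0 <- stats::uniroot(function(b) {
    mean(sigmoid(eta0 + b)) - config$positive_fraction_target
  }, lower = -50, upper = 50)$root
  p_true <- sigmoid(eta0 + b0)
  label <- stats::rbinom(n, 1L, p_true)

  assay_pool <- c("IFNg ELISPOT", "ICS", "multimer/tetramer",
                  "51 Chromium release", "ELISA")
  assays <- data.table::data.table(
    peptide = peptide,
    allele = allele,
    assay = assay_pool[sample.int(length(assay_pool), n, replace = TRUE)],
    outcome = ifelse(label == 1L, "Positive", "Negative"),
    n_subjects_tested = sample(4:40, n, replace = TRUE),
    n_subjects_responded = 0L
  )
  assays$n_subjects_responded <- ifelse(
    label == 1L, pmax(1L, round(assays$n_subjects_tested * 0.3)), 0L)

  features <- data.table::data.table(
    peptide = peptide, allele = allele,
    ic50_nm = ic50, tap = tap, tpm = tpm
  )

  # contamination: disjoint in-place corruptions, then appended duplicates
  cont <- config$contamination
  counts <- floor(cont[c("bad_assay", "two_digit_allele", "wrong_length",
                         "thin_negatives")] * n)
  avail <- sample.int(n)
  taken <- 0L
  pick <- function(k) {
    out <- avail[seq_len(k) + taken]
    taken <<- taken + k
    out
  }
  clean_flag <- rep(TRUE, n)
  if (counts[["bad_assay"]] > 0L) {
    i <- pick(counts[["bad_assay"]])
    assays$assay[i] <- "proliferation assay"
    clean_flag[i] <- FALSE
  }
  if (counts[["two_digit_allele"]] > 0L) {
    i <- pick(counts[["two_digit_allele"]])
    assays$allele[i] <- paste0("HLA-", substr(assays$allele[i], 5, 5),
                               sample(1:9, length(i), replace = TRUE))
    clean_flag[i] <- FALSE
  }
  if (counts[["wrong_length"]] > 0L) {
    i <- pick(counts[["wrong_length"]])
    extra <- vapply(seq_along(i), function(j) {
      paste(sample(res, 4, replace = TRUE), collapse = "")
    }, character(1))
    assays$peptide[i] <- paste0(assays$peptide[i], extra)  # 12-15 mer
    clean_flag[i] <- FALSE
  }
  if (counts[["thin_negatives"]] > 0L) {
    i <- pick(counts[["thin_negatives"]])
    assays$outcome[i] <- "Negative"
    assays$n_subjects_tested[i] <- sample(1:3, length(i), replace = TRUE)
    assays$n_subjects_responded[i] <- 0L
    clean_flag[i] <- FALSE
  }
  n_dup <- floor(cont[["duplicates"]] * n)
  if (n_dup > 0L) {
    di <- sample(which(clean_flag), n_dup, replace = TRUE)
    assays <- rbind(assays, assays[di])
  }

  truth <- structure(list(
    key = paste(peptide, allele, sep = "|"),
    p_true = p_true,
    clean = clean_flag,
    anchors = anchors,
    intercept = b0,
    coefficients = rc,
    seed = config$seed
  ), class = "neoimm_truth")

  list(assays = assays, features = features, pseudo_table = ptab,
       truth = truth)
}

#' @export
print.neoimm_truth <- function(x, ...) {
  cat("Synthetic truth: ", length(x$p_true), " records, intercept ",
      signif(x$intercept, 4), ", coefficients ",
      paste(names(x$coefficients), x$coefficients, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Bayes-optimal reference scores for simulated records
#'
#' Returns each record's latent probability `p_true` under the planted rule
#' -- the Bayes-optimal scorer of the sampled labels, against which trained
#' models' rank correlation is measured.
#'
#' @param truth A `neoimm_truth` from [simulate_assays()].
#' @param records Rows generated by the matching simulation (any table with
#'   `peptide` and `allele` columns).
#' @return Numeric vector of probabilities, one per row of `records`.
#' @export
oracle_scores <- function(truth, records) {
  stopifnot(inherits(truth, "neoimm_truth"))
  key <- paste(toupper(trimws(records$peptide)),
               normalize_allele_name(records$allele), sep = "|")
  idx <- match(key, truth$key)
  if (anyNA(idx)) {
    stop("record/truth mismatch: ", sum(is.na(idx)),
         " record(s) not generated by this truth", call. = FALSE)
  }
  truth$p_true[idx]
}
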