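#' Triplicate Cq quality control
#'
#' qPCR samples are run in triplicate on each channel; a sample whose
#' triplicates disagree too much is unreliable. A sample fails QC when the
#' sample standard deviation (n - 1 denominator) of either its target or its
#' normalizer triplicate exceeds `max_sd` cycles.
#'
#' @param qpcr Tidy qPCR table: `sample_id`, `strain`, `assay`, `channel`
#'   (`"target"` or `"normalizer"`), `cq1`, `cq2`, `cq3`.
#' @param max_sd Maximum allowed triplicate standard deviation in cycles
#'   (default 0.4).
#' @return Tibble per `sample_id` x `assay`: `sd_target`, `sd_normalizer`,
#'   `pass`.
#' @export
qc_triplicates <- function(qpcr, max_sd = 0.4) {
  assert_columns(qpcr, c("sample_id", "assay", "channel", "cq1", "cq2", "cq3"),
                 "qPCR table")
  cq <- as.matrix(qpcr[, c("cq1", "cq2", "cq3")])
  if (!all(is.finite(cq))) abort("non-finite Cq value in qPCR table")
  if (any(cq <= 0)) abort("Cq values must be positive")
  qpcr |>
    as_tibble() |>
    dplyr::mutate(cq_sd = apply(cq, 1L, sd)) |>
    dplyr::group_by(.data$sample_id, .data$assay) |>
    dplyr::summarise(
      sd_target = .data$cq_sd[.data$channel == "target"][1],
      sd_normalizer = .data$cq_sd[.data$channel == "normalizer"][1],
      .groups = "drop"
    ) |>
    dplyr::mutate(pass = .data$sd_target <= max_sd & .data$sd_normalizer <= max_sd)
}

#' Per-sample delta-Ct
#'
#' `mean(target Cq) - mean(normalizer Cq)` for every sample x assay that
#' passes triplicate QC; failing samples are excluded with a message.
#'
#' @inheritParams qc_triplicates
#' @param max_sd Triplicate QC threshold; set to `Inf` to skip QC.
#' @return Tibble: `sample_id`, `strain`, `assay`, `delta_ct`.
#' @export
delta_ct <- function(qpcr, max_sd = 0.4) {
  assert_columns(qpcr, c("sample_id", "strain", "assay", "channel",
                         "cq1", "cq2", "cq3"), "qPCR table")
  qc <- qc_triplicates(qpcr, max_sd = max_sd)
  n_fail <- sum(!qc$pass)
  if (n_fail > 0) {
    inform(sprintf("delta_ct: excluded %d sample(s) failing the Cq-SD %.2g filter",
                   n_fail, max_sd))
  }
  keep <- qc[qc$pass, c("sample_id", "assay")]
  qpcr |>
    as_tibble() |>
    dplyr::inner_join(keep, by = c("sample_id", "assay")) |>
    dplyr::mutate(cq_mean = (.data$cq1 + .data$cq2 + .data$cq3) / 3) |>
    dplyr::group_by(.data$sample_id, .data$strain, .data$assay) |>
    dplyr::summarise(
      delta_ct = .data$cq_mean[.data$channel == "target"][1] -
        .data$cq_mean[.data$channel == "normalizer"][1],
      .groups = "drop"
    )
}

#' Relative fold change by the 2^-ddCt method
#'
#' `fc = 2^-(delta_ct - reference_dct)`, so a sample amplifying earlier than
#' the reference (smaller delta-Ct) has `fc > 1`. `log2_fc` is exactly
#' `-ddct`.
#'
#' @param dct Tibble from [delta_ct()] (columns `sample_id`, `strain`,
#'   `assay`, `delta_ct`).
#' @param reference_dct Scalar reference delta-Ct (the calibrator).
#' @return Input tibble plus `ddct`, `fc`, `log2_fc`.
#' @export
fold_change <- function(dct, reference_dct) {
  assert_columns(dct, "delta_ct", "delta-Ct table")
  stopifnot(is.numeric(reference_dct), length(reference_dct) == 1L,
            is.finite(reference_dct))
  dct |>
    as_tibble() |>
    dplyr::mutate(
      ddct = .data$delta_ct - reference_dct,
      log2_fc = -.data$ddct,
      fc = 2^(-.data$ddct)
    )
}

#' Density fold change relative to a random reference-strain sample
#'
#' Workflow for symbiont density: target = a single-copy bacterial gene,
#' normalizer = a conserved single-copy host gene. The calibrator is one
#' randomly selected sample of `reference_strain` (seedable; the chosen
#' sample id is recorded in attribute `reference_sample`).
#'
#' @inheritParams delta_ct
#' @param reference_strain Strain supplying the calibrator sample
#'   (default `"wMel"`).
#' @param seed Optional integer making the calibrator choice reproducible.
#' @return Fold-change tibble as in [fold_change()].
#' @export
quantify_density <- function(qpcr, reference_strain = "wMel", max_sd = 0.4,
                             seed = NULL) {
  dct <- delta_ct(qpcr, max_sd = max_sd)
  refs <- dct[dct$strain == reference_strain, , drop = FALSE]
  if (nrow(refs) == 0) {
    abort(sprintf("no QC-passing samples of reference strain %s", reference_strain))
  }
  pick <- with_seed(seed, refs$sample_id[sample.int(nrow(refs), 1L)])
  out <- fold_change(dct, refs$delta_ct[refs$sample_id == pick][1])
  attr(out, "reference_sample") <- pick
  out
}

#' Transcript-level fold change relative to reference assay groups
#'
#' Workflow for transcript levels normalised to an exogenous spike-in
#' control: the calibrator delta-Ct is the unweighted mean of the per-sample
#' delta-Ct values over the designated reference assay groups (averaging in
#' delta-Ct space, i.e. log2 space, because fold changes are ratios).
#'
#' @inheritParams delta_ct
#' @param reference_assays Character vector of assay names whose samples form
#'   the calibrator group.
#' @return Fold-change tibble as in [fold_change()], with attribute
#'   `reference_dct`.
#' @export
quantify_transcripts <- function(qpcr, reference_assays, max_sd = 0.4) {
  stopifnot(is.character(reference_assays), length(reference_assays) >= 1)
  dct <- delta_ct(qpcr, max_sd = max_sd)
  ref <- dct$delta_ct[dct$assay %in% reference_assays]
  if (length(ref) == 0) {
    abort("no QC-passing samples in the reference assay groups")
  }
  out <- fold_change(dct, mean(ref))
  attr(out, "reference_dct") <- mean(ref)
  out
}

#' Pairwise strain comparisons of log2 fold change
#'
#' Welch two-sample t tests of each strain's `log2_fc` against the reference
#' strain's, with Benjamini-Hochberg adjustment across the compared strains.
#' Strains with fewer than two QC-passing samples are excluded with a
#' warning.
#'
#' @param fc Fold-change tibble (needs `strain`, `log2_fc`).
#' @param reference_strain Baseline strain (default `"wMel"`).
#' @param p_adjust Multiplicity adjustment (default `"BH"`).
#' @return Tibble: `strain`, `n`, `estimate` (mean log2-fc difference vs the
#'   reference), `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
compare_to_reference_strain <- function(fc, reference_strain = "wMel",
                                        p_adjust = "BH") {
  assert_columns(fc, c("strain", "log2_fc"), "fold-change table")
  ref <- fc$log2_fc[fc$strain == reference_strain]
  if (length(ref) < 2) abort(sprintf("reference strain %s needs >= 2 samples",
                                     reference_strain))
  strains <- setdiff(unique(fc$strain), reference_strain)
  rows <- lapply(strains, function(s) {
    x <- fc$log2_fc[fc$strain == s]
    if (length(x) < 2) {
      warn(sprintf("strain %s has < 2 samples; excluded from comparisons", s))
      return(NULL)
    }
    tt <- stats::t.test(x, ref)
    tibble(
      strain = s, n = length(x),
      estimate = mean(x) - mean(ref),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$p_adjusted <- p.adjust(out$p_value, method = p_adjust)
  out
}
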