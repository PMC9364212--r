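# Synthetic-study generator: a complete fake study (tree, strain truth,
# vial-level hatch counts, Cq triplicates, development times) with every
# generating parameter recorded, so the whole pipeline can be tested for
# parameter recovery end-to-end.

#' Generate a synthetic CI study with known ground truth
#'
#' The generative model mirrors the structure the analysis assumes:
#' * a unit-height Yule strain phylogeny;
#' * strain-level log2 cifB-transcript level evolving under lambda-scaled
#'   Brownian motion, with CI strength linked through a logistic curve
#'   `s* = logistic(intercept + slope * level)` (keeps `s*` in `[0, 1]`);
#' * independent Brownian log2 density and cifA levels, and per-strain
#'   normal development times;
#' * per vial, eggs laid ~ Poisson(`mean_eggs`) truncated at 1 and eggs
#'   hatched ~ Binomial(eggs, p) with `p = compat_hatch` in compatible
#'   crosses and `compat_hatch * (1 - s*)` in the CI cross;
#' * Cq triplicates ~ Normal(true Cq, `cq_sd`) around a true delta-Ct of
#'   `-log2(true fold change)`.
#'
#' @param n_strains Number of strains (tips), default 10.
#' @param slope,intercept Logistic-link coefficients from cifB level to CI
#'   strength (defaults 2 and 0).
#' @param lam Pagel's lambda used to simulate the cifB levels (default 1).
#' @param sigma2 Brownian rate for all simulated log2 traits (default 1).
#' @param vials_per_cross Vials per strain per cross type (default 30).
#' @param mean_eggs Poisson mean of eggs laid per vial (default 40).
#' @param compat_hatch Hatch probability in compatible crosses (default 0.9).
#' @param cq_sd Within-triplicate Cq standard deviation in cycles
#'   (default 0.2).
#' @param samples_per_strain qPCR samples per strain per assay (default 6).
#' @param n_reference_strains How many strains' transcript assays form the
#'   calibrator group (default: 4, capped at `n_strains`).
#' @param seed Optional master seed; every component gets a stable child
#'   seed.
#' @return A `ci_study` list: `tree`, `truth` (per-strain tibble), `vials`,
#'   `qpcr_density`, `qpcr_cifA`, `qpcr_cifB`, `development`, and `params`
#'   (the full generating configuration, suitable for a manifest).
#' @examples
#' study <- make_study(n_strains = 6, seed = 7)
#' head(study$vials)
#' @export
make_study <- function(n_strains = 10, slope = 2, intercept = 0, lam = 1,
                       sigma2 = 1, vials_per_cross = 30, mean_eggs = 40,
                       compat_hatch = 0.9, cq_sd = 0.2,
                       samples_per_strain = 6, n_reference_strains = NULL,
                       seed = NULL) {
  n_reference_strains <- n_reference_strains %||% min(4L, n_strains)
  stopifnot(n_strains >= 2, vials_per_cross >= 1, mean_eggs > 0,
            compat_hatch > 0, compat_hatch <= 1, cq_sd >= 0,
            samples_per_strain >= 2,
            n_reference_strains >= 1, n_reference_strains <= n_strains)
  seeds <- function(stage) if (is.null(seed)) NULL else child_seed(seed, stage)

  tree <- simulate_yule(n_strains, seed = seeds("tree"))
  strains <- sprintf("s%02d", seq_len(n_strains))
  tree$tip.label <- strains

  cifB <- simulate_bm(tree, sigma2 = sigma2, lambda = lam, seed = seeds("cifB"))
  cifA <- simulate_bm(tree, sigma2 = sigma2, lambda = lam, seed = seeds("cifA"))
  density <- simulate_bm(tree, sigma2 = sigma2, lambda = lam, seed = seeds("density"))
  s_star <- stats::plogis(intercept + slope * cifB)

  truth <- with_seed(seeds("development"), tibble(
    strain = strains,
    s_star = unname(s_star[strains]),
    density_log2 = unname(density[strains]),
    cifA_log2 = unname(cifA[strains]),
    cifB_log2 = unname(cifB[strains]),
    larval_h = rnorm(n_strains, 120, 8),
    pupal_h = rnorm(n_strains, 100, 6)
  ))
  truth$egg_adult_h <- truth$larval_h + truth$pupal_h

  cross_types <- c("UU", "UI", "IU", "II")
  vials <- with_seed(seeds("vials"), {
    grid <- tidyr::expand_grid(strain = strains, cross_type = cross_types,
                               vial = seq_len(vials_per_cross))
    eggs <- rpois(nrow(grid), mean_eggs)
    eggs[eggs == 0] <- 1L
    p <- ifelse(grid$cross_type == "UI",
                compat_hatch * (1 - truth$s_star[match(grid$strain, strains)]),
                compat_hatch)
    tibble(
      strain = grid$strain, cross_type = grid$cross_type,
      eggs_laid = eggs, eggs_hatched = rbinom(nrow(grid), eggs, p)
    )
  })

  make_qpcr <- function(log2_fc, assay_prefix, stage, base_cq = 18) {
    with_seed(seeds(stage), {
      grid <- tidyr::expand_grid(strain = strains, rep = seq_len(samples_per_strain))
      dct <- -log2_fc[match(grid$strain, strains)]
      rows <- lapply(seq_len(nrow(grid)), function(i) {
        sid <- sprintf("%s_%s_r%02d", assay_prefix, grid$strain[i], grid$rep[i])
        assay <- paste0(assay_prefix, "_", grid$strain[i])
        tibble(
          sample_id = sid, strain = grid$strain[i], assay = assay,
          channel = c("target", "normalizer"),
          cq1 = rnorm(2, c(base_cq + dct[i], base_cq), cq_sd),
          cq2 = rnorm(2, c(base_cq + dct[i], base_cq), cq_sd),
          cq3 = rnorm(2, c(base_cq + dct[i], base_cq), cq_sd)
        )
      })
      dplyr::bind_rows(rows)
    })
  }
  qpcr_density <- make_qpcr(density, "ftsZ", "qpcr_density")
  qpcr_density$assay <- "ftsZ"  # one shared density assay across strains
  qpcr_cifA <- make_qpcr(cifA, "cifA", "qpcr_cifA")
  qpcr_cifB <- make_qpcr(cifB, "cifB", "qpcr_cifB")

  development <- with_seed(seeds("dev_obs"), {
    grid <- tidyr::expand_grid(strain = strains, rep = seq_len(10))
    i <- match(grid$strain, strains)
    tibble(
      strain = grid$strain,
      larval_h = rnorm(nrow(grid), truth$larval_h[i], 2),
      pupal_h = rnorm(nrow(grid), truth$pupal_h[i], 2)
    ) |>
      dplyr::mutate(egg_adult_h = .data$larval_h + .data$pupal_h)
  })

  ref_strains <- strains[seq_len(n_reference_strains)]
  params <- list(
    n_strains = n_strains, slope = slope, intercept = intercept, lam = lam,
    sigma2 = sigma2, vials_per_cross = vials_per_cross, mean_eggs = mean_eggs,
    compat_hatch = compat_hatch, cq_sd = cq_sd,
    samples_per_strain = samples_per_strain,
    reference_strains = ref_strains,
    reference_assays_cifA = paste0("cifA_", ref_strains),
    reference_assays_cifB = paste0("cifB_", ref_strains),
    seed = seed
  )
  structure(
    list(tree = tree, truth = truth, vials = vials,
         qpcr_density = qpcr_density, qpcr_cifA = qpcr_cifA,
         qpcr_cifB = qpcr_cifB, development = development, params = params),
    class = "ci_study"
  )
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Writes `tree.nwk`, `vials.csv`, `qpcr_density.csv`, `qpcr_cifA.csv`,
#' `qpcr_cifB.csv`, `development.csv`, `truth.csv` and `manifest.json`
#' under `dir`.
#'
#' @param study A `ci_study` from [make_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ci_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(study$vials, file.path(dir, "vials.csv"), row.names = FALSE)
  utils::write.csv(study$qpcr_density, file.path(dir, "qpcr_density.csv"), row.names = FALSE)
  utils::write.csv(study$qpcr_cifA, file.path(dir, "qpcr_cifA.csv"), row.names = FALSE)
  utils::write.csv(study$qpcr_cifB, file.path(dir, "qpcr_cifB.csv"), row.names = FALSE)
  utils::write.csv(study$development, file.path(dir, "development.csv"), row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(study$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' True-vs-estimated recovery table for a synthetic study
#'
#' Joins pipeline estimates back onto the generating truth and reports the
#' bias per parameter (and interval coverage where an interval exists).
#' Transcript truths are centred on the calibrator group the estimates used,
#' so truth and estimate live on the same scale.
#'
#' @param study A `ci_study` from [make_study()].
#' @param ci Optional [ci_strength()] result on `study$vials`.
#' @param transcripts Optional [quantify_transcripts()] result on
#'   `study$qpcr_cifB`.
#' @param fit Optional `pgls_fit` of mean CI strength on mean cifB level.
#' @return Tibble: `parameter`, `strain` (NA for global parameters), `true`,
#'   `estimate`, `bias`, `covered` (NA when no interval applies).
#' @export
recovery_report <- function(study, ci = NULL, transcripts = NULL, fit = NULL) {
  stopifnot(inherits(study, "ci_study"))
  out <- list()
  if (!is.null(ci)) {
    if (!all(ci$strain %in% study$truth$strain)) {
      abort("ci estimates contain strains not in the study")
    }
    j <- dplyr::left_join(ci, study$truth[, c("strain", "s_star")], by = "strain")
    out$ci <- tibble(
      parameter = "s_h", strain = j$strain, true = j$s_star,
      estimate = j$mean_sh, bias = j$mean_sh - j$s_star,
      covered = j$s_star >= j$bca_lo & j$s_star <= j$bca_hi
    )
  }
  if (!is.null(transcripts)) {
    est <- transcripts |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(estimate = mean(.data$log2_fc), .groups = "drop")
    if (!all(est$strain %in% study$truth$strain)) {
      abort("transcript estimates contain strains not in the study")
    }
    ref <- study$params$reference_strains
    centred <- study$truth$cifB_log2 -
      mean(study$truth$cifB_log2[study$truth$strain %in% ref])
    j <- dplyr::left_join(
      est, tibble(strain = study$truth$strain, true = centred), by = "strain"
    )
    out$tx <- tibble(
      parameter = "cifB_log2_fc", strain = j$strain, true = j$true,
      estimate = j$estimate, bias = j$estimate - j$true, covered = NA
    )
  }
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "pgls_fit"))
    co <- fit$coefficients[2, ]
    tcrit <- stats::qt(0.975, fit$df)
    out$fit <- tibble(
      parameter = c("slope", "lambda"), strain = NA_character_,
      true = c(study$params$slope, study$params$lam),
      estimate = c(co$estimate, fit$lambda),
      bias = estimate - true,
      covered = c(
        study$params$slope >= co$estimate - tcrit * co$std.error &
          study$params$slope <= co$estimate + tcrit * co$std.error,
        NA
      )
    )
  }
  dplyr::bind_rows(out)
}
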