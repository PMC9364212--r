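# Pipeline orchestration: one config, deterministic seeding, one output dir.

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML (or already-parsed list) with:
#' * `paths`: `tree`, `vials`, and optionally `qpcr_density`, `qpcr_cifA`,
#'   `qpcr_cifB`, `development`, `alignment_cifA`, `alignment_cifB`,
#'   `tm_scores` — all resolved relative to the config file;
#' * `scheme`: optional `compatible`, `ci_cross`, `overrides` for
#'   [cross_scheme()];
#' * `reference`: `density_strain` (default `"wMel"`-like first strain),
#'   `assays_cifA`, `assays_cifB` (calibrator assay groups);
#' * `subsets`: named lists of strains to *drop* in sensitivity reruns,
#'   e.g. `drop_non_ci`, `drop_low_density`;
#' * `bootstrap`: `B` (default 10000) and `conf` (default 0.95);
#' * `fdr`: p-adjustment method (default `"BH"`); `min_eggs` (default 10);
#' * `seed`: master seed (default 1).
#'
#' @param config Path to a YAML file, or a list with the fields above.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  base <- "."
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- modifyList(
    list(
      paths = list(), scheme = list(), reference = list(), subsets = list(),
      bootstrap = list(B = 10000, conf = 0.95),
      fdr = "BH", min_eggs = 10, seed = 1
    ),
    config
  )
  cfg$paths <- lapply(cfg$paths, function(p) {
    p <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(p)) abort(sprintf("configured input does not exist: %s", p))
    p
  })
  if (is.null(cfg$paths$tree) || is.null(cfg$paths$vials)) {
    abort("config must provide paths$tree and paths$vials")
  }
  structure(cfg, class = c("run_config", "list"))
}

build_scheme <- function(cfg) {
  cross_scheme(
    compatible = cfg$scheme$compatible %||% c("UU", "IU", "II"),
    ci_cross = cfg$scheme$ci_cross %||% "UI",
    overrides = cfg$scheme$overrides %||% list()
  )
}

pgls_safely <- function(data, formula, tree) {
  tryCatch(
    suppressWarnings(pgls_model_choice(data, formula, tree)),
    error = function(e) NULL
  )
}

#' Run the full comparative pipeline
#'
#' Executes, in order: CI-strength estimation, qPCR quantification
#' (density and transcript levels, when inputs are configured),
#' strain-level PGLS of CI strength against each available predictor (on
#' the full strain set and each configured drop-subset, reporting the
#' AIC-preferred lambda treatment), phylogenetic-signal tests (Pagel's
#' lambda on continuous predictors; Fritz-Purvis D on binary codings
#' derived from the CI classification), and sequence/structure divergence
#' statistics when alignments are configured. All randomness fans out from
#' `config$seed` through stable per-stage child seeds.
#'
#' @param config A `run_config` (or path / list accepted by
#'   [read_run_config()]).
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV/JSON together with a run manifest.
#' @return A named list bundle with elements `ci`, `quant`, `traits`,
#'   `comparative`, `signal`, `divergence` (some `NULL` when inputs are
#'   absent), invisibly when `out_dir` is used.
#' @export
run_all <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  seed <- cfg$seed
  tree <- read_newick(cfg$paths$tree)
  vials <- as_tibble(utils::read.csv(cfg$paths$vials))
  strains <- unique(vials$strain)
  for (nm in names(cfg$subsets)) {
    unknown <- setdiff(cfg$subsets[[nm]], strains)
    if (length(unknown)) {
      abort(sprintf("subset '%s' names unknown strain(s): %s",
                    nm, paste(unknown, collapse = ", ")))
    }
  }
  missing_tips <- setdiff(strains, tree$tip.label)
  if (length(missing_tips)) {
    abort(sprintf("strains absent from tree: %s", paste(missing_tips, collapse = ", ")))
  }

  # -- stage 1: CI strength ---------------------------------------------------
  ci <- ci_strength(
    vials, scheme = build_scheme(cfg), min_eggs = cfg$min_eggs,
    B = cfg$bootstrap$B, conf = cfg$bootstrap$conf,
    seed = child_seed(seed, "ci_strength"), quiet = TRUE
  )

  # -- stage 2: quantification ------------------------------------------------
  quant <- list()
  if (!is.null(cfg$paths$qpcr_density)) {
    qd <- as_tibble(utils::read.csv(cfg$paths$qpcr_density))
    ref_strain <- cfg$reference$density_strain %||% qd$strain[1]
    quant$density <- quantify_density(
      qd, reference_strain = ref_strain, seed = child_seed(seed, "quant_density")
    )
    quant$density_tests <- compare_to_reference_strain(
      quant$density, reference_strain = ref_strain, p_adjust = cfg$fdr
    )
  }
  for (gene in c("cifA", "cifB")) {
    key <- paste0("qpcr_", gene)
    if (is.null(cfg$paths[[key]])) next
    qt <- as_tibble(utils::read.csv(cfg$paths[[key]]))
    ref_assays <- cfg$reference[[paste0("assays_", gene)]] %||%
      unique(qt$assay)[seq_len(min(4, length(unique(qt$assay))))]
    quant[[gene]] <- quantify_transcripts(qt, reference_assays = ref_assays)
  }

  # -- strain-level trait table ----------------------------------------------
  traits <- tibble(strain = ci$strain, ci_strength = ci$mean_sh)
  mean_by_strain <- function(fc, col_name) {
    fc |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(!!col_name := mean(.data$log2_fc), .groups = "drop")
  }
  if (!is.null(quant$density)) {
    traits <- dplyr::left_join(traits, mean_by_strain(quant$density, "density_log2"),
                               by = "strain")
  }
  for (gene in c("cifA", "cifB")) {
    if (!is.null(quant[[gene]])) {
      traits <- dplyr::left_join(
        traits, mean_by_strain(quant[[gene]], paste0(gene, "_log2")), by = "strain"
      )
    }
  }
  if (!is.null(cfg$paths$development)) {
    dev <- as_tibble(utils::read.csv(cfg$paths$development))
    dev_means <- dev |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean), .groups = "drop")
    traits <- dplyr::left_join(traits, dev_means, by = "strain")
  }

  # -- stage 3: comparative regressions --------------------------------------
  predictors <- setdiff(names(traits), c("strain", "ci_strength"))
  subset_sets <- c(list(full = character(0)), cfg$subsets)
  comparative <- purrr::map_dfr(names(subset_sets), function(sub) {
    kept <- traits[!traits$strain %in% subset_sets[[sub]], , drop = FALSE]
    purrr::map_dfr(predictors, function(p) {
      mc <- pgls_safely(kept, stats::as.formula(paste("ci_strength ~", p)), tree)
      if (is.null(mc)) return(NULL)
      g <- glance(mc$preferred)
      co <- mc$preferred$coefficients[2, ]
      tibble(
        subset = sub, predictor = p, n = g$nobs,
        slope = co$estimate, p_value = co$p.value,
        r.squared = g$r.squared, lambda = g$lambda,
        lambda_type = g$lambda_type, AIC = g$AIC,
        AIC_lambda1 = mc$aic$AIC[mc$aic$model == "lambda_1"]
      )
    })
  })

  # -- stage 4: phylogenetic signal ------------------------------------------
  signal <- list()
  signal$lambda <- purrr::map_dfr(predictors, function(p) {
    x <- setNames(traits[[p]], traits$strain)
    x <- x[!is.na(x)]
    if (length(x) < 4) return(NULL)
    res <- tryCatch(suppressWarnings(pagel_lambda_signal(tree, x)),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::mutate(glance(res), trait = p, .before = 1)
  })
  binary <- list(
    strong_ci = setNames(as.numeric(ci$category == "strong"), ci$strain),
    ci = setNames(as.numeric(ci$category != "none"), ci$strain)
  )
  signal$d <- purrr::map_dfr(names(binary), function(nm) {
    x <- binary[[nm]]
    if (length(unique(x)) < 2) {
      warn(sprintf("binary trait '%s' has a single state; D skipped", nm))
      return(NULL)
    }
    res <- d_statistic(tree, x, B = cfg$bootstrap$B_signal %||% 1000,
                       seed = child_seed(seed, paste0("d_", nm)))
    dplyr::mutate(glance(res), trait = nm, .before = 1)
  })

  # -- stage 5: divergence ----------------------------------------------------
  divergence <- NULL
  if (!is.null(cfg$paths$alignment_cifA) && !is.null(cfg$paths$alignment_cifB)) {
    ia <- identity_matrix(cfg$paths$alignment_cifA)
    ib <- identity_matrix(cfg$paths$alignment_cifB)
    divergence <- list(
      identity_cifA = ia, identity_cifB = ib,
      paired = paired_similarity_test(
        ia, ib,
        strain_of_a = unlist(cfg$strain_of_cifA %||% NULL),
        strain_of_b = unlist(cfg$strain_of_cifB %||% NULL),
        B = cfg$bootstrap$B, seed = child_seed(seed, "divergence")
      )
    )
    if (!is.null(cfg$paths$tm_scores)) {
      tm <- as_tibble(utils::read.csv(cfg$paths$tm_scores))
      divergence$structure_cor <- structure_sequence_correlation(tm, ia)
    }
  }

  bundle <- list(ci = ci, quant = quant, traits = traits,
                 comparative = comparative, signal = signal,
                 divergence = divergence, config = cfg)
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    if (!is.null(df) && nrow(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wcsv(as_tibble(bundle$ci), "ci_strength.csv")
  wcsv(bundle$traits, "traits.csv")
  wcsv(bundle$comparative, "pgls.csv")
  wcsv(bundle$signal$lambda, "signal_lambda.csv")
  wcsv(bundle$signal$d, "signal_d.csv")
  if (!is.null(bundle$quant$density)) wcsv(bundle$quant$density, "density_fc.csv")
  if (!is.null(bundle$quant$density_tests)) {
    wcsv(bundle$quant$density_tests, "density_tests.csv")
  }
  for (gene in c("cifA", "cifB")) {
    if (!is.null(bundle$quant[[gene]])) {
      wcsv(bundle$quant[[gene]], paste0(gene, "_fc.csv"))
    }
  }
  if (!is.null(bundle$divergence)) {
    wcsv(bundle$divergence$paired$pairs, "divergence_pairs.csv")
    jsonlite::write_json(
      list(test = bundle$divergence$paired$test,
           medians = bundle$divergence$paired$medians,
           structure_cor = bundle$divergence$structure_cor),
      file.path(out_dir, "divergence.json"), auto_unbox = TRUE, digits = NA
    )
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ciphylo")),
    seed = bundle$config$seed,
    config = unclass(bundle$config),
    written = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
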