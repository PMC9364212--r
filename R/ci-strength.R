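#' Define which cross types count as compatible
#'
#' A CI assay crosses females and males of each infection status. The cross of
#' an uninfected female with an infected male (`UI`) is the incompatible (CI)
#' cross; by default the other three (`UU`, `IU`, `II`) form the compatible
#' baseline. Some strains need overrides — e.g. a strain whose uninfected
#' males are inviable can only use the infected x infected cross as its
#' baseline.
#'
#' @param compatible Character vector of compatible cross types.
#' @param ci_cross The CI cross type (must not be in `compatible`).
#' @param overrides Named list mapping a strain to its own compatible set,
#'   e.g. `list(wAur = "II")`.
#' @return A `cross_scheme` list used by [compute_sh()] and [ci_strength()].
#' @export
cross_scheme <- function(compatible = c("UU", "IU", "II"), ci_cross = "UI",
                         overrides = list()) {
  if (ci_cross %in% compatible) abort("the CI cross cannot be in the compatible set")
  for (s in names(overrides)) {
    if (ci_cross %in% overrides[[s]]) {
      abort(sprintf("override for %s includes the CI cross", s))
    }
  }
  structure(
    list(compatible = compatible, ci_cross = ci_cross, overrides = overrides),
    class = "cross_scheme"
  )
}

compatible_for <- function(scheme, strain) {
  scheme$overrides[[strain]] %||% scheme$compatible
}

#' Per-vial hatch rate
#'
#' Proportion of laid eggs that hatched within the scoring window.
#'
#' @param eggs_laid,eggs_hatched Non-negative integer vectors with
#'   `eggs_hatched <= eggs_laid`.
#' @return Numeric vector of proportions in `[0, 1]`.
#' @export
hatch_rate <- function(eggs_laid, eggs_hatched) {
  stopifnot(length(eggs_laid) == length(eggs_hatched))
  if (any(eggs_laid < 0 | eggs_hatched < 0)) abort("egg counts must be non-negative")
  if (any(eggs_hatched > eggs_laid)) abort("eggs_hatched exceeds eggs_laid")
  if (any(eggs_laid == 0)) abort("hatch rate undefined for vials with zero eggs laid")
  eggs_hatched / eggs_laid
}

#' Exclude low-count vials
#'
#' Vials in which too few eggs were laid carry almost no information about
#' the hatch proportion and are excluded (default: fewer than ten eggs).
#'
#' @param vials Data frame with columns `strain`, `cross_type`, `eggs_laid`,
#'   `eggs_hatched`.
#' @param min_eggs Minimum eggs laid for a vial to be retained (default 10,
#'   i.e. vials with <= 9 eggs are dropped).
#' @param quiet Suppress the message reporting how many vials were removed.
#' @return The retained rows, as a tibble.
#' @export
filter_vials <- function(vials, min_eggs = 10, quiet = FALSE) {
  assert_columns(vials, c("strain", "cross_type", "eggs_laid", "eggs_hatched"),
                 "vial table")
  keep <- vials$eggs_laid >= min_eggs
  if (!quiet) {
    inform(sprintf("filter_vials: removed %d of %d vials with fewer than %d eggs laid",
                   sum(!keep), length(keep), min_eggs))
  }
  as_tibble(vials[keep, , drop = FALSE])
}

#' Per-vial CI strength
#'
#' For each CI-cross vial `i` of a strain, CI strength is
#' `s_h = 1 - h_i / h_compat`, where `h_i` is that vial's hatch rate and
#' `h_compat` is the unweighted mean of the per-vial hatch rates over the
#' strain's compatible cross types. `s_h = 1` means no eggs hatched in the CI
#' cross; `s_h = 0` means no deviation from average compatibility; values are
#' negative when the CI vial out-hatches the baseline.
#'
#' @param vials Filtered vial table (see [filter_vials()]); may contain one
#'   or many strains.
#' @param scheme A [cross_scheme()].
#' @return Tibble with one row per CI-cross vial: `strain`, `eggs_laid`,
#'   `eggs_hatched`, `hatch_rate`, `compat_mean`, `sh`.
#' @export
compute_sh <- function(vials, scheme = cross_scheme()) {
  assert_columns(vials, c("strain", "cross_type", "eggs_laid", "eggs_hatched"),
                 "vial table")
  vials |>
    as_tibble() |>
    dplyr::group_by(.data$strain) |>
    dplyr::group_modify(function(df, key) {
      compat_types <- compatible_for(scheme, key$strain)
      ci <- df[df$cross_type == scheme$ci_cross, , drop = FALSE]
      compat <- df[df$cross_type %in% compat_types, , drop = FALSE]
      if (nrow(ci) == 0) abort(sprintf("strain %s: no CI-cross vials after filtering", key$strain))
      if (nrow(compat) == 0) abort(sprintf("strain %s: no compatible-cross vials after filtering", key$strain))
      h_compat <- mean(hatch_rate(compat$eggs_laid, compat$eggs_hatched))
      if (h_compat == 0) {
        abort(sprintf("strain %s: compatible-cross mean hatch is zero; s_h undefined", key$strain))
      }
      h_ci <- hatch_rate(ci$eggs_laid, ci$eggs_hatched)
      tibble(
        eggs_laid = ci$eggs_laid, eggs_hatched = ci$eggs_hatched,
        hatch_rate = h_ci, compat_mean = h_compat, sh = 1 - h_ci / h_compat
      )
    }) |>
    dplyr::ungroup()
}

#' Classify a strain's CI phenotype
#'
#' `none` when the CI-vs-compatible hatch difference is not significant at
#' `alpha`; otherwise `strong` when the mean CI-cross hatch rate is below
#' `strong_hatch_max` (default 20% egg hatch) and `weak` otherwise.
#'
#' @param p_value Two-sided Mann-Whitney p-value (CI vs compatible hatch).
#' @param mean_ci_hatch Mean hatch rate of the CI-cross vials.
#' @param alpha Significance threshold (default 0.05).
#' @param strong_hatch_max Strong/weak hatch-rate boundary (default 0.20).
#' @return Character vector in `{"none", "weak", "strong"}`.
#' @export
classify_strain <- function(p_value, mean_ci_hatch, alpha = 0.05,
                            strong_hatch_max = 0.20) {
  dplyr::case_when(
    p_value >= alpha ~ "none",
    mean_ci_hatch < strong_hatch_max ~ "strong",
    TRUE ~ "weak"
  )
}

#' Estimate CI strength per strain
#'
#' Full per-strain workflow: exclude low-count vials, compute per-vial
#' `s_h` against the strain's compatible-cross baseline, bootstrap a BCa
#' interval for the mean `s_h` (resampling the per-vial `s_h` values with the
#' baseline held fixed), test CI-cross vs compatible-cross hatch rates with a
#' Mann-Whitney U test, and classify the phenotype.
#'
#' @param vials Vial table: `strain`, `cross_type`, `eggs_laid`,
#'   `eggs_hatched`.
#' @param scheme A [cross_scheme()].
#' @param min_eggs Low-count exclusion threshold (default 10).
#' @param B Bootstrap replicates for the BCa interval (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional master seed; each strain gets a stable child seed so
#'   results do not depend on strain order.
#' @param quiet Suppress the vial-filtering message.
#' @return A tibble of class `ci_strength` with one row per strain:
#'   `strain`, `n_ci_vials`, `n_compat_vials`, `mean_sh`, `bca_lo`, `bca_hi`,
#'   `mean_ci_hatch`, `compat_mean`, `mwu_u`, `p_value`, `category`,
#'   plus attribute `sh` holding the per-vial values.
#' @examples
#' study <- make_study(n_strains = 4, seed = 1)
#' ci_strength(study$vials, B = 500, seed = 1)
#' @export
ci_strength <- function(vials, scheme = cross_scheme(), min_eggs = 10,
                        B = 10000, conf = 0.95, seed = NULL, quiet = FALSE) {
  kept <- filter_vials(vials, min_eggs = min_eggs, quiet = quiet)
  per_vial <- compute_sh(kept, scheme)
  res <- lapply(split(kept, kept$strain), function(df) {
    strain <- df$strain[[1]]
    compat_types <- compatible_for(scheme, strain)
    sh <- per_vial$sh[per_vial$strain == strain]
    ci_h <- per_vial$hatch_rate[per_vial$strain == strain]
    compat <- df[df$cross_type %in% compat_types, , drop = FALSE]
    compat_h <- hatch_rate(compat$eggs_laid, compat$eggs_hatched)
    strain_seed <- if (is.null(seed)) NULL else child_seed(seed, strain)
    if (length(sh) >= 2) {
      # sorted so the interval is invariant to vial row order
      bca <- bca_interval(sort(sh), B = B, conf = conf, seed = strain_seed)
    } else {
      warn(sprintf("strain %s: a single CI vial; no bootstrap interval", strain))
      bca <- tibble(lo = NA_real_, hi = NA_real_)
    }
    mwu <- mwu_test(ci_h, compat_h)
    tibble(
      strain = strain,
      n_ci_vials = length(sh), n_compat_vials = nrow(compat),
      mean_sh = mean(sh), bca_lo = bca$lo, bca_hi = bca$hi,
      mean_ci_hatch = mean(ci_h), compat_mean = mean(compat_h),
      mwu_u = mwu$statistic, p_value = mwu$p_value,
      category = classify_strain(mwu$p_value, mean(ci_h))
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "sh") <- per_vial
  attr(out, "conf") <- conf
  class(out) <- c("ci_strength", class(out))
  out
}
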