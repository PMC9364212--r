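# broom-style methods ----------------------------------------------------------

#' Tidy a phylogenetic regression fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' One-row summary of a phylogenetic regression fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return Tibble: `r.squared`, `lambda`, `lambda_type`, `sigma2`, `logLik`,
#'   `AIC`, `df.residual`, `nobs`.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(
    r.squared = x$r.squared, lambda = x$lambda, lambda_type = x$lambda_type,
    sigma2 = x$sigma2, logLik = x$logLik, AIC = x$AIC,
    df.residual = x$df, nobs = x$n
  )
}

#' One-row summary of a Fritz-Purvis D result
#'
#' @param x A `d_result`.
#' @param ... Unused.
#' @return Tibble: `D`, `P1`, `P0`, `obs_sum`, `mean_rand`, `mean_bm`, `B`,
#'   `nobs`, `k_ones`.
#' @method glance d_result
#' @export
glance.d_result <- function(x, ...) {
  tibble(
    D = x$D, P1 = x$P1, P0 = x$P0, obs_sum = x$obs_sum,
    mean_rand = mean(x$null_rand), mean_bm = mean(x$null_bm),
    B = x$B, nobs = x$n, k_ones = x$k_ones
  )
}

#' Tidy the null distributions of a Fritz-Purvis D result
#'
#' @param x A `d_result`.
#' @param ... Unused.
#' @return Tibble with `null` (`"random"` / `"brownian"`) and `sum`.
#' @method tidy d_result
#' @export
tidy.d_result <- function(x, ...) {
  tibble(
    null = rep(c("random", "brownian"), c(x$B, x$B)),
    sum = c(x$null_rand, x$null_bm)
  )
}

#' One-row summary of a Pagel's lambda signal test
#'
#' @param x A `lambda_signal`.
#' @param ... Unused.
#' @return Tibble: `lambda`, `logLik`, `logLik0`, `LRT`, `p.value`, `nobs`.
#' @method glance lambda_signal
#' @export
glance.lambda_signal <- function(x, ...) {
  tibble(
    lambda = x$lambda, logLik = x$logLik, logLik0 = x$logLik0,
    LRT = x$LRT, p.value = x$p_value, nobs = x$n
  )
}

# plotting ---------------------------------------------------------------------

#' Plot per-strain CI-strength estimates
#'
#' Point estimates of mean `s_h` with BCa interval bars, coloured by
#' phenotype category.
#'
#' @param object A [ci_strength()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ci_strength
#' @export
autoplot.ci_strength <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$strain, .data$mean_sh),
    y = 100 * .data$mean_sh, colour = .data$category
  )) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * .data$bca_lo, ymax = 100 * .data$bca_hi),
      width = 0.25
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "CI strength, s_h (%)", colour = "CI phenotype") +
    ggplot2::theme_minimal()
}

#' Plot the null distributions behind a D statistic
#'
#' Histograms of the random-shuffle and Brownian-threshold sister-clade
#' sums with the observed sum marked.
#'
#' @param object A `d_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot d_result
#' @export
autoplot.d_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sum, fill = .data$null)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::geom_vline(xintercept = object$obs_sum, linetype = 2) +
    ggplot2::labs(
      x = "sister-clade sum", y = "count", fill = "null",
      title = sprintf("D = %.2f (P1 = %.3f, P0 = %.3f)",
                      object$D, object$P1, object$P0)
    ) +
    ggplot2::theme_minimal()
}

#' Plot D distributions across tree sizes
#'
#' One panel per generating condition, showing how the D distributions for
#' random and Brownian-threshold traits separate as taxa are added.
#'
#' @param object A `d_power_sim` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot d_power_sim
#' @export
autoplot.d_power_sim <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(
    x = factor(.data$n_taxa), y = .data$D, fill = .data$condition
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "taxa", y = "Fritz-Purvis D", fill = "generating condition") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a phylogenetic regression
#'
#' @param data Trait table used for the fit.
#' @param fit The `pgls_fit` returned by [pgls()] on that table.
#' @param formula The same `response ~ predictor` formula.
#' @param tip Tip-label column (default `"strain"`).
#' @return A ggplot object with the GLS line overlaid.
#' @export
plot_pgls <- function(data, fit, formula, tip = "strain") {
  vars <- all.vars(formula)
  co <- fit$coefficients$estimate
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[vars[2]]], y = .data[[vars[1]]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = co[1], slope = co[2], colour = "steelblue") +
    ggplot2::labs(
      title = sprintf("PGLS: R^2 = %.2f, lambda = %.2f", fit$r.squared, fit$lambda)
    ) +
    ggplot2::theme_minimal()
}
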