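#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Nonparametric bootstrap interval for a univariate statistic (the mean by
#' default), with the bias correction `z0` and the jackknife acceleration `a`:
#' \deqn{z_0 = \Phi^{-1}(\#\{\theta^*_b < \hat\theta\} / B), \quad
#'       a = \frac{\sum_i (\bar\theta_{(.)} - \theta_{(i)})^3}
#'                {6 [\sum_i (\bar\theta_{(.)} - \theta_{(i)})^2]^{3/2}}}
#' The interval endpoints are the empirical `Phi(z0 + (z0 + z_alpha) /
#' (1 - a (z0 + z_alpha)))` percentiles of the bootstrap distribution
#' (quantile type 7). With `z0 = 0` and `a = 0` this reduces to the ordinary
#' percentile interval.
#'
#' @param x Numeric vector of at least two values.
#' @param B Number of bootstrap resamples (>= 100).
#' @param conf Confidence level, default 0.95.
#' @param statistic Function mapping a numeric vector to a scalar (default
#'   [mean()]).
#' @param seed Optional integer seed for the resampling.
#' @return A tibble with columns `lo`, `hi`, `estimate`, `z0`, `accel`,
#'   `conf`, `B`.
#' @examples
#' bca_interval(c(0.8, 0.9, 0.85, 0.95, 0.7), B = 2000, seed = 1)
#' @export
bca_interval <- function(x, B = 10000, conf = 0.95, statistic = mean, seed = NULL) {
  stopifnot(is.numeric(x), length(x) >= 2, conf > 0, conf < 1)
  if (B < 100) abort("`B` must be at least 100")
  if (length(unique(x)) == 1L) {
    warn("all sample values identical; BCa interval is degenerate")
    v <- statistic(x)
    return(tibble(
      lo = v, hi = v, estimate = v, z0 = 0, accel = 0, conf = conf, B = as.integer(B)
    ))
  }
  n <- length(x)
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    if (identical(statistic, mean)) {
      colMeans(matrix(x[idx], nrow = n))
    } else {
      apply(matrix(x[idx], nrow = n), 2L, statistic)
    }
  })
  res <- bca_from_replicates(boots, x, statistic = statistic, conf = conf)
  res$B <- as.integer(B)
  res
}

#' BCa endpoints from precomputed bootstrap replicates
#'
#' The formula-level core of [bca_interval()], exposed so that the bootstrap
#' distribution can be supplied directly — e.g. an exhaustive enumeration of
#' every resample of a tiny sample, where the BCa endpoints can be computed
#' by hand.
#'
#' @param replicates Numeric vector of bootstrap statistic values.
#' @param x The original sample (used for the jackknife acceleration).
#' @param statistic Statistic function, default [mean()].
#' @param conf Confidence level.
#' @return A tibble as in [bca_interval()] (without `B`).
#' @export
bca_from_replicates <- function(replicates, x, statistic = mean, conf = 0.95) {
  theta_hat <- statistic(x)
  B <- length(replicates)
  prop <- sum(replicates < theta_hat) / B
  # clamp so z0 is finite when the bootstrap distribution sits entirely on
  # one side of the point estimate
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- qnorm(prop)
  n <- length(x)
  jack <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  dj <- mean(jack) - jack
  denom <- sum(dj^2)^1.5
  a <- if (denom == 0) 0 else sum(dj^3) / (6 * denom)
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  z <- qnorm(alpha)
  adj <- pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  ends <- unname(quantile(replicates, probs = adj, type = 7))
  tibble(
    lo = ends[1], hi = ends[2], estimate = theta_hat,
    z0 = z0, accel = a, conf = conf
  )
}

# Mann-Whitney U with half-counted ties: U = #{x > y} + 0.5 #{x == y}
mwu_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of whether two samples come from the same
#' distribution. For small groups (both n <= 8) the p-value is computed by
#' exhaustive enumeration of all group-label assignments (valid under ties);
#' otherwise a tie-corrected normal approximation (without continuity
#' correction) is used.
#'
#' @param x,y Numeric vectors (e.g. CI-cross and compatible-cross hatch
#'   rates).
#' @param exact_max Largest per-group size for which exact enumeration is
#'   used (default 8).
#' @return A tibble with `statistic` (U for `x`), `p_value`, `method`,
#'   `n_x`, `n_y`.
#' @export
mwu_test <- function(x, y, exact_max = 8) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  u <- mwu_u(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    pool <- c(x, y)
    combs <- combn(n1 + n2, n1)
    us <- apply(combs, 2L, function(idx) mwu_u(pool[idx], pool[-idx]))
    # two-sided: permutations at least as far from the null mean as observed
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    nn <- n1 + n2
    t_sizes <- table(c(x, y))
    tie_term <- sum(t_sizes^3 - t_sizes) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation, tie-corrected"
  }
  tibble(
    statistic = u, p_value = min(p, 1), method = method,
    n_x = n1, n_y = n2
  )
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped; ties in the absolute differences take average ranks. For n <= 25
#' non-zero pairs the p-value is exact, from the full sign-flip distribution
#' of the rank sum (computed by dynamic programming, valid under ties);
#' larger samples use the tie-corrected normal approximation.
#'
#' @param x,y Paired numeric vectors, or `y = NULL` to treat `x` as
#'   differences.
#' @return Tibble: `statistic` (V, rank sum of positive differences),
#'   `p_value`, `n` (non-zero pairs), `method`.
#' @export
signed_rank_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(statistic = 0, p_value = 1, n = 0L,
                  method = "all differences zero"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # distribution of 2V over all 2^n sign assignments; average ranks are
    # half-integers, so doubling keeps everything integral
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    dist <- numeric(tot + 1)
    dist[1] <- 1
    for (ri in r2) {
      dist[(ri + 1):(tot + 1)] <- dist[(ri + 1):(tot + 1)] + dist[1:(tot + 1 - ri)]
    }
    v2 <- as.integer(round(2 * v))
    p_ge <- sum(dist[(v2 + 1):(tot + 1)]) / 2^n
    p_le <- sum(dist[1:(v2 + 1)]) / 2^n
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact sign-flip enumeration"
  } else {
    mu <- n * (n + 1) / 4
    t_sizes <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(t_sizes^3 - t_sizes) / 48
    p <- 2 * pnorm(-abs((v - mu) / sqrt(sigma2)))
    method <- "normal approximation, tie-corrected"
  }
  tibble(statistic = v, p_value = min(p, 1), n = n, method = method)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()])
#' followed by Dunn's pairwise z tests on the pooled ranks, with multiplicity
#' adjustment across pairs (Holm by default).
#'
#' @param data Data frame with one row per observation.
#' @param value,group Column names (strings) holding the response and the
#'   grouping factor; defaults `"hatch_rate"` and `"cross_type"`.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()];
#'   default `"holm"`.
#' @return A list with `omnibus` (tibble: `statistic`, `df`, `p_value`) and
#'   `pairwise` (tibble: `group1`, `group2`, `z`, `p_value`, `p_adjusted`).
#' @export
kruskal_dunn <- function(data, value = "hatch_rate", group = "cross_type",
                         p_adjust = "holm") {
  assert_columns(data, c(value, group), "kruskal_dunn data")
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 3) abort("Dunn's test requires at least 3 groups")
  if (any(table(g) == 0)) abort("every group must be non-empty")
  if (length(unique(v)) == 1L) {
    # H = 0 by convention: every rank is the midrank, no spread to explain
    kw <- list(statistic = c(H = 0), parameter = c(df = nlevels(g) - 1),
               p.value = 1)
  } else {
    kw <- kruskal.test(v, g)
  }
  r <- rank(v)
  nn <- length(v)
  t_sizes <- table(v)
  tie_term <- sum(t_sizes^3 - t_sizes) / (12 * (nn - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- combn(levels(g), 2)
  z <- apply(pairs, 2L, function(p) {
    se <- sqrt((nn * (nn + 1) / 12 - tie_term) * (1 / ns[p[1]] + 1 / ns[p[2]]))
    if (se == 0) return(0)
    (rbar[p[1]] - rbar[p[2]]) / se
  })
  praw <- 2 * pnorm(-abs(z))
  list(
    omnibus = tibble(
      statistic = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value
    ),
    pairwise = tibble(
      group1 = pairs[1, ], group2 = pairs[2, ], z = unname(z),
      p_value = unname(praw),
      p_adjusted = p.adjust(praw, method = p_adjust)
    )
  )
}
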