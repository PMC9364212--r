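# Core generalized least squares machinery. V is the (possibly
# lambda-transformed) phylogenetic covariance; all sums of squares are taken
# in the V-whitened space, the convention of the comparative-methods
# literature.

gls_core <- function(y, X, V) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  L <- tryCatch(chol(V), error = function(e) {
    abort("covariance matrix is not positive definite (singular V?)")
  })
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(Xw)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) abort("design matrix is collinear")
  beta <- solve(qrX, crossprod(Xw, yw))
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  df <- n - ncol(X)
  sigma2 <- if (df > 0) rss / df else NA_real_
  se <- sqrt(diag(solve(qrX)) * sigma2)
  tval <- drop(beta) / se
  pval <- 2 * pt(-abs(tval), df)
  # intercept-only whitened fit for R^2
  ones_w <- backsolve(L, rep(1, n), transpose = TRUE)
  b0 <- sum(ones_w * yw) / sum(ones_w^2)
  rss0 <- sum((yw - ones_w * b0)^2)
  r2 <- if (ncol(X) > 1) 1 - rss / rss0 else NA_real_
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdetV + n)
  list(
    beta = drop(beta), se = se, statistic = tval, p_value = pval, df = df,
    rss = rss, rss0 = rss0, sigma2 = sigma2, r.squared = r2, logLik = ll,
    n = n
  )
}

new_pgls_fit <- function(core, terms, lambda, lambda_type, flat = FALSE,
                         call_info = NULL) {
  k <- length(core$beta) + 1 + if (lambda_type == "ML") 1 else 0
  structure(
    list(
      coefficients = tibble(
        term = terms, estimate = core$beta, std.error = core$se,
        statistic = core$statistic, p.value = core$p_value
      ),
      lambda = lambda, lambda_type = lambda_type,
      logLik = core$logLik, AIC = 2 * k - 2 * core$logLik, k = k,
      sigma2 = core$sigma2, r.squared = core$r.squared, df = core$df,
      n = core$n, flat_likelihood = flat, call_info = call_info
    ),
    class = "pgls_fit"
  )
}

#' Generalized least squares fit with a fixed covariance
#'
#' Fits `y = b0 + b1 x + e`, `e ~ N(0, sigma2 V)`, by GLS:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`. Inference uses the residual variance
#' estimate with `n - 2` degrees of freedom; `R^2` is `1 - RSS/RSS0` with
#' both residual sums computed in the V-whitened space; the log-likelihood
#' (and hence AIC) uses the ML variance. With `V = I` this reproduces
#' ordinary least squares.
#'
#' @param y,x Named numeric vectors (or `tip,value` data frames) over the
#'   same tips.
#' @param V Covariance matrix with dimnames covering those tips, e.g. from
#'   [phylo_vcv()] / [lambda_transform()].
#' @return A `pgls_fit` object; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()].
#' @export
gls_fit <- function(y, x, V) {
  y <- as_trait_vector(y); x <- as_trait_vector(x)
  tips <- names(y)
  stopifnot(setequal(tips, names(x)), all(tips %in% rownames(V)))
  x <- x[tips]
  V <- V[tips, tips]
  X <- cbind(`(Intercept)` = 1, x = x)
  core <- gls_core(y, X, V)
  new_pgls_fit(core, c("(Intercept)", "x"), lambda = NA_real_,
               lambda_type = "fixed")
}

profile_loglik <- function(y, X, C, lambda) {
  gls_core(y, X, lambda_transform(C, lambda))$logLik
}

# Maximise the GLS profile log-likelihood over lambda in [0, 1]; boundary
# candidates are checked explicitly because optimize() only searches the
# interior.
maximize_lambda <- function(y, X, C, tol = 1e-6) {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  ll_grid <- vapply(grid, function(l) profile_loglik(y, X, C, l), numeric(1))
  flat <- (max(ll_grid) - min(ll_grid)) < 1e-8
  if (flat) {
    warn("profile likelihood is flat in lambda (star-like tree or too few tips)")
    return(list(lambda = 1, logLik = ll_grid[length(grid)], flat = TRUE))
  }
  opt <- optimize(function(l) profile_loglik(y, X, C, l),
                  interval = c(0, 1), maximum = TRUE, tol = tol)
  cand <- rbind(
    c(opt$maximum, opt$objective),
    c(0, ll_grid[1]),
    c(1, ll_grid[length(grid)])
  )
  best <- cand[which.max(cand[, 2]), ]
  list(lambda = best[1], logLik = best[2], flat = FALSE)
}

#' Maximum-likelihood Pagel's lambda regression
#'
#' Profiles the GLS log-likelihood of `y ~ x` over `lambda` in `[0, 1]`,
#' where `V(lambda)` multiplies the off-diagonal of the phylogenetic
#' covariance `C`, and returns the fit at the maximising value.
#'
#' @inheritParams gls_fit
#' @param C Untransformed phylogenetic covariance (from [phylo_vcv()]).
#' @param tol Optimiser tolerance on lambda (default 1e-6).
#' @return A `pgls_fit` with `lambda_type = "ML"`; `flat_likelihood` flags a
#'   likelihood that does not depend on lambda.
#' @export
profile_lambda <- function(y, x, C, tol = 1e-6) {
  y <- as_trait_vector(y); x <- as_trait_vector(x)
  tips <- names(y)
  stopifnot(setequal(tips, names(x)), all(tips %in% rownames(C)))
  x <- x[tips]
  C <- C[tips, tips]
  X <- cbind(`(Intercept)` = 1, x = x)
  opt <- maximize_lambda(y, X, C, tol = tol)
  core <- gls_core(y, X, lambda_transform(C, opt$lambda))
  new_pgls_fit(core, c("(Intercept)", "x"), lambda = opt$lambda,
               lambda_type = "ML", flat = opt$flat)
}

#' Phylogenetic regression from a tidy trait table
#'
#' Data-frame-first interface to [gls_fit()] / [profile_lambda()]: aligns the
#' table's tips with the tree (pruning unused tips), builds the phylogenetic
#' covariance and fits a single-predictor phylogenetic regression.
#'
#' @param data Data frame with one row per tip.
#' @param formula Two-sided formula `response ~ predictor` naming columns of
#'   `data`.
#' @param tree A `phylo` whose tip labels cover `data[[tip]]`.
#' @param tip Name of the column holding tip labels (default `"strain"`).
#' @param lambda `"ML"` (default) to estimate Pagel's lambda by maximum
#'   likelihood, or a fixed number in `[0, 1]`.
#' @return A `pgls_fit` object.
#' @examples
#' tr <- simulate_yule(10, seed = 2)
#' df <- tibble::tibble(
#'   strain = tr$tip.label,
#'   x = simulate_bm(tr, seed = 3),
#'   y = simulate_bm(tr, seed = 4)
#' )
#' fit <- pgls(df, y ~ x, tr)
#' tidy(fit)
#' @export
pgls <- function(data, formula, tree, tip = "strain", lambda = "ML") {
  vars <- all.vars(formula)
  if (length(vars) != 2) abort("formula must be `response ~ predictor`")
  assert_columns(data, c(tip, vars), "trait table")
  if (anyDuplicated(data[[tip]])) abort("duplicate tips in trait table")
  keep <- complete.cases(data[, vars])
  data <- data[keep, , drop = FALSE]
  tips <- as.character(data[[tip]])
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    abort(sprintf("tips absent from tree: %s", paste(missing, collapse = ", ")))
  }
  tree <- ape::keep.tip(tree, tips)
  C <- phylo_vcv(tree)
  y <- setNames(as.numeric(data[[vars[1]]]), tips)
  x <- setNames(as.numeric(data[[vars[2]]]), tips)
  fit <- if (identical(lambda, "ML")) {
    profile_lambda(y, x, C)
  } else {
    stopifnot(is.numeric(lambda), length(lambda) == 1L)
    f <- gls_fit(y, x, lambda_transform(C, lambda))
    f$lambda <- lambda
    f
  }
  fit$call_info <- list(formula = deparse(formula), n = length(y))
  fit$coefficients$term[2] <- vars[2]
  fit
}

#' Phylogenetic regression with AIC-based lambda model choice
#'
#' Fits the regression twice — estimating Pagel's lambda by maximum
#' likelihood and fixing `lambda = 1` (pure Brownian residuals) — and
#' reports both with the lower-AIC fit marked preferred. When the ML
#' estimate is exactly 1 the two likelihoods coincide and the AICs differ by
#' 2 (the extra parameter).
#'
#' @inheritParams pgls
#' @return List with `preferred` (a `pgls_fit`), `fits` (named list), and
#'   `aic` (tibble: `model`, `lambda`, `logLik`, `AIC`, `preferred`).
#' @export
pgls_model_choice <- function(data, formula, tree, tip = "strain") {
  fit_ml <- pgls(data, formula, tree, tip = tip, lambda = "ML")
  fit_bm <- pgls(data, formula, tree, tip = tip, lambda = 1)
  aic <- tibble(
    model = c("lambda_ML", "lambda_1"),
    lambda = c(fit_ml$lambda, 1),
    logLik = c(fit_ml$logLik, fit_bm$logLik),
    AIC = c(fit_ml$AIC, fit_bm$AIC)
  )
  aic$preferred <- aic$AIC == min(aic$AIC)
  preferred <- if (fit_ml$AIC <= fit_bm$AIC) fit_ml else fit_bm
  list(preferred = preferred, fits = list(lambda_ML = fit_ml, lambda_1 = fit_bm),
       aic = aic)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic GLS (%s lambda%s), n = %d\n",
    x$lambda_type,
    if (!is.na(x$lambda)) sprintf(" = %.3f", x$lambda) else "",
    x$n
  ))
  print(x$coefficients)
  cat(sprintf("R^2 = %.3f | logLik = %.3f | AIC = %.3f\n",
              x$r.squared, x$logLik, x$AIC))
  invisible(x)
}
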