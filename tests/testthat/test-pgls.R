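test_that("GLS with identity covariance reproduces OLS", {
  set.seed(10)
  n <- 25
  tips <- sprintf("t%02d", 1:n)
  x <- setNames(rnorm(n), tips)
  y <- setNames(1 + 0.8 * x + rnorm(n, 0, 0.5), tips)
  V <- diag(n); dimnames(V) <- list(tips, tips)
  fit <- gls_fit(y, x, V)
  ols <- summary(lm(y ~ x))
  expect_equal(tidy(fit)$estimate, unname(coef(ols)[, 1]), tolerance = 1e-8)
  expect_equal(tidy(fit)$std.error, unname(coef(ols)[, 2]), tolerance = 1e-8)
  expect_equal(tidy(fit)$p.value, unname(coef(ols)[, 4]), tolerance = 1e-8)
  expect_equal(glance(fit)$r.squared, ols$r.squared, tolerance = 1e-8)
})

test_that("GLS coefficients match an explicit dense matrix solve", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  y <- c(A = 1, B = 2, C = 3, D = 4)
  x <- c(A = 0, B = 1, C = 2, D = 3)
  V <- phylo_vcv(tr)
  fit <- gls_fit(y, x, V)
  beta <- oracle_gls_beta(y[rownames(V)], cbind(1, x[rownames(V)]), V)
  expect_equal(tidy(fit)$estimate, drop(beta), ignore_attr = TRUE)
})

test_that("an exact linear relation gives R^2 = 1 and zero residual variance", {
  tr <- fixture_tree(10)
  x <- simulate_bm(tr, seed = 2)
  y <- 3 - 2 * x
  fit <- gls_fit(y, x, phylo_vcv(tr))
  expect_equal(fit$r.squared, 1)
  expect_equal(fit$sigma2, 0, tolerance = 1e-20)
})

test_that("GLS agrees with nlme::gls under Brownian correlation", {
  skip_if_not_installed("nlme")
  tr <- fixture_tree(20, seed = 77)
  df <- data.frame(strain = tr$tip.label,
                   x = simulate_bm(tr, seed = 5))
  df$y <- 1 + 0.5 * df$x + simulate_bm(tr, seed = 6)
  fit <- pgls(df, y ~ x, tr, lambda = 1)
  ref <- nlme::gls(y ~ x, data = df, method = "ML",
                   correlation = ape::corBrownian(1, tr, form = ~strain))
  expect_equal(tidy(fit)$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("R^2 is invariant to affine rescaling of the predictor", {
  tr <- fixture_tree(15, seed = 3)
  df <- data.frame(strain = tr$tip.label, x = simulate_bm(tr, seed = 8))
  df$y <- 0.3 * df$x + simulate_bm(tr, seed = 9)
  f1 <- pgls(df, y ~ x, tr, lambda = 1)
  df$x <- 100 * df$x - 7
  f2 <- pgls(df, y ~ x, tr, lambda = 1)
  expect_equal(f1$r.squared, f2$r.squared, tolerance = 1e-10)
})

test_that("profiled likelihood at the optimum dominates the boundary values", {
  for (seed in c(11, 12, 13)) {
    tr <- simulate_yule(40, seed = seed)
    y <- simulate_bm(tr, lambda = 0.5, seed = seed + 100)
    x <- simulate_bm(tr, seed = seed + 200)
    fit <- profile_lambda(y, x, phylo_vcv(tr))
    C <- phylo_vcv(tr)
    for (lam in c(0, 1)) {
      alt <- gls_fit(y, x, lambda_transform(C, lam))
      expect_gte(fit$logLik, alt$logLik - 1e-6)
    }
  }
})

test_that("ML lambda matches the nlme corPagel profile on interior optima", {
  skip_if_not_installed("nlme")
  for (s in c(310, 330, 340)) {
    tr <- simulate_yule(60, seed = s)
    df <- data.frame(strain = tr$tip.label, x = simulate_bm(tr, seed = s + 1))
    df$y <- 0.4 * df$x + simulate_bm(tr, lambda = 0.6, seed = s + 2)
    fit <- pgls(df, y ~ x, tr)
    ref <- nlme::gls(y ~ x, data = df, method = "ML",
                     correlation = ape::corPagel(0.5, tr, form = ~strain))
    lam_ref <- coef(ref$modelStruct$corStruct, unconstrained = FALSE)
    expect_equal(fit$lambda, unname(lam_ref), tolerance = 1e-4)
    expect_equal(tidy(fit)$estimate, unname(coef(ref)), tolerance = 1e-4)
    expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-5)
  }
})

test_that("a star tree yields a flat profile that is flagged", {
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1,F:1);")
  y <- setNames(rnorm(6), star$tip.label)
  x <- setNames(rnorm(6), star$tip.label)
  expect_warning(fit <- profile_lambda(y, x, phylo_vcv(star)), "flat")
  expect_true(fit$flat_likelihood)
})

test_that("model choice reports both AICs; identical fits differ by the extra parameter", {
  tr <- simulate_yule(50, seed = 44)
  df <- data.frame(strain = tr$tip.label, x = simulate_bm(tr, seed = 45))
  df$y <- 0.6 * df$x + simulate_bm(tr, seed = 46)
  mc <- pgls_model_choice(df, y ~ x, tr)
  expect_equal(nrow(mc$aic), 2)
  expect_equal(mc$preferred$AIC, min(mc$aic$AIC))
  if (mc$fits$lambda_ML$lambda == 1) {
    expect_equal(mc$fits$lambda_ML$AIC - mc$fits$lambda_1$AIC, 2)
  }
  # smoke at study scale
  tr10 <- simulate_yule(10, seed = 47)
  d10 <- data.frame(strain = tr10$tip.label, x = simulate_bm(tr10, seed = 48))
  d10$y <- d10$x + simulate_bm(tr10, seed = 49)
  expect_s3_class(suppressWarnings(pgls_model_choice(d10, y ~ x, tr10))$preferred,
                  "pgls_fit")
})

test_that("lambda-corrected models are preferred for lambda-generated data", {
  wins <- 0
  for (seed in 1:60) {
    tr <- simulate_yule(40, seed = 900 + seed)
    x <- simulate_bm(tr, seed = 1900 + seed)
    y <- simulate_bm(tr, lambda = 0.3, seed = 2900 + seed)
    df <- data.frame(strain = tr$tip.label, x = x, y = y)
    mc <- suppressWarnings(pgls_model_choice(df, y ~ x, tr))
    wins <- wins + (mc$aic$model[which.min(mc$aic$AIC)] == "lambda_ML")
  }
  expect_gt(wins, 30)
})
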