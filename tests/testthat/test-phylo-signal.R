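test_that("sister-clade sums match hand recursion on the balanced 4-tip tree", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(sister_clade_sum(tr, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_equal(sister_clade_sum(tr, c(A = 1, B = 0, C = 1, D = 0)), 2)
  # inversion symmetry
  x <- c(A = 1, B = 0, C = 0, D = 1)
  expect_equal(sister_clade_sum(tr, x), sister_clade_sum(tr, 1 - x))
  star <- read_newick("(A:1,B:1,C:1);")
  expect_error(sister_clade_sum(star, c(A = 1, B = 0, C = 0)), "polytomy")
})

test_that("sister-clade sum equals the independent recursion on all small trees", {
  # exhaustive: every rooted binary topology on <= 6 tips x every two-state
  # assignment, on two branch-length settings
  for (n in 2:6) {
    labels <- LETTERS[1:n]
    topos <- enumerate_topologies(as.list(labels))
    states <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    colnames(states) <- labels
    states <- states[rowSums(states) %in% 1:(n - 1), , drop = FALSE]
    for (ti in seq_along(topos)) {
      for (len in c(1, 0.37)) {
        tr <- read_newick(topology_to_newick(topos[[ti]], len = len))
        A <- ciphylo:::sister_contrast_matrix(tr)
        sums <- colSums(abs(A %*% t(states[, tr$tip.label, drop = FALSE])))
        oracle <- apply(states, 1, function(s) {
          oracle_sister_sum(tr, setNames(s, labels))
        })
        expect_equal(unname(sums), unname(oracle), tolerance = 1e-12)
      }
    }
  }
})

test_that("D is invariant to uniform branch-length rescaling", {
  tr <- simulate_yule(20, seed = 61)
  x <- threshold_binary(simulate_bm(tr, seed = 62), 8)
  d1 <- d_statistic(tr, x, B = 400, seed = 63)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 13.7
  d2 <- d_statistic(tr2, x, B = 400, seed = 63)
  expect_equal(d1$D, d2$D, tolerance = 1e-10)
  expect_equal(d1$P1, d2$P1)
})

test_that("D results are reproducible and validate their inputs", {
  tr <- simulate_yule(15, seed = 70)
  x <- threshold_binary(simulate_bm(tr, seed = 71), 7)
  a <- d_statistic(tr, x, B = 300, seed = 5)
  b <- d_statistic(tr, x, B = 300, seed = 5)
  expect_equal(a$D, b$D)
  expect_identical(a$null_rand, b$null_rand)
  expect_error(d_statistic(tr, setNames(rep(1, 15), tr$tip.label), B = 100),
               "both states")
  expect_error(d_statistic(tr, x + 0.5, B = 100), "binary")
})

test_that("a maximally clumped trait gives negative D on a balanced tree", {
  nw <- "((((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1):1,(((I:1,J:1):1,(K:1,L:1):1):1,((M:1,N:1):1,(O:1,P:1):1):1):1);"
  tr <- read_newick(nw)
  clumped <- setNames(as.numeric(tr$tip.label %in% LETTERS[1:8]), tr$tip.label)
  d <- d_statistic(tr, clumped, B = 2000, seed = 8)
  expect_lt(d$D, 0)
  expect_lt(d$P1, 0.05)
})

test_that("glance/tidy/autoplot expose the D result components", {
  tr <- simulate_yule(12, seed = 80)
  x <- threshold_binary(simulate_bm(tr, seed = 81), 6)
  d <- d_statistic(tr, x, B = 200, seed = 82)
  g <- glance(d)
  expect_equal(g$D, (g$obs_sum - g$mean_bm) / (g$mean_rand - g$mean_bm))
  expect_equal(nrow(tidy(d)), 400)
  expect_s3_class(autoplot(d), "ggplot")
})

test_that("Pagel's lambda signal matches phytools and its boundary identity", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule(40, seed = 90)
  x <- simulate_bm(tr, lambda = 0.6, seed = 91)
  mine <- pagel_lambda_signal(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda", test = TRUE)
  expect_equal(mine$lambda, ref$lambda, tolerance = 0.01)
  expect_equal(mine$logLik, ref$logL, tolerance = 1e-3)
  expect_equal(mine$p_value, ref$P, tolerance = 0.02)
  if (mine$lambda == 0) {
    expect_equal(mine$LRT, 0)
    expect_equal(mine$p_value, 1)
  }
})

test_that("lambda = 0 fits yield LRT = 0 and p = 1", {
  tr <- simulate_yule(30, seed = 95)
  # iid values: optimum typically at the lambda = 0 boundary
  x <- setNames(rnorm(30), tr$tip.label)
  res <- pagel_lambda_signal(tr, x)
  if (res$lambda == 0) {
    expect_equal(res$LRT, 0)
    expect_equal(res$p_value, 1)
  }
  expect_gte(res$LRT, 0)
})

test_that("power simulation is deterministic and validates prevalence", {
  a <- d_power_sim(taxa = c(10, 25), prevalence = 0.4, reps = 5, B = 100, seed = 3)
  b <- d_power_sim(taxa = c(10, 25), prevalence = 0.4, reps = 5, B = 100, seed = 3)
  expect_equal(a$draws, b$draws)
  expect_equal(a$overlap, b$overlap)
  expect_equal(nrow(a$draws), 2 * 2 * 5)
  expect_error(d_power_sim(taxa = 10, prevalence = 0.01, reps = 2, B = 50),
               "prevalence")
  expect_s3_class(autoplot(a), "ggplot")
})

test_that("the published binary codings have the reported prevalences", {
  b <- binary_trait_assignments()
  expect_equal(nrow(b), 10)
  expect_equal(sum(b$density_low), 4)
  expect_setequal(b$strain[b$density_low == 1], c("wAno", "wBai", "wBoc", "wTsa"))
  expect_equal(sum(b$cifA_high), 3)
  expect_equal(sum(b$cifB_high), 6)
  expect_setequal(b$strain[b$cifB_high == 1],
                  c("wAno", "wAur", "wHa", "wRi", "wTei", "wTri"))
  expect_equal(sum(b$strong_ci), 6)
  expect_equal(sum(b$ci), 8)
  for (col in setdiff(names(b), "strain")) {
    expect_setequal(unique(b[[col]]), c(0, 1))
  }
})
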