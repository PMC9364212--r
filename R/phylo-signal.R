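# Fritz-Purvis D for binary traits -------------------------------------------
#
# The observed quantity is the sum over internal nodes of the absolute
# difference between the two daughters' nodal values, where nodal values come
# from a root-ward pass assigning each internal node the
# branch-length-weighted (inverse-length, i.e. Felsenstein's ancestral
# estimate) average of its daughters. That pass is linear in the tip values,
# so we precompute a contrast matrix A with one row per internal node:
# sister_sum(x) = sum(|A x|). Both nulls then vectorise into single matrix
# products, which is what makes B = 1000 permutations per null cheap.

assert_bifurcating <- function(tree) {
  tab <- tabulate(tree$edge[, 1])
  if (any(tab[tab > 0] != 2)) {
    abort("tree contains a polytomy; the sister-clade sum requires a fully bifurcating tree")
  }
  invisible(tree)
}

sister_contrast_matrix <- function(tree) {
  validate_phylo(tree)
  assert_bifurcating(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  W <- matrix(0, n + m, n)
  W[cbind(seq_len(n), seq_len(n))] <- 1
  A <- matrix(0, m, n, dimnames = list(NULL, tree$tip.label))
  parents <- unique(po$edge[, 1])  # postorder: children before parents
  for (p in parents) {
    idx <- which(po$edge[, 1] == p)
    ch <- po$edge[idx, 2]
    v <- po$edge.length[idx]
    u <- if (any(v == 0)) {
      if (all(v == 0)) c(0.5, 0.5) else as.numeric(v == 0)
    } else {
      1 / v
    }
    u <- u / sum(u)
    W[p, ] <- u[1] * W[ch[1], ] + u[2] * W[ch[2], ]
    A[p - n, ] <- W[ch[1], ] - W[ch[2], ]
  }
  A
}

#' Sister-clade sum of a binary trait
#'
#' Internal quantity of the Fritz-Purvis D statistic: nodal values are
#' assigned root-ward as the branch-length-weighted average of each node's
#' two daughters, and the sister-clade sum is the total absolute difference
#' between daughter values across internal nodes. Clumped traits give small
#' sums; phylogenetically random traits give large ones.
#'
#' @param tree Fully bifurcating `phylo` with branch lengths.
#' @param trait Named binary (0/1) vector or `tip,value` data frame covering
#'   all tips.
#' @return The sister-clade sum (scalar).
#' @export
sister_clade_sum <- function(tree, trait) {
  A <- sister_contrast_matrix(tree)
  x <- as_trait_vector(trait, tree)
  if (!setequal(names(x), tree$tip.label)) abort("trait must cover every tip")
  sum(abs(A %*% x[colnames(A)]))
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Locates the observed sister-clade sum between two simulated expectations:
#' \deqn{D = \frac{\Sigma d_{obs} - \overline{\Sigma d_{BM}}}
#'                {\overline{\Sigma d_{rand}} - \overline{\Sigma d_{BM}}}}
#' where the random null shuffles the trait across tips (`B` permutations)
#' and the Brownian null draws `B` continuous traits under Brownian motion
#' and thresholds each at the observed prevalence. `D = 1` is the random
#' expectation, `D = 0` the Brownian (clumped) expectation; strongly clumped
#' traits go negative. `P1` is the fraction of random-null sums at or below
#' the observed sum (departure from randomness); `P0` the fraction of
#' Brownian-null sums at or above it (departure from Brownian clumping).
#'
#' @inheritParams sister_clade_sum
#' @param B Simulated datasets per null (default 1000).
#' @param seed Optional integer for reproducible nulls.
#' @return A `d_result` object; see [glance.d_result()].
#' @examples
#' tr <- simulate_yule(20, seed = 1)
#' x <- threshold_binary(simulate_bm(tr, seed = 2), 10)
#' glance(d_statistic(tr, x, B = 200, seed = 3))
#' @export
d_statistic <- function(tree, trait, B = 1000, seed = NULL) {
  A <- sister_contrast_matrix(tree)
  x <- as_trait_vector(trait, tree)
  if (!setequal(names(x), tree$tip.label)) abort("trait must cover every tip")
  x <- x[colnames(A)]
  if (!all(x %in% c(0, 1))) abort("trait must be binary 0/1")
  k <- sum(x == 1)
  n <- length(x)
  if (k == 0 || k == n) abort("binary trait must contain both states")
  obs <- sum(abs(A %*% x))
  V <- phylo_vcv(tree)[colnames(A), colnames(A)]
  with_seed(seed, {
    idx <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
    Xr <- matrix(x[idx], n, B)
    sums_rand <- colSums(abs(A %*% Xr))
    Y <- rmvn_chol(V, B)
    Xb <- apply(Y, 2L, function(col) {
      out <- numeric(n)
      out[order(-col, colnames(A))[seq_len(k)]] <- 1
      out
    })
    sums_bm <- colSums(abs(A %*% Xb))
    denom <- mean(sums_rand) - mean(sums_bm)
    if (abs(denom) < 1e-12) {
      abort("degenerate scaling: random and Brownian null means coincide")
    }
    structure(
      list(
        D = (obs - mean(sums_bm)) / denom,
        P1 = mean(sums_rand <= obs),
        P0 = mean(sums_bm >= obs),
        obs_sum = obs, null_rand = sums_rand, null_bm = sums_bm,
        B = as.integer(B), n = n, k_ones = k, seed = seed
      ),
      class = "d_result"
    )
  })
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf(
    "Fritz-Purvis D = %.3f (P1 = %.3f, P0 = %.3f; n = %d tips, %d in state 1, B = %d)\n",
    x$D, x$P1, x$P0, x$n, x$k_ones, x$B
  ))
  invisible(x)
}

# Pagel's lambda as a signal test ---------------------------------------------

#' Phylogenetic signal in a continuous trait (Pagel's lambda)
#'
#' Intercept-only maximum-likelihood fit of Pagel's lambda over `[0, 1]`
#' (the regression machinery of [profile_lambda()] with a constant design),
#' followed by a likelihood-ratio test against `lambda = 0` (no signal),
#' with the p-value from the upper tail of a chi-squared with 1 df.
#'
#' @param tree A `phylo` with branch lengths (n >= 4 tips).
#' @param trait Named continuous vector or `tip,value` data frame.
#' @return A `lambda_signal` object with fields `lambda`, `logLik`,
#'   `logLik0`, `LRT`, `p_value`; see [glance.lambda_signal()].
#' @export
pagel_lambda_signal <- function(tree, trait) {
  x <- as_trait_vector(trait, tree)
  if (length(x) < 4) abort("lambda signal test needs at least 4 tips")
  tree <- ape::keep.tip(tree, names(x))
  C <- phylo_vcv(tree)[names(x), names(x)]
  X <- matrix(1, length(x), 1, dimnames = list(NULL, "(Intercept)"))
  opt <- maximize_lambda(x, X, C)
  ll0 <- profile_loglik(x, X, C, 0)
  lrt <- max(0, 2 * (opt$logLik - ll0))
  structure(
    list(
      lambda = opt$lambda, logLik = opt$logLik, logLik0 = ll0,
      LRT = lrt, p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
      n = length(x), flat_likelihood = opt$flat
    ),
    class = "lambda_signal"
  )
}

#' @export
print.lambda_signal <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.3f (LRT = %.3f vs lambda = 0, p = %.4f, n = %d)\n",
              x$lambda, x$LRT, x$p_value, x$n))
  invisible(x)
}

# Tree-size power simulation ---------------------------------------------------

overlap_coefficient <- function(a, b, bins = 20) {
  rng <- range(c(a, b))
  if (diff(rng) == 0) return(1)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  pa <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE), bins) / length(a)
  pb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE), bins) / length(b)
  sum(pmin(pa, pb))
}

#' Tree-size power simulation for the D statistic
#'
#' How well does D separate a phylogenetically random binary trait from a
#' Brownian-threshold one as phylogenies grow? For each taxon count a set of
#' unit-height Yule trees is simulated; under the `lambda = 1` condition the
#' trait is Brownian motion thresholded at the target prevalence, under
#' `lambda = 0` the same number of 1s is assigned uniformly at random. D is
#' computed for every replicate and the per-size overlap between the two D
#' distributions (histogram overlap coefficient) summarises how
#' distinguishable the conditions are.
#'
#' @param taxa Integer vector of tree sizes (default `c(10, 25, 50, 100)`).
#' @param prevalence Fraction of tips in state 1; `round(prevalence * n)`
#'   must lie in `[1, n - 1]` for every size.
#' @param reps Replicates per size x condition cell (default 100).
#' @param B Null permutations inside each D computation (default 1000).
#' @param seed Optional integer for full reproducibility.
#' @return A `d_power_sim` list: `draws` (tibble: `n_taxa`, `condition`,
#'   `rep`, `D`) and `overlap` (tibble: `n_taxa`, `overlap`).
#' @export
d_power_sim <- function(taxa = c(10, 25, 50, 100), prevalence = 0.5,
                        reps = 100, B = 1000, seed = NULL) {
  stopifnot(is.numeric(prevalence), length(prevalence) == 1L,
            prevalence > 0, prevalence < 1)
  ks <- round(prevalence * taxa)
  if (any(ks < 1 | ks > taxa - 1)) {
    abort("infeasible prevalence: round(prevalence * n) must be in [1, n - 1]")
  }
  with_seed(seed, {
    draws <- purrr::map_dfr(seq_along(taxa), function(i) {
      n <- taxa[i]; k <- ks[i]
      purrr::map_dfr(seq_len(reps), function(r) {
        tr <- simulate_yule(n)
        x_bm <- threshold_binary(simulate_bm(tr), k)
        x_rand <- setNames(numeric(n), tr$tip.label)
        x_rand[sample.int(n, k)] <- 1
        tibble(
          n_taxa = n, rep = r,
          condition = c("lambda_1", "lambda_0"),
          D = c(d_statistic(tr, x_bm, B = B)$D,
                d_statistic(tr, x_rand, B = B)$D)
        )
      })
    })
    overlap <- draws |>
      dplyr::group_by(.data$n_taxa) |>
      dplyr::summarise(
        overlap = overlap_coefficient(
          .data$D[.data$condition == "lambda_0"],
          .data$D[.data$condition == "lambda_1"]
        ),
        .groups = "drop"
      )
    structure(list(draws = draws, overlap = overlap,
                   prevalence = prevalence, reps = reps, B = B, seed = seed),
              class = "d_power_sim")
  })
}

#' Published binary trait codings for the ten focal strains
#'
#' The study's binary trait assignments over its ten Wolbachia strains:
#' low testes density, high cifA[T1] and cifB[T1] transcript levels, strong
#' CI, and CI induction (strong plus the two weak inducers).
#'
#' @return Tibble with column `strain` and one 0/1 column per trait
#'   (`density_low`, `cifA_high`, `cifB_high`, `strong_ci`, `ci`).
#' @export
binary_trait_assignments <- function() {
  strains <- c("wMel", "wRi", "wAno", "wAur", "wTri", "wHa", "wBai",
               "wBoc", "wTei", "wTsa")
  as01 <- function(members) as.numeric(strains %in% members)
  strong <- c("wAno", "wAur", "wBai", "wHa", "wRi", "wTri")
  tibble(
    strain = strains,
    density_low = as01(c("wAno", "wBai", "wBoc", "wTsa")),
    cifA_high = as01(c("wAno", "wRi", "wTri")),
    cifB_high = as01(c("wAno", "wAur", "wHa", "wRi", "wTei", "wTri")),
    strong_ci = as01(strong),
    ci = as01(c(strong, "wMel", "wBoc"))
  )
}
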