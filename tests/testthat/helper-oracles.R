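# Independent reference implementations used as oracles. These deliberately
# take different computational routes from the package code they check.

# Sister-clade sum by direct recursion over the ape edge table (the package
# uses a precomputed linear contrast operator instead).
oracle_sister_sum <- function(tree, trait) {
  n <- ape::Ntip(tree)
  rec <- function(node) {
    if (node <= n) {
      return(list(val = unname(trait[tree$tip.label[node]]), s = 0))
    }
    idx <- which(tree$edge[, 1] == node)
    kids <- tree$edge[idx, 2]
    lens <- tree$edge.length[idx]
    a <- rec(kids[1]); b <- rec(kids[2])
    w <- if (all(lens == 0)) c(0.5, 0.5)
         else if (any(lens == 0)) as.numeric(lens == 0)
         else 1 / lens
    w <- w / sum(w)
    list(val = w[1] * a$val + w[2] * b$val, s = a$s + b$s + abs(a$val - b$val))
  }
  rec(n + 1)$s
}

# All rooted binary topologies on a label set, as nested pair lists, built by
# inserting each new tip on every edge (including above the current root).
enumerate_topologies <- function(labels) {
  insert_all <- function(tr, tip) {
    res <- list(list(tr, tip))
    if (is.list(tr)) {
      for (lh in insert_all(tr[[1]], tip)) res <- c(res, list(list(lh, tr[[2]])))
      for (rh in insert_all(tr[[2]], tip)) res <- c(res, list(list(tr[[1]], rh)))
    }
    res
  }
  trees <- list(labels[[1]])
  for (tip in labels[-1]) {
    trees <- unlist(lapply(trees, insert_all, tip = tip), recursive = FALSE)
  }
  trees
}

topology_to_newick <- function(tr, len = 1) {
  rec <- function(x) {
    if (!is.list(x)) return(sprintf("%s:%g", x, len))
    sprintf("(%s,%s):%g", rec(x[[1]]), rec(x[[2]]), len)
  }
  if (!is.list(tr)) stop("need at least two tips")
  sprintf("(%s,%s);", rec(tr[[1]]), rec(tr[[2]]))
}

# Mann-Whitney U by direct pair counting (no ranks), enumerated over all
# group-label assignments.
oracle_mwu_exact_p <- function(x, y) {
  count_u <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  obs <- count_u(x, y)
  combs <- utils::combn(length(pool), n1)
  us <- apply(combs, 2, function(i) count_u(pool[i], pool[-i]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Kruskal-Wallis H from the textbook rank formula (no tie correction; for
# tie-free fixtures only).
oracle_kruskal_h <- function(groups) {
  v <- unlist(groups)
  r <- rank(v)
  n <- length(v)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(splits, function(g) length(g) * mean(g)^2, numeric(1))) -
    3 * (n + 1)
  h
}

# GLS coefficients by explicit dense matrix algebra.
oracle_gls_beta <- function(y, X, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# small random ultrametric fixture shared by a few files
fixture_tree <- function(n = 12, seed = 421) simulate_yule(n, seed = seed)
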