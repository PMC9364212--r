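#' Read a Newick tree with validation
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the rest
#' of the pipeline relies on: unique tip labels, non-negative branch lengths,
#' and a syntactically valid string (unbalanced parentheses or a missing
#' terminating semicolon are reported with the offending character offset).
#'
#' @param text A Newick string, or the path to a file containing one.
#' @return An object of class `phylo` (see [ape::read.tree()]).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[();]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("malformed Newick: unmatched ')' at character offset %d", i))
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf(
      "malformed Newick: %d unclosed '(' remaining at character offset %d",
      depth, length(chars)
    ))
  }
  if (!grepl(";\\s*$", text)) {
    abort(sprintf(
      "malformed Newick: missing terminating ';' at character offset %d",
      nchar(text)
    ))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("malformed Newick: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("malformed Newick: ape could not parse the string")
  validate_phylo(tree)
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) abort("expected an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(sprintf("duplicate tip label(s): %s", paste(dup, collapse = ", ")))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("negative branch lengths are not allowed")
  }
  tree
}

#' Write a tree as a Newick string
#'
#' Branch lengths are written with 10 significant digits so that
#' `read_newick(write_newick(tree))` round-trips topology and lengths.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` (default) the string is returned.
#' @return The Newick string, invisibly if written to `file`.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylo(tree)
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared path length from the root to the most recent common
#' ancestor of tips `i` and `j`; the diagonal holds root-to-tip distances.
#' This is the covariance structure implied by Brownian trait evolution and is
#' the `V` consumed by [pgls()] and [simulate_bm()].
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transformation of a covariance matrix
#'
#' Multiplies the off-diagonal (shared-history) entries of a phylogenetic
#' covariance matrix by `lambda`, leaving the diagonal untouched.
#' `lambda = 1` returns the matrix unchanged (pure Brownian motion);
#' `lambda = 0` removes all phylogenetic covariance.
#'
#' The transform is canonically defined for ultrametric trees; a warning is
#' emitted when the diagonal indicates a non-ultrametric source tree.
#'
#' @param C Covariance matrix from [phylo_vcv()].
#' @param lambda Scalar in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single number in [0, 1]")
  }
  d <- diag(C)
  if (length(d) > 1L && (max(d) - min(d)) > 1e-8 * max(d)) {
    warn("lambda transform applied to a non-ultrametric covariance matrix")
  }
  out <- C * lambda
  diag(out) <- d
  out
}

# Sample `m` zero-mean MVN draws with covariance `V` (columns are draws).
# Cholesky with an eigenvalue fallback for singular V (e.g. duplicated tips).
rmvn_chol <- function(V, m) {
  n <- nrow(V)
  L <- tryCatch(chol(V), error = function(e) NULL)
  z <- matrix(rnorm(n * m), n, m)
  if (!is.null(L)) {
    out <- crossprod(L, z)
  } else {
    e <- eigen(V, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    out <- e$vectors %*% (sqrt(lam) * z)
  }
  rownames(out) <- rownames(V)
  out
}

#' Simulate a continuous trait under lambda-scaled Brownian motion
#'
#' Tip values are drawn from a zero-mean multivariate normal with covariance
#' `sigma2 * lambda_transform(phylo_vcv(tree), lambda)`.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param sigma2 Brownian rate (trait variance per unit branch length), > 0.
#' @param lambda Pagel's lambda in `[0, 1]`; 1 is pure Brownian motion.
#' @param seed Optional integer for a reproducible draw.
#' @return A named numeric vector of tip values.
#' @examples
#' tr <- simulate_yule(8, seed = 1)
#' simulate_bm(tr, sigma2 = 1, lambda = 1, seed = 42)
#' @export
simulate_bm <- function(tree, sigma2 = 1, lambda = 1, seed = NULL) {
  stopifnot(is.numeric(sigma2), length(sigma2) == 1L, sigma2 > 0)
  V <- lambda_transform(phylo_vcv(tree), lambda) * sigma2
  with_seed(seed, {
    x <- rmvn_chol(V, 1L)[, 1L]
    names(x) <- rownames(V)
    x
  })
}

#' Simulate a pure-birth (Yule) tree rescaled to unit height
#'
#' Standard null generator for tree-size power studies: a constant-rate
#' pure-birth tree, ultrametric by construction, rescaled so every
#' root-to-tip distance is exactly 1 (removing the speciation rate as a
#' nuisance parameter).
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer for a reproducible tree.
#' @return An ultrametric `phylo` with tip labels `t1 ... tn` and height 1.
#' @export
simulate_yule <- function(n_tips, seed = NULL) {
  stopifnot(is.numeric(n_tips), length(n_tips) == 1L, n_tips >= 2)
  with_seed(seed, {
    tree <- ape::rphylo(as.integer(n_tips), birth = 1, death = 0)
    depths <- ape::node.depth.edgelength(tree)
    h <- max(depths[seq_len(ape::Ntip(tree))])
    tree$edge.length <- tree$edge.length / h
    tree
  })
}

#' Convert a continuous trait to binary at a fixed prevalence
#'
#' Assigns state 1 to the `k_ones` largest values and 0 to the rest; ties are
#' broken deterministically by tip-label sort order so repeated runs agree.
#' Used to build the Brownian-threshold null of [d_statistic()] at the
#' observed prevalence.
#'
#' @param values Named numeric vector (tip label -> value), or a data frame
#'   with columns `tip` and `value`.
#' @param k_ones Number of tips to assign state 1 (between 1 and n - 1).
#' @return A named numeric vector of 0/1 in the input order.
#' @export
threshold_binary <- function(values, k_ones) {
  values <- as_trait_vector(values)
  n <- length(values)
  if (!is.numeric(k_ones) || length(k_ones) != 1L || k_ones < 1 || k_ones > n - 1) {
    abort("`k_ones` must be between 1 and n - 1")
  }
  ord <- order(-values, names(values))
  out <- setNames(numeric(n), names(values))
  out[ord[seq_len(k_ones)]] <- 1
  out
}

#' Coerce a trait table to a named vector
#'
#' Accepts the package's tabular trait interchange format (columns `tip` and
#' `value`) or an already-named vector, and validates names against an
#' optional tree.
#'
#' @param x Named vector or data frame with columns `tip`, `value`.
#' @param tree Optional `phylo`; if given, names must be a subset of its tips.
#' @return Named numeric vector.
#' @export
as_trait_vector <- function(x, tree = NULL) {
  if (is.data.frame(x)) {
    assert_columns(x, c("tip", "value"), "trait table")
    v <- setNames(as.numeric(x$value), as.character(x$tip))
  } else if (is.numeric(x) && !is.null(names(x))) {
    v <- x
  } else {
    abort("trait must be a named numeric vector or a data frame with columns tip, value")
  }
  if (anyDuplicated(names(v))) abort("duplicate tip names in trait")
  if (!is.null(tree)) {
    extra <- setdiff(names(v), tree$tip.label)
    if (length(extra)) {
      abort(sprintf("trait tips not in tree: %s", paste(extra, collapse = ", ")))
    }
  }
  v
}
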