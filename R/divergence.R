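# Sequence divergence and structure-sequence concordance ----------------------

GAP_CHARS <- c("-", ".")

#' Percent identity over shared alignment sites
#'
#' Given two rows of one multiple alignment, identity is computed only over
#' columns where both sequences have a residue (gaps in either sequence are
#' ignored): `100 * matches / shared_sites`.
#'
#' @param a,b Equal-length gapped sequences (character scalars).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("AC-T", "ACGT")  # 100: three shared sites, all equal
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) abort("aligned sequences must have equal length")
  shared <- !(av %in% GAP_CHARS) & !(bv %in% GAP_CHARS)
  if (!any(shared)) abort("no shared (mutually ungapped) sites; identity undefined")
  100 * sum(av[shared] == bv[shared]) / sum(shared)
}

#' All-vs-all percent identity matrix
#'
#' @param aln Named character vector of gapped sequences of equal length, a
#'   `Biostrings::AAStringSet`, or the path to an aligned FASTA file (read
#'   with Biostrings).
#' @return Symmetric matrix of percent identities with 100 on the diagonal.
#' @export
identity_matrix <- function(aln) {
  if (is.character(aln) && length(aln) == 1L && file.exists(aln)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("reading FASTA requires the Biostrings package")
    }
    aln <- Biostrings::readAAStringSet(aln)
  }
  if (inherits(aln, "XStringSet")) {
    aln <- setNames(as.character(aln), names(aln))
  }
  stopifnot(is.character(aln), !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L) {
    abort("alignment rows differ in length; input must be an alignment")
  }
  n <- length(aln)
  out <- matrix(100, n, n, dimnames = list(names(aln), names(aln)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        out[i, j] <- out[j, i] <- pairwise_identity(aln[[i]], aln[[j]])
      }
    }
  }
  out
}

# Collapse an identity matrix keyed by sequence id to unordered strain-pair
# means, for strains carrying multiple gene copies.
strain_pair_identities <- function(mat, strain_of = NULL) {
  ids <- rownames(mat)
  strains <- if (is.null(strain_of)) ids else {
    missing <- setdiff(ids, names(strain_of))
    if (length(missing)) {
      abort(sprintf("no strain mapping for: %s", paste(missing, collapse = ", ")))
    }
    as.character(strain_of[ids])
  }
  pairs <- which(upper.tri(mat), arr.ind = TRUE)
  df <- tibble(
    strain_a = strains[pairs[, 1]], strain_b = strains[pairs[, 2]],
    identity = mat[pairs]
  )
  df <- df[df$strain_a != df$strain_b, , drop = FALSE]
  key_a <- pmin(df$strain_a, df$strain_b)
  key_b <- pmax(df$strain_a, df$strain_b)
  tibble(strain_a = key_a, strain_b = key_b, identity = df$identity) |>
    dplyr::group_by(.data$strain_a, .data$strain_b) |>
    dplyr::summarise(identity = mean(.data$identity), .groups = "drop")
}

#' Matched-pairs comparison of two protein families' divergence
#'
#' Tests whether one protein family (e.g. the rescue factor CifA) is more
#' conserved than another (the CI-inducing CifB) across the same strain
#' pairs. Off-diagonal identities are collapsed to unordered strain-pair
#' means (so strains with multiple gene copies contribute their average),
#' the two matrices are joined on strain pair, and the paired differences
#' are tested with a two-sided Wilcoxon matched-pairs signed-rank test.
#' Each family's median identity also gets a BCa bootstrap confidence
#' interval.
#'
#' @param mat_a,mat_b Identity matrices from [identity_matrix()].
#' @param strain_of_a,strain_of_b Optional named character vectors mapping
#'   sequence ids to strains (defaults: ids are strains).
#' @param conf Confidence level for the median intervals (default 0.95).
#' @param B Bootstrap replicates for the median intervals (default 10000).
#' @param seed Optional integer seed.
#' @return List with `test` (tibble: `statistic`, `p_value`, `n_pairs`,
#'   `method`), `medians` (tibble per family: `median`, `lo`, `hi`) and
#'   `pairs` (the joined per-pair identities).
#' @export
paired_similarity_test <- function(mat_a, mat_b, strain_of_a = NULL,
                                   strain_of_b = NULL, conf = 0.95,
                                   B = 10000, seed = NULL) {
  pa <- strain_pair_identities(mat_a, strain_of_a)
  pb <- strain_pair_identities(mat_b, strain_of_b)
  pairs <- dplyr::inner_join(pa, pb, by = c("strain_a", "strain_b"),
                             suffix = c("_a", "_b"))
  if (nrow(pairs) == 0) abort("no strain pairs shared between the two matrices")
  if (nrow(pairs) < 6) {
    warn("fewer than 6 shared pairs; exact signed-rank test on a tiny sample")
  }
  sr <- signed_rank_test(pairs$identity_a, pairs$identity_b)
  test <- tibble(statistic = sr$statistic, p_value = sr$p_value,
                 n_pairs = nrow(pairs), method = sr$method)
  med_ci <- function(x, which) {
    s <- if (is.null(seed)) NULL else child_seed(seed, which)
    if (length(unique(x)) == 1L) {
      return(tibble(median = x[1], lo = x[1], hi = x[1]))
    }
    ci <- bca_interval(x, B = B, conf = conf, statistic = median, seed = s)
    tibble(median = median(x), lo = ci$lo, hi = ci$hi)
  }
  medians <- dplyr::bind_rows(
    dplyr::mutate(med_ci(pairs$identity_a, "a"), family = "a", .before = 1),
    dplyr::mutate(med_ci(pairs$identity_b, "b"), family = "b", .before = 1)
  )
  list(test = test, medians = medians, pairs = pairs)
}

#' Symmetrise a template/experiment TM-score table
#'
#' Structure-alignment scores depend on which structure is the template, so
#' each comparison is run in both orientations and averaged.
#'
#' @param tm Data frame with columns `id_a`, `id_b`, `score_ab`, `score_ba`.
#' @return Tibble `id_a`, `id_b`, `tm_score` (the orientation mean), keyed
#'   by unordered pair.
#' @export
symmetrize_tm_scores <- function(tm) {
  assert_columns(tm, c("id_a", "id_b", "score_ab", "score_ba"), "TM-score table")
  tibble(
    id_a = pmin(as.character(tm$id_a), as.character(tm$id_b)),
    id_b = pmax(as.character(tm$id_a), as.character(tm$id_b)),
    tm_score = (tm$score_ab + tm$score_ba) / 2
  )
}

#' Correlation of structural similarity with sequence identity
#'
#' Pearson correlation between per-pair TM scores (orientation-averaged) and
#' percent sequence identity; p-value from the t transform of r with
#' `N - 2` degrees of freedom.
#'
#' @param tm TM-score table (`id_a`, `id_b`, `score_ab`, `score_ba`), or an
#'   already-symmetrised tibble with `tm_score`.
#' @param ident Identity matrix from [identity_matrix()] covering the same
#'   ids.
#' @return Tibble: `r`, `r.squared`, `statistic`, `p_value`, `n`.
#' @export
structure_sequence_correlation <- function(tm, ident) {
  tm <- if ("tm_score" %in% names(tm)) as_tibble(tm) else symmetrize_tm_scores(tm)
  idx <- cbind(match(tm$id_a, rownames(ident)), match(tm$id_b, rownames(ident)))
  if (anyNA(idx)) abort("TM-score ids missing from the identity matrix")
  x <- ident[idx]
  y <- tm$tm_score
  if (length(y) < 3) abort("need at least 3 pairs for a correlation")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble(
    r = unname(ct$estimate), r.squared = unname(ct$estimate)^2,
    statistic = unname(ct$statistic), p_value = ct$p.value, n = length(y)
  )
}
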