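# Random-forest association of pathway scores with tag-locus log2 CNAs.
#
# Each pathway score vector is fitted by a regression forest on the
# samples x tag-loci design matrix of log2 copy-number alterations. The
# importance of locus i is the mean, over trees, of the increase in
# held-out prediction error when the locus's values are permuted; dividing
# by its standard error over trees gives the normalized importance
# Ibar = I_i(p) / sigma_i(p) that the significance stage tests.

#' Random-forest parameters
#'
#' @param n_trees number of trees N (default 1000).
#' @param predictors_per_split predictors tried at each split, M; default
#'   `ceiling(sqrt(n))` of the n tag-loci.
#' @param samples_per_tree samples drawn per tree WITHOUT replacement;
#'   default `ceiling(sqrt(x))` of the x samples. The deliberately small
#'   subsample leaves a large held-out set per tree on which permutation
#'   importance is measured.
#' @param min_node_size nodes of this size or smaller are not split
#'   (default 5).
#' @param seed integer seed; identical seed gives identical forests.
#' @return a `forest_params` list.
#' @export
forest_params <- function(n_trees = 1000, predictors_per_split = NULL,
                          samples_per_tree = NULL, min_node_size = 5,
                          seed = 1L) {
  if (n_trees < 2) .stopf("n_trees must be >= 2 (standard errors need >= 2 trees)")
  structure(list(n_trees = as.integer(n_trees),
                 predictors_per_split = predictors_per_split,
                 samples_per_tree = samples_per_tree,
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' Build the samples x tag-loci design matrix of log2 CNAs
#'
#' Column t is the log2-transformed copy-number row of tag-locus t's
#' representative locus; columns follow the tags' genomic order.
#'
#' @param CN a [copy_number_matrix()].
#' @param tags a `tag_locus_set` from [detect_tag_loci()]; all
#'   representatives must be present in `CN`.
#' @param sample_ids optional sample ids the design must cover (e.g. the
#'   columns of the pathway-score matrix); a mismatch is an error listing
#'   the symmetric difference.
#' @return numeric matrix, samples x tag-loci.
#' @export
build_design <- function(CN, tags, sample_ids = NULL) {
  stopifnot(inherits(CN, "cn_matrix"), inherits(tags, "tag_locus_set"))
  missing <- setdiff(tags$tag_id, rownames(CN$values))
  if (length(missing))
    .stopf("tag representatives absent from copy-number matrix: %s",
           paste(missing, collapse = ", "))
  X <- t(log2(CN$values[tags$tag_id, , drop = FALSE]))
  if (!is.null(sample_ids)) {
    extra <- setdiff(rownames(X), sample_ids)
    lacking <- setdiff(sample_ids, rownames(X))
    if (length(extra) || length(lacking))
      .stopf("sample sets differ; only in copy number: {%s}; only in scores: {%s}",
             paste(extra, collapse = ", "), paste(lacking, collapse = ", "))
    X <- X[sample_ids, , drop = FALSE]
  }
  X
}

.normalized_importance <- function(I, se) {
  if (any(se == 0 & I != 0))
    .stopf("zero standard error with nonzero importance; increase n_trees")
  ifelse(se == 0, 0, I / se)
}

#' Fit a forest and compute per-locus normalized importance
#'
#' Grows `n_trees` regression trees, each on a small subsample drawn
#' without replacement, each split choosing the best of
#' `predictors_per_split` randomly chosen predictors. Per tree and locus,
#' the importance contribution is the held-out MSE with the locus's values
#' permuted minus the unpermuted held-out MSE (loci unused by a tree
#' contribute exactly 0). `I` is the mean over trees, `se` the standard
#' error (sd over trees / sqrt(N)), and `ibar = I / se` (defined as 0 when
#' both are 0, e.g. for a constant response).
#'
#' All internal randomness is keyed by locus id, not column position, so
#' permuting the design's columns permutes the output rows identically.
#'
#' @param A_p numeric pathway-score vector, one value per sample, aligned
#'   with the rows of `X` (names checked when both are present).
#' @param X design matrix from [build_design()]; needs >= 10 samples and
#'   locus ids as colnames.
#' @param params a [forest_params()].
#' @return a data frame with one row per locus: `locus`, `importance`,
#'   `se`, `ibar`.
#' @export
fit_importance <- function(A_p, X, params = forest_params()) {
  stopifnot(inherits(params, "forest_params"), is.matrix(X))
  if (is.null(colnames(X))) .stopf("design matrix needs locus ids as colnames")
  x <- nrow(X)
  if (length(A_p) != x) .stopf("length(A_p) != nrow(X)")
  if (x < 10) .stopf("need >= 10 samples (got %d)", x)
  if (!is.null(names(A_p)) && !is.null(rownames(X))) {
    if (!setequal(names(A_p), rownames(X)))
      .stopf("sample sets of scores and design differ; only in scores: {%s}; only in design: {%s}",
             paste(setdiff(names(A_p), rownames(X)), collapse = ", "),
             paste(setdiff(rownames(X), names(A_p)), collapse = ", "))
    X <- X[names(A_p), , drop = FALSE]
  }
  n <- ncol(X)
  mtry <- params$predictors_per_split %||% ceiling(sqrt(n))
  spt <- params$samples_per_tree %||% ceiling(sqrt(x))
  if (mtry < 1 || mtry > n) .stopf("predictors_per_split out of [1, %d]", n)
  if (spt < 2 || spt > x) .stopf("samples_per_tree out of [2, %d]", x)
  if (x - spt < 2)
    .stopf(paste0("fewer than 2 held-out samples per tree; add samples or ",
                  "reduce samples_per_tree"))
  res <- .rf_importance_cpp(unname(X), as.numeric(A_p), colnames(X),
                            params$n_trees, as.integer(mtry), as.integer(spt),
                            params$min_node_size, as.numeric(params$seed))
  I <- unname(res$mean)
  se <- unname(res$sd) / sqrt(params$n_trees)
  data.frame(locus = colnames(X), importance = I, se = se,
             ibar = .normalized_importance(I, se),
             stringsAsFactors = FALSE)
}
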