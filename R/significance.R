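# Permutation null, Z-test p-values and Benjamini-Hochberg FDR.
#
# The null distribution of normalized importance is built by permuting the
# sample order of the pathway-score vector and, independently, the sample
# rows of the design matrix (rows move jointly across columns, preserving
# the inter-locus correlation structure), then refitting the forest. The
# observed Ibar is converted to a one-sided upper-tail p-value against a
# normal fit (mu0, s0) of the null; associations manifest as importance
# above the null, never as a deficit.

#' Permutation null of normalized importance
#'
#' @param A_p pathway-score vector (one value per sample).
#' @param X design matrix, samples x loci.
#' @param params a [forest_params()].
#' @param n_perm number of permutations; enforced minimum 20 for pooled and
#'   100 for per-locus nulls.
#' @param pooling `"pooled"` (default: one null over all loci, stable at
#'   modest n_perm) or `"per_locus"`.
#' @param seed seed for the permutation streams (defaults to
#'   `params$seed`); each permutation gets a derived sub-seed.
#' @return a `null_model` list: `pooling`, `null_ibar` (n_perm x loci
#'   matrix), `mu0`, `s0`, `n_perm`.
#' @export
permutation_null <- function(A_p, X, params = forest_params(), n_perm = 100,
                             pooling = c("pooled", "per_locus"),
                             seed = params$seed) {
  pooling <- match.arg(pooling)
  min_perm <- if (pooling == "pooled") 20L else 100L
  if (n_perm < min_perm)
    .stopf("n_perm must be >= %d for %s nulls (got %d)", min_perm, pooling, n_perm)
  x <- nrow(X)
  if (length(A_p) != x) .stopf("length(A_p) != nrow(X)")
  Ap <- unname(as.numeric(A_p))
  Xu <- unname(X)
  colnames(Xu) <- colnames(X)
  nulls <- matrix(NA_real_, n_perm, ncol(X), dimnames = list(NULL, colnames(X)))
  for (t in seq_len(n_perm)) {
    st <- derive_seed(seed, "perm", t)
    perm <- withr::with_seed(st, list(a = sample.int(x), x = sample.int(x)))
    fp <- params
    fp$seed <- derive_seed(st, "fit")
    nulls[t, ] <- fit_importance(Ap[perm$a], Xu[perm$x, , drop = FALSE], fp)$ibar
  }
  if (pooling == "pooled") {
    mu0 <- mean(nulls)
    s0 <- sd(as.vector(nulls))
  } else {
    mu0 <- colMeans(nulls)
    s0 <- apply(nulls, 2, sd)
  }
  if (any(s0 == 0)) .stopf("null variance zero")
  structure(list(pooling = pooling, null_ibar = nulls, mu0 = mu0, s0 = s0,
                 n_perm = n_perm),
            class = "null_model")
}

#' Z-test p-value of normalized importance against a permutation null
#'
#' One-sided upper tail: `p = 1 - Phi((ibar - mu0) / s0)`, floored at the
#' smallest positive double so p lies in (0, 1].
#'
#' @param ibar numeric vector of observed normalized importances (finite).
#' @param null a `null_model` from [permutation_null()].
#' @param locus locus ids matching `ibar` (required for per-locus nulls).
#' @return numeric vector of p-values.
#' @export
z_pvalue <- function(ibar, null, locus = NULL) {
  stopifnot(inherits(null, "null_model"))
  if (any(!is.finite(ibar))) .stopf("non-finite normalized importance")
  if (null$pooling == "per_locus") {
    if (is.null(locus)) .stopf("per-locus null requires locus ids")
    mu0 <- null$mu0[locus]
    s0 <- null$s0[locus]
    if (anyNA(mu0)) .stopf("unknown locus id(s) for per-locus null")
  } else {
    mu0 <- null$mu0
    s0 <- null$s0
  }
  unname(pmax(pnorm((ibar - mu0) / s0, lower.tail = FALSE), .Machine$double.xmin))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    .stopf("p-values must lie in (0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Associate every pathway with every tag-locus
#'
#' For each pathway: fits the observed forest, builds its permutation null,
#' and converts each locus's normalized importance to a Z-test p-value.
#' q-values are then computed over all (locus, pathway) pairs of this call
#' by [bh_fdr()] and pairs with `q < alpha` are flagged significant. Each
#' pathway's forest and null use sub-seeds derived from the pathway NAME,
#' so adding or removing a pathway never changes another pathway's
#' importances or p-values (only the shared FDR step couples pathways).
#'
#' @param scores pathway x sample score matrix from [pathway_scores()].
#' @param X design matrix from [build_design()] (rows = the same samples).
#' @param params a [forest_params()].
#' @param n_perm,pooling passed to [permutation_null()].
#' @param alpha FDR threshold for the `significant` flag (default 0.05,
#'   strict `q < alpha`).
#' @param seed master seed (defaults to `params$seed`).
#' @return an `association_table` data frame: `locus`, `pathway`, `ibar`,
#'   `p`, `q`, `significant`.
#' @export
associate_pathways <- function(scores, X, params = forest_params(),
                               n_perm = 100, pooling = "pooled",
                               alpha = 0.05, seed = params$seed) {
  stopifnot(is.matrix(scores), is.matrix(X))
  if (!setequal(colnames(scores), rownames(X)))
    .stopf("sample sets differ; only in scores: {%s}; only in design: {%s}",
           paste(setdiff(colnames(scores), rownames(X)), collapse = ", "),
           paste(setdiff(rownames(X), colnames(scores)), collapse = ", "))
  X <- X[colnames(scores), , drop = FALSE]
  rows <- vector("list", nrow(scores))
  for (k in seq_len(nrow(scores))) {
    pw <- rownames(scores)[k]
    fp <- params
    fp$seed <- derive_seed(seed, pw, "obs")
    obs <- fit_importance(unname(scores[k, ]), X, fp)
    null <- permutation_null(unname(scores[k, ]), X, params, n_perm = n_perm,
                             pooling = pooling,
                             seed = derive_seed(seed, pw, "null"))
    p <- z_pvalue(obs$ibar, null, locus = obs$locus)
    rows[[k]] <- data.frame(locus = obs$locus, pathway = pw,
                            ibar = obs$ibar, p = p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  structure(out, class = c("association_table", "data.frame"))
}
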