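# Per-sample pathway expression fold-change scores.
#
# A pathway p in disease sample j is scored as
#   A_{p,j} = log2( sum_{i in LE(p)} E_{i,j} / sum_{i in LE(p)} E_i^N ),
# a ratio of sums over the pathway's leading-edge genes, where E_i^N is the
# mean expression of gene i over the control samples. The ratio-of-sums
# reading is the default; a mean-of-ratios variant is available for
# sensitivity analysis.

#' Control baseline expression per gene
#'
#' @param E an [expression_matrix()] with labels and at least one control
#'   sample.
#' @return named numeric vector `E_i^N`: the arithmetic mean expression of
#'   each gene over the control samples.
#' @export
control_baseline <- function(E) {
  stopifnot(inherits(E, "expr_matrix"))
  if (is.null(E$labels)) .stopf("control_baseline requires class labels")
  ctl <- samples_of(E, "control")
  if (!length(ctl)) .stopf("no control samples")
  rowMeans(E$values[, ctl, drop = FALSE])
}

#' Pathway fold-change score matrix
#'
#' Computes \eqn{A_{p,j}} for every pathway with a leading-edge set and
#' every disease sample.
#'
#' @param E an [expression_matrix()] with labels.
#' @param leading_edges a `gsea_result` from [run_gsea()], or a list of
#'   `leading_edge_set` objects.
#' @param baseline per-gene control baseline from [control_baseline()]
#'   (computed from `E` if omitted).
#' @param method `"ratio_of_sums"` (default, the literal reading of the
#'   score definition) or `"mean_of_ratios"` (log2 of the mean per-gene
#'   ratio, for sensitivity analysis).
#' @param epsilon optional clamp applied to zero numerator/denominator sums;
#'   by default a zero sum is an error naming the pathway and sample.
#' @return numeric matrix, pathways x disease samples, of signed log2
#'   fold-change scores.
#' @export
pathway_scores <- function(E, leading_edges, baseline = NULL,
                           method = c("ratio_of_sums", "mean_of_ratios"),
                           epsilon = NULL) {
  stopifnot(inherits(E, "expr_matrix"))
  method <- match.arg(method)
  if (is.null(baseline)) baseline <- control_baseline(E)
  le_list <- if (inherits(leading_edges, "gsea_result")) {
    stats::setNames(leading_edges$leading_edge, leading_edges$pathway)
  } else {
    stats::setNames(lapply(leading_edges, `[[`, "genes"),
                    vapply(leading_edges, `[[`, "", "pathway"))
  }
  dis <- samples_of(E, "disease")
  out <- matrix(NA_real_, length(le_list), length(dis),
                dimnames = list(names(le_list), dis))
  for (p in names(le_list)) {
    genes <- le_list[[p]]
    missing <- setdiff(genes, rownames(E$values))
    if (length(missing))
      .stopf("leading-edge genes of '%s' absent from expression matrix: %s",
             p, paste(missing, collapse = ", "))
    ev <- E$values[genes, dis, drop = FALSE]
    bv <- baseline[genes]
    if (anyNA(bv)) .stopf("baseline missing for leading-edge genes of '%s'", p)
    if (method == "ratio_of_sums") {
      num <- colSums(ev)
      den <- sum(bv)
      if (den <= 0) {
        if (is.null(epsilon))
          .stopf("zero baseline sum for pathway '%s'", p)
        den <- max(den, epsilon)
      }
      if (any(num <= 0)) {
        if (is.null(epsilon))
          .stopf("zero expression sum for pathway '%s', sample '%s'",
                 p, dis[which(num <= 0)[1]])
        num <- pmax(num, epsilon)
      }
      out[p, ] <- log2(num / den)
    } else {
      if (any(bv <= 0) || any(ev <= 0)) {
        if (is.null(epsilon))
          .stopf("zero expression/baseline for pathway '%s' under mean_of_ratios", p)
        bv <- pmax(bv, epsilon); ev <- pmax(ev, epsilon)
      }
      out[p, ] <- log2(colMeans(ev / bv))
    }
  }
  out
}
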