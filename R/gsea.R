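# Gene ranking, enrichment scores and leading-edge extraction.
#
# The ranking metric is the canonical signal-to-noise ratio
# (mu_d - mu_c) / (sd_d + sd_c) with each class sd floored at
# sigma_floor * |mu| of that class; the running-sum enrichment score
# follows the standard weighted Kolmogorov-Smirnov form. Pathways are
# classified over-/under-expressed purely by the sign of the enrichment
# score; no permutation significance screen is applied at this stage.

#' Rank genes by disease-vs-control signal-to-noise ratio
#'
#' Genes are ordered from most disease-up to most disease-down by
#' \eqn{(\mu_d - \mu_c) / (\sigma_d + \sigma_c)}, where each class standard
#' deviation is floored at `sigma_floor * |mu|` of that class. Ties are
#' broken by lexicographic gene id.
#'
#' @param E an [expression_matrix()] with labels; each class needs at least
#'   2 samples.
#' @param sigma_floor relative sd floor (default 0.2, the usual GSEA
#'   adjustment that keeps near-constant genes from dominating the ranking).
#' @return a `ranked_genes` data frame with columns `gene` and `metric`,
#'   sorted by non-increasing metric.
#' @export
rank_genes <- function(E, sigma_floor = 0.2) {
  stopifnot(inherits(E, "expr_matrix"))
  if (is.null(E$labels)) .stopf("rank_genes requires class labels")
  d <- E$values[, samples_of(E, "disease"), drop = FALSE]
  c_ <- E$values[, samples_of(E, "control"), drop = FALSE]
  if (ncol(d) < 2 || ncol(c_) < 2)
    .stopf("each class needs >= 2 samples (got %d disease, %d control)",
           ncol(d), ncol(c_))
  mu_d <- rowMeans(d); mu_c <- rowMeans(c_)
  sd_d <- pmax(apply(d, 1, sd), sigma_floor * abs(mu_d))
  sd_c <- pmax(apply(c_, 1, sd), sigma_floor * abs(mu_c))
  denom <- sd_d + sd_c
  if (any(denom == 0))
    .stopf("zero ranking denominator after flooring for gene(s): %s",
           paste(rownames(E$values)[denom == 0], collapse = ", "))
  metric <- (mu_d - mu_c) / denom
  o <- order(-metric, rownames(E$values))
  structure(data.frame(gene = rownames(E$values)[o], metric = metric[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_genes", "data.frame"))
}

#' Running-sum enrichment score of a gene set
#'
#' Walks the ranked list accumulating `|metric|^weight_exponent / N_R` at
#' set members (hits, `N_R` = total hit weight) and `-1/(N - N_H)` at
#' non-members. The enrichment score ES is the running-sum value of maximal
#' absolute deviation from zero; ties in |deviation| are resolved toward
#' the earliest rank. `|ES| <= 1` always holds.
#'
#' @param ranked a `ranked_genes` data frame from [rank_genes()].
#' @param gene_set character vector of member gene ids; must intersect the
#'   ranked list and must not cover it entirely.
#' @param weight_exponent hit-weight exponent (default 1, canonical GSEA;
#'   0 gives the unweighted Kolmogorov-Smirnov statistic).
#' @return an `es_result` list: `es`, `running_sum`, `argmax`, `argmin`
#'   (ranks of the running-sum extrema), `hit_ranks`, `genes` (the ranked
#'   ids) and `weight_exponent`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_genes"))
  N <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  NH <- sum(hit)
  if (NH == 0) .stopf("empty intersection of gene set and ranked list")
  if (NH == N) .stopf("gene set covers the whole ranked list (miss denominator zero)")
  w <- abs(ranked$metric)^weight_exponent
  NR <- sum(w[hit])
  if (NR == 0)
    .stopf("all hit weights are zero; use weight_exponent = 0 for unweighted scores")
  step <- ifelse(hit, w / NR, -1 / (N - NH))
  rs <- cumsum(step)
  argmax <- which.max(rs)              # earliest rank on ties
  argmin <- which.min(rs)
  es <- if (abs(rs[argmax]) > abs(rs[argmin]) ||
            (abs(rs[argmax]) == abs(rs[argmin]) && argmax <= argmin))
    rs[argmax] else rs[argmin]
  structure(list(es = es, running_sum = rs, argmax = argmax, argmin = argmin,
                 hit_ranks = which(hit), genes = ranked$gene,
                 weight_exponent = weight_exponent),
            class = "es_result")
}

#' Leading-edge genes of an enrichment result
#'
#' For a positive ES, the leading edge is the set members appearing at or
#' before the rank where the running sum attains its maximum; for a
#' negative ES it is the mirrored convention, members at or after the rank
#' of the running-sum minimum. These are the genes that drive the pathway's
#' over-/under-expression.
#'
#' @param es an `es_result` from [enrichment_score()]; `es$es` must be
#'   nonzero.
#' @param pathway optional pathway name to record.
#' @return a `leading_edge_set` list: `pathway`, `sign` (`"over"` or
#'   `"under"`) and `genes`.
#' @export
leading_edge <- function(es, pathway = NA_character_) {
  stopifnot(inherits(es, "es_result"))
  if (es$es == 0) .stopf("degenerate enrichment (ES = 0)")
  if (es$es > 0) {
    ranks <- es$hit_ranks[es$hit_ranks <= es$argmax]
    sign <- "over"
  } else {
    ranks <- es$hit_ranks[es$hit_ranks >= es$argmin]
    sign <- "under"
  }
  structure(list(pathway = pathway, sign = sign, genes = es$genes[ranks]),
            class = "leading_edge_set")
}

#' Run GSEA over a pathway collection
#'
#' Ranks the genes once, then computes the enrichment score and the
#' leading-edge set of every pathway. Pathways with no gene in the ranked
#' list, covering the entire list, or with ES exactly 0 are skipped with a
#' warning.
#'
#' @param E an [expression_matrix()] with labels.
#' @param pathways a [pathway_collection()].
#' @inheritParams rank_genes
#' @inheritParams enrichment_score
#' @return a `gsea_result` data frame with one row per scored pathway:
#'   `pathway`, `es`, `sign`, `n_hits`, `n_leading_edge` and a list-column
#'   `leading_edge` of gene-id vectors.
#' @export
run_gsea <- function(E, pathways, weight_exponent = 1, sigma_floor = 0.2) {
  stopifnot(inherits(pathways, "pathway_collection"))
  ranked <- rank_genes(E, sigma_floor = sigma_floor)
  rows <- list()
  for (nm in names(pathways)) {
    hit_n <- sum(ranked$gene %in% pathways[[nm]])
    if (hit_n == 0 || hit_n == nrow(ranked)) {
      .warnf("pathway '%s' skipped (%s)", nm,
             if (hit_n == 0) "no genes in ranked list" else "covers whole list")
      next
    }
    es <- enrichment_score(ranked, pathways[[nm]], weight_exponent)
    if (es$es == 0) {
      .warnf("pathway '%s' skipped (ES = 0)", nm)
      next
    }
    le <- leading_edge(es, pathway = nm)
    rows[[nm]] <- data.frame(pathway = nm, es = es$es, sign = le$sign,
                             n_hits = hit_n, n_leading_edge = length(le$genes),
                             stringsAsFactors = FALSE)
    rows[[nm]]$leading_edge <- list(le$genes)
  }
  if (!length(rows)) .stopf("no pathway could be scored")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("gsea_result", "data.frame"))
}
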