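# Post-association summaries: alteration-frequency profile, per-locus
# pathway counts, chromosome pathway-sharing matrices, driver-gene pathway
# enrichment and per-gene differential expression.

#' Alteration-frequency profile over tag-loci
#'
#' Fraction of samples whose |log2 CNA| strictly exceeds `threshold` at
#' each tag-locus representative. The threshold is interpreted on the log2
#' scale so deletions can exceed it in absolute value.
#'
#' @param CN a [copy_number_matrix()].
#' @param tags a `tag_locus_set`; representatives must be present in `CN`.
#' @param threshold log2 units (default 1.5, strict).
#' @return data frame: `tag_id`, `chrom`, `pos`, `frequency`.
#' @export
alteration_frequency <- function(CN, tags, threshold = 1.5) {
  stopifnot(inherits(CN, "cn_matrix"), inherits(tags, "tag_locus_set"))
  missing <- setdiff(tags$tag_id, rownames(CN$values))
  if (length(missing))
    .stopf("tag representatives absent from copy-number matrix: %s",
           paste(missing, collapse = ", "))
  l2 <- log2(CN$values[tags$tag_id, , drop = FALSE])
  data.frame(tag_id = tags$tag_id, chrom = tags$chrom,
             pos = CN$pos[match(tags$tag_id, rownames(CN$values))],
             frequency = rowMeans(abs(l2) > threshold),
             stringsAsFactors = FALSE)
}

#' Number of distinct significantly associated pathways per tag-locus
#'
#' @param assoc an `association_table` from [associate_pathways()].
#' @return data frame `locus`, `n_pathways`, one row per locus appearing in
#'   `assoc` (0 when a locus has no significant pathway).
#' @export
pathway_counts <- function(assoc) {
  stopifnot(inherits(assoc, "association_table"))
  loci <- unique(assoc$locus)
  sig <- assoc[assoc$significant, c("locus", "pathway")]
  sig <- unique(sig)
  counts <- table(factor(sig$locus, levels = loci))
  data.frame(locus = loci, n_pathways = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Chromosome pathway-sharing matrix
#'
#' `counts[c1, c2]` is the number of distinct pathways significantly
#' associated with at least one tag-locus on chromosome c1 AND at least one
#' on c2; the diagonal counts the pathways on each chromosome. Symmetric by
#' construction, with each diagonal entry at least as large as every
#' off-diagonal entry in its row.
#'
#' @param assoc an `association_table`; if it carries a `direction` column
#'   (added by [run_pipeline()]), `direction` selects the pathway class.
#' @param tags a `tag_locus_set` resolving each locus to a chromosome.
#' @param direction optional `"over"` or `"under"`.
#' @return integer matrix over the chromosomes of `tags`.
#' @export
chromosome_sharing <- function(assoc, tags, direction = NULL) {
  stopifnot(inherits(assoc, "association_table"), inherits(tags, "tag_locus_set"))
  if (!is.null(direction)) {
    if (is.null(assoc$direction))
      .stopf("association table has no direction column")
    assoc <- assoc[assoc$direction == direction, , drop = FALSE]
  }
  chroms <- unique(tags$chrom)
  counts <- matrix(0L, length(chroms), length(chroms),
                   dimnames = list(chroms, chroms))
  sig <- assoc[assoc$significant, , drop = FALSE]
  if (nrow(sig)) {
    chr_of <- tags$chrom[match(sig$locus, tags$tag_id)]
    if (anyNA(chr_of))
      .stopf("locus not resolvable to a chromosome: %s",
             paste(unique(sig$locus[is.na(chr_of)]), collapse = ", "))
    for (pw in unique(sig$pathway)) {
      cs <- unique(chr_of[sig$pathway == pw])
      counts[cs, cs] <- counts[cs, cs] + 1L
    }
  }
  counts
}

# one-sided over-representation tail of the hypergeometric distribution
.fisher_over_p <- function(overlap, pathway_size, n_drivers, universe_size) {
  phyper(overlap - 1, n_drivers, universe_size - n_drivers, pathway_size,
         lower.tail = FALSE)
}

#' Driver-gene enrichment of pathways (one-sided Fisher test)
#'
#' For each pathway, tests over-representation of driver genes via the
#' hypergeometric tail of the 2x2 table (in-pathway/driver vs complements),
#' restricted to a gene universe.
#'
#' @param pathways a [pathway_collection()] (memberships are intersected
#'   with the universe; pathways empty after intersection are skipped with
#'   a warning).
#' @param drivers character vector of driver gene ids (must lie in the
#'   universe).
#' @param universe character vector of gene ids, e.g. the rownames of the
#'   filtered expression matrix.
#' @return data frame sorted by p ascending (ties by name): `pathway`,
#'   `overlap`, `pathway_size`, `n_drivers`, `universe_size`, `p`.
#' @export
driver_enrichment <- function(pathways, drivers, universe) {
  stopifnot(inherits(pathways, "pathway_collection"))
  universe <- unique(universe)
  if (!length(universe)) .stopf("empty universe")
  outside <- setdiff(drivers, universe)
  if (length(outside))
    .stopf("driver genes outside the universe: %s", paste(outside, collapse = ", "))
  drivers <- unique(drivers)
  rows <- list()
  for (nm in names(pathways)) {
    members <- intersect(pathways[[nm]], universe)
    if (!length(members)) {
      .warnf("pathway '%s' empty after intersecting with universe; skipped", nm)
      next
    }
    k <- length(intersect(members, drivers))
    rows[[nm]] <- data.frame(
      pathway = nm, overlap = k, pathway_size = length(members),
      n_drivers = length(drivers), universe_size = length(universe),
      p = .fisher_over_p(k, length(members), length(drivers), length(universe)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("no pathway overlaps the universe")
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene differential expression between disease and control
#'
#' Two-sided t-test per gene (Welch by default; set `var_equal = TRUE` for
#' the pooled-variance Student flavor) with Benjamini-Hochberg q-values.
#' Genes with zero variance in both classes and equal means get t = 0,
#' p = 1 and are flagged in the `degenerate` column.
#'
#' @param E an [expression_matrix()] with labels, >= 2 samples per class.
#' @param var_equal pooled-variance test instead of Welch.
#' @return data frame: `gene`, `t`, `df`, `p`, `q`, `degenerate`.
#' @export
differential_expression <- function(E, var_equal = FALSE) {
  stopifnot(inherits(E, "expr_matrix"))
  if (is.null(E$labels)) .stopf("differential_expression requires class labels")
  d <- E$values[, samples_of(E, "disease"), drop = FALSE]
  c_ <- E$values[, samples_of(E, "control"), drop = FALSE]
  n1 <- ncol(d); n2 <- ncol(c_)
  if (n1 < 2 || n2 < 2) .stopf("each class needs >= 2 samples")
  m1 <- rowMeans(d); m2 <- rowMeans(c_)
  v1 <- apply(d, 1, var); v2 <- apply(c_, 1, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  degenerate <- se == 0 & m1 == m2
  separated <- se == 0 & m1 != m2
  t <- ifelse(se == 0, 0, (m1 - m2) / se)
  p <- ifelse(se == 0, 1, 2 * pt(-abs(t), df))
  if (any(separated)) {
    # zero variance in both classes but unequal means: perfectly separated
    .warnf("%d gene(s) with zero variance but unequal means; p floored",
           sum(separated))
    t[separated] <- sign(m1 - m2)[separated] * Inf
    p[separated] <- .Machine$double.xmin
  }
  degenerate <- degenerate | separated
  data.frame(gene = rownames(E$values), t = t, df = ifelse(se == 0, NA, df),
             p = p, q = bh_fdr(p), degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}
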