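# Tag-locus detection: greedy reduction of the locus set to representative
# loci. Scanning each chromosome left to right, a region starts at the
# first unassigned locus (its seed, which becomes the representative) and
# accumulates consecutive loci while the correlation criterion holds
# strictly. Correlations are computed on log2-transformed copy numbers,
# matching the association design matrix. The default criterion compares
# every candidate against the seed ("seed" mode, the formal region
# definition); "chain" mode compares consecutive pairs instead and yields
# coarser regions when correlation decays with distance.

#' Detect tag-loci by greedy correlation clustering
#'
#' @param CN a [copy_number_matrix()] with at least 2 samples.
#' @param r_threshold Pearson correlation threshold; a candidate joins the
#'   region only when its correlation strictly exceeds it (default 0.95).
#' @param mode `"seed"` (candidate vs region seed, default) or `"chain"`
#'   (candidate vs previous locus).
#' @return a `tag_locus_set` data frame with one row per region: `tag_id`
#'   (the representative, i.e. first, locus), `chrom`, `span_start`,
#'   `span_end` (0-based half-open over member positions), `n_members`, and
#'   list-columns `members` and `genes` (genes filled by [assign_genes()]).
#'   Regions partition the input loci and never cross chromosomes. A locus
#'   with zero variance becomes a singleton region with a warning.
#' @export
detect_tag_loci <- function(CN, r_threshold = 0.95, mode = c("seed", "chain")) {
  stopifnot(inherits(CN, "cn_matrix"))
  mode <- match.arg(mode)
  if (ncol(CN$values) < 2) .stopf("need >= 2 samples to correlate loci")
  l2 <- log2(CN$values)
  ids <- rownames(l2)
  const <- apply(l2, 1, function(v) max(v) == min(v))
  if (any(const))
    .warnf("%d constant locus vector(s); treated as singleton regions",
           sum(const))
  regions <- list()
  for (ch in unique(CN$chrom)) {
    idx <- which(CN$chrom == ch)
    i <- 1L
    while (i <= length(idx)) {
      seed <- idx[i]
      members <- seed
      if (!const[seed]) {
        j <- i + 1L
        ref <- seed
        while (j <= length(idx)) {
          cand <- idx[j]
          if (const[cand]) break
          r <- cor(l2[ref, ], l2[cand, ])
          if (!(r > r_threshold)) break
          members <- c(members, cand)
          if (mode == "chain") ref <- cand
          j <- j + 1L
        }
      }
      regions[[length(regions) + 1L]] <- members
      i <- i + length(members)
    }
  }
  tag_rows <- vapply(regions, `[[`, 0L, 1L)
  spacing <- if (nrow(l2) > 1) {
    d <- diff(CN$pos)[diff(CN$pos) > 0]
    if (length(d)) min(d) else 1
  } else 1
  out <- data.frame(
    tag_id = ids[tag_rows],
    chrom = CN$chrom[tag_rows],
    span_start = vapply(regions, function(m) min(CN$pos[m]), 0),
    span_end = vapply(regions, function(m) max(CN$pos[m]) + spacing, 0),
    n_members = lengths(regions),
    stringsAsFactors = FALSE)
  out$members <- lapply(regions, function(m) ids[m])
  out$genes <- rep(list(character(0)), nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("tag_locus_set", "data.frame"))
}

#' Assign genes to tag-locus regions by interval overlap
#'
#' A gene is assigned to every region whose span its interval overlaps
#' (half-open overlap: `gene_start < span_end + flank` and
#' `gene_end > span_start - flank`), so a gene may belong to more than one
#' region.
#'
#' @param tags a `tag_locus_set` from [detect_tag_loci()].
#' @param annotation a [gene_annotation()] data frame; every annotation
#'   chromosome must occur among the tag-loci.
#' @param flank bp added on each side of every region span (default 0).
#' @return `tags` with the `genes` list-column filled.
#' @export
assign_genes <- function(tags, annotation, flank = 0) {
  stopifnot(inherits(tags, "tag_locus_set"))
  if (!nrow(annotation)) .stopf("empty annotation")
  unmatched <- setdiff(unique(annotation$chrom), unique(tags$chrom))
  if (length(unmatched))
    .stopf("annotation chromosomes absent from loci: %s",
           paste(unmatched, collapse = ", "))
  tags$genes <- lapply(seq_len(nrow(tags)), function(k) {
    on_chr <- annotation$chrom == tags$chrom[k]
    hit <- on_chr &
      annotation$start < tags$span_end[k] + flank &
      annotation$end > tags$span_start[k] - flank
    annotation$gene_id[hit]
  })
  tags
}
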