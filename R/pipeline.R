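# End-to-end orchestration: simulate/ingest -> GSEA -> pathway scores ->
# tag-loci -> random-forest association -> permutation test -> reports,
# from a single config with a manifest for provenance. FDR is applied
# within each pathway direction (over-/under-expressed) by default; a
# pooled option exists.

#' Pipeline configuration
#'
#' Exactly one of `synthetic` or `inputs` must be given.
#'
#' @param synthetic a [synthetic_config()] to simulate the cohort.
#' @param inputs named list of file paths: `expression`, `labels` (2-column
#'   TSV sample_id/label), `copy_number`, `pathways` (GMT); optional
#'   `annotation` (BED) and `drivers` (one gene per line).
#' @param weight_exponent,sigma_floor GSEA options, see [run_gsea()].
#' @param score_method see [pathway_scores()].
#' @param r_threshold,tag_mode tag-locus options, see [detect_tag_loci()].
#' @param forest a [forest_params()].
#' @param n_perm,pooling,alpha significance options, see
#'   [permutation_null()] and [associate_pathways()].
#' @param fdr_scope `"per_direction"` (default: q-values computed separately
#'   over associations to over- and to under-expressed pathways) or
#'   `"pooled"`.
#' @param cna_threshold log2 threshold of the alteration-frequency profile.
#' @param seed global seed driving every stochastic stage.
#' @param outdir output directory for stage artifacts and the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL,
                       weight_exponent = 1, sigma_floor = 0.2,
                       score_method = "ratio_of_sums",
                       r_threshold = 0.95, tag_mode = "seed",
                       forest = forest_params(),
                       n_perm = 100, pooling = "pooled", alpha = 0.05,
                       fdr_scope = c("per_direction", "pooled"),
                       cna_threshold = 1.5, seed = 1L, outdir = tempfile("pathqtl_run_")) {
  if (is.null(synthetic) == is.null(inputs))
    .stopf("exactly one of 'synthetic' or 'inputs' must be given")
  fdr_scope <- match.arg(fdr_scope)
  structure(list(synthetic = synthetic, inputs = inputs,
                 weight_exponent = weight_exponent, sigma_floor = sigma_floor,
                 score_method = score_method,
                 r_threshold = r_threshold, tag_mode = tag_mode,
                 forest = forest, n_perm = n_perm, pooling = pooling,
                 alpha = alpha, fdr_scope = fdr_scope,
                 cna_threshold = cna_threshold, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .stopf("stage '%s' failed: %s\n  replay: run_pipeline(<config>) after fixing the stage inputs",
           name, conditionMessage(e))
  })
}

.read_labels_file <- function(path) {
  df <- read.delim(path, colClasses = "character")
  stats::setNames(df$label, df$sample_id)
}

#' Run the full pathway-CNA association pipeline
#'
#' Stages, in order: load or simulate the cohort; low-signal filtering;
#' GSEA (ranking, enrichment scores, leading edges); pathway fold-change
#' scores; tag-locus detection (+ gene assignment when annotation is
#' available); design-matrix construction; per-direction random-forest
#' association with permutation null, Z-test and BH FDR; downstream
#' reports (alteration frequencies, per-locus pathway counts, chromosome
#' sharing matrices, differential expression, driver enrichment when a
#' driver list is given). All artifacts are written under
#' `config$outdir` as TSVs plus a `manifest.json` recording seed, package
#' version, per-stage row counts and the association-table checksum.
#' Identical config and seed produce a byte-identical association table.
#'
#' @param config a [run_config()].
#' @return (invisibly) a result bundle: all stage outputs plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "pathqtl",
                   version = as.character(utils::packageVersion("pathqtl")),
                   seed = config$seed, stages = list())

  data <- .stage("data", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- derive_seed(config$seed, "data")
      generate_dataset(cfg)
    } else {
      inp <- config$inputs
      labels <- .read_labels_file(inp$labels)
      list(expression = read_expression(inp$expression, labels = labels),
           copy_number = read_copy_number(inp$copy_number),
           pathways = read_gene_sets(inp$pathways),
           annotation = if (!is.null(inp$annotation)) read_annotation(inp$annotation),
           drivers = if (!is.null(inp$drivers)) read_driver_genes(inp$drivers))
    }
  })
  E <- .stage("filter", filter_low_signal(data$expression))
  manifest$stages$filter <- list(genes = nrow(E$values), samples = ncol(E$values))

  gsea <- .stage("gsea", run_gsea(E, data$pathways,
                                  weight_exponent = config$weight_exponent,
                                  sigma_floor = config$sigma_floor))
  gsea_out <- gsea[, c("pathway", "es", "sign", "n_hits", "n_leading_edge")]
  gsea_out$leading_edge <- vapply(gsea$leading_edge, paste, "", collapse = ";")
  write.table(gsea_out, file.path(config$outdir, "gsea.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$gsea <- list(pathways = nrow(gsea),
                               over = sum(gsea$sign == "over"),
                               under = sum(gsea$sign == "under"))

  scores <- .stage("score", pathway_scores(E, gsea, method = config$score_method))
  .write_matrix_tsv(scores, file.path(config$outdir, "pathway_scores.tsv"), "pathway")
  manifest$stages$score <- list(pathways = nrow(scores), samples = ncol(scores))

  tags <- .stage("tagloci", {
    tg <- detect_tag_loci(data$copy_number, r_threshold = config$r_threshold,
                          mode = config$tag_mode)
    if (!is.null(data$annotation)) tg <- assign_genes(tg, data$annotation)
    tg
  })
  tag_out <- tags[, c("tag_id", "chrom", "span_start", "span_end", "n_members")]
  tag_out$genes <- vapply(tags$genes, paste, "", collapse = ";")
  write.table(tag_out, file.path(config$outdir, "tag_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$tagloci <- list(tag_loci = nrow(tags),
                                  loci = nrow(data$copy_number$values))

  X <- .stage("design", build_design(data$copy_number, tags,
                                     sample_ids = colnames(scores)))

  assoc <- .stage("associate", {
    parts <- list()
    directions <- if (config$fdr_scope == "per_direction")
      unique(gsea$sign) else "all"
    for (dir in directions) {
      pws <- if (dir == "all") gsea$pathway else gsea$pathway[gsea$sign == dir]
      a <- associate_pathways(scores[pws, , drop = FALSE], X,
                              params = config$forest, n_perm = config$n_perm,
                              pooling = config$pooling, alpha = config$alpha,
                              seed = derive_seed(config$seed, "associate"))
      a$direction <- gsea$sign[match(a$pathway, gsea$pathway)]
      parts[[dir]] <- a
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "alpha") <- config$alpha
    structure(out, class = c("association_table", "data.frame"))
  })
  assoc_path <- file.path(config$outdir, "associations.tsv")
  assoc_out <- assoc
  assoc_out$ibar <- .fmt_num(assoc_out$ibar)
  assoc_out$p <- .fmt_num(assoc_out$p)
  assoc_out$q <- .fmt_num(assoc_out$q)
  write.table(assoc_out, assoc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$associate <- list(pairs = nrow(assoc),
                                    significant = sum(assoc$significant))

  reports <- .stage("report", {
    rep <- list(alteration_frequency =
                  alteration_frequency(data$copy_number, tags,
                                       threshold = config$cna_threshold),
                pathway_counts = pathway_counts(assoc),
                differential_expression = differential_expression(E))
    for (dir in intersect(c("over", "under"), unique(assoc$direction)))
      rep[[paste0("sharing_", dir)]] <- chromosome_sharing(assoc, tags, dir)
    if (!is.null(data$drivers))
      rep$driver_enrichment <- driver_enrichment(data$pathways, data$drivers,
                                                 rownames(E$values))
    rep
  })
  write.table(reports$alteration_frequency,
              file.path(config$outdir, "alteration_frequency.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(reports$pathway_counts,
              file.path(config$outdir, "pathway_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(reports$differential_expression,
              file.path(config$outdir, "differential_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in grep("^sharing_", names(reports), value = TRUE))
    write.table(reports[[nm]], file.path(config$outdir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE)
  if (!is.null(reports$driver_enrichment))
    write.table(reports$driver_enrichment,
                file.path(config$outdir, "driver_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  manifest$associations_md5 <- unname(tools::md5sum(assoc_path))
  manifest$config <- .serialize_config(config)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  invisible(list(data = data, expression = E, gsea = gsea, scores = scores,
                 tags = tags, design = X, associations = assoc,
                 reports = reports, manifest = manifest))
}

.serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$forest <- unclass(cfg$forest)
  if (!is.null(cfg$synthetic)) cfg$synthetic <- unclass(cfg$synthetic)
  cfg
}
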