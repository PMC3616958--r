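# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: log-scale expression with group differences confined to
# pathway genes, locally correlated copy-number blocks with chromosome-scale
# signature amplifications/deletions, and planted locus -> pathway effects
# with a recorded ground truth. It is a stand-in for a tumor/control array
# cohort, not a realistic array noise model.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the cohort the pipeline was designed around: 158 disease
#' and 21 control samples, chromosome-scale signature events (an
#' amplification emulating chromosome-7 gains, a deletion emulating
#' chromosome-10 losses), and copy-number blocks whose adjacent loci are
#' highly correlated.
#'
#' @param n_disease,n_control sample counts.
#' @param n_chromosomes number of synthetic chromosomes.
#' @param loci_per_chromosome loci on each chromosome.
#' @param block_size loci per correlated block (blocks tile each chromosome;
#'   use 1 for independent loci).
#' @param within_block_r target Pearson correlation between any two loci of
#'   one block (latent-factor construction; must be in (0, 1)).
#' @param n_pathways,genes_per_pathway pathway gene sets (disjoint).
#' @param n_background_genes genes outside every pathway.
#' @param planted_effects list of `list(block=, pathway=, beta=)` triples:
#'   the log-scale expression of every gene of `pathway` gains
#'   `beta * log2(CNA)` of the block's representative locus, per disease
#'   sample. Empty list = global null.
#' @param expression_noise_sd per-gene Gaussian noise sd on the log2 scale
#'   (0.5 is a typical microarray log-scale residual spread).
#' @param baseline_range uniform range of per-gene baseline log2 intensity.
#' @param cna_sd marginal sd of locus log2 copy-number ratios before
#'   signature events (0.5 spans diploid to one-copy gains/losses).
#' @param signature_events list of `list(chrom=, sign=, fraction=, magnitude=)`:
#'   each adds `sign * magnitude` (log2 units) to every locus of `chrom` in a
#'   random `fraction` of samples. Defaults: one-copy gain (log2(3/2)) on
#'   chromosome 1 and one-copy loss (log2(1/2)) on chromosome 2, each in 80%
#'   of samples, the canonical signature pattern of the emulated tumor type.
#' @param locus_spacing bp between consecutive loci.
#' @param seed master seed; one seed drives split per-component streams, so
#'   e.g. changing `n_pathways` does not perturb the copy-number draws.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_disease = 158, n_control = 21,
                             n_chromosomes = 4, loci_per_chromosome = 50,
                             block_size = 5, within_block_r = 0.98,
                             n_pathways = 20, genes_per_pathway = 25,
                             n_background_genes = 500,
                             planted_effects = list(list(block = 1L, pathway = 1L, beta = 0.5)),
                             expression_noise_sd = 0.5,
                             baseline_range = c(5, 10),
                             cna_sd = 0.5,
                             signature_events = list(
                               list(chrom = 1L, sign = 1L, fraction = 0.8, magnitude = log2(3 / 2)),
                               list(chrom = 2L, sign = -1L, fraction = 0.8, magnitude = 1.0)),
                             locus_spacing = 1e5, seed = 1L) {
  cfg <- list(n_disease = n_disease, n_control = n_control,
              n_chromosomes = n_chromosomes,
              loci_per_chromosome = loci_per_chromosome,
              block_size = block_size, within_block_r = within_block_r,
              n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
              n_background_genes = n_background_genes,
              planted_effects = planted_effects,
              expression_noise_sd = expression_noise_sd,
              baseline_range = baseline_range, cna_sd = cna_sd,
              signature_events = signature_events,
              locus_spacing = locus_spacing, seed = seed)
  counts <- c("n_disease", "n_control", "n_chromosomes", "loci_per_chromosome",
              "block_size", "n_pathways", "genes_per_pathway")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1)
      .stopf("%s must be a positive count", f)
  if (within_block_r >= 1 || within_block_r <= 0)
    .stopf("within_block_r must be in (0, 1); %g is infeasible", within_block_r)
  n_blocks <- n_chromosomes * ceiling(loci_per_chromosome / block_size)
  for (pe in planted_effects) {
    if (!all(c("block", "pathway", "beta") %in% names(pe)))
      .stopf("planted effects need block, pathway and beta")
    if (pe$block < 1 || pe$block > n_blocks)
      .stopf("planted block index %d out of range [1, %d]", pe$block, n_blocks)
    if (pe$pathway < 1 || pe$pathway > n_pathways)
      .stopf("planted pathway index %d out of range [1, %d]", pe$pathway, n_pathways)
  }
  for (ev in signature_events)
    if (ev$chrom < 1 || ev$chrom > n_chromosomes)
      .stopf("signature event chromosome %d out of range", ev$chrom)
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic expression + copy-number dataset
#'
#' Copy-number blocks are built from a single latent factor per block with
#' loadings solved from `within_block_r` (the log2 value of locus i in block
#' b is `cna_sd * (sqrt(r) g_b + sqrt(1-r) e_i)`), so the population
#' correlation of any two loci within a block equals `within_block_r` and
#' loci of different blocks are independent. Signature events then shift all
#' loci of one chromosome in a random subset of samples. Expression of a
#' pathway gene in a disease sample is baseline + the sum of its planted
#' `beta * log2(CNA)` terms (evaluated at each planted block's first locus,
#' the block representative) + Gaussian noise; control samples carry
#' baseline + noise only.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` list with elements `expression`
#'   ([expression_matrix()]), `copy_number` ([copy_number_matrix()], disease
#'   samples only), `pathways` ([pathway_collection()]), `annotation`
#'   ([gene_annotation()]) and `truth` (planted triples and block
#'   boundaries). Identical config and seed give identical datasets.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  dis <- sprintf("GBM_%03d", seq_len(cfg$n_disease))
  ctl <- sprintf("CTRL_%03d", seq_len(cfg$n_control))

  # --- copy number ------------------------------------------------------
  per_chr_blocks <- ceiling(cfg$loci_per_chromosome / cfg$block_size)
  chrom <- character(0); pos <- numeric(0); block_of <- integer(0)
  locus_ids <- character(0)
  b <- 0L
  block_rows <- list()
  for (c in seq_len(cfg$n_chromosomes)) {
    for (bb in seq_len(per_chr_blocks)) {
      b <- b + 1L
      first <- (bb - 1L) * cfg$block_size + 1L
      last <- min(bb * cfg$block_size, cfg$loci_per_chromosome)
      k <- seq(first, last)
      ids <- sprintf("L%02d_%04d", c, k)
      locus_ids <- c(locus_ids, ids)
      chrom <- c(chrom, rep(sprintf("chr%d", c), length(k)))
      pos <- c(pos, (k - 1) * cfg$locus_spacing)
      block_of <- c(block_of, rep(b, length(k)))
      block_rows[[b]] <- ids
    }
  }
  m <- length(locus_ids)
  n <- cfg$n_disease
  r <- cfg$within_block_r
  lg2 <- withr::with_seed(derive_seed(cfg$seed, "cn"), {
    out <- matrix(0, m, n, dimnames = list(locus_ids, dis))
    for (blk in seq_len(b)) {
      rows <- block_rows[[blk]]
      g <- rnorm(n)
      eps <- matrix(rnorm(length(rows) * n), length(rows), n)
      out[rows, ] <- cfg$cna_sd *
        (sqrt(r) * matrix(g, length(rows), n, byrow = TRUE) + sqrt(1 - r) * eps)
    }
    out
  })
  event_samples <- withr::with_seed(derive_seed(cfg$seed, "events"), {
    lapply(cfg$signature_events, function(ev)
      sample(n, round(ev$fraction * n)))
  })
  for (i in seq_along(cfg$signature_events)) {
    ev <- cfg$signature_events[[i]]
    rows <- chrom == sprintf("chr%d", ev$chrom)
    lg2[rows, event_samples[[i]]] <- lg2[rows, event_samples[[i]]] +
      ev$sign * ev$magnitude
  }
  CN <- copy_number_matrix(2^lg2, chrom, pos)

  # --- pathways and annotation -----------------------------------------
  pw_names <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  sets <- lapply(seq_len(cfg$n_pathways), function(p)
    sprintf("g_pw%02d_%03d", p, seq_len(cfg$genes_per_pathway)))
  names(sets) <- pw_names
  pathways <- pathway_collection(sets, rep("synthetic pathway", cfg$n_pathways))
  bg <- if (cfg$n_background_genes > 0)
    sprintf("g_bg_%04d", seq_len(cfg$n_background_genes)) else character(0)
  genes <- c(unlist(sets, use.names = FALSE), bg)

  annotation <- withr::with_seed(derive_seed(cfg$seed, "annot"), {
    gchr <- sample(cfg$n_chromosomes, length(genes), replace = TRUE)
    span <- cfg$loci_per_chromosome * cfg$locus_spacing
    gstart <- floor(runif(length(genes), 0, span - 3e4))
    gene_annotation(genes, sprintf("chr%d", gchr), gstart, gstart + 3e4)
  })

  # --- expression -------------------------------------------------------
  reps <- vapply(block_rows, `[[`, "", 1L)  # block representative = first locus
  expr <- withr::with_seed(derive_seed(cfg$seed, "expr"), {
    base <- runif(length(genes), cfg$baseline_range[1], cfg$baseline_range[2])
    names(base) <- genes
    E <- matrix(rnorm(length(genes) * (cfg$n_disease + cfg$n_control),
                      sd = cfg$expression_noise_sd),
                length(genes), cfg$n_disease + cfg$n_control,
                dimnames = list(genes, c(dis, ctl)))
    E <- E + base
    for (pe in cfg$planted_effects) {
      x <- lg2[reps[pe$block], ]                     # log2 CNA, disease only
      rows <- sets[[pe$pathway]]
      E[rows, dis] <- E[rows, dis] +
        matrix(pe$beta * x, length(rows), cfg$n_disease, byrow = TRUE)
    }
    E[E < 0] <- 0
    E
  })
  labels <- c(rep("disease", cfg$n_disease), rep("control", cfg$n_control))
  names(labels) <- c(dis, ctl)

  truth <- list(
    blocks = data.frame(block = seq_len(b),
                        chrom = chrom[match(reps, locus_ids)],
                        representative = reps,
                        n_members = lengths(block_rows),
                        stringsAsFactors = FALSE),
    members = block_rows,
    planted = do.call(rbind, c(list(
      data.frame(block = integer(0), representative = character(0),
                 pathway = character(0), beta = numeric(0),
                 stringsAsFactors = FALSE)),
      lapply(cfg$planted_effects, function(pe)
        data.frame(block = as.integer(pe$block),
                   representative = reps[pe$block],
                   pathway = pw_names[pe$pathway], beta = pe$beta,
                   stringsAsFactors = FALSE)))))

  structure(list(expression = expression_matrix(expr, labels),
                 copy_number = CN, pathways = pathways,
                 annotation = annotation, truth = truth,
                 config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d genes x %d samples, %d loci, ",
                     "%d pathways, %d planted effect(s)\n"),
              nrow(x$expression$values), ncol(x$expression$values),
              nrow(x$copy_number$values), length(x$pathways),
              nrow(x$truth$planted)))
  invisible(x)
}

#' Write a synthetic dataset to disk in the package's file formats
#'
#' Emits expression TSV, labels TSV, copy-number TSV, pathway GMT, BED
#' annotation and a truth JSON into `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  labs <- dataset$expression$labels
  write.table(data.frame(sample_id = names(labs), label = labs),
              file.path(dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_copy_number(dataset$copy_number, file.path(dir, "copy_number.tsv"))
  write_gene_sets(dataset$pathways, file.path(dir, "pathways.gmt"))
  ann <- dataset$annotation
  write.table(ann[, c("chrom", "start", "end", "gene_id")],
              file.path(dir, "annotation.bed"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
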