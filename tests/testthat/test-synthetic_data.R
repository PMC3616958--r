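test_that("generation is deterministic and validates its config", {
  cfg <- null_config(seed = 3, n_disease = 20, n_pathways = 3)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  expect_error(synthetic_config(within_block_r = 1), "infeasible")
  expect_error(synthetic_config(planted_effects = list(list(block = 1e6, pathway = 1, beta = 1))),
               "out of range")
})

test_that("shapes, labels and truth are mutually consistent", {
  cfg <- synthetic_config(n_disease = 12, n_control = 5, n_chromosomes = 3,
                          loci_per_chromosome = 7, block_size = 3,
                          n_pathways = 4, genes_per_pathway = 6,
                          n_background_genes = 20, seed = 8)
  ds <- generate_dataset(cfg)
  expect_identical(dim(ds$expression$values), c(4L * 6L + 20L, 17L))
  expect_identical(dim(ds$copy_number$values), c(21L, 12L))
  expect_identical(sum(ds$expression$labels == "disease"), 12L)
  # copy-number samples are exactly the disease samples
  expect_setequal(colnames(ds$copy_number$values), samples_of(ds$expression, "disease"))
  # truth refers only to generated entities; blocks partition the loci
  expect_true(all(unlist(ds$truth$members) %in% rownames(ds$copy_number$values)))
  expect_identical(sort(unlist(ds$truth$members)), sort(rownames(ds$copy_number$values)))
  expect_true(all(ds$truth$planted$pathway %in% names(ds$pathways)))
  expect_true(all(ds$expression$values >= 0))
})

test_that("latent-factor calibration reaches the target adjacent correlation", {
  cfg <- synthetic_config(n_disease = 200, n_control = 5, n_chromosomes = 2,
                          loci_per_chromosome = 25, block_size = 5,
                          within_block_r = 0.99, n_pathways = 2,
                          genes_per_pathway = 5, n_background_genes = 10,
                          planted_effects = list(), signature_events = list(),
                          seed = 7)
  ds <- generate_dataset(cfg)
  l2 <- log2(ds$copy_number$values)
  rs <- unlist(lapply(ds$truth$members, function(m) {
    if (length(m) < 2) return(NULL)
    vapply(seq_len(length(m) - 1), function(i) cor(l2[m[i], ], l2[m[i + 1], ]), 0)
  }))
  expect_gte(mean(rs > 0.95), 0.95)
})

test_that("under the global null, disease and control expression agree in law", {
  cfg <- null_config(seed = 21, n_disease = 40, n_pathways = 4)
  ds <- generate_dataset(cfg)
  d <- as.vector(ds$expression$values[, samples_of(ds$expression, "disease")])
  c_ <- as.vector(ds$expression$values[, samples_of(ds$expression, "control")])
  expect_gt(suppressWarnings(ks.test(d, c_)$p.value), 0.01)
})

test_that("signature events raise the alteration frequency on their chromosome", {
  cfg <- synthetic_config(n_disease = 80, n_control = 5, n_chromosomes = 3,
                          loci_per_chromosome = 10, block_size = 1,
                          n_pathways = 2, genes_per_pathway = 5,
                          n_background_genes = 10, planted_effects = list(),
                          signature_events = list(
                            list(chrom = 1L, sign = 1L, fraction = 0.8, magnitude = 1.0),
                            list(chrom = 2L, sign = -1L, fraction = 0.8, magnitude = 1.0)),
                          seed = 5)
  ds <- generate_dataset(cfg)
  l2 <- log2(ds$copy_number$values)
  freq <- function(ch) mean(abs(l2[ds$copy_number$chrom == ch, ]) > 0.5)
  expect_gt(freq("chr1"), freq("chr3") + 0.3)   # amplification target
  expect_gt(freq("chr2"), freq("chr3") + 0.3)   # deletion target
  # directional: events push log2 values the stated way
  expect_gt(median(l2[ds$copy_number$chrom == "chr1", ]), 0)
  expect_lt(median(l2[ds$copy_number$chrom == "chr2", ]), 0)
})

test_that("planted effects couple pathway-gene expression to the block representative", {
  cfg <- synthetic_config(n_disease = 100, n_control = 10, n_chromosomes = 2,
                          loci_per_chromosome = 10, block_size = 5,
                          n_pathways = 3, genes_per_pathway = 10,
                          n_background_genes = 30,
                          planted_effects = list(list(block = 1L, pathway = 2L, beta = 1.0)),
                          signature_events = list(), seed = 13)
  ds <- generate_dataset(cfg)
  x <- log2(ds$copy_number$values[ds$truth$planted$representative, ])
  dis <- samples_of(ds$expression, "disease")
  planted_gene <- ds$pathways[[ds$truth$planted$pathway]][1]
  other_gene <- ds$pathways[["PW01"]][1]
  expect_gt(cor(ds$expression$values[planted_gene, dis], x), 0.5)
  expect_lt(abs(cor(ds$expression$values[other_gene, dis], x)), 0.4)
})

test_that("write_dataset emits readable artifacts", {
  cfg <- null_config(seed = 2, n_disease = 10, n_pathways = 2)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  E <- read_expression(file.path(dir, "expression.tsv"))
  expect_identical(E$values, ds$expression$values)
  CN <- read_copy_number(file.path(dir, "copy_number.tsv"))
  expect_identical(CN$values, ds$copy_number$values)
  pw <- read_gene_sets(file.path(dir, "pathways.gmt"))
  expect_identical(names(pw), names(ds$pathways))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_named(truth, c("blocks", "members", "planted"))
})
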