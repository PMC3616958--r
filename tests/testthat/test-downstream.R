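make_assoc <- function(locus, pathway, q, direction = NULL) {
  df <- data.frame(locus = locus, pathway = pathway,
                   ibar = 1, p = pmin(q, 1), q = q,
                   significant = q < 0.05, stringsAsFactors = FALSE)
  if (!is.null(direction)) df$direction <- direction
  structure(df, class = c("association_table", "data.frame"))
}

simple_tags <- function(tag_ids, chroms) {
  CN <- make_cn(matrix(rep(2^seq_along(tag_ids), 4), length(tag_ids), 4),
                chrom = chroms, pos = rep(0, length(tag_ids)), loci = tag_ids)
  structure(data.frame(tag_id = rownames(CN$values), chrom = CN$chrom,
                       span_start = 0, span_end = 100,
                       n_members = 1L, stringsAsFactors = FALSE),
            class = c("tag_locus_set", "data.frame"))
}

test_that("alteration frequency counts strict |log2 CNA| exceedances", {
  vals <- rbind(all_amp = rep(4, 10),                     # log2 = 2 > 1.5
                boundary = rep(2^1.5, 10),                # exactly 1.5 -> 0
                mixed = c(2^2, 2^-2, 2^2, rep(1, 7)))     # 3 of 10
  CN <- make_cn(vals, pos = c(0, 100, 200), loci = rownames(vals))
  tags <- detect_tag_loci(CN, r_threshold = 0.999)
  expect_warning(tags <- detect_tag_loci(CN, r_threshold = 0.999), "constant")
  af <- alteration_frequency(CN, tags)
  freq <- stats::setNames(af$frequency, af$tag_id)
  expect_equal(unname(freq["all_amp"]), 1)
  expect_equal(unname(freq["boundary"]), 0)
  expect_equal(unname(freq["mixed"]), 0.3)
  # invariant to sample order, monotone in the threshold
  CNp <- make_cn(vals[, c(5, 1, 9, 2, 3, 4, 10, 6, 7, 8)],
                 pos = c(0, 100, 200), loci = rownames(vals))
  expect_equal(alteration_frequency(CNp, tags)$frequency, af$frequency)
  af2 <- alteration_frequency(CN, tags, threshold = 2.5)
  expect_true(all(af2$frequency <= af$frequency))
})

test_that("pathway_counts counts distinct significant pathways per locus", {
  assoc <- make_assoc(locus = c("t1", "t1", "t1", "t2"),
                      pathway = c("P1", "P2", "P2", "P1"),
                      q = c(0.01, 0.02, 0.02, 0.9))
  pc <- pathway_counts(assoc)
  expect_identical(pc$n_pathways[pc$locus == "t1"], 2L)   # P2 deduplicated
  expect_identical(pc$n_pathways[pc$locus == "t2"], 0L)
  none <- make_assoc("t1", "P1", 0.9)
  expect_identical(pathway_counts(none)$n_pathways, 0L)
})

test_that("chromosome sharing is symmetric with dominant diagonal", {
  tags <- simple_tags(c("t1", "t2", "t3"), c("chr7", "chr10", "chr4"))
  assoc <- make_assoc(locus = c("t1", "t2"), pathway = c("P", "P"),
                      q = c(0.01, 0.01))
  m <- chromosome_sharing(assoc, tags)
  expect_identical(m["chr7", "chr10"], 1L)
  expect_identical(m["chr10", "chr7"], 1L)
  expect_identical(m["chr7", "chr7"], 1L)
  expect_identical(sum(m["chr4", ]), 0L)
  empty <- chromosome_sharing(make_assoc("t1", "P", 0.9), tags)
  expect_true(all(empty == 0L))

  # randomized property: symmetry and diagonal dominance
  set.seed(12)
  for (rep in 1:10) {
    n <- 30
    assoc <- make_assoc(locus = sample(c("t1", "t2", "t3"), n, TRUE),
                        pathway = sample(sprintf("P%d", 1:6), n, TRUE),
                        q = runif(n, 0, 0.1))
    m <- chromosome_sharing(assoc, tags)
    expect_identical(m, t(m))
    expect_true(all(diag(m) >= apply(m, 1, max)))
  }
  # direction column filters
  assoc_d <- make_assoc(c("t1", "t3"), c("P", "Q"), c(0.01, 0.01),
                        direction = c("over", "under"))
  m_over <- chromosome_sharing(assoc_d, tags, direction = "over")
  expect_identical(m_over["chr7", "chr7"], 1L)
  expect_identical(m_over["chr4", "chr4"], 0L)
})

test_that("driver enrichment equals the hypergeometric tail", {
  pw <- pathway_collection(list(big = sprintf("g%03d", 1:10),
                                none = sprintf("x%03d", 1:5),
                                all = sprintf("d%02d", 1:10)))
  universe <- c(sprintf("g%03d", 1:60), sprintf("x%03d", 1:5),
                sprintf("d%02d", 1:10), sprintf("u%03d", 1:25))
  drivers <- c(sprintf("g%03d", 1:5), sprintf("d%02d", 1:5))
  res <- driver_enrichment(pw, drivers, universe)
  for (k in seq_len(nrow(res)))
    expect_equal(res$p[k],
                 brute_hyper_tail(res$overlap[k], res$pathway_size[k],
                                  res$n_drivers[k], res$universe_size[k]))
  expect_true(all(diff(res$p) >= 0))                 # sorted ascending
  # no overlap -> p close to 1; worked closed-form example
  expect_equal(pathqtl:::.fisher_over_p(0, 5, 10, 100), 1)
  expect_equal(pathqtl:::.fisher_over_p(5, 10, 10, 100),
               brute_hyper_tail(5, 10, 10, 100))
  # degenerate: pathway = drivers = universe -> overlap forced, p = 1
  pw2 <- pathway_collection(list(d = c("a", "b")))
  res2 <- driver_enrichment(pw2, c("a", "b"), c("a", "b"))
  expect_equal(res2$p, 1)
  expect_error(driver_enrichment(pw2, "zz", c("a", "b")), "outside")
  expect_warning(driver_enrichment(pathway_collection(list(d = c("a", "b"), o = "q")),
                                   "a", c("a", "b")), "skipped")
})

test_that("differential expression matches t.test and handles degenerates", {
  set.seed(31)
  vals <- matrix(abs(rnorm(40, 6)), 5, 8)
  vals[1, ] <- c(1, 2, 3, 1.5, 4, 5, 6, 4.5)
  vals <- rbind(vals, flat = rep(3, 8))
  E <- make_expr(vals, 4, 4, genes = c(sprintf("g%d", 1:5), "flat"))
  de <- differential_expression(E)
  for (g in sprintf("g%d", 1:5)) {
    tt <- t.test(E$values[g, 1:4], E$values[g, 5:8])
    expect_equal(de$t[de$gene == g], unname(tt$statistic))
    expect_equal(de$p[de$gene == g], tt$p.value)
  }
  expect_identical(de$t[de$gene == "flat"], 0)
  expect_identical(de$p[de$gene == "flat"], 1)
  expect_true(de$degenerate[de$gene == "flat"])
  expect_equal(de$q, bh_fdr(de$p))
  # label swap negates t, keeps p
  E2 <- expression_matrix(E$values, ifelse(E$labels == "disease", "control", "disease"))
  de2 <- differential_expression(E2)
  expect_equal(de2$t, -de$t)
  expect_equal(de2$p, de$p)
  # pooled-variance flavor agrees with var.equal t.test
  dp <- differential_expression(E, var_equal = TRUE)
  ttp <- t.test(E$values["g1", 1:4], E$values["g1", 5:8], var.equal = TRUE)
  expect_equal(dp$t[dp$gene == "g1"], unname(ttp$statistic))
  expect_equal(dp$p[dp$gene == "g1"], ttp$p.value)
})
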