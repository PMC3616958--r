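test_that("signal-to-noise ranking matches the floored closed form", {
  # disease (4,4), control (2,2): sd floors 0.2*4=0.8 and 0.2*2=0.4
  vals <- rbind(gA = c(4, 4, 2, 2),
                gB = c(1, 3, 2, 2),     # equal class means -> metric 0
                gC = c(2, 2, 4, 4))     # mirrored -> negative metric
  E <- make_expr(vals, 2, 2, genes = rownames(vals))
  r <- rank_genes(E)
  expect_equal(r$metric[r$gene == "gA"], 2 / (0.8 + 0.4), tolerance = 5e-4)
  expect_identical(r$gene[1], "gA")
  expect_identical(r$gene[3], "gC")
  expect_equal(r$metric[r$gene == "gB"], 0)
  expect_true(all(diff(r$metric) <= 0))

  # swapping class labels negates every metric and reverses the order
  E2 <- expression_matrix(E$values, ifelse(E$labels == "disease", "control", "disease"))
  r2 <- rank_genes(E2)
  expect_equal(r2$metric[match(r$gene, r2$gene)], -r$metric)
  expect_identical(r2$gene, rev(r$gene))

  expect_error(rank_genes(make_expr(vals[, c(1, 3, 4)], 1, 2)), ">= 2 samples")
  vals0 <- rbind(vals, gZ = c(0, 0, 0, 0))
  expect_error(rank_genes(make_expr(vals0, 2, 2, genes = rownames(vals0))),
               "gZ")
})

test_that("enrichment score equals the brute-force running sum", {
  set.seed(42)
  for (rep in 1:40) {
    N <- sample(5:12, 1)
    ranked <- make_ranked(sort(round(rnorm(N), 2), decreasing = TRUE))
    size <- sample(1:4, 1)
    gene_set <- sample(ranked$gene, size)
    w <- sample(c(0, 1), 1)
    if (w == 1 && all(ranked$metric[ranked$gene %in% gene_set] == 0)) next
    es <- enrichment_score(ranked, gene_set, weight_exponent = w)
    oracle <- brute_es(ranked$metric, ranked$gene %in% gene_set, w)
    expect_equal(es$es, oracle$es)
    expect_equal(es$running_sum, oracle$running)
    expect_lte(abs(es$es), 1)
  }
})

test_that("enrichment score closed-form anchors and errors", {
  ranked <- make_ranked(c(3, 2, 1, 0, -1, -2))
  # single hit at rank 1, unweighted -> ES = 1
  es1 <- enrichment_score(ranked, ranked$gene[1], weight_exponent = 0)
  expect_equal(es1$es, 1)
  # single hit at rank N: running sum decreases to its minimum at rank N-1
  esN <- enrichment_score(ranked, ranked$gene[6], weight_exponent = 0)
  expect_equal(esN$es, -1)
  expect_identical(esN$argmin, 5L)
  expect_error(enrichment_score(ranked, "absent"), "empty intersection")
  expect_error(enrichment_score(ranked, ranked$gene), "whole ranked list")
  expect_error(enrichment_score(ranked, ranked$gene[4], weight_exponent = 1),
               "zero")
})

test_that("leading edge is the hits at or before/after the extremum", {
  # hits {2,5} of 6 with a heavy rank-2 weight: running sum peaks at rank 2,
  # so only the rank-2 hit is in the leading edge
  ranked <- make_ranked(c(3, 2.9, 0.5, 0.4, 0.1, 0.05))
  gene_set <- ranked$gene[c(2, 5)]
  es <- enrichment_score(ranked, gene_set, weight_exponent = 1)
  expect_gt(es$es, 0)
  expect_identical(es$argmax, 2L)
  le <- leading_edge(es, "P")
  expect_identical(le$sign, "over")
  expect_identical(le$genes, ranked$gene[2])

  # all hits before the argmax -> whole intersection
  es2 <- enrichment_score(ranked, ranked$gene[1:2], weight_exponent = 1)
  le2 <- leading_edge(es2)
  expect_setequal(le2$genes, ranked$gene[1:2])

  fake <- structure(list(es = 0), class = "es_result")
  expect_error(leading_edge(fake), "degenerate")
})

test_that("reversal symmetry: reversed, negated lists mirror ES and leading edge", {
  set.seed(7)
  for (rep in 1:25) {
    N <- sample(6:12, 1)
    metric <- sort(rnorm(N), decreasing = TRUE)
    ranked <- make_ranked(metric)
    gene_set <- sample(ranked$gene, sample(2:4, 1))
    rev_ranked <- structure(data.frame(gene = rev(ranked$gene),
                                       metric = rev(-ranked$metric),
                                       stringsAsFactors = FALSE),
                            class = c("ranked_genes", "data.frame"))
    es <- enrichment_score(ranked, gene_set, weight_exponent = 1)
    es_rev <- enrichment_score(rev_ranked, gene_set, weight_exponent = 1)
    # at an exact |max| == |min| tie the earliest-rank tie-break is not
    # reversal-invariant; symmetry is only claimed off ties
    if (abs(abs(es$running_sum[es$argmax]) - abs(es$running_sum[es$argmin])) < 1e-9) next
    expect_equal(es_rev$es, -es$es)
    if (es$es != 0) {
      le <- leading_edge(es)
      le_rev <- leading_edge(es_rev)
      expect_setequal(le$genes, le_rev$genes)
      expect_true(le$sign != le_rev$sign)
      # leading edge is a non-empty subset of the hits
      expect_true(all(le$genes %in% intersect(gene_set, ranked$gene)))
      expect_gt(length(le$genes), 0)
    }
  }
})

test_that("run_gsea classifies pathways by ES sign and skips degenerates", {
  set.seed(30)
  vals <- matrix(abs(rnorm(80, 7)), 20, 4)
  vals[1:5, 1:2] <- vals[1:5, 1:2] + 3        # disease-up block
  vals[6:10, 1:2] <- vals[6:10, 1:2] - 3      # disease-down block
  vals[vals < 0] <- 0
  E <- make_expr(vals, 2, 2)
  pw <- pathway_collection(list(up = rownames(E$values)[1:5],
                                down = rownames(E$values)[6:10],
                                ghost = c("nope1", "nope2")))
  expect_warning(g <- run_gsea(E, pw), "ghost")
  expect_identical(g$sign[g$pathway == "up"], "over")
  expect_identical(g$sign[g$pathway == "down"], "under")
  expect_true(all(lengths(g$leading_edge) == g$n_leading_edge))
})
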