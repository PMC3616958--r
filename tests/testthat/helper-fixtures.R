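# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (loops, exhaustive enumeration) and never call the code paths they
# check.

# small labelled expression matrix: genes x (disease, control) blocks
make_expr <- function(values, n_disease, n_control,
                      genes = sprintf("g%02d", seq_len(nrow(values)))) {
  samples <- c(sprintf("D%02d", seq_len(n_disease)),
               sprintf("C%02d", seq_len(n_control)))
  dimnames(values) <- list(genes, samples)
  labels <- c(rep("disease", n_disease), rep("control", n_control))
  expression_matrix(values, labels)
}

# ranked list container built directly (documented data frame contract)
make_ranked <- function(metric, genes = sprintf("g%02d", seq_along(metric))) {
  o <- order(-metric, genes)
  structure(data.frame(gene = genes[o], metric = metric[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_genes", "data.frame"))
}

make_cn <- function(values, chrom = rep("chr1", nrow(values)),
                    pos = (seq_len(nrow(values)) - 1) * 100,
                    loci = sprintf("L%02d", seq_len(nrow(values))),
                    samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(loci, samples)
  copy_number_matrix(values, chrom, pos)
}

# brute-force running-sum enrichment score (independent of cumsum path)
brute_es <- function(metric, is_hit, weight_exponent) {
  N <- length(metric)
  NH <- sum(is_hit)
  NR <- sum(abs(metric[is_hit])^weight_exponent)
  running <- numeric(N)
  s <- 0
  for (i in seq_len(N)) {
    s <- s + if (is_hit[i]) abs(metric[i])^weight_exponent / NR else -1 / (N - NH)
    running[i] <- s
  }
  best <- running[1]
  for (i in seq_len(N)) if (abs(running[i]) > abs(best)) best <- running[i]
  list(es = best, running = running)
}

# literal Benjamini-Hochberg step-up definition (double loop)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, ps[j] * m / j)
    q[i] <- min(cand, 1)
  }
  q[order(o)]
}

# exhaustive hypergeometric upper-tail sum via binomial coefficients
brute_hyper_tail <- function(overlap, pathway_size, n_drivers, universe_size) {
  lo <- max(0, n_drivers + pathway_size - universe_size)
  hi <- min(n_drivers, pathway_size)
  if (overlap > hi) return(0)
  ks <- max(overlap, lo):hi
  sum(choose(n_drivers, ks) * choose(universe_size - n_drivers, pathway_size - ks)) /
    choose(universe_size, pathway_size)
}

# two loci whose sample correlation on the log2 scale is exactly at (or one
# ulp below) `target`, after the 2^x / log2 round trip the detector performs
make_boundary_cn <- function(n = 24, target = 0.95, seed = 99) {
  set.seed(seed)
  x <- rnorm(n); z <- rnorm(n)
  xc <- x - mean(x)
  zc <- z - mean(z)
  zc <- zc - sum(zc * xc) / sum(xc^2) * xc
  xs <- xc / sqrt(sum(xc^2))
  zs <- zc / sqrt(sum(zc^2))
  mk <- function(a) {
    vals <- rbind(2^xs, 2^(a * xs + sqrt(1 - a^2) * zs))
    list(vals = vals, r = cor(log2(vals[1, ]), log2(vals[2, ])))
  }
  a <- target
  res <- mk(a)
  while (res$r > target) {
    a <- a - 1e-12
    res <- mk(a)
  }
  stopifnot(res$r > target - 1e-9)   # at the boundary, not merely below it
  make_cn(res$vals)
}

# global-null synthetic config used by the calibration-style tests
null_config <- function(seed, n_disease = 60, n_pathways = 20) {
  synthetic_config(n_disease = n_disease, n_control = 15,
                   n_chromosomes = 5, loci_per_chromosome = 10,
                   block_size = 1, within_block_r = 0.5,
                   n_pathways = n_pathways, genes_per_pathway = 25,
                   n_background_genes = 300,
                   planted_effects = list(), signature_events = list(),
                   seed = seed)
}
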