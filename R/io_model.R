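# Domain containers and readers/writers for the tabular formats the
# pipeline consumes: gene x sample expression (TSV), locus x sample copy
# number (TSV with coordinates), GMT gene sets, BED-like gene annotation
# and plain driver-gene lists. Coordinates are 0-based half-open
# throughout; 1-based tabular annotation must be declared explicitly.

# Constructors -----------------------------------------------------------

#' Expression matrix with sample class labels
#'
#' Container for nonnegative, log-scale expression intensities
#' \eqn{E_{i,j}} (genes x samples) with an optional per-sample class label
#' (`"disease"` or `"control"`).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be finite
#'   and `>= 0` (log-scale intensities; zeros encode censored weak signal).
#' @param labels optional character vector of `"disease"`/`"control"`, one
#'   per column (named by sample id or positionally aligned). When present,
#'   both classes must be represented.
#' @return an object of class `expr_matrix` with elements `values` and
#'   `labels`.
#' @export
expression_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    .stopf("duplicate gene ids: %s",
           paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    .stopf("duplicate sample ids")
  if (any(!is.finite(values)) || any(values < 0))
    .stopf("expression values must be finite and >= 0")
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      missing <- setdiff(colnames(values), names(labels))
      if (length(missing))
        .stopf("labels missing for samples: %s", paste(missing, collapse = ", "))
      unknown <- setdiff(names(labels), colnames(values))
      if (length(unknown))
        .stopf("labels given for unknown samples: %s", paste(unknown, collapse = ", "))
      labels <- labels[colnames(values)]
    } else if (length(labels) != ncol(values)) {
      .stopf("labels length (%d) != number of samples (%d)",
             length(labels), ncol(values))
    } else {
      names(labels) <- colnames(values)
    }
    if (!all(labels %in% c("disease", "control")))
      .stopf("labels must be 'disease' or 'control'")
    if (!all(c("disease", "control") %in% labels))
      .stopf("need at least one disease and one control sample")
  }
  structure(list(values = values, labels = labels), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples", nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels))
    cat(sprintf(" (%d disease, %d control)",
                sum(x$labels == "disease"), sum(x$labels == "control")))
  cat("\n")
  invisible(x)
}

#' Sample ids of one class
#' @param E an `expr_matrix` with labels.
#' @param class `"disease"` or `"control"`.
#' @return character vector of sample ids.
#' @export
samples_of <- function(E, class = c("disease", "control")) {
  class <- match.arg(class)
  if (is.null(E$labels)) .stopf("expression matrix has no labels")
  names(E$labels)[E$labels == class]
}

#' Copy-number matrix with genomic coordinates
#'
#' Locus x sample copy-number ratios (1.0 = diploid-normal), kept sorted by
#' (chromosome, position). Values are strictly positive; the log2 transform
#' is applied downstream at modeling time.
#'
#' @param values numeric matrix, loci in rows (rownames = locus ids),
#'   samples in columns; all values finite and `> 0`.
#' @param chrom character vector of chromosome names, one per locus.
#' @param pos numeric vector of 0-based positions (bp), one per locus.
#' @return an object of class `cn_matrix` with elements `values`, `chrom`,
#'   `pos`.
#' @export
copy_number_matrix <- function(values, chrom, pos) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("copy-number values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("copy-number matrix needs locus rownames and sample colnames")
  if (anyDuplicated(rownames(values))) .stopf("duplicate locus ids")
  if (length(chrom) != nrow(values) || length(pos) != nrow(values))
    .stopf("chrom/pos must have one entry per locus")
  if (any(!is.finite(values)) || any(values <= 0))
    .stopf("copy-number values must be finite and > 0; use clamp_epsilon when reading")
  chrom <- as.character(chrom)
  o <- order(chrom, pos)
  if (!identical(o, seq_along(o))) {
    .warnf("loci not sorted by (chromosome, position); sorting")
    values <- values[o, , drop = FALSE]
    chrom <- chrom[o]
    pos <- pos[o]
  }
  structure(list(values = values, chrom = chrom, pos = pos), class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("<cn_matrix> %d loci x %d samples on %d chromosome(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$chrom))))
  invisible(x)
}

#' Collection of named gene sets (pathways)
#'
#' @param sets named list of character vectors of member gene ids; names are
#'   pathway names (unique), sets are non-empty, members unique within a set.
#' @param descriptions optional character vector of descriptions, recycled
#'   or named by pathway.
#' @return an object of class `pathway_collection` (a named list with a
#'   `descriptions` attribute).
#' @export
pathway_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    .stopf("sets must be a named list")
  if (anyDuplicated(names(sets)))
    .stopf("duplicate pathway name: %s",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  for (nm in names(sets)) {
    if (!length(sets[[nm]])) .stopf("pathway '%s' is empty", nm)
    if (anyDuplicated(sets[[nm]])) .stopf("pathway '%s' has duplicate genes", nm)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, median size %g\n",
              length(x), stats::median(lengths(x))))
  invisible(x)
}

#' Gene annotation table
#'
#' @param gene_id,chrom,start,end vectors describing one interval per gene;
#'   coordinates 0-based half-open, `start < end`.
#' @return a `data.frame` with columns gene_id, chrom, start, end.
#' @export
gene_annotation <- function(gene_id, chrom, start, end) {
  ann <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    stringsAsFactors = FALSE)
  if (any(ann$start >= ann$end)) .stopf("annotation requires start < end")
  if (anyDuplicated(ann)) .stopf("duplicate (gene, location) records")
  ann
}

# Readers / writers ------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' One pathway per line: name, description, then member genes, all
#' tab-separated. Duplicate genes within a set are removed with a warning;
#' duplicate pathway names are an error.
#'
#' @param path path to a GMT file.
#' @return a [pathway_collection()].
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .stopf("no gene sets in '%s'", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    .stopf("malformed GMT line %d in '%s': fewer than 3 fields", bad[1], path)
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    .stopf("duplicate pathway name in '%s': %s", path,
           paste(unique(nms[duplicated(nms)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes
  })
  names(sets) <- nms
  ndup <- sum(vapply(sets, anyDuplicated, 0L) > 0)
  if (ndup > 0) {
    .warnf("%d gene set(s) contained duplicate genes; deduplicated", ndup)
    sets <- lapply(sets, unique)
  }
  pathway_collection(sets, desc)
}

#' Write gene sets to a GMT file
#' @param pathways a [pathway_collection()].
#' @param path output path.
#' @export
write_gene_sets <- function(pathways, path) {
  desc <- attr(pathways, "descriptions")
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, desc[[nm]], pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# full-precision numeric formatting for TSV round-trips
.fmt_num <- function(x) sprintf("%.17g", x)

.write_matrix_tsv <- function(values, path, id_col, extra = NULL) {
  body <- matrix(.fmt_num(values), nrow = nrow(values))
  df <- data.frame(rownames(values), stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- id_col
  if (!is.null(extra)) df <- cbind(df, extra, stringsAsFactors = FALSE)
  colnames(body) <- colnames(values)
  df <- cbind(df, as.data.frame(body, stringsAsFactors = FALSE, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.parse_numeric_body <- function(raw, path, what) {
  mat <- as.matrix(raw)
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  bad <- which(is.na(num) & !(mat %in% c("NA")), arr.ind = TRUE)
  if (nrow(bad))
    .stopf("non-numeric %s value '%s' at row %d, column %d of '%s'",
           what, mat[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], path)
  if (anyNA(num)) .stopf("missing %s values in '%s'", what, path)
  dimnames(num) <- dimnames(mat)
  num
}

#' Read a gene x sample expression TSV
#'
#' The file has a header of sample ids and gene ids in the first column.
#' Row and column order is preserved.
#'
#' @param path path to the TSV.
#' @param labels optional named character vector mapping sample id to
#'   `"disease"`/`"control"`; an entry for an unknown sample is an error.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, labels = NULL) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) .stopf("'%s' has no sample columns", path)
  if (nrow(raw) == 0) .stopf("no genes in '%s'", path)
  ids <- raw[[1]]
  vals <- .parse_numeric_body(raw[, -1, drop = FALSE], path, "expression")
  rownames(vals) <- ids
  expression_matrix(vals, labels = labels)
}

#' Write an expression matrix to TSV (full precision)
#' @param E an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(E, path) {
  .write_matrix_tsv(E$values, path, "gene_id")
}

#' Read a locus x sample copy-number TSV
#'
#' Expected columns: `locus_id`, `chrom`, `pos`, then one column per sample.
#' Loci are sorted by (chromosome, position) with a warning if the file was
#' unsorted. Values must be strictly positive ratios (1.0 = diploid);
#' non-positive values are an error unless `clamp_epsilon` is given, in
#' which case they are clamped to it with a warning (log2 is applied
#' downstream, so zeros cannot be represented).
#'
#' @param path path to the TSV.
#' @param clamp_epsilon optional positive value replacing entries `<= 0`.
#' @return a [copy_number_matrix()].
#' @export
read_copy_number <- function(path, clamp_epsilon = NULL) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("locus_id", "chrom", "pos")
  if (!all(need %in% colnames(raw)[1:3]))
    .stopf("'%s' must start with columns locus_id, chrom, pos", path)
  if (ncol(raw) < 4) .stopf("'%s' has no sample columns", path)
  vals <- .parse_numeric_body(raw[, -(1:3), drop = FALSE], path, "copy-number")
  rownames(vals) <- raw$locus_id
  if (any(vals <= 0)) {
    if (is.null(clamp_epsilon))
      .stopf(paste0("copy-number values <= 0 in '%s'; pass clamp_epsilon ",
                    "(e.g. 1e-6) to clamp them for the log2 transform"), path)
    .warnf("%d copy-number value(s) <= 0 clamped to %g", sum(vals <= 0), clamp_epsilon)
    vals[vals <= 0] <- clamp_epsilon
  }
  copy_number_matrix(vals, raw$chrom, as.numeric(raw$pos))
}

#' Write a copy-number matrix to TSV (full precision)
#' @param CN a [copy_number_matrix()].
#' @param path output path.
#' @export
write_copy_number <- function(CN, path) {
  .write_matrix_tsv(CN$values, path, "locus_id",
                    extra = data.frame(chrom = CN$chrom, pos = .fmt_num(CN$pos),
                                       stringsAsFactors = FALSE))
}

#' Read gene annotation (BED or 1-based TSV)
#'
#' BED input (`format = "bed"`, no header: chrom, start, end, name) is taken
#' as-is (0-based half-open). A headered 1-based inclusive table
#' (`format = "tsv1"`, columns gene_id, chrom, start, end) is converted to
#' 0-based half-open.
#'
#' @param path input path.
#' @param format `"bed"` or `"tsv1"`.
#' @return a [gene_annotation()] data frame.
#' @export
read_annotation <- function(path, format = c("bed", "tsv1")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- read.delim(path, header = FALSE, colClasses = "character")
    if (ncol(df) < 4) .stopf("BED file '%s' needs at least 4 columns", path)
    gene_annotation(df[[4]], df[[1]], as.numeric(df[[2]]), as.numeric(df[[3]]))
  } else {
    df <- read.delim(path, colClasses = "character")
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% colnames(df)))
      .stopf("'%s' must have columns gene_id, chrom, start, end", path)
    gene_annotation(df$gene_id, df$chrom,
                    as.numeric(df$start) - 1, as.numeric(df$end))
  }
}

#' Read a plain one-gene-per-line driver list
#' @param path input path; blank lines and `#` comments are skipped.
#' @return character vector of unique gene ids.
#' @export
read_driver_genes <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

# Expression preprocessing ----------------------------------------------

#' Remove weak-signal genes
#'
#' Drops every row whose fraction of zero (log-transformed) values is
#' strictly greater than `max_zero_frac`; remaining rows keep their order.
#' Zeros encode censored weak probe signal, so rows dominated by them carry
#' no usable intensity information.
#'
#' @param E an [expression_matrix()].
#' @param max_zero_frac maximum tolerated zero fraction (default 0.10;
#'   a row at exactly the threshold is retained).
#' @return the filtered [expression_matrix()].
#' @export
filter_low_signal <- function(E, max_zero_frac = 0.10) {
  stopifnot(inherits(E, "expr_matrix"))
  frac0 <- rowMeans(E$values == 0)
  keep <- frac0 <= max_zero_frac
  if (!any(keep)) .stopf("empty matrix after filtering")
  expression_matrix(E$values[keep, , drop = FALSE], labels = E$labels)
}

#' Collapse probesets to genes
#'
#' For each gene, keeps the probe row with the highest mean intensity over
#' the disease samples (over all samples if no labels); ties are broken by
#' the lexicographically smallest probe id.
#'
#' @param E an [expression_matrix()] whose rows are probe ids.
#' @param probe_gene_map named character vector: names are probe ids,
#'   values are gene ids. Every row of `E` must be mapped.
#' @return an [expression_matrix()] with one row per gene.
#' @export
collapse_probesets <- function(E, probe_gene_map) {
  stopifnot(inherits(E, "expr_matrix"))
  probes <- rownames(E$values)
  unmapped <- setdiff(probes, names(probe_gene_map))
  if (length(unmapped))
    .stopf("unmapped probes: %s", paste(unmapped, collapse = ", "))
  cols <- if (!is.null(E$labels)) samples_of(E, "disease") else colnames(E$values)
  mean_int <- rowMeans(E$values[, cols, drop = FALSE])
  genes <- probe_gene_map[probes]
  chosen <- vapply(split(probes, genes)[unique(genes)], function(ps) {
    best <- ps[mean_int[ps] == max(mean_int[ps])]
    sort(best)[1]
  }, "")
  out <- E$values[chosen, , drop = FALSE]
  rownames(out) <- names(chosen)
  expression_matrix(out, labels = E$labels)
}
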