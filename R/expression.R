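#' Construct an expression study
#'
#' An `expression_study` bundles a nonnegative genes-by-samples value matrix
#' with per-sample design metadata (line, donor, condition, day, replicate)
#' and a scale tag. It is the universal input of the pipeline: the simulator
#' emits one, the factorization consumes one, and projections match two of
#' them on their shared gene space.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be finite
#'   and nonnegative; integral when `scale = "counts"`.
#' @param samples Data frame with one row per matrix column, containing at
#'   least `sample_id`, `line_id`, `donor_id`, `condition`, `day`,
#'   `replicate`. Rows are re-ordered to match the matrix columns.
#' @param scale One of `"counts"`, `"rpkm"`, `"log2rpkm"`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, samples, scale = c("rpkm", "counts", "log2rpkm")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (is.null(colnames(values)) && ncol(values) > 0) {
    stop("values must have sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (!is.numeric(values) || any(!is.finite(values))) stop("values must be finite numeric")
  if (any(values < 0)) stop("values must be nonnegative")
  if (scale == "counts" && any(abs(values - round(values)) > 1e-8)) {
    stop("scale = 'counts' requires integral values")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "line_id", "donor_id", "condition", "day", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata")
  absent <- setdiff(colnames(values), samples$sample_id)
  if (length(absent)) {
    stop("samples present in matrix but absent from metadata: ", paste(absent, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  # line -> donor mapping must be a function
  map <- unique(samples[, c("line_id", "donor_id")])
  if (anyDuplicated(map$line_id)) stop("inconsistent line -> donor mapping in metadata")
  structure(list(values = values, samples = samples, scale = scale),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  lines: %s\n", paste(unique(x$samples$line_id), collapse = ", ")))
  cat(sprintf("  conditions: %s | days: %s\n",
              paste(unique(x$samples$condition), collapse = ", "),
              paste(sort(unique(x$samples$day)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Read an expression study from TSV files
#'
#' The expression file has a gene-id first column and one numeric column per
#' sample; the metadata file is keyed by `sample_id`. Samples present in the
#' matrix but missing from the metadata are an error (named in the message);
#' extra metadata rows are dropped.
#'
#' @param path Expression TSV (gene ids in the first column).
#' @param metadata_path Sample metadata TSV.
#' @param scale Scale tag to attach (the file does not carry one).
#' @return An `expression_study`.
#' @export
read_expression <- function(path, metadata_path, scale = "rpkm") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric expression cells in columns: ",
                      paste(names(vals)[!num], collapse = ", "))
  values <- as.matrix(vals)
  rownames(values) <- gene_ids
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  expression_study(values, meta, scale = scale)
}

#' Write an expression study to TSV files
#'
#' Values are written at full double precision (round-trips exactly through
#' [read_expression()]).
#'
#' @param study An `expression_study`.
#' @param path Output expression TSV.
#' @param metadata_path Output metadata TSV (omitted when `NULL`).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(study, path, metadata_path = NULL) {
  df <- data.frame(gene_id = rownames(study$values),
                   study$values, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_full(df, path)
  if (!is.null(metadata_path)) write_tsv_full(study$samples, metadata_path)
  invisible(path)
}

# full-precision deterministic TSV writer shared by all output paths
write_tsv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' RPKM-normalize a count study
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm[g, s] = counts[g, s] / (length_kb[g] * mapped_millions[s])`, with the
#' library size of sample `s` taken as the column sum of the supplied count
#' matrix divided by 1e6.
#'
#' @param study An `expression_study` on the `counts` scale.
#' @param gene_lengths Named numeric vector of transcript lengths in bases;
#'   must cover every gene.
#' @return The study on the `rpkm` scale.
#' @export
rpkm_normalize <- function(study, gene_lengths) {
  stopifnot(inherits(study, "expression_study"))
  if (study$scale != "counts") stop("rpkm_normalize requires scale = 'counts'")
  g <- rownames(study$values)
  miss <- setdiff(g, names(gene_lengths))
  if (length(miss)) stop("missing gene lengths for: ", paste(utils::head(miss, 5), collapse = ", "))
  len <- as.numeric(gene_lengths[g])
  if (any(!is.finite(len)) || any(len <= 0)) stop("gene lengths must be positive")
  libsize <- colSums(study$values)
  if (any(libsize == 0)) stop("zero column sum in sample(s): ",
                              paste(colnames(study$values)[libsize == 0], collapse = ", "))
  rpkm <- study$values / (len / 1e3) # per kilobase
  rpkm <- sweep(rpkm, 2, libsize / 1e6, "/")
  expression_study(rpkm, study$samples, scale = "rpkm")
}

#' Log2 transform with pseudocount
#'
#' @param study An `expression_study` with nonnegative values.
#' @param pseudocount Added before the log; default 1.
#' @return The study with `value -> log2(value + pseudocount)` and scale
#'   `log2rpkm`.
#' @export
log_transform <- function(study, pseudocount = 1) {
  stopifnot(inherits(study, "expression_study"))
  if (any(study$values < 0)) stop("log_transform requires nonnegative values")
  expression_study(log2(study$values + pseudocount), study$samples, scale = "log2rpkm")
}

#' Restrict two studies to their shared gene space
#'
#' Matching is by exact, case-sensitive identifier. Both outputs carry the
#' intersection in the same order (order of appearance in `a`).
#'
#' @param a,b `expression_study` objects.
#' @return List with elements `a`, `b` (restricted studies) and
#'   `n_shared` (intersection size).
#' @export
match_genes <- function(a, b) {
  stopifnot(inherits(a, "expression_study"), inherits(b, "expression_study"))
  shared <- intersect(rownames(a$values), rownames(b$values))
  if (length(shared) == 0) stop("empty gene intersection between studies")
  list(a = expression_study(a$values[shared, , drop = FALSE], a$samples, a$scale),
       b = expression_study(b$values[shared, , drop = FALSE], b$samples, b$scale),
       n_shared = length(shared))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description strings.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, genes) paste(c(nm, d, genes), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a square labeled kinship matrix from TSV
#'
#' @param path TSV with row and column labels (first column = row labels).
#' @return Symmetric numeric matrix with unit diagonal checked.
#' @export
read_kinship <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("kinship matrix must be square with matching labels")
  }
  if (max(abs(m - t(m))) > 1e-8) stop("kinship matrix must be symmetric")
  m
}

#' Write a kinship matrix to TSV
#'
#' @param kinship Square labeled symmetric matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_kinship <- function(kinship, path) {
  df <- data.frame(id = rownames(kinship), kinship, check.names = FALSE)
  write_tsv_full(df, path)
}

#' Read per-gene annotations (evolutionary era, pHaplo, set labels)
#'
#' @param path TSV with columns `gene_id` and any of `era` (integer 1-5),
#'   `phaplo` (in `[0,1]`).
#' @return Data frame of annotations, validated.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(ann)) stop("annotation file needs a gene_id column")
  if ("era" %in% names(ann)) {
    ok <- is.na(ann$era) | (ann$era %in% 1:5)
    if (!all(ok)) stop("era values must be integers in 1..5")
  }
  if ("phaplo" %in% names(ann)) {
    ok <- is.na(ann$phaplo) | (ann$phaplo >= 0 & ann$phaplo <= 1)
    if (!all(ok)) stop("phaplo values must lie in [0, 1]")
  }
  ann
}
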