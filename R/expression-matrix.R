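#' Validate a feature-by-sample expression matrix
#'
#' An expression matrix in this package is a plain numeric matrix with unique
#' feature identifiers as rownames and unique sample identifiers as colnames,
#' holding finite, non-negative FPKM-like values. The same container is used
#' for isoform-, gene- and protein-level data.
#'
#' @param x numeric matrix, features in rows, samples in columns.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (features x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry feature rownames and sample colnames")
  dup_f <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(unique(dup_s), collapse = ", "))
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf(
      "expression values must be finite and >= 0; first offending entry at feature '%s', sample '%s' (value %s)",
      rownames(x)[i], colnames(x)[j], format(x[bad[1L]])))
  }
  invisible(x)
}

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of sample ids and feature ids in the first column.
#' Gzip-compressed files are read transparently.
#'
#' @param path path to a TSV (or other delimited) file; `.gz` accepted.
#' @param sep field delimiter, tab by default.
#' @return validated numeric matrix (features x samples).
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("expression file needs a feature-id column plus >= 1 sample column")
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
      stop(sprintf("non-numeric expression value at feature '%s', sample '%s'",
                   ids[bad], colnames(body)[j]))
    }
  }
  x <- as.matrix(body)
  rownames(x) <- ids
  validate_expression(x)
  x
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: header row of sample ids, feature ids in
#' the first column (named `feature_id`). Values are formatted with
#' `signif(digits)` so a write/read round trip is lossless up to that
#' precision.
#'
#' @param x validated expression matrix.
#' @param path output path; a `.gz` suffix writes gzip.
#' @param digits significant digits kept in the text representation.
#' @export
write_expression <- function(x, path, digits = 6) {
  validate_expression(x)
  df <- data.frame(feature_id = rownames(x), signif(x, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a transcript annotation table
#'
#' TSV with columns `isoform_id`, `gene_id`, `is_coding` (0/1 or
#' logical), `length_nt`.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with those four columns, `is_coding` logical.
#' @export
read_transcript_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_transcript_annotation(ann)
}

#' @rdname read_transcript_annotation
#' @param ann data.frame to validate in place of a file.
#' @export
validate_transcript_annotation <- function(ann) {
  need <- c("isoform_id", "gene_id", "is_coding", "length_nt")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  dup <- ann$isoform_id[duplicated(ann$isoform_id)]
  if (length(dup)) stop("duplicate isoform ids in annotation: ",
                        paste(unique(dup), collapse = ", "))
  ann$is_coding <- as.logical(ann$is_coding)
  if (anyNA(ann$is_coding)) stop("is_coding must be 0/1 or logical")
  if (any(!is.finite(ann$length_nt) | ann$length_nt < 1))
    stop("length_nt must be >= 1")
  ann
}

#' Read a sample annotation table
#'
#' TSV with columns `sample_id`, `subtype`, `split` (split values
#' `discovery` / `validation`).
#'
#' @param path path to the sample annotation TSV.
#' @return data.frame with those three columns.
#' @export
read_sample_annotation <- function(path) {
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_annotation(s)
}

#' @rdname read_sample_annotation
#' @param s data.frame to validate in place of a file.
#' @export
validate_sample_annotation <- function(s) {
  need <- c("sample_id", "subtype", "split")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("sample annotation missing columns: ",
                         paste(miss, collapse = ", "))
  dup <- s$sample_id[duplicated(s$sample_id)]
  if (length(dup)) stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(s$split), c("discovery", "validation"))
  if (length(bad)) stop("split must be 'discovery' or 'validation'; found: ",
                        paste(bad, collapse = ", "))
  s
}

# align an expression matrix with a sample annotation restricted to one split;
# returns list(x, subtype factor) in matching order
align_split <- function(x, samples, split = "discovery") {
  validate_expression(x)
  samples <- validate_sample_annotation(samples)
  keep <- samples[samples$split == split, , drop = FALSE]
  missing <- setdiff(keep$sample_id, colnames(x))
  if (length(missing)) stop("samples annotated but absent from matrix: ",
                            paste(missing, collapse = ", "))
  xs <- x[, keep$sample_id, drop = FALSE]
  list(x = xs, subtype = factor(keep$subtype))
}
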