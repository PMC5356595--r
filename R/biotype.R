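#' Classify transcripts into mRNA / lncRNA / small ncRNA biotypes
#'
#' Coding transcripts are mRNA regardless of length. Non-coding transcripts
#' longer than 200 nt are long non-coding RNA; non-coding transcripts of at
#' most 200 nt are small ncRNA (miRNA hosts, snoRNA, ...). The three classes
#' partition any valid annotation set.
#'
#' @param ann transcript annotation data.frame
#'   (see [read_transcript_annotation()]).
#' @return factor with levels `mRNA`, `lncRNA`, `small_ncRNA`, one per row.
#' @export
classify_biotype <- function(ann) {
  ann <- validate_transcript_annotation(ann)
  out <- ifelse(ann$is_coding, "mRNA",
                ifelse(ann$length_nt > 200, "lncRNA", "small_ncRNA"))
  factor(out, levels = c("mRNA", "lncRNA", "small_ncRNA"))
}

#' Aggregate isoform expression to gene level
#'
#' Gene-level FPKM is the per-sample sum of the gene's isoform rows, so total
#' expression per sample is conserved exactly.
#'
#' @param x isoform-level expression matrix.
#' @param ann transcript annotation covering every feature of `x`.
#' @return gene-by-sample expression matrix; genes ordered by first
#'   appearance of their isoforms in `x`, sample order preserved.
#' @export
aggregate_gene_level <- function(x, ann) {
  validate_expression(x)
  ann <- validate_transcript_annotation(ann)
  miss <- setdiff(rownames(x), ann$isoform_id)
  if (length(miss)) stop("isoforms without annotation: ", paste(miss, collapse = ", "))
  gene <- ann$gene_id[match(rownames(x), ann$isoform_id)]
  glev <- unique(gene)
  g <- rowsum(x, group = factor(gene, levels = glev), reorder = FALSE)
  validate_expression(g)
  g
}

#' Flag outlier samples in principal-component space
#'
#' A reproducible stand-in for visual PCA outlier screening: samples are
#' log2(x + 1)-transformed, projected on the top principal components, and a
#' sample is flagged when on any retained component its score lies more than
#' `mad_multiplier` MADs from that component's median. Off the default
#' pipeline path; opt in explicitly.
#'
#' @param x expression matrix (features x samples).
#' @param n_components number of leading components examined (default 2).
#' @param mad_multiplier flag threshold k in `|score - median| > k * MAD`
#'   (default 6).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_pca_outliers <- function(x, n_components = 2, mad_multiplier = 6) {
  validate_expression(x)
  if (ncol(x) < 3L) stop("need at least 3 samples for PCA screening")
  if (ncol(x) <= n_components)
    stop("fewer samples (", ncol(x), ") than requested components + 1")
  lx <- t(log2(x + 1))
  keep <- apply(lx, 2L, stats::var) > 0
  if (!any(keep)) return(character(0))
  pc <- stats::prcomp(lx[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  flagged <- rep(FALSE, ncol(x))
  for (j in seq_len(k)) {
    s <- pc$x[, j]
    m <- stats::mad(s)
    if (m > 0) flagged <- flagged | abs(s - stats::median(s)) > mad_multiplier * m
  }
  colnames(x)[flagged]
}
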