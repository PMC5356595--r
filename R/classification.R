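#' Rank-based AUC of a single marker
#'
#' Area under the ROC curve via the rank-sum (Mann-Whitney) formulation with
#' midrank handling of ties: the probability that a random positive scores
#' above a random negative, counting ties as 1/2. Identical to the ROC area
#' of any monotone single-feature classifier, so no per-feature model fit is
#' needed.
#'
#' @param values numeric scores (e.g. expression of one feature).
#' @param positive logical (or 0/1) vector marking the positive class.
#' @return AUC in `[0, 1]`.
#' @export
marker_auc <- function(values, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  r <- rank(values)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest AUC table for every feature and subtype
#'
#' @param x expression matrix over all samples.
#' @param samples sample annotation with discovery/validation split.
#' @param level label recorded in the output (`"isoform"` or `"gene"`).
#' @return data.frame: `feature_id`, `target_subtype`, `auc_discovery`,
#'   `auc_validation`, `level`.
#' @export
marker_auc_table <- function(x, samples, level = "isoform") {
  disc <- align_split(x, samples, "discovery")
  vali <- align_split(x, samples, "validation")
  subtypes <- levels(disc$subtype)
  out <- vector("list", length(subtypes))
  for (i in seq_along(subtypes)) {
    pos_d <- disc$subtype == subtypes[i]
    pos_v <- vali$subtype == subtypes[i]
    out[[i]] <- data.frame(
      feature_id = rownames(x),
      target_subtype = subtypes[i],
      auc_discovery = apply(disc$x, 1L, marker_auc, positive = pos_d),
      auc_validation = apply(vali$x, 1L, marker_auc, positive = pos_v),
      level = level, row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare isoform-level against gene-level discrimination
#'
#' For every isoform and target subtype, `delta = isoform AUC - AUC of its
#' gene` (gene-level expression being the sum of the gene's isoforms).
#' A positive delta means the isoform separates the subtype better than its
#' whole gene.
#'
#' @param iso_auc isoform-level table from [marker_auc_table()].
#' @param gene_auc gene-level table from [marker_auc_table()] on the
#'   aggregated matrix.
#' @param ann transcript annotation mapping isoforms to genes.
#' @param split which AUC column to compare (`"discovery"` default).
#' @return data.frame `feature_id`, `gene_id`, `target_subtype`,
#'   `auc_isoform`, `auc_gene`, `delta`; attribute `fraction_better` gives
#'   the fraction of positive deltas.
#' @export
compare_isoform_gene_auc <- function(iso_auc, gene_auc, ann,
                                     split = c("discovery", "validation")) {
  split <- match.arg(split)
  col <- paste0("auc_", split)
  ann <- validate_transcript_annotation(ann)
  gene <- ann$gene_id[match(iso_auc$feature_id, ann$isoform_id)]
  if (anyNA(gene))
    stop("isoforms without gene mapping: ",
         paste(utils::head(iso_auc$feature_id[is.na(gene)]), collapse = ", "))
  key_i <- paste(gene, iso_auc$target_subtype)
  key_g <- paste(gene_auc$feature_id, gene_auc$target_subtype)
  m <- match(key_i, key_g)
  if (anyNA(m))
    stop("genes without a gene-level AUC: ",
         paste(utils::head(unique(gene[is.na(m)])), collapse = ", "))
  out <- data.frame(feature_id = iso_auc$feature_id, gene_id = gene,
                    target_subtype = iso_auc$target_subtype,
                    auc_isoform = iso_auc[[col]],
                    auc_gene = gene_auc[[col]][m],
                    stringsAsFactors = FALSE)
  out$delta <- out$auc_isoform - out$auc_gene
  attr(out, "fraction_better") <- mean(out$delta > 0)
  out
}

# log2(x+1) then center/scale each feature by its discovery statistics
panel_transform <- function(xt, center = NULL, scale = NULL) {
  z <- log2(xt + 1)
  if (is.null(center)) center <- colMeans(z)
  z <- sweep(z, 2, center, "-")
  if (is.null(scale)) {
    scale <- sqrt(colMeans(z^2))
    scale[scale == 0] <- 1
  }
  list(z = sweep(z, 2, scale, "/"), center = center, scale = scale)
}

#' L1-penalized logistic marker panel for a two-class separation
#'
#' Selects a sparse panel distinguishing two subtypes (e.g. Luminal A vs B)
#' by lasso logistic regression on log2(x+1)-standardized features. The
#' penalty is chosen by stratified cross-validated binomial deviance on the
#' discovery samples; selected features are ordered by decreasing absolute
#' standardized coefficient.
#'
#' @param x expression matrix restricted to discovery samples of the two
#'   classes (features x samples).
#' @param labels vector with exactly two distinct values, one per column.
#' @param penalty_grid optional decreasing lambda sequence; `NULL` lets
#'   glmnet build its own path.
#' @param nfolds stratified CV folds (default 5).
#' @param seed integer governing the fold assignment.
#' @return object of class `panel_model`: `class_pair`, `positive_class`,
#'   `selected_features` (ordered), `coefficients` (standardized scale),
#'   `intercept`, `penalty_strength` (chosen lambda), `center`/`scale`
#'   transform parameters, `seed`. An all-shrunk solution returns an empty
#'   selection with a warning, not an error.
#' @export
fit_l1_panel <- function(x, labels, penalty_grid = NULL, nfolds = 5,
                         seed = 1L) {
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stop("labels must contain exactly two classes")
  y <- as.integer(labels == classes[2])
  if (min(table(y)) < 2) stop("need >= 2 samples in each class")
  tr <- panel_transform(t(x))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in 0:1) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(tr$z, y, family = "binomial", alpha = 1,
                          lambda = penalty_grid, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  nz <- which(cf[-1, 1] != 0)
  if (length(nz) == 0)
    warning("penalty shrank every coefficient to zero: no panel selected")
  ord <- nz[order(-abs(cf[-1, 1][nz]))]
  structure(list(class_pair = classes,
                 positive_class = classes[2],
                 selected_features = colnames(tr$z)[ord],
                 coefficients = stats::setNames(cf[-1, 1][ord], colnames(tr$z)[ord]),
                 intercept = cf[1, 1],
                 penalty_strength = cv$lambda.min,
                 center = tr$center, scale = tr$scale,
                 seed = as.integer(seed)),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("L1 logistic panel ", x$class_pair[1], " vs ", x$class_pair[2],
      ": ", length(x$selected_features), " features (lambda = ",
      signif(x$penalty_strength, 3), ")\n", sep = "")
  if (length(x$selected_features))
    print(utils::head(data.frame(feature = x$selected_features,
                                 coef = unname(x$coefficients)), 10))
  invisible(x)
}

#' Incremental AUC curve of a marker panel
#'
#' For k = 1..K, refits an unpenalized logistic model on the top-k panel
#' features (discovery samples) and reports the AUC of the fitted scores on
#' the discovery and on the held-out validation samples. Validation columns
#' are standardized with the discovery transform, never refitted.
#'
#' @param panel a `panel_model`.
#' @param x_discovery,x_validation expression matrices (features x samples)
#'   for the two splits, restricted to the two classes.
#' @param labels_discovery,labels_validation class labels per column.
#' @param k_max largest panel size evaluated (default: full panel).
#' @return data.frame `k`, `feature_added`, `auc_discovery`,
#'   `auc_validation`.
#' @export
incremental_panel_auc <- function(panel, x_discovery, labels_discovery,
                                  x_validation, labels_validation,
                                  k_max = length(panel$selected_features)) {
  K <- length(panel$selected_features)
  if (K == 0) stop("panel is empty")
  if (k_max > K) stop("k_max exceeds panel size (", K, ")")
  feats <- panel$selected_features
  pos_d <- labels_discovery == panel$positive_class
  pos_v <- labels_validation == panel$positive_class
  zd <- panel_transform(t(x_discovery[feats, , drop = FALSE]),
                        panel$center[feats], panel$scale[feats])$z
  zv <- panel_transform(t(x_validation[feats, , drop = FALSE]),
                        panel$center[feats], panel$scale[feats])$z
  out <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    dk <- as.data.frame(zd[, seq_len(k), drop = FALSE])
    names(dk) <- paste0("f", seq_len(k))
    vk <- as.data.frame(zv[, seq_len(k), drop = FALSE])
    names(vk) <- names(dk)
    fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                       data = cbind(y = as.integer(pos_d), dk)))
    sc_d <- stats::predict(fit, newdata = dk)
    sc_v <- stats::predict(fit, newdata = vk)
    out[[k]] <- data.frame(k = k, feature_added = feats[k],
                           auc_discovery = marker_auc(sc_d, pos_d),
                           auc_validation = marker_auc(sc_v, pos_v),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
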