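#' Decision thresholds for the subtype-specificity rules
#'
#' Two rule paths declare a feature specific to a target subtype, both
#' requiring over-expression (`t1 > 0`):
#' primary — `fdr1 < fdr1_max` and `fdr2 > fdr2_primary` (the rest of the
#' subtypes look homogeneous); rescue — `fdr1 < fdr1_max`,
#' `fdr2 > fdr2_rescue` and median fold change above `fc_min` (a slightly
#' heterogeneous rest is compensated by a large fold change).
#'
#' @param fdr1_max FDR ceiling on the one-vs-rest t statistic (default 0.01).
#' @param fdr2_primary FDR floor on the rest-homogeneity chi-squared for the
#'   primary path (default 0.10).
#' @param fdr2_rescue FDR floor for the rescue path (default 0.01).
#' @param fc_min fold-change gate of the rescue path (default 5).
#' @param pseudocount added to both medians in the fold change (default 0.01
#'   FPKM) so ratios stay finite with zero medians.
#' @param reference `"unweighted"` (default) contrasts the target against the
#'   plain mean of the other group coefficients; `"pooled"` weights the other
#'   groups by their sample sizes.
#' @return list of class `spec_thresholds`.
#' @export
specificity_thresholds <- function(fdr1_max = 0.01, fdr2_primary = 0.10,
                                   fdr2_rescue = 0.01, fc_min = 5,
                                   pseudocount = 0.01,
                                   reference = c("unweighted", "pooled")) {
  reference <- match.arg(reference)
  for (v in c(fdr1_max, fdr2_primary, fdr2_rescue))
    if (v < 0 || v > 1) stop("FDR thresholds must lie in [0, 1]")
  if (fc_min <= 1) stop("fc_min must exceed 1")
  structure(list(fdr1_max = fdr1_max, fdr2_primary = fdr2_primary,
                 fdr2_rescue = fdr2_rescue, fc_min = fc_min,
                 pseudocount = pseudocount, reference = reference),
            class = "spec_thresholds")
}

#' One-vs-rest robust t statistic (T1)
#'
#' Contrasts the target group's log-mean coefficient against the mean of the
#' other groups' coefficients, standardized by the robust (sandwich) standard
#' error; positive values mean over-expression in the target. The two-sided
#' p-value uses a Student-t reference whose degrees of freedom come from the
#' Satterthwaite combination of the per-group variance components
#' (df_g = n_g - 1), matching the statistic's "robust t-test" character at
#' moderate group sizes.
#'
#' @param fit a `qp_fit`.
#' @param target one of the fit's group labels.
#' @return named vector `c(t1, p1)`.
#' @export
t1_statistic <- function(fit, target) {
  g <- match(target, fit$group_labels)
  if (is.na(g)) stop("unknown target group: ", target)
  G <- length(fit$group_labels)
  if (G < 2) stop("need >= 2 groups")
  contrast <- rep(-1 / (G - 1), G)
  contrast[g] <- 1
  es <- wald_contrast(fit, contrast)
  t1 <- if (es["se"] > 0) es["estimate"] / es["se"] else if (es["estimate"] == 0) 0 else sign(es["estimate"]) * Inf
  comp <- contrast^2 * diag(fit$cov_beta)
  df <- satterthwaite_df(sum(comp), comp, fit$n_g)
  c(t1 = unname(t1), p1 = 2 * stats::pt(-abs(unname(t1)), df))
}

# Satterthwaite df for a variance that is a sum of independent per-group
# components `comp` with df_g = n_g - 1 each
satterthwaite_df <- function(total, comp, n_g) {
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1)
  denom <- rowSums(sweep(comp^2, 2, pmax(n_g - 1, 1), "/"))
  df <- total^2 / pmax(denom, 1e-300)
  pmax(df, 1)
}

#' Rest-homogeneity chi-squared statistic (T2)
#'
#' Wald test that the group coefficients remaining after excluding
#' `excluded` are all equal, using the fit's robust covariance. With the
#' diagonal covariance of the one-way design this is the precision-weighted
#' heterogeneity quadratic form on `#remaining - 1` degrees of freedom.
#'
#' @param fit a `qp_fit`.
#' @param excluded character vector of group labels to exclude.
#' @return named vector `c(t2, df2, p2)`.
#' @export
t2_statistic <- function(fit, excluded) {
  keep <- setdiff(fit$group_labels, excluded)
  if (length(keep) < 2) stop("need >= 2 groups remaining after exclusion")
  idx <- match(keep, fit$group_labels)
  b <- fit$beta[idx]
  v <- diag(fit$cov_beta)[idx]
  if (any(!is.finite(v)))
    stop("singular covariance (converged = ", fit$converged, ")")
  u <- 1 / pmax(v, 1e-300)
  bw <- sum(u * b) / sum(u)
  t2 <- sum(u * (b - bw)^2)
  df2 <- length(keep) - 1L
  c(t2 = t2, df2 = df2, p2 = stats::pchisq(t2, df2, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validated wrapper over the BH step-up adjustment: monotone, in `[0, 1]`,
#' order-preserving with the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Median fold change of a target subtype against the pooled rest
#'
#' @param values expression values of one feature across samples.
#' @param subtype group label per sample.
#' @param target subtype whose median goes in the numerator.
#' @param pseudocount added to both medians.
#' @return positive scalar
#'   `(median(target) + pseudocount) / (median(rest) + pseudocount)`.
#' @export
median_fold_change <- function(values, subtype, target, pseudocount = 0.01) {
  sel <- subtype == target
  if (!any(sel) || all(sel)) stop("target and rest must both be non-empty")
  (stats::median(values[sel]) + pseudocount) /
    (stats::median(values[!sel]) + pseudocount)
}

#' Apply the two-path specificity decision rule
#'
#' Pure, vectorized decision: primary path `fdr1 < fdr1_max & fdr2 >
#' fdr2_primary`, rescue path `fdr1 < fdr1_max & fdr2 > fdr2_rescue &
#' fold_change > fc_min`, both requiring `t1 > 0`; primary is preferred when
#' both hold.
#'
#' @param fdr1,fdr2,fold_change,t1 numeric vectors (recycled to a common
#'   length).
#' @param thresholds a [specificity_thresholds()] list.
#' @return data.frame with logical `decision` and character `rule_path`
#'   (`"primary"`, `"rescue"` or `"none"`).
#' @export
decide_specific <- function(fdr1, fdr2, fold_change, t1,
                            thresholds = specificity_thresholds()) {
  over <- t1 > 0
  primary <- fdr1 < thresholds$fdr1_max & fdr2 > thresholds$fdr2_primary & over
  rescue <- fdr1 < thresholds$fdr1_max & fdr2 > thresholds$fdr2_rescue &
    fold_change > thresholds$fc_min & over
  path <- ifelse(primary, "primary", ifelse(rescue, "rescue", "none"))
  data.frame(decision = primary | rescue, rule_path = path,
             stringsAsFactors = FALSE)
}

row_medians <- function(m) apply(m, 1L, stats::median)

#' Identify subtype-specific features
#'
#' Fits every feature with the robust quasi-Poisson one-way model, computes
#' the one-vs-rest T1 and rest-homogeneity T2 statistics for every subtype,
#' adjusts p-values by Benjamini-Hochberg across features separately for T1
#' and T2 within each target subtype, gates on fold change, and applies the
#' two-path decision rule. Non-converged features are excluded from testing
#' and reported via a message and the `n_excluded` attribute.
#'
#' @param x expression matrix (features x samples).
#' @param samples either a sample annotation data.frame (its `discovery`
#'   split is used) or a vector/factor of subtype labels per column of `x`.
#' @param thresholds a [specificity_thresholds()] list.
#' @param control a [qp_control()] list for the per-feature fits.
#' @param fits optional precomputed `qp_fits` for `x` (skips refitting).
#' @return data.frame, one row per feature x subtype: `feature_id`,
#'   `subtype`, `t1`, `p1`, `fdr1`, `t2`, `df2`, `p2`, `fdr2`,
#'   `fold_change`, `decision`, `rule_path`; attribute `n_excluded` counts
#'   non-converged features.
#' @export
run_specificity <- function(x, samples, thresholds = specificity_thresholds(),
                            control = qp_control(), fits = NULL) {
  if (is.data.frame(samples)) {
    al <- align_split(x, samples, "discovery")
    x <- al$x; subtype <- al$subtype
  } else {
    subtype <- factor(samples)
  }
  if (nlevels(subtype) < 2) stop("need >= 2 subtypes")
  if (is.null(fits)) fits <- fit_qp_matrix(x, subtype, control)
  G <- length(fits$group_labels)
  keep <- fits$converged
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message(n_excl, " feature(s) excluded: fit did not converge")
  beta <- fits$beta[keep, , drop = FALSE]
  vb <- fits$var_beta[keep, , drop = FALSE]
  xk <- x[keep, , drop = FALSE]
  Fn <- nrow(beta)
  gi <- as.integer(factor(subtype, levels = fits$group_labels))

  res <- vector("list", G)
  for (g in seq_len(G)) {
    other <- setdiff(seq_len(G), g)
    w_ref <- if (thresholds$reference == "pooled")
      fits$n_g[other] / sum(fits$n_g[other]) else rep(1 / (G - 1), G - 1)
    a <- rep(0, G); a[other] <- -w_ref; a[g] <- 1
    comp <- sweep(vb, 2, a^2, "*")
    se2 <- rowSums(comp)
    est <- beta[, g] - drop(beta[, other, drop = FALSE] %*% w_ref)
    se <- sqrt(se2)
    t1 <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
    p1 <- 2 * stats::pt(-abs(t1), satterthwaite_df(se2, comp, fits$n_g))

    bo <- beta[, other, drop = FALSE]
    u <- 1 / pmax(vb[, other, drop = FALSE], 1e-300)
    bw <- rowSums(u * bo) / rowSums(u)
    t2 <- rowSums(u * (bo - bw)^2)
    df2 <- G - 2L
    p2 <- stats::pchisq(t2, df2, lower.tail = FALSE)

    tgt <- gi == g
    fc <- (row_medians(xk[, tgt, drop = FALSE]) + thresholds$pseudocount) /
      (row_medians(xk[, !tgt, drop = FALSE]) + thresholds$pseudocount)

    fdr1 <- bh_fdr(p1)
    fdr2 <- bh_fdr(p2)
    dec <- decide_specific(fdr1, fdr2, fc, t1, thresholds)
    res[[g]] <- data.frame(feature_id = rownames(beta),
                           subtype = fits$group_labels[g],
                           t1 = t1, p1 = p1, fdr1 = fdr1,
                           t2 = t2, df2 = df2, p2 = p2, fdr2 = fdr2,
                           fold_change = fc,
                           decision = dec$decision, rule_path = dec$rule_path,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Rank a specificity (or co-expression) result table
#'
#' Reproducible "top list" order: `fdr1` ascending, then `|t1|` descending,
#' ties broken lexicographically by feature id.
#'
#' @param results data.frame from [run_specificity()] or
#'   [run_coexpression()].
#' @param decided_only keep only rows with `decision == TRUE` (default).
#' @return reordered data.frame.
#' @export
rank_markers <- function(results, decided_only = TRUE) {
  if (decided_only) results <- results[results$decision, , drop = FALSE]
  results[order(results$fdr1, -abs(results$t1), results$feature_id), ,
          drop = FALSE]
}
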