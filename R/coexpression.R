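#' Identify features co-expressed in a pair of subtypes
#'
#' Extends the single-subtype procedure to every unordered subtype pair: T1
#' contrasts the mean of the pair's log-mean coefficients against the mean of
#' the remaining groups' coefficients; T2 tests homogeneity of the remaining
#' groups; an optional within-pair Wald equality gate (on by default) demands
#' that the two pair members themselves look alike, which keeps strong
#' single-subtype markers out of the pair calls. FDR adjustment is across
#' features, separately per pair and per statistic.
#'
#' @param x expression matrix (features x samples).
#' @param samples sample annotation data.frame (discovery split used) or a
#'   vector of subtype labels per column.
#' @param thresholds a [specificity_thresholds()] list; the pair decision
#'   uses `fdr1 < fdr1_max`, `fdr2 > fdr2_primary` and `t1 > 0`.
#' @param control a [qp_control()] list.
#' @param within_pair_gate require the within-pair equality p-value to be at
#'   least `within_pair_alpha` (default `TRUE`).
#' @param within_pair_alpha significance level of the within-pair gate
#'   (default 0.05).
#' @param fits optional precomputed `qp_fits`.
#' @return data.frame, one row per feature x pair: `feature_id`, `subtype`,
#'   `subtype2` (alphabetical within pair), `t1`, `p1`, `fdr1`, `t2`, `df2`,
#'   `p2`, `fdr2`, `within_pair_p`, `decision`.
#' @export
run_coexpression <- function(x, samples, thresholds = specificity_thresholds(),
                             control = qp_control(), within_pair_gate = TRUE,
                             within_pair_alpha = 0.05, fits = NULL) {
  if (is.data.frame(samples)) {
    al <- align_split(x, samples, "discovery")
    x <- al$x; subtype <- al$subtype
  } else {
    subtype <- factor(samples)
  }
  G <- nlevels(subtype)
  if (G < 3) stop("co-expression needs >= 3 subtypes")
  if (is.null(fits)) fits <- fit_qp_matrix(x, subtype, control)
  keep <- fits$converged
  if (any(!keep)) message(sum(!keep), " feature(s) excluded: fit did not converge")
  beta <- fits$beta[keep, , drop = FALSE]
  vb <- fits$var_beta[keep, , drop = FALSE]
  labels <- fits$group_labels
  pairs <- utils::combn(G, 2)

  res <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    rest <- setdiff(seq_len(G), c(a, b))
    cvec <- rep(0, G); cvec[c(a, b)] <- 1 / 2; cvec[rest] <- -1 / length(rest)
    comp <- sweep(vb, 2, cvec^2, "*")
    se2 <- rowSums(comp)
    est <- (beta[, a] + beta[, b]) / 2 -
      rowMeans(beta[, rest, drop = FALSE])
    se <- sqrt(se2)
    t1 <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
    p1 <- 2 * stats::pt(-abs(t1), satterthwaite_df(se2, comp, fits$n_g))

    if (length(rest) >= 2) {
      br <- beta[, rest, drop = FALSE]
      u <- 1 / pmax(vb[, rest, drop = FALSE], 1e-300)
      bw <- rowSums(u * br) / rowSums(u)
      t2 <- rowSums(u * (br - bw)^2)
      df2 <- length(rest) - 1L
      p2 <- stats::pchisq(t2, df2, lower.tail = FALSE)
    } else {
      t2 <- rep(0, nrow(beta)); df2 <- 0L; p2 <- rep(1, nrow(beta))
    }

    wp_v <- vb[, c(a, b), drop = FALSE]
    wp_z <- (beta[, a] - beta[, b]) / sqrt(rowSums(wp_v))
    wp_df <- satterthwaite_df(rowSums(wp_v), wp_v, fits$n_g[c(a, b)])
    within_pair_p <- 2 * stats::pt(-abs(wp_z), wp_df)

    fdr1 <- bh_fdr(p1)
    fdr2 <- bh_fdr(p2)
    decision <- fdr1 < thresholds$fdr1_max & fdr2 > thresholds$fdr2_primary &
      t1 > 0
    if (within_pair_gate) decision <- decision & within_pair_p >= within_pair_alpha
    res[[p]] <- data.frame(feature_id = rownames(beta),
                           subtype = labels[a], subtype2 = labels[b],
                           t1 = t1, p1 = p1, fdr1 = fdr1,
                           t2 = t2, df2 = df2, p2 = p2, fdr2 = fdr2,
                           within_pair_p = within_pair_p,
                           decision = decision,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "n_excluded") <- sum(!keep)
  out
}
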