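#' Control parameters for the robust quasi-Poisson fitter
#'
#' @param tol convergence tolerance on the maximum absolute change of the
#'   log-scale group coefficients.
#' @param max_iter maximum IWLS iterations.
#' @param huber_c Huber tuning constant applied to standardized Pearson
#'   residuals (1.345 gives ~95% normal-model efficiency).
#' @param robust logical; `FALSE` disables the robustness weights, reducing
#'   the fit to the plain quasi-Poisson IWLS whose solution is the group
#'   sample mean.
#' @param pseudocount floor mean (FPKM) assigned to groups whose observations
#'   are all zero, and added inside the initialization.
#' @param cov_type `"sandwich"` (default; robust empirical covariance) or
#'   `"model"` (model-based, dispersion floored at 1).
#' @return list of class `qp_control`.
#' @export
qp_control <- function(tol = 1e-8, max_iter = 50L, huber_c = 1.345,
                       robust = TRUE, pseudocount = 0.01,
                       cov_type = c("sandwich", "model")) {
  cov_type <- match.arg(cov_type)
  if (tol <= 0 || max_iter < 1 || huber_c <= 0 || pseudocount <= 0)
    stop("invalid control parameters")
  structure(list(tol = tol, max_iter = as.integer(max_iter), huber_c = huber_c,
                 robust = isTRUE(robust), pseudocount = pseudocount,
                 cov_type = cov_type),
            class = "qp_control")
}

# E[psi_c(Z)^2] under Z ~ N(0,1): consistency constant for the Huber-
# winsorized dispersion estimate.
huber_kappa <- function(c) {
  (2 * stats::pnorm(c) - 1) - 2 * c * stats::dnorm(c) + 2 * c^2 * stats::pnorm(-c)
}

#' Batch robust quasi-Poisson one-way fits over an expression matrix
#'
#' Fits, for every feature (row) at once, the log-link one-way model
#' `E[y] = exp(beta_g)`, `Var[y] = phi * E[y]` by iterative weighted least
#' squares. Each IWLS step multiplies the usual GLM weight by a Huber
#' robustness weight `psi(r)/r` computed on Pearson residuals standardized by
#' a jointly iterated robust dispersion; with the one-way design the weighted
#' least-squares step reduces to a per-group Newton update, which is applied
#' to all features simultaneously.
#'
#' Groups whose observations are all zero are assigned the floor mean
#' `pseudocount` and flagged; non-convergence is reported via the
#' `converged` field, never as an error.
#'
#' @param x features x samples matrix (non-negative, finite).
#' @param groups factor/vector of group labels, one per column of `x`;
#'   every group needs >= 2 samples.
#' @param control a [qp_control()] list.
#' @return object of class `qp_fits`: list with `group_labels`;
#'   `beta` (features x groups, log mean); `var_beta` (features x groups;
#'   the one-way design makes the coefficient covariance diagonal);
#'   `phi` (per-feature dispersion, >= 0, unfloored); `robust_weights`
#'   (features x samples, in \[0, 1\]); `n_iter`, `converged`,
#'   `all_zero_group` (features x groups logical); `control`.
#' @export
fit_qp_matrix <- function(x, groups, control = qp_control()) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list("f1", names(x)))
  if (any(!is.finite(x) | x < 0)) stop("x must be finite and non-negative")
  groups <- factor(groups)
  if (length(groups) != ncol(x)) stop("length(groups) must equal ncol(x)")
  ng <- table(groups)
  if (any(ng == 0)) stop("empty group: ", paste(names(ng)[ng == 0], collapse = ", "))
  if (any(ng < 2)) stop("every group needs >= 2 observations")
  G <- nlevels(groups)
  S <- ncol(x); Fn <- nrow(x)
  gi <- as.integer(groups)
  M <- matrix(0, S, G); M[cbind(seq_len(S), gi)] <- 1  # sample x group indicator
  cc <- control$huber_c
  kap <- if (control$robust) huber_kappa(cc) else 1

  dimnames(M) <- list(NULL, levels(groups))
  grp_sum <- x %*% M
  rownames(grp_sum) <- rownames(x)                                  # F x G
  nvec <- as.numeric(ng)
  grp_mean <- sweep(grp_sum, 2, nvec, "/")
  zero_grp <- grp_sum == 0
  beta <- log(grp_mean + control$pseudocount)
  beta[zero_grp] <- log(control$pseudocount)

  phi <- rep(1, Fn)
  w <- matrix(1, Fn, S)
  converged <- rep(FALSE, Fn)
  n_iter <- rep(control$max_iter, Fn)
  delta_prev <- NULL
  dphi_prev <- NULL

  for (it in seq_len(control$max_iter)) {
    mu <- exp(beta)[, gi, drop = FALSE]
    res <- x - mu
    r <- res / sqrt(mu)                               # Pearson residuals
    if (control$robust) {
      # dispersion below 1 is not credible for FPKM; flooring the
      # standardization scale also prevents implosive downweighting on
      # highly skewed low-expression features
      s <- sqrt(pmax(phi, 1))
      w <- pmin((cc * s) / pmax(abs(r), 1e-300), 1)
    }
    # dispersion: weighted mean square of Huber-winsorized Pearson residuals,
    # df-corrected and normal-model consistency-corrected
    psi2 <- (w * r)^2
    sw <- rowSums(w)
    phi_new <- rowSums(w * psi2) / (pmax(sw - G, 1) * kap)
    # Steffensen cycle: 2 plain steps, then extrapolate; the non-robust path
    # is plain Newton and needs no acceleration
    accel <- control$robust && it > 4L && it %% 3L == 0L
    if (control$robust && accel && !is.null(dphi_prev)) {
      dphi <- phi_new - phi
      rho_p <- dphi / dphi_prev
      okp <- is.finite(rho_p) & abs(rho_p) < 0.98 & rho_p != 0 &
        abs(dphi) < 0.05 * pmax(phi, 1)
      if (any(okp)) {
        extra <- dphi[okp] * rho_p[okp] / (1 - rho_p[okp])
        phi_new[okp] <- phi_new[okp] + pmax(pmin(extra, phi[okp] / 2), -phi[okp] / 2)
      }
    }
    dphi_prev <- phi_new - phi
    phi <- phi_new

    num <- (w * res) %*% M
    den <- (w %*% M) * exp(beta)
    delta <- num / den
    delta[zero_grp] <- 0
    beta <- beta + delta
    # the reweighting makes the fixed-point iteration linearly convergent;
    # an elementwise Aitken (secant) extrapolation on the same Steffensen
    # cycle collapses the geometric tail once the per-coordinate rate is
    # stable
    if (!is.null(delta_prev) && accel) {
      rho <- delta / delta_prev
      ok <- is.finite(rho) & abs(rho) < 0.98 & rho != 0 & abs(delta) < 0.1
      if (any(ok)) {
        extra <- pmax(pmin(delta[ok] * rho[ok] / (1 - rho[ok]), 2), -2)
        beta[ok] <- beta[ok] + extra
      }
    }
    delta_prev <- delta
    newly <- !converged & apply(abs(delta), 1, max) < control$tol
    n_iter[newly] <- it
    converged <- converged | newly
    if (all(converged)) break
  }

  mu <- exp(beta)[, gi, drop = FALSE]
  res <- x - mu
  # sandwich (robust empirical) variance per group coefficient; the one-way
  # indicator design keeps coefficients orthogonal, so the covariance is
  # diagonal and stored as a features x groups matrix. The bread uses the
  # exact derivative of the Huber estimating function: unwinsorized points
  # contribute mu, winsorized points psi/2 (psi = w * (y - mu)), so heavy
  # downweighting correctly widens the standard error.
  psi <- w * res
  inl <- w >= 1 - 1e-12
  bread <- (inl %*% M) * exp(beta) - 0.5 * ((psi * !inl) %*% M)
  bread <- pmax(bread, 1e-12)
  if (control$cov_type == "sandwich") {
    meat <- (psi^2) %*% M
    hc <- rep(nvec / pmax(nvec - 1, 1), each = Fn)
    var_beta <- meat * hc / bread^2
  } else {
    var_beta <- pmax(phi, 1) / (exp(beta) * (w %*% M))
  }
  # all-zero groups sit at the floor mean; give them the model-based variance
  # at that floor so T1/T2 remain defined for pervasive-zero features
  if (any(zero_grp)) {
    vz <- outer(pmax(phi, 1), control$pseudocount * nvec, "/")
    var_beta[zero_grp] <- vz[zero_grp]
  }

  structure(list(group_labels = levels(groups),
                 beta = structure(beta, dimnames = list(rownames(x), levels(groups))),
                 var_beta = structure(var_beta, dimnames = list(rownames(x), levels(groups))),
                 phi = stats::setNames(phi, rownames(x)),
                 robust_weights = structure(w, dimnames = dimnames(x)),
                 n_iter = n_iter, converged = converged,
                 all_zero_group = zero_grp,
                 n_g = stats::setNames(nvec, levels(groups)),
                 groups = groups, control = control),
            class = "qp_fits")
}

#' Robust quasi-Poisson one-way fit for a single feature
#'
#' Convenience wrapper over [fit_qp_matrix()] for one response vector.
#'
#' @param y non-negative numeric vector.
#' @param groups group labels, one per element of `y`.
#' @param control a [qp_control()] list.
#' @return object of class `qp_fit`: `group_labels`, `beta` (named vector,
#'   log scale), `cov_beta` (diagonal matrix), `phi`, `robust_weights`,
#'   `n_iter`, `converged`, `all_zero_group`.
#' @export
fit_robust_qp <- function(y, groups, control = qp_control()) {
  fits <- fit_qp_matrix(matrix(y, nrow = 1, dimnames = list("y", NULL)),
                        groups, control)
  qp_fit_at(fits, 1L)
}

# extract the i-th feature of a qp_fits batch as a single qp_fit
qp_fit_at <- function(fits, i) {
  v <- fits$var_beta[i, ]
  structure(list(group_labels = fits$group_labels,
                 beta = fits$beta[i, ],
                 cov_beta = diag(v, nrow = length(v)),
                 n_g = fits$n_g,
                 phi = unname(fits$phi[i]),
                 robust_weights = fits$robust_weights[i, ],
                 n_iter = fits$n_iter[i],
                 converged = fits$converged[i],
                 all_zero_group = fits$all_zero_group[i, ],
                 control = fits$control),
            class = "qp_fit")
}

#' @export
print.qp_fit <- function(x, ...) {
  cat("Robust quasi-Poisson one-way fit (", length(x$group_labels), " groups)\n", sep = "")
  print(data.frame(group = x$group_labels, beta = x$beta,
                   se = sqrt(diag(x$cov_beta)), mean = exp(x$beta),
                   row.names = NULL))
  cat(sprintf("phi = %.4g; %s in %d iterations\n", x$phi,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
print.qp_fits <- function(x, ...) {
  cat("Robust quasi-Poisson batch fit: ", nrow(x$beta), " features x ",
      length(x$group_labels), " groups; ",
      sum(x$converged), " converged\n", sep = "")
  invisible(x)
}

#' Wald estimate and standard error for a linear contrast of group effects
#'
#' @param fit a `qp_fit` object.
#' @param contrast numeric vector, one weight per group.
#' @return named vector `c(estimate, se)` where
#'   `estimate = sum(contrast * beta)` and
#'   `se = sqrt(t(contrast) %*% cov_beta %*% contrast)`.
#' @export
wald_contrast <- function(fit, contrast) {
  if (!inherits(fit, "qp_fit")) stop("fit must be a qp_fit")
  if (length(contrast) != length(fit$beta))
    stop("contrast length must equal the number of groups")
  est <- sum(contrast * fit$beta)
  v <- drop(t(contrast) %*% fit$cov_beta %*% contrast)
  if (!is.finite(v) || v < 0)
    stop("singular or invalid covariance (converged = ", fit$converged, ")")
  c(estimate = est, se = sqrt(v))
}
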