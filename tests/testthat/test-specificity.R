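make_fit <- function(beta, var, n = 30) {
  G <- length(beta)
  structure(list(group_labels = LETTERS[1:G], beta = setNames(beta, LETTERS[1:G]),
                 cov_beta = diag(var, nrow = G), phi = 1,
                 robust_weights = rep(1, G * n), n_iter = 1, converged = TRUE,
                 all_zero_group = setNames(rep(FALSE, G), LETTERS[1:G]),
                 n_g = setNames(rep(n, G), LETTERS[1:G]),
                 control = qp_control()),
            class = "qp_fit")
}

test_that("T1 matches hand-computed contrast arithmetic and is antisymmetric", {
  f <- make_fit(beta = c(2, 0, 0, 0, 0), var = rep(0.04, 5))
  r <- t1_statistic(f, "A")
  # contrast (1, -1/4 x4): est = 2, var = 0.04 * (1 + 4/16)
  expect_equal(unname(r["t1"]), 2 / sqrt(0.04 * 1.25), tolerance = 1e-12)
  expect_lt(r["p1"], 1e-6)
  # equal betas -> t1 = 0, p = 1
  f0 <- make_fit(beta = rep(1.3, 4), var = rep(0.1, 4))
  expect_equal(unname(t1_statistic(f0, "B")), c(0, 1), tolerance = 1e-12)
  # under-expressed target flips the sign
  fu <- make_fit(beta = c(-2, 0, 0, 0, 0), var = rep(0.04, 5))
  expect_equal(unname(t1_statistic(fu, "A")["t1"]),
               -unname(t1_statistic(f, "A")["t1"]), tolerance = 1e-12)
})

test_that("T2 is the precision-weighted heterogeneity quadratic form", {
  f <- make_fit(beta = c(5, 1, 2, 1.5, 1), var = c(0.1, 0.2, 0.1, 0.05, 0.2))
  r <- t2_statistic(f, excluded = "A")
  b <- f$beta[2:5]; v <- diag(f$cov_beta)[2:5]
  u <- 1 / v; bw <- sum(u * b) / sum(u)
  expect_equal(unname(r["t2"]), sum(u * (b - bw)^2), tolerance = 1e-12)
  expect_equal(unname(r["df2"]), 3)
  expect_equal(unname(r["p2"]),
               pchisq(sum(u * (b - bw)^2), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical remaining betas -> t2 = 0, p2 = 1
  f0 <- make_fit(beta = c(9, 2, 2, 2), var = rep(0.3, 4))
  expect_equal(unname(t2_statistic(f0, "A")[c("t2", "p2")]), c(0, 1))
  expect_error(t2_statistic(f, excluded = LETTERS[1:4]), "2 groups")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  # oracle: p * n / rank then cumulative min from the largest p down
  p <- c(0.01, 0.02, 0.03, 0.04)
  raw <- p * length(p) / rank(p)
  oracle <- rev(cummin(rev(raw[order(p)])))[rank(p)]
  expect_equal(bh_fdr(p), oracle)
  expect_equal(bh_fdr(p), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  pr <- runif(50)
  expect_equal(bh_fdr(pr), p.adjust(pr, "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("median fold change follows its definition", {
  v <- c(10, 10, 10, 2, 2, 2)
  g <- rep(c("T", "R"), each = 3)
  expect_equal(median_fold_change(v, g, "T", pseudocount = 1e-9), 5,
               tolerance = 1e-6)
  expect_equal(median_fold_change(rep(4, 6), g, "T"), 1)
  expect_equal(median_fold_change(c(1, 1, 1, 0, 0, 0), g, "T", 0.01),
               1.01 / 0.01)
  expect_error(median_fold_change(v, rep("T", 6), "T"), "non-empty")
})

test_that("the two decision paths reproduce the published rule grid", {
  th <- specificity_thresholds()
  grid <- expand.grid(fdr1 = c(0.005, 0.05), fdr2 = c(0.005, 0.05, 0.2),
                      fc = c(1.5, 6), t1 = c(-3, 3))
  d <- decide_specific(grid$fdr1, grid$fdr2, grid$fc, grid$t1, th)
  expected_decision <-
    (grid$fdr1 < 0.01 & grid$fdr2 > 0.10 & grid$t1 > 0) |
    (grid$fdr1 < 0.01 & grid$fdr2 > 0.01 & grid$fc > 5 & grid$t1 > 0)
  expect_equal(d$decision, expected_decision)
  # named cases
  expect_equal(unlist(decide_specific(0.005, 0.2, 1.5, 3, th)),
               c(decision = "TRUE", rule_path = "primary"))
  expect_equal(unlist(decide_specific(0.005, 0.05, 6, 3, th)),
               c(decision = "TRUE", rule_path = "rescue"))
  expect_equal(unlist(decide_specific(0.5, 0.9, 100, 3, th)),
               c(decision = "FALSE", rule_path = "none"))
  # purity: same input, same output
  expect_identical(decide_specific(0.005, 0.2, 1.5, 3, th),
                   decide_specific(0.005, 0.2, 1.5, 3, th))
})

test_that("specificity scan recovers planted markers and stays quiet on constants", {
  d <- simulate_dataset(planted_scenario(seed = 71, n_genes = 400,
                                         n_specific = 8, n_coexpressed = 2))
  dp <- discovery_part(d)
  x <- rbind(dp$x, flatline = rep(3, ncol(dp$x)))
  sp <- suppressMessages(run_specificity(x, dp$subtype))
  expect_false(any(sp$decision[sp$feature_id == "flatline"]))
  ts <- d$truth[d$truth$pattern == "specific", ]
  det <- sp[sp$decision, ]
  hit <- paste(ts$isoform_id, ts$subtype) %in%
    paste(det$feature_id, det$subtype)
  expect_gte(mean(hit), 0.85)
  # declared subtype matches planted subtype for nearly all detections
  m <- det[det$feature_id %in% ts$isoform_id, ]
  expect_gte(mean(m$subtype == ts$subtype[match(m$feature_id, ts$isoform_id)]),
             0.95)
})

test_that("statistics are invariant to subtype label order", {
  d <- simulate_dataset(planted_scenario(seed = 72, n_genes = 100,
                                         n_specific = 4, n_coexpressed = 1))
  dp <- discovery_part(d)
  sp1 <- suppressMessages(run_specificity(dp$x, dp$subtype))
  rev_subtype <- factor(as.character(dp$subtype),
                        levels = rev(levels(dp$subtype)))
  sp2 <- suppressMessages(run_specificity(dp$x, rev_subtype))
  key <- function(s) s[order(s$feature_id, s$subtype), ]
  s1 <- key(sp1); s2 <- key(sp2)
  expect_equal(s1$t1, s2$t1, tolerance = 1e-10)
  expect_equal(s1$t2, s2$t2, tolerance = 1e-10)
  expect_equal(s1$decision, s2$decision)
})

test_that("ranking is deterministic: fdr1, then |t1|, then feature id", {
  df <- data.frame(feature_id = c("b", "a", "c"), subtype = "A",
                   t1 = c(5, -7, 5), fdr1 = c(0.001, 0.001, 0.0005),
                   decision = TRUE)
  r <- rank_markers(df)
  expect_equal(r$feature_id, c("c", "a", "b"))
})
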