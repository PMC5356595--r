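test_that("rank-based AUC equals brute-force pair counting", {
  # worked case: positives {3, 5} vs negatives {1, 4} -> 3 of 4 pairs won
  expect_equal(marker_auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(marker_auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(marker_auc(rep(2, 8), rep(c(TRUE, FALSE), 4)), 0.5)

  brute <- function(v, pos) {
    p <- v[pos]; n <- v[!pos]
    mean(outer(p, n, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(61)
  for (i in 1:50) {
    ns <- sample(4:200, 1)
    v <- sample(round(rnorm(ns), 1))  # rounded -> plenty of ties
    pos <- runif(ns) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(marker_auc(v, pos), brute(v, pos), tolerance = 1e-12)
    # label-flip antisymmetry under midranks
    expect_equal(marker_auc(v, pos) + marker_auc(v, !pos), 1, tolerance = 1e-12)
  }
  expect_error(marker_auc(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  v <- rnorm(100)
  pos <- runif(100) < 0.5
  expect_equal(marker_auc(v, pos),
               as.numeric(suppressMessages(pROC::auc(pROC::roc(pos, v,
                 direction = "<", quiet = TRUE)))),
               tolerance = 1e-12)
})

test_that("isoform-vs-gene AUC comparison is exact for single-isoform genes", {
  d <- simulate_dataset(planted_scenario(seed = 63, n_genes = 60,
                                         n_specific = 5, n_coexpressed = 0))
  # force some single-isoform genes by using the generator's annotation
  iso <- marker_auc_table(d$expression, d$samples, level = "isoform")
  gx <- aggregate_gene_level(d$expression, d$annotation)
  gene <- marker_auc_table(gx, d$samples, level = "gene")
  cmp <- compare_isoform_gene_auc(iso, gene, d$annotation)
  expect_true(all(cmp$delta >= -1 & cmp$delta <= 1))
  singles <- names(which(table(d$annotation$gene_id) == 1))
  single_iso <- d$annotation$isoform_id[d$annotation$gene_id %in% singles]
  expect_true(all(abs(cmp$delta[cmp$feature_id %in% single_iso]) < 1e-12))
  # a signal-carrying isoform beats its gene when a sibling adds noise
  ts <- d$truth[d$truth$pattern == "specific", ]
  multi <- ts[ts$isoform_id %in%
                d$annotation$isoform_id[!(d$annotation$gene_id %in% singles)], ]
  if (nrow(multi) > 0) {
    rows <- cmp[cmp$feature_id %in% multi$isoform_id &
                  cmp$target_subtype == multi$subtype[1], ]
    expect_gte(max(rows$delta), 0)
  }
})

test_that("lasso panel finds a perfectly separating feature first", {
  set.seed(64)
  n <- 60; p <- 40
  lab <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rqp(p * n, 10, 2), p, n,
              dimnames = list(sprintf("f%02d", 1:p), sprintf("s%02d", 1:n)))
  x["f07", ] <- ifelse(lab == "B", 200, 1)    # complete separation
  pm <- fit_l1_panel(x, lab, seed = 2)
  expect_equal(pm$selected_features[1], "f07")
  expect_equal(pm$class_pair, c("A", "B"))
  # penalty -> infinity: empty selection is a warning, not an error
  expect_warning(pm0 <- fit_l1_panel(x, lab, penalty_grid = c(1e4, 9e3),
                                     seed = 2), "no panel selected")
  expect_length(pm0$selected_features, 0)
  expect_error(fit_l1_panel(x, rep("A", n)), "two classes")
})

test_that("planted two-class panels are recovered with high held-out AUC", {
  recovered <- auc5 <- numeric(3)
  for (i in 1:3) {
    set.seed(400 + i)
    n <- 200; p <- 500
    lab <- rep(c("LumA", "LumB"), each = 100)
    mu <- matrix(20, p, n)
    mu[1:5, lab == "LumB"] <- 160
    x <- matrix(rgamma(p * n, shape = mu / 5, scale = 5), p, n,
                dimnames = list(sprintf("iso%03d", 1:p), sprintf("d%03d", 1:n)))
    xv <- matrix(rgamma(p * n, shape = mu / 5, scale = 5), p, n,
                 dimnames = dimnames(x))
    pm <- fit_l1_panel(x, lab, seed = i)
    recovered[i] <- sum(sprintf("iso%03d", 1:5) %in% pm$selected_features)
    k5 <- min(5, length(pm$selected_features))
    curve <- incremental_panel_auc(pm, x, lab, xv, lab, k_max = k5)
    auc5[i] <- curve$auc_validation[k5]
    # k = K consistency and bounded AUCs
    expect_true(all(curve$auc_discovery >= 0 & curve$auc_discovery <= 1))
    expect_error(incremental_panel_auc(pm, x, lab, xv, lab,
                                       k_max = length(pm$selected_features) + 1),
                 "exceeds")
  }
  expect_gte(mean(recovered), 4)
  expect_gte(mean(auc5), 0.95)
})

test_that("panel fitting is deterministic given a seed", {
  set.seed(65)
  n <- 80; p <- 60
  lab <- rep(c("A", "B"), each = n / 2)
  mu <- matrix(15, p, n); mu[1:3, lab == "B"] <- 90
  x <- matrix(rgamma(p * n, shape = mu / 4, scale = 4), p, n,
              dimnames = list(sprintf("f%02d", 1:p), sprintf("s%02d", 1:n)))
  p1 <- fit_l1_panel(x, lab, seed = 9)
  p2 <- fit_l1_panel(x, lab, seed = 9)
  expect_identical(p1$selected_features, p2$selected_features)
  expect_equal(p1$coefficients, p2$coefficients)
})
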