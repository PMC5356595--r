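test_that("expression TSV round trip preserves values and identifiers", {
  x <- tiny_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, path)
  expect_equal(read_expression(path), x)

  set.seed(31)
  for (i in 1:5) {
    r <- matrix(signif(rgamma(30, 2, 0.1), 6), nrow = 5,
                dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
    write_expression(r, path)
    expect_equal(read_expression(path), r, tolerance = 1e-6)
  }
  # gzip accepted
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_expression(x, gz)
  expect_equal(read_expression(gz), x)
})

test_that("invalid expression input is rejected with located errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "isoA\t1.5\t-1.0"), path)
  expect_error(read_expression(path), "isoA.*s2|s2.*isoA")
  writeLines(c("feature_id\ts1", "isoA\t1", "isoA\t2"), path)
  expect_error(read_expression(path), "duplicate feature ids: isoA")
  writeLines(c("feature_id\ts1", "isoA\tnot_a_number"), path)
  expect_error(read_expression(path), "non-numeric")
  m <- tiny_matrix()
  m[1, 1] <- NA
  expect_error(validate_expression(m), "finite")
})

test_that("biotype classification follows the coding/200-nt rule and partitions", {
  ann <- data.frame(isoform_id = c("i1", "i2", "i3", "i4"),
                    gene_id = "g", is_coding = c(FALSE, FALSE, TRUE, FALSE),
                    length_nt = c(500, 80, 80, 201))
  b <- classify_biotype(ann)
  expect_equal(as.character(b), c("lncRNA", "small_ncRNA", "mRNA", "lncRNA"))
  # exact boundary: 200 nt non-coding is small ncRNA
  expect_equal(as.character(classify_biotype(
    data.frame(isoform_id = "i", gene_id = "g", is_coding = FALSE,
               length_nt = 200))), "small_ncRNA")
  # partition: every record gets exactly one of the three classes
  set.seed(7)
  ann_r <- data.frame(isoform_id = paste0("t", 1:200), gene_id = "g",
                      is_coding = runif(200) < 0.5,
                      length_nt = sample(20:5000, 200))
  expect_false(anyNA(classify_biotype(ann_r)))
})

test_that("gene aggregation sums isoforms and conserves per-sample totals", {
  x <- matrix(c(1, 2, 2.5, 0, 5, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("i1", "i2", "i3"), c("s1", "s2")))
  ann <- data.frame(isoform_id = c("i1", "i2", "i3"),
                    gene_id = c("G1", "G1", "G2"),
                    is_coding = TRUE, length_nt = 1000)
  g <- aggregate_gene_level(x, ann)
  expect_equal(g["G1", ], c(s1 = 3.5, s2 = 2.0))
  expect_equal(g["G2", ], x["i3", ])          # single-isoform identity
  expect_equal(colSums(g), colSums(x))        # conservation

  set.seed(11)
  xr <- matrix(rgamma(200, 2, 0.5), nrow = 20,
               dimnames = list(paste0("i", 1:20), paste0("s", 1:10)))
  annr <- data.frame(isoform_id = paste0("i", 1:20),
                     gene_id = paste0("G", sample(1:6, 20, replace = TRUE)),
                     is_coding = TRUE, length_nt = 1000)
  expect_equal(colSums(aggregate_gene_level(xr, annr)), colSums(xr))
  expect_error(aggregate_gene_level(xr, annr[-1, ]), "without annotation: i1")
})

test_that("PCA outlier flagging finds a gross outlier and nothing else", {
  set.seed(5)
  x <- matrix(rgamma(50 * 20, shape = 4, scale = 5), nrow = 50,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:20)))
  expect_identical(flag_pca_outliers(x), character(0))
  xo <- x
  xo[, 7] <- xo[, 7] * 1000
  expect_identical(flag_pca_outliers(xo), "s7")
  # verify by direct distance computation on the PC scores
  pc <- prcomp(t(log2(xo + 1)))
  d1 <- abs(pc$x[, 1] - median(pc$x[, 1])) / mad(pc$x[, 1])
  expect_gt(d1["s7"], 6)
  # infinite threshold flags nothing; constant matrix flags nothing
  expect_identical(flag_pca_outliers(xo, mad_multiplier = Inf), character(0))
  const <- matrix(3, 10, 5, dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
  expect_identical(flag_pca_outliers(const), character(0))
  expect_error(flag_pca_outliers(x[, 1:2, drop = FALSE]), "3 samples")
})

test_that("annotation readers validate structure", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsubtype\tsplit", "a\tBasal\tdiscovery",
               "b\tHer2\ttest"), p)
  expect_error(read_sample_annotation(p), "split")
  writeLines(c("isoform_id\tgene_id\tis_coding\tlength_nt",
               "i1\tg1\t1\t500", "i1\tg1\t0\t100"), p)
  expect_error(read_transcript_annotation(p), "duplicate")
  writeLines(c("isoform_id\tgene_id\tis_coding\tlength_nt",
               "i1\tg1\t1\t500", "i2\tg1\t0\t100"), p)
  ann <- read_transcript_annotation(p)
  expect_type(ann$is_coding, "logical")
})
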