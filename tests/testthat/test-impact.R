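impactFixture <- function() {
  mat <- rbind(
    target = c(20, 22, 21, 24, 25, 23),
    ref    = c(15, 16, 15.5, 15, 16, 15.2),
    other1 = c(18, 18.5, 19, 20, 21, 20.5),
    other2 = c(25, 24, 26, 23, 22, 24.5)
  )
  colnames(mat) <- paste0("s", 1:6)
  makeCt(mat, group = rep(c("PC", "DC"), each = 3))
}

test_that("delta-Ct normalization subtracts the reference per sample", {
  ce <- makeCt(rbind(t = c(20, 22), r = c(15, 16)))
  ne <- normalizeToReference(ce, "t", "r")
  expect_equal(ne$delta_ct, c(5, 6))
  expect_identical(attr(ne, "reference"), "r")

  expect_warning(selfNe <- normalizeToReference(ce, "t", "t"), "reference")
  expect_equal(selfNe$delta_ct, c(0, 0))

  ## anti-symmetry
  ce4 <- impactFixture()
  ab <- normalizeToReference(ce4, "target", "ref")
  ba <- normalizeToReference(ce4, "ref", "target")
  expect_equal(ab$delta_ct, -ba$delta_ct)

  expect_error(normalizeToReference(ce, "t", "nope"), "not present")
})

test_that("Grubbs' test matches the closed-form critical values", {
  g3 <- grubbsTest(c(1, 2, 3))
  expect_equal(g3$G, 1)
  expect_equal(g3$critical, 1.1543, tolerance = 1e-4)
  expect_false(g3$is_outlier)

  g4 <- grubbsTest(c(1, 1, 1, 10))
  expect_equal(g4$G, 1.5)
  expect_equal(g4$critical, 1.4812, tolerance = 1e-4)
  expect_true(g4$is_outlier)
  expect_equal(g4$outlier, 10)

  const <- grubbsTest(c(2, 2, 2))
  expect_false(const$is_outlier)
  expect_true(is.na(const$G))

  expect_error(grubbsTest(c(1, 2)), "at least 3")
})

test_that("group comparison is a pooled-variance Student t-test with tiers", {
  ne <- data.frame(sample = paste0("s", 1:6),
                   group = rep(c("A", "B"), each = 3),
                   delta_ct = c(1, 2, 3, 2, 3, 4))
  cmp <- compareGroups(ne, "A", "B")
  expect_equal(cmp$t, -1.2247, tolerance = 1e-4)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_value, 0.2878, tolerance = 1e-3)
  expect_identical(cmp$tier, "ns")

  ## sign anti-symmetry, p unchanged
  rev <- compareGroups(ne, "B", "A")
  expect_equal(rev$t, -cmp$t)
  expect_equal(rev$p_value, cmp$p_value)

  ## identical groups
  same <- data.frame(group = rep(c("A", "B"), each = 3),
                     delta_ct = rep(c(1, 2, 3), 2))
  cmp0 <- compareGroups(same, "A", "B")
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p_value, 1)

  expect_error(compareGroups(ne, "A", "Z"), "absent")
})

test_that("significance tiers map p-values to the published bands", {
  tiers <- vapply(c(5e-5, 5e-4, 0.005, 0.03, 0.08, 0.5),
                  miRGstab:::.significanceTier, character(1))
  expect_identical(tiers, c("****", "***", "**", "*", "#", "ns"))
})

test_that("Grubbs screening removes at most one point per group and is disclosed", {
  ne <- data.frame(group = rep(c("A", "B"), c(5, 4)),
                   delta_ct = c(1, 1.1, 0.9, 1, 8, 1, 1.2, 0.8, 1.1))
  flagged <- compareGroups(ne, "A", "B", screenOutliers = FALSE)
  expect_equal(flagged$outliers$A, 8)
  screened <- compareGroups(ne, "A", "B", screenOutliers = TRUE)
  expect_equal(screened$outliers$A, 8)
  expect_equal(screened$mean_a, mean(c(1, 1.1, 0.9, 1)), tolerance = 1e-12)
  expect_equal(screened$df, 6)  # one point removed from group A
  expect_equal(flagged$df, 7)
})

test_that("gene-gene correlation reports r, R2 and band", {
  ce <- impactFixture()
  self <- geneCorrelation(ce, "target", "target")
  expect_equal(self$r_squared, 1)

  anti <- makeCt(rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 1.5, 2)))
  rep <- geneCorrelation(anti, "a", "b")
  expect_equal(rep$r, -1)
  expect_equal(rep$r_squared, 1)
  expect_identical(rep$band, "very strong")
})

test_that("heatmap clustering matches a naive average-linkage oracle", {
  set.seed(55)
  for (seed in 1:6) {
    nG <- 4 + seed %% 3
    ct <- randomCt(nG + 1, 6, seed = 300 + seed)
    ce <- makeCt(ct)
    res <- clusterHeatmap(ce, reference = rownames(ct)[1])
    D <- as.matrix(1 - cor(t(res$matrix)))
    oracle <- naiveAverageLinkage(D)
    expect_equal(res$rowDendrogram$height, oracle$heights, tolerance = 1e-9)
    expect_identical(hclustMerges(res$rowDendrogram), oracle$merges)
  }
})

test_that("clustering is invariant to per-sample offsets and row affine maps", {
  ct <- randomCt(6, 6, seed = 66)
  ce <- makeCt(ct)
  res <- clusterHeatmap(ce, reference = "g1")

  offs <- seq(-3, 2, length.out = 6)
  ceOff <- makeCt(sweep(ct, 2, offs, "+"))
  resOff <- clusterHeatmap(ceOff, reference = "g1")
  expect_equal(res$rowDendrogram$height, resOff$rowDendrogram$height,
               tolerance = 1e-9)
  expect_identical(hclustMerges(res$rowDendrogram),
                   hclustMerges(resOff$rowDendrogram))
  expect_equal(res$matrix, resOff$matrix, tolerance = 1e-9)

  ## correlation distance is zero under positive-slope affine transforms
  x <- res$matrix[1, ]
  expect_equal(1 - cor(x, 3.2 * x + 7), 0, tolerance = 1e-12)

  ## identical gene rows merge first at distance 0
  dup <- rbind(ct, g7 = ct["g2", ] + 1)  # duplicate profile of g2
  resDup <- clusterHeatmap(makeCt(dup), reference = "g1")
  expect_equal(resDup$rowDendrogram$height[1], 0, tolerance = 1e-12)
  expect_identical(hclustMerges(resDup$rowDendrogram)[[1]],
                   c("g2", "g7"))
})

test_that("zero-variance rows are excluded from the dendrogram with a warning", {
  ct <- randomCt(5, 5, seed = 70)
  ct["g3", ] <- ct["g1", ] + 2  # constant delta-Ct against reference g1
  expect_warning(res <- clusterHeatmap(makeCt(ct), reference = "g1"), "g3")
  expect_identical(res$dropped_rows, "g3")
  expect_false("g3" %in% res$rowDendrogram$labels)
  expect_true("g3" %in% rownames(res$matrix))
})
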