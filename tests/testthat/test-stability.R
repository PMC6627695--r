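toyCt <- function() {
  makeCt(rbind(g1 = c(20, 20, 20), g2 = c(20, 21, 22), g3 = c(20, 19, 18)))
}

test_that("relative quantities follow (1+E)^(Ctmin - Ct)", {
  ce <- makeCt(matrix(c(20, 21, 22), 1))
  expect_equal(unname(relativeQuantities(ce)[1, ]), c(1, 0.5, 0.25))
  expect_equal(unname(relativeQuantities(ce, efficiency = 0.9)[1, ]),
               c(1, 1.9^-1, 1.9^-2), tolerance = 1e-12)
  const <- makeCt(matrix(rep(18, 4), 1))
  expect_equal(unname(relativeQuantities(const)[1, ]), rep(1, 4))
  expect_error(relativeQuantities(ce, efficiency = 1.5), "\\(0, 1\\]")
  expect_error(relativeQuantities(ce, efficiency = 0), "\\(0, 1\\]")

  q <- relativeQuantities(makeCt(randomCt(6, 5, seed = 3)))
  expect_equal(unname(apply(q, 1, max)), rep(1, 6))
  expect_true(all(q > 0 & q <= 1))
})

test_that("BestKeeper dispersion is the mean absolute deviation of Ct", {
  ce <- makeCt(rbind(g1 = c(19, 21), g2 = c(20, 20), g3 = c(15, 19)))
  bk <- bestKeeper(ce)
  expect_equal(bk$value[match(c("g2", "g1", "g3"), bk$gene)], c(0, 1, 2))
  expect_equal(bk$rank[match(c("g2", "g1", "g3"), bk$gene)], c(1L, 2L, 3L))
  expect_equal(bk$cv_pct[bk$gene == "g1"], 100 * 1 / 20)
})

test_that("geNorm reproduces the worked three-gene example exactly", {
  gn <- geNorm(toyCt())
  M <- setNames(gn$table$value, gn$table$gene)
  expect_equal(M[c("g1", "g2", "g3")], c(g1 = 1, g2 = 1.5, g3 = 1.5))
  ## tie at the first exclusion removes the later gene (g3)
  expect_identical(gn$trace$excluded, "g3")
  expect_identical(sort(gn$finalPair), c("g1", "g2"))
  expect_equal(gn$finalM, 1)
  rk <- setNames(gn$table$rank, gn$table$gene)
  expect_identical(rk[c("g1", "g2", "g3")], c(g1 = 1L, g2 = 2L, g3 = 3L))
})

test_that("delta-Ct stability equals the mean pairwise SD on the toy example", {
  dt <- deltaCtStability(toyCt())
  v <- setNames(dt$value, dt$gene)
  expect_equal(v[c("g1", "g2", "g3")], c(g1 = 1, g2 = 1.5, g3 = 1.5))

  dup <- makeCt(rbind(a = c(20, 21, 23), b = c(22, 23, 25)))
  expect_equal(deltaCtStability(dup)$value, c(0, 0))
})

test_that("geNorm stepwise exclusion matches a from-scratch oracle (n <= 6)", {
  for (seed in 1:12) {
    n <- 3 + (seed %% 4)
    ct <- randomCt(n, 8, seed = 100 + seed)
    gn <- geNorm(makeCt(ct))
    oracle <- naiveGeNorm(ct)
    expect_identical(gn$trace$excluded, oracle$excluded)
    expect_identical(gn$finalPair, oracle$finalPair)
    expect_equal(gn$finalM, oracle$finalM, tolerance = 1e-9)
    got <- setNames(gn$table$rank, gn$table$gene)
    expect_identical(got[names(oracle$ranks)], oracle$ranks)
  }
})

test_that("delta-Ct matches its naive oracle and the geNorm cross-identity", {
  for (seed in 1:5) {
    ct <- randomCt(10, 12, seed = 200 + seed)
    dt <- deltaCtStability(makeCt(ct))
    oracle <- naiveDeltaCt(ct)
    expect_equal(setNames(dt$value, dt$gene)[names(oracle)], oracle,
                 tolerance = 1e-9)
  }
})

test_that("NormFinder collapses to zero on identical genes and recovers shifts", {
  ## identical rows plus arbitrary per-sample offsets: everything vanishes
  base <- c(20, 21, 19, 22, 20, 21.5, 18, 23)
  mat <- matrix(rep(base, each = 4), 4, byrow = FALSE)
  dimnames(mat) <- list(paste0("g", 1:4), paste0("s", 1:8))
  ce <- makeCt(mat, group = rep(c("A", "B"), each = 4))
  nf <- normFinder(ce, useGroups = TRUE)
  expect_equal(nf$table$value, rep(0, 4), tolerance = 1e-12)
  expect_equal(max(abs(colSums(nf$result$d))), 0, tolerance = 1e-12)
  nf1 <- normFinder(ce, useGroups = FALSE)
  expect_equal(nf1$table$value, rep(0, 4), tolerance = 1e-12)

  expect_error(normFinder(ce[, 1:4], useGroups = TRUE), ">= 2 groups")

  ## a +2-cycle shift in one group makes that gene the least stable
  cfg <- synthConfig(nGenes = 20L, nStable = 0L, nUnstableVar = 0L,
                     nShifted = 1L, shiftSize = 2, noiseRange = c(0.8, 0.8))
  hits <- vapply(1:200, function(r) {
    sim <- simulateCtExperiment(cfg, seed = 5000 + r)
    nf <- normFinder(sim$experiment, useGroups = TRUE)
    worst <- nf$table$gene[nf$table$rank == nrow(nf$table)]
    sim$truth$role[worst] == "group_shifted"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("per-sample offsets cancel in ratio methods but not in BestKeeper", {
  ct <- randomCt(8, 10, seed = 77)
  ce <- makeCt(ct, group = rep(c("A", "B"), each = 5))
  offs <- seq(-2, 2.5, length.out = 10)
  ceOff <- makeCt(sweep(ct, 2, offs, "+"), group = ce$group)

  for (fn in list(
    function(x) geNorm(x)$table,
    deltaCtStability,
    function(x) normFinder(x, useGroups = TRUE)$table
  )) {
    a <- fn(ce); b <- fn(ceOff)
    expect_lt(max(abs(a$value - b$value[match(a$gene, b$gene)])), 1e-9)
  }
  bk0 <- bestKeeper(ce); bk1 <- bestKeeper(ceOff)
  expect_gt(max(abs(bk0$value - bk1$value[match(bk0$gene, bk1$gene)])), 0.1)
})

test_that("scaling per-gene deviations by alpha scales BestKeeper and delta-Ct", {
  ct <- randomCt(6, 9, seed = 88)
  alpha <- 2.5
  scaled <- rowMeans(ct) + alpha * (ct - rowMeans(ct))
  a <- bestKeeper(makeCt(ct)); b <- bestKeeper(makeCt(scaled))
  expect_equal(b$value[match(a$gene, b$gene)], alpha * a$value,
               tolerance = 1e-12)
  a <- deltaCtStability(makeCt(ct)); b <- deltaCtStability(makeCt(scaled))
  expect_equal(b$value[match(a$gene, b$gene)], alpha * a$value,
               tolerance = 1e-9)
})

test_that("inflating one gene's noise never improves its rank under any method", {
  set.seed(99)
  nG <- 10; nS <- 12
  base <- runif(nG, 15, 25)
  eps <- matrix(rnorm(nG * nS), nG, nS)
  group <- rep(c("A", "B"), each = 6)
  rankAt <- function(alpha) {
    mat <- base + eps
    mat[1, ] <- base[1] + alpha * eps[1, ]
    dimnames(mat) <- list(paste0("g", 1:nG), paste0("s", 1:nS))
    ce <- makeCt(mat, group = group)
    tabs <- runAllStability(ce, dataset = "pooled")
    vapply(tabs, function(t) t$rank[t$gene == "g1"], integer(1))
  }
  ranks <- vapply(c(0.5, 1, 2, 4), rankAt, integer(4))
  for (m in seq_len(nrow(ranks))) {
    expect_true(all(diff(ranks[m, ]) >= 0), info = rownames(ranks)[m])
  }
})

test_that("runAllStability handles toy, constant and per-tissue datasets", {
  tabs <- runAllStability(makeCt(rbind(g1 = c(20, 20, 20),
                                       g2 = c(20, 21, 22),
                                       g3 = c(20, 19, 18))))
  expect_named(tabs, c("bestkeeper", "genorm", "deltact", "normfinder"))
  for (t in tabs) expect_setequal(t$rank, 1:3)

  constant <- makeCt(matrix(rep(c(20, 18, 22), 4), 3,
                            dimnames = list(paste0("g", 1:3),
                                            paste0("s", 1:4))))
  tabs <- runAllStability(constant)
  for (t in tabs) expect_equal(t$value, rep(0, 3), tolerance = 1e-12)

  sim <- simulateCtExperiment(synthConfig(), seed = 4L)
  perTissue <- runAllStability(sim$experiment, dataset = "PC")
  expect_identical(unique(perTissue$genorm$dataset), "PC")
  expect_setequal(perTissue$normfinder$rank, 1:47)
  expect_error(runAllStability(sim$experiment, dataset = "XX"), "group label")
})
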