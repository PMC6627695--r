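## Fixture builders and independent brute-force oracles.  The oracles
## deliberately recompute everything from scratch with naive loops so they
## share no code path with the package implementations.

makeCt <- function(mat, group = NULL, donor = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  if (is.null(group)) group <- rep("all", ncol(mat))
  CtExperiment(mat, group = group, donor = donor)
}

randomCt <- function(nGenes, nSamples, seed, lo = 14, hi = 26, sd = 1) {
  set.seed(seed)
  base <- runif(nGenes, lo, hi)
  mat <- base + matrix(rnorm(nGenes * nSamples, sd = sd), nGenes, nSamples)
  dimnames(mat) <- list(paste0("g", seq_len(nGenes)),
                        paste0("s", seq_len(nSamples)))
  mat
}

## naive geNorm: pairwise SD of log2 ratios recomputed from scratch each
## exclusion round; ties exclude the later gene in input order
naiveGeNorm <- function(ct) {
  y <- -ct  # log2 q at E = 1, up to a per-gene constant that SD ignores
  genes <- rownames(ct)
  pairSD <- function(j, k) sd(y[j, ] - y[k, ])
  alive <- genes
  excluded <- character()
  Mfinal3 <- NULL
  while (length(alive) > 2L) {
    M <- vapply(alive, function(j) {
      mean(vapply(setdiff(alive, j), function(k) pairSD(j, k), numeric(1)))
    }, numeric(1))
    if (length(alive) == 3L) Mfinal3 <- M
    worst <- names(M)[M >= max(M) - 1e-12]
    drop <- worst[length(worst)]
    excluded <- c(excluded, drop)
    alive <- setdiff(alive, drop)
  }
  pairM <- Mfinal3[alive]
  ord <- alive[order(pairM, match(alive, genes))]
  ranks <- setNames(integer(length(genes)), genes)
  ranks[ord] <- c(1L, 2L)
  ranks[rev(excluded)] <- seq(3L, length(genes))
  list(excluded = excluded, finalPair = alive,
       finalM = pairSD(alive[1L], alive[2L]), ranks = ranks)
}

## naive delta-Ct: mean over partners of sd of per-sample Ct differences
naiveDeltaCt <- function(ct) {
  genes <- rownames(ct)
  vapply(genes, function(g) {
    mean(vapply(setdiff(genes, g),
                function(h) sd(ct[g, ] - ct[h, ]), numeric(1)))
  }, numeric(1))
}

## naive average-linkage agglomeration on a symmetric distance matrix;
## returns merge heights and the leaf set formed at each merge
naiveAverageLinkage <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  heights <- numeric()
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bestD <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_len(a - 1L)) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < bestD - 1e-12) {
          bestD <- d
          best <- c(b, a)
        }
      }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    heights <- c(heights, bestD)
    merges[[length(merges) + 1L]] <- sort(merged)
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

## leaf sets formed at each merge of an hclust tree
hclustMerges <- function(h) {
  sets <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    grab <- function(v) {
      if (v < 0) h$labels[-v] else sets[[v]]
    }
    sets[[i]] <- sort(c(grab(h$merge[i, 1L]), grab(h$merge[i, 2L])))
  }
  sets
}
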