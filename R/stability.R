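## The four reference-gene stability estimators.  All pairwise-SD machinery
## (geNorm V_jk, delta-Ct) runs on the covariance matrix of log2 relative
## quantities over samples: sd(y_j - y_k) = sqrt(C_jj + C_kk - 2 C_jk),
## which is exact and makes stepwise exclusion a subset operation.

.checkEfficiency <- function(efficiency, genes) {
  if (is.null(names(efficiency))) {
    if (length(efficiency) == 1L) {
      efficiency <- rep(efficiency, length(genes))
    }
    if (length(efficiency) != length(genes)) {
      stop("efficiency must be scalar or one value per gene")
    }
    names(efficiency) <- genes
  } else {
    if (!all(genes %in% names(efficiency))) {
      stop("efficiency map is missing genes: ",
           paste(setdiff(genes, names(efficiency)), collapse = ", "))
    }
    efficiency <- efficiency[genes]
  }
  if (any(efficiency <= 0 | efficiency > 1)) {
    stop("amplification efficiency must lie in (0, 1]")
  }
  efficiency
}

.completeCt <- function(x) {
  ct <- ctValues(x)
  if (anyNA(ct)) {
    stop("Ct matrix contains undetected calls; run filterCompleteDetection() first")
  }
  ct
}

## log2 relative quantity: log2 q_gs = (Ctmin_g - Ct_gs) * log2(1 + E_g)
.log2RelQuant <- function(ct, efficiency) {
  eff <- .checkEfficiency(efficiency, rownames(ct))
  (apply(ct, 1L, min) - ct) * log2(1 + eff)
}

#' Relative quantities from Ct values
#'
#' Transforms quantification cycles into relative quantities
#' \eqn{q_{gs} = (1+E_g)^{Ct_{min,g} - Ct_{gs}}}, where \eqn{E_g} is the
#' gene's amplification efficiency (default 1, i.e. perfect doubling and
#' \eqn{q = 2^{-\Delta Ct}}) and \eqn{Ct_{min,g}} is the gene's minimum
#' cycle over the analyzed samples, so the most abundant sample of each
#' gene has \eqn{q = 1}.
#'
#' @param x a complete \linkS4class{CtExperiment}
#' @param efficiency scalar or per-gene named vector in (0, 1].
#' @return A genes x samples numeric matrix of relative quantities in
#'   (0, 1], with a per-row maximum of exactly 1.
#' @examples
#' ce <- CtExperiment(matrix(c(20, 21, 22), 1,
#'                    dimnames = list("g", c("a", "b", "c"))),
#'                    group = rep("all", 3))
#' relativeQuantities(ce)  # 1, 0.5, 0.25
#' @export
relativeQuantities <- function(x, efficiency = 1) {
  ct <- .completeCt(x)
  2^.log2RelQuant(ct, efficiency)
}

.stabilityTable <- function(method, dataset, gene, value, extra = NULL) {
  out <- data.frame(method = method, dataset = dataset, gene = gene,
                    value = as.numeric(value),
                    rank = rank(value, ties.method = "first"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' BestKeeper dispersion ranking
#'
#' BestKeeper works on raw Ct values: each candidate's dispersion is the
#' mean absolute deviation of its Ct around the gene's arithmetic mean
#' (the applet's "SD (+/- Ct)"), with the coefficient of variation
#' \code{cv_pct = 100 * dispersion / mean} reported as an auxiliary
#' diagnostic.  Lower dispersion = more stable; genes are ranked ascending.
#' Because it uses Ct directly, BestKeeper is sensitive to per-sample
#' technical offsets that the ratio-based estimators cancel.
#'
#' @param x a complete \linkS4class{CtExperiment}
#' @param dataset label stored in the output (defaults to \code{"pooled"}).
#' @return A stability table: \code{data.frame} with columns
#'   \code{method}, \code{dataset}, \code{gene}, \code{value}, \code{rank},
#'   \code{cv_pct}, sorted by rank.
#' @export
bestKeeper <- function(x, dataset = "pooled") {
  ct <- .completeCt(x)
  if (ncol(ct) < 2L) stop("need at least 2 samples")
  mu <- rowMeans(ct)
  mad <- rowMeans(abs(ct - mu))
  .stabilityTable("bestkeeper", dataset, rownames(ct), mad,
                  extra = data.frame(cv_pct = 100 * mad / mu))
}

## pairwise SD matrix of log2-ratio fold changes between genes
.pairwiseV <- function(y) {
  C <- stats::cov(t(y))
  v <- diag(C)
  V <- sqrt(pmax(outer(v, v, "+") - 2 * C, 0))
  diag(V) <- 0
  V
}

#' geNorm stability value M by stepwise exclusion
#'
#' For each gene pair the pairwise variation \eqn{V_{jk}} is the sample
#' standard deviation (n-1) of the log2 expression ratio across samples;
#' a gene's M value is the mean of its pairwise variations with all other
#' remaining candidates.  The gene with the largest M is excluded and M is
#' recomputed, down to the final, most stable pair, which shares the final
#' M.  Ranks follow reverse exclusion order; the final pair takes ranks 1
#' and 2 ordered by M in the last three-gene iteration.  Ties at any
#' exclusion step remove the gene occurring later in input order.
#'
#' @param x a complete \linkS4class{CtExperiment} with >= 3 genes and
#'   >= 2 samples
#' @param efficiency scalar or per-gene named vector in (0, 1].
#' @param dataset label stored in the output.
#' @return A list with \code{table} (stability table of the initial
#'   full-panel M values and final ranks), \code{trace} (\code{data.frame}
#'   of \code{step}, \code{excluded}, \code{M} at exclusion),
#'   \code{finalPair} and \code{finalM}.
#' @references Vandesompele et al. (2002) Genome Biology 3:research0034.
#' @export
geNorm <- function(x, efficiency = 1, dataset = "pooled") {
  ct <- .completeCt(x)
  if (nrow(ct) < 3L) stop("geNorm needs at least 3 genes")
  if (ncol(ct) < 2L) stop("geNorm needs at least 2 samples")
  y <- .log2RelQuant(ct, efficiency)
  genes <- rownames(ct)
  V <- .pairwiseV(y)
  n <- length(genes)

  initialM <- rowSums(V) / (n - 1)
  names(initialM) <- genes

  alive <- seq_len(n)
  trace <- data.frame(step = integer(), excluded = character(),
                      M = numeric(), stringsAsFactors = FALSE)
  lastTripleM <- NULL
  step <- 0L
  while (length(alive) > 2L) {
    M <- rowSums(V[alive, alive, drop = FALSE]) / (length(alive) - 1L)
    if (length(alive) == 3L) lastTripleM <- stats::setNames(M, genes[alive])
    worst <- max(M)
    drop <- max(which(M >= worst - 1e-12))  # tie: later input order
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     excluded = genes[alive[drop]],
                                     M = M[drop], stringsAsFactors = FALSE))
    alive <- alive[-drop]
  }
  finalM <- V[alive[1L], alive[2L]]
  finalPair <- genes[alive]

  ## final pair ordered by M in the last 3-gene iteration (tie: input order)
  mPair <- lastTripleM[finalPair]
  pairOrder <- order(mPair, seq_along(mPair))
  rk <- integer(n)
  names(rk) <- genes
  rk[finalPair[pairOrder]] <- c(1L, 2L)
  rk[rev(trace$excluded)] <- seq(3L, n)

  tab <- data.frame(method = "genorm", dataset = dataset, gene = genes,
                    value = unname(initialM), rank = unname(rk[genes]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, trace = trace, finalPair = finalPair, finalM = finalM)
}

#' Comparative delta-Ct stability
#'
#' Scores each candidate by the mean, over all other candidates, of the
#' sample standard deviation (n-1) of the pairwise delta-Ct (log2
#' expression difference) across samples.  With perfect efficiency this is
#' exactly the mean of geNorm's pairwise variations computed on the full
#' panel, but without stepwise exclusion.  Lower = more stable.
#'
#' @inheritParams geNorm
#' @return A stability table (\code{method = "deltact"}).
#' @references Silver et al. (2006) BMC Molecular Biology 7:33.
#' @export
deltaCtStability <- function(x, efficiency = 1, dataset = "pooled") {
  ct <- .completeCt(x)
  if (nrow(ct) < 2L) stop("need at least 2 genes")
  if (ncol(ct) < 2L) stop("need at least 2 samples")
  y <- .log2RelQuant(ct, efficiency)
  V <- .pairwiseV(y)
  value <- rowSums(V) / (nrow(ct) - 1L)
  .stabilityTable("deltact", dataset, rownames(ct), value)
}

#' NormFinder model-based stability
#'
#' Fits the two-way model of Andersen et al. on log2 relative quantities:
#' per-sample technical effects are removed by subtracting each sample's
#' mean over genes, then each gene's intragroup variance
#' \eqn{\hat\sigma^2_{ig}} is estimated with a finite-panel bias
#' correction (clipped at zero), and, in multi-group mode, its intergroup
#' deviation \eqn{d_{ig}} (doubly centered, so deviations sum to zero over
#' genes within each group and over groups within each gene) is shrunk
#' toward zero in proportion to its estimation variance.  The stability
#' value averages, over groups, the magnitude of the shrunk deviation plus
#' the intragroup standard error \eqn{\sqrt{\hat\sigma^2_{ig}/n_g}}.  In
#' single-group mode (used for one tissue at a time) the stability is
#' simply \eqn{\sqrt{\hat\sigma^2_g}}.  Lower = more stable.
#'
#' @inheritParams geNorm
#' @param useGroups if \code{TRUE} (default) use the \code{group} factor of
#'   \code{x} for the intra/intergroup decomposition; requires >= 2 groups
#'   of >= 2 samples.  If \code{FALSE}, single-group mode.
#' @return A list with \code{table} (stability table,
#'   \code{method = "normfinder"}) and \code{result}, a list holding the
#'   per-gene-per-group \code{sigma2} matrix and, in multi-group mode,
#'   the raw (\code{d}) and shrunk (\code{dShrunk}) intergroup deviations
#'   and the intergroup variance estimate \code{gamma2}.
#' @references Andersen, Jensen & Orntoft (2004) Cancer Research 64:5245.
#' @export
normFinder <- function(x, efficiency = 1, useGroups = TRUE,
                       dataset = "pooled") {
  ct <- .completeCt(x)
  k <- nrow(ct)
  if (k < 3L) stop("NormFinder needs at least 3 genes")
  y <- .log2RelQuant(ct, efficiency)
  z <- sweep(y, 2L, colMeans(y))  # remove per-sample effects
  genes <- rownames(ct)

  groups <- if (useGroups) droplevels(x$group) else
    factor(rep("all", ncol(ct)))
  ng <- table(groups)
  if (useGroups) {
    if (nlevels(groups) < 2L) stop("useGroups requires >= 2 groups")
    if (any(ng < 2L)) {
      stop("singleton group(s): ",
           paste(names(ng)[ng < 2L], collapse = ", "))
    }
  } else if (any(ng < 2L)) {
    stop("need at least 2 samples")
  }
  G <- nlevels(groups)

  sigma2 <- matrix(NA_real_, k, G, dimnames = list(genes, levels(groups)))
  zbar <- sigma2
  for (g in levels(groups)) {
    zg <- z[, groups == g, drop = FALSE]
    zbar[, g] <- rowMeans(zg)
    s2 <- apply(zg, 1L, stats::var)
    ## unbiased under the two-way model: E[s2_i] = (1-2/k) sigma2_i + mean/k
    sigma2[, g] <- pmax(0, k / (k - 2) * (s2 - mean(s2) / (k - 1)))
  }

  if (G == 1L) {
    rho <- sqrt(sigma2[, 1L])
    result <- list(sigma2 = sigma2, d = NULL, dShrunk = NULL, gamma2 = NULL)
  } else {
    d <- zbar - rowMeans(zbar)
    v <- sweep(sigma2, 2L, as.numeric(ng[colnames(sigma2)]), "/")
    gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(v))
    shrink <- if (gamma2 > 0) gamma2 / (gamma2 + v) else 0 * v
    dShrunk <- d * shrink
    rho <- rowMeans(abs(dShrunk) + sqrt(v))
    result <- list(sigma2 = sigma2, d = d, dShrunk = dShrunk,
                   gamma2 = gamma2)
  }
  list(table = .stabilityTable("normfinder", dataset, genes, rho),
       result = result)
}

.selectDataset <- function(x, dataset) {
  if (identical(dataset, "pooled")) return(x)
  if (!(dataset %in% levels(x$group))) {
    stop("dataset must be \"pooled\" or a group label; got: ", dataset)
  }
  x[, x$group == dataset]
}

#' Run all four stability estimators on one dataset
#'
#' Executes BestKeeper, geNorm, the comparative delta-Ct method and
#' NormFinder on a selected sample subset with consistent gene ordering.
#' The pooled dataset runs NormFinder in multi-group mode (the group
#' factor supplies the intergroup decomposition); a single-tissue dataset
#' runs it in single-group mode.
#'
#' @param x a complete \linkS4class{CtExperiment}
#' @param dataset \code{"pooled"} (all samples) or one group label.
#' @param efficiency scalar or per-gene named vector in (0, 1].
#' @return A named list of four stability tables
#'   (\code{bestkeeper}, \code{genorm}, \code{deltact},
#'   \code{normfinder}); the geNorm trace and NormFinder decomposition are
#'   attached as attributes \code{"genorm_fit"} and \code{"normfinder_fit"}.
#' @examples
#' ce <- simulateCtExperiment(synthConfig(), seed = 11L)$experiment
#' tabs <- runAllStability(ce, dataset = "pooled")
#' head(tabs$genorm)
#' @export
runAllStability <- function(x, dataset = "pooled", efficiency = 1) {
  xs <- .selectDataset(x, dataset)
  gn <- geNorm(xs, efficiency, dataset = dataset)
  multiGroup <- identical(dataset, "pooled") &&
    nlevels(droplevels(xs$group)) >= 2L
  nf <- normFinder(xs, efficiency, useGroups = multiGroup,
                   dataset = dataset)
  out <- list(
    bestkeeper = bestKeeper(xs, dataset = dataset),
    genorm = gn$table,
    deltact = deltaCtStability(xs, efficiency, dataset = dataset),
    normfinder = nf$table
  )
  attr(out, "genorm_fit") <- gn
  attr(out, "normfinder_fit") <- nf$result
  out
}
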