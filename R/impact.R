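## How the choice of reference gene changes downstream conclusions:
## delta-Ct normalization, group testing with outlier screening,
## gene-gene correlation, and correlation-distance clustering.

#' Normalize a target gene against a reference gene
#'
#' Per-sample \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}; lower values
#' mean more target relative to the reference.  Group labels are carried
#' along for testing and plotting.
#'
#' @param x a \linkS4class{CtExperiment}; both genes must be completely
#'   detected.
#' @param target,reference gene identifiers present in \code{x}.
#' @return A \code{data.frame} with columns \code{sample}, \code{group},
#'   \code{delta_ct}, plus attributes \code{target} and \code{reference}.
#'   Normalizing a gene against itself is allowed (all zeros) but raises a
#'   warning.
#' @export
normalizeToReference <- function(x, target, reference) {
  ct <- ctValues(x)
  for (g in c(target, reference)) {
    if (!(g %in% rownames(ct))) stop("gene not present: ", g)
    if (anyNA(ct[g, ])) stop("gene not completely detected: ", g)
  }
  if (identical(target, reference)) {
    warning("target equals reference; all delta-Ct values are zero")
  }
  out <- data.frame(
    sample = colnames(ct),
    group = as.character(x$group),
    delta_ct = ct[target, ] - ct[reference, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "target") <- target
  attr(out, "reference") <- reference
  out
}

#' Grubbs' test for a single outlier
#'
#' Two-sided Grubbs' test: \eqn{G = \max_i |x_i - \bar x| / s} (n-1
#' standard deviation), compared with the critical value
#' \eqn{\frac{N-1}{\sqrt N}\sqrt{t^2 / (N - 2 + t^2)}} where \eqn{t} is
#' the upper \eqn{\alpha/(2N)} Student-t quantile on \eqn{N-2} degrees of
#' freedom.  Flags the most extreme point iff \eqn{G} exceeds the
#' critical value.
#'
#' @param x numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @return A list with \code{G}, \code{critical}, \code{outlier} (the
#'   flagged value or \code{NA}), \code{index}, and \code{is_outlier}.
#'   A zero-variance vector yields \code{G = NA} and no outlier.
#' @examples
#' grubbsTest(c(1, 1, 1, 10))  # G = 1.5 > 1.4812: outlier
#' @export
grubbsTest <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3L) stop("Grubbs' test needs at least 3 observations")
  s <- stats::sd(x)
  if (s == 0) {
    return(list(G = NA_real_, critical = NA_real_, outlier = NA_real_,
                index = NA_integer_, is_outlier = FALSE))
  }
  dev <- abs(x - mean(x))
  idx <- which.max(dev)
  G <- dev[idx] / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  critical <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  flag <- G > critical
  list(G = G, critical = critical,
       outlier = if (flag) x[idx] else NA_real_,
       index = if (flag) idx else NA_integer_,
       is_outlier = flag)
}

.significanceTier <- function(p) {
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**"
  else if (p <= 0.05) "*"
  else if (p <= 0.1) "#"
  else "ns"
}

#' Compare normalized expression between two groups
#'
#' Unpaired two-tailed Student's t-test with pooled variance on the
#' \eqn{\Delta Ct} values of two groups, with optional single-pass
#' two-sided Grubbs screening (at most one point removed per group,
#' alpha = 0.05) before testing.  Screening is off by default; flagged
#' points are always reported.  Significance tiers: **** p <= 1e-4,
#' *** p <= 1e-3, ** p <= 0.01, * p <= 0.05, # for the trend band
#' 0.05 < p <= 0.1, otherwise ns.
#'
#' @param ne a normalized-expression table from [normalizeToReference()].
#' @param groupA,groupB group labels.
#' @param screenOutliers remove (not just flag) a Grubbs outlier per group.
#' @return A list with \code{groups}, \code{t}, \code{df}, \code{p_value},
#'   \code{tier}, \code{mean_a}, \code{mean_b}, and \code{outliers}
#'   (named list of flagged values per group, post-screening disclosure).
#' @export
compareGroups <- function(ne, groupA, groupB, screenOutliers = FALSE) {
  xa <- ne$delta_ct[ne$group == groupA]
  xb <- ne$delta_ct[ne$group == groupB]
  if (length(xa) == 0L || length(xb) == 0L) {
    stop("group absent from normalized table")
  }
  outliers <- list()
  for (nm in c(groupA, groupB)) {
    v <- if (nm == groupA) xa else xb
    gt <- if (length(v) >= 3L) grubbsTest(v) else
      list(is_outlier = FALSE, outlier = NA_real_, index = NA_integer_)
    outliers[[nm]] <- if (gt$is_outlier) gt$outlier else numeric()
    if (screenOutliers && gt$is_outlier) {
      if (nm == groupA) xa <- xa[-gt$index] else xb <- xb[-gt$index]
    }
  }
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("need >= 2 samples per group after screening")
  }
  df0 <- length(xa) + length(xb) - 2
  if (stats::sd(c(xa - mean(xa), xb - mean(xb))) == 0) {
    ## degenerate pooled variance: equal means give t = 0, otherwise the
    ## difference is infinitely many pooled SDs away
    tt <- if (mean(xa) == mean(xb)) {
      list(statistic = c(t = 0), parameter = df0, p.value = 1)
    } else {
      list(statistic = c(t = sign(mean(xa) - mean(xb)) * Inf),
           parameter = df0, p.value = 0)
    }
  } else {
    tt <- stats::t.test(xa, xb, var.equal = TRUE)
  }
  p <- tt$p.value
  list(groups = c(groupA, groupB),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = p, tier = .significanceTier(p),
       mean_a = mean(xa), mean_b = mean(xb),
       outliers = outliers)
}

#' Pearson correlation between two genes' Ct profiles
#'
#' @param x a \linkS4class{CtExperiment}
#' @param geneA,geneB gene identifiers, completely detected.
#' @return A list with \code{r}, \code{r_squared}, \code{band} and
#'   \code{n_samples}.
#' @export
geneCorrelation <- function(x, geneA, geneB) {
  ct <- ctValues(x)
  for (g in c(geneA, geneB)) {
    if (!(g %in% rownames(ct))) stop("gene not present: ", g)
    if (anyNA(ct[g, ])) stop("gene not completely detected: ", g)
  }
  if (ncol(ct) < 3L) stop("need at least 3 samples")
  r <- stats::cor(ct[geneA, ], ct[geneB, ])
  list(r = r, r_squared = r^2, band = correlationBand(r^2),
       n_samples = ncol(ct))
}

## correlation distance (1 - Pearson r) between rows of m
.correlationDist <- function(m) {
  stats::as.dist(1 - stats::cor(t(m)))
}

#' Reference-normalized heatmap clustering
#'
#' Reproduces the clustering behind reference-gene impact heatmaps:
#' (1) every gene is normalized against the chosen reference
#' (per-sample \eqn{\Delta Ct}) and the reference row is dropped;
#' (2) each row is centered to mean zero; (3) pairwise distance is
#' 1 - Pearson correlation; (4) rows and columns are clustered by
#' average-linkage agglomeration.  Rows whose centered values have zero
#' variance have undefined correlation distance; they are excluded from
#' the row dendrogram with a warning and reported.
#'
#' @param x a complete \linkS4class{CtExperiment} with >= 3 genes
#'   (besides the reference) and >= 3 samples.
#' @param reference reference gene identifier.
#' @return A list with \code{rowDendrogram} and \code{colDendrogram}
#'   (\code{\link[stats]{hclust}} objects), \code{matrix} (the row-centered
#'   \eqn{\Delta Ct} matrix actually clustered), and
#'   \code{dropped_rows} (zero-variance rows excluded from clustering).
#' @export
clusterHeatmap <- function(x, reference) {
  ct <- .completeCt(x)
  if (!(reference %in% rownames(ct))) stop("gene not present: ", reference)
  norm <- sweep(ct[setdiff(rownames(ct), reference), , drop = FALSE],
                2L, ct[reference, ])
  if (nrow(norm) < 3L || ncol(norm) < 3L) {
    stop("need at least 3 non-reference genes and 3 samples")
  }
  centered <- norm - rowMeans(norm)
  rowVar <- apply(centered, 1L, stats::var)
  zero <- rowVar < 1e-20  # numerically constant after centering
  dropped <- rownames(centered)[zero]
  if (length(dropped)) {
    warning("zero-variance row(s) excluded from clustering: ",
            paste(dropped, collapse = ", "))
  }
  keep <- centered[!zero, , drop = FALSE]
  colVar <- apply(keep, 2L, stats::var)
  if (any(colVar == 0)) {
    stop("zero-variance sample column(s); correlation distance undefined")
  }
  list(
    rowDendrogram = stats::hclust(.correlationDist(keep), method = "average"),
    colDendrogram = stats::hclust(.correlationDist(t(keep)),
                                  method = "average"),
    matrix = centered,
    dropped_rows = dropped
  )
}
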