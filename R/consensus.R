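#' Geometric-mean consensus ranking
#'
#' Combines the integer ranks produced by several stability estimators
#' into a comprehensive stability ordering: each gene's score is the
#' geometric mean of its per-method ranks (never the raw stability
#' values), and the final consensus rank orders genes by ascending
#' geomean.  Ties in geomean are broken by the better comparative
#' delta-Ct rank (when present), then by input gene order.
#'
#' @param tables list of stability tables (as returned by the estimator
#'   functions or [runAllStability()]) covering an identical gene set on
#'   the same dataset; two or more methods required.
#' @return A \code{data.frame} with one \code{rank_<method>} column per
#'   input method, plus \code{geomean} and \code{consensus_rank}, ordered
#'   by consensus rank.
#' @examples
#' ce <- simulateCtExperiment(synthConfig(), seed = 3L)$experiment
#' head(combineRankings(runAllStability(ce)))
#' @export
combineRankings <- function(tables) {
  if (length(tables) < 1L) stop("need at least one stability table")
  methods <- vapply(tables, function(t) t$method[1L], character(1))
  if (anyDuplicated(methods)) stop("duplicate methods in input tables")
  genes <- tables[[1L]]$gene
  for (t in tables) {
    if (!setequal(t$gene, genes) || anyDuplicated(t$gene) ||
        length(t$gene) != length(genes)) {
      stop("gene sets differ between tables: ",
           paste(union(setdiff(t$gene, genes), setdiff(genes, t$gene)),
                 collapse = ", "))
    }
  }
  rankMat <- vapply(tables, function(t) t$rank[match(genes, t$gene)],
                    numeric(length(genes)))
  rankMat <- matrix(rankMat, nrow = length(genes),
                    dimnames = list(genes, methods))
  geomean <- exp(rowMeans(log(rankMat)))
  tieKey <- if ("deltact" %in% methods) rankMat[, "deltact"] else
    seq_along(genes)
  ord <- order(geomean, tieKey, seq_along(genes))
  consensus <- integer(length(genes))
  consensus[ord] <- seq_along(genes)

  out <- data.frame(gene = genes, rankMat, geomean = geomean,
                    consensus_rank = consensus,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[1L + seq_along(methods)] <- paste0("rank_", methods)
  out <- out[order(out$consensus_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of per-method top-k stable genes
#'
#' For each method's top-k most stable genes, computes all Venn region
#' cardinalities (which combination of methods proposes which genes), the
#' four-way style overlap summary behind "top 15 per algorithm" Venn
#' diagrams.
#'
#' @param tables list of stability tables over a common gene set.
#' @param k number of top-ranked genes per method.
#' @return A list with \code{sets} (named list of top-k gene vectors),
#'   \code{regions} (named integer vector; names are "+"-joined method
#'   combinations, values are counts of genes exclusive to that
#'   combination) and \code{union_size}.
#' @export
topKOverlap <- function(tables, k) {
  methods <- vapply(tables, function(t) t$method[1L], character(1))
  nGenes <- length(tables[[1L]]$gene)
  if (k > nGenes) stop("k exceeds the number of genes")
  sets <- lapply(tables, function(t) t$gene[t$rank <= k])
  names(sets) <- methods
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, methods))
  key <- apply(membership, 1L, function(row) {
    paste(methods[row], collapse = "+")
  })
  regions <- table(key)
  list(sets = sets,
       regions = stats::setNames(as.integer(regions), names(regions)),
       union_size = length(universe))
}
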