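#' Read a wide Ct table and sample sheet
#'
#' Reads a CSV/TSV table with gene identifiers in the first column and one
#' column per sample (header row = sample ids), as exported from
#' high-throughput qRT-PCR platforms, together with a sample sheet mapping
#' samples to donors and groups.
#'
#' @param path path to the Ct table.
#' @param sampleSheet path to a CSV/TSV with columns \code{sample_id},
#'   \code{donor_id} (optional) and \code{group}, or a data.frame of the
#'   same shape.  If \code{NULL} every sample is assigned to a single
#'   \code{"all"} group.
#' @param sep field separator; guessed from the file extension when
#'   \code{NULL} (".tsv"/".txt" = tab, otherwise comma).
#' @param missingTokens character vector of cell values treated as
#'   undetected.  Matching is done after trimming whitespace.
#' @param ctDialect label recorded on the returned object; metadata only.
#'
#' @return A \linkS4class{CtExperiment} preserving the input gene and
#'   sample ordering, with missing tokens mapped to \code{NA}.
#' @seealso [writeCtTable()], [filterCompleteDetection()]
#' @export
readCtTable <- function(path, sampleSheet = NULL, sep = NULL,
                        missingTokens = c("", "NA", "NaN", "Undetermined"),
                        ctDialect = c("Ct", "Crt")) {
  ctDialect <- match.arg(ctDialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .guessSep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = character(0))
  genes <- trimws(raw[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells <- trimws(cells)
  isMissing <- cells %in% missingTokens
  ct <- suppressWarnings(as.numeric(cells))
  bad <- which(!isMissing & is.na(ct))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    stop(sprintf(
      "non-numeric Ct value \"%s\" at gene \"%s\" (row %d), sample \"%s\" (column %d)",
      cells[bad[1L]], genes[i], i, samples[j], j
    ))
  }
  ct[isMissing] <- NA_real_
  dim(ct) <- dim(cells)
  dimnames(ct) <- list(genes, samples)

  if (is.null(sampleSheet)) {
    group <- rep("all", length(samples))
    donor <- NULL
  } else {
    sheet <- if (is.character(sampleSheet)) {
      utils::read.table(sampleSheet, header = TRUE, sep = .guessSep(sampleSheet),
                        colClasses = "character", check.names = FALSE)
    } else {
      as.data.frame(sampleSheet, stringsAsFactors = FALSE)
    }
    need <- c("sample_id", "group")
    if (!all(need %in% colnames(sheet))) {
      stop("sample sheet must contain columns: ", paste(need, collapse = ", "))
    }
    idx <- match(samples, sheet$sample_id)
    if (anyNA(idx)) {
      stop("samples absent from sample sheet: ",
           paste(samples[is.na(idx)], collapse = ", "))
    }
    group <- sheet$group[idx]
    donor <- if ("donor_id" %in% colnames(sheet)) sheet$donor_id[idx] else NULL
  }
  CtExperiment(ct, group = group, donor = donor, ctDialect = ctDialect)
}

.guessSep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Write a CtExperiment back to a wide table
#'
#' Emits the same wide dialect [readCtTable()] consumes (first column
#' \code{gene_id}, one column per sample), so write-then-read round trips
#' bit-identically.  Undetected calls are written as the first missing
#' token (default \code{"NA"}).
#'
#' @param x a \linkS4class{CtExperiment}
#' @param path output path; separator guessed from the extension.
#' @param missingToken string used for undetected calls.
#' @return \code{path}, invisibly.
#' @export
writeCtTable <- function(x, path, missingToken = "NA") {
  ct <- ctValues(x)
  cells <- matrix(sprintf("%.17g", ct), nrow(ct), ncol(ct),
                  dimnames = dimnames(ct))  # round-trip exact
  cells[is.na(ct)] <- missingToken
  df <- data.frame(gene_id = rownames(ct), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .guessSep(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write the sample sheet of a CtExperiment
#'
#' @param x a \linkS4class{CtExperiment}
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSampleSheet <- function(x, path) {
  cd <- SummarizedExperiment::colData(x)
  df <- data.frame(
    sample_id = colnames(x),
    donor_id = if ("donor" %in% colnames(cd)) cd$donor else NA_character_,
    group = as.character(x$group),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname filterCompleteDetection
#' @export
setMethod("filterCompleteDetection", "CtExperiment", function(x, ...) {
  ct <- ctValues(x)
  keep <- rowSums(is.na(ct)) == 0L
  if (!any(keep)) stop("no completely detected genes")
  out <- x[keep, ]
  S4Vectors::metadata(out)$n_removed_undetected <- sum(!keep)
  message(sum(!keep), " gene(s) removed by complete-detection filter; ",
          sum(keep), " retained")
  out
})

#' Per-gene descriptive statistics
#'
#' Computes, per gene over a sample subset, the number of values, the
#' arithmetic mean Ct, the ordinary sample standard deviation (n-1
#' denominator), and the range.  This is the plain descriptive SD; it is
#' deliberately distinct from BestKeeper's mean-absolute-deviation
#' dispersion (see [bestKeeper()]).
#'
#' @param x a \linkS4class{CtExperiment}
#' @param group optional single group label; statistics are then computed
#'   over that group's samples only (at least 2 required).
#' @return A \code{data.frame} with columns \code{gene}, \code{n},
#'   \code{mean}, \code{sd}, \code{min}, \code{max}.
#' @export
describeCt <- function(x, group = NULL) {
  ct <- ctValues(x)
  if (!is.null(group)) {
    if (!(group %in% levels(x$group))) {
      stop("group not in design: ", group)
    }
    sel <- x$group == group
    if (sum(sel) < 2L) stop("group ", group, " has fewer than 2 samples")
    ct <- ct[, sel, drop = FALSE]
  }
  data.frame(
    gene = rownames(ct),
    n = rowSums(!is.na(ct)),
    mean = rowMeans(ct, na.rm = TRUE),
    sd = apply(ct, 1L, stats::sd, na.rm = TRUE),
    min = apply(ct, 1L, min, na.rm = TRUE),
    max = apply(ct, 1L, max, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Qualitative band for a squared Pearson correlation
#'
#' R-squared above 0.8 is read as a very strong interrelationship, below
#' 0.6 as fair, and intermediate otherwise.
#'
#' @param r2 squared Pearson correlation in [0, 1].
#' @return \code{"very strong"}, \code{"intermediate"} or \code{"fair"}.
#' @export
correlationBand <- function(r2) {
  stopifnot(is.numeric(r2), r2 >= 0, r2 <= 1)
  ifelse(r2 > 0.8, "very strong", ifelse(r2 < 0.6, "fair", "intermediate"))
}

#' Between-group correlation of per-gene mean Ct
#'
#' Correlates, gene by gene, the arithmetic-mean Ct of two sample groups —
#' the tissue-vs-tissue scatter used to ask how similar two expression
#' contexts are.  Pairing is per gene (group-mean vectors), since donor
#' pairing is not generally available.
#'
#' @param x a complete \linkS4class{CtExperiment}
#' @param groupA,groupB group labels present in the design.
#' @return A list with \code{r}, \code{r_squared}, \code{band},
#'   \code{n_genes}, and the two mean vectors (\code{mean_a},
#'   \code{mean_b}).
#' @export
datasetCorrelation <- function(x, groupA, groupB) {
  for (g in c(groupA, groupB)) {
    if (!(g %in% levels(x$group))) stop("group not in design: ", g)
  }
  ct <- ctValues(x)
  ma <- rowMeans(ct[, x$group == groupA, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(ct[, x$group == groupB, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(ma) & is.finite(mb)
  if (sum(ok) < 3L) stop("fewer than 3 paired genes; correlation undefined")
  r <- stats::cor(ma[ok], mb[ok])
  list(r = r, r_squared = r^2, band = correlationBand(r^2),
       n_genes = sum(ok), mean_a = ma[ok], mean_b = mb[ok])
}
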