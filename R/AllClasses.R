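#' CtExperiment: a container for qRT-PCR quantification-cycle matrices
#'
#' \code{CtExperiment} extends
#' \linkS4class{SummarizedExperiment} with a single
#' \code{"ct"} assay holding quantification-cycle values (Ct or Crt; PCR
#' cycles) for genes (rows, typically miRNA/snRNA assays) by samples
#' (columns).  Undetected calls are stored as \code{NA}.  Column data must
#' carry a \code{group} factor (e.g. PC/DC/HYP chondrocyte regions) and may
#' carry a \code{donor} identifier.
#'
#' Validity requires unique, non-empty row and column names, all present Ct
#' values finite and strictly positive, and every sample assigned to exactly
#' one group.
#'
#' @slot ctDialect character scalar recording whether the source reported
#'   "Ct" or "Crt" values; metadata only, the two are treated as the same
#'   currency throughout.
#'
#' @seealso [CtExperiment()] for the constructor, [readCtTable()] for file
#'   input, [filterCompleteDetection()] for the detection filter.
#' @export
setClass("CtExperiment",
  contains = "SummarizedExperiment",
  slots = c(ctDialect = "character"),
  prototype = prototype(ctDialect = "Ct")
)

.validCtExperiment <- function(object) {
  msg <- character()
  if (!("ct" %in% SummarizedExperiment::assayNames(object))) {
    msg <- c(msg, "assay 'ct' is required")
  } else {
    ct <- SummarizedExperiment::assay(object, "ct")
    present <- ct[!is.na(ct)]
    if (any(!is.finite(present))) {
      msg <- c(msg, "all present Ct values must be finite")
    } else if (any(present <= 0)) {
      msg <- c(msg, "all present Ct values must be > 0")
    }
  }
  rn <- rownames(object)
  cn <- colnames(object)
  if (is.null(rn) || anyNA(rn) || any(rn == "")) {
    msg <- c(msg, "gene (row) names must be present and non-empty")
  } else if (anyDuplicated(rn)) {
    msg <- c(msg, sprintf(
      "duplicate gene ids: %s",
      paste(unique(rn[duplicated(rn)]), collapse = ", ")
    ))
  }
  if (is.null(cn) || anyNA(cn) || any(cn == "")) {
    msg <- c(msg, "sample (column) names must be present and non-empty")
  } else if (anyDuplicated(cn)) {
    msg <- c(msg, sprintf(
      "duplicate sample ids: %s",
      paste(unique(cn[duplicated(cn)]), collapse = ", ")
    ))
  }
  if (!("group" %in% colnames(SummarizedExperiment::colData(object)))) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (anyNA(object$group)) {
    msg <- c(msg, "every sample needs a non-missing group label")
  }
  if (length(object@ctDialect) != 1L ||
      !(object@ctDialect %in% c("Ct", "Crt"))) {
    msg <- c(msg, "ctDialect must be \"Ct\" or \"Crt\"")
  }
  if (length(msg)) msg else TRUE
}

setValidity("CtExperiment", .validCtExperiment)

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of quantification-cycle values, genes in rows,
#'   samples in columns; \code{NA} marks undetected calls.  Must carry row
#'   and column names.
#' @param group factor or character vector of group labels, one per sample
#'   (recycled against \code{colnames(ct)}).
#' @param donor optional donor/subject identifier per sample.
#' @param ctDialect \code{"Ct"} (default) or \code{"Crt"}; recorded as
#'   metadata only.
#'
#' @return A \linkS4class{CtExperiment}.
#' @examples
#' ct <- matrix(c(20, 21, 22, 15, 15.5, 16), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("miR-a", "miR-b"), c("s1", "s2", "s3")))
#' ce <- CtExperiment(ct, group = c("PC", "DC", "DC"))
#' ce
#' @export
CtExperiment <- function(ct, group, donor = NULL, ctDialect = c("Ct", "Crt")) {
  ctDialect <- match.arg(ctDialect)
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  if (length(group) != ncol(ct)) {
    stop("'group' must have one entry per sample (", ncol(ct), ")")
  }
  cd <- S4Vectors::DataFrame(group = factor(group), row.names = colnames(ct))
  if (!is.null(donor)) cd$donor <- as.character(donor)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ct = ct), colData = cd
  )
  new("CtExperiment", se, ctDialect = ctDialect)
}

#' @describeIn CtExperiment Show a compact summary including detection
#'   completeness and group sizes.
#' @param object a \code{CtExperiment}
#' @export
setMethod("show", "CtExperiment", function(object) {
  callNextMethod()
  ct <- SummarizedExperiment::assay(object, "ct")
  nmiss <- sum(is.na(ct))
  cat(sprintf(
    "ctDialect: %s | undetected calls: %d (%.1f%%)\n",
    object@ctDialect, nmiss, 100 * nmiss / max(1L, length(ct))
  ))
  gs <- table(object$group)
  cat("groups:", paste(sprintf("%s=%d", names(gs), gs), collapse = ", "), "\n")
})
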