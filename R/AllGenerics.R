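#' @rdname ctValues
#' @export
setGeneric("ctValues", function(x, ...) standardGeneric("ctValues"))

#' @rdname ctValues
#' @export
setGeneric("ctDialect", function(x) standardGeneric("ctDialect"))

#' Keep only completely detected genes
#'
#' Restricts a Ct matrix to assays with a reported quantification cycle in
#' every sample — the detection filter applied before any stability
#' analysis, since genes with dropout cannot be scored by the pairwise
#' estimators.  Gene order is preserved and the number of removed genes is
#' recorded in \code{metadata(x)$n_removed_undetected} and reported via
#' \code{message()}.
#'
#' @param x a \linkS4class{CtExperiment}
#' @param ... unused
#' @return The filtered \code{CtExperiment}.  Errors if no gene survives.
#' @examples
#' ce <- simulateCtExperiment(synthConfig(missingRate = 0.05), seed = 7L)$experiment
#' filterCompleteDetection(ce)
#' @export
setGeneric("filterCompleteDetection",
  function(x, ...) standardGeneric("filterCompleteDetection"))

#' Accessors for CtExperiment
#'
#' \code{ctValues} returns the Ct matrix (genes x samples, \code{NA} =
#' undetected); \code{ctDialect} returns the recorded quantification-cycle
#' dialect ("Ct" or "Crt").
#'
#' @param x a \linkS4class{CtExperiment}
#' @param ... unused
#' @return \code{ctValues}: a numeric matrix; \code{ctDialect}: a character
#'   scalar.
#' @name ctValues
#' @aliases ctValues,CtExperiment-method ctDialect,CtExperiment-method
#' @examples
#' ce <- simulateCtExperiment(synthConfig(), seed = 1L)$experiment
#' ctValues(ce)[1:3, 1:4]
#' ctDialect(ce)
NULL

#' @rdname ctValues
#' @export
setMethod("ctValues", "CtExperiment", function(x, ...) {
  SummarizedExperiment::assay(x, "ct")
})

#' @rdname ctValues
#' @export
setMethod("ctDialect", "CtExperiment", function(x) x@ctDialect)
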