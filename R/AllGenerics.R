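#' Accessors for ExpressionStudy objects
#'
#' `exprValues()` returns the log2 expression matrix (genes in rows; missing
#' cells are `NA`), `missingMask()` the logical missingness mask,
#' `geneIds()`/`sampleIds()` the dimension identifiers, and
#' `studyConditions()`, `sampleTypes()` and `sampleBatches()` the per-sample
#' annotation vectors (named by sample).
#'
#' @param x An [ExpressionStudy-class] object.
#' @return A matrix, logical matrix, or named character vector as described.
#' @name study-accessors
#' @aliases exprValues missingMask geneIds sampleIds studyConditions
#'   sampleTypes sampleBatches
NULL

#' @rdname study-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname study-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname study-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname study-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname study-accessors
#' @export
setGeneric("studyConditions", function(x) standardGeneric("studyConditions"))

#' @rdname study-accessors
#' @export
setGeneric("sampleTypes", function(x) standardGeneric("sampleTypes"))

#' @rdname study-accessors
#' @export
setGeneric("sampleBatches", function(x) standardGeneric("sampleBatches"))

#' Accessors for CoexpressionNetwork objects
#'
#' `networkEdges()` returns the edge table (`gene_a`, `gene_b`, `weight`,
#' `p_edge`), `networkNodes()` the node identifiers (including isolated
#' genes), and `nodeDegrees()` the per-node edge count.
#'
#' @param x A [CoexpressionNetwork-class] object.
#' @return A data frame, character vector, or named integer vector.
#' @name network-accessors
#' @aliases networkEdges networkNodes nodeDegrees
NULL

#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname network-accessors
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))
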