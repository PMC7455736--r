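#' Accessors for methylTIME containers
#'
#' \code{betaValues} returns the probes x samples beta matrix;
#' \code{cellTypes} the per-replicate class labels of a
#' \linkS4class{ReferencePanel}; \code{cancerFamily} the cell-line family
#' labels of cancer replicates; \code{plantedDMPs} the simulated per-class
#' DMP index (\code{NULL} for real panels); \code{trueProportions} and
#' \code{spikedClass} the ground truth of a \linkS4class{MixtureSet};
#' \code{signatureValues} the [0,100]-scaled probes x classes matrix of a
#' \linkS4class{SignatureMatrix} and \code{provenance} its per-probe
#' selection trace; \code{cellProportions} the samples x classes estimate
#' matrix of a \linkS4class{DeconvolutionResult} and \code{fitDiagnostics}
#' its per-sample RMSE/correlation/permutation-p/chosen-nu table.
#'
#' @param x a methylTIME object.
#' @return See description; matrices keep probe/sample dimnames.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("cancerFamily", function(x) standardGeneric("cancerFamily"))

#' @rdname accessors
#' @export
setGeneric("plantedDMPs", function(x) standardGeneric("plantedDMPs"))

#' @rdname accessors
#' @export
setGeneric("trueProportions", function(x) standardGeneric("trueProportions"))

#' @rdname accessors
#' @export
setGeneric("spikedClass", function(x) standardGeneric("spikedClass"))

#' @rdname accessors
#' @export
setGeneric("signatureValues", function(x) standardGeneric("signatureValues"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("cellProportions", function(x) standardGeneric("cellProportions"))

#' @rdname accessors
#' @export
setGeneric("fitDiagnostics", function(x) standardGeneric("fitDiagnostics"))
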