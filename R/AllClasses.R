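#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.validBeta <- function(x, what = "beta matrix") {
    if (!is.matrix(x) || !is.numeric(x))
        return(sprintf("%s must be a numeric matrix", what))
    if (anyNA(x))
        return(sprintf("%s contains missing values", what))
    if (min(x) < 0 || max(x) > 1)
        return(sprintf("%s values must lie in [0,1]", what))
    if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
        return(sprintf("%s must have unique probe row names", what))
    TRUE
}

#' Reference panel of pure-population methylomes
#'
#' A \linkS4class{SummarizedExperiment} holding replicate beta-value profiles
#' of flow-sorted (or simulated pure) cell populations. The \code{"beta"}
#' assay is probes x replicates with values in [0,1]; \code{colData} carries
#' \code{cellType} (one of the panel's cell classes) and \code{cancerFamily}
#' (\code{NA} for non-cancer replicates, otherwise a cell-line family label
#' such as \code{"MB-like"}/\code{"MRT-like"}). For simulated panels,
#' \code{metadata()$plantedDMPs} records the per-class planted
#' differentially methylated probe sets with direction.
#'
#' @export
setClass("ReferencePanel", contains = "SummarizedExperiment")

setValidity("ReferencePanel", function(object) {
    if (!"beta" %in% assayNames(object))
        return("assay 'beta' is required")
    ok <- .validBeta(assay(object, "beta"))
    if (!isTRUE(ok)) return(ok)
    cd <- colData(object)
    if (!"cellType" %in% colnames(cd))
        return("colData column 'cellType' is required")
    tab <- table(cd$cellType)
    if (any(tab < 2))
        return(sprintf("every cell class needs >= 2 replicates (violated by: %s)",
                       paste(names(tab)[tab < 2], collapse = ", ")))
    dmps <- metadata(object)$plantedDMPs
    if (!is.null(dmps)) {
        all_idx <- unlist(lapply(dmps, function(d) c(d$hypo, d$hyper)),
                          use.names = FALSE)
        if (anyDuplicated(all_idx))
            return("planted DMP sets must be disjoint between classes")
    }
    TRUE
})

#' Simulated bulk mixtures with known composition
#'
#' A \linkS4class{SummarizedExperiment} of simulated bulk beta-value profiles
#' (assay \code{"beta"}, probes x samples) paired with their ground truth:
#' \code{metadata()$trueProportions} is a samples x classes matrix of mixing
#' fractions (rows sum to 1), and \code{colData} column \code{spikedClass}
#' names the cell class given a set proportion in each sample.
#'
#' @export
setClass("MixtureSet", contains = "SummarizedExperiment")

setValidity("MixtureSet", function(object) {
    if (!"beta" %in% assayNames(object))
        return("assay 'beta' is required")
    ok <- .validBeta(assay(object, "beta"))
    if (!isTRUE(ok)) return(ok)
    tp <- metadata(object)$trueProportions
    if (is.null(tp))
        return("metadata 'trueProportions' is required")
    if (!is.matrix(tp) || nrow(tp) != ncol(object))
        return("trueProportions must be a samples x classes matrix")
    if (min(tp) < 0)
        return("trueProportions must be non-negative")
    if (any(abs(rowSums(tp) - 1) > 1e-9))
        return("each trueProportions row must sum to 1 (tolerance 1e-9)")
    if (!"spikedClass" %in% colnames(colData(object)))
        return("colData column 'spikedClass' is required")
    TRUE
})

#' Cell-type signature matrix for deconvolution
#'
#' Selected differentially methylated probes x cell classes, with mean
#' beta-values scaled to [0,100] (CIBERSORT-compatible layout). The
#' \code{provenance} slot traces each probe to the pairwise comparisons that
#' selected it and the direction of differential methylation.
#'
#' @slot values numeric matrix, probes x classes, entries in [0,100].
#' @slot provenance data.frame with columns \code{probe},
#'   \code{comparisons} (semicolon-separated \code{A.vs.B} strings) and
#'   \code{direction}.
#' @slot params the \code{SignatureParams} list used for selection.
#' @export
setClass("SignatureMatrix",
    representation(values = "matrix", provenance = "data.frame",
                   params = "list"))

setValidity("SignatureMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v) || anyNA(v))
        return("values must be a complete numeric matrix")
    if (min(v) < 0 || max(v) > 100)
        return("signature values must lie in [0,100]")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        return("probe IDs (rownames) must be unique")
    if (is.null(colnames(v)))
        return("class names (colnames) are required")
    pv <- object@provenance
    if (nrow(pv) > 0 && !all(rownames(v) %in% pv$probe))
        return("every probe must be traceable to >= 1 pairwise comparison")
    TRUE
})

#' Result of a relative-mode deconvolution run
#'
#' Per-sample cell-class proportion estimates (rows sum to 1, entries >= 0)
#' with fit diagnostics: RMSE and Pearson correlation between the fitted and
#' observed standardized mixture, the permutation p-value, and the chosen
#' nu for each sample.
#'
#' @slot proportions samples x classes matrix of fractions.
#' @slot rmse,pearson,permP,chosenNu per-sample numeric vectors
#'   (\code{permP} is \code{NA} when permutations were disabled).
#' @slot nProbesUsed number of signature probes found in the mixture.
#' @export
setClass("DeconvolutionResult",
    representation(proportions = "matrix", rmse = "numeric",
                   pearson = "numeric", permP = "numeric",
                   chosenNu = "numeric", nProbesUsed = "integer"))

setValidity("DeconvolutionResult", function(object) {
    p <- object@proportions
    if (min(p) < -1e-12) return("proportions must be non-negative")
    rs <- rowSums(p)
    if (any(abs(rs - 1) > 1e-9 & rs != 0))
        return("each proportions row must sum to 1 (tolerance 1e-9)")
    n <- nrow(p)
    for (sl in c("rmse", "pearson", "permP", "chosenNu"))
        if (length(slot(object, sl)) != n)
            return(sprintf("slot '%s' must have one entry per sample", sl))
    pp <- object@permP
    if (any(!is.na(pp) & (pp <= 0 | pp > 1)))
        return("permutation p-values must lie in (0,1]")
    TRUE
})

#' Consensus clustering result
#'
#' @slot consensusMatrices list (one per k) of symmetric co-assignment
#'   frequency matrices with unit diagonal.
#' @slot pac named numeric: proportion of ambiguous clustering per k.
#' @slot deltaArea named numeric: relative change in the consensus CDF area
#'   per k.
#' @slot optimalK integer chosen by PAC minimization.
#' @slot labels integer cluster labels at \code{optimalK}.
#' @slot settings list of reps, subsample fraction and seed.
#' @export
setClass("ConsensusResult",
    representation(consensusMatrices = "list", pac = "numeric",
                   deltaArea = "numeric", optimalK = "integer",
                   labels = "integer", settings = "list"))

setValidity("ConsensusResult", function(object) {
    for (cm in object@consensusMatrices) {
        if (min(cm) < 0 || max(cm) > 1) return("consensus entries must be in [0,1]")
        if (max(abs(cm - t(cm))) > 1e-12) return("consensus matrices must be symmetric")
        if (any(abs(diag(cm) - 1) > 1e-12)) return("consensus diagonal must be 1")
    }
    k <- object@optimalK
    labs <- object@labels
    if (length(labs) && length(unique(labs)) != k)
        return("labels must take exactly optimalK distinct values")
    TRUE
})
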