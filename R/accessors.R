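#' @rdname accessors
setMethod("betaValues", "SummarizedExperiment",
          function(x) assay(x, "beta"))

#' @rdname accessors
setMethod("cellTypes", "ReferencePanel",
          function(x) as.character(colData(x)$cellType))

#' @rdname accessors
setMethod("cancerFamily", "ReferencePanel",
          function(x) as.character(colData(x)$cancerFamily))

#' @rdname accessors
setMethod("plantedDMPs", "ReferencePanel",
          function(x) metadata(x)$plantedDMPs)

#' @rdname accessors
setMethod("trueProportions", "MixtureSet",
          function(x) metadata(x)$trueProportions)

#' @rdname accessors
setMethod("spikedClass", "MixtureSet",
          function(x) as.character(colData(x)$spikedClass))

#' @rdname accessors
setMethod("signatureValues", "SignatureMatrix", function(x) x@values)

#' @rdname accessors
setMethod("provenance", "SignatureMatrix", function(x) x@provenance)

#' @rdname accessors
setMethod("cellProportions", "DeconvolutionResult", function(x) x@proportions)

#' @rdname accessors
setMethod("fitDiagnostics", "DeconvolutionResult", function(x)
    data.frame(sample = rownames(x@proportions), rmse = x@rmse,
               pearson = x@pearson, permP = x@permP, chosenNu = x@chosenNu,
               row.names = NULL))

setMethod("show", "ReferencePanel", function(object) {
    tab <- table(cellTypes(object))
    cat("ReferencePanel:", nrow(object), "probes,", ncol(object),
        "replicate profiles,", length(tab), "cell classes\n")
    cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab),
                            collapse = " "), "\n")
    fam <- cancerFamily(object)
    if (any(!is.na(fam)))
        cat("  cancer-line families:",
            paste(names(table(fam)), collapse = ", "), "\n")
    if (!is.null(plantedDMPs(object)))
        cat("  simulated panel with planted DMP index\n")
})

setMethod("show", "MixtureSet", function(object) {
    cat("MixtureSet:", ncol(object), "simulated mixtures over",
        nrow(object), "probes,", ncol(trueProportions(object)),
        "classes with recorded ground truth\n")
})

setMethod("show", "SignatureMatrix", function(object) {
    v <- object@values
    cat("SignatureMatrix:", nrow(v), "probes x", ncol(v),
        "cell classes (values scaled to [0,100])\n")
    cat("  classes:", paste(colnames(v), collapse = " "), "\n")
})

setMethod("show", "DeconvolutionResult", function(object) {
    p <- object@proportions
    cat("DeconvolutionResult:", nrow(p), "samples x", ncol(p),
        "cell classes (relative mode,", object@nProbesUsed,
        "signature probes used)\n")
    cat(sprintf("  median fit: RMSE %.3f, Pearson r %.3f\n",
                stats::median(object@rmse), stats::median(object@pearson)))
})

setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult: k searched over",
        paste(names(object@pac), collapse = ","),
        "| optimal k =", object@optimalK, "(PAC minimization)\n")
    print(round(object@pac, 4))
})
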