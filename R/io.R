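#' Read a beta-value matrix from TSV/CSV
#'
#' Expects probe IDs in the first column and sample IDs in the header
#' (comma- or tab-separated, autodetected). Values are validated to [0,1]
#' (an offending cell is reported by probe and sample), duplicate probe IDs
#' are rejected, and probes with missing values are dropped with a message.
#'
#' @param path file path.
#' @return probes x samples numeric matrix.
#' @export
readBetaMatrix <- function(path) {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    probes <- as.character(dt[[1]])
    if (anyDuplicated(probes))
        stop("duplicate probe ID(s): ",
             paste(unique(probes[duplicated(probes)]), collapse = ", "))
    m <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric beta values in ", path)
    rownames(m) <- probes
    if (anyNA(m)) {
        drop <- rowSums(is.na(m)) > 0
        message("dropping ", sum(drop), " probe(s) with missing values")
        m <- m[!drop, , drop = FALSE]
    }
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop(sprintf("beta value out of [0,1] at probe %s, sample %s (%g)",
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                     m[bad[1, , drop = FALSE]]))
    m
}

#' Write a beta-value (or proportions) matrix as TSV
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @param idColumn header of the first (row-ID) column.
#' @return invisibly, \code{path}.
#' @export
writeBetaMatrix <- function(x, path, idColumn = "probe") {
    # full 17-significant-digit formatting so write/read round trips are
    # bit-identical
    chr <- matrix(sprintf("%.17g", x), nrow = nrow(x),
                  dimnames = dimnames(x))
    df <- data.frame(rownames(x), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- idColumn
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read / write a signature matrix in CIBERSORT tabular layout
#'
#' TSV with a \code{NAME} first column of probe IDs and one column per cell
#' class; values in [0,100].
#'
#' @param path file path.
#' @return \code{readSignatureMatrix}: a \linkS4class{SignatureMatrix}
#'   (provenance marked as imported).
#' @export
readSignatureMatrix <- function(path) {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- as.character(dt[[1]])
    prov <- data.frame(probe = rownames(m), comparisons = "imported",
                       direction = "unknown", stringsAsFactors = FALSE)
    new("SignatureMatrix", values = m, provenance = prov, params = list())
}

#' @param sig a \linkS4class{SignatureMatrix}.
#' @rdname readSignatureMatrix
#' @export
writeSignatureMatrix <- function(sig, path) {
    stopifnot(is(sig, "SignatureMatrix"))
    writeBetaMatrix(signatureValues(sig), path, idColumn = "NAME")
}

#' Run the full pipeline from a configuration list
#'
#' Executes the requested stages in dependency order - \code{simulate}
#' (reference panel + tumor mixtures), \code{signature}, \code{deconvolve},
#' \code{benchmark} (recovery evaluation) - writing every artifact as TSV
#' under \code{outDir} plus a JSON run manifest (package version, seed,
#' stage parameters, output checksums). All randomness flows from the single
#' \code{seed} through fixed per-stage offsets, so a rerun with the same
#' config reproduces identical outputs.
#'
#' @param config a configuration list, or the path to a JSON or YAML file
#'   holding one, with elements \code{stages} (subset of the above, in
#'   any order), \code{seed}, \code{outDir}, and optional parameter blocks
#'   \code{panel} (arguments to \code{\link{panelConfig}}), \code{mixture}
#'   (arguments to \code{\link{simulateTumorMixtures}}), \code{signature}
#'   (arguments to \code{\link{signatureParams}}) and \code{deconv}
#'   (arguments to \code{\link{deconvParams}}).
#' @return the manifest, invisibly (also written to
#'   \code{outDir/manifest.json}).
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1) {
        config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
            if (!requireNamespace("yaml", quietly = TRUE))
                stop("reading YAML configs requires the 'yaml' package")
            yaml::read_yaml(config)
        } else {
            jsonlite::read_json(config, simplifyVector = TRUE)
        }
    }
    stopifnot(is.list(config), !is.null(config$outDir))
    seed <- as.integer(config$seed %||% 1L)
    stages <- config$stages %||% c("simulate", "signature", "deconvolve",
                                   "benchmark")
    known <- c("simulate", "signature", "deconvolve", "benchmark")
    if (!all(stages %in% known))
        stop("unknown stage(s): ",
             paste(setdiff(stages, known), collapse = ", "))
    needs <- list(signature = "simulate", deconvolve = c("simulate", "signature"),
                  benchmark = c("simulate", "signature", "deconvolve"))
    for (st in stages) {
        miss <- setdiff(needs[[st]], stages)
        if (length(miss))
            stop("stage '", st, "' requires stage(s): ",
                 paste(miss, collapse = ", "))
    }
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    message("run seed: ", seed)

    outputs <- character(0)
    emit <- function(x, name, idColumn = "probe") {
        p <- file.path(config$outDir, name)
        writeBetaMatrix(x, p, idColumn = idColumn)
        outputs[[name]] <<- unname(tools::md5sum(p))
        p
    }

    panel <- mixtures <- sig <- result <- NULL
    if ("simulate" %in% stages) {
        pc <- do.call(panelConfig, utils::modifyList(
            list(seed = seed), config$panel %||% list()))
        panel <- generateReferencePanel(pc)
        emit(betaValues(panel), "reference_panel.tsv")
        margs <- utils::modifyList(list(seed = seed + 1L),
                                   config$mixture %||% list())
        mixtures <- do.call(simulateTumorMixtures, c(list(panel), margs))
        emit(betaValues(mixtures), "mixtures.tsv")
        emit(trueProportions(mixtures), "true_proportions.tsv",
             idColumn = "sample")
    }
    if ("signature" %in% stages) {
        sp <- do.call(signatureParams, config$signature %||% list())
        sig <- buildSignature(panel, sp)
        writeSignatureMatrix(sig, file.path(config$outDir, "signature.tsv"))
        outputs[["signature.tsv"]] <-
            unname(tools::md5sum(file.path(config$outDir, "signature.tsv")))
    }
    if ("deconvolve" %in% stages) {
        dp <- do.call(deconvParams, utils::modifyList(
            list(nPermutations = 0L, seed = seed + 2L),
            config$deconv %||% list()))
        result <- deconvolve(mixtures, sig, dp)
        emit(cellProportions(result), "proportions.tsv", idColumn = "sample")
    }
    summary <- NULL
    if ("benchmark" %in% stages) {
        rep <- evaluateRecovery(cellProportions(result),
                                trueProportions(mixtures),
                                scope = "spiked_only",
                                spiked = spikedClass(mixtures))
        summary <- list(pearson = rep$pearson, spearman = rep$spearman,
                        rmse = rep$rmse, unattributed = rep$unattributed,
                        nPoints = rep$nPoints,
                        meanCancer = mean(cellProportions(result)[, "Cancer"]))
    }

    manifest <- list(package = "methylTIME",
                     version = as.character(utils::packageVersion("methylTIME")),
                     seed = seed, stages = stages,
                     parameters = config[intersect(names(config),
                                                   c("panel", "mixture",
                                                     "signature", "deconv"))],
                     outputs = as.list(outputs), benchmark = summary)
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
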