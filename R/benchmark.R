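#' Score recovery of known mixture compositions
#'
#' Compares estimated against true proportions over a chosen scope of
#' (sample, class) points: \code{"all_classes"} flattens the full matrices;
#' \code{"spiked_only"} scores each sample's spiked class only, excluding
#' samples whose spiked class is Cancer (the benchmark's fixed compartment);
#' \code{"noncancer_only"} flattens all non-cancer columns.
#'
#' @param estimates,truth samples x classes matrices sharing dimnames.
#' @param scope one of \code{"all_classes"}, \code{"spiked_only"},
#'   \code{"noncancer_only"}.
#' @param spiked character vector naming each sample's spiked class
#'   (required for \code{"spiked_only"}).
#' @return list of class \code{"RecoveryReport"}: \code{pearson},
#'   \code{spearman}, \code{rmse}, \code{unattributed} (mean per-sample
#'   estimate mass on classes with zero truth), \code{nPoints}.
#' @export
evaluateRecovery <- function(estimates, truth,
                             scope = c("all_classes", "spiked_only",
                                       "noncancer_only"),
                             spiked = NULL) {
    scope <- match.arg(scope)
    stopifnot(is.matrix(estimates), is.matrix(truth))
    if (!identical(dim(estimates), dim(truth)))
        stop("estimates and truth must have identical dimensions")
    if (!is.null(rownames(truth)))
        estimates <- estimates[rownames(truth), colnames(truth),
                               drop = FALSE]

    if (scope == "spiked_only") {
        if (is.null(spiked) || length(spiked) != nrow(truth))
            stop("'spiked' labels are required for scope = 'spiked_only'")
        keep <- spiked != "Cancer"
        idx <- cbind(which(keep), match(spiked[keep], colnames(truth)))
        e <- estimates[idx]
        t_ <- truth[idx]
    } else if (scope == "noncancer_only") {
        cols <- setdiff(colnames(truth), "Cancer")
        e <- as.numeric(estimates[, cols])
        t_ <- as.numeric(truth[, cols])
    } else {
        e <- as.numeric(estimates)
        t_ <- as.numeric(truth)
    }

    unattributed <- mean(vapply(seq_len(nrow(truth)), function(i) {
        z <- truth[i, ] == 0
        if (!any(z)) 0 else sum(estimates[i, z])
    }, numeric(1)))

    structure(list(
        pearson = if (stats::sd(e) == 0 || stats::sd(t_) == 0) NA_real_
                  else stats::cor(e, t_),
        spearman = if (stats::sd(e) == 0 || stats::sd(t_) == 0) NA_real_
                   else stats::cor(e, t_, method = "spearman"),
        rmse = sqrt(mean((e - t_)^2)),
        unattributed = unattributed,
        nPoints = length(e)), class = "RecoveryReport")
}

#' End-to-end benchmark: simulate, deconvolve, evaluate
#'
#' Simulates tumor mixtures from the panel, deconvolves them with the given
#' signature, and scores recovery (spiked scope plus all-classes scope and a
#' per-class breakdown). Fully reproducible from \code{seed}.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param sig a \linkS4class{SignatureMatrix} built from it.
#' @param deconv a \code{\link{deconvParams}} object.
#' @param nPerClass,cancerFraction,noiseConcentration mixture settings
#'   passed to \code{\link{simulateTumorMixtures}}.
#' @param seed integer seed for the simulation.
#' @return list with \code{report} (spiked-scope
#'   \code{RecoveryReport}), \code{allClasses} (all-classes report),
#'   \code{perClass} (data.frame of per-spiked-class Pearson r and RMSE),
#'   \code{meanCancer} (mean estimated Cancer proportion),
#'   \code{mixtures} and \code{result}.
#' @export
runBenchmark <- function(panel, sig, deconv = deconvParams(nPermutations = 0L),
                         nPerClass = 100L, cancerFraction = 0.75,
                         noiseConcentration = 1000, seed = 1L) {
    mixtures <- simulateTumorMixtures(panel, nPerClass = nPerClass,
                                      cancerFraction = cancerFraction,
                                      noiseConcentration = noiseConcentration,
                                      seed = seed)
    result <- deconvolve(mixtures, sig, deconv)
    est <- cellProportions(result)
    truth <- trueProportions(mixtures)
    spiked <- spikedClass(mixtures)

    report <- evaluateRecovery(est, truth, scope = "spiked_only",
                               spiked = spiked)
    allClasses <- evaluateRecovery(est, truth, scope = "all_classes")
    perClass <- do.call(rbind, lapply(setdiff(unique(spiked), "Cancer"),
        function(cl) {
            i <- spiked == cl
            e <- est[i, cl]
            t_ <- truth[i, cl]
            data.frame(class = cl,
                       pearson = if (stats::sd(e) == 0 ||
                                     stats::sd(t_) == 0) NA_real_
                                 else stats::cor(e, t_),
                       rmse = sqrt(mean((e - t_)^2)),
                       n = sum(i))
        }))
    list(report = report, allClasses = allClasses, perClass = perClass,
         meanCancer = mean(est[, "Cancer"]),
         mixtures = mixtures, result = result)
}
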