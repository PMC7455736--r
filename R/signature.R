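#' Feature-selection parameters for signature construction
#'
#' @param deltaMin minimum absolute median beta difference between the two
#'   groups for a probe to be a candidate (default 0.2).
#' @param fdrMax maximum Benjamini-Hochberg adjusted p-value (default 0.01).
#' @param maxDMPs per-pairwise-comparison cap on selected probes (even,
#'   >= 2; default 200). Half the cap is taken from the positively and half
#'   from the negatively ranked beta-delta lists, so selection is balanced
#'   between hypo- and hyper-methylated probes.
#' @param fdrScope \code{"per_comparison"} (default) adjusts p-values within
#'   each pairwise comparison; \code{"global"} adjusts across all
#'   comparisons of a panel jointly.
#' @return A validated list of class \code{"SignatureParams"}.
#' @export
signatureParams <- function(deltaMin = 0.2, fdrMax = 0.01, maxDMPs = 200L,
                            fdrScope = c("per_comparison", "global")) {
    if (deltaMin <= 0 || deltaMin >= 1) stop("deltaMin must be in (0,1)")
    if (fdrMax <= 0 || fdrMax >= 1) stop("fdrMax must be in (0,1)")
    if (maxDMPs < 2 || maxDMPs %% 2 != 0)
        stop("maxDMPs must be an even count >= 2")
    structure(list(deltaMin = deltaMin, fdrMax = fdrMax,
                   maxDMPs = as.integer(maxDMPs),
                   perDirectionCap = as.integer(maxDMPs / 2),
                   fdrScope = match.arg(fdrScope)),
              class = "SignatureParams")
}

#' QC thresholds for post-selection signature filtering
#'
#' @param cancerMeanDiff between-family mean beta difference above which a
#'   probe is cell-line-variable (default 0.1).
#' @param cancerSD within-MB-family SD above which a probe is cell-line
#'   variable (default 0.15). Removal requires BOTH conditions.
#' @param lowVarianceSD per-tumor-type average SD below which a probe is
#'   flagged as (near-)invariant in tumors (default 0.005); flagged probes
#'   are retained by default.
#' @return A list of class \code{"QcThresholds"}.
#' @export
qcThresholds <- function(cancerMeanDiff = 0.1, cancerSD = 0.15,
                         lowVarianceSD = 0.005) {
    stopifnot(cancerMeanDiff > 0, cancerSD > 0, lowVarianceSD > 0)
    structure(list(cancerMeanDiff = cancerMeanDiff, cancerSD = cancerSD,
                   lowVarianceSD = lowVarianceSD), class = "QcThresholds")
}

# Per-class summary statistics reused across all pairwise comparisons.
classStats <- function(b, ct) {
    classes <- unique(ct)
    n <- vapply(classes, function(cl) sum(ct == cl), integer(1))
    mean <- vapply(classes, function(cl)
        rowMeans(b[, ct == cl, drop = FALSE]), numeric(nrow(b)))
    med <- vapply(classes, function(cl)
        rowMedians2(b[, ct == cl, drop = FALSE]), numeric(nrow(b)))
    var <- vapply(classes, function(cl) {
        x <- b[, ct == cl, drop = FALSE]
        rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
    }, numeric(nrow(b)))
    list(classes = classes, n = n, mean = mean, median = med, var = var)
}

# Vectorized Welch two-sample t-test from cached per-class moments.
welchP <- function(m1, v1, n1, m2, v2, n2) {
    se2 <- v1 / n1 + v2 / n2
    se2 <- pmax(se2, .Machine$double.xmin)
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[!is.finite(df) | df <= 0] <- 1
    2 * stats::pt(-abs(tstat), df)
}

.selectBalanced <- function(delta, q, probes, params) {
    keep <- abs(delta) >= params$deltaMin & q <= params$fdrMax
    pick <- function(dir) {
        i <- which(keep & sign(delta) == dir)
        if (!length(i)) return(integer(0))
        # rank by |delta| descending; ties broken lexicographically by probe
        i[order(-abs(delta[i]), probes[i])][seq_len(min(length(i),
                                                        params$perDirectionCap))]
    }
    pos <- pick(1)
    neg <- pick(-1)
    data.frame(probe = probes[c(pos, neg)],
               delta = delta[c(pos, neg)],
               q = q[c(pos, neg)],
               direction = rep(c("hyper", "hypo"),
                               c(length(pos), length(neg))),
               stringsAsFactors = FALSE)
}

#' Balanced selection of differentially methylated probes between two groups
#'
#' Per-probe Welch two-sample test on beta-values with Benjamini-Hochberg
#' adjustment across all probes of the comparison; candidates must satisfy
#' \code{|median beta difference| >= deltaMin} and adjusted p
#' \code{<= fdrMax}. Candidates are split by the sign of the difference,
#' each direction ranked by absolute difference (descending, probe-ID
#' tie-break), and the top \code{maxDMPs/2} taken per direction.
#'
#' @param groupA,groupB probes x replicates beta matrices sharing the same
#'   probe universe, >= 2 replicates each.
#' @param params a \code{\link{signatureParams}} object.
#' @return data.frame with columns \code{probe}, \code{delta} (median
#'   A - median B), \code{q} and \code{direction} (\code{"hyper"}: higher in
#'   A). At most \code{maxDMPs} rows.
#' @export
pairwiseDMPs <- function(groupA, groupB, params = signatureParams()) {
    if (!identical(rownames(groupA), rownames(groupB)))
        stop("groups must share an identical probe universe")
    if (ncol(groupA) < 2 || ncol(groupB) < 2)
        stop("each group needs >= 2 replicates")
    b <- cbind(groupA, groupB)
    ct <- rep(c("A", "B"), c(ncol(groupA), ncol(groupB)))
    st <- classStats(b, ct)
    delta <- st$median[, "A"] - st$median[, "B"]
    p <- welchP(st$mean[, "A"], st$var[, "A"], st$n["A"],
                st$mean[, "B"], st$var[, "B"], st$n["B"])
    q <- stats::p.adjust(p, method = "BH")
    .selectBalanced(delta, q, rownames(groupA), params)
}

#' Build a cell-type signature matrix from a reference panel
#'
#' Runs \code{\link{pairwiseDMPs}} over all unordered pairs of cell classes,
#' takes the union of selected probes (a probe selected by several
#' comparisons appears once), computes the per-class mean beta on those
#' probes, and scales values by 100 into [0,100]. Selection provenance
#' (contributing comparisons and direction) is recorded per probe.
#'
#' @param panel a \linkS4class{ReferencePanel} with >= 2 classes.
#' @param params a \code{\link{signatureParams}} object.
#' @return A \linkS4class{SignatureMatrix}.
#' @export
buildSignature <- function(panel, params = signatureParams()) {
    stopifnot(is(panel, "ReferencePanel"))
    b <- betaValues(panel)
    ct <- cellTypes(panel)
    st <- classStats(b, ct)
    classes <- st$classes
    if (length(classes) < 2) stop("panel needs >= 2 classes")
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    probes <- rownames(b)

    # per-comparison raw p matrices are needed for the global FDR option
    rawP <- lapply(pairs, function(pr)
        welchP(st$mean[, pr[1]], st$var[, pr[1]], st$n[pr[1]],
               st$mean[, pr[2]], st$var[, pr[2]], st$n[pr[2]]))
    if (params$fdrScope == "global") {
        qAll <- stats::p.adjust(unlist(rawP), method = "BH")
        qList <- split(qAll, rep(seq_along(rawP), each = length(probes)))
    } else {
        qList <- lapply(rawP, stats::p.adjust, method = "BH")
    }

    sel <- vector("list", length(pairs))
    for (i in seq_along(pairs)) {
        pr <- pairs[[i]]
        delta <- st$median[, pr[1]] - st$median[, pr[2]]
        s <- .selectBalanced(delta, qList[[i]], probes, params)
        if (nrow(s)) s$comparison <- paste(pr[1], pr[2], sep = ".vs.")
        sel[[i]] <- s
    }
    sel <- do.call(rbind, sel[vapply(sel, nrow, integer(1)) > 0])
    if (is.null(sel) || nrow(sel) == 0)
        stop("no probes selected: no pair of classes is separable under ",
             "the given thresholds")

    union <- sort(unique(sel$probe))
    prov <- do.call(rbind, lapply(split(sel, sel$probe), function(d)
        data.frame(probe = d$probe[1],
                   comparisons = paste(sort(unique(d$comparison)),
                                       collapse = ";"),
                   direction = paste(sort(unique(d$direction)),
                                     collapse = ";"),
                   stringsAsFactors = FALSE)))
    rownames(prov) <- NULL

    values <- st$mean[union, , drop = FALSE] * 100
    values <- pmin(pmax(values, 0), 100)
    new("SignatureMatrix", values = values,
        provenance = prov[match(union, prov$probe), , drop = FALSE],
        params = unclass(params))
}

#' Remove signature probes confounded by cancer cell-line variability
#'
#' Removes probes on which the two cancer cell-line families diverge:
#' removal requires BOTH an absolute between-family mean beta difference
#' exceeding \code{thresholds$cancerMeanDiff} AND an SD across MB-family
#' lines exceeding \code{thresholds$cancerSD} (a conjunction; probes failing
#' only one condition are retained).
#'
#' @param sig a \linkS4class{SignatureMatrix}.
#' @param mbLines,mrtLines probes x profiles beta matrices for the two
#'   cell-line families, covering the signature probes, >= 2 profiles each.
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return list with \code{signature} (filtered \linkS4class{SignatureMatrix})
#'   and \code{removed} (data.frame: probe, meanDiff, mbSD).
#' @export
filterCancerLineVariability <- function(sig, mbLines, mrtLines,
                                        thresholds = qcThresholds()) {
    stopifnot(is(sig, "SignatureMatrix"))
    if (ncol(mbLines) < 2 || ncol(mrtLines) < 2)
        stop("each cell-line family needs >= 2 profiles")
    probes <- rownames(signatureValues(sig))
    if (!all(probes %in% rownames(mbLines)) ||
        !all(probes %in% rownames(mrtLines)))
        stop("cell-line matrices must cover all signature probes")
    mb <- mbLines[probes, , drop = FALSE]
    mrt <- mrtLines[probes, , drop = FALSE]
    meanDiff <- abs(rowMeans(mb) - rowMeans(mrt))
    mbSD <- sqrt(rowSums((mb - rowMeans(mb))^2) / (ncol(mb) - 1))
    drop <- meanDiff > thresholds$cancerMeanDiff & mbSD > thresholds$cancerSD
    removed <- data.frame(probe = probes[drop], meanDiff = meanDiff[drop],
                          mbSD = mbSD[drop], row.names = NULL)
    keep <- probes[!drop]
    filtered <- new("SignatureMatrix",
                    values = signatureValues(sig)[keep, , drop = FALSE],
                    provenance = sig@provenance[
                        sig@provenance$probe %in% keep, , drop = FALSE],
                    params = sig@params)
    list(signature = filtered, removed = removed)
}

#' Flag signature probes with extremely low variance in tumors
#'
#' Computes, for each signature probe, the SD across samples within each
#' tumor type and averages these SDs over tumor types; probes whose average
#' falls below \code{threshold} are flagged as (near-)invariant. Flagged
#' probes are reported, not removed: near-invariant probes can simply track
#' cell types whose infiltration is uniformly low, so they are retained by
#' default (use \code{\link{filterCancerLineVariability}}-style subsetting
#' manually if removal is wanted). The report groups each flagged probe by
#' the signature class whose profile it tracks (the class with the most
#' extreme scaled value).
#'
#' @param sig a \linkS4class{SignatureMatrix}.
#' @param tumorBetasByType named list of probes x samples beta matrices,
#'   one per tumor type, each covering the signature probes.
#' @param threshold average-SD threshold (default 0.005).
#' @return data.frame with columns \code{probe}, \code{avgSD},
#'   \code{flagged}, \code{trackedClass}.
#' @export
flagLowVarianceProbes <- function(sig, tumorBetasByType, threshold = 0.005) {
    stopifnot(is(sig, "SignatureMatrix"))
    if (!is.list(tumorBetasByType) || length(tumorBetasByType) == 0)
        stop("tumorBetasByType must be a non-empty list of beta matrices")
    probes <- rownames(signatureValues(sig))
    sds <- vapply(tumorBetasByType, function(m) {
        if (!all(probes %in% rownames(m)))
            stop("every tumor-type matrix must cover the signature probes")
        x <- m[probes, , drop = FALSE]
        sqrt(rowSums((x - rowMeans(x))^2) / (ncol(x) - 1))
    }, numeric(length(probes)))
    avgSD <- rowMeans(as.matrix(sds))
    v <- signatureValues(sig)
    z <- scale(t(v))
    z[!is.finite(z)] <- 0
    tracked <- colnames(v)[apply(abs(z), 2L, which.max)]
    data.frame(probe = probes, avgSD = avgSD, flagged = avgSD < threshold,
               trackedClass = tracked, row.names = NULL)
}

#' Grid search over signature-construction parameters
#'
#' Builds one signature per combination of median beta-delta threshold and
#' per-pairwise probe cap, deconvolves a benchmark mixture set with each,
#' and scores each grid point by mean recovery correlation, RMSE, and the
#' mean estimate mass assigned to classes absent from the truth
#' ("unattributed"). The winner minimizes the sum of per-metric ranks
#' (correlation ranked descending, RMSE and unattributed ascending; ties
#' broken by grid order). A grid point whose signature build or
#' deconvolution fails is recorded with \code{NA} metrics, not fatal.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param benchmarkMixtures a \linkS4class{MixtureSet} with ground truth.
#' @param deltas candidate \code{deltaMin} values (default 0.2, 0.3).
#' @param ndmpGrid candidate \code{maxDMPs} values (default 100..500).
#' @param deconvParams a \code{\link{deconvParams}} object (permutations are
#'   typically disabled for the search).
#' @param scope recovery scope passed to \code{\link{evaluateRecovery}}.
#' @return list with \code{table} (one row per grid point: delta, maxDMPs,
#'   nProbes, pearson, rmse, unattributed), \code{best} (the winning
#'   \code{SignatureParams}) and \code{bestSignature}.
#' @export
gridSearchSignature <- function(panel, benchmarkMixtures,
                                deltas = c(0.2, 0.3),
                                ndmpGrid = c(100L, 200L, 300L, 400L, 500L),
                                deconvParams = methylTIME::deconvParams(
                                    nPermutations = 0L),
                                scope = "spiked_only") {
    stopifnot(is(panel, "ReferencePanel"), is(benchmarkMixtures, "MixtureSet"))
    grid <- expand.grid(delta = deltas, maxDMPs = ndmpGrid,
                        KEEP.OUT.ATTRS = FALSE)
    res <- data.frame(grid, nProbes = NA_integer_, pearson = NA_real_,
                      rmse = NA_real_, unattributed = NA_real_)
    sigs <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        out <- tryCatch({
            params <- signatureParams(deltaMin = grid$delta[i],
                                      maxDMPs = grid$maxDMPs[i])
            sig <- buildSignature(panel, params)
            dec <- deconvolve(benchmarkMixtures, sig, deconvParams)
            rep <- evaluateRecovery(cellProportions(dec),
                                    trueProportions(benchmarkMixtures),
                                    scope = scope,
                                    spiked = spikedClass(benchmarkMixtures))
            list(sig = sig, rep = rep)
        }, error = function(e) e)
        if (inherits(out, "error")) {
            message("grid point ", i, " failed: ", conditionMessage(out))
            next
        }
        sigs[[i]] <- out$sig
        res$nProbes[i] <- nrow(signatureValues(out$sig))
        res$pearson[i] <- out$rep$pearson
        res$rmse[i] <- out$rep$rmse
        res$unattributed[i] <- out$rep$unattributed
    }
    ok <- !is.na(res$pearson)
    if (!any(ok)) stop("every grid point failed")
    score <- rank(-res$pearson[ok]) + rank(res$rmse[ok]) +
        rank(res$unattributed[ok])
    win <- which(ok)[which.min(score)]
    list(table = res,
         best = signatureParams(deltaMin = res$delta[win],
                                maxDMPs = res$maxDMPs[win]),
         bestSignature = sigs[[win]])
}
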