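#' meTIL score: 5-CpG methylation surrogate of T-lymphocyte infiltration
#'
#' Centers and scales each of the five meTIL probes across the cohort, takes
#' the first principal component of the resulting 5-dimensional profiles,
#' and orients its sign to correlate non-negatively with hypomethylation
#' (1 - mean beta over the five probes), so higher scores mean more
#' T-lymphocyte infiltration. Zero-variance probes are dropped from the
#' component with a message (not an error); if all five are constant the
#' score is all-zero and flagged degenerate. A scaled-mean variant
#' (\code{method = "mean"}: mean of the per-probe z-scores of
#' hypomethylation) is available.
#'
#' @param beta probes x samples beta matrix containing all five meTIL
#'   probes; >= 2 samples.
#' @param panel a \code{\link{genePanel}} supplying \code{metilProbes}.
#' @param method \code{"pc1"} (default) or \code{"mean"}.
#' @return named numeric vector of per-sample scores, with attribute
#'   \code{"degenerate"}.
#' @export
metilScore <- function(beta, panel = genePanel(),
                       method = c("pc1", "mean")) {
    method <- match.arg(method)
    probes <- panel$metilProbes
    missing <- setdiff(probes, rownames(beta))
    if (length(missing))
        stop("missing meTIL probe(s): ", paste(missing, collapse = ", "))
    if (ncol(beta) < 2) stop("need >= 2 samples")
    x <- t(beta[probes, , drop = FALSE])     # samples x 5
    sds <- apply(x, 2L, stats::sd)
    if (all(sds == 0)) {
        out <- stats::setNames(rep(0, nrow(x)), rownames(x))
        attr(out, "degenerate") <- TRUE
        return(out)
    }
    if (any(sds == 0)) {
        message("dropping zero-variance meTIL probe(s): ",
                paste(colnames(x)[sds == 0], collapse = ", "))
        x <- x[, sds > 0, drop = FALSE]
    }
    z <- scale(x)
    hypo <- 1 - rowMeans(x)
    score <- if (method == "pc1") stats::prcomp(z, center = FALSE)$x[, 1]
             else rowMeans(-z)
    if (stats::sd(hypo) > 0 && stats::cor(score, hypo) < 0)
        score <- -score
    out <- stats::setNames(as.numeric(score), rownames(x))
    attr(out, "degenerate") <- FALSE
    out
}

#' Cytolytic score (CYT)
#'
#' Per-sample mean of GZMA and PRF1 log-scale expression. The default is the
#' arithmetic mean; a geometric-mean variant is available behind
#' \code{geometric = TRUE}.
#'
#' @param expr genes x samples log-scale expression matrix containing both
#'   genes.
#' @param panel a \code{\link{genePanel}} supplying \code{cytGenes}.
#' @param geometric use the geometric mean of the two values.
#' @return named numeric vector of per-sample scores.
#' @export
cytScore <- function(expr, panel = genePanel(), geometric = FALSE) {
    genes <- panel$cytGenes
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
        stop("missing cytolytic gene(s): ", paste(missing, collapse = ", "))
    x <- expr[genes, , drop = FALSE]
    if (geometric) apply(x, 2L, function(v) exp(mean(log(pmax(v, 1e-12)))))
    else colMeans(x)
}

#' Microglial share of the monocyte signal
#'
#' For the microglia and peripheral-monocyte gene panels separately, each
#' gene is z-standardized across samples and the z-scores averaged over the
#' panel; both panel scores are then min-max rescaled to [0,1] across the
#' cohort (avoiding negative-score ratio pathologies) and the microglial
#' fraction is \code{microglia / (microglia + peripheral)}. Samples at 0/0
#' are returned as \code{NA} and flagged.
#'
#' @param expr genes x samples expression matrix (gene symbols or Ensembl
#'   IDs as rownames); >= 2 samples; at least one gene of each panel must be
#'   present.
#' @param panel a \code{\link{genePanel}}.
#' @return named numeric vector of per-sample fractions in [0,1] (or
#'   \code{NA}), with attribute \code{"undefined"} (logical per sample).
#' @export
microgliaFraction <- function(expr, panel = genePanel()) {
    if (ncol(expr) < 2) stop("need >= 2 samples")
    panelScore <- function(genes) {
        present <- rownames(expr) %in% c(genes, names(genes))
        if (!any(present)) return(NULL)
        z <- t(scale(t(expr[present, , drop = FALSE])))
        z[!is.finite(z)] <- 0
        colMeans(z)
    }
    mg <- panelScore(panel$microgliaGenes)
    pm <- panelScore(panel$peripheralGenes)
    if (is.null(mg) || is.null(pm))
        stop("expression matrix contains no genes from the microglia ",
             "and/or peripheral panel")
    rescale01 <- function(v) {
        r <- range(v)
        if (r[1] == r[2]) rep(0.5, length(v)) else (v - r[1]) / (r[2] - r[1])
    }
    m <- rescale01(mg)
    p <- rescale01(pm)
    undef <- (m + p) == 0
    frac <- ifelse(undef, NA_real_, m / (m + p))
    names(frac) <- colnames(expr)
    attr(frac, "undefined") <- undef
    frac
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based per-sample enrichment: genes are ordered by expression
#' (descending) and a weighted running sum walks the list - in-set genes
#' increment it proportionally to their rank weight raised to \code{alpha}
#' (the rank weight of the gene at position i among N genes is N - i + 1),
#' out-of-set genes decrement it uniformly. The score is the sum of the
#' running deviations over all positions, so coordinated high expression of
#' the set yields a positive score. Scores are comparable within a cohort;
#' optional normalization divides by the number of genes.
#'
#' @param expr genes x samples expression matrix.
#' @param geneSet character vector of gene IDs; after intersection with the
#'   expression rownames it must be non-empty and smaller than the gene
#'   universe.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide scores by the universe size (default FALSE).
#' @return named numeric vector of per-sample enrichment scores.
#' @export
ssgseaScore <- function(expr, geneSet, alpha = 0.25, normalize = FALSE) {
    genes <- rownames(expr)
    set <- intersect(geneSet, genes)
    if (length(set) == 0)
        stop("gene set is empty after intersection with the expression matrix")
    if (length(set) >= length(genes))
        stop("gene set must be smaller than the gene universe")
    N <- length(genes)
    inSet <- genes %in% set
    nOut <- N - length(set)
    scores <- apply(expr, 2L, function(v) {
        ord <- order(v, decreasing = TRUE)
        isIn <- inSet[ord]
        w <- (N - seq_len(N) + 1)^alpha * isIn
        pIn <- cumsum(w) / sum(w)
        pOut <- cumsum(!isIn) / nOut
        sum(pIn - pOut)
    })
    if (normalize) scores <- scores / N
    scores
}
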