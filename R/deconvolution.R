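#' Deconvolution parameters
#'
#' @param nuGrid nu values tried per sample; the nu minimizing the fit RMSE
#'   is kept (default 0.25, 0.5, 0.75, the conventional linear-kernel grid
#'   for support-vector mixture regression).
#' @param nPermutations permutations for the significance null (default
#'   1000; 0 disables permutation p-values).
#' @param quantileNormalize kept for interface completeness; the supported
#'   (and default) setting is \code{FALSE} - deconvolution runs without
#'   quantile normalization.
#' @param cost regularization constant of the SVR (conventional default 1).
#' @param engine \code{"primal"} (default) solves the linear-kernel nu-SVR
#'   objective directly in its 13-parameter primal form; \code{"libsvm"}
#'   fits the equivalent dual through \pkg{e1071}. Both optimize the same
#'   objective and agree in the estimated proportions to well under 0.01;
#'   the primal route is orders of magnitude faster on signature-sized
#'   problems because the dual has one variable per probe.
#' @param seed integer seed for the permutation null.
#' @return A list of class \code{"DeconvParams"}.
#' @export
deconvParams <- function(nuGrid = c(0.25, 0.5, 0.75),
                         nPermutations = 1000L,
                         quantileNormalize = FALSE, cost = 1,
                         engine = c("primal", "libsvm"), seed = 1L) {
    if (any(nuGrid <= 0 | nuGrid >= 1)) stop("each nu must lie in (0,1)")
    if (nPermutations < 0) stop("nPermutations must be >= 0")
    if (isTRUE(quantileNormalize))
        stop("quantile normalization is not supported; deconvolution runs ",
             "without it")
    structure(list(nuGrid = nuGrid,
                   nPermutations = as.integer(nPermutations),
                   quantileNormalize = FALSE, cost = cost,
                   engine = match.arg(engine),
                   seed = as.integer(seed)),
              class = "DeconvParams")
}

# Linear-kernel nu-SVR solved in the primal. The objective (the same one
# libsvm's nu-regression dual optimizes) is
#   0.5 ||w||^2 + C * (nu * n * eps + sum_i max(0, |y_i - Xw - b| - eps)),
# convex in (w, b, eps >= 0). With a linear kernel and K classes this has
# only K + 2 free parameters, so direct minimization (L-BFGS-B on a lightly
# huberized hinge, eps parameterized on the log scale) is exact and cheap,
# where the dual carries one variable per probe. th0 allows warm starts
# along the nu grid.
.nusvrPrimal <- function(X, y, nu, C = 1, th0 = NULL) {
    n <- nrow(X)
    p <- ncol(X)
    d <- 1e-4   # hinge smoothing width; << the standardized residual scale
    obj <- function(th) {
        w <- th[1:p]
        r <- y - as.numeric(X %*% w) - th[p + 1]
        t_ <- abs(r) - exp(th[p + 2])
        h <- ifelse(t_ <= 0, 0, ifelse(t_ < d, t_^2 / (2 * d), t_ - d / 2))
        0.5 * sum(w^2) + C * (nu * n * exp(th[p + 2]) + sum(h))
    }
    grad <- function(th) {
        w <- th[1:p]
        eps <- exp(th[p + 2])
        r <- y - as.numeric(X %*% w) - th[p + 1]
        t_ <- abs(r) - eps
        hp <- ifelse(t_ <= 0, 0, ifelse(t_ < d, t_ / d, 1)) * sign(r)
        c(w - C * as.numeric(crossprod(X, hp)), -C * sum(hp),
          C * (nu * n - sum(abs(hp))) * eps)
    }
    if (is.null(th0)) {
        w0 <- as.numeric(solve(crossprod(X) + diag(1e-6, p),
                               crossprod(X, y)))
        r0 <- y - as.numeric(X %*% w0)
        th0 <- c(w0, mean(r0),
                 log(max(stats::quantile(abs(r0 - mean(r0)), 1 - nu),
                         1e-6)))
    } else {
        th0[p + 2] <- th0[p + 2] + log(2)  # unpin eps from the previous nu
    }
    o <- stats::optim(th0, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 300L))
    list(w = o$par[seq_len(p)], th = o$par)
}

# One-sample nu-SVR core: standardized signature Xs (probes x classes),
# standardized mixture y. Returns proportions (clamped, normalized), RMSE,
# Pearson r of the fit, and the chosen nu.
.svrCore <- function(Xs, y, nuGrid, cost, engine = "primal") {
    best <- NULL
    th <- NULL
    for (nu in nuGrid) {
        if (engine == "primal") {
            fit <- .nusvrPrimal(Xs, y, nu, C = cost, th0 = th)
            th <- fit$th
            w <- fit$w
        } else {
            fit <- e1071::svm(Xs, y, type = "nu-regression",
                              kernel = "linear", nu = nu, cost = cost,
                              scale = FALSE)
            w <- as.numeric(t(fit$coefs) %*% fit$SV)
        }
        w[w < 0] <- 0
        if (sum(w) > 0) {
            p <- w / sum(w)
            k <- as.numeric(Xs %*% p)
        } else {
            p <- w
            k <- rep(0, length(y))
        }
        rmse <- sqrt(mean((k - y)^2))
        r <- suppressWarnings(stats::cor(k, y))
        if (is.na(r)) r <- 0
        if (is.null(best) || rmse < best$rmse)
            best <- list(p = p, rmse = rmse, r = r, nu = nu)
    }
    best
}

#' Estimate relative cell-class proportions by nu-SVR deconvolution
#'
#' Relative-mode deconvolution of bulk beta-value profiles against a
#' [0,100]-scaled signature matrix. The probe sets are intersected (probes in
#' the signature but absent from the mixture are dropped with a message) and
#' mixture values rescaled x100 to the signature scale. The signature is
#' z-standardized over all entries jointly; each mixture is z-standardized
#' over its probes. For each nu in the grid a linear-kernel nu-support-vector
#' regression of the mixture on the signature columns is fitted; the nu
#' minimizing the RMSE between the fitted and observed standardized mixture
#' is kept. Negative coefficients are clamped to zero and the remainder
#' normalized to sum 1.
#'
#' Permutation significance: a shared null distribution of fit correlations
#' is built from \code{nPermutations} random permutations of pooled mixture
#' values run through the same fitting core; each sample's p-value is the
#' add-one-smoothed fraction of null correlations at or above its observed
#' fit correlation (floored at \code{1/(nPermutations+1)}).
#'
#' @param mixture a \linkS4class{MixtureSet}, or a probes x samples beta
#'   matrix in [0,1].
#' @param sig a \linkS4class{SignatureMatrix} with >= 2 classes.
#' @param params a \code{\link{deconvParams}} object.
#' @return A \linkS4class{DeconvolutionResult}.
#' @examples
#' panel <- generateReferencePanel(panelConfig(nProbes = 4000,
#'                                             dmpsPerClass = 40))
#' sig <- buildSignature(panel)
#' mixes <- simulateTumorMixtures(panel, nPerClass = 2)
#' res <- deconvolve(mixes, sig, deconvParams(nPermutations = 0))
#' head(cellProportions(res))
#' @export
deconvolve <- function(mixture, sig, params = deconvParams()) {
    stopifnot(is(sig, "SignatureMatrix"))
    if (is(mixture, "MixtureSet") || is(mixture, "SummarizedExperiment"))
        mixture <- betaValues(mixture)
    stopifnot(is.matrix(mixture))
    X <- signatureValues(sig)
    if (ncol(X) < 2) stop("signature must have >= 2 classes")

    shared <- intersect(rownames(X), rownames(mixture))
    if (length(shared) == 0)
        stop("no signature probes found in the mixture")
    if (length(shared) < 0.5 * nrow(X))
        stop(sprintf("only %d of %d signature probes present in the mixture (< 50%%)",
                     length(shared), nrow(X)))
    nDropped <- nrow(X) - length(shared)
    if (nDropped > 0)
        message(nDropped, " signature probes absent from the mixture were dropped")
    X <- X[shared, , drop = FALSE]
    Y <- mixture[shared, , drop = FALSE] * 100

    Xs <- (X - mean(X)) / stats::sd(X)
    n <- ncol(Y)
    classes <- colnames(X)
    props <- matrix(0, nrow = n, ncol = length(classes),
                    dimnames = list(colnames(Y), classes))
    rmse <- pearson <- chosenNu <- numeric(n)
    for (j in seq_len(n)) {
        y <- Y[, j]
        sdy <- stats::sd(y)
        if (sdy == 0) stop("mixture sample ", colnames(Y)[j],
                           " has zero variance over the signature probes")
        y <- (y - mean(y)) / sdy
        fit <- .svrCore(Xs, y, params$nuGrid, params$cost, params$engine)
        props[j, ] <- fit$p
        rmse[j] <- fit$rmse
        pearson[j] <- fit$r
        chosenNu[j] <- fit$nu
    }

    permP <- rep(NA_real_, n)
    if (params$nPermutations > 0) {
        nullR <- withSeed(params$seed, {
            pool <- as.numeric(Y)
            vapply(seq_len(params$nPermutations), function(i) {
                yr <- sample(pool, nrow(Xs))
                s <- stats::sd(yr)
                if (s == 0) return(0)
                .svrCore(Xs, (yr - mean(yr)) / s, params$nuGrid,
                         params$cost, params$engine)$r
            }, numeric(1))
        })
        permP <- vapply(pearson, function(r)
            (1 + sum(nullR >= r)) / (params$nPermutations + 1), numeric(1))
    }

    new("DeconvolutionResult", proportions = props, rmse = rmse,
        pearson = pearson, permP = permP, chosenNu = chosenNu,
        nProbesUsed = length(shared))
}

#' Renormalize estimates over the non-cancer compartment
#'
#' Drops the Cancer class and renormalizes the remaining classes to sum 1
#' per sample, giving infiltration "as a proportion of all non-cancer cell
#' types". Samples with zero non-cancer mass are returned as all-zero rows
#' and flagged degenerate.
#'
#' @param result a \linkS4class{DeconvolutionResult} (or samples x classes
#'   proportions matrix) containing a Cancer column.
#' @return list with \code{proportions} (samples x non-cancer classes) and
#'   \code{degenerate} (logical per sample).
#' @export
nonCancerProportions <- function(result) {
    p <- if (is(result, "DeconvolutionResult")) cellProportions(result)
         else result
    if (!"Cancer" %in% colnames(p)) stop("no Cancer class in result")
    q <- p[, setdiff(colnames(p), "Cancer"), drop = FALSE]
    tot <- rowSums(q)
    degenerate <- tot == 0
    q[!degenerate, ] <- q[!degenerate, , drop = FALSE] / tot[!degenerate]
    list(proportions = q, degenerate = degenerate)
}

#' Tumor-infiltrating-lymphocyte fraction
#'
#' Sum of the Treg, CD4T, CD8T and NK estimates per sample, either on the
#' raw relative scale or renormalized over the non-cancer compartment.
#'
#' @param x a \linkS4class{DeconvolutionResult} or samples x classes
#'   proportions matrix containing the four TIL classes.
#' @param renormalize if \code{TRUE}, compute on non-cancer-renormalized
#'   proportions (requires a Cancer column).
#' @return named numeric vector of per-sample TIL fractions.
#' @export
tilFraction <- function(x, renormalize = FALSE) {
    p <- if (is(x, "DeconvolutionResult")) cellProportions(x) else x
    til <- c("Treg", "CD4T", "CD8T", "NK")
    missing <- setdiff(til, colnames(p))
    if (length(missing))
        stop("missing TIL class column(s): ", paste(missing, collapse = ", "))
    if (renormalize) p <- nonCancerProportions(p)$proportions
    rowSums(p[, til, drop = FALSE])
}
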