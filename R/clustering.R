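#' Consensus k-means clustering of immune-profile matrices
#'
#' For each k in \code{kMin:kMax}, repeatedly subsamples the samples
#' (fraction \code{subsampleFraction}, without replacement), runs k-means
#' (Euclidean distance on the proportion vectors, \code{nstart} restarts)
#' on each subsample, and accumulates the consensus matrix: the fraction of
#' co-subsampled runs in which each sample pair lands in the same cluster.
#' The optimal k minimizes the PAC (proportion of ambiguous clustering: the
#' fraction of off-diagonal consensus entries strictly inside (0.1, 0.9));
#' ties go to the smaller k. Final labels are a hierarchical (average
#' linkage) cut of the optimal consensus matrix into k groups.
#'
#' @param profiles samples x cell-type matrix of non-negative proportions.
#' @param kMin,kMax search range for k (default 2 to 6).
#' @param reps subsampling repetitions per k (default 1000).
#' @param subsampleFraction fraction of samples per repetition (default 0.8).
#' @param nstart k-means restarts per repetition (default 10).
#' @param seed integer seed.
#' @return A \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(profiles, kMin = 2L, kMax = 6L, reps = 1000L,
                             subsampleFraction = 0.8, nstart = 10L,
                             seed = 1L) {
    stopifnot(is.matrix(profiles))
    if (min(profiles) < 0) stop("profiles must be non-negative")
    n <- nrow(profiles)
    if (n < kMax + 2) stop("too few samples for the requested k range")
    if (all(apply(profiles, 2L, function(x) length(unique(x))) == 1))
        stop("degenerate input: all samples identical, no partition is stable")
    if (is.null(rownames(profiles)))
        rownames(profiles) <- sprintf("S%04d", seq_len(n))

    withSeed(seed, {
        ks <- kMin:kMax
        nSub <- max(ks[length(ks)] + 1L, round(subsampleFraction * n))
        cons <- vector("list", length(ks))
        names(cons) <- as.character(ks)
        for (ki in seq_along(ks)) {
            k <- ks[ki]
            co <- matrix(0, n, n)     # co-cluster counts
            tog <- matrix(0, n, n)    # co-subsample counts
            for (r in seq_len(reps)) {
                idx <- sample.int(n, nSub)
                km <- suppressWarnings(
                    stats::kmeans(profiles[idx, , drop = FALSE], centers = k,
                                  nstart = nstart, iter.max = 50L))
                tog[idx, idx] <- tog[idx, idx] + 1
                for (cl in seq_len(k)) {
                    m <- idx[km$cluster == cl]
                    co[m, m] <- co[m, m] + 1
                }
            }
            cm <- ifelse(tog > 0, co / tog, 0)
            diag(cm) <- 1
            dimnames(cm) <- list(rownames(profiles), rownames(profiles))
            cons[[ki]] <- cm
        }

        lower <- lower.tri(cons[[1]])
        pac <- vapply(cons, function(cm) {
            v <- cm[lower]
            mean(v > 0.1 & v < 0.9)
        }, numeric(1))

        # area under the consensus CDF and its relative change by k
        area <- vapply(cons, function(cm) {
            v <- sort(cm[lower])
            mean(stats::ecdf(v)(seq(0, 1, length.out = 100)))
        }, numeric(1))
        deltaArea <- c(area[1], diff(area) / pmax(area[-length(area)], 1e-12))
        names(deltaArea) <- names(area)

        optimalK <- ks[which.min(pac)]
        hc <- stats::hclust(stats::as.dist(1 - cons[[as.character(optimalK)]]),
                            method = "average")
        labels <- stats::cutree(hc, k = optimalK)

        new("ConsensusResult", consensusMatrices = cons, pac = pac,
            deltaArea = deltaArea, optimalK = as.integer(optimalK),
            labels = as.integer(labels),
            settings = list(reps = reps,
                            subsampleFraction = subsampleFraction,
                            nstart = nstart, seed = seed))
    })
}

#' Train a transfer classifier on immune-cluster labels
#'
#' Fits a linear-kernel max-margin (SVM) classifier on immune-proportion
#' vectors so cluster labels derived in one cohort can be projected onto new
#' cohorts.
#'
#' @param profiles samples x cell-type matrix.
#' @param labels cluster label per sample (>= 2 classes, each with >= 3
#'   samples).
#' @return list of class \code{"clusterClassifier"}: the fitted model, the
#'   feature (cell-type) names, the label levels, and the training accuracy.
#' @export
trainClusterClassifier <- function(profiles, labels) {
    stopifnot(is.matrix(profiles), nrow(profiles) == length(labels))
    labels <- factor(labels)
    if (nlevels(labels) < 2) stop("need >= 2 label classes")
    if (any(table(labels) < 3)) stop("every class needs >= 3 samples")
    model <- e1071::svm(profiles, labels, kernel = "linear",
                        type = "C-classification")
    acc <- mean(stats::predict(model, profiles) == labels)
    structure(list(model = model, features = colnames(profiles),
                   levels = levels(labels), accuracy = acc),
              class = "clusterClassifier")
}

#' Project cluster labels onto new immune profiles
#'
#' @param classifier a \code{\link{trainClusterClassifier}} fit.
#' @param profiles samples x cell-type matrix carrying (in any order) the
#'   cell-type columns seen at training.
#' @return factor of predicted labels, one per sample.
#' @export
predictCluster <- function(classifier, profiles) {
    stopifnot(inherits(classifier, "clusterClassifier"))
    missing <- setdiff(classifier$features, colnames(profiles))
    if (length(missing))
        stop("profiles lack cell-type column(s): ",
             paste(missing, collapse = ", "))
    stats::predict(classifier$model,
                   profiles[, classifier$features, drop = FALSE])
}
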