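# Association layer: rank-based group tests with post hoc comparisons,
# categorical association, correlation, and median-split survival analysis.

# Dunn's rank-based pairwise z tests (tie-corrected), BH-adjusted.
.dunnTest <- function(values, groups) {
    groups <- factor(groups)
    r <- rank(values)
    N <- length(values)
    ties <- table(r)
    tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
    sigma2 <- N * (N + 1) / 12 - tieCorr
    meanRank <- tapply(r, groups, mean)
    ng <- tapply(r, groups, length)
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    out <- do.call(rbind, lapply(pairs, function(pr) {
        z <- (meanRank[pr[1]] - meanRank[pr[2]]) /
            sqrt(sigma2 * (1 / ng[pr[1]] + 1 / ng[pr[2]]))
        data.frame(pair = paste(pr, collapse = " - "), z = as.numeric(z),
                   p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
    }))
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}

#' Kruskal-Wallis group tests with Dunn's post hoc comparisons
#'
#' For every cell type (column of \code{profiles}): a Kruskal-Wallis omnibus
#' test across the groups, with Benjamini-Hochberg adjustment of the omnibus
#' p-values across cell types, and tie-corrected Dunn's rank-based pairwise
#' z tests (BH-adjusted within each cell type's pairwise family).
#'
#' @param profiles samples x cell-type matrix of values.
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @return list of class \code{"AssociationReport"}: \code{omnibus}
#'   (data.frame: feature, statistic, df, p, q, direction = group with the
#'   highest median) and \code{posthoc} (data.frame: feature, pair, z, p,
#'   p_adj).
#' @export
groupTests <- function(profiles, groups) {
    stopifnot(is.matrix(profiles) || is.data.frame(profiles))
    profiles <- as.matrix(profiles)
    if (is.null(colnames(profiles)))
        colnames(profiles) <- sprintf("feature%d", seq_len(ncol(profiles)))
    groups <- factor(groups)
    if (nlevels(groups) < 2) stop("need >= 2 groups")
    if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
    if (ncol(profiles) == 0) stop("empty cell-type set")

    omnibus <- do.call(rbind, lapply(colnames(profiles), function(f) {
        x <- profiles[, f]
        if (length(unique(x)) == 1) {
            # no rank variation: the statistic is 0 by definition, where
            # the tie correction would otherwise produce 0/0
            kw <- list(statistic = 0, parameter = nlevels(groups) - 1,
                       p.value = 1)
        } else {
            kw <- stats::kruskal.test(x, groups)
        }
        med <- tapply(x, groups, stats::median)
        data.frame(feature = f, statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p = kw$p.value,
                   direction = names(which.max(med)),
                   stringsAsFactors = FALSE)
    }))
    omnibus$q <- stats::p.adjust(omnibus$p, method = "BH")
    omnibus <- omnibus[, c("feature", "statistic", "df", "p", "q",
                           "direction")]

    posthoc <- do.call(rbind, lapply(colnames(profiles), function(f)
        cbind(feature = f, .dunnTest(profiles[, f], groups))))
    rownames(posthoc) <- NULL
    structure(list(omnibus = omnibus, posthoc = posthoc),
              class = "AssociationReport")
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction; degrees of freedom (r-1)(c-1).
#'
#' @param table 2-D non-negative integer contingency table, both margins
#'   with >= 2 non-empty categories.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chiSquareTest <- function(table) {
    table <- as.matrix(table)
    if (any(table < 0) || any(table != round(table)))
        stop("contingency table must hold non-negative integer counts")
    if (nrow(table) < 2 || ncol(table) < 2)
        stop("both margins need >= 2 categories")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("contingency table has an all-zero row or column")
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Rank correlation with significance test
#'
#' Spearman's rank correlation by default (the package's convention for all
#' correlation tests), with an asymptotic p-value; Pearson available behind
#' the \code{method} flag.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return list with \code{rho}, \code{p}, \code{n}, \code{method}.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
    method <- match.arg(method)
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3) stop("need >= 3 observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in x or y")
    ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
         method = method)
}

#' Median split into high/low strata
#'
#' \code{"high"} means strictly greater than the median; ties at the median
#' go to \code{"low"}.
#'
#' @param values numeric vector of length >= 2.
#' @return factor with levels \code{low}, \code{high} and attribute
#'   \code{"rule"} recording the cutoff.
#' @export
medianSplit <- function(values) {
    if (length(values) < 2) stop("need >= 2 values")
    m <- stats::median(values)
    labels <- factor(ifelse(values > m, "high", "low"),
                     levels = c("low", "high"))
    if (any(table(labels) == 0))
        stop("degenerate input: median split leaves an empty stratum")
    attr(labels, "rule") <- sprintf("high iff value > median (%g)", m)
    labels
}

#' Survival association of a per-sample value or stratification
#'
#' Numeric input is median-split into high/low strata
#' (\code{\link{medianSplit}} rule: ties at the median go low). Reports the
#' two-group log-rank test together with a univariate Cox
#' proportional-hazards fit on the high-vs-low indicator (Efron ties),
#' giving the hazard ratio of the high stratum with its Wald 95% CI and
#' p-value.
#'
#' @param values numeric per-sample values (median-split internally) or a
#'   two-level factor/character of precomputed strata.
#' @param clinical data.frame with columns \code{survival_time} (> 0) and
#'   \code{event} (0/1), one row per sample, in the same order.
#' @return list of class \code{"SurvivalResult"}: \code{logrank}
#'   (statistic, p), \code{hr}, \code{ci_lower}, \code{ci_upper},
#'   \code{p} (Wald), \code{n}, \code{rule}.
#' @export
survivalAssociation <- function(values, clinical) {
    stopifnot(all(c("survival_time", "event") %in% colnames(clinical)))
    if (any(clinical$survival_time <= 0))
        stop("survival_time must be positive")
    if (!all(clinical$event %in% c(0, 1)))
        stop("event must be 0/1")
    if (is.numeric(values)) {
        if (length(unique(values)) == 1)
            stop("covariate is constant")
        strata <- medianSplit(values)
        rule <- attr(strata, "rule")
    } else {
        strata <- factor(values)
        if (nlevels(strata) != 2) stop("need exactly 2 strata")
        rule <- "precomputed strata"
    }
    if (length(strata) != nrow(clinical))
        stop("values and clinical table differ in length")
    ev <- tapply(clinical$event, strata, sum)
    if (any(ev == 0))
        stop("each stratum needs >= 1 event for the log-rank test")

    surv <- survival::Surv(clinical$survival_time, clinical$event)
    lr <- survival::survdiff(surv ~ strata)
    cox <- survival::coxph(surv ~ strata, ties = "efron")
    s <- summary(cox)
    structure(list(
        logrank = list(statistic = lr$chisq,
                       p = stats::pchisq(lr$chisq, df = 1,
                                         lower.tail = FALSE)),
        hr = unname(s$conf.int[1, "exp(coef)"]),
        ci_lower = unname(s$conf.int[1, "lower .95"]),
        ci_upper = unname(s$conf.int[1, "upper .95"]),
        p = unname(s$coefficients[1, "Pr(>|z|)"]),
        n = nrow(clinical), rule = rule), class = "SurvivalResult")
}
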