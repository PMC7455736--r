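# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Mean-preserving beta-distributed noise: draws with the given means and a
# common concentration (shape1+shape2). concentration = Inf returns the means
# exactly (degenerate no-noise mode). Means are nudged off the {0,1}
# boundary so shapes stay positive; draws are supported on [0,1] by
# construction.
rbetaMean <- function(n, mean, concentration) {
    if (is.infinite(concentration)) return(rep(mean, length.out = n))
    if (concentration <= 0) stop("noise concentration must be positive")
    m <- pmin(pmax(mean, 1e-6), 1 - 1e-6)
    stats::rbeta(n, shape1 = m * concentration,
                 shape2 = (1 - m) * concentration)
}

# Row medians for small-replicate matrices without a matrixStats dependency.
rowMedians2 <- function(x) apply(x, 1L, stats::median)

probeIDs <- function(n) sprintf("cg%08d", seq_len(n))

# Mean per-class profile of a reference panel (probes x classes).
classMeanProfiles <- function(panel) {
    b <- betaValues(panel)
    ct <- cellTypes(panel)
    classes <- unique(ct)
    out <- vapply(classes, function(cl)
        rowMeans(b[, ct == cl, drop = FALSE]), numeric(nrow(b)))
    dimnames(out) <- list(rownames(b), classes)
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
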