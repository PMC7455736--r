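# Shared fixtures and independent oracles used across test files.

# Compact 12-class panel: fewer probes/DMPs than the study-scale default but
# the same roster, with 4 replicates so per-comparison FDR control retains
# the planted probes at this reduced probe count.
smallPanelConfig <- function(seed = 42L, replicatesPerClass = 4L, ...) {
    panelConfig(nProbes = 3000L, dmpsPerClass = 20L,
                replicatesPerClass = replicatesPerClass, seed = seed, ...)
}

# Hand-built two-group beta matrices with near-zero within-group noise, used
# to drive selection oracles deterministically.
twoGroupBetas <- function(meansA, meansB, reps = 3L, jitter = 1e-3) {
    n <- length(meansA)
    ids <- sprintf("cg%08d", seq_len(n))
    jit <- function(m, r) m + jitter * (r - (reps + 1) / 2)
    A <- vapply(seq_len(reps), function(r) jit(meansA, r), numeric(n))
    B <- vapply(seq_len(reps), function(r) jit(meansB, r), numeric(n))
    rownames(A) <- rownames(B) <- ids
    colnames(A) <- sprintf("A%d", seq_len(reps))
    colnames(B) <- sprintf("B%d", seq_len(reps))
    list(A = pmin(pmax(A, 0), 1), B = pmin(pmax(B, 0), 1), ids = ids)
}

# Adjusted Rand index between two labelings (independent of the clustering
# code under test).
ari <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sumIJ <- sum(comb2(tab))
    sumI <- sum(comb2(rowSums(tab)))
    sumJ <- sum(comb2(colSums(tab)))
    nC2 <- comb2(sum(tab))
    expected <- sumI * sumJ / nC2
    (sumIJ - expected) / ((sumI + sumJ) / 2 - expected)
}

# Brute-force Benjamini-Hochberg step-up: q_i = min_{j: p_(j) >= p_(i)}
# min(1, m p_(j) / j), computed by direct enumeration.
bhStepUp <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    sorted <- p[o]
    for (i in seq_len(m))
        q[o[i]] <- min(1, min(sorted[i:m] * m / (i:m)))
    q
}

# Non-negative least squares oracle for the deconvolution contract, via an
# implementation independent of the SVR path.
nnlsProportions <- function(Xs, y) {
    w <- pracma::lsqnonneg(Xs, y)$x
    w / sum(w)
}

# Compositions with a designed CD8T gradient (and fixed monocyte share),
# the fixture on which planted expression signals are recovered.
gradientProportions <- function(n = 60, seed = 4) {
    set.seed(seed)
    cd8 <- runif(n, 0, 0.5)
    mono <- 0.2
    rest <- 1 - cd8 - mono
    tp <- cbind(CD8T = cd8, Monocyte = mono, Treg = rest / 3,
                "B-cell" = rest / 3, Cancer = rest / 3)
    rownames(tp) <- sprintf("S%03d", seq_len(n))
    tp
}

# Planted three-archetype immune-profile cohort for clustering tests.
archetypeProfiles <- function(n = 150L, noiseSD = 0.03, seed = 7L) {
    classes <- c("Treg", "CD4T", "CD8T", "B-cell", "NK", "Eosinophil",
                 "Neutrophil", "Monocyte", "Endothelial", "Glia", "Neuron")
    arch <- rbind(
        CD8high = c(.02, .05, .60, .05, .05, .04, .04, .05, .04, .03, .03),
        Treghigh = c(.55, .10, .03, .06, .06, .05, .05, .04, .02, .02, .02),
        Monohigh = c(.04, .05, .03, .05, .05, .05, .05, .55, .05, .04, .04))
    colnames(arch) <- classes
    set.seed(seed)
    lab <- rep(1:3, length.out = n)
    x <- arch[lab, ] + matrix(rnorm(n * ncol(arch), 0, noiseSD), n)
    x <- pmax(x, 0)
    x <- x / rowSums(x)
    rownames(x) <- sprintf("S%03d", seq_len(n))
    list(profiles = x, labels = lab)
}
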