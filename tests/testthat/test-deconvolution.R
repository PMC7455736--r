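# A compact panel/signature pair shared across deconvolution tests.
dcPanel <- generateReferencePanel(
    panelConfig(classNames = c("CD8T", "Treg", "B-cell", "Monocyte",
                               "Cancer"),
                nProbes = 1000, dmpsPerClass = 40, replicatesPerClass = 4,
                seed = 21))
dcSig <- buildSignature(dcPanel)

# mixtures of signature columns on the beta scale, as a probes x samples
# matrix compatible with deconvolve()
blend <- function(sig, weights) {
    v <- signatureValues(sig) / 100
    m <- v %*% weights
    colnames(m) <- paste0("mix", seq_len(ncol(m)))
    m
}

test_that("a pure signature column is recovered as a pure sample", {
    w <- matrix(c(1, 0, 0, 0, 0), ncol = 1)
    res <- deconvolve(blend(dcSig, w), dcSig, deconvParams(nPermutations = 0))
    expect_gte(cellProportions(res)[1, "CD8T"], 0.99)
})

test_that("noiseless blends match truth and an NNLS oracle within 0.01", {
    skip_if_not_installed("pracma")
    classes <- colnames(signatureValues(dcSig))
    w <- matrix(0, length(classes), 3)
    rownames(w) <- classes
    w[c("CD8T", "Treg"), 1] <- 0.5
    w[c("B-cell", "Cancer"), 2] <- c(0.25, 0.75)
    w[, 3] <- c(0.1, 0.2, 0.3, 0.15, 0.25)
    m <- blend(dcSig, w)
    res <- deconvolve(m, dcSig, deconvParams(nPermutations = 0))
    p <- cellProportions(res)
    expect_lt(max(abs(p - t(w))), 0.01)

    # independent constrained least-squares oracle on the same
    # standardized problem
    X <- signatureValues(dcSig)
    Xs <- (X - mean(X)) / sd(X)
    for (j in 1:3) {
        y <- m[, j] * 100
        y <- (y - mean(y)) / sd(y)
        expect_lt(max(abs(p[j, ] - nnlsProportions(Xs, y))), 0.01)
    }
})

test_that("primal and libsvm engines agree on structured mixtures", {
    mix <- simulateTumorMixtures(dcPanel, nPerClass = 1, seed = 22)
    p1 <- cellProportions(deconvolve(mix, dcSig,
        deconvParams(nPermutations = 0, engine = "primal")))
    p2 <- cellProportions(deconvolve(mix, dcSig,
        deconvParams(nPermutations = 0, engine = "libsvm")))
    expect_lt(max(abs(p1 - p2)), 0.01)
})

test_that("estimates are invariant to positive rescaling of the mixture", {
    w <- matrix(c(0.2, 0.3, 0.1, 0.15, 0.25), ncol = 1)
    m <- blend(dcSig, w)
    r1 <- cellProportions(deconvolve(m, dcSig,
                                     deconvParams(nPermutations = 0)))
    r2 <- cellProportions(deconvolve(m * 0.4, dcSig,
                                     deconvParams(nPermutations = 0)))
    expect_lt(max(abs(r1 - r2)), 1e-6)
})

test_that("estimates rise monotonically with the true fraction on noiseless input", {
    fracs <- c(0.1, 0.3, 0.5, 0.7)
    est <- vapply(fracs, function(f) {
        w <- matrix(c(f, rep((1 - f) / 4, 4)), ncol = 1)
        res <- deconvolve(blend(dcSig, w), dcSig,
                          deconvParams(nPermutations = 0))
        cellProportions(res)[1, "CD8T"]
    }, numeric(1))
    expect_true(all(diff(est) > 0))
})

test_that("relative-mode conservation holds on noisy mixtures", {
    mix <- simulateTumorMixtures(dcPanel, nPerClass = 3,
                                 noiseConcentration = 100, seed = 23)
    p <- cellProportions(deconvolve(mix, dcSig,
                                    deconvParams(nPermutations = 0)))
    expect_true(all(p >= 0))
    expect_true(all(abs(rowSums(p) - 1) <= 1e-9))
})

test_that("permutation p-values flag pure signal and respect their floor", {
    w <- matrix(c(0.4, 0.3, 0.1, 0.1, 0.1), ncol = 1)
    res <- deconvolve(blend(dcSig, w), dcSig,
                      deconvParams(nPermutations = 1000, seed = 7))
    d <- fitDiagnostics(res)
    expect_lte(d$permP[1], 0.01)
    expect_gte(d$permP[1], 1 / 1001)
    expect_true(d$chosenNu %in% c(0.25, 0.5, 0.75))
})

test_that("deconvolution contracts are enforced", {
    w <- matrix(rep(0.2, 5), ncol = 1)
    m <- blend(dcSig, w)
    bad <- m
    rownames(bad) <- paste0("xx", seq_len(nrow(bad)))
    expect_error(deconvolve(bad, dcSig, deconvParams(nPermutations = 0)),
                 "no signature probes")
    half <- m[seq_len(floor(nrow(m) * 0.4)), , drop = FALSE]
    expect_error(deconvolve(half, dcSig, deconvParams(nPermutations = 0)),
                 "50%")
    oneClass <- new("SignatureMatrix",
                    values = signatureValues(dcSig)[, 1, drop = FALSE],
                    provenance = provenance(dcSig), params = list())
    expect_error(deconvolve(m, oneClass, deconvParams(nPermutations = 0)),
                 ">= 2 classes")
    expect_error(deconvParams(nuGrid = c(0.5, 1.2)), "nu")
    expect_error(deconvParams(quantileNormalize = TRUE), "quantile")
})

test_that("non-cancer renormalization handles uniform, pure and degenerate rows", {
    classes <- c("Treg", "CD4T", "CD8T", "B-cell", "NK", "Eosinophil",
                 "Neutrophil", "Monocyte", "Endothelial", "Glia", "Neuron",
                 "Cancer")
    p <- rbind(c(rep(0.25 / 11, 11), 0.75),
               c(rep(0, 11), 1),
               c(0, 0, 0.5, rep(0, 8), 0.5))
    colnames(p) <- classes
    out <- nonCancerProportions(p)
    expect_equal(unname(out$proportions[1, ]), rep(1 / 11, 11),
                 tolerance = 1e-12)
    expect_identical(out$degenerate, c(FALSE, TRUE, FALSE))
    expect_true(all(out$proportions[2, ] == 0))
    expect_equal(unname(out$proportions[3, "CD8T"]), 1.0)
    expect_error(nonCancerProportions(p[, 1:11]), "Cancer")
})

test_that("TIL fraction sums the four lymphocyte classes on both scales", {
    classes <- c("Treg", "CD4T", "CD8T", "NK", "Monocyte", "Cancer")
    p <- rbind(a = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.75),
               b = c(0, 0, 0, 0, 0.25, 0.75),
               c = c(0.1, 0.1, 0, 0, 0.3, 0.5))
    colnames(p) <- classes
    expect_equal(unname(tilFraction(p)), c(0.2, 0, 0.2), tolerance = 1e-12)
    expect_equal(unname(tilFraction(p, renormalize = TRUE))[3], 0.4,
                 tolerance = 1e-12)
    expect_error(tilFraction(p[, -1]), "Treg")
})
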