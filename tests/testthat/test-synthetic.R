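test_that("reference panel generation honors the configuration", {
    cfg <- smallPanelConfig()
    panel <- generateReferencePanel(cfg)
    expect_s4_class(panel, "ReferencePanel")
    expect_identical(length(unique(cellTypes(panel))), 12L)
    b <- betaValues(panel)
    expect_true(min(b) >= 0 && max(b) <= 1)
    expect_true(all(grepl("^cg\\d{8}$", rownames(b))))
    expect_identical(ncol(b), 12L * cfg$replicatesPerClass)
})

test_that("panel configuration rejects impossible designs", {
    expect_error(panelConfig(nProbes = 100, dmpsPerClass = 20),
                 "disjoint")
    expect_error(panelConfig(replicatesPerClass = 1), "replicates")
    expect_error(panelConfig(plantedDelta = 0), "plantedDelta")
    expect_error(panelConfig(plantedDelta = 1.2), "plantedDelta")
    expect_error(panelConfig(noiseConcentration = -1), "positive")
})

test_that("degenerate no-noise mode yields identical replicates", {
    panel <- generateReferencePanel(
        smallPanelConfig(noiseConcentration = Inf))
    b <- betaValues(panel)
    ct <- cellTypes(panel)
    for (cl in unique(ct)) {
        sub <- b[, ct == cl, drop = FALSE]
        expect_true(all(sub == sub[, 1]))
    }
})

test_that("planted DMP effect sizes are recoverable from the emitted matrix", {
    panel <- generateReferencePanel(smallPanelConfig(seed = 1L))
    b <- betaValues(panel)
    ct <- cellTypes(panel)
    dmps <- plantedDMPs(panel)
    for (cl in unique(ct)) {
        own <- b[c(dmps[[cl]]$hypo, dmps[[cl]]$hyper), ct == cl,
                 drop = FALSE]
        oth <- b[c(dmps[[cl]]$hypo, dmps[[cl]]$hyper), ct != cl,
                 drop = FALSE]
        deltas <- abs(rowMeans(own) - rowMeans(oth))
        expect_gte(median(deltas), 0.4)
    }
})

test_that("generation is seed-reproducible and seed-sensitive", {
    p1 <- generateReferencePanel(smallPanelConfig(seed = 5L))
    p2 <- generateReferencePanel(smallPanelConfig(seed = 5L))
    p3 <- generateReferencePanel(smallPanelConfig(seed = 6L))
    expect_identical(betaValues(p1), betaValues(p2))
    expect_false(identical(betaValues(p1), betaValues(p3)))
})

test_that("cancer-line divergence is planted exactly", {
    panel <- generateReferencePanel(smallPanelConfig())
    lines <- generateCancerLines(panel, nDivergent = 50,
                                 divergenceDelta = 0.3, familySD = 0.2)
    b <- betaValues(lines)
    fam <- cancerFamily(lines)
    mb <- b[, which(!is.na(fam) & fam == "MB-like"), drop = FALSE]
    mrt <- b[, which(!is.na(fam) & fam == "MRT-like"), drop = FALSE]
    meanDiff <- abs(rowMeans(mb) - rowMeans(mrt))
    mbSD <- apply(mb, 1, sd)
    hit <- meanDiff > 0.1 & mbSD > 0.15
    expect_identical(sum(hit), 50L)
    expect_setequal(rownames(b)[hit], metadata(lines)$divergentProbes)

    none <- generateCancerLines(panel, nDivergent = 0)
    b0 <- betaValues(none)
    fam0 <- cancerFamily(none)
    mb0 <- b0[, which(!is.na(fam0) & fam0 == "MB-like"), drop = FALSE]
    mrt0 <- b0[, which(!is.na(fam0) & fam0 == "MRT-like"), drop = FALSE]
    hit0 <- abs(rowMeans(mb0) - rowMeans(mrt0)) > 0.1 &
        apply(mb0, 1, sd) > 0.15
    expect_identical(sum(hit0), 0L)
})

test_that("cancer-line generation demands enough cancer replicates", {
    panel <- generateReferencePanel(
        smallPanelConfig(replicatesPerClass = 3L))
    expect_error(generateCancerLines(panel), ">= 4 replicates")
    noCancer <- generateReferencePanel(panelConfig(
        classNames = c("CD8T", "Treg"), nProbes = 200,
        dmpsPerClass = 10, seed = 1))
    expect_error(generateCancerLines(noCancer), "no Cancer class")
})

test_that("tumor mixtures carry exact ground truth at the set cancer fraction", {
    panel <- generateReferencePanel(smallPanelConfig())
    mix <- simulateTumorMixtures(panel, nPerClass = 3, seed = 2)
    tp <- trueProportions(mix)
    expect_identical(ncol(mix), 36L)
    expect_true(all(abs(rowSums(tp) - 1) <= 1e-9))
    expect_true(all(tp >= 0))
    expect_true(all(tp[, "Cancer"] == 0.75))
    expect_true(min(betaValues(mix)) >= 0 && max(betaValues(mix)) <= 1)
    expect_error(simulateTumorMixtures(panel, cancerFraction = 1),
                 "cancerFraction")
})

test_that("zero-noise mixtures equal the weighted mean of class profiles", {
    panel <- generateReferencePanel(smallPanelConfig())
    mix <- simulateTumorMixtures(panel, nPerClass = 2,
                                 noiseConcentration = Inf, seed = 3)
    b <- betaValues(panel)
    ct <- cellTypes(panel)
    means <- vapply(colnames(trueProportions(mix)), function(cl)
        rowMeans(b[, ct == cl, drop = FALSE]), numeric(nrow(b)))
    expected <- means %*% t(trueProportions(mix))
    expect_equal(unname(betaValues(mix)), unname(expected),
                 tolerance = 1e-12)
})

test_that("expression generator plants recoverable cytolytic signal", {
    tp <- gradientProportions(n = 60, seed = 4)

    noiseless <- generateExpressionProfiles(tp, noiseSD = 0, seed = 5)
    keep <- !attr(noiseless, "isAnchor")
    cyt <- cytScore(noiseless)[keep]
    fit <- lm(cyt ~ tp[, "CD8T"])
    expect_lt(max(abs(residuals(fit))), 1e-9)   # exact affine function

    noisy <- generateExpressionProfiles(tp, noiseSD = 0.1, seed = 5)
    keep <- !attr(noisy, "isAnchor")
    drv <- colMeans(noisy[c("GZMA", "PRF1"), keep])
    expect_gte(cor(tp[, "CD8T"], drv, method = "spearman"), 0.9)

    expect_error(generateExpressionProfiles(tp, noiseSD = -1), "noiseSD")
})

test_that("planted microglial share is recovered by the expression ratio", {
    expr <- generateExpressionProfiles(gradientProportions(n = 60, seed = 4),
                                       microgliaShare = 0.7,
                                       noiseSD = 0.1, seed = 6)
    frac <- microgliaFraction(expr)
    med <- median(frac[!attr(expr, "isAnchor")])
    expect_lt(abs(med - 0.7), 0.05)
})

test_that("clinical annotation generator honors censoring and the null", {
    cl0 <- generateClinicalAnnotations(100, plantedHR = 2, censorRate = 0,
                                       seed = 1)
    expect_true(all(cl0$event == 1L))
    expect_true(all(cl0$survival_time > 0))
    expect_error(generateClinicalAnnotations(100, censorRate = 1),
                 "censorRate")
    expect_error(generateClinicalAnnotations(1), "n must be")
    expect_error(generateClinicalAnnotations(10, plantedHR = 0),
                 "plantedHR")

    # under the null (HR = 1) the log-rank test should rarely reject
    hits <- vapply(1:40, function(s) {
        cl <- generateClinicalAnnotations(500, plantedHR = 1,
                                          censorRate = 0.1, seed = s)
        sa <- survivalAssociation(factor(cl$group), cl)
        sa$logrank$p > 0.05
    }, logical(1))
    expect_gte(sum(hits), 36L)   # >= 90% of seeds non-significant
})

test_that("planted hazard ratio is recovered by Cox regression", {
    cl <- generateClinicalAnnotations(500, plantedHR = 2, censorRate = 0,
                                      seed = 3)
    sa <- survivalAssociation(factor(cl$group, levels = c("low", "high")),
                              cl)
    expect_gte(sa$hr, 1.6)
    expect_lte(sa$hr, 2.5)
    expect_true(sa$ci_lower <= 2 && sa$ci_upper >= 2)
})
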