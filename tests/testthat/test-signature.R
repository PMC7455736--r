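test_that("identical groups yield an empty selection", {
    g <- twoGroupBetas(rep(0.5, 20), rep(0.5, 20))
    sel <- pairwiseDMPs(g$A, g$A)
    expect_identical(nrow(sel), 0L)
})

test_that("balanced selection matches a brute-force ranking oracle", {
    # 10 probes: 4 at delta +0.5 (graded), 4 at -0.5 (graded), 2 at +0.05
    deltas <- c(0.50, 0.48, 0.46, 0.44, -0.50, -0.47, -0.45, -0.43,
                0.05, 0.04)
    g <- twoGroupBetas(0.4 + deltas, rep(0.4, 10))
    sel <- pairwiseDMPs(g$A, g$B, signatureParams(maxDMPs = 4))

    # independent oracle: exhaustive rank enumeration over qualifying probes
    qual <- which(abs(deltas) >= 0.2)
    pos <- qual[deltas[qual] > 0]
    neg <- qual[deltas[qual] < 0]
    expPos <- g$ids[pos[order(-deltas[pos])][1:2]]
    expNeg <- g$ids[neg[order(deltas[neg])][1:2]]
    expect_setequal(sel$probe[sel$direction == "hyper"], expPos)
    expect_setequal(sel$probe[sel$direction == "hypo"], expNeg)
    expect_false(any(g$ids[9:10] %in% sel$probe))
    expect_lte(nrow(sel), 4L)
})

test_that("per-direction caps are never exceeded under defaults", {
    # 300 probes per direction all differential: selection must cap at
    # 100 per direction, 200 total
    deltas <- c(runif(300, 0.3, 0.5), -runif(300, 0.3, 0.5),
                rep(0, 100))
    g <- twoGroupBetas(pmin(0.45 + deltas, 1), rep(0.45, 700))
    sel <- pairwiseDMPs(g$A, g$B)
    expect_lte(nrow(sel), 200L)
    expect_lte(sum(sel$direction == "hyper"), 100L)
    expect_lte(sum(sel$direction == "hypo"), 100L)
    expect_identical(nrow(sel), 200L)   # enough candidates to fill the cap
})

test_that("signature equals a by-hand union and scaled class means", {
    # 3-class panel with disjoint known DMP blocks and near-zero noise
    base <- rep(0.5, 60)
    mk <- function(shift) {
        m <- base
        m[shift] <- base[shift] + c(rep(0.4, 5), rep(-0.4, 5))
        m
    }
    blocks <- list(1:10, 11:20, 21:30)
    means <- lapply(blocks, mk)
    reps <- 3
    ids <- sprintf("cg%08d", 1:60)
    betas <- do.call(cbind, lapply(means, function(m)
        vapply(1:reps, function(r) m + 1e-3 * (r - 2), numeric(60))))
    rownames(betas) <- ids
    colnames(betas) <- sprintf("%s_r%d", rep(c("X", "Y", "Z"), each = reps),
                               rep(1:reps, 3))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = betas),
        colData = S4Vectors::DataFrame(
            cellType = rep(c("X", "Y", "Z"), each = reps),
            cancerFamily = NA_character_,
            row.names = colnames(betas)))
    panel <- new("ReferencePanel", se)

    sig <- buildSignature(panel, signatureParams())
    # by-hand oracle: every blocked probe differs by 0.4 between its class
    # and both others, so the union is exactly the 30 planted probes and
    # values are per-class means x 100
    expect_setequal(rownames(signatureValues(sig)), ids[1:30])
    ct <- rep(c("X", "Y", "Z"), each = reps)
    expected <- vapply(c("X", "Y", "Z"), function(cl)
        rowMeans(betas[rownames(signatureValues(sig)), ct == cl]) * 100,
        numeric(30))
    expect_equal(signatureValues(sig)[, c("X", "Y", "Z")], expected,
                 tolerance = 1e-12)
})

test_that("default synthetic panel gives a 12-class signature tracking planted DMPs", {
    panel <- generateReferencePanel(smallPanelConfig())
    sig <- buildSignature(panel)
    v <- signatureValues(sig)
    expect_identical(ncol(v), 12L)
    expect_true(min(v) >= 0 && max(v) <= 100)

    planted <- unlist(lapply(plantedDMPs(panel), function(d)
        c(d$hypo, d$hyper)), use.names = FALSE)
    expect_gte(mean(rownames(v) %in% planted), 0.95)
})

test_that("selection is invariant to sample and probe shuffling", {
    panel <- generateReferencePanel(smallPanelConfig(seed = 9L))
    b <- betaValues(panel)
    ct <- cellTypes(panel)
    a <- b[, ct == "CD8T"]
    c_ <- b[, ct == "Treg"]
    s1 <- pairwiseDMPs(a, c_)
    set.seed(1)
    pr <- sample(nrow(b))
    s2 <- pairwiseDMPs(a[pr, ], c_[pr, ])
    s3 <- pairwiseDMPs(a[, c(3, 1, 4, 2)], c_[, c(2, 4, 1, 3)])
    expect_setequal(s1$probe, s2$probe)
    expect_setequal(s1$probe, s3$probe)
})

test_that("cancer-line filter applies the threshold conjunction", {
    ids <- sprintf("cg%08d", 1:4)
    v <- matrix(50, 4, 2, dimnames = list(ids, c("A", "Cancer")))
    prov <- data.frame(probe = ids, comparisons = "A.vs.Cancer",
                       direction = "hyper")
    sig <- new("SignatureMatrix", values = v, provenance = prov,
               params = list())

    # per-probe construction: (meanDiff, mbSD) =
    #   cg1: (0.2, 0.2)  -> removed (both exceeded)
    #   cg2: (0.2, 0.05) -> retained (SD below)
    #   cg3: (0.05, 0.2) -> retained (diff below)
    #   cg4: (0.0, 0.0)  -> retained
    mkLines <- function(center, spread)
        cbind(center - spread / sqrt(2), center + spread / sqrt(2))
    mb <- rbind(mkLines(0.60, 0.2), mkLines(0.60, 0.05),
                mkLines(0.45, 0.2), mkLines(0.40, 0))
    mrt <- rbind(mkLines(0.40, 0), mkLines(0.40, 0),
                 mkLines(0.40, 0), mkLines(0.40, 0))
    rownames(mb) <- rownames(mrt) <- ids

    out <- filterCancerLineVariability(sig, mb, mrt)
    expect_identical(out$removed$probe, ids[1])
    expect_setequal(rownames(signatureValues(out$signature)), ids[2:4])

    same <- filterCancerLineVariability(sig, mb, mb)
    expect_identical(nrow(same$removed), 0L)
    expect_error(filterCancerLineVariability(sig, mb[, 1, drop = FALSE],
                                             mrt), ">= 2 profiles")
})

test_that("low-variance flagging uses the per-type average SD threshold", {
    ids <- sprintf("cg%08d", 1:2)
    v <- matrix(c(10, 90, 50, 50), 2, 2,
                dimnames = list(ids, c("A", "B")))
    sig <- new("SignatureMatrix", values = v,
               provenance = data.frame(probe = ids, comparisons = "A.vs.B",
                                       direction = "hyper"),
               params = list())
    mkType <- function(sds) {
        spread <- sds / sqrt(2)
        m <- cbind(0.5 - spread, 0.5 + spread)
        rownames(m) <- ids
        m
    }
    # probe 1 average SD 0.004 (flag), probe 2 average SD 0.006 (no flag)
    types <- list(T1 = mkType(c(0.003, 0.005)),
                  T2 = mkType(c(0.005, 0.007)))
    rep <- flagLowVarianceProbes(sig, types)
    expect_identical(rep$flagged, c(TRUE, FALSE))
    expect_equal(rep$avgSD, c(0.004, 0.006), tolerance = 1e-12)
    expect_error(flagLowVarianceProbes(sig, list()), "non-empty")
})

test_that("parameter grid search evaluates the documented grid and picks the winner", {
    panel <- generateReferencePanel(
        panelConfig(classNames = c("CD8T", "Treg", "Monocyte", "Cancer"),
                    nProbes = 800, dmpsPerClass = 40,
                    replicatesPerClass = 4, seed = 3))
    mix <- simulateTumorMixtures(panel, nPerClass = 4, seed = 4)

    single <- gridSearchSignature(panel, mix, deltas = 0.2,
                                  ndmpGrid = 100L)
    expect_identical(nrow(single$table), 1L)
    expect_identical(single$best$maxDMPs, 100L)

    full <- gridSearchSignature(panel, mix)
    expect_identical(nrow(full$table), 10L)

    # a grid point too strict to select anything fails gracefully and the
    # informative point wins
    suppressMessages(
        two <- gridSearchSignature(panel, mix, deltas = c(0.2, 0.95),
                                   ndmpGrid = 100L))
    expect_true(is.na(two$table$pearson[two$table$delta == 0.95]))
    expect_identical(two$best$deltaMin, 0.2)
})
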