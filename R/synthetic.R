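#' Configuration for a simulated reference panel
#'
#' Describes a panel of pure-population methylomes with class-specific
#' planted differentially methylated probe (DMP) blocks. Defaults follow the
#' study design this package targets: 12 broad cell classes (Treg, CD4T,
#' CD8T, B-cell, NK, Eosinophil, Neutrophil, Monocyte, Endothelial, Glia,
#' Neuron, Cancer), 20,000 probes, 400 planted DMPs per class (half hypo-,
#' half hyper-methylated) at a beta difference of 0.5 against the shared
#' baseline.
#'
#' @param classNames character vector of cell-class labels; must include
#'   \code{"Cancer"} for tumor-mixture simulation.
#' @param replicatesPerClass replicate profiles per class (>= 2).
#' @param nProbes total probe count; must be at least
#'   \code{length(classNames) * dmpsPerClass} so planted blocks are disjoint.
#' @param dmpsPerClass planted DMPs per class (even, half per direction).
#' @param plantedDelta beta difference of planted DMPs, in (0, 1].
#' @param noiseConcentration positive scalar controlling replicate
#'   dispersion around class means (beta-distribution concentration;
#'   \code{Inf} = no noise). Default 100 gives a replicate SD of about 0.05
#'   at beta = 0.5, typical of well-behaved sorted-population arrays.
#' @param seed integer seed for reproducible generation.
#' @return A validated list of class \code{"PanelConfig"}.
#' @export
panelConfig <- function(classNames = c("Treg", "CD4T", "CD8T", "B-cell",
                                       "NK", "Eosinophil", "Neutrophil",
                                       "Monocyte", "Endothelial", "Glia",
                                       "Neuron", "Cancer"),
                        replicatesPerClass = 3L,
                        nProbes = 20000L,
                        dmpsPerClass = 400L,
                        plantedDelta = 0.5,
                        noiseConcentration = 100,
                        seed = 1L) {
    stopifnot(length(classNames) >= 2, !anyDuplicated(classNames))
    if (replicatesPerClass < 2)
        stop("replicatesPerClass must be >= 2")
    if (dmpsPerClass < 2 || dmpsPerClass %% 2 != 0)
        stop("dmpsPerClass must be an even count >= 2")
    if (nProbes < length(classNames) * dmpsPerClass)
        stop("nProbes too small: planted DMP blocks must be disjoint ",
             "(need >= ", length(classNames) * dmpsPerClass, ")")
    if (plantedDelta <= 0 || plantedDelta > 1)
        stop("plantedDelta must lie in (0,1]")
    if (noiseConcentration <= 0)
        stop("noiseConcentration must be positive")
    structure(list(classNames = classNames,
                   replicatesPerClass = as.integer(replicatesPerClass),
                   nProbes = as.integer(nProbes),
                   dmpsPerClass = as.integer(dmpsPerClass),
                   plantedDelta = plantedDelta,
                   noiseConcentration = noiseConcentration,
                   seed = as.integer(seed)),
              class = "PanelConfig")
}

#' Generate a simulated reference panel of pure-population methylomes
#'
#' Draws a shared baseline beta profile and, for each cell class, shifts a
#' disjoint block of \code{dmpsPerClass} probes by \code{plantedDelta}
#' relative to that baseline (half hypo-, half hyper-methylated). Baselines
#' for planted probes are drawn so the shifted class mean stays inside
#' [0.05, 0.95], preserving the full planted effect size. Replicate profiles
#' are beta-distributed around the class means with dispersion set by
#' \code{noiseConcentration}, so emitted values never leave [0,1].
#'
#' @param config a \code{\link{panelConfig}} object.
#' @return A \linkS4class{ReferencePanel}; \code{plantedDMPs()} returns the
#'   per-class probe indices with direction.
#' @examples
#' panel <- generateReferencePanel(panelConfig(nProbes = 6000,
#'                                             dmpsPerClass = 40))
#' panel
#' @export
generateReferencePanel <- function(config = panelConfig()) {
    stopifnot(inherits(config, "PanelConfig"))
    withSeed(config$seed, {
        K <- length(config$classNames)
        d <- config$dmpsPerClass
        P <- config$nProbes
        ids <- probeIDs(P)
        baseline <- stats::runif(P, 0.1, 0.9)

        # disjoint planted blocks, half hypo / half hyper per class;
        # baselines at planted probes are redrawn to leave room for the
        # full shift so the planted effect size is not clipped
        planted <- vector("list", K)
        names(planted) <- config$classNames
        delta <- config$plantedDelta
        for (k in seq_len(K)) {
            block <- ((k - 1L) * d + 1L):(k * d)
            hypo <- block[seq_len(d / 2L)]
            hyper <- block[(d / 2L + 1L):d]
            baseline[hypo] <- stats::runif(length(hypo),
                                           min(delta + 0.05, 0.95), 0.95)
            baseline[hyper] <- stats::runif(length(hyper), 0.05,
                                            max(0.95 - delta, 0.05))
            planted[[k]] <- list(hypo = ids[hypo], hyper = ids[hyper])
        }
        classMeans <- matrix(baseline, nrow = P, ncol = K,
                             dimnames = list(ids, config$classNames))
        for (k in seq_len(K)) {
            hypo <- match(planted[[k]]$hypo, ids)
            hyper <- match(planted[[k]]$hyper, ids)
            classMeans[hypo, k] <- baseline[hypo] - delta
            classMeans[hyper, k] <- baseline[hyper] + delta
        }

        R <- config$replicatesPerClass
        betas <- matrix(0, nrow = P, ncol = K * R)
        ct <- rep(config$classNames, each = R)
        colnames(betas) <- sprintf("%s_rep%d", ct, rep(seq_len(R), times = K))
        rownames(betas) <- ids
        for (j in seq_len(K * R)) {
            m <- classMeans[, match(ct[j], config$classNames)]
            betas[, j] <- rbetaMean(P, m, config$noiseConcentration)
        }

        se <- SummarizedExperiment(
            assays = list(beta = betas),
            colData = DataFrame(cellType = ct,
                                cancerFamily = NA_character_,
                                row.names = colnames(betas)))
        metadata(se)$plantedDMPs <- planted
        metadata(se)$config <- config
        new("ReferencePanel", se)
    })
}

#' Split simulated cancer replicates into divergent cell-line families
#'
#' Splits the Cancer replicates of a simulated panel into two cell-line
#' families (\code{"MB-like"} and \code{"MRT-like"}) and plants exactly
#' \code{nDivergent} probes on which the families diverge: the planted
#' pattern has an exact between-family mean beta difference of
#' \code{divergenceDelta} and an exact MB-like within-family SD of
#' \code{familySD}, so the downstream cancer-line QC filter (mean difference
#' > 0.1 and MB-family SD > 0.15) removes precisely these probes when both
#' parameters exceed the thresholds. To make the divergent set exact, cancer
#' replicates are set to their class mean on all non-divergent probes; this
#' is a fixture-grade generator for exercising the QC filter, not a model of
#' cell-line epigenomes.
#'
#' Divergent probes are planted inside the Cancer class's own DMP block
#' (falling back to unplanted probes if the block is too small) so that they
#' enter the signature and the filter has something to remove.
#'
#' @param panel a simulated \linkS4class{ReferencePanel} whose Cancer class
#'   has >= 4 replicates.
#' @param nDivergent number of probes to make family-divergent.
#' @param divergenceDelta planted between-family mean beta difference.
#' @param familySD planted SD across MB-like replicates at divergent probes.
#' @param seed integer seed.
#' @return The panel with cancer replicates relabelled by family and the
#'   divergent pattern planted; \code{metadata()$divergentProbes} lists the
#'   affected probe IDs.
#' @export
generateCancerLines <- function(panel, nDivergent = 50,
                                divergenceDelta = 0.3, familySD = 0.2,
                                seed = 1L) {
    stopifnot(is(panel, "ReferencePanel"))
    idx <- which(cellTypes(panel) == "Cancer")
    if (length(idx) == 0) stop("panel has no Cancer class")
    if (length(idx) < 4)
        stop("Cancer class needs >= 4 replicates to form two families")
    withSeed(seed, {
        b <- betaValues(panel)
        nMB <- ceiling(length(idx) / 2)
        mb <- idx[seq_len(nMB)]
        mrt <- idx[(nMB + 1L):length(idx)]

        cancerMean <- rowMeans(b[, idx, drop = FALSE])
        b[, idx] <- cancerMean   # noise-free off the divergent set

        divIDs <- character(0)
        if (nDivergent > 0) {
            dmps <- plantedDMPs(panel)
            pool <- if (!is.null(dmps) && !is.null(dmps$Cancer))
                c(dmps$Cancer$hypo, dmps$Cancer$hyper) else character(0)
            if (length(pool) < nDivergent)
                pool <- c(pool, setdiff(rownames(b), pool))
            divIDs <- pool[seq_len(nDivergent)]
            di <- match(divIDs, rownames(b))

            # exact planted pattern: MRT-like constant at `lo`; MB-like at
            # `lo + divergenceDelta` plus zero-mean deviations whose sample
            # SD is exactly familySD.
            dev <- seq_len(nMB) - (nMB + 1) / 2
            dev <- dev / stats::sd(dev) * familySD
            lo <- 0.25
            hi <- lo + divergenceDelta
            if (hi + max(dev) > 1 || hi + min(dev) < 0)
                stop("divergenceDelta/familySD too large to stay in [0,1]")
            b[di, mrt] <- lo
            b[di, mb] <- rep(hi + dev, each = length(di))
        }

        out <- panel
        assay(out, "beta") <- b
        fam <- as.character(colData(out)$cancerFamily)
        fam[mb] <- "MB-like"
        fam[mrt] <- "MRT-like"
        colData(out)$cancerFamily <- fam
        metadata(out)$divergentProbes <- divIDs
        validObject(out)
        out
    })
}

#' Simulate bulk tumor mixtures with known composition
#'
#' Emulates in-silico tumor benchmarking mixtures: the per-class mean beta
#' profiles of the panel are combined by a weighted mean. For each cell
#' class in turn, \code{nPerClass} samples are generated in which that
#' (spiked) class receives a set proportion of the non-cancer compartment
#' (drawn uniformly from [0,1] per sample and recorded exactly), the
#' remaining non-cancer classes receive uniform random proportions
#' renormalized to the rest of the compartment, the whole non-cancer vector
#' is scaled by \code{1 - cancerFraction}, and the Cancer class is fixed at
#' \code{cancerFraction} exactly. With the 12-class default panel and
#' \code{nPerClass = 100} this yields 1200 simulated samples. Bounded
#' beta-distributed noise (concentration \code{noiseConcentration}) is added
#' around each weighted-mean profile; \code{Inf} disables it.
#'
#' @param panel a \linkS4class{ReferencePanel} including a Cancer class.
#' @param nPerClass simulated samples per spiked class.
#' @param cancerFraction fixed Cancer proportion in [0,1).
#' @param noiseConcentration beta concentration of measurement noise around
#'   the mixed profile; default 1000 (SD about 0.016 at beta = 0.5).
#' @param seed integer seed.
#' @return A \linkS4class{MixtureSet} with exact \code{trueProportions}.
#' @export
simulateTumorMixtures <- function(panel, nPerClass = 100L,
                                  cancerFraction = 0.75,
                                  noiseConcentration = 1000,
                                  seed = 1L) {
    stopifnot(is(panel, "ReferencePanel"))
    if (cancerFraction < 0 || cancerFraction >= 1)
        stop("cancerFraction must lie in [0,1)")
    means <- classMeanProfiles(panel)
    classes <- colnames(means)
    if (!"Cancer" %in% classes) stop("panel must include a Cancer class")
    if (length(classes) < 2) stop("panel needs >= 2 classes")
    nonCancer <- setdiff(classes, "Cancer")

    withSeed(seed, {
        nTot <- nPerClass * length(classes)
        props <- matrix(0, nrow = nTot, ncol = length(classes),
                        dimnames = list(NULL, classes))
        spiked <- character(nTot)
        i <- 0L
        for (cl in classes) {
            for (s in seq_len(nPerClass)) {
                i <- i + 1L
                w <- numeric(length(nonCancer))
                names(w) <- nonCancer
                if (cl == "Cancer") {
                    u <- stats::runif(length(nonCancer))
                    w[] <- u / sum(u)
                } else {
                    setProp <- stats::runif(1)
                    others <- setdiff(nonCancer, cl)
                    u <- stats::runif(length(others))
                    w[cl] <- setProp
                    w[others] <- u / sum(u) * (1 - setProp)
                }
                props[i, nonCancer] <- w * (1 - cancerFraction)
                props[i, "Cancer"] <- cancerFraction
                spiked[i] <- cl
            }
        }
        rownames(props) <- sprintf("mix_%s_%03d",
                                   rep(classes, each = nPerClass),
                                   rep(seq_len(nPerClass),
                                       times = length(classes)))

        mixed <- means %*% t(props)   # probes x samples weighted means
        if (!is.infinite(noiseConcentration)) {
            noisy <- rbetaMean(length(mixed), as.numeric(mixed),
                               noiseConcentration)
            mixed <- matrix(noisy, nrow = nrow(mixed),
                            dimnames = dimnames(mixed))
        }
        colnames(mixed) <- rownames(props)

        se <- SummarizedExperiment(
            assays = list(beta = mixed),
            colData = DataFrame(spikedClass = spiked,
                                row.names = colnames(mixed)))
        metadata(se)$trueProportions <- props
        metadata(se)$cancerFraction <- cancerFraction
        new("MixtureSet", se)
    })
}

#' Default validation gene panels
#'
#' The fixed gene panels used by the validation scores: the 5-CpG meTIL
#' probe set; the cytolytic-score genes GZMA and PRF1; and the
#' microglia-vs-peripheral-monocyte expression panels (6 microglial, 7
#' peripheral, 2 pan-monocyte genes), with Ensembl IDs retained alongside
#' symbols.
#'
#' @return A list of class \code{"GenePanel"} with elements
#'   \code{metilProbes}, \code{cytGenes}, \code{microgliaGenes},
#'   \code{peripheralGenes}, \code{panMonocyteGenes}.
#' @export
genePanel <- function() {
    structure(list(
        metilProbes = c("cg20792833", "cg23642747", "cg12069309",
                        "cg20425130", "cg21554552"),
        cytGenes = c("GZMA", "PRF1"),
        microgliaGenes = c(P2RY13 = "ENSG00000181631",
                           P2RY12 = "ENSG00000169313",
                           GPR34 = "ENSG00000171659",
                           SLC2A5 = "ENSG00000142583",
                           OLFML3 = "ENSG00000116774",
                           TMEM119 = "ENSG00000183160"),
        peripheralGenes = c(F10 = "ENSG00000126218",
                            EMILIN2 = "ENSG00000132205",
                            F5 = "ENSG00000198734",
                            C3 = "ENSG00000125730",
                            GDA = "ENSG00000119125",
                            SELL = "ENSG00000188404",
                            HP = "ENSG00000257017"),
        panMonocyteGenes = c(CD11B = "ENSG00000169896",
                             CD45 = "ENSG00000081237")),
        class = "GenePanel")
}

#' Simulate expression profiles with planted cytolytic and microglial signal
#'
#' Generates a log-scale expression matrix matched to a set of mixture
#' compositions. GZMA and PRF1 increase affinely with the CD8T fraction
#' (planting a cytolytic signal); microglia-panel and peripheral-panel genes
#' track a per-sample latent microglial fraction of the monocyte compartment
#' centred on \code{microgliaShare}. Because the downstream microglia ratio
#' standardizes and min-max rescales panel scores across the cohort, the
#' generator appends pure-microglia and pure-peripheral anchor profiles
#' (sorted-cell controls, flagged in the \code{"isAnchor"} attribute) so the
#' rescaled scores are anchored at the ends of the biological range and the
#' planted share is recoverable.
#'
#' @param trueProportions samples x classes matrix with rows summing to 1;
#'   must contain \code{CD8T} and \code{Monocyte} columns.
#' @param genes a \code{\link{genePanel}}.
#' @param microgliaShare planted cohort-level microglial share of the
#'   monocyte signal, in [0,1].
#' @param noiseSD Gaussian SD of log-scale measurement noise (>= 0).
#' @param nBackground number of uninformative background genes.
#' @param seed integer seed.
#' @return genes x samples numeric matrix (log-scale, non-negative), with
#'   attributes \code{isAnchor} (logical per sample) and
#'   \code{latentMicroglia} (per-sample planted fraction).
#' @export
generateExpressionProfiles <- function(trueProportions, genes = genePanel(),
                                       microgliaShare = 0.5, noiseSD = 0.1,
                                       nBackground = 50L, seed = 1L) {
    stopifnot(is.matrix(trueProportions))
    if (any(abs(rowSums(trueProportions) - 1) > 1e-9))
        stop("trueProportions rows must sum to 1")
    if (noiseSD < 0) stop("noiseSD must be non-negative")
    if (microgliaShare < 0 || microgliaShare > 1)
        stop("microgliaShare must lie in [0,1]")
    for (cl in c("CD8T", "Monocyte"))
        if (!cl %in% colnames(trueProportions))
            stop("trueProportions must contain a '", cl, "' column")

    withSeed(seed, {
        n <- nrow(trueProportions)
        sampleIDs <- rownames(trueProportions) %||% sprintf("S%03d", seq_len(n))
        cd8 <- trueProportions[, "CD8T"]

        # latent microglial fraction per bulk sample, centred on the share
        jit <- if (noiseSD > 0) stats::rnorm(n, 0, 0.05) else numeric(n)
        latent <- pmin(pmax(microgliaShare + jit, 0), 1)

        nAnchor <- 3L
        anchorIDs <- c(sprintf("MGref%d", seq_len(nAnchor)),
                       sprintf("PMref%d", seq_len(nAnchor)))
        latentAll <- c(latent, rep(1, nAnchor), rep(0, nAnchor))
        ids <- c(sampleIDs, anchorIDs)
        N <- length(ids)

        geneIDs <- c(genes$cytGenes, names(genes$microgliaGenes),
                     names(genes$peripheralGenes),
                     names(genes$panMonocyteGenes),
                     sprintf("BG%03d", seq_len(nBackground)))
        expr <- matrix(0, nrow = length(geneIDs), ncol = N,
                       dimnames = list(geneIDs, ids))

        noise <- function(k) if (noiseSD > 0) stats::rnorm(k, 0, noiseSD) else 0
        cyt <- 2 + 8 * c(cd8, rep(0, 2 * nAnchor))
        for (g in genes$cytGenes) expr[g, ] <- pmax(cyt + noise(N), 0)
        for (g in names(genes$microgliaGenes))
            expr[g, ] <- pmax(2 + 6 * latentAll + noise(N), 0)
        for (g in names(genes$peripheralGenes))
            expr[g, ] <- pmax(2 + 6 * (1 - latentAll) + noise(N), 0)
        for (g in names(genes$panMonocyteGenes))
            expr[g, ] <- pmax(5 + noise(N), 0)
        bg <- sprintf("BG%03d", seq_len(nBackground))
        expr[bg, ] <- pmax(matrix(stats::rnorm(length(bg) * N, 5, 1),
                                  length(bg), N), 0)

        attr(expr, "isAnchor") <- c(rep(FALSE, n), rep(TRUE, 2 * nAnchor))
        attr(expr, "latentMicroglia") <- latentAll
        expr
    })
}

#' Simulate clinical annotations with a planted hazard ratio
#'
#' Exponential survival times whose hazard is multiplied by
#' \code{plantedHR} for the high-covariate group (covariate drawn uniform,
#' split at its median). Each subject is independently censored with
#' probability \code{censorRate}, in which case the recorded time is drawn
#' uniformly before the event time.
#'
#' @param n number of subjects (>= 2).
#' @param plantedHR hazard ratio of the high group (> 0).
#' @param covariate name of the covariate column in the output.
#' @param censorRate independent censoring probability in [0,1).
#' @param baseHazard baseline exponential hazard (events per month).
#' @param seed integer seed.
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{survival_time} (months, > 0), \code{event} (0/1) and the named
#'   covariate.
#' @export
generateClinicalAnnotations <- function(n, plantedHR = 2,
                                        covariate = "score",
                                        censorRate = 0, baseHazard = 0.02,
                                        seed = 1L) {
    if (n < 2) stop("n must be >= 2")
    if (plantedHR <= 0) stop("plantedHR must be positive")
    if (censorRate < 0 || censorRate >= 1)
        stop("censorRate must lie in [0,1)")
    withSeed(seed, {
        x <- stats::runif(n)
        high <- x > stats::median(x)
        rate <- baseHazard * ifelse(high, plantedHR, 1)
        time <- stats::rexp(n, rate = rate)
        event <- rep(1L, n)
        cens <- stats::runif(n) < censorRate
        time[cens] <- stats::runif(sum(cens), 0, time[cens])
        event[cens] <- 0L
        time <- pmax(time, 1e-6)
        out <- data.frame(sample_id = sprintf("P%04d", seq_len(n)),
                          group = ifelse(high, "high", "low"),
                          survival_time = time, event = event)
        out[[covariate]] <- x
        out
    })
}
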