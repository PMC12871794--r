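## Simulation experiments: calibration/inflation/power grid across
## observation scales, additive-lambda recovery, and the CV experiment.

.TRANSFORM_LABELS <- function(lambdas, includeRint) {
  c(sprintf("lambda=%g", lambdas), if (includeRint) "rint")
}

#' Rejection-rate grid across interaction strength and observation scale
#'
#' For every cell of {gamma values} x {observation scales}, simulates
#' replicate cohorts, tests each polygenic score column in its own model on
#' every transformed version of the phenotype (the Box-Cox grid plus RINT),
#' and records the fraction of tests rejected at the Bonferroni-corrected
#' threshold. A pooled summary of the RINT false-positive rate over the
#' null (gamma = 0) cells is attached as the \code{rintFprNull} attribute,
#' alongside per-cell rates in the result.
#'
#' Tests are per PGS column (m per replicate), so rejection fractions pool
#' columns and replicates. Replicates of different cells use independent
#' seed streams unless \code{matchedLatent} is set, in which case the three
#' observation scales of a given gamma share latent draws (useful to verify
#' that rank-based quantities are identical across observed scales).
#'
#' @param nSamples,nPgs,h2,envVar,envType,envFreq generative parameters; see
#'   [simulationConfig()]. Defaults are the desk-scale study size
#'   n = 20,000 (the reference conditions use n = 100,000).
#' @param gammas interaction coefficients to cross with the scales.
#' @param scales observation scales to include.
#' @param nReplicates replicate cohorts per cell.
#' @param lambdas Box-Cox grid.
#' @param includeRint also test the RINT-transformed phenotype.
#' @param alpha family-wise level; threshold is alpha / (#transforms).
#' @param seed master seed; all cell streams derive from it.
#' @param matchedLatent reuse latent draws across scales within a gamma.
#' @return data.frame with one row per (gamma, scale, transform):
#'   gamma, scale, transform, rejectionRate, nTests, nReplicates, threshold,
#'   meanCv (mean coefficient of variation of the observed phenotype).
#'   Attribute \code{rintFprNull} holds the pooled null RINT rejection
#'   fraction and its test count.
#' @export
runScenarioGrid <- function(nSamples = 20000, nPgs = 25, h2 = 0.3,
                            envVar = 0.2, gammas = c(0, 0.1),
                            scales = c("identity", "exponential", "inverse_logit"),
                            nReplicates = 100, lambdas = lambdaGrid(),
                            includeRint = TRUE, alpha = 0.05, seed = 1L,
                            envType = "binary", envFreq = 0.5,
                            matchedLatent = FALSE) {
  nT <- length(lambdas) + as.integer(includeRint)
  threshold <- alpha / nT
  labels <- .TRANSFORM_LABELS(lambdas, includeRint)

  rows <- list()
  rintNullSig <- 0L; rintNullTot <- 0L
  cellId <- 0L
  for (gi in seq_along(gammas)) {
    for (si in seq_along(scales)) {
      cellId <- cellId + 1L
      rej <- matrix(0L, nReplicates, nT)
      cvs <- numeric(nReplicates)
      nFailed <- 0L
      for (r in seq_len(nReplicates)) {
        cellSeed <- if (matchedLatent) {
          seed + 1009L * gi + r            # same latent stream across scales
        } else {
          seed + 100003L * cellId + r
        }
        cfg <- simulationConfig(nSamples = nSamples, nPgs = nPgs, h2 = h2,
                                envVar = envVar, gamma = gammas[gi],
                                observationScale = scales[si],
                                envType = envType, envFreq = envFreq,
                                seed = cellSeed)
        res <- tryCatch({
          ch <- simulateCohort(cfg)
          cvs[r] <- stats::sd(ch@yObserved) / mean(ch@yObserved)
          pmat <- sapply(lambdas, function(l)
            scanInteractions(boxCox(ch@yObserved, l), ch@G, ch@E)$p)
          if (includeRint)
            pmat <- cbind(pmat, scanInteractions(rint(ch@yObserved), ch@G, ch@E)$p)
          pmat
        }, error = function(e) NULL)
        if (is.null(res)) { nFailed <- nFailed + 1L; next }
        rej[r, ] <- colSums(res < threshold)
      }
      if (nFailed > 0)
        message(sprintf("cell gamma=%g scale=%s: %d failed replicate(s) excluded",
                        gammas[gi], scales[si], nFailed))
      nOk <- nReplicates - nFailed
      nTests <- nOk * nPgs
      rates <- colSums(rej) / nTests
      rows[[length(rows) + 1L]] <- data.frame(
        gamma = gammas[gi], scale = scales[si], transform = labels,
        rejectionRate = rates, nTests = nTests, nReplicates = nOk,
        threshold = threshold, meanCv = mean(cvs[seq_len(nReplicates)]),
        stringsAsFactors = FALSE)
      if (includeRint && gammas[gi] == 0) {
        rintNullSig <- rintNullSig + sum(rej[, nT])
        rintNullTot <- rintNullTot + nTests
      }
    }
  }
  out <- do.call(rbind, rows)
  if (includeRint)
    attr(out, "rintFprNull") <- c(fpr = rintNullSig / max(rintNullTot, 1L),
                                  nTests = rintNullTot)
  out
}

#' Most-additive lambda of a profile
#'
#' The grid lambda with the largest interaction p-value (least evidence of
#' interaction). Ties are broken toward the lambda closest to 1 (no
#' transformation), then toward the smaller lambda.
#'
#' @param profile a [LambdaProfile-class].
#' @return a single lambda from the grid.
#' @export
estimateAdditiveLambda <- function(profile) {
  stopifnot(is(profile, "LambdaProfile"))
  pv <- profile@pValues
  lam <- profile@lambdas
  cand <- which(pv == max(pv))
  if (length(cand) > 1L) {
    d <- abs(lam[cand] - 1)
    cand <- cand[d == min(d)]
    if (length(cand) > 1L) cand <- cand[which.min(lam[cand])]
  }
  lam[cand[1]]
}

#' Recovery of the additive scale over replicates
#'
#' Simulates additive (gamma = 0) cohorts observed on a chosen scale, profiles
#' the interaction p-value of the combined polygenic signal across the
#' Box-Cox grid, and returns each replicate's most-additive lambda. For an
#' exponentially observed additive trait the estimates concentrate near
#' lambda = 0 (the log scale).
#'
#' @param nReplicates number of replicate cohorts.
#' @param nSamples cohort size (single-score cohorts, m = 1, carrying the
#'   full heritable fraction — the clearest setting for scale recovery).
#' @param observationScale observed scale of the simulated trait.
#' @param h2,envVar,envType,envFreq generative parameters.
#' @param lambdas Box-Cox grid.
#' @param seed master seed.
#' @return numeric vector of estimated lambdas, one per replicate.
#' @export
recoverAdditiveLambda <- function(nReplicates = 50, nSamples = 20000,
                                  observationScale = "exponential",
                                  h2 = 0.3, envVar = 0.2, lambdas = lambdaGrid(),
                                  envType = "binary", envFreq = 0.5, seed = 1L) {
  vapply(seq_len(nReplicates), function(r) {
    cfg <- simulationConfig(nSamples = nSamples, nPgs = 1, h2 = h2,
                            envVar = envVar, gamma = 0,
                            observationScale = observationScale,
                            envType = envType, envFreq = envFreq,
                            seed = seed + r)
    ch <- simulateCohort(cfg)
    pv <- vapply(lambdas, function(l)
      scanInteractions(boxCox(ch@yObserved, l), ch@G, ch@E)$p[1], numeric(1))
    prof <- new("LambdaProfile", lambdas = as.numeric(lambdas), pValues = pv,
                gammaHats = rep(NA_real_, length(lambdas)), rintP = NA_real_,
                threshold = 0.05 / length(lambdas),
                classification = classifyScaleDependence(
                  pv, lambdas, 0.05 / length(lambdas)))
    estimateAdditiveLambda(prof)
  }, numeric(1))
}

#' Sign-flipping (XOR-like) cohort
#'
#' A constructed architecture in which the polygenic score increases the
#' phenotype when E = 1 and decreases it when E = 0 (effect +c / -c). The
#' sign flip survives every monotone transformation, so the interaction is
#' scale-independent by construction.
#'
#' @param nSamples cohort size.
#' @param effect the magnitude c of the group-specific score effect.
#' @param seed integer seed.
#' @return a [Cohort-class] observed on the (shifted) identity scale.
#' @export
signFlipCohort <- function(nSamples = 2000, effect = 0.3, seed = 1L) {
  set.seed(seed)
  g <- stats::rnorm(nSamples)
  E <- as.numeric(stats::rbinom(nSamples, 1L, 0.5))
  yLatent <- effect * g * (2 * E - 1) + stats::rnorm(nSamples)
  yObserved <- .observe(yLatent, "identity", NA_real_)
  cfg <- simulationConfig(nSamples = nSamples, nPgs = 1, h2 = 0, envVar = 0,
                          gamma = 2 * effect, seed = seed)
  new("Cohort", G = matrix(g, ncol = 1, dimnames = list(NULL, "PGS_1")),
      E = E, covariates = matrix(numeric(0), nSamples, 0),
      yLatent = yLatent, yObserved = yObserved,
      trueBeta = -effect, trueAlpha = 0, trueGamma = 2 * effect,
      config = cfg)
}

#' Coefficient-of-variation experiment
#'
#' Asks how the coefficient of variation (CV) of a multiplicative phenotype
#' governs the distortion of the cross-group genetic correlation on the
#' default (exponentiated) scale. For each target CV, a two-group cohort is
#' simulated with partially distinct per-group SNP effects on the latent
#' (log) scale; the latent variance is set from the lognormal identity
#' \eqn{CV^2 = e^{\sigma^2} - 1}. Group-stratified GWAS are run on the
#' default and log scales and the naive effect-size correlation between
#' groups is computed on each; the reported quantity is the absolute change
#' after log scaling. Within a replicate the same panel, effects and noise
#' draws are reused across all CV levels (only the latent variance changes),
#' so the CV effect is isolated from simulation noise.
#'
#' @param cvGrid increasing positive CV targets.
#' @param nSnps unlinked SNPs in the panel.
#' @param nPerGroup samples per group.
#' @param effectCor correlation of the two groups' true latent effects.
#' @param h2Latent fraction of latent variance that is genetic.
#' @param nReplicates replicates (matched across CV levels).
#' @param seed master seed.
#' @return data.frame: cv, meanAbsChange, seAbsChange, meanRgLog,
#'   meanRgDefault, nReplicates.
#' @export
runCvExperiment <- function(cvGrid = c(0.05, 0.1, 0.2, 0.5, 1.0),
                            nSnps = 200, nPerGroup = 2000, effectCor = 0.5,
                            h2Latent = 0.5, nReplicates = 20, seed = 1L) {
  if (any(cvGrid <= 0) || is.unsorted(cvGrid, strictly = TRUE))
    stop("cvGrid must be positive and strictly increasing")
  n <- 2L * nPerGroup
  change <- matrix(NA_real_, nReplicates, length(cvGrid))
  rgLog <- matrix(NA_real_, nReplicates, length(cvGrid))
  rgDef <- matrix(NA_real_, nReplicates, length(cvGrid))

  for (r in seq_len(nReplicates)) {
    set.seed(seed + 7919L * r)
    f <- stats::runif(nSnps, 0.1, 0.9)
    dos <- matrix(stats::rbinom(n * nSnps, 2L, rep(f, each = n)), n, nSnps,
                  dimnames = list(NULL, sprintf("snp%d", seq_len(nSnps))))
    groups <- rep(c("A", "B"), each = nPerGroup)
    u <- stats::rnorm(nSnps)
    bA <- u
    bB <- effectCor * u + sqrt(1 - effectCor^2) * stats::rnorm(nSnps)
    noise <- stats::rnorm(n)
    map <- data.frame(snp = colnames(dos), chr = 1L,
                      bp = seq_len(nSnps) * 10000L, a1 = "A", a2 = "B",
                      freq = f, stringsAsFactors = FALSE)

    # raw genetic scores, centred and standardised once per replicate
    gscore <- numeric(n)
    idxA <- which(groups == "A"); idxB <- which(groups == "B")
    gscore[idxA] <- as.vector(dos[idxA, ] %*% bA)
    gscore[idxB] <- as.vector(dos[idxB, ] %*% bB)
    gA <- (gscore[idxA] - mean(gscore[idxA])) / stats::sd(gscore[idxA])
    gB <- (gscore[idxB] - mean(gscore[idxB])) / stats::sd(gscore[idxB])
    z <- numeric(n); z[idxA] <- gA; z[idxB] <- gB

    for (ci in seq_along(cvGrid)) {
      sigma2 <- log(1 + cvGrid[ci]^2)
      yLat <- sqrt(sigma2) * (sqrt(h2Latent) * z + sqrt(1 - h2Latent) * noise)
      yDef <- exp(yLat)
      panelA <- new("GenotypePanel", dosages = dos[idxA, , drop = FALSE],
                    snpMap = map, trueEffects = bA)
      panelB <- new("GenotypePanel", dosages = dos[idxB, , drop = FALSE],
                    snpMap = map, trueEffects = bB)
      gwasAlog <- runGwas(panelA, yLat[idxA])
      gwasBlog <- runGwas(panelB, yLat[idxB])
      gwasAdef <- runGwas(panelA, yDef[idxA])
      gwasBdef <- runGwas(panelB, yDef[idxB])
      snps <- map$snp
      rl <- naiveGeneticCorrelation(gwasAlog, gwasBlog, snps)
      rd <- naiveGeneticCorrelation(gwasAdef, gwasBdef, snps)
      rgLog[r, ci] <- rl; rgDef[r, ci] <- rd
      change[r, ci] <- abs(rl - rd)
    }
  }
  data.frame(cv = cvGrid,
             meanAbsChange = colMeans(change),
             seAbsChange = apply(change, 2, stats::sd) / sqrt(nReplicates),
             meanRgLog = colMeans(rgLog),
             meanRgDefault = colMeans(rgDef),
             nReplicates = nReplicates)
}
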