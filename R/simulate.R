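## Generative simulation of cohorts and genotype panels.

#' Construct a SimulationConfig
#'
#' Defaults reproduce the reference simulation conditions: n = 100,000
#' samples, m = 25 polygenic scores, heritable fraction 0.3, environmental
#' fraction 0.2, unit-variance Gaussian noise, binary (Sex-like,
#' Bernoulli(0.5)) environment and identity observation scale.
#'
#' @param nSamples cohort size n.
#' @param nPgs number of polygenic score columns m.
#' @param h2 fraction of latent variance explained by the scores.
#' @param envVar fraction of latent variance explained by the environment.
#' @param gamma scalar interaction coefficient applied to every score column.
#' @param observationScale \code{"identity"}, \code{"exponential"} or
#'   \code{"inverse_logit"}.
#' @param locationShift nonnegative shift added to the latent trait before
#'   the observation map; \code{NA} (default) uses the automatic rule: on the
#'   identity scale the minimum latent value is placed 6 latent standard
#'   deviations above zero so the observed phenotype is safely positive; the
#'   exponential and inverse-logit maps are already positive, so no shift.
#' @param envType \code{"binary"} or \code{"gaussian"}.
#' @param envFreq success probability for a binary environment.
#' @param seed integer random seed.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nSamples = 100000, nPgs = 25, h2 = 0.3,
                             envVar = 0.2, gamma = 0,
                             observationScale = "identity",
                             locationShift = NA_real_,
                             envType = "binary", envFreq = 0.5, seed = 1L) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nPgs = as.integer(nPgs),
      h2 = as.numeric(h2), envVar = as.numeric(envVar),
      gamma = as.numeric(gamma), observationScale = observationScale,
      locationShift = as.numeric(locationShift),
      envType = envType, envFreq = as.numeric(envFreq),
      seed = as.integer(seed))
}

.observe <- function(yLatent, scale, shift) {
  if (is.na(shift)) {
    shift <- if (scale == "identity") {
      s <- stats::sd(yLatent)
      max(0, 6 * s - min(yLatent))
    } else 0
  }
  x <- yLatent + shift
  y <- switch(scale,
    identity = x,
    exponential = exp(x),
    inverse_logit = 1 / (1 + exp(-x))
  )
  if (any(y <= 0))
    stop(sprintf(
      "observed phenotype not strictly positive (Box-Cox requires Y > 0); smallest value is %g; increase locationShift",
      min(y)))
  y
}

#' Simulate a cohort under the latent interaction model
#'
#' Draws \eqn{G} with independent standard-normal columns, an environment
#' \eqn{E} (binary or Gaussian), unit-variance noise, and assembles
#' \eqn{Y' = G\beta + E\alpha + (G*E)\gamma + \epsilon}. \eqn{\beta} is
#' constant across columns and scaled so \eqn{var(G\beta)} is the \code{h2}
#' fraction of the total latent variance \eqn{1/(1-h2-envVar)}; \eqn{\alpha}
#' likewise for \code{envVar}. The interaction coefficient \code{gamma} is a
#' scalar applied to every column's product with E and its variance
#' contribution is on top of the three stated fractions. The observed
#' phenotype is \eqn{Y = f(Y' + shift)} for the configured observation scale.
#'
#' @param config a [SimulationConfig-class].
#' @return a validated [Cohort-class]; reproducible from \code{config@seed}.
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nSamples
  m <- config@nPgs
  total <- 1 / (1 - config@h2 - config@envVar)

  G <- matrix(stats::rnorm(n * m), n, m,
              dimnames = list(NULL, paste0("PGS_", seq_len(m))))
  E <- if (config@envType == "binary") {
    as.numeric(stats::rbinom(n, 1L, config@envFreq))
  } else {
    stats::rnorm(n)
  }
  varE <- if (config@envType == "binary") config@envFreq * (1 - config@envFreq) else 1

  beta <- rep(if (config@h2 > 0) sqrt(config@h2 * total / m) else 0, m)
  alpha <- if (config@envVar > 0) sqrt(config@envVar * total / varE) else 0
  eps <- stats::rnorm(n)

  yLatent <- as.vector(G %*% beta) + alpha * E +
    config@gamma * rowSums(G) * E + eps
  yObserved <- .observe(yLatent, config@observationScale, config@locationShift)

  new("Cohort", G = G, E = E, covariates = matrix(numeric(0), n, 0),
      yLatent = yLatent, yObserved = yObserved,
      trueBeta = beta, trueAlpha = alpha, trueGamma = config@gamma,
      config = config)
}

#' Indices retained after symmetric tail filtering
#'
#' Emulates phenotype outlier exclusion: drops samples strictly above the
#' (1 - tailFraction) empirical quantile or strictly below the tailFraction
#' quantile (linear-interpolation quantiles, \code{type = 7}). With
#' \code{tailFraction = 0} everything is retained; a constant vector is
#' always fully retained. Idempotent at a fixed tail fraction on its own
#' output only in distribution terms; on a grid it simply never empties.
#'
#' @param y finite phenotype vector.
#' @param tailFraction fraction in [0, 0.5) removed from each tail
#'   (reference analyses use 1e-4, i.e. the top/bottom 0.01\%).
#' @return integer vector of retained indices (subset of \code{seq_along(y)}).
#' @export
filterOutliers <- function(y, tailFraction = 1e-4) {
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite")
  if (tailFraction < 0 || tailFraction >= 0.5)
    stop("tailFraction must lie in [0, 0.5)")
  if (tailFraction == 0) return(seq_along(y))
  q <- stats::quantile(y, c(tailFraction, 1 - tailFraction), type = 7, names = FALSE)
  keep <- which(y >= q[1] & y <= q[2])
  if (length(keep) == 0L) stop("no samples retained after outlier filtering")
  keep
}

#' Simulate a genotype panel and phenotype with known architecture
#'
#' Draws unlinked SNP dosages Binomial(2, freq), builds a latent phenotype
#' additively from per-SNP true effects (optionally group-specific, e.g. one
#' effect vector per sex) plus Gaussian noise, and optionally exponentiates
#' it to emulate a multiplicative (log-additive) trait.
#'
#' @param nSamples number of samples.
#' @param nSnps number of SNPs.
#' @param freq allele frequencies: a single range \code{c(lo, hi)} to draw
#'   from uniformly, or a length-\code{nSnps} vector; all values in (0,1).
#' @param effects per-SNP effects: numeric vector of length \code{nSnps}, a
#'   named list of such vectors (one per group), or NULL for all-zero.
#' @param groups optional factor/character of group labels per sample; when
#'   \code{effects} is a list and \code{groups} is NULL, samples are split
#'   evenly at random across the effect groups.
#' @param noiseSd standard deviation of the latent noise.
#' @param multiplicative when TRUE the observed phenotype is
#'   \code{exp(latent)}; otherwise it equals the latent phenotype.
#' @param intercept latent intercept.
#' @param chr chromosome label for the SNP map.
#' @param spacingBp spacing between consecutive SNP positions (1-based).
#' @param seed integer random seed.
#' @return list with elements \code{panel} (a [GenotypePanel-class]) and
#'   \code{samples} (data.frame: sampleId, group, yLatent, yObserved),
#'   sharing sample order.
#' @export
simulateGenotypeCohort <- function(nSamples, nSnps, freq = c(0.05, 0.95),
                                   effects = NULL, groups = NULL,
                                   noiseSd = 0, multiplicative = FALSE,
                                   intercept = 0, chr = 1L,
                                   spacingBp = 10000L, seed = 1L) {
  if (nSamples < 1 || nSnps < 1) stop("nSamples and nSnps must be positive")
  set.seed(seed)
  f <- if (length(freq) == nSnps) {
    as.numeric(freq)
  } else if (length(freq) == 2L) {
    stats::runif(nSnps, freq[1], freq[2])
  } else {
    rep(as.numeric(freq), length.out = nSnps)
  }
  if (any(f <= 0 | f >= 1))
    stop("allele frequencies must lie strictly in (0,1); a SNP with frequency 0 or 1 is monomorphic")

  dos <- sapply(f, function(p) stats::rbinom(nSamples, 2L, p))
  dos <- matrix(dos, nSamples, nSnps)
  snpIds <- sprintf("snp%d", seq_len(nSnps))
  colnames(dos) <- snpIds
  map <- data.frame(snp = snpIds, chr = chr,
                    bp = seq_len(nSnps) * as.integer(spacingBp),
                    a1 = "A", a2 = "B", freq = f,
                    stringsAsFactors = FALSE)

  if (is.null(effects)) effects <- rep(0, nSnps)
  if (is.list(effects)) {
    if (is.null(groups)) {
      groups <- factor(sample(rep(names(effects), length.out = nSamples)),
                       levels = names(effects))
    } else {
      groups <- factor(groups, levels = names(effects))
    }
    gscore <- numeric(nSamples)
    for (g in names(effects)) {
      idx <- which(groups == g)
      gscore[idx] <- as.vector(dos[idx, , drop = FALSE] %*% effects[[g]])
    }
  } else {
    if (is.null(groups)) groups <- factor(rep("all", nSamples))
    gscore <- as.vector(dos %*% effects)
  }

  yLatent <- intercept + gscore +
    if (noiseSd > 0) stats::rnorm(nSamples, 0, noiseSd) else 0
  yObserved <- if (multiplicative) exp(yLatent) else yLatent

  panel <- new("GenotypePanel", dosages = dos, snpMap = map, trueEffects = effects)
  samples <- data.frame(sampleId = sprintf("S%d", seq_len(nSamples)),
                        group = groups, yLatent = yLatent,
                        yObserved = yObserved, stringsAsFactors = FALSE)
  list(panel = panel, samples = samples)
}

#' Empirical pairwise LD (r-squared) of a panel
#'
#' Squared Pearson correlation between dosage columns, the LD source for
#' clumping simulated panels. Zero-variance SNPs get NA rows/columns.
#'
#' @param panel a [GenotypePanel-class].
#' @return symmetric p x p matrix with SNP ids as dimnames.
#' @export
ldMatrix <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  r <- suppressWarnings(stats::cor(panel@dosages))
  r * r
}
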