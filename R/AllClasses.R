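#' @import methods
NULL

OBSERVATION_SCALES <- c("identity", "exponential", "inverse_logit")
ENV_TYPES <- c("binary", "gaussian")

#' SimulationConfig: generative parameters for a simulated cohort
#'
#' Holds every parameter of the latent-trait generative model
#' \deqn{Y' = G\beta + E\alpha + (G*E)\gamma + \epsilon,\qquad Y = f(Y' + s)}
#' where \eqn{G} is an n x m matrix of independent standard-normal polygenic
#' scores, \eqn{E} the environment, \eqn{\epsilon \sim N(0,1)} and \eqn{f}
#' one of three observation scales (identity, exponential, inverse-logit).
#' \eqn{\beta} and \eqn{\alpha} are scaled so that the genetic and
#' environmental components explain fractions \code{h2} and \code{envVar} of
#' the latent variance; the residual fraction is supplied by the unit-variance
#' noise, so the total latent variance is \eqn{1/(1 - h^2 - v_E)}.
#'
#' @slot nSamples integer, cohort size n.
#' @slot nPgs integer, number of polygenic score columns m.
#' @slot h2 fraction of latent variance explained by the scores, in [0,1).
#' @slot envVar fraction of latent variance explained by E, in [0,1).
#' @slot gamma scalar interaction coefficient applied to every score column.
#' @slot observationScale one of \code{"identity"}, \code{"exponential"},
#'   \code{"inverse_logit"}.
#' @slot locationShift nonnegative shift added to the latent trait before the
#'   observation map; \code{NA} requests the automatic rule (identity scale:
#'   place the minimum at 6 latent standard deviations above zero, so power
#'   transforms are defined; other scales: 0).
#' @slot envType environment distribution, \code{"binary"} (Bernoulli) or
#'   \code{"gaussian"}.
#' @slot envFreq success probability of a binary environment.
#' @slot seed integer random seed.
#'
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig", representation(
  nSamples = "integer", nPgs = "integer", h2 = "numeric", envVar = "numeric",
  gamma = "numeric", observationScale = "character", locationShift = "numeric",
  envType = "character", envFreq = "numeric", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be positive")
  if (object@nPgs < 1L) msg <- c(msg, "nPgs must be positive")
  if (object@h2 < 0 || object@h2 >= 1) msg <- c(msg, "h2 must be in [0,1)")
  if (object@envVar < 0 || object@envVar >= 1) msg <- c(msg, "envVar must be in [0,1)")
  if (object@h2 + object@envVar >= 1)
    msg <- c(msg, "h2 + envVar must be < 1 (noise supplies the rest)")
  if (!object@observationScale %in% OBSERVATION_SCALES)
    msg <- c(msg, paste("observationScale must be one of:",
                        paste(OBSERVATION_SCALES, collapse = ", ")))
  if (!object@envType %in% ENV_TYPES)
    msg <- c(msg, paste("envType must be one of:", paste(ENV_TYPES, collapse = ", ")))
  if (object@envFreq <= 0 || object@envFreq >= 1)
    msg <- c(msg, "envFreq must be in (0,1)")
  if (!is.na(object@locationShift) && object@locationShift < 0)
    msg <- c(msg, "locationShift must be nonnegative (or NA for automatic)")
  if (length(msg)) msg else TRUE
})

#' Cohort: sample-aligned simulated data
#'
#' @slot G n x m matrix of polygenic score values.
#' @slot E length-n environment vector.
#' @slot covariates optional n x k covariate matrix (0 columns when absent).
#' @slot yLatent latent-scale phenotype Y'.
#' @slot yObserved observed phenotype Y = f(Y' + shift), strictly positive
#'   (in (0,1) for the inverse-logit scale).
#' @slot trueBeta length-m generative score effects.
#' @slot trueAlpha generative environment effect.
#' @slot trueGamma generative interaction coefficient (scalar, applied to
#'   every score column).
#' @slot config the [SimulationConfig-class] that produced the cohort.
#' @export
setClass("Cohort", representation(
  G = "matrix", E = "numeric", covariates = "matrix",
  yLatent = "numeric", yObserved = "numeric",
  trueBeta = "numeric", trueAlpha = "numeric", trueGamma = "numeric",
  config = "ANY"
))

setValidity("Cohort", function(object) {
  n <- nrow(object@G)
  msg <- character()
  if (length(object@E) != n) msg <- c(msg, "E must have length nrow(G)")
  if (length(object@yLatent) != n) msg <- c(msg, "yLatent must have length nrow(G)")
  if (length(object@yObserved) != n) msg <- c(msg, "yObserved must have length nrow(G)")
  if (nrow(object@covariates) != 0L && nrow(object@covariates) != n)
    msg <- c(msg, "C must have nrow(G) rows (or none)")
  if (length(object@trueBeta) != ncol(object@G))
    msg <- c(msg, "trueBeta must have length ncol(G)")
  if (any(object@yObserved <= 0))
    msg <- c(msg, sprintf(
      "yObserved must be strictly positive for power transforms; smallest value is %g",
      min(object@yObserved)))
  if (length(msg)) msg else TRUE
})

#' GenotypePanel: dosage matrix with SNP map
#'
#' @slot dosages n x p matrix of allele dosages in [0, 2]; columns named by
#'   SNP id.
#' @slot snpMap data.frame with columns \code{snp}, \code{chr}, \code{bp}
#'   (1-based), \code{a1}, \code{a2}, \code{freq}.
#' @slot trueEffects generative per-SNP effects: a numeric vector, or a named
#'   list of vectors for group-specific architectures.
#' @export
setClass("GenotypePanel", representation(
  dosages = "matrix", snpMap = "data.frame", trueEffects = "ANY"
))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  map <- object@snpMap
  need <- c("snp", "chr", "bp", "a1", "a2", "freq")
  if (!all(need %in% names(map)))
    msg <- c(msg, paste("snpMap must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(map) != ncol(object@dosages))
      msg <- c(msg, "snpMap must have one row per dosage column")
    if (any(map$freq <= 0 | map$freq >= 1))
      msg <- c(msg, "allele frequencies must lie in (0,1)")
    for (ch in unique(map$chr)) {
      bp <- map$bp[map$chr == ch]
      if (any(diff(bp) <= 0)) {
        msg <- c(msg, sprintf("base-pair positions must be strictly increasing within chromosome %s", ch))
        break
      }
    }
  }
  if (any(object@dosages < 0 | object@dosages > 2))
    msg <- c(msg, "dosages must lie in [0,2]")
  if (length(msg)) msg else TRUE
})

#' InteractionFit: one PGSxE interaction model fit
#'
#' @slot gammaHat interaction estimate(s); a named vector when the
#'   environment is a multi-level factor.
#' @slot gammaSe standard error(s) matching \code{gammaHat}.
#' @slot pInteraction two-sided Wald p-value for the interaction (joint F
#'   p-value for multi-level environments).
#' @slot coefficients data.frame of all fitted terms (term, estimate, se,
#'   statistic, p).
#' @slot nUsed number of rows used after listwise deletion.
#' @export
setClass("InteractionFit", representation(
  gammaHat = "numeric", gammaSe = "numeric", pInteraction = "numeric",
  coefficients = "data.frame", nUsed = "integer"
))

setValidity("InteractionFit", function(object) {
  msg <- character()
  if (!(object@pInteraction > 0 && object@pInteraction <= 1))
    msg <- c(msg, "pInteraction must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' LambdaProfile: interaction p-values across the Box-Cox grid
#'
#' @slot lambdas Box-Cox grid.
#' @slot pValues interaction p-value at each lambda.
#' @slot gammaHats interaction estimate at each lambda.
#' @slot rintP interaction p-value after RINT (NA when not requested).
#' @slot threshold significance cutoff used for classification.
#' @slot classification \code{"scale_dependent"}, \code{"scale_independent"}
#'   or \code{"not_significant"}.
#' @export
setClass("LambdaProfile", representation(
  lambdas = "numeric", pValues = "numeric", gammaHats = "numeric",
  rintP = "numeric", threshold = "numeric", classification = "character"
))

setValidity("LambdaProfile", function(object) {
  msg <- character()
  if (length(object@lambdas) != length(object@pValues))
    msg <- c(msg, "lambdas and pValues must have the same length")
  if (!object@classification %in%
      c("scale_dependent", "scale_independent", "not_significant"))
    msg <- c(msg, "unknown classification")
  if (length(msg)) msg else TRUE
})

#' ClumpParams: greedy LD-clumping parameters
#'
#' Defaults follow standard GWAS reporting practice: r-squared threshold 0.1,
#' 250 kb window, genome-wide significance 5e-8.
#'
#' @slot r2Threshold r-squared above which a neighbour joins the lead's clump.
#' @slot windowBp window half-width in base pairs around the lead.
#' @slot pThreshold p-value below which a lead is reported as a hit.
#' @export
setClass("ClumpParams", representation(
  r2Threshold = "numeric", windowBp = "numeric", pThreshold = "numeric"
))

setValidity("ClumpParams", function(object) {
  msg <- character()
  if (object@r2Threshold <= 0 || object@r2Threshold > 1)
    msg <- c(msg, "r2Threshold must lie in (0,1]")
  if (object@windowBp <= 0) msg <- c(msg, "windowBp must be positive")
  if (object@pThreshold <= 0 || object@pThreshold > 1)
    msg <- c(msg, "pThreshold must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' PrsModel: SNP weights with the scale and threshold they were trained on
#'
#' @slot weights data.frame with columns \code{snp}, \code{a1}, \code{weight}.
#' @slot trainScale \code{"default"} or \code{"log"}: the phenotype scale of
#'   the GWAS the weights come from.
#' @slot pThresholdUsed the selected p-value inclusion threshold.
#' @export
setClass("PrsModel", representation(
  weights = "data.frame", trainScale = "character", pThresholdUsed = "numeric"
))

setValidity("PrsModel", function(object) {
  msg <- character()
  if (!all(c("snp", "a1", "weight") %in% names(object@weights)))
    msg <- c(msg, "weights must have columns snp, a1, weight")
  else {
    if (nrow(object@weights) == 0L) msg <- c(msg, "weights must be nonempty")
    if (anyDuplicated(object@weights$snp)) msg <- c(msg, "duplicate SNP ids in weights")
  }
  if (!object@trainScale %in% c("default", "log"))
    msg <- c(msg, "trainScale must be 'default' or 'log'")
  if (length(msg)) msg else TRUE
})

## show methods ---------------------------------------------------------------

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: n =", object@nSamples, ", m =", object@nPgs,
      ", h2 =", object@h2, ", envVar =", object@envVar,
      ", gamma =", object@gamma, "\n  scale =", object@observationScale,
      ", envType =", object@envType, ", seed =", object@seed, "\n")
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort:", nrow(object@G), "samples,", ncol(object@G), "PGS columns,",
      ncol(object@covariates), "covariates\n  yObserved range: [",
      signif(min(object@yObserved), 4), ",", signif(max(object@yObserved), 4), "]\n")
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object@dosages), "samples x",
      ncol(object@dosages), "SNPs on chromosome(s)",
      paste(unique(object@snpMap$chr), collapse = ","), "\n")
})

setMethod("show", "InteractionFit", function(object) {
  cat("InteractionFit: gamma =", signif(object@gammaHat, 4),
      "(se", paste0(signif(object@gammaSe, 4), ")"),
      " p =", format(object@pInteraction, digits = 3),
      " n =", object@nUsed, "\n")
})

setMethod("show", "LambdaProfile", function(object) {
  cat("LambdaProfile over", length(object@lambdas), "lambdas in [",
      min(object@lambdas), ",", max(object@lambdas), "]\n",
      " min p =", format(min(object@pValues), digits = 3),
      " p(lambda=1) =", format(object@pValues[which.min(abs(object@lambdas - 1))], digits = 3),
      if (!is.na(object@rintP)) paste(" RINT p =", format(object@rintP, digits = 3)) else "",
      "\n  threshold =", format(object@threshold, digits = 3),
      "->", object@classification, "\n")
})

setMethod("show", "PrsModel", function(object) {
  cat("PrsModel:", nrow(object@weights), "SNPs, trained on the",
      object@trainScale, "scale, p threshold", object@pThresholdUsed, "\n")
})

## accessors ------------------------------------------------------------------

#' Accessors for scaleGxE objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{pValues()} and \code{lambdas()} extract a profile's grid and
#' p-values, \code{rintP()} its RINT p-value, \code{classification()} its
#' scale-dependence call, \code{pInteraction()} a fit's interaction p-value,
#' and \code{prsWeights()} a score model's weight table.
#'
#' @param x a scaleGxE S4 object.
#' @return the extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setMethod("pValues", "LambdaProfile", function(x) x@pValues)

#' @rdname accessors
#' @export
setGeneric("lambdas", function(x) standardGeneric("lambdas"))
#' @rdname accessors
#' @export
setMethod("lambdas", "LambdaProfile", function(x) x@lambdas)

#' @rdname accessors
#' @export
setGeneric("rintP", function(x) standardGeneric("rintP"))
#' @rdname accessors
#' @export
setMethod("rintP", "LambdaProfile", function(x) x@rintP)

#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))
#' @rdname accessors
#' @export
setMethod("classification", "LambdaProfile", function(x) x@classification)

#' @rdname accessors
#' @export
setGeneric("pInteraction", function(x) standardGeneric("pInteraction"))
#' @rdname accessors
#' @export
setMethod("pInteraction", "InteractionFit", function(x) x@pInteraction)

#' @rdname accessors
#' @export
setGeneric("gammaHat", function(x) standardGeneric("gammaHat"))
#' @rdname accessors
#' @export
setMethod("gammaHat", "InteractionFit", function(x) x@gammaHat)

#' @rdname accessors
#' @export
setGeneric("prsWeights", function(x) standardGeneric("prsWeights"))
#' @rdname accessors
#' @export
setMethod("prsWeights", "PrsModel", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosages)

#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setMethod("snpMap", "GenotypePanel", function(x) x@snpMap)
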