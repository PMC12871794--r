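## Polygenic score construction and scale-aware evaluation.

#' Score a panel with a weight table
#'
#' Plain weighted dosage sum over the model's SNPs. Effect alleles are
#' assumed to match the panel's a1 coding (the simulated panels always do).
#'
#' @param model a [PrsModel-class] or a weights data.frame (snp, a1, weight).
#' @param panel a [GenotypePanel-class].
#' @return numeric score per sample.
#' @export
scorePrs <- function(model, panel) {
  w <- if (is(model, "PrsModel")) model@weights else model
  idx <- match(w$snp, colnames(panel@dosages))
  if (anyNA(idx))
    stop("panel is missing SNP(s): ", paste(w$snp[is.na(idx)], collapse = ", "))
  as.vector(panel@dosages[, idx, drop = FALSE] %*% w$weight)
}

#' Build a p-value-threshold polygenic score
#'
#' Clump-then-threshold construction: the GWAS is clumped once, and for each
#' threshold in the grid the clump leads with p below it define the weight
#' set (weight = GWAS beta). Each candidate score is evaluated on a tuning
#' cohort by squared Pearson correlation with the tuning phenotype taken on
#' the same scale the GWAS was run on, and the threshold maximising that
#' R-squared is selected (first maximum on ties). The tuning cohort must be
#' disjoint from the GWAS cohort.
#'
#' @param gwas GWAS summary data.frame.
#' @param ld pairwise r-squared matrix for clumping.
#' @param params a [ClumpParams-class]; its \code{pThreshold} is ignored
#'   here in favour of \code{thresholdGrid}.
#' @param thresholdGrid candidate p-value inclusion thresholds (default
#'   spans 5e-8 to 0.5).
#' @param tuningPanel a [GenotypePanel-class] for threshold selection.
#' @param tuningY tuning phenotype on the default scale (strictly positive
#'   when \code{trainScale = "log"}).
#' @param trainScale scale the GWAS was run on: \code{"default"} or
#'   \code{"log"}.
#' @return a [PrsModel-class].
#' @export
buildPrs <- function(gwas, ld, params = clumpParams(),
                     thresholdGrid = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5),
                     tuningPanel, tuningY, trainScale = c("default", "log")) {
  trainScale <- match.arg(trainScale)
  leads <- clumpSnps(gwas, ld, params)
  yTune <- if (trainScale == "log") {
    if (any(tuningY <= 0)) stop("tuning phenotype must be positive on the log scale")
    log(tuningY)
  } else tuningY

  r2 <- rep(NA_real_, length(thresholdGrid))
  weightSets <- vector("list", length(thresholdGrid))
  for (i in seq_along(thresholdGrid)) {
    keep <- leads$lead[leads$p < thresholdGrid[i]]
    if (!length(keep)) next
    w <- data.frame(snp = keep,
                    a1 = gwas$a1[match(keep, gwas$snp)],
                    weight = gwas$beta[match(keep, gwas$snp)],
                    stringsAsFactors = FALSE)
    weightSets[[i]] <- w
    score <- scorePrs(w, tuningPanel)
    r2[i] <- if (stats::sd(score) == 0) 0 else stats::cor(yTune, score)^2
  }
  if (all(is.na(r2)))
    stop("empty weight set at every threshold in the grid")
  best <- which.max(r2)  # first maximum
  new("PrsModel", weights = weightSets[[best]], trainScale = trainScale,
      pThresholdUsed = thresholdGrid[best])
}

#' Relative R-squared between a log-scale and a baseline score
#'
#' \eqn{(R^2_{log} - R^2_{baseline}) / R^2_{baseline}}.
#'
#' @param r2Log,r2Baseline the two R-squared values.
#' @return the relative change.
#' @export
relativeR2 <- function(r2Log, r2Baseline) (r2Log - r2Baseline) / r2Baseline

.evalR2 <- function(yEval, term, covariates, metric) {
  d <- data.frame(.y = yEval, .s = term)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  fit <- stats::lm(.y ~ ., data = d)
  fv <- stats::fitted(fit)
  if (metric == "pearson_r2") stats::cor(yEval, fv)^2
  else stats::cor(yEval, fv, method = "spearman")^2
}

#' Scale-aware evaluation of a polygenic score
#'
#' Computes the score on an evaluation panel and regresses the phenotype on
#' it (plus covariates). When the score was trained on the log scale but is
#' evaluated on the default scale, the score enters the model exponentiated
#' (\eqn{y = \exp(PGS_{log})\beta + C\eta + \epsilon}); in every other
#' combination the score enters linearly and only the phenotype is mapped to
#' the evaluation scale. R-squared is
#' the squared Pearson (or Spearman) correlation between the phenotype on
#' the evaluation scale and the fitted values. Per-group values refit the
#' evaluation regression within each group.
#'
#' @param model a [PrsModel-class].
#' @param panel evaluation [GenotypePanel-class].
#' @param y phenotype on the default (observed) scale, sample-aligned.
#' @param covariates optional covariates for the evaluation model.
#' @param groups optional factor of group labels for per-group evaluation.
#' @param metric \code{"pearson_r2"} or \code{"spearman_r2"}.
#' @param evalScale evaluate on the \code{"default"} or \code{"log"} scale
#'   (the latter requires positive y).
#' @param baselineModel optional second [PrsModel-class]; when supplied, the
#'   result gains a \code{relativeR2} attribute comparing \code{model}
#'   (treated as the log-scale score) against it per row.
#' @return data.frame with columns group, n, r2 (first row \code{overall});
#'   with \code{baselineModel}, extra columns r2Baseline and relativeR2.
#' @export
evaluatePrs <- function(model, panel, y, covariates = NULL, groups = NULL,
                        metric = c("pearson_r2", "spearman_r2"),
                        evalScale = c("default", "log"),
                        baselineModel = NULL) {
  metric <- match.arg(metric)
  evalScale <- match.arg(evalScale)
  if (evalScale == "log" && any(y <= 0))
    stop(sprintf("log-scale evaluation requires positive phenotype; smallest value is %g", min(y)))
  yEval <- if (evalScale == "log") log(y) else y

  term1 <- .prsTerm(model, panel, evalScale)
  res <- .evalTable(yEval, term1, covariates, groups, metric)
  if (!is.null(baselineModel)) {
    term0 <- .prsTerm(baselineModel, panel, evalScale)
    base <- .evalTable(yEval, term0, covariates, groups, metric)
    res$r2Baseline <- base$r2
    res$relativeR2 <- relativeR2(res$r2, base$r2)
  }
  res
}

.prsTerm <- function(model, panel, evalScale) {
  score <- scorePrs(model, panel)
  if (model@trainScale == "log" && evalScale == "default") exp(score) else score
}

.evalTable <- function(yEval, term, covariates, groups, metric) {
  out <- data.frame(group = "overall", n = length(yEval),
                    r2 = .evalR2(yEval, term, covariates, metric),
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    groups <- factor(groups)
    for (g in levels(groups)) {
      idx <- which(groups == g)
      cv <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
      out <- rbind(out, data.frame(
        group = g, n = length(idx),
        r2 = .evalR2(yEval[idx], term[idx], cv, metric),
        stringsAsFactors = FALSE))
    }
  }
  out
}
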