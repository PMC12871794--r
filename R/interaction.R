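## PGSxE interaction fitting, lambda profiling and scale-dependence calls.

.dropIncomplete <- function(df) df[stats::complete.cases(df), , drop = FALSE]

#' Fit the PGSxE interaction model on one phenotype scale
#'
#' Ordinary least squares of
#' \deqn{y = \mu + PGS\,\beta + E\,\alpha + (PGS*E)\,\gamma + C\eta + (C*E)\sigma + \epsilon}
#' with the covariate-by-environment block included by default, which is
#' required for proper confounder adjustment in interaction models. The
#' reported p-value is the two-sided Wald t-test on the interaction
#' coefficient (residual degrees of freedom); for a multi-level factor
#' environment it is the joint F-test over all interaction contrasts.
#' Categorical covariates and environments are expanded to treatment
#' contrasts against the first sorted level. Rows with any missing value are
#' dropped listwise before fitting.
#'
#' @param y numeric phenotype (already on the scale to be tested).
#' @param pgs numeric polygenic score vector.
#' @param e environment: numeric, or factor/character for categorical.
#' @param covariates optional matrix/data.frame of covariates.
#' @param includeCovByE include the covariate-by-environment block
#'   (default TRUE).
#' @param robust use heteroskedasticity-robust (HC1 sandwich) standard
#'   errors instead of the classical ones (default FALSE: plain linear-model
#'   inference).
#' @return an [InteractionFit-class].
#' @export
fitInteraction <- function(y, pgs, e, covariates = NULL,
                           includeCovByE = TRUE, robust = FALSE) {
  n0 <- length(y)
  if (length(pgs) != n0 || length(e) != n0)
    stop("y, pgs and e must be sample-aligned")
  d <- data.frame(.y = y, .pgs = pgs, .e = if (is.character(e)) factor(e) else e)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates, stringsAsFactors = TRUE)
    if (nrow(cv) != n0) stop("covariates must be sample-aligned")
    if (is.null(colnames(covariates)) && !is.data.frame(covariates))
      names(cv) <- paste0("C", seq_along(cv))
    cv[] <- lapply(cv, function(x) if (is.character(x)) factor(x) else x)
    d <- cbind(d, cv)
  }
  d <- .dropIncomplete(d)
  nUsed <- nrow(d)
  if (nUsed < 5L) stop("too few complete rows to fit the interaction model")

  if (stats::var(d$.pgs) == 0) stop("zero-variance pgs")
  eNum <- if (is.factor(d$.e)) length(unique(d$.e)) > 1 else stats::var(d$.e) > 0
  if (!eNum) stop("zero-variance environment E")
  if (stats::var(d$.y) == 0) stop("zero-variance phenotype")

  covNames <- setdiff(names(d), c(".y", ".pgs", ".e"))
  rhs <- ".pgs * .e"
  if (length(covNames)) {
    ct <- paste0("`", covNames, "`")
    rhs <- paste(rhs, "+", paste(ct, collapse = " + "))
    if (includeCovByE)
      rhs <- paste(rhs, "+", paste(paste0(ct, ":.e"), collapse = " + "))
  }
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)

  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design after contrast expansion; dropped columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))

  vc <- if (robust) sandwich::vcovHC(fit, type = "HC1") else stats::vcov(fit)
  se <- sqrt(diag(vc))
  tval <- cf / se
  df <- stats::df.residual(fit)
  pv <- 2 * stats::pt(-abs(tval), df)
  coefTab <- data.frame(term = names(cf), estimate = unname(cf),
                        se = unname(se), statistic = unname(tval),
                        p = unname(pv), stringsAsFactors = FALSE)

  intIdx <- grep("^\\.pgs:\\.e", names(cf))
  if (!length(intIdx)) stop("interaction term missing from the fit")
  if (length(intIdx) == 1L) {
    pInt <- pv[intIdx]
  } else {
    # joint Wald F over all pgs-by-level contrasts
    b <- cf[intIdx]
    V <- vc[intIdx, intIdx, drop = FALSE]
    Fstat <- drop(t(b) %*% solve(V, b)) / length(b)
    pInt <- stats::pf(Fstat, length(b), df, lower.tail = FALSE)
  }
  pInt <- max(pInt, .Machine$double.xmin)  # keep inside (0,1]

  new("InteractionFit",
      gammaHat = unname(cf[intIdx]), gammaSe = unname(se[intIdx]),
      pInteraction = pInt, coefficients = coefTab, nUsed = as.integer(nUsed))
}

#' Fast per-column interaction scan
#'
#' Tests every column of a score matrix in its own model
#' \code{y ~ pgs_j + e + pgs_j:e} via closed-form normal equations on
#' centred moments. Algebraically identical to [fitInteraction()] without
#' covariates (equality is enforced by the test suite); used by the
#' simulation drivers where thousands of single-score fits are needed.
#'
#' @param y numeric phenotype on the scale to be tested.
#' @param G n x m matrix of scores.
#' @param e numeric environment vector.
#' @return data.frame with one row per column: pgs, gammaHat, se, statistic, p.
#' @export
scanInteractions <- function(y, G, e) {
  n <- length(y)
  if (nrow(G) != n || length(e) != n) stop("y, G and e must be sample-aligned")
  if (stats::var(e) == 0) stop("zero-variance environment E")
  m <- ncol(G)

  Sg <- colSums(G); Sg2 <- colSums(G * G)
  GE <- G * e
  SgE <- colSums(GE); Sg2E <- colSums(G * GE)
  SgE2 <- colSums(GE * e); Sg2E2 <- colSums(GE * GE)
  SE <- sum(e); SE2 <- sum(e * e)
  Sy <- sum(y); Sy2 <- sum(y * y); SEy <- sum(e * y)
  Sgy <- as.vector(crossprod(G, y))
  SgEy <- as.vector(crossprod(GE, y))

  Cyy <- Sy2 - Sy^2 / n
  CEE <- SE2 - SE^2 / n
  CEy <- SEy - SE * Sy / n

  out <- data.frame(pgs = colnames(G) %||% paste0("PGS_", seq_len(m)),
                    gammaHat = NA_real_, se = NA_real_,
                    statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    S <- matrix(c(
      Sg2[j] - Sg[j]^2 / n,      SgE[j] - Sg[j] * SE / n,  Sg2E[j] - Sg[j] * SgE[j] / n,
      SgE[j] - Sg[j] * SE / n,   CEE,                      SgE2[j] - SE * SgE[j] / n,
      Sg2E[j] - Sg[j] * SgE[j] / n, SgE2[j] - SE * SgE[j] / n, Sg2E2[j] - SgE[j]^2 / n
    ), 3, 3)
    cv <- c(Sgy[j] - Sg[j] * Sy / n, CEy, SgEy[j] - SgE[j] * Sy / n)
    Sinv <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Sinv)) next
    b <- Sinv %*% cv
    rss <- max(Cyy - sum(b * cv), 0)
    se <- sqrt(rss / (n - 4) * Sinv[3, 3])
    tv <- b[3] / se
    out$gammaHat[j] <- b[3]
    out$se[j] <- se
    out$statistic[j] <- tv
    out$p[j] <- 2 * stats::pt(-abs(tv), n - 4)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("lambda", "p"))

#' Profile the interaction p-value across the Box-Cox grid
#'
#' For each lambda in the grid, transforms the (positive) phenotype with
#' [boxCox()] and fits the interaction model; optionally appends a RINT fit.
#' The significance threshold defaults to a Bonferroni correction of
#' \code{alpha} over the number of transformations tested in the profile
#' (grid points plus RINT when included), and drives the scale-dependence
#' classification. RINT is excluded from the classification itself.
#'
#' @param y strictly positive phenotype on the observed (default) scale.
#' @param pgs,e,covariates,includeCovByE as in [fitInteraction()].
#' @param lambdas Box-Cox grid; default [lambdaGrid()] (25 points in [-1,2]).
#' @param includeRint also fit the RINT-transformed phenotype (default TRUE).
#' @param alpha family-wise level before Bonferroni correction.
#' @param threshold explicit significance cutoff; overrides the Bonferroni
#'   default when supplied.
#' @return a [LambdaProfile-class].
#' @export
profileLambda <- function(y, pgs, e, covariates = NULL, lambdas = lambdaGrid(),
                          includeRint = TRUE, alpha = 0.05, threshold = NULL,
                          includeCovByE = TRUE) {
  if (!length(lambdas)) stop("lambdas must be nonempty")
  if (is.null(threshold))
    threshold <- alpha / (length(lambdas) + as.integer(includeRint))

  fits <- lapply(lambdas, function(l) {
    tryCatch(
      fitInteraction(boxCox(y, l), pgs, e, covariates, includeCovByE),
      error = function(err)
        stop(sprintf("lambda = %g: %s", l, conditionMessage(err)), call. = FALSE)
    )
  })
  pv <- vapply(fits, function(f) f@pInteraction, numeric(1))
  gh <- vapply(fits, function(f) f@gammaHat[1], numeric(1))
  rp <- NA_real_
  if (includeRint)
    rp <- fitInteraction(rint(y), pgs, e, covariates, includeCovByE)@pInteraction

  cls <- classifyScaleDependence(pv, lambdas, threshold)
  new("LambdaProfile", lambdas = as.numeric(lambdas), pValues = pv,
      gammaHats = gh, rintP = rp, threshold = threshold, classification = cls)
}

#' Classify an interaction as scale-dependent or -independent
#'
#' An interaction significant on every considered scale is
#' scale-independent; one significant on the default scale (lambda = 1) but
#' removable by some transformation in the family is scale-dependent; one
#' not significant at lambda = 1 is not significant. RINT is not part of the
#' considered family by default.
#'
#' @param pValues interaction p-values along the grid.
#' @param lambdas matching grid; must contain \code{defaultLambda}.
#' @param threshold significance cutoff.
#' @param defaultLambda the untransformed scale (default 1).
#' @return one of \code{"not_significant"}, \code{"scale_independent"},
#'   \code{"scale_dependent"}.
#' @export
classifyScaleDependence <- function(pValues, lambdas, threshold,
                                    defaultLambda = 1) {
  if (length(pValues) != length(lambdas))
    stop("pValues and lambdas must have the same length")
  i1 <- which(abs(lambdas - defaultLambda) < 1e-9)
  if (!length(i1)) stop("default lambda not present in the grid")
  if (pValues[i1[1]] >= threshold) return("not_significant")
  if (all(pValues < threshold)) return("scale_independent")
  "scale_dependent"
}

#' Plot a lambda profile
#'
#' The p-value of the interaction term against the Box-Cox parameter, with
#' the significance threshold as a dashed line and the RINT p-value (when
#' present) as a point at the right edge.
#'
#' @param profile a [LambdaProfile-class].
#' @return a ggplot object.
#' @export
plotLambdaProfile <- function(profile) {
  df <- data.frame(lambda = profile@lambdas, p = profile@pValues)
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = lambda, y = -log10(p))) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(profile@threshold), linetype = "dashed") +
    ggplot2::labs(x = expression(lambda), y = expression(-log[10](p)),
                  subtitle = paste("classification:", profile@classification))
  if (!is.na(profile@rintP)) {
    gp <- gp + ggplot2::annotate("point", x = max(df$lambda) + 0.15,
                                 y = -log10(profile@rintP),
                                 shape = 17, color = "darkorange")
  }
  gp
}
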