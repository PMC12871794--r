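## Desk-scale GWAS, greedy LD clumping and min-p shared-hit identification.

#' Construct ClumpParams
#'
#' @param r2Threshold LD r-squared threshold (default 0.1).
#' @param windowBp window size in base pairs (default 250 kb).
#' @param pThreshold significance threshold for reported hits (default 5e-8).
#' @return a validated [ClumpParams-class].
#' @export
clumpParams <- function(r2Threshold = 0.1, windowBp = 250000, pThreshold = 5e-8) {
  new("ClumpParams", r2Threshold = as.numeric(r2Threshold),
      windowBp = as.numeric(windowBp), pThreshold = as.numeric(pThreshold))
}

.checkGwasTable <- function(gwas) {
  need <- c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p", "n")
  if (!all(need %in% names(gwas)))
    stop("GWAS table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(gwas$snp)) stop("GWAS table has duplicate SNP ids")
  ok <- !is.na(gwas$p)
  if (any(gwas$p[ok] <= 0 | gwas$p[ok] > 1)) stop("p-values must lie in (0,1]")
  if (any(gwas$se[!is.na(gwas$se)] <= 0)) stop("standard errors must be positive")
  invisible(gwas)
}

#' Per-SNP association scan
#'
#' For every SNP, OLS of the phenotype on dosage plus covariates; reports
#' the dosage coefficient, its classical standard error and two-sided
#' p-value. Implemented by residualising phenotype and dosages on the
#' covariates (Frisch-Waugh) with the correct residual degrees of freedom,
#' which is exactly the full OLS fit. A zero-variance SNP yields a row of
#' missing statistics and a warning rather than an error.
#'
#' @param panel a [GenotypePanel-class].
#' @param y numeric phenotype, sample-aligned with the panel.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return a GWAS summary data.frame (one row per SNP) with columns
#'   snp, chr, bp, a1, a2, beta, se, p, n.
#' @export
runGwas <- function(panel, y, covariates = NULL) {
  stopifnot(is(panel, "GenotypePanel"))
  X <- panel@dosages
  n <- nrow(X)
  if (length(y) != n) stop("y must be sample-aligned with the panel")

  k <- 0L
  if (!is.null(covariates)) {
    Cm <- as.matrix(covariates)
    if (nrow(Cm) != n) stop("covariates must be sample-aligned")
    k <- ncol(Cm)
    Q <- qr.Q(qr(cbind(1, Cm)))
    y <- y - Q %*% crossprod(Q, y)
    X <- X - Q %*% crossprod(Q, X)
  } else {
    y <- y - mean(y)
    X <- sweep(X, 2, colMeans(X))
  }
  df <- n - k - 2L  # intercept + covariates + dosage

  sxx <- colSums(X * X)
  zero <- sxx < .Machine$double.eps * n
  if (any(zero))
    warning("zero-variance SNP(s): ",
            paste(panel@snpMap$snp[zero], collapse = ", "),
            "; statistics set to NA")
  sxy <- as.vector(crossprod(X, y))
  beta <- ifelse(zero, NA_real_, sxy / sxx)
  syy <- sum(y * y)
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  se[zero] <- NA_real_
  tv <- beta / se
  pv <- pmax(2 * stats::pt(-abs(tv), df), .Machine$double.xmin)

  out <- data.frame(snp = panel@snpMap$snp, chr = panel@snpMap$chr,
                    bp = panel@snpMap$bp, a1 = panel@snpMap$a1,
                    a2 = panel@snpMap$a2, beta = as.vector(beta),
                    se = as.vector(se), p = as.vector(pv), n = n,
                    stringsAsFactors = FALSE)
  .checkGwasTable(out)
  out
}

.ldLookup <- function(ld, a, b) {
  i <- match(a, rownames(ld)); j <- match(b, colnames(ld))
  v <- rep(NA_real_, length(b))
  ok <- !is.na(j)
  if (!is.na(i) && any(ok)) v[ok] <- ld[i, j[ok]]
  v
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unassigned SNP with the smallest p-value (ties:
#' smaller position, then lexicographic id), makes it a clump lead, and
#' assigns to its clump every unassigned SNP on the same chromosome within
#' \code{windowBp} whose r-squared with the lead is at least
#' \code{r2Threshold}. SNPs with missing p-values are never leads. A missing
#' LD entry for an in-window pair is treated as r-squared 0 (the pair stays
#' unclumped) and is reported via a message.
#'
#' @param gwas GWAS summary data.frame (see [runGwas()]).
#' @param ld symmetric matrix of pairwise r-squared with SNP-id dimnames
#'   (e.g. from [ldMatrix()]).
#' @param params a [ClumpParams-class].
#' @return data.frame with one row per lead: lead, chr, bp, p, nMembers,
#'   members (comma-separated, lead included), hit (p < pThreshold).
#' @export
clumpSnps <- function(gwas, ld, params = clumpParams()) {
  .checkGwasTable(gwas)
  validObject(params)
  g <- gwas[!is.na(gwas$p), , drop = FALSE]
  ord <- order(g$p, g$bp, g$snp)
  g <- g[ord, , drop = FALSE]

  assigned <- logical(nrow(g))
  leads <- list()
  missingLd <- 0L
  for (i in seq_len(nrow(g))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    lead <- g[i, ]
    cand <- which(!assigned & g$chr == lead$chr &
                    abs(g$bp - lead$bp) <= params@windowBp)
    members <- lead$snp
    if (length(cand)) {
      r2 <- .ldLookup(ld, lead$snp, g$snp[cand])
      nMiss <- sum(is.na(r2))
      if (nMiss) { missingLd <- missingLd + nMiss; r2[is.na(r2)] <- 0 }
      take <- cand[r2 >= params@r2Threshold]
      if (length(take)) {
        assigned[take] <- TRUE
        members <- c(members, g$snp[take])
      }
    }
    leads[[length(leads) + 1L]] <- data.frame(
      lead = lead$snp, chr = lead$chr, bp = lead$bp, p = lead$p,
      nMembers = length(members), members = paste(members, collapse = ","),
      hit = lead$p < params@pThreshold, stringsAsFactors = FALSE)
  }
  if (missingLd > 0)
    message(missingLd, " in-window pair(s) had no LD entry; treated as r2 = 0")
  do.call(rbind, leads)
}

#' Shared and study-specific hits between two GWAS
#'
#' Builds the min-p table (each SNP gets the smaller of its two p-values),
#' clumps it, keeps leads with min-p below the significance threshold, and
#' labels each lead \code{shared} when its p-value is below the threshold in
#' both studies, else \code{a_only} / \code{b_only}.
#'
#' @param gwasA,gwasB GWAS summary data.frames over the same SNP universe.
#' @param ld pairwise r-squared matrix.
#' @param params a [ClumpParams-class].
#' @return list with \code{leads} (data.frame: lead, chr, bp, pMin, pA, pB,
#'   label), \code{counts} (named vector over the three labels) and
#'   \code{percentShared} (100 * shared / total leads; NaN with no leads).
#' @export
sharedHits <- function(gwasA, gwasB, ld, params = clumpParams()) {
  .checkGwasTable(gwasA); .checkGwasTable(gwasB)
  dAB <- setdiff(gwasA$snp, gwasB$snp)
  dBA <- setdiff(gwasB$snp, gwasA$snp)
  if (length(dAB) || length(dBA))
    stop("SNP universes differ (symmetric difference of size ",
         length(dAB) + length(dBA), ")")
  b <- gwasB[match(gwasA$snp, gwasB$snp), , drop = FALSE]
  minTab <- gwasA
  minTab$p <- pmin(gwasA$p, b$p)

  cl <- clumpSnps(minTab, ld, params)
  cl <- cl[cl$p < params@pThreshold, , drop = FALSE]
  pA <- gwasA$p[match(cl$lead, gwasA$snp)]
  pB <- b$p[match(cl$lead, b$snp)]
  label <- ifelse(pA < params@pThreshold & pB < params@pThreshold, "shared",
                  ifelse(pA < params@pThreshold, "a_only", "b_only"))
  leads <- data.frame(lead = cl$lead, chr = cl$chr, bp = cl$bp,
                      pMin = cl$p, pA = pA, pB = pB, label = label,
                      stringsAsFactors = FALSE)
  counts <- c(shared = sum(label == "shared"),
              a_only = sum(label == "a_only"),
              b_only = sum(label == "b_only"))
  list(leads = leads, counts = counts,
       percentShared = if (nrow(leads)) 100 * counts[["shared"]] / nrow(leads) else NaN)
}

#' Naive genetic correlation from effect sizes
#'
#' Pearson correlation of the estimated per-SNP effects of two GWAS over a
#' set of mutually independent SNPs (e.g. clump leads or simulated unlinked
#' panels). This is a desk-scale effect-size correlation, \emph{not} an
#' LD-score-regression genetic correlation: it ignores LD structure and
#' sampling-error attenuation, and is meaningful here only for unlinked
#' SNPs with well-estimated effects.
#'
#' @param gwasA,gwasB GWAS summary data.frames.
#' @param snps SNP ids over which to correlate (>= 10).
#' @return correlation in [-1, 1]; symmetric in its arguments.
#' @export
naiveGeneticCorrelation <- function(gwasA, gwasB, snps) {
  if (length(snps) < 10)
    stop("need at least 10 independent SNPs for a stable estimate")
  ba <- gwasA$beta[match(snps, gwasA$snp)]
  bb <- gwasB$beta[match(snps, gwasB$snp)]
  if (anyNA(ba) || anyNA(bb)) stop("some requested SNPs are missing a beta")
  stats::cor(ba, bb)
}
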