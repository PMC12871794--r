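# Two-group multiplicative cohort fixture: group M sits several log-units
# above group F, so M dominates the phenotypic variance on the default
# (exponentiated) scale. The scored weights are M's true effects; F's
# architecture is only partially aligned (loading 0.6), so on the log scale
# M shows strong and F moderate R2, while on the default scale the overall
# R2 is set by M alone.
makeTwoGroupCohort <- function(n = 3000, nsnp = 40, seed = 21) {
  set.seed(seed)
  effM <- rnorm(nsnp, 0, 0.3)
  effF <- 0.6 * effM + rnorm(nsnp, 0, 0.3 * sqrt(1 - 0.36))
  groups <- factor(rep(c("F", "M"), length.out = n))
  g <- simulateGenotypeCohort(n, nsnp, effects = list(F = effF, M = effM),
                              groups = groups, noiseSd = 0.6, seed = seed)
  yLog <- g$samples$yLatent + ifelse(groups == "M", 3, 0)
  list(panel = g$panel, y = exp(yLog), groups = groups,
       weights = data.frame(snp = g$panel@snpMap$snp, a1 = "A",
                            weight = effM, stringsAsFactors = FALSE))
}

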