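# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (normal equations, literal greedy
# definitions) rather than reusing any package internals.

# OLS by explicit normal equations: coefficients, classical SEs, t p-values.
olsOracle <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- unname(sqrt(diag(solve(XtX)) * sigma2))
  tv <- as.vector(b) / se
  list(beta = as.vector(b), se = se,
       p = unname(2 * pt(-abs(tv), df)), df = df)
}

# Literal re-execution of the greedy clumping definition.
clumpOracle <- function(tab, ldm, r2thr, window) {
  tab <- tab[!is.na(tab$p), ]
  remaining <- tab$snp
  leads <- character()
  members <- list()
  while (length(remaining)) {
    sub <- tab[tab$snp %in% remaining, ]
    sub <- sub[order(sub$p, sub$bp, sub$snp), ]
    lead <- sub$snp[1]
    leadRow <- sub[1, ]
    remaining <- setdiff(remaining, lead)
    mem <- lead
    for (s in remaining) {
      row <- tab[tab$snp == s, ]
      if (row$chr != leadRow$chr) next
      if (abs(row$bp - leadRow$bp) > window) next
      r2 <- ldm[lead, s]
      if (is.na(r2)) r2 <- 0
      if (r2 >= r2thr) mem <- c(mem, s)
    }
    remaining <- setdiff(remaining, mem)
    leads <- c(leads, lead)
    members[[lead]] <- mem
  }
  list(leads = leads, members = members)
}

# Small GWAS table builder for clumping/shared-hit tests.
makeGwasTab <- function(snp, bp, p, chr = 1, beta = 1, se = 0.1, n = 1000) {
  data.frame(snp = snp, chr = chr, bp = bp, a1 = "A", a2 = "B",
             beta = beta, se = se, p = p, n = n, stringsAsFactors = FALSE)
}
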