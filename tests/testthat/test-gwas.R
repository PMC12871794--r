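test_that("noiseless phenotype recovers the dosage coefficient exactly", {
  g <- simulateGenotypeCohort(300, 4, seed = 2)
  y <- 2 * g$panel@dosages[, 3]
  gw <- runGwas(g$panel, y)
  expect_equal(gw$beta[3], 2, tolerance = 1e-12)
  expect_lt(gw$p[3], 1e-200)
  expect_identical(gw$snp, g$panel@snpMap$snp)
})

test_that("per-SNP statistics equal a full lm fit, with and without covariates", {
  set.seed(3)
  g <- simulateGenotypeCohort(150, 20, effects = rnorm(20, 0, 0.1),
                              noiseSd = 1, seed = 3)
  covs <- cbind(age = rnorm(150), pc1 = rnorm(150))
  y <- g$samples$yObserved + 0.5 * covs[, 1]
  gw <- runGwas(g$panel, y, covariates = covs)
  for (j in c(1, 7, 20)) {
    fit <- summary(lm(y ~ g$panel@dosages[, j] + covs))
    expect_equal(gw$beta[j], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(gw$se[j], fit$coefficients[2, 2], tolerance = 1e-10)
    expect_equal(gw$p[j], fit$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("null GWAS p-values are calibrated", {
  g <- simulateGenotypeCohort(500, 1000, seed = 4)
  set.seed(5)
  y <- rnorm(500)
  gw <- runGwas(g$panel, y)
  frac <- mean(gw$p < 0.05)
  ci <- qbinom(c(0.0005, 0.9995), 1000, 0.05) / 1000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("zero-variance SNPs warn and yield missing statistics", {
  g <- simulateGenotypeCohort(100, 3, seed = 6)
  g$panel@dosages[, 2] <- 1  # force monomorphic dosage column
  set.seed(1); y <- rnorm(100)
  expect_warning(gw <- runGwas(g$panel, y), "zero-variance")
  expect_true(is.na(gw$beta[2]) && is.na(gw$p[2]))
  expect_false(anyNA(gw$beta[c(1, 3)]))
})

test_that("three tightly linked SNPs collapse to the strongest lead", {
  tab <- makeGwasTab(c("a", "b", "c"), bp = c(1000, 2000, 3000),
                     p = c(1e-10, 1e-9, 1e-8))
  ldm <- matrix(0.9, 3, 3, dimnames = list(tab$snp, tab$snp)); diag(ldm) <- 1
  cl <- clumpSnps(tab, ldm, clumpParams())
  expect_equal(nrow(cl), 1)
  expect_identical(cl$lead, "a")
  expect_equal(cl$nMembers, 3)
  expect_true(cl$hit)
})

test_that("SNPs outside the window stay independent leads", {
  tab <- makeGwasTab(c("a", "b"), bp = c(1, 300001), p = c(1e-10, 1e-9))
  ldm <- matrix(1, 2, 2, dimnames = list(tab$snp, tab$snp))
  cl <- clumpSnps(tab, ldm, clumpParams())
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$lead, c("a", "b"))
})

test_that("clumping matches the literal greedy oracle on random instances", {
  for (s in 1:10) {
    set.seed(2000 + s)
    nsnp <- 20
    tab <- makeGwasTab(sprintf("s%02d", 1:nsnp),
                       bp = sort(sample(1:500000, nsnp)),
                       p = 10^runif(nsnp, -12, 0))
    r <- matrix(runif(nsnp^2), nsnp)
    ldm <- (r + t(r)) / 2; diag(ldm) <- 1
    dimnames(ldm) <- list(tab$snp, tab$snp)
    prm <- clumpParams(r2Threshold = 0.4, windowBp = 100000, pThreshold = 1e-4)
    cl <- clumpSnps(tab, ldm, prm)
    orc <- clumpOracle(tab, ldm, 0.4, 100000)
    expect_identical(cl$lead, orc$leads)
    for (i in seq_len(nrow(cl)))
      expect_setequal(strsplit(cl$members[i], ",")[[1]], orc$members[[cl$lead[i]]])
  }
})

test_that("clump output is invariant to input row order", {
  set.seed(11)
  tab <- makeGwasTab(sprintf("s%d", 1:12), bp = sort(sample(1e6, 12)),
                     p = 10^runif(12, -9, 0))
  r <- matrix(runif(144), 12); ldm <- (r + t(r)) / 2; diag(ldm) <- 1
  dimnames(ldm) <- list(tab$snp, tab$snp)
  a <- clumpSnps(tab, ldm, clumpParams())
  b <- clumpSnps(tab[sample(12), ], ldm, clumpParams())
  expect_identical(a, b)
})

test_that("every clump lead has the smallest p-value in its clump", {
  set.seed(12)
  tab <- makeGwasTab(sprintf("s%d", 1:30), bp = sort(sample(2e6, 30)),
                     p = 10^runif(30, -10, 0))
  r <- matrix(runif(900), 30); ldm <- (r + t(r)) / 2; diag(ldm) <- 1
  dimnames(ldm) <- list(tab$snp, tab$snp)
  cl <- clumpSnps(tab, ldm, clumpParams(r2Threshold = 0.3, windowBp = 500000))
  for (i in seq_len(nrow(cl))) {
    mem <- strsplit(cl$members[i], ",")[[1]]
    expect_true(all(cl$p[i] <= tab$p[match(mem, tab$snp)]))
  }
})

test_that("missing LD entries are treated as unlinked, with a message", {
  tab <- makeGwasTab(c("a", "b"), bp = c(1000, 2000), p = c(1e-9, 1e-8))
  ldm <- matrix(1, 1, 1, dimnames = list("a", "a"))  # no entry for b
  expect_message(cl <- clumpSnps(tab, ldm, clumpParams()), "treated as r2 = 0")
  expect_equal(nrow(cl), 2)
})

test_that("shared-hit labels follow the per-study threshold rule", {
  tab <- function(p) makeGwasTab(sprintf("s%d", 1:10),
                                 bp = seq(1e5, 1e6, length.out = 10), p = p)
  pa <- c(1e-9, 1e-9,  0.5, 1e-3, 0.9, 1e-10, 0.2, 0.8, 0.5, 0.9)
  pb <- c(1e-10, 0.13, 1e-9, 1e-3, 0.9, 1e-9, 0.2, 0.8, 0.5, 0.9)
  ldm <- diag(10); dimnames(ldm) <- list(tab(pa)$snp, tab(pa)$snp)
  res <- sharedHits(tab(pa), tab(pb), ldm, clumpParams())
  lab <- setNames(res$leads$label, res$leads$lead)
  # hand enumeration: unlinked SNPs, window excludes neighbours at 1e5 spacing?
  # spacing 1e5 means neighbours are within 250kb, but r2=0 keeps them apart.
  expect_identical(unname(lab["s1"]), "shared")
  expect_identical(unname(lab["s2"]), "a_only")   # pB = 0.13 fails threshold
  expect_identical(unname(lab["s3"]), "b_only")
  expect_identical(unname(lab["s6"]), "shared")
  expect_equal(sum(res$counts), 4)
  expect_equal(res$percentShared, 50)
})

test_that("shared hits are symmetric with swapped labels", {
  set.seed(13)
  n <- 15
  ta <- makeGwasTab(sprintf("s%d", 1:n), bp = seq(1e5, 3e6, length.out = n),
                    p = 10^runif(n, -12, 0))
  tb <- ta; tb$p <- 10^runif(n, -12, 0)
  ldm <- diag(n); dimnames(ldm) <- list(ta$snp, ta$snp)
  ab <- sharedHits(ta, tb, ldm, clumpParams())
  ba <- sharedHits(tb, ta, ldm, clumpParams())
  expect_setequal(ab$leads$lead, ba$leads$lead)
  m <- match(ab$leads$lead, ba$leads$lead)
  swap <- c(shared = "shared", a_only = "b_only", b_only = "a_only")
  expect_identical(unname(swap[ab$leads$label]), ba$leads$label[m])
})

test_that("differing SNP universes are rejected with the difference size", {
  ta <- makeGwasTab(c("a", "b"), bp = c(1, 2e6), p = c(1e-9, 0.5))
  tb <- makeGwasTab(c("a", "c"), bp = c(1, 2e6), p = c(1e-9, 0.5))
  ldm <- diag(2); dimnames(ldm) <- list(c("a", "b"), c("a", "b"))
  expect_error(sharedHits(ta, tb, ldm, clumpParams()), "size 2")
})

test_that("naive genetic correlation has the expected fixed points", {
  set.seed(14)
  g <- simulateGenotypeCohort(300, 20, effects = rnorm(20, 0, 0.3),
                              noiseSd = 1, seed = 14)
  gw <- runGwas(g$panel, g$samples$yObserved)
  expect_equal(naiveGeneticCorrelation(gw, gw, gw$snp), 1.0)
  neg <- gw; neg$beta <- -neg$beta
  expect_equal(naiveGeneticCorrelation(gw, neg, gw$snp), -1.0)
  expect_error(naiveGeneticCorrelation(gw, gw, gw$snp[1:5]), "at least 10")
  # symmetry
  g2 <- runGwas(g$panel, rev(g$samples$yObserved))
  expect_equal(naiveGeneticCorrelation(gw, g2, gw$snp),
               naiveGeneticCorrelation(g2, gw, gw$snp))
})

test_that("uncorrelated architectures give a near-zero estimate", {
  set.seed(15)
  nsnp <- 60
  effA <- rnorm(nsnp, 0, 0.5); effB <- rnorm(nsnp, 0, 0.5)
  gA <- simulateGenotypeCohort(4000, nsnp, effects = effA, noiseSd = 0.5, seed = 16)
  gB <- simulateGenotypeCohort(4000, nsnp, effects = effB, noiseSd = 0.5, seed = 17)
  gwA <- runGwas(gA$panel, gA$samples$yObserved)
  gwB <- runGwas(gB$panel, gB$samples$yObserved)
  expect_lt(abs(naiveGeneticCorrelation(gwA, gwB, gwA$snp) - cor(effA, effB)), 0.1)
})
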