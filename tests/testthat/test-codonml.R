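test_that("GY94 generator has the required structure", {
  sense <- senseCodons()
  piU <- setNames(rep(1 / 61, 61), sense)
  Q <- buildGY94Matrix(piU, kappa = 1, omega = 1, scale = FALSE)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  ## kappa = omega = 1, uniform pi: all single-nucleotide rates equal
  off <- Q[Q > 0]
  expect_equal(max(off), min(off))
  ## multi-nucleotide changes are forbidden
  expect_equal(Q["AAA", "ACC"], 0)
  expect_equal(Q["AAA", "CCC"], 0)

  ## kappa multiplies synonymous transitions, omega nonsynonymous changes
  set.seed(3)
  pi <- rgamma(61, 2); pi <- setNames(pi / sum(pi), sense)
  Q2 <- buildGY94Matrix(pi, kappa = 3, omega = 0.2, scale = FALSE)
  expect_equal(Q2["TTT", "TTC"], pi["TTC"] * 3, ignore_attr = TRUE)  # syn ts
  expect_equal(Q2["TTT", "TTA"], pi["TTA"] * 0.2, ignore_attr = TRUE) # nonsyn tv
  expect_equal(Q2["TTT", "CTT"], pi["CTT"] * 3 * 0.2, ignore_attr = TRUE) # nonsyn ts

  ## detailed balance pi_i q_ij = pi_j q_ji on random entries
  for (k in 1:100) {
    i <- sample(61, 1); j <- sample(61, 1)
    expect_equal(pi[i] * Q2[i, j], pi[j] * Q2[j, i], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  ## scaled matrix: one expected substitution per unit time
  Q3 <- buildGY94Matrix(pi, 3, 0.2, scale = TRUE)
  expect_equal(-sum(pi * diag(Q3)), 1, tolerance = 1e-12)
  expect_error(buildGY94Matrix(pi * 2, 2, 1), "frequencies")
})

test_that("transition matrices are stochastic and stationary", {
  set.seed(9)
  sense <- senseCodons()
  pi <- rgamma(61, 2); pi <- setNames(pi / sum(pi), sense)
  Q <- buildGY94Matrix(pi, 2.5, 0.4)
  Pfun <- OhnologEvo:::.qEigen(Q, pi)
  for (t in runif(5, 0, 5)) {
    P <- Pfun(t)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(as.numeric(pi %*% P), unname(pi), tolerance = 1e-9)
  }
})

test_that("pruning equals the two-taxon closed form", {
  gt <- readGeneTree("(a:0.3,b:0.2);")
  spec <- codonModelSpec(kappa = 2, omega = 0.5)
  sim <- simulateCodonAlignment(gt, spec, 40, seed = 7)
  lnL <- as.numeric(computeTreeLoglik(sim$alignment, gt, spec))
  Q <- gy94Oracle(spec$pi, 2, 0.5)
  P <- as.matrix(Matrix::expm(Q * 0.5))
  sense <- senseCodons()
  seqs <- as.character(alignedSeqs(sim$alignment))
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(seqs[["a"]]); cb <- split3(seqs[["b"]])
  oracle <- sum(log(spec$pi[ca] *
                    P[cbind(match(ca, sense), match(cb, sense))]))
  expect_equal(lnL, oracle, tolerance = 1e-8)
})

test_that("identical one-codon sequences at zero branch length give ln pi", {
  aln <- codonAlignment(c(a = "ATG", b = "ATG"))
  gt <- readGeneTree("(a:0,b:0);")
  spec <- codonModelSpec(2, 0.5)
  lnL <- as.numeric(computeTreeLoglik(aln, gt, spec))
  expect_equal(lnL, log(spec$pi[["ATG"]]), tolerance = 1e-9)
})

test_that("likelihood is invariant to rerooting under a reversible model", {
  nw <- "((a:0.2,b:0.3):0.1,(c:0.15,d:0.25):0.12);"
  gt <- readGeneTree(nw)
  spec <- codonModelSpec(2, 0.3)
  sim <- simulateCodonAlignment(gt, spec, 60, seed = 12)
  l1 <- as.numeric(computeTreeLoglik(sim$alignment, gt, spec))
  tr2 <- ape::root(ape::unroot(treePhylo(gt)), outgroup = "c",
                   resolve.root = TRUE)
  l2 <- as.numeric(computeTreeLoglik(sim$alignment, geneTree(tr2), spec))
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("gaps and ambiguity integrate over sense codons", {
  alnFull <- codonAlignment(c(a = "ATGAAA", b = "ATGAAA"))
  alnMiss <- codonAlignment(c(a = "ATGAAA", b = "ATG---"))
  alnAmb <- codonAlignment(c(a = "ATGAAA", b = "ATGANA"))
  gt <- readGeneTree("(a:0.1,b:0.1);")
  spec <- codonModelSpec(2, 0.5)
  lFull <- attr(computeTreeLoglik(alnFull, gt, spec), "siteLogLik")
  lMiss <- attr(computeTreeLoglik(alnMiss, gt, spec), "siteLogLik")
  lAmb <- attr(computeTreeLoglik(alnAmb, gt, spec), "siteLogLik")
  ## missing codon integrates to the stationary probability of the other tip
  expect_equal(lMiss[2], log(spec$pi[["AAA"]]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(lMiss, lAmb, tolerance = 1e-12)
  expect_equal(lFull[1], lMiss[1], tolerance = 1e-12)
})

test_that("nested fits never lose likelihood and the LRT behaves", {
  nw <- "(((t1:0.15,t2:0.15):0.1,t3:0.2)#1:0.05,(t4:0.15,t5:0.2):0.05);"
  gt <- readGeneTree(nw)
  spec <- codonModelSpec(2, 0.15)
  sim <- simulateCodonAlignment(gt, spec, 120, seed = 21)
  m0 <- fitCodonModel(sim$alignment, gt, "M0", omegaStarts = 0.3)
  b2 <- fitCodonModel(sim$alignment, gt, "branch2", omegaStarts = 0.3,
                      branchLengths = m0)
  expect_gte(logLik2(b2), logLik2(m0) - 1e-6)
  lrt <- likelihoodRatioTest(m0, b2)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$p_value, 0); expect_lte(lrt$p_value, 1)
  expect_equal(nrow(b2@starts), 1L)

  ## equal likelihoods: stat 0, p 1
  lrt0 <- likelihoodRatioTest(m0, m0, df = 1)
  expect_equal(lrt0$stat, 0); expect_equal(lrt0$p_value, 1)
  ## chi-square quantile identity
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  ## df override and failure flag
  expect_warning(likelihoodRatioTest(b2, m0, df = 1), "optimization failure")
  expect_error(fitCodonModel(sim$alignment,
                             geneTree(treePhylo(gt)), "branch2"),
               "foreground")
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("simulation respects its determinism and omega contracts", {
  gt <- readGeneTree("((a:0.2,b:0.2):0.1,c:0.3);")
  s1 <- simulateCodonAlignment(gt, codonModelSpec(2, 0.3), 50, seed = 4)
  s2 <- simulateCodonAlignment(gt, codonModelSpec(2, 0.3), 50, seed = 4)
  expect_identical(as.character(alignedSeqs(s1$alignment)),
                   as.character(alignedSeqs(s2$alignment)))

  ## omega = 0: every substitution event is synonymous, so the protein
  ## sequences never change (pathway-averaged NG86 counts can still assign
  ## small fractional Nd to synonymous codons connected only through
  ## nonsynonymous intermediates, e.g. the two arginine codon groups)
  s0 <- simulateCodonAlignment(gt, codonModelSpec(2, 0), 300, seed = 5)
  prot <- translateAlignment(s0$alignment)
  expect_equal(length(unique(unname(prot))), 1L)
  seqs <- as.character(alignedSeqs(s0$alignment))
  for (p in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    r <- ng86Pairwise(seqs[[p[1]]], seqs[[p[2]]])
    expect_lt(r$Nd, 0.05 * max(r$Sd, 1))
  }

  ## long single branch reaches stationarity
  gtL <- readGeneTree("(x:25,y:25);")
  sL <- simulateCodonAlignment(gtL, codonModelSpec(2, 0.5), 10000, seed = 6)
  seqsL <- as.character(alignedSeqs(sL$alignment))
  codons <- substring(seqsL[["x"]], seq(1, 29998, 3), seq(3, 30000, 3))
  emp <- table(factor(codons, levels = senseCodons())) / 10000
  spec <- codonModelSpec(2, 0.5)
  tv <- 0.5 * sum(abs(as.numeric(emp) - spec$pi))
  expect_lt(tv, 0.05)
})
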