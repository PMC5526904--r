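.divTrees <- function(n = 10, bl = 0.25) {
  list(a = makeBalancedTree("a", n, bl), b = makeBalancedTree("b", n, bl))
}

.jointTree <- function(ta, tb) {
  ape::read.tree(text = sprintf("(%s:0.3,%s:0.3);",
                                sub(";$", "", ta), sub(";$", "", tb)))
}

test_that("Fitch counts agree with hand-traced columns", {
  tr <- ape::read.tree(text = "((x1:1,x2:1):1,(x3:1,x4:1):1);")
  aln <- c(x1 = "AAC", x2 = "ACC", x3 = "AGC", x4 = "AGG")
  ## col1: all A -> 0; col2: A,C,G,G -> 2; col3: C,C,C,G -> 1
  expect_equal(fitchCounts(tr, aln), c(0L, 2L, 1L))
  ## wildcards never add changes
  alnX <- c(x1 = "AAC", x2 = "-CC", x3 = "AXC", x4 = "ACG")
  expect_equal(fitchCounts(tr, alnX), c(0L, 1L, 1L))
})

test_that("identical rate profiles give theta near zero", {
  tr <- .divTrees()
  sim <- simulateDivergentClusters(tr$a, tr$b, 400, theta = 0, shape = 0.6,
                                   seed = 2)
  res <- estimateType1Divergence(sim$alignment, .jointTree(tr$a, tr$b),
                                 paste0("a", 1:10), paste0("b", 1:10),
                                 nBootstrap = 0)
  expect_lt(divergenceTheta(res), 0.1)
  expect_gt(res@pValue, 0.05)
})

test_that("planted divergence is recovered and posteriors rank true sites", {
  tr <- .divTrees()
  sim <- simulateDivergentClusters(tr$a, tr$b, 500, theta = 0.4, shape = 0.6,
                                   seed = 5)
  res <- estimateType1Divergence(sim$alignment, .jointTree(tr$a, tr$b),
                                 paste0("a", 1:10), paste0("b", 1:10),
                                 nBootstrap = 50)
  expect_lt(abs(divergenceTheta(res) - 0.4), 0.2)
  expect_lt(res@pValue, 0.01)
  expect_true(all(sitePosteriors(res) >= 0 & sitePosteriors(res) <= 1))
  ## divergent columns receive higher posteriors on average
  truth <- sim$truth$params$divergent
  expect_gt(mean(sitePosteriors(res)[truth]),
            mean(sitePosteriors(res)[!truth]))
  expect_true(is.finite(res@se) && res@se > 0)
})

test_that("posteriors are invariant to column order", {
  tr <- .divTrees(8)
  sim <- simulateDivergentClusters(tr$a, tr$b, 200, theta = 0.3, shape = 0.6,
                                   seed = 7)
  joint <- .jointTree(tr$a, tr$b)
  ids <- c(paste0("a", 1:8), paste0("b", 1:8))
  res <- estimateType1Divergence(sim$alignment, joint, paste0("a", 1:8),
                                 paste0("b", 1:8), nBootstrap = 0)
  set.seed(1)
  perm <- sample(200)
  permute <- function(s) paste(strsplit(s, "")[[1]][perm], collapse = "")
  alnP <- vapply(sim$alignment, permute, "")
  resP <- estimateType1Divergence(alnP, joint, paste0("a", 1:8),
                                  paste0("b", 1:8), nBootstrap = 0)
  expect_equal(resP@posteriors, res@posteriors[perm], tolerance = 1e-8)
  expect_equal(resP@theta, res@theta, tolerance = 1e-6)
})

test_that("label-permuted clusters show little divergence", {
  tr <- .divTrees(8)
  sim <- simulateDivergentClusters(tr$a, tr$b, 300, theta = 0.4, shape = 0.6,
                                   seed = 9)
  joint <- .jointTree(tr$a, tr$b)
  ids <- c(paste0("a", 1:8), paste0("b", 1:8))
  set.seed(42)
  thetas <- vapply(1:20, function(i) {
    grpA <- sample(ids, 8)
    grpB <- setdiff(ids, grpA)
    r <- tryCatch(
      estimateType1Divergence(sim$alignment, joint, grpA, grpB,
                              nBootstrap = 0),
      error = function(e) NULL)
    if (is.null(r)) NA_real_ else r@theta
  }, 0)
  expect_lt(median(thetas, na.rm = TRUE), 0.1)
})

test_that("iterative cutoff selection removes the top posterior columns", {
  tr <- .divTrees()
  sim <- simulateDivergentClusters(tr$a, tr$b, 400, theta = 0.25, shape = 0.6,
                                   seed = 11)
  res <- estimateType1Divergence(sim$alignment, .jointTree(tr$a, tr$b),
                                 paste0("a", 1:10), paste0("b", 1:10),
                                 nBootstrap = 0)
  expect_lt(res@pValue, 0.05)
  sel <- selectDivergentSites(res, alpha = 0.05)
  expect_gt(length(sel@selectedSites), 0)
  ## removed columns are exactly the top original posteriors, so the cutoff
  ## is the highest remaining posterior and all selected sites exceed it
  post <- sitePosteriors(res)
  expect_equal(sel@cutoff, max(post[-sel@selectedSites]))
  expect_true(all(post[sel@selectedSites] > sel@cutoff))
  expect_setequal(sel@selectedSites,
                  order(post, decreasing = TRUE)[seq_along(sel@selectedSites)])

  ## non-significant initial fit: empty selection, undefined cutoff
  sim0 <- simulateDivergentClusters(tr$a, tr$b, 300, theta = 0, shape = 0.6,
                                    seed = 2)
  res0 <- estimateType1Divergence(sim0$alignment, .jointTree(tr$a, tr$b),
                                  paste0("a", 1:10), paste0("b", 1:10),
                                  nBootstrap = 0)
  sel0 <- selectDivergentSites(res0)
  expect_true(is.na(sel0@cutoff))
  expect_equal(length(sel0@selectedSites), 0L)
})

test_that("bootstrap SE shrinks with alignment length", {
  tr <- .divTrees()
  joint <- .jointTree(tr$a, tr$b)
  ses <- vapply(c(100, 300, 1000), function(n) {
    sim <- simulateDivergentClusters(tr$a, tr$b, n, theta = 0.3, shape = 0.6,
                                     seed = 31)
    set.seed(1)
    estimateType1Divergence(sim$alignment, joint, paste0("a", 1:10),
                            paste0("b", 1:10), nBootstrap = 80)@se
  }, 0)
  expect_true(all(diff(ses) < 0))
})

test_that("cluster preconditions are enforced", {
  tr <- .divTrees(4)
  sim <- simulateDivergentClusters(tr$a, tr$b, 50, 0, seed = 1)
  joint <- .jointTree(tr$a, tr$b)
  expect_error(estimateType1Divergence(sim$alignment, joint,
                                       paste0("a", 1:3), paste0("b", 1:4)),
               "at least 4")
  expect_error(estimateType1Divergence(sim$alignment, joint,
                                       paste0("a", 1:4), c("a1", paste0("b", 1:3))),
               "disjoint")
  ## zero-variation alignment
  alnConst <- setNames(rep(strrep("A", 50), 8),
                       c(paste0("a", 1:4), paste0("b", 1:4)))
  expect_error(estimateType1Divergence(alnConst, joint, paste0("a", 1:4),
                                       paste0("b", 1:4)),
               "zero-variation")
})
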