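.mkLoci <- function(ids, region) {
  data.frame(gene_id = ids, chrom = region, order_index = seq_along(ids),
             stringsAsFactors = FALSE)
}

.pairFam <- function(aGenes, bGenes) {
  do.call(rbind, lapply(seq_along(aGenes), function(i)
    data.frame(family_id = paste0("f", i), gene_id = c(aGenes[i], bGenes[i]),
               anchor_id = paste0("o", i), stringsAsFactors = FALSE)))
}

test_that("outgroup anchoring drops, splits and preserves families", {
  fam <- data.frame(family_id = c("F", "F", "F"),
                    gene_id = c("P1", "P2", "P3"))
  hits <- data.frame(query_id = c("P1", "P2", "P3"),
                     subject_id = c("O1", "O1", "O2"),
                     evalue = 1e-30, bitscore = c(300, 300, 300))
  out <- anchorParalogFamilies(fam, hits)
  ## P1,P2 share anchor O1; P3 becomes a singleton subgroup and is dropped
  expect_setequal(out$gene_id, c("P1", "P2"))
  expect_equal(unique(out$anchor_id), "O1")

  ## no hit below the threshold: member discarded (E < 1e-10, strict)
  hits2 <- transform(hits, evalue = c(1e-30, 1e-10, 1e-30))
  out2 <- anchorParalogFamilies(fam, hits2)
  expect_equal(nrow(out2), 0L)   # P2 dropped -> P1 alone with O1, P3 alone

  ## all members share one anchor: family unchanged
  hits3 <- transform(hits, subject_id = "O5")
  out3 <- anchorParalogFamilies(fam, hits3)
  expect_setequal(out3$gene_id, c("P1", "P2", "P3"))
  expect_equal(unique(out3$family_id), "F")
  expect_equal(unique(out3$anchor_id), "O5")
})

test_that("monotone runs of anchored pairs become direct/inverted blocks", {
  A <- .mkLoci(paste0("a", 1:10), "A")
  B <- .mkLoci(paste0("b", 1:10), "B")
  fam <- .pairFam(paste0("a", c(1, 3, 7)), paste0("b", c(1, 3, 7)))
  bl <- detectSyntenicBlocks(A, B, fam, windowSize = 10, minPairs = 3)
  expect_equal(nrow(syntenyBlocks(bl)), 1L)
  expect_equal(syntenyBlocks(bl)$orientation, "direct")
  expect_equal(syntenyBlocks(bl)$n_pairs, 3L)

  famInv <- .pairFam(paste0("a", 1:3), paste0("b", c(10, 9, 8)))
  blInv <- detectSyntenicBlocks(A, B, famInv, windowSize = 10, minPairs = 3)
  expect_equal(syntenyBlocks(blInv)$orientation, "inverted")
  expect_equal(syntenyBlocks(blInv)$n_pairs, 3L)

  ## no anchored pairs -> empty result
  blEmpty <- detectSyntenicBlocks(A, B, .pairFam("ax", "bx"))
  expect_equal(nrow(syntenyBlocks(blEmpty)), 0L)

  expect_error(detectSyntenicBlocks(A, B, fam, windowSize = 1), "windowSize")
  expect_error(detectSyntenicBlocks(A, B, fam, minPairs = 1), "minPairs")
})

test_that("detected blocks match the exhaustive window-search oracle", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    npairs <- sample(4:min(n, 12), 1)
    ai <- sort(sample(n, npairs))
    bi <- sample(n, npairs)
    pairs <- data.frame(gene_a = paste0("a", ai), rank_a = ai,
                        gene_b = paste0("b", bi), rank_b = bi,
                        family_id = paste0("f", seq_len(npairs)),
                        stringsAsFactors = FALSE)
    A <- .mkLoci(paste0("a", 1:n), "A")
    B <- .mkLoci(paste0("b", 1:n), "B")
    fam <- .pairFam(pairs$gene_a, pairs$gene_b)
    w <- sample(c(5, 8, 12), 1)
    got <- detectSyntenicBlocks(A, B, fam, windowSize = w, minPairs = 3)
    oracle <- syntenyOracle(pairs, w, 3)
    gotKeys <- sort(vapply(split(syntenyPairs(got), syntenyPairs(got)$block_id),
      function(d) paste(sort(paste(d$gene_a, d$gene_b, sep = "|")),
                        collapse = ";"), ""))
    oracleKeys <- sort(vapply(oracle, function(o)
      paste(sort(o$pairs), collapse = ";"), ""))
    expect_equal(unname(gotKeys), unname(oracleKeys), info = paste("rep", rep))
  }
})

test_that("block detection is symmetric in the two regions", {
  for (s in 1:5) {
    w <- simulateWgdGeneOrders(150, 0.5, nInversions = 1, nTranslocations = 1,
                               seed = s)
    b1 <- detectSyntenicBlocks(w$regionA, w$regionB, w$families)
    b2 <- detectSyntenicBlocks(w$regionB, w$regionA, w$families)
    k1 <- sort(paste(syntenyPairs(b1)$gene_a, syntenyPairs(b1)$gene_b))
    k2 <- sort(paste(syntenyPairs(b2)$gene_b, syntenyPairs(b2)$gene_a))
    expect_equal(k1, k2, info = paste("seed", s))
    expect_equal(sort(table(syntenyBlocks(b1)$orientation)),
                 sort(table(syntenyBlocks(b2)$orientation)))
  }
})

test_that("shuffled gene orders yield only short, still-monotone blocks", {
  w <- simulateWgdGeneOrders(1000, 0.3, 0, 0, seed = 13)
  real <- detectSyntenicBlocks(w$regionA, w$regionB, w$families)
  set.seed(13)
  rb <- w$regionB
  rb$order_index <- sample(rb$order_index)
  null <- detectSyntenicBlocks(w$regionA, rb, w$families)
  ## conserved order shows up as one long run; random order only produces
  ## short chance runs near the minimum block size
  expect_gte(max(syntenyBlocks(real)$n_pairs), 30)
  expect_lte(max(syntenyBlocks(null)$n_pairs), 8)
  expect_lt(nrow(syntenyBlocks(null)), 0.5 * nrow(w$truePairs))
  ## every reported block satisfies strict monotonicity
  for (bid in unique(syntenyPairs(null)$block_id)) {
    d <- syntenyPairs(null)[syntenyPairs(null)$block_id == bid, ]
    d <- d[order(d$rank_a), ]
    expect_true(all(diff(d$rank_a) > 0))
    expect_true(all(diff(d$rank_b) > 0) || all(diff(d$rank_b) < 0))
  }
})

test_that("self-comparison excludes trivial and near-window self pairs", {
  loci <- .mkLoci(paste0("g", 1:40), "X")
  ## paralog pairs 10 ranks apart plus a self pair
  fam <- rbind(.pairFam(paste0("g", 1:5), paste0("g", 21:25)),
               data.frame(family_id = "fs", gene_id = c("g30", "g30"),
                          anchor_id = "os"))
  bl <- detectSyntenicBlocks(loci, loci, fam, windowSize = 10, minPairs = 3)
  p <- syntenyPairs(bl)
  expect_true(all(p$gene_a != p$gene_b))
  expect_true(all(abs(p$rank_a - p$rank_b) >= 10))
  expect_gte(nrow(p), 3L)
  counts <- sharedPairCounts(bl)
  expect_equal(counts$total_distinct, nrow(unique(p[, c("gene_a", "gene_b")])))
})
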