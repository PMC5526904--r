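## fixture: a small domtblout in the HMMER text layout
.writeDomtbl <- function(rows) {
  path <- tempfile(fileext = ".domtblout")
  hdr <- c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
           "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  writeLines(c(hdr, rows), path)
  path
}

.domRow <- function(target, tlen, qlen, seqE, cE, iE, hf, ht) {
  sprintf("%s - %d FUN14 PF04930.10 %d %g 55 0.1 1 1 %g %g 50 0.1 %d %d 1 %d 1 %d 0.9 -",
          target, tlen, qlen, seqE, cE, iE, hf, ht, ht - hf + 1, ht - hf + 1)
}

test_that("domtblout parsing and threshold filtering are inclusive", {
  path <- .writeDomtbl(c(
    .domRow("protA", 200, 102, 1e-2, 1e-2, 5e-3, 26, 76),    # cov 51/102 = 0.5
    .domRow("protB", 200, 102, 1e-30, 1e-30, 1e-30, 27, 76), # cov 50/102 < 0.5
    .domRow("protC", 200, 102, 1e-30, 1e-30, 1e-30, 51, 102),# cov 52/102 ~ 0.51
    .domRow("protD", 200, 102, 2e-2, 1e-30, 1e-30, 1, 102),  # seq E too high
    .domRow("protE", 200, 102, 1e-30, 2e-2, 1e-30, 1, 102))) # dom cE too high
  hits <- readDomtblout(path)
  expect_equal(nrow(hits), 5L)
  expect_equal(hits$hmm_length[1], 102L)

  kept <- filterDomainHits(hits)
  expect_equal(kept$target_id, c("protA", "protC"))
  ## coverage of protC checked against an independent span computation
  expect_equal((hits$hmm_to[3] - hits$hmm_from[3] + 1) / 102, 52 / 102)

  ## independent-E dialect: protE passes on i-Evalue
  keptI <- filterDomainHits(hits, domEvalueKind = "independent")
  expect_true("protE" %in% keptI$target_id)

  ## filtering is idempotent
  expect_identical(filterDomainHits(kept), kept)
  expect_error(filterDomainHits(transform(hits, hmm_length = 0)),
               "hmm_length")
})

test_that("summed-envelope coverage rescues split domain hits", {
  path <- .writeDomtbl(c(
    .domRow("protS", 300, 100, 1e-20, 1e-20, 1e-20, 1, 30),
    .domRow("protS", 300, 100, 1e-20, 1e-20, 1e-20, 41, 70)))
  hits <- readDomtblout(path)
  expect_equal(nrow(filterDomainHits(hits)), 0L)               # best single 0.3
  expect_equal(nrow(filterDomainHits(hits, merge = "summed")), 2L) # union 0.6
})

test_that("greedy clustering follows identity and short-coverage thresholds", {
  set.seed(11)
  base <- paste(sample(OhnologEvo:::.AA, 100, replace = TRUE), collapse = "")
  ident <- base
  ## ~90% identity: substitute every 10th position
  div <- strsplit(base, "")[[1]]
  for (i in seq(5, 95, by = 10)) div[i] <- setdiff(c("P", "G"), div[i])[1]
  div <- paste(div, collapse = "")
  sub60 <- substr(base, 21, 80)

  cl <- clusterRedundantSequences(c(s1 = base, s2 = ident))
  expect_equal(length(unique(cl$representative_id)), 1L)

  cl2 <- clusterRedundantSequences(c(s1 = base, s2 = div))
  expect_equal(length(unique(cl2$representative_id)), 2L)

  ## exact substring: identity 1, coverage of shorter 1 >= 0.6
  cl3 <- clusterRedundantSequences(c(long = base, short = sub60))
  expect_equal(length(unique(cl3$representative_id)), 1L)
  expect_equal(unique(cl3$representative_id), "long")

  ## clusters partition the input; input order never matters
  seqs <- c(a = base, b = div, c = sub60, d = ident)
  cl4 <- clusterRedundantSequences(seqs)
  expect_setequal(cl4$member_id, names(seqs))
  expect_false(anyDuplicated(cl4$member_id) > 0)
  cl5 <- clusterRedundantSequences(seqs[c(3, 1, 4, 2)])
  expect_equal(length(unique(cl4$representative_id)),
               length(unique(cl5$representative_id)))
  expect_error(clusterRedundantSequences(character(0)), "empty")
})

test_that("reverse-best-hit rule accepts non-best forward hits", {
  fw <- data.frame(query_id = "q", subject_id = c("A", "B"),
                   evalue = c(1e-5, 1e-6), bitscore = c(100, 200))
  rv <- rbind(
    data.frame(query_id = "A", subject_id = c("q", "x"),
               evalue = c(1e-6, 1e-3), bitscore = c(300, 100)),
    data.frame(query_id = "B", subject_id = c("other", "q"),
               evalue = c(1e-9, 1e-6), bitscore = c(400, 300)))
  ## A ranks second forward yet is accepted; B's reverse best is elsewhere
  expect_equal(assignOrthologs("q", fw, rv), "A")

  ## forward E-value gate applies regardless of the reverse result
  fw2 <- transform(fw, evalue = c(1e-2, 1e-6))
  expect_equal(assignOrthologs("q", fw2, rv), character(0))

  ## reverse best-hit ties break by bitscore, then e-value, then subject id
  rvTie <- data.frame(query_id = "A", subject_id = c("q", "p"),
                      evalue = c(1e-6, 1e-6), bitscore = c(300, 300))
  expect_equal(assignOrthologs("q", fw[1, ], rvTie), character(0)) # "p" < "q"
  rvTie2 <- transform(rvTie, subject_id = c("q", "r"))
  expect_equal(assignOrthologs("q", fw[1, ], rvTie2), "A")
  ## both tie orders give the same decision
  expect_equal(assignOrthologs("q", fw[1, ], rvTie2[2:1, ]), "A")

  expect_error(assignOrthologs("q", fw, list(A = rv[rv$query_id == "A", ])),
               "missing reverse")
})

test_that("planted hit tables are recovered exactly, decoys excluded", {
  hits <- simulateHitTable(6, 8, noiseHits = 2, rankTwoQueries = "q4",
                           seed = 3)
  planted <- unlist(hits$truth$params$planted)
  for (q in names(planted)) {
    got <- assignOrthologs(q, hits$forward, hits$reverse)
    expect_equal(got, unname(planted[q]), info = q)
  }
  ## the decoy outranks the planted ortholog in the forward table
  fw4 <- hits$forward[hits$forward$query_id == "q4", ]
  fw4 <- fw4[order(-fw4$bitscore), ]
  expect_equal(fw4$subject_id[1], "decoy_q4")
  expect_false("decoy_q4" %in% assignOrthologs("q4", hits$forward, hits$reverse))
})
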