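## Outgroup-anchored paralog-family refinement and sliding-window detection
## of conserved syntenic blocks (paralogons) as WGD evidence.

#' Filter and split paralog families by outgroup anchoring
#'
#' Members without any outgroup hit below \code{eMax} are discarded; each
#' family is partitioned by its members' top outgroup hit; subgroups with at
#' least two surviving members are kept and anchored to the shared outgroup
#' protein.
#'
#' @param families data.frame (family_id, gene_id).
#' @param outgroupHits data.frame of BLAST hits of family members against the
#'   outgroup proteome (query_id, subject_id, evalue, bitscore).
#' @param eMax strict E-value threshold; hits must satisfy
#'   \code{evalue < eMax} (default 1e-10).
#' @return data.frame (family_id, gene_id, anchor_id); family ids of split
#'   subgroups are suffixed with the anchor.
#' @export
anchorParalogFamilies <- function(families, outgroupHits, eMax = 1e-10) {
  hits <- outgroupHits[outgroupHits$evalue < eMax, , drop = FALSE]
  topHit <- function(gene) {
    h <- hits[hits$query_id == gene, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    .rankHits(h)$subject_id[1]
  }
  out <- list()
  for (fam in unique(families$family_id)) {
    members <- families$gene_id[families$family_id == fam]
    anchors <- vapply(members, topHit, "")
    keep <- !is.na(anchors)
    members <- members[keep]; anchors <- anchors[keep]
    for (anc in unique(anchors)) {
      sub <- members[anchors == anc]
      if (length(sub) < 2L) next
      famId <- if (length(unique(anchors)) > 1L) paste(fam, anc, sep = ".") else fam
      out[[length(out) + 1L]] <- data.frame(
        family_id = famId, gene_id = sub, anchor_id = anc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(family_id = character(), gene_id = character(),
                      anchor_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## anchored pair list between two locus tables: genes in region A and B whose
## anchored (sub)family is the same; one row per cross pair
.anchoredPairs <- function(regionA, regionB, anchoredFamilies, selfComparison,
                          windowSize) {
  fam <- anchoredFamilies
  a <- merge(fam, regionA[, c("gene_id", "order_index")], by = "gene_id")
  b <- merge(fam, regionB[, c("gene_id", "order_index")], by = "gene_id")
  if (!nrow(a) || !nrow(b)) return(NULL)
  pairs <- merge(a, b, by = "family_id", suffixes = c("_a", "_b"))
  if (!nrow(pairs)) return(NULL)
  if (selfComparison) {
    pairs <- pairs[pairs$gene_id_a != pairs$gene_id_b &
                   abs(pairs$order_index_a - pairs$order_index_b) >= windowSize, ,
                   drop = FALSE]
    ## self-comparison is symmetric: keep each unordered pair once, oriented
    ## with the lower A rank first
    pairs <- pairs[pairs$order_index_a < pairs$order_index_b, , drop = FALSE]
  }
  if (!nrow(pairs)) return(NULL)
  data.frame(gene_a = pairs$gene_id_a, rank_a = pairs$order_index_a,
             gene_b = pairs$gene_id_b, rank_b = pairs$order_index_b,
             family_id = pairs$family_id, stringsAsFactors = FALSE)
}

## maximal strictly-monotone runs over pairs sorted by rank_a, with
## consecutive rank gaps < windowSize in BOTH regions (two pairs can only
## extend a run when a window of windowSize gene ranks contains both in each
## region; the two-sided constraint keeps detection symmetric in A and B)
.monotoneRuns <- function(pairs, windowSize, minPairs) {
  p <- pairs[order(pairs$rank_a, pairs$rank_b), , drop = FALSE]
  n <- nrow(p)
  runs <- list()
  emit <- function(idx, dir) {
    if (length(idx) >= minPairs)
      runs[[length(runs) + 1L]] <<- list(idx = idx,
        orientation = if (dir > 0) "direct" else "inverted")
  }
  i <- 1L
  while (i < n) {
    j <- i + 1L
    ## find the next usable step from i
    step <- function(x, y) {
      p$rank_a[y] > p$rank_a[x] &&
        (p$rank_a[y] - p$rank_a[x]) <= (windowSize - 1L) &&
        abs(p$rank_b[y] - p$rank_b[x]) <= (windowSize - 1L) &&
        p$rank_b[y] != p$rank_b[x]
    }
    if (!step(i, j)) { i <- j; next }
    dir <- sign(p$rank_b[j] - p$rank_b[i])
    idx <- c(i, j)
    k <- j
    while (k < n) {
      nxt <- k + 1L
      if (step(k, nxt) && sign(p$rank_b[nxt] - p$rank_b[k]) == dir) {
        idx <- c(idx, nxt); k <- nxt
      } else break
    }
    emit(idx, dir)
    i <- k                                  # peak pair may seed the next run
  }
  list(pairs = p, runs = runs)
}

#' Detect conserved syntenic blocks between two genomic regions
#'
#' Slides a window of \code{windowSize} gene ranks along region A, collects
#' anchored paralog pairs, and extracts maximal runs whose region-B ranks are
#' strictly increasing (direct) or strictly decreasing (inverted);
#' overlapping runs of the same orientation are merged. Blocks with fewer
#' than \code{minPairs} pairs are dropped.
#'
#' When both regions are the same locus table (self-comparison, e.g. two
#' segments of one chromosome), trivial self-pairs are excluded and the two
#' members of a pair must be at least \code{windowSize} ranks apart.
#'
#' @param regionA,regionB gene-locus data.frames with columns gene_id and
#'   order_index (see [readGeneLociBed()]).
#' @param anchoredFamilies data.frame (family_id, gene_id, anchor_id) from
#'   [anchorParalogFamilies()], or any family table whose family_id groups
#'   paralogs.
#' @param windowSize window length in gene ranks (default 100).
#' @param minPairs minimum anchored pairs per reported block (default 3).
#' @return a [SyntenyBlockSet-class].
#' @export
detectSyntenicBlocks <- function(regionA, regionB, anchoredFamilies,
                                 windowSize = 100, minPairs = 3) {
  if (windowSize < 2) stop("windowSize must be >= 2")
  if (minPairs < 2) stop("minPairs must be >= 2")
  selfCmp <- identical(regionA$gene_id, regionB$gene_id)
  pairs <- .anchoredPairs(regionA, regionB, anchoredFamilies, selfCmp, windowSize)
  detect <- function(p) {
    ## scan in region-A order and region-B order and pool the maximal runs:
    ## a run broken by an interleaving pair in one order can still be
    ## contiguous in the other, and the union is symmetric in A and B
    resA <- .monotoneRuns(p, windowSize, minPairs)
    swapped <- data.frame(gene_a = p$gene_b, rank_a = p$rank_b,
                          gene_b = p$gene_a, rank_b = p$rank_a,
                          family_id = p$family_id, stringsAsFactors = FALSE)
    resB <- .monotoneRuns(swapped, windowSize, minPairs)
    key <- function(d) paste(d$gene_a, d$gene_b, sep = "\r")
    blocks <- list()
    add <- function(sub, orientation) {
      blocks[[length(blocks) + 1L]] <<- list(keys = sort(key(sub)),
                                             orientation = orientation)
    }
    for (r in resA$runs) add(resA$pairs[r$idx, ], r$orientation)
    for (r in resB$runs) {
      sub <- resB$pairs[r$idx, ]
      sub <- data.frame(gene_a = sub$gene_b, rank_a = sub$rank_b,
                        gene_b = sub$gene_a, rank_b = sub$rank_a,
                        stringsAsFactors = FALSE)
      add(sub, r$orientation)
    }
    ## drop duplicates and blocks contained in a larger block
    keep <- rep(TRUE, length(blocks))
    for (x in seq_along(blocks)) {
      if (!keep[x]) next
      for (y in seq_along(blocks)) {
        if (x == y || !keep[x]) next
        sx <- blocks[[x]]$keys; sy <- blocks[[y]]$keys
        if (blocks[[x]]$orientation != blocks[[y]]$orientation) next
        if (length(sx) < length(sy) && all(sx %in% sy)) keep[x] <- FALSE
        else if (length(sx) == length(sy) && all(sx %in% sy) && y < x)
          keep[x] <- FALSE
      }
    }
    blocks[keep]
  }
  empty <- new("SyntenyBlockSet",
    blocks = data.frame(block_id = integer(), orientation = character(),
                        n_pairs = integer(), span_a = integer(),
                        span_b = integer(), stringsAsFactors = FALSE),
    pairs = data.frame(block_id = integer(), gene_a = character(),
                       rank_a = integer(), gene_b = character(),
                       rank_b = integer(), family_id = character(),
                       stringsAsFactors = FALSE))
  if (is.null(pairs)) return(empty)
  found <- detect(pairs)
  if (!length(found)) return(empty)
  pairKey <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  ## deterministic block order: leftmost region-A rank, then orientation
  starts <- vapply(found, function(b)
    min(pairs$rank_a[pairKey %in% b$keys]), 0)
  found <- found[order(starts,
                       vapply(found, `[[`, "", "orientation"))]
  blocks <- list(); bpairs <- list()
  for (bi in seq_along(found)) {
    sub <- pairs[pairKey %in% found[[bi]]$keys, , drop = FALSE]
    sub <- sub[order(sub$rank_a), , drop = FALSE]
    blocks[[bi]] <- data.frame(
      block_id = bi, orientation = found[[bi]]$orientation,
      n_pairs = nrow(sub),
      span_a = max(sub$rank_a) - min(sub$rank_a) + 1L,
      span_b = max(sub$rank_b) - min(sub$rank_b) + 1L,
      stringsAsFactors = FALSE)
    sub$block_id <- bi
    bpairs[[bi]] <- sub[, c("block_id", "gene_a", "rank_a", "gene_b",
                            "rank_b", "family_id")]
  }
  new("SyntenyBlockSet", blocks = do.call(rbind, blocks),
      pairs = do.call(rbind, bpairs))
}

#' Distinct gene pairs shared across all blocks of a SyntenyBlockSet
#'
#' Reports both the per-block pair counts and the total number of distinct
#' anchored pairs over all blocks (a pair shared between an increasing and a
#' decreasing run is counted once).
#'
#' @param x a [SyntenyBlockSet-class].
#' @return list with \code{per_block} (named integer vector) and
#'   \code{total_distinct} (integer).
#' @export
sharedPairCounts <- function(x) {
  p <- syntenyPairs(x)
  key <- paste(p$gene_a, p$gene_b, sep = "|")
  list(per_block = tapply(key, p$block_id, function(k) length(unique(k))),
       total_distinct = length(unique(key)))
}

#' Write a SyntenyBlockSet as TSV
#' @param x a [SyntenyBlockSet-class].
#' @param blocksPath,pairsPath output paths.
#' @export
writeSyntenyBlocks <- function(x, blocksPath, pairsPath) {
  write.table(syntenyBlocks(x), blocksPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(syntenyPairs(x), pairsPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}
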