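## Synthetic-data generators with recorded ground truth. All generators are
## pure functions of (parameters, seed); a single user seed fans out into
## independent per-generator streams so adding a generator never perturbs
## existing fixtures.

.generatorSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.truth <- function(generator, seed, ...) {
  structure(list(generator = generator, seed = seed, params = list(...)),
            class = "SimulationTruth")
}

#' Write a SimulationTruth record as JSON
#' @param truth a SimulationTruth.
#' @param path output path.
#' @export
writeSimulationTruth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Simulate a codon alignment under a GY94 model on a tree
#'
#' Root codons are drawn from the model's equilibrium frequencies and
#' evolved along each branch by sampling from \code{exp(Q_c t)} per branch
#' class and site class. Stop codons are never emitted (the state space is
#' the sense codons).
#'
#' @param geneTree a [GeneTree-class] (or ape phylo) with branch lengths.
#' @param spec a [codonModelSpec()].
#' @param nCodons number of codon sites.
#' @param seed integer seed.
#' @return list(alignment = [CodonAlignment-class], truth = SimulationTruth
#'   with the per-site class assignment).
#' @export
simulateCodonAlignment <- function(geneTree, spec, nCodons, seed) {
  if (nCodons < 1) stop("nCodons must be >= 1")
  if (inherits(geneTree, "phylo")) geneTree <- geneTree(geneTree)
  tree <- treePhylo(geneTree)
  set.seed(.generatorSeed(seed, "codon_alignment"))
  Pclos <- .specPclosures(spec)
  edgeClass <- branchClasses(geneTree)
  classIdx <- match(edgeClass, Pclos$classes)
  if (anyNA(classIdx)) {
    if (length(Pclos$classes) == 1L) classIdx <- rep(1L, length(edgeClass))
    else stop("edge class not covered by the model spec")
  }
  sense <- names(spec$pi)
  K <- length(spec$props)
  siteClass <- sample.int(K, nCodons, replace = TRUE, prob = spec$props)
  tr <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  cIdx <- classIdx[ord]
  ntip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  states <- matrix(0L, ntip + tr$Nnode, nCodons)
  states[root, ] <- sample.int(length(sense), nCodons, replace = TRUE,
                               prob = spec$pi)
  for (e in rev(seq_len(nrow(tr$edge)))) {        # preorder
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    for (k in unique(siteClass)) {
      cols <- which(siteClass == k)
      P <- Pclos$Pfun[[k, cIdx[e]]](tr$edge.length[e])
      ps <- states[par, cols]
      for (s in unique(ps)) {
        i <- cols[ps == s]
        states[child, i] <- sample.int(length(sense), length(i),
                                       replace = TRUE, prob = P[s, ])
      }
    }
  }
  seqs <- vapply(seq_len(ntip), function(t)
    paste(sense[states[t, ]], collapse = ""), "")
  names(seqs) <- tr$tip.label
  aln <- codonAlignment(seqs, spec$codeId)
  list(alignment = aln,
       truth = .truth("simulate_codon_alignment", seed,
                      kappa = spec$kappa, omega = spec$omega,
                      props = spec$props, n_codons = nCodons,
                      site_class = siteClass,
                      tree = ape::write.tree(tree)))
}

#' Simulate duplicated gene orders produced by a WGD
#'
#' An ancestral gene order is duplicated into two regions; each copy is
#' dropped independently with probability \code{1 - retention}; the stated
#' numbers of random segment inversions and translocations are applied to
#' region B. Every ancestral gene has a distinct outgroup anchor, so
#' anchored paralog families are exact.
#'
#' @param nGenes ancestral gene count (>= 10).
#' @param retention per-copy keep probability in (0, 1].
#' @param nInversions,nTranslocations rearrangements applied to region B.
#' @param seed integer seed.
#' @return list with regionA / regionB locus data.frames, families (one per
#'   ancestral gene with both surviving copies), truePairs (gene pairs
#'   surviving in both regions), trueBlocks (a [SyntenyBlockSet-class] of
#'   the planted monotone runs), and truth.
#' @export
simulateWgdGeneOrders <- function(nGenes, retention, nInversions = 0,
                                  nTranslocations = 0, seed = 1) {
  if (nGenes < 10) stop("nGenes must be >= 10")
  if (retention <= 0 || retention > 1) {
    if (retention != 0) stop("retention must lie in (0, 1]")
  }
  if (nInversions < 0 || nTranslocations < 0) stop("parameters out of range")
  set.seed(.generatorSeed(seed, "wgd_gene_orders"))
  anc <- seq_len(nGenes)
  keepA <- runif(nGenes) < retention
  keepB <- runif(nGenes) < retention
  orderA <- anc[keepA]
  orderB <- anc[keepB]
  ## rearrange region B's retained order
  segment <- function(n) {
    if (n < 2) return(c(1L, 1L))
    len <- max(2L, min(n, 1L + stats::rgeom(1, prob = 0.08)))
    s <- sample.int(n - len + 1L, 1)
    c(s, s + len - 1L)
  }
  if (length(orderB) >= 2) {
    for (i in seq_len(nInversions)) {
      sg <- segment(length(orderB))
      orderB[sg[1]:sg[2]] <- rev(orderB[sg[1]:sg[2]])
    }
    for (i in seq_len(nTranslocations)) {
      sg <- segment(length(orderB))
      piece <- orderB[sg[1]:sg[2]]
      rest <- orderB[-(sg[1]:sg[2])]
      at <- sample.int(length(rest) + 1L, 1)
      orderB <- append(rest, piece, after = at - 1L)
    }
  }
  locus <- function(order, region) {
    if (!length(order))
      return(data.frame(gene_id = character(), chrom = character(),
                        order_index = integer(), strand = character(),
                        family_id = character(), stringsAsFactors = FALSE))
    data.frame(gene_id = paste0(region, "_g", order), chrom = region,
               order_index = seq_along(order),
               strand = sample(c("+", "-"), length(order), replace = TRUE),
               family_id = paste0("fam", order), stringsAsFactors = FALSE)
  }
  regionA <- locus(orderA, "regA")
  regionB <- locus(orderB, "regB")
  shared <- intersect(orderA, orderB)
  families <- if (length(shared)) do.call(rbind, lapply(shared, function(g)
    data.frame(family_id = paste0("fam", g),
               gene_id = c(paste0("regA_g", g), paste0("regB_g", g)),
               anchor_id = paste0("out", g), stringsAsFactors = FALSE)))
    else data.frame(family_id = character(), gene_id = character(),
                    anchor_id = character(), stringsAsFactors = FALSE)
  truePairs <- if (length(shared)) data.frame(
    gene_a = paste0("regA_g", shared),
    rank_a = match(shared, orderA),
    gene_b = paste0("regB_g", shared),
    rank_b = match(shared, orderB),
    family_id = paste0("fam", shared), stringsAsFactors = FALSE)
    else NULL
  trueBlocks <- if (!is.null(truePairs) && nrow(truePairs) >= 2) {
    res <- .monotoneRuns(truePairs, windowSize = nGenes + 1L, minPairs = 2)
    blocks <- lapply(seq_along(res$runs), function(bi) {
      sub <- res$pairs[res$runs[[bi]]$idx, , drop = FALSE]
      sub$block_id <- bi
      sub
    })
    if (length(blocks)) do.call(rbind, blocks) else NULL
  } else NULL
  list(regionA = regionA, regionB = regionB, families = families,
       truePairs = truePairs, trueBlockPairs = trueBlocks,
       truth = .truth("simulate_wgd_gene_orders", seed, n_genes = nGenes,
                      retention = retention, n_inversions = nInversions,
                      n_translocations = nTranslocations,
                      shared_genes = shared))
}

#' Build a balanced binary tree for simulations
#'
#' Tips are named \code{prefix1..prefixN}; every tip branch has length
#' \code{tipLength} and internal branches half of it.
#'
#' @param prefix tip-name prefix.
#' @param nTips number of tips.
#' @param tipLength terminal branch length.
#' @return Newick string.
#' @export
makeBalancedTree <- function(prefix, nTips, tipLength = 0.25) {
  tips <- sprintf("%s%d:%g", prefix, seq_len(nTips), tipLength)
  inner <- tipLength / 2
  while (length(tips) > 1) {
    nxt <- character(0)
    for (i in seq(1, length(tips) - 1, by = 2))
      nxt <- c(nxt, sprintf("(%s,%s):%g", tips[i], tips[i + 1], inner))
    if (length(tips) %% 2) nxt <- c(nxt, tips[length(tips)])
    tips <- nxt
  }
  paste0(sub(":[0-9.eE+-]+$", "", tips), ";")
}

#' Simulate protein clusters with a fraction of rate-divergent columns
#'
#' For each column, with probability theta the two clusters draw
#' independent gamma rates, otherwise one shared rate; residues evolve
#' under a uniform 20-state exchangeability model along each cluster tree.
#'
#' @param treeA,treeB [ape::phylo] trees (or Newick strings) for the two
#'   clusters; tip label sets must be disjoint.
#' @param nColumns alignment columns.
#' @param theta true fraction of divergent columns in [0, 1].
#' @param shape gamma shape of the rate distribution (mean 1).
#' @param seed integer seed.
#' @return list(alignment = named character vector over all tips,
#'   truth = SimulationTruth with the divergent-column mask and rates).
#' @export
simulateDivergentClusters <- function(treeA, treeB, nColumns, theta,
                                      shape = 1, seed = 1) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (is.character(treeA)) treeA <- ape::read.tree(text = treeA)
  if (is.character(treeB)) treeB <- ape::read.tree(text = treeB)
  if (length(intersect(treeA$tip.label, treeB$tip.label)))
    stop("cluster trees must have disjoint tip labels")
  set.seed(.generatorSeed(seed, "divergent_clusters"))
  divergent <- runif(nColumns) < theta
  shared <- rgamma(nColumns, shape = shape, rate = shape)
  ratesA <- ifelse(divergent, rgamma(nColumns, shape = shape, rate = shape),
                   shared)
  ratesB <- ifelse(divergent, rgamma(nColumns, shape = shape, rate = shape),
                   shared)
  evolve <- function(tree, rates) {
    tr <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(tr$tip.label)
    root <- tr$edge[nrow(tr$edge), 1]
    st <- matrix(0L, ntip + tr$Nnode, nColumns)
    st[root, ] <- sample.int(20L, nColumns, replace = TRUE)
    for (e in rev(seq_len(nrow(tr$edge)))) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      t <- tr$edge.length[e]
      psame <- 1 / 20 + 19 / 20 * exp(-20 / 19 * rates * t)
      stay <- runif(nColumns) < psame
      st[child, ] <- st[par, ]
      n <- sum(!stay)
      if (n) {
        shift <- sample.int(19L, n, replace = TRUE)
        st[child, !stay] <- 1L + (st[par, !stay] - 1L + shift) %% 20L
      }
    }
    out <- vapply(seq_len(ntip), function(t)
      paste(.AA[st[t, ]], collapse = ""), "")
    names(out) <- tr$tip.label
    out
  }
  aln <- c(evolve(treeA, ratesA), evolve(treeB, ratesB))
  list(alignment = aln,
       truth = .truth("simulate_divergent_clusters", seed, theta = theta,
                      shape = shape, n_columns = nColumns,
                      divergent = divergent, rates_a = ratesA,
                      rates_b = ratesB))
}

#' Simulate forward/reverse similarity-hit tables with planted orthologs
#'
#' Planted query-subject pairs receive mutually best E-values; noise hits
#' get worse E-values; reverse tables are constructed consistently. A
#' subset of planted orthologs can be demoted to forward rank 2 by a decoy
#' subject whose reverse best hit is a third protein, exercising the
#' reverse-best-hit (not bidirectional-best) rule.
#'
#' @param nQueries,nSubjects sizes of the two proteomes (queries "q1"...,
#'   subjects "s1"...).
#' @param plantedOrthologMap named character vector query -> subject
#'   (injective); default plants "qi" -> "si" for all queries.
#' @param noiseHits number of random noise hits per query (default 2).
#' @param rankTwoQueries queries whose planted ortholog is pushed to
#'   forward rank 2 by a decoy.
#' @param seed integer seed.
#' @return list(forward, reverse data.frames with query_id, subject_id,
#'   evalue, bitscore; truth).
#' @export
simulateHitTable <- function(nQueries, nSubjects, plantedOrthologMap = NULL,
                             noiseHits = 2, rankTwoQueries = character(0),
                             seed = 1) {
  queries <- paste0("q", seq_len(nQueries))
  subjects <- paste0("s", seq_len(nSubjects))
  if (is.null(plantedOrthologMap))
    plantedOrthologMap <- setNames(subjects[seq_len(min(nQueries, nSubjects))],
                                   queries[seq_len(min(nQueries, nSubjects))])
  if (anyDuplicated(plantedOrthologMap) || anyDuplicated(names(plantedOrthologMap)))
    stop("plantedOrthologMap must be injective")
  set.seed(.generatorSeed(seed, "hit_table"))
  fw <- list(); rv <- list()
  row <- function(q, s, e, b) data.frame(query_id = q, subject_id = s,
                                         evalue = e, bitscore = b,
                                         stringsAsFactors = FALSE)
  for (q in queries) {
    planted <- plantedOrthologMap[q]
    if (!is.na(planted)) {
      fw[[length(fw) + 1L]] <- row(q, planted, 10^-runif(1, 40, 60),
                                   500 + runif(1, 0, 50))
      rv[[length(rv) + 1L]] <- row(planted, q, 10^-runif(1, 40, 60),
                                   500 + runif(1, 0, 50))
      if (q %in% rankTwoQueries) {
        decoy <- paste0("decoy_", q)
        fw[[length(fw) + 1L]] <- row(q, decoy, 10^-runif(1, 60, 80), 700)
        rv[[length(rv) + 1L]] <- rbind(row(decoy, paste0("other_", q),
                                           1e-70, 800),
                                       row(decoy, q, 1e-50, 400))
      }
    }
    if (noiseHits > 0 && nSubjects > 1) {
      pool <- setdiff(subjects, planted)
      ns <- sample(pool, min(noiseHits, length(pool)))
      for (s in ns) {
        fw[[length(fw) + 1L]] <- row(q, s, 10^-runif(1, 4, 8),
                                     100 + runif(1, 0, 50))
        ## noise subject's reverse best is its own planted query (if any),
        ## otherwise a third protein
        own <- names(plantedOrthologMap)[plantedOrthologMap == s]
        bestq <- if (length(own)) own else paste0("other_", s)
        rv[[length(rv) + 1L]] <- rbind(row(s, bestq, 1e-60, 600),
                                       row(s, q, 10^-runif(1, 4, 8), 120))
      }
    }
  }
  forward <- do.call(rbind, fw)
  reverse <- unique(do.call(rbind, rv))
  list(forward = forward, reverse = reverse,
       truth = .truth("simulate_hit_table", seed,
                      planted = as.list(plantedOrthologMap),
                      n_queries = nQueries, n_subjects = nSubjects,
                      noise_hits = noiseHits,
                      rank_two_queries = rankTwoQueries))
}
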