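## Readers/writers for the standard formats consumed by the pipeline, codon
## alignment construction from protein alignments, and domain partitioning.

#' Read a FASTA file of protein or DNA sequences
#'
#' @param path file path.
#' @param moltype "protein" or "dna".
#' @return an AAStringSet or DNAStringSet; ids are the first whitespace token
#'   of each header.
#' @export
readFasta <- function(path, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  x <- if (moltype == "protein") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate sequence ids in ", path)
  x
}

#' Write sequences to FASTA
#' @param x an XStringSet or named character vector.
#' @param path output path.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write an alignment in sequential PHYLIP format
#'
#' Relaxed PHYLIP: full ids (padded to a common width), sequential layout.
#' @param x an XStringSet of equal-width aligned sequences.
#' @param path output path.
#' @export
writePhylip <- function(x, path) {
  w <- Biostrings::width(x)
  stopifnot(length(unique(w)) == 1L)
  ids <- formatC(names(x), width = max(nchar(names(x))) + 2L, flag = "-")
  lines <- c(sprintf(" %d %d", length(x), w[1]),
             paste0(ids, as.character(x)))
  writeLines(lines, path)
  invisible(path)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue becomes its source codon; each protein gap becomes
#' "---". A terminal stop codon on a CDS is stripped. The translation of
#' every emitted codon must equal the aligned residue.
#'
#' @param proteinAln named AAStringSet (or character vector) of equal-length
#'   aligned protein sequences.
#' @param cds named DNAStringSet (or character vector) of unaligned coding
#'   sequences, keyed by the same ids.
#' @param geneticCodeId NCBI genetic-code id.
#' @return a [CodonAlignment-class].
#' @export
backtranslateAlignment <- function(proteinAln, cds, geneticCodeId = "1") {
  prot <- if (is.character(proteinAln)) proteinAln else as.character(proteinAln)
  cdsc <- if (is.character(cds)) cds else as.character(cds)
  if (is.null(names(prot)) || is.null(names(cdsc)))
    stop("proteinAln and cds must be named")
  code <- geneticCode(geneticCodeId)
  out <- character(length(prot))
  for (i in seq_along(prot)) {
    id <- names(prot)[i]
    if (!id %in% names(cdsc)) stop("missing CDS for id '", id, "'")
    codons <- .splitCodons(cdsc[[id]])
    if (length(codons) && !is.na(code[codons[length(codons)]]) &&
        code[codons[length(codons)]] == "*")
      codons <- codons[-length(codons)]
    residues <- strsplit(prot[i], "")[[1]]
    ungapped <- residues[residues != "-"]
    if (length(codons) != length(ungapped))
      stop(sprintf("length mismatch for '%s': %d codons vs %d residues",
                   id, length(codons), length(ungapped)))
    stops <- which(!.isAmbiguousCodon(codons) & code[codons] == "*")
    if (length(stops))
      stop(sprintf("internal stop codon in '%s' at codon %d", id, stops[1]))
    for (j in seq_along(ungapped)) {
      aa <- translateCodons(codons[j], code)
      if (aa != "X" && aa != ungapped[j] && ungapped[j] != "X")
        stop(sprintf(
          "translation mismatch in '%s' at residue %d (expected %s, codon %s=%s)",
          id, j, ungapped[j], codons[j], aa))
    }
    row <- rep("---", length(residues))
    row[residues != "-"] <- codons
    out[i] <- paste(row, collapse = "")
  }
  names(out) <- names(prot)
  codonAlignment(out, geneticCodeId)
}

#' Translate a codon alignment back to a protein alignment
#' @param x a [CodonAlignment-class].
#' @return named character vector of aligned protein sequences.
#' @export
translateAlignment <- function(x) {
  code <- geneticCode(geneticCodeId(x))
  vapply(as.character(alignedSeqs(x)), function(s)
    paste(translateCodons(.splitCodons(s), code), collapse = ""), "")
}

#' Define a domain partition on a reference protein
#'
#' Residue ranges are 1-based inclusive on the ungapped reference sequence
#' (the "1-49 aa" convention of domain annotations).
#'
#' @param name partition name.
#' @param start,end 1-based inclusive residue range.
#' @return a one-row data.frame (name, start, end).
#' @export
domainPartition <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid residue range: need 1 <= start <= end")
  data.frame(name = as.character(name), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Check a partition scheme for overlaps
#' @param partitions data.frame of [domainPartition()] rows.
#' @keywords internal
.checkPartitionScheme <- function(partitions) {
  p <- partitions[order(partitions$start), , drop = FALSE]
  if (nrow(p) > 1L && any(p$start[-1] <= p$end[-nrow(p)]))
    stop("partitions overlap within one scheme")
  invisible(p)
}

#' Extract the codon columns of a residue range on a reference sequence
#'
#' Maps a 1-based inclusive residue range on the ungapped reference through
#' the alignment gaps and returns the corresponding codon columns.
#'
#' @param codonAln a [CodonAlignment-class].
#' @param partition a one-row data.frame from [domainPartition()] (or a
#'   numeric \code{c(start, end)}).
#' @param referenceId id of the reference sequence.
#' @return a [CodonAlignment-class] restricted to the selected codon columns.
#' @export
mapResidueRanges <- function(codonAln, partition, referenceId) {
  if (is.numeric(partition))
    partition <- domainPartition("range", partition[1], partition[2])
  seqs <- as.character(alignedSeqs(codonAln))
  if (!referenceId %in% names(seqs))
    stop("reference sequence '", referenceId, "' absent from alignment")
  refCodons <- .splitCodons(seqs[[referenceId]])
  nongap <- which(refCodons != "---")
  if (partition$end > length(nongap))
    stop(sprintf("range %d-%d exceeds reference length %d",
                 partition$start, partition$end, length(nongap)))
  cols <- nongap[partition$start:partition$end]   # codon column indices
  sub <- vapply(seqs, function(s) {
    codons <- .splitCodons(s)
    paste(codons[cols], collapse = "")
  }, "")
  codonAlignment(sub, geneticCodeId(codonAln))
}

## ---- trees ----------------------------------------------------------------

#' Read a gene tree with codeml-style branch marks
#'
#' Accepts Newick in which tip or internal-node labels carry a "#k" suffix
#' (marks that branch) or a "$k" suffix (marks the whole subtree). Marked
#' classes are named "foreground" when k = 1 and "class<k>" otherwise;
#' unmarked edges are "background". A sidecar two-column TSV
#' (node label -> class) can be supplied instead of inline marks.
#'
#' @param newick path to a Newick file, or a Newick string.
#' @param branchClassFile optional TSV with columns \code{label} and
#'   \code{class}; a label marks the edge above that tip/node, and internal
#'   labels mark their whole subtree.
#' @return a [GeneTree-class].
#' @export
readGeneTree <- function(newick, branchClassFile = NULL) {
  txt <- if (file.exists(newick)) paste(readLines(newick), collapse = "") else newick
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick input")
  geneTree(tr, branchClassFile = branchClassFile)
}

#' Construct a GeneTree from an ape phylo
#'
#' @param tree an [ape::phylo]; labels may carry "#k"/"$k" marks.
#' @param foreground optional character vector of tip labels: the edges of
#'   the smallest clade containing them (or the terminal edges themselves,
#'   when \code{foregroundMode = "branch"}) are labeled "foreground".
#' @param foregroundMode "clade" (all edges of the spanned clade) or
#'   "branch" (only the listed terminal branches).
#' @param branchClassFile optional sidecar TSV, see [readGeneTree()].
#' @return a [GeneTree-class].
#' @export
geneTree <- function(tree, foreground = NULL,
                     foregroundMode = c("clade", "branch"),
                     branchClassFile = NULL) {
  foregroundMode <- match.arg(foregroundMode)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  cls <- rep("background", nrow(tree$edge))

  labelOf <- function(node) {
    if (node <= ntip) tree$tip.label[node]
    else if (!is.null(tree$node.label)) tree$node.label[node - ntip]
    else NA_character_
  }
  markFrom <- function(lbl) {
    m <- regmatches(lbl, regexec("([#$])(\\w+)\\s*$", lbl))[[1]]
    if (length(m) == 0L) NULL else m
  }
  className <- function(k) if (k == "1") "foreground" else paste0("class", k)

  ## inline marks
  allNodes <- seq_len(ntip + tree$Nnode)
  stripped <- FALSE
  for (node in allNodes) {
    lbl <- labelOf(node)
    if (is.na(lbl) || !nzchar(lbl)) next
    m <- markFrom(lbl)
    if (is.null(m)) next
    stripped <- TRUE
    base <- sub("([#$])(\\w+)\\s*$", "", lbl)
    if (node <= ntip) tree$tip.label[node] <- base
    else tree$node.label[node - ntip] <- base
    if (m[2] == "#") {
      cls[tree$edge[, 2] == node] <- className(m[3])
    } else {
      desc <- .subtreeEdges(tree, node)
      cls[desc] <- className(m[3])
    }
  }

  ## sidecar map
  if (!is.null(branchClassFile)) {
    map <- read.table(branchClassFile, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (!all(c("label", "class") %in% names(map)))
      stop("branch class file needs columns 'label' and 'class'")
    for (i in seq_len(nrow(map))) {
      lbl <- map$label[i]
      node <- if (lbl %in% tree$tip.label) match(lbl, tree$tip.label)
              else if (!is.null(tree$node.label) && lbl %in% tree$node.label)
                ntip + match(lbl, tree$node.label)
              else stop("branch class label '", lbl, "' not found in tree")
      if (node <= ntip) cls[tree$edge[, 2] == node] <- map$class[i]
      else cls[.subtreeEdges(tree, node)] <- map$class[i]
    }
  }

  ## explicit foreground tips
  if (!is.null(foreground)) {
    miss <- setdiff(foreground, tree$tip.label)
    if (length(miss)) stop("foreground tips not in tree: ",
                           paste(miss, collapse = ", "))
    tips <- match(foreground, tree$tip.label)
    if (foregroundMode == "branch" || length(tips) == 1L) {
      cls[tree$edge[, 2] %in% tips] <- "foreground"
    } else {
      mrca <- ape::getMRCA(tree, tips)
      cls[.subtreeEdges(tree, mrca)] <- "foreground"
    }
  }
  new("GeneTree", tree = tree, branchClass = cls)
}

## edges (rows of tree$edge) inside the clade rooted at `node`, including the
## edge leading to `node` itself
.subtreeEdges <- function(tree, node) {
  edges <- integer(0)
  stack <- node
  lead <- which(tree$edge[, 2] == node)
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- which(tree$edge[, 1] == nd)
    edges <- c(edges, kids)
    stack <- c(stack, tree$edge[kids, 2])
  }
  c(lead, edges)
}

#' Write a GeneTree as Newick with codeml-style marks
#' @param x a [GeneTree-class].
#' @param path output path; when NULL the Newick string is returned.
#' @export
writeGeneTree <- function(x, path = NULL) {
  tr <- x@tree
  cls <- x@branchClass
  marked <- which(cls != "background")
  for (e in marked) {
    node <- tr$edge[e, 2]
    k <- if (cls[e] == "foreground") "1" else sub("^class", "", cls[e])
    tag <- paste0("#", k)
    if (node <= length(tr$tip.label)) {
      if (!endsWith(tr$tip.label[node], tag))
        tr$tip.label[node] <- paste0(tr$tip.label[node], tag)
    } else {
      if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
      i <- node - length(tr$tip.label)
      if (!endsWith(tr$node.label[i], tag))
        tr$node.label[i] <- paste0(tr$node.label[i], tag)
    }
  }
  txt <- ape::write.tree(tr)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

## ---- gene loci ------------------------------------------------------------

#' Read gene loci from a 6-column BED file
#'
#' Genes are ranked along each chromosome by start coordinate to produce
#' \code{order_index}.
#'
#' @param path BED file (chrom, start, end, name, score, strand).
#' @return data.frame (gene_id, chrom, start, end, strand, order_index).
#' @export
readGeneLociBed <- function(path) {
  bed <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("need 6-column BED (chrom start end name score strand)")
  df <- data.frame(gene_id = bed[[4]], chrom = bed[[1]],
                   start = bed[[2]], end = bed[[3]], strand = bed[[6]],
                   stringsAsFactors = FALSE)
  .rankLoci(df)
}

#' Read gene loci from a GFF3 file
#'
#' Uses rtracklayer when available; keeps \code{type == "gene"} records and
#' takes the gene id from the ID attribute.
#'
#' @param path GFF3 file.
#' @return data.frame as in [readGeneLociBed()].
#' @export
readGeneLociGff <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- rtracklayer::readGFF(path)
    g <- g[g$type == "gene", , drop = FALSE]
    df <- data.frame(gene_id = as.character(g$ID), chrom = as.character(g$seqid),
                     start = g$start, end = g$end, strand = as.character(g$strand),
                     stringsAsFactors = FALSE)
  } else {
    raw <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      quote = "", stringsAsFactors = FALSE)
    raw <- raw[raw[[3]] == "gene", , drop = FALSE]
    id <- sub(".*ID=([^;]+).*", "\\1", raw[[9]])
    df <- data.frame(gene_id = id, chrom = raw[[1]], start = raw[[4]],
                     end = raw[[5]], strand = raw[[7]], stringsAsFactors = FALSE)
  }
  .rankLoci(df)
}

.rankLoci <- function(df) {
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in locus table")
  df$order_index <- NA_integer_
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    df$order_index[i] <- rank(df$start[i], ties.method = "first")
  }
  df[order(df$chrom, df$order_index), , drop = FALSE]
}
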