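## Screening logic over externally produced similarity-search tables:
## HMMER domain-hit filtering, CD-HIT-style redundancy clustering, and the
## reverse-best-hit orthology rule.

#' Read an HMMER domtblout table
#'
#' @param path hmmsearch \code{--domtblout} output.
#' @return data.frame with columns target_id, target_len, query_domain,
#'   hmm_length, seq_evalue, dom_cevalue, dom_ievalue, hmm_from, hmm_to,
#'   env_from, env_to.
#' @export
readDomtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(target_id = character(), target_len = integer(),
                      query_domain = character(), hmm_length = integer(),
                      seq_evalue = numeric(), dom_cevalue = numeric(),
                      dom_ievalue = numeric(), hmm_from = integer(),
                      hmm_to = integer(), env_from = integer(),
                      env_to = integer(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\\s+")
  get <- function(i, fn) fn(vapply(f, `[[`, "", i))
  data.frame(
    target_id = get(1, as.character), target_len = get(3, as.integer),
    query_domain = get(4, as.character), hmm_length = get(6, as.integer),
    seq_evalue = get(7, as.numeric), dom_cevalue = get(12, as.numeric),
    dom_ievalue = get(13, as.numeric), hmm_from = get(16, as.integer),
    hmm_to = get(17, as.integer), env_from = get(20, as.integer),
    env_to = get(21, as.integer), stringsAsFactors = FALSE)
}

#' Read a BLAST tabular (outfmt 6) file
#'
#' Standard 12 columns: qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore.
#'
#' @param path BLAST \code{-outfmt 6} output.
#' @return data.frame with those columns as query_id, subject_id, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @export
readBlastTab <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected 12-column BLAST outfmt 6")
  tab <- tab[, 1:12]
  names(tab) <- cols
  tab
}

#' Filter domain hits on E-values and HMM coverage
#'
#' Keeps hits with sequence E-value and per-domain E-value at or below the
#' thresholds and HMM-model coverage at or above \code{minCoverage}
#' (all thresholds inclusive). Coverage is
#' \code{(hmm_to - hmm_from + 1) / hmm_length} for the best single domain,
#' or the union of a target's HMM spans when \code{merge = "summed"}.
#'
#' @param hits data.frame from [readDomtblout()].
#' @param seqEMax,domEMax E-value thresholds (default 1e-2 each).
#' @param minCoverage minimum fraction of the HMM covered (default 0.5).
#' @param domEvalueKind which per-domain E-value column to test:
#'   "conditional" (default) or "independent".
#' @param merge "best" (default): each domain row stands alone; "summed":
#'   coverage is computed from the union of all passing rows of a target and
#'   all rows of a covered target are kept.
#' @return the filtered data.frame, input order preserved.
#' @export
filterDomainHits <- function(hits, seqEMax = 1e-2, domEMax = 1e-2,
                             minCoverage = 0.5,
                             domEvalueKind = c("conditional", "independent"),
                             merge = c("best", "summed")) {
  domEvalueKind <- match.arg(domEvalueKind)
  merge <- match.arg(merge)
  if (!nrow(hits)) return(hits)
  if (any(hits$hmm_length <= 0)) stop("non-positive hmm_length")
  if (any(hits$hmm_from > hits$hmm_to) || any(hits$hmm_from < 1) ||
      any(hits$hmm_to > hits$hmm_length))
    stop("malformed HMM coordinates")
  domE <- if (domEvalueKind == "conditional") hits$dom_cevalue else hits$dom_ievalue
  passE <- hits$seq_evalue <= seqEMax & domE <= domEMax
  if (merge == "best") {
    cov <- (hits$hmm_to - hits$hmm_from + 1) / hits$hmm_length
    keep <- passE & cov >= minCoverage
  } else {
    keep <- logical(nrow(hits))
    for (tg in unique(hits$target_id[passE])) {
      rows <- which(hits$target_id == tg & passE)
      iv <- cbind(hits$hmm_from[rows], hits$hmm_to[rows])
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      covered <- 0L; curS <- iv[1, 1]; curE <- iv[1, 2]
      if (nrow(iv) > 1L) for (r in 2:nrow(iv)) {
        if (iv[r, 1] <= curE + 1L) curE <- max(curE, iv[r, 2])
        else { covered <- covered + curE - curS + 1L; curS <- iv[r, 1]; curE <- iv[r, 2] }
      }
      covered <- covered + curE - curS + 1L
      if (covered / hits$hmm_length[rows[1]] >= minCoverage) keep[rows] <- TRUE
    }
  }
  hits[keep, , drop = FALSE]
}

## uniform hit ordering: bitscore desc, then e-value asc, then subject id
.rankHits <- function(tab) {
  tab[order(-tab$bitscore, tab$evalue, tab$subject_id), , drop = FALSE]
}

#' Greedy incremental redundancy clustering (CD-HIT semantics)
#'
#' Sequences are sorted by length descending (ties by id); each sequence
#' joins the best-matching existing representative whose local-alignment
#' identity is at least \code{identityMin} with aligned coverage of the
#' shorter sequence at least \code{shortCoverageMin}, else founds a new
#' cluster. Identity is matches / local-alignment columns; the representative
#' is the longest (first) member.
#'
#' @param seqs named AAStringSet or character vector of protein sequences.
#' @param identityMin minimum local identity (default 0.95).
#' @param shortCoverageMin minimum aligned fraction of the shorter sequence
#'   (default 0.6).
#' @return data.frame (representative_id, member_id).
#' @export
clusterRedundantSequences <- function(seqs, identityMin = 0.95,
                                      shortCoverageMin = 0.6) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  if (length(seqs) < 1L) stop("empty input")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  ord <- order(-Biostrings::width(seqs), names(seqs))
  seqs <- seqs[ord]
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  reps <- integer(0)                       # indices into seqs
  assignment <- integer(length(seqs))
  len <- Biostrings::width(seqs)
  for (i in seq_along(seqs)) {
    bestRep <- 0L; bestIdent <- -1
    for (r in reps) {
      aln <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[r]],
                                           type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 10, gapExtension = 0.5)
      ncolAln <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (ncolAln == 0L) next
      ident <- Biostrings::nmatch(aln) / ncolAln
      shortLen <- min(len[i], len[r])
      spanShort <- if (len[i] <= len[r])
        Biostrings::width(Biostrings::pattern(aln)) else
        Biostrings::width(Biostrings::subject(aln))
      if (ident >= identityMin && spanShort / shortLen >= shortCoverageMin &&
          ident > bestIdent) {
        bestIdent <- ident; bestRep <- r
      }
    }
    if (bestRep > 0L) assignment[i] <- bestRep
    else { reps <- c(reps, i); assignment[i] <- i }
  }
  data.frame(representative_id = names(seqs)[assignment],
             member_id = names(seqs), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Assign putative orthologs by the reverse-best-hit rule
#'
#' A forward hit (any rank) is accepted when its reverse best hit against the
#' query proteome is the query itself. The forward hit is deliberately not
#' required to rank first.
#'
#' @param queryId the query protein id.
#' @param forwardHits data.frame of BLAST hits for the query (columns
#'   query_id, subject_id, evalue, bitscore).
#' @param reverseHits either a single data.frame of all reverse hits (each
#'   candidate subject as query_id against the query proteome) or a named
#'   list of per-subject data.frames.
#' @param eMax E-value threshold applied to both directions (default 1e-3).
#' @return character vector of accepted ortholog subject ids (sorted).
#' @export
assignOrthologs <- function(queryId, forwardHits, reverseHits, eMax = 1e-3) {
  fw <- forwardHits[forwardHits$query_id == queryId & forwardHits$evalue <= eMax, ,
                    drop = FALSE]
  if (!nrow(fw)) return(character(0))
  candidates <- unique(fw$subject_id)
  revTab <- function(subj) {
    if (is.data.frame(reverseHits)) {
      reverseHits[reverseHits$query_id == subj, , drop = FALSE]
    } else {
      if (is.null(reverseHits[[subj]]))
        stop("missing reverse hit table for candidate '", subj, "'")
      reverseHits[[subj]]
    }
  }
  accepted <- character(0)
  for (subj in candidates) {
    rv <- revTab(subj)
    if (is.data.frame(reverseHits) && !nrow(rv))
      stop("missing reverse hit table for candidate '", subj, "'")
    rv <- rv[rv$evalue <= eMax, , drop = FALSE]
    if (!nrow(rv)) next
    best <- .rankHits(rv)$subject_id[1]
    if (best == queryId) accepted <- c(accepted, subj)
  }
  sort(accepted)
}
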