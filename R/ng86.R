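## Nei-Gojobori (1986) pairwise dN/dS with equal pathway weighting,
## stop-codon-avoiding pathways and Jukes-Cantor correction; clade- and
## domain-level summaries.

.ohnoCache <- new.env(parent = emptyenv())

#' Synonymous/nonsynonymous site counts of one codon
#'
#' For each codon position, the fraction of the single-nucleotide changes
#' that are synonymous is computed after excluding changes to stop codons
#' and renormalizing over the remaining (non-stop) changes; the
#' nonsynonymous fraction is its complement. S and N are the sums over the
#' three positions.
#'
#' @param codon a 3-letter sense codon.
#' @param code genetic-code table from [geneticCode()].
#' @return named numeric c(S = ..., N = ...).
#' @export
ng86CodonSites <- function(codon, code = geneticCode()) {
  aa <- code[codon]
  if (is.na(aa)) stop("ambiguous or unknown codon: ", codon)
  if (aa == "*") stop("stop codon has no site decomposition: ", codon)
  S <- 0
  nPos <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    syn <- 0L; nonstop <- 0L
    for (nt in setdiff(.NUC, base)) {
      nb <- codon
      substr(nb, pos, pos) <- nt
      aan <- code[nb]
      if (aan == "*") next
      nonstop <- nonstop + 1L
      if (aan == aa) syn <- syn + 1L
    }
    if (nonstop > 0L) {
      S <- S + syn / nonstop
      nPos <- nPos + 1
    }
  }
  c(S = S, N = nPos - S)
}

## per-code lookup tables, memoized
.ng86Tables <- function(codeId) {
  key <- paste0("ng86_", codeId)
  if (!is.null(.ohnoCache[[key]])) return(.ohnoCache[[key]])
  code <- geneticCode(codeId)
  sense <- senseCodons(code)
  ns <- length(sense)
  sites <- t(vapply(sense, ng86CodonSites, c(S = 0, N = 0), code = code))

  ## pairwise difference counts (Sd, Nd) averaged over stop-avoiding
  ## mutational pathways
  classifyStep <- function(from, to) {
    if (code[from] == code[to]) c(1, 0) else c(0, 1)
  }
  pathCounts <- function(a, b) {
    diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    k <- length(diffs)
    if (k == 0L) return(c(0, 0))
    if (k == 1L) return(classifyStep(a, b))
    perms <- .permutations(diffs)
    paths <- matrix(NA_real_, nrow(perms), 2)
    ok <- logical(nrow(perms))
    for (p in seq_len(nrow(perms))) {
      cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
      for (pos in perms[p, ]) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(b, pos, pos)
        if (code[nxt] == "*") { blocked <- TRUE; break }
        st <- classifyStep(cur, nxt)
        sd <- sd + st[1]; nd <- nd + st[2]
        cur <- nxt
      }
      if (!blocked) { paths[p, ] <- c(sd, nd); ok[p] <- TRUE }
    }
    if (!any(ok)) {
      ## all pathways pass through a stop: fall back to equal weighting over
      ## all pathways, counting stop-passing steps by their amino acid change
      for (p in seq_len(nrow(perms))) {
        cur <- a; sd <- 0; nd <- 0
        for (pos in perms[p, ]) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(b, pos, pos)
          st <- if (code[cur] == code[nxt]) c(1, 0) else c(0, 1)
          sd <- sd + st[1]; nd <- nd + st[2]
          cur <- nxt
        }
        paths[p, ] <- c(sd, nd); ok[p] <- TRUE
      }
    }
    colMeans(paths[ok, , drop = FALSE])
  }
  Sd <- matrix(0, ns, ns, dimnames = list(sense, sense))
  Nd <- Sd
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i < j) {
      pc <- pathCounts(sense[i], sense[j])
      Sd[i, j] <- Sd[j, i] <- pc[1]
      Nd[i, j] <- Nd[j, i] <- pc[2]
    }
  }
  tabs <- list(sense = sense, sites = sites, Sd = Sd, Nd = Nd)
  .ohnoCache[[key]] <- tabs
  tabs
}

.permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

#' NG86 pairwise dN/dS between two codon sequences
#'
#' Codons containing gaps or ambiguity in either sequence are pairwise
#' deleted. Site counts are averaged over the two sequences; difference
#' counts average equally over all shortest mutational pathways that avoid
#' stop codons. Proportions receive the Jukes-Cantor correction
#' \code{d = -3/4 log(1 - 4/3 p)}; p >= 3/4 yields a flagged undefined
#' distance.
#'
#' @param a,b codon sequences (character strings, equal length, in frame).
#' @param codeId NCBI genetic-code id.
#' @return list with Sd, Nd, S_bar, N_bar, pS, pN, dS, dN, omega,
#'   n_codons_used, dS_defined, dN_defined. omega is NA when dS is 0 or
#'   undefined.
#' @export
ng86Pairwise <- function(a, b, codeId = "1") {
  ca <- .splitCodons(toupper(a))
  cb <- .splitCodons(toupper(b))
  if (length(ca) != length(cb)) stop("length mismatch between sequences")
  tabs <- .ng86Tables(codeId)
  usable <- !(ca == "---" | cb == "---" |
              .isAmbiguousCodon(ca) | .isAmbiguousCodon(cb))
  usable <- usable & ca %in% tabs$sense & cb %in% tabs$sense
  ca <- ca[usable]; cb <- cb[usable]
  n <- length(ca)
  if (n == 0L)
    return(list(Sd = 0, Nd = 0, S_bar = 0, N_bar = 0, pS = NA_real_,
                pN = NA_real_, dS = NA_real_, dN = NA_real_, omega = NA_real_,
                n_codons_used = 0L, dS_defined = FALSE, dN_defined = FALSE))
  Sa <- sum(tabs$sites[ca, "S"]); Na <- sum(tabs$sites[ca, "N"])
  Sb <- sum(tabs$sites[cb, "S"]); Nb <- sum(tabs$sites[cb, "N"])
  S_bar <- (Sa + Sb) / 2; N_bar <- (Na + Nb) / 2
  idx <- cbind(match(ca, tabs$sense), match(cb, tabs$sense))
  Sd <- sum(tabs$Sd[idx]); Nd <- sum(tabs$Nd[idx])
  pS <- if (S_bar > 0) Sd / S_bar else NA_real_
  pN <- if (N_bar > 0) Nd / N_bar else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(c(NA_real_, FALSE))
    if (p >= 0.75) return(c(NA_real_, FALSE))
    c(-0.75 * log(1 - 4 * p / 3), TRUE)
  }
  s <- jc(pS); nn <- jc(pN)
  dS <- s[1]; dN <- nn[1]
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  list(Sd = Sd, Nd = Nd, S_bar = S_bar, N_bar = N_bar, pS = pS, pN = pN,
       dS = dS, dN = dN, omega = omega, n_codons_used = n,
       dS_defined = as.logical(s[2]), dN_defined = as.logical(nn[2]))
}

#' Clade-level dN/dS summaries, optionally per domain partition
#'
#' Computes [ng86Pairwise()] for all unordered within-clade pairs, over the
#' full alignment and each domain partition, and reports mean dN, mean dS
#' and omega. Pairs with an undefined distance are excluded from the
#' affected average and counted.
#'
#' @param codonAln a [CodonAlignment-class].
#' @param cladeMembers named list: clade name -> character vector of
#'   sequence ids.
#' @param partitions optional data.frame of [domainPartition()] rows
#'   (columns name, start, end).
#' @param referenceId reference sequence id for mapping partition residue
#'   ranges (required when partitions are given).
#' @param omegaMode "ratio_of_means" (default): omega = mean dN / mean dS;
#'   "mean_of_ratios": mean of per-pair omega values.
#' @return data.frame (clade, partition, mean_dN, mean_dS, omega, n_pairs,
#'   n_undefined); partition "full" covers the whole alignment.
#' @export
cladeRateSummary <- function(codonAln, cladeMembers, partitions = NULL,
                             referenceId = NULL,
                             omegaMode = c("ratio_of_means", "mean_of_ratios")) {
  omegaMode <- match.arg(omegaMode)
  alns <- list(full = codonAln)
  if (!is.null(partitions)) {
    if (is.null(referenceId))
      stop("referenceId is required when partitions are given")
    .checkPartitionScheme(partitions)
    for (i in seq_len(nrow(partitions)))
      alns[[partitions$name[i]]] <-
        mapResidueRanges(codonAln, partitions[i, , drop = FALSE], referenceId)
  }
  rows <- list()
  for (clade in names(cladeMembers)) {
    ids <- cladeMembers[[clade]]
    for (part in names(alns)) {
      seqs <- as.character(alignedSeqs(alns[[part]]))
      present <- intersect(ids, names(seqs))
      if (length(present) < 2L)
        stop("clade '", clade, "' has fewer than 2 usable members")
      prs <- utils::combn(present, 2)
      dN <- dS <- om <- numeric(ncol(prs))
      for (k in seq_len(ncol(prs))) {
        r <- ng86Pairwise(seqs[[prs[1, k]]], seqs[[prs[2, k]]],
                          geneticCodeId(codonAln))
        dN[k] <- r$dN; dS[k] <- r$dS; om[k] <- r$omega
      }
      meanDN <- mean(dN, na.rm = TRUE)
      meanDS <- mean(dS, na.rm = TRUE)
      omega <- if (omegaMode == "ratio_of_means") {
        if (is.finite(meanDS) && meanDS > 0) meanDN / meanDS else NA_real_
      } else mean(om, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        clade = clade, partition = part, mean_dN = meanDN, mean_dS = meanDS,
        omega = omega, n_pairs = ncol(prs),
        n_undefined = sum(is.na(dN) | is.na(dS)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
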