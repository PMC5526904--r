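## Goldman-Yang (1994) codon substitution model: equilibrium frequencies,
## generator construction, and the structural tables shared with the
## simulator.

## per-code structural tables over sense codons: single-nt neighbor mask,
## transition mask, synonymous mask
.gy94Structure <- function(codeId) {
  key <- paste0("gy94_", codeId)
  if (!is.null(.ohnoCache[[key]])) return(.ohnoCache[[key]])
  code <- geneticCode(codeId)
  sense <- senseCodons(code)
  ns <- length(sense)
  chars <- do.call(rbind, strsplit(sense, ""))
  single <- matrix(FALSE, ns, ns); transit <- single; synon <- single
  isTs <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
                          (x == "C" & y == "T") | (x == "T" & y == "C")
  for (i in seq_len(ns)) {
    di <- chars[rep(i, ns), , drop = FALSE] != chars
    ndiff <- rowSums(di)
    nb <- which(ndiff == 1L)
    single[i, nb] <- TRUE
    for (j in nb) {
      pos <- which(di[j, ])
      transit[i, j] <- isTs(chars[i, pos], chars[j, pos])
      synon[i, j] <- code[sense[i]] == code[sense[j]]
    }
  }
  out <- list(sense = sense, single = single, transition = transit,
              synonymous = synon)
  .ohnoCache[[key]] <- out
  out
}

#' Estimate sense-codon equilibrium frequencies from a codon alignment
#'
#' @param x a [CodonAlignment-class].
#' @param mode "F3x4" (position-specific nucleotide frequencies, codeml
#'   convention; default), "F1x4", "F61" (observed codon frequencies) or
#'   "uniform".
#' @return named numeric vector over the sense codons, summing to 1; a small
#'   floor keeps every frequency positive.
#' @export
codonFrequencies <- function(x, mode = c("F3x4", "F1x4", "F61", "uniform")) {
  mode <- match.arg(mode)
  code <- geneticCode(geneticCodeId(x))
  sense <- senseCodons(code)
  if (mode == "uniform")
    return(setNames(rep(1 / length(sense), length(sense)), sense))
  codons <- unlist(lapply(as.character(alignedSeqs(x)), .splitCodons))
  codons <- codons[codons != "---" & !.isAmbiguousCodon(codons)]
  pi <- switch(mode,
    F61 = {
      cnt <- table(factor(codons, levels = sense))
      as.numeric(cnt)
    },
    F3x4 = {
      m <- do.call(rbind, strsplit(codons, ""))
      f <- vapply(1:3, function(p)
        as.numeric(table(factor(m[, p], levels = .NUC))), numeric(4))
      f <- sweep(f, 2, colSums(f), "/")
      ch <- do.call(rbind, strsplit(sense, ""))
      f[cbind(match(ch[, 1], .NUC), 1)] *
        f[cbind(match(ch[, 2], .NUC), 2)] *
        f[cbind(match(ch[, 3], .NUC), 3)]
    },
    F1x4 = {
      nt <- unlist(strsplit(codons, ""))
      f <- as.numeric(table(factor(nt, levels = .NUC)))
      f <- f / sum(f)
      ch <- do.call(rbind, strsplit(sense, ""))
      f[match(ch[, 1], .NUC)] * f[match(ch[, 2], .NUC)] * f[match(ch[, 3], .NUC)]
    })
  pi <- pi + 1e-8 * sum(pi)          # keep strictly positive
  setNames(pi / sum(pi), sense)
}

#' Build a GY94 codon rate matrix
#'
#' \code{q_ij = 0} for multi-nucleotide changes; otherwise proportional to
#' the target frequency \code{pi_j}, multiplied by \code{kappa} for
#' transitions and \code{omega} for nonsynonymous changes. Rows sum to zero.
#'
#' @param pi sense-codon frequencies (named, summing to 1).
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param codeId NCBI genetic-code id.
#' @param scale when TRUE (default) the matrix is scaled so the expected
#'   number of substitutions per codon per unit time is 1 at equilibrium;
#'   mixture models rescale externally at the site-class mixture instead.
#' @return 61 x 61 generator matrix over the sense codons.
#' @export
buildGY94Matrix <- function(pi, kappa, omega, codeId = "1", scale = TRUE) {
  st <- .gy94Structure(codeId)
  if (length(pi) != length(st$sense)) stop("pi must cover all sense codons")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-6) stop("invalid frequencies")
  pi <- pi[st$sense]
  Q <- matrix(0, length(pi), length(pi), dimnames = list(st$sense, st$sense))
  Q[st$single] <- rep(pi, each = length(pi))[st$single]
  Q[st$single & st$transition] <- Q[st$single & st$transition] * kappa
  Q[st$single & !st$synonymous] <- Q[st$single & !st$synonymous] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    r <- -sum(pi * diag(Q))
    if (r > 0) Q <- Q / r
  }
  Q
}

## expected substitution rate of an (unscaled) generator at equilibrium
.qRate <- function(Q, pi) -sum(pi * diag(Q))

## eigendecomposition of a reversible generator via symmetrization;
## returns closure P(t)
.qEigen <- function(Q, pi) {
  d <- sqrt(pi)
  A <- Q * (d %o% (1 / d))            # diag(d) Q diag(1/d), symmetric
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  U <- e$vectors
  lam <- e$values
  left <- (1 / d) * U                 # diag(1/d) U
  right <- t(U) * rep(d, each = ncol(U))  # t(U) diag(d)
  function(t) {
    P <- left %*% (exp(lam * t) * right)
    P[P < 0] <- 0
    P
  }
}
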