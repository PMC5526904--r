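#' CodonAlignment: aligned in-frame coding sequences
#'
#' A multiple alignment of coding sequences in which gaps occur in whole
#' codons, every non-gap unambiguous codon is a sense codon, and the
#' alignment width is divisible by three. This is the substrate of all
#' dN/dS computation.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of equal-width aligned sequences.
#' @slot geneticCodeId NCBI genetic-code id (default "1").
#' @export
setClass("CodonAlignment",
  representation(seqs = "DNAStringSet", geneticCodeId = "character"),
  prototype(geneticCodeId = "1")
)

setValidity("CodonAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment must contain at least one sequence")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) return("all rows must have equal length")
  if (w[1] %% 3L != 0L) return("alignment width must be divisible by 3")
  nm <- names(s)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    return("sequence ids must be non-empty and unique")
  code <- geneticCode(object@geneticCodeId)
  chars <- as.character(s)
  for (i in seq_along(chars)) {
    codons <- .splitCodons(chars[i])
    bad <- grepl("-", codons, fixed = TRUE) & codons != "---"
    if (any(bad))
      return(sprintf("sequence '%s': gaps must occur in whole-codon units", nm[i]))
    plain <- codons[codons != "---" & !.isAmbiguousCodon(codons)]
    if (any(code[plain] == "*"))
      return(sprintf("sequence '%s': internal stop codon", nm[i]))
  }
  TRUE
})

#' Construct a CodonAlignment
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector of
#'   equal-length aligned coding sequences (gaps as "-").
#' @param geneticCodeId NCBI genetic-code id.
#' @return a [CodonAlignment-class] object.
#' @export
codonAlignment <- function(seqs, geneticCodeId = "1") {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  new("CodonAlignment", seqs = seqs, geneticCodeId = as.character(geneticCodeId))
}

#' GeneTree: a phylogeny with branch class labels
#'
#' Wraps an [ape::phylo] tree and a per-edge class label used by branch,
#' clade and branch-site codon models ("background" everywhere by default;
#' codeml-style "#1" / "$1" suffixes on labels mark foreground branches or
#' clades).
#'
#' @slot tree an [ape::phylo] object.
#' @slot branchClass character vector, one label per edge (row of
#'   \code{tree$edge}).
#' @export
setClass("GeneTree",
  representation(tree = "ANY", branchClass = "character")
)

setValidity("GeneTree", function(object) {
  tr <- object@tree
  if (!inherits(tr, "phylo")) return("tree must be an ape 'phylo' object")
  if (anyDuplicated(tr$tip.label)) return("leaf names must be unique")
  if (length(object@branchClass) != nrow(tr$edge))
    return("branchClass must have one entry per edge")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    return("branch lengths must be >= 0")
  TRUE
})

#' SyntenyBlockSet: detected runs of anchored paralog pairs
#'
#' @slot blocks data.frame with one row per block (block_id, orientation,
#'   n_pairs, span_a, span_b).
#' @slot pairs data.frame with one row per anchored pair in a block
#'   (block_id, gene_a, rank_a, gene_b, rank_b, family_id).
#' @export
setClass("SyntenyBlockSet",
  representation(blocks = "data.frame", pairs = "data.frame")
)

#' CodonFitResult: a fitted codon substitution model
#'
#' @slot family model family ("M0", "branch2", "M1a", "M2a_rel", "CmC",
#'   "branchsiteA").
#' @slot lnL maximized log-likelihood.
#' @slot estimates named list of ML parameter estimates (kappa, omegas,
#'   site-class proportions, branch lengths).
#' @slot nFreeParams number of free parameters.
#' @slot starts data.frame recording every optimization start and its final
#'   lnL and convergence code.
#' @slot spec internal fitted model specification.
#' @export
setClass("CodonFitResult",
  representation(family = "character", lnL = "numeric", estimates = "list",
                 nFreeParams = "numeric", starts = "data.frame", spec = "list")
)

#' DivergenceResult: type-I functional divergence between paralog clusters
#'
#' @slot theta ML estimate of the divergence coefficient in [0, 1].
#' @slot se bootstrap standard error of theta.
#' @slot lrtStat likelihood-ratio statistic for theta = 0.
#' @slot pValue chi-square (1 df) p-value.
#' @slot posteriors per-column posterior probability of rate divergence.
#' @slot cutoff posterior cutoff from the iterative selection (NA until
#'   [selectDivergentSites()] is run, or when the fit is not significant).
#' @slot selectedSites alignment column indices above the cutoff.
#' @slot data internal per-column change counts and model parameters, kept so
#'   the fit can be recomputed on column subsets.
#' @export
setClass("DivergenceResult",
  representation(theta = "numeric", se = "numeric", lrtStat = "numeric",
                 pValue = "numeric", posteriors = "numeric", cutoff = "numeric",
                 selectedSites = "integer", data = "list")
)
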