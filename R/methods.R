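## Accessors and show methods.

#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))
#' Aligned sequences of a CodonAlignment
#' @param x a [CodonAlignment-class].
#' @return a [Biostrings::DNAStringSet].
#' @export
#' @describeIn CodonAlignment aligned sequences
setMethod("alignedSeqs", "CodonAlignment", function(x) x@seqs)

#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))
#' @describeIn CodonAlignment number of codon columns
#' @param x a CodonAlignment
#' @export
setMethod("nCodons", "CodonAlignment", function(x)
  Biostrings::width(x@seqs)[1] %/% 3L)

#' @export
setGeneric("geneticCodeId", function(x) standardGeneric("geneticCodeId"))
#' @describeIn CodonAlignment genetic-code id
#' @export
setMethod("geneticCodeId", "CodonAlignment", function(x) x@geneticCodeId)

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d sequences x %d codons (genetic code %s)\n",
              length(object@seqs), nCodons(object), object@geneticCodeId))
})

setMethod("show", "GeneTree", function(object) {
  cls <- table(object@branchClass)
  cat(sprintf("GeneTree: %d tips, %d edges; branch classes: %s\n",
              length(object@tree$tip.label), nrow(object@tree$edge),
              paste(sprintf("%s (%d)", names(cls), cls), collapse = ", ")))
})

#' @export
setGeneric("treePhylo", function(x) standardGeneric("treePhylo"))
#' @describeIn GeneTree underlying ape phylo object
#' @param x a GeneTree
#' @export
setMethod("treePhylo", "GeneTree", function(x) x@tree)

#' @export
setGeneric("branchClasses", function(x) standardGeneric("branchClasses"))
#' @describeIn GeneTree per-edge class labels
#' @export
setMethod("branchClasses", "GeneTree", function(x) x@branchClass)

setMethod("show", "SyntenyBlockSet", function(object) {
  b <- object@blocks
  cat(sprintf("SyntenyBlockSet: %d blocks (%d direct, %d inverted), %d anchored pairs\n",
              nrow(b), sum(b$orientation == "direct"),
              sum(b$orientation == "inverted"), nrow(object@pairs)))
})

#' @export
setGeneric("syntenyBlocks", function(x) standardGeneric("syntenyBlocks"))
#' @describeIn SyntenyBlockSet one row per detected block
#' @param x a SyntenyBlockSet
#' @export
setMethod("syntenyBlocks", "SyntenyBlockSet", function(x) x@blocks)

#' @export
setGeneric("syntenyPairs", function(x) standardGeneric("syntenyPairs"))
#' @describeIn SyntenyBlockSet one row per anchored pair within blocks
#' @export
setMethod("syntenyPairs", "SyntenyBlockSet", function(x) x@pairs)

setMethod("show", "CodonFitResult", function(object) {
  cat(sprintf("CodonFitResult: family %s, lnL = %.4f, %d free parameters\n",
              object@family, object@lnL, object@nFreeParams))
  om <- object@estimates[grepl("^omega", names(object@estimates))]
  if (length(om))
    cat("  ", paste(sprintf("%s = %.4g", names(om), unlist(om)), collapse = ", "), "\n")
})

#' @export
setGeneric("logLik2", function(x) standardGeneric("logLik2"))
#' @describeIn CodonFitResult maximized log-likelihood
#' @param x a CodonFitResult
#' @export
setMethod("logLik2", "CodonFitResult", function(x) x@lnL)

#' @export
setGeneric("mlEstimates", function(x) standardGeneric("mlEstimates"))
#' @describeIn CodonFitResult named list of ML estimates
#' @export
setMethod("mlEstimates", "CodonFitResult", function(x) x@estimates)

setMethod("show", "DivergenceResult", function(object) {
  cat(sprintf("DivergenceResult: theta = %.3f (SE %.3f), LRT = %.3f, p = %.3g\n",
              object@theta, object@se, object@lrtStat, object@pValue))
  if (!is.na(object@cutoff))
    cat(sprintf("  %d sites selected at posterior cutoff %.3f\n",
                length(object@selectedSites), object@cutoff))
})

#' @export
setGeneric("divergenceTheta", function(x) standardGeneric("divergenceTheta"))
#' @describeIn DivergenceResult estimated divergence coefficient
#' @param x a DivergenceResult
#' @export
setMethod("divergenceTheta", "DivergenceResult", function(x) x@theta)

#' @export
setGeneric("sitePosteriors", function(x) standardGeneric("sitePosteriors"))
#' @describeIn DivergenceResult per-column posterior probabilities
#' @export
setMethod("sitePosteriors", "DivergenceResult", function(x) x@posteriors)
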