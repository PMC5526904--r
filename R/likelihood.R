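## Phylogenetic likelihood of a codon alignment under a (possibly
## branch/site-class structured) GY94 model, by pruning with per-class
## transition matrices.

#' Construct a codon model specification
#'
#' The specification holds everything the likelihood engine and the
#' simulator need: kappa, the site-class mixture, per-branch-class omega
#' values and the codon equilibrium frequencies.
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega numeric matrix (site classes x branch classes) of dN/dS
#'   ratios; a single number or vector is promoted. Column names name the
#'   branch classes (default "background"); a single-column matrix applies
#'   to every branch class.
#' @param props site-class proportions (default: one class).
#' @param pi sense-codon frequencies (named; default uniform).
#' @param codeId NCBI genetic-code id.
#' @param family optional model-family label.
#' @return an internal model specification (list with class
#'   "CodonModelSpec").
#' @export
codonModelSpec <- function(kappa, omega, props = NULL, pi = NULL,
                           codeId = "1", family = "custom") {
  if (!is.matrix(omega)) omega <- matrix(omega, ncol = 1)
  if (is.null(colnames(omega))) colnames(omega) <- if (ncol(omega) == 1)
    "background" else c("background", "foreground", seq_len(ncol(omega) - 2))[seq_len(ncol(omega))]
  if (is.null(props)) props <- rep(1 / nrow(omega), nrow(omega))
  if (abs(sum(props) - 1) > 1e-8 || any(props < 0))
    stop("site-class proportions must be >= 0 and sum to 1")
  if (any(omega < 0)) stop("omega must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  sense <- senseCodons(geneticCode(codeId))
  if (is.null(pi)) pi <- setNames(rep(1 / length(sense), length(sense)), sense)
  if (abs(sum(pi) - 1) > 1e-6 || any(pi < 0)) stop("invalid frequencies")
  structure(list(kappa = kappa, omega = omega, props = props,
                 pi = pi[sense], codeId = codeId, family = family),
            class = "CodonModelSpec")
}

## transition-probability closures per (site class, branch class), scaled so
## that the expected substitutions per codon per unit branch length is 1 at
## the site-class mixture (per branch class)
.specPclosures <- function(spec) {
  K <- nrow(spec$omega)
  classes <- colnames(spec$omega)
  Qs <- vector("list", K * length(classes))
  dim(Qs) <- c(K, length(classes))
  rates <- matrix(0, K, length(classes))
  for (k in seq_len(K)) for (c in seq_along(classes)) {
    Q <- buildGY94Matrix(spec$pi, spec$kappa, spec$omega[k, c],
                         spec$codeId, scale = FALSE)
    Qs[[k, c]] <- Q
    rates[k, c] <- .qRate(Q, spec$pi)
  }
  scale <- colSums(rates * spec$props)     # per branch class
  Pfun <- vector("list", K * length(classes))
  dim(Pfun) <- c(K, length(classes))
  for (k in seq_len(K)) for (c in seq_along(classes)) {
    sc <- if (scale[c] > 0) scale[c] else 1
    Pfun[[k, c]] <- .qEigen(Qs[[k, c]] / sc, spec$pi)
  }
  list(Pfun = Pfun, classes = classes)
}

## codon alignment -> integer states per tip (1-based sense index, 0 missing)
## with pattern compression; tips ordered as tree$tip.label
.patternData <- function(codonAln, tree) {
  seqs <- as.character(alignedSeqs(codonAln))
  miss <- setdiff(tree$tip.label, names(seqs))
  if (length(miss)) stop("leaf without sequence: ", paste(miss, collapse = ", "))
  code <- geneticCode(geneticCodeId(codonAln))
  sidx <- .senseIndex(code)
  states <- vapply(tree$tip.label, function(id) {
    codons <- .splitCodons(seqs[[id]])
    v <- sidx[codons]
    v[is.na(v)] <- 0L                      # gaps, ambiguity -> missing
    as.integer(v)
  }, integer(nCodons(codonAln)))
  if (is.null(dim(states)))                # single-codon alignment
    states <- matrix(states, nrow = 1,
                     dimnames = list(NULL, tree$tip.label))
  states <- t(states)
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  patterns <- states[, first, drop = FALSE]
  weights <- as.numeric(table(factor(key, levels = key[first])))
  list(patterns = patterns, weights = weights,
       patternOf = match(key, key[first]))
}

#' Log-likelihood of a codon alignment on a tree under a codon model
#'
#' Felsenstein pruning with transition matrices \code{exp(Q_c t)} per branch
#' class, site-class mixtures summed with their proportions; gap or
#' ambiguous codons integrate over all sense codons.
#'
#' @param codonAln a [CodonAlignment-class].
#' @param geneTree a [GeneTree-class] (or ape phylo; all branches
#'   "background") with branch lengths.
#' @param spec a [codonModelSpec()].
#' @return the log-likelihood (numeric scalar) with attribute
#'   \code{"siteLogLik"} giving per-codon-site values.
#' @export
computeTreeLoglik <- function(codonAln, geneTree, spec) {
  if (inherits(geneTree, "phylo")) geneTree <- geneTree(geneTree)
  tree <- treePhylo(geneTree)
  pat <- .patternData(codonAln, tree)
  ll <- .treeLoglikFromPatterns(pat, tree, branchClasses(geneTree), spec)
  ll
}

## core shared with the fitter (patterns precomputed)
.treeLoglikFromPatterns <- function(pat, tree, edgeClass, spec) {
  Pclos <- .specPclosures(spec)
  tr <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  cls <- edgeClass[ord]
  tE <- tr$edge.length
  if (is.null(tE)) stop("tree must have branch lengths")
  if (any(tE < 0)) stop("negative branch length")
  classIdx <- match(cls, Pclos$classes)
  if (anyNA(classIdx)) {
    ## single-column spec applies to every branch class
    if (length(Pclos$classes) == 1L) classIdx <- rep(1L, length(cls))
    else stop("edge class not covered by the model spec: ",
              paste(setdiff(cls, Pclos$classes), collapse = ", "))
  }
  K <- length(spec$props)
  npat <- ncol(pat$patterns)
  cll <- matrix(0, K, npat)
  for (k in seq_len(K)) {
    Plist <- lapply(seq_len(nrow(tr$edge)), function(e)
      Pclos$Pfun[[k, classIdx[e]]](tE[e]))
    cll[k, ] <- prune_loglik(tr$edge, Plist, pat$patterns, unname(spec$pi),
                             length(tr$tip.label), tr$Nnode)
  }
  ## mix site classes on the log scale
  mx <- apply(cll, 2, max)
  mixed <- mx + log(colSums(exp(sweep(cll, 2, mx, "-")) * spec$props))
  lnL <- sum(mixed * pat$weights)
  attr(lnL, "siteLogLik") <- mixed[pat$patternOf]
  lnL
}
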