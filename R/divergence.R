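## Type-I functional divergence between two paralog clusters: per-site
## substitution counts by tree-aware (Fitch) parsimony, a two-component
## Poisson-gamma rate model with a fraction theta of independently-evolving
## sites, per-site posteriors and the iterative posterior-cutoff selection.

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Per-column Fitch parsimony substitution counts
#'
#' Minimum number of residue changes per alignment column on a tree.
#' Unknown residues (gaps, X) act as wildcards. Multifurcations are folded
#' child by child.
#'
#' @param tree an [ape::phylo] whose tips are alignment row ids.
#' @param aln named character vector (or AAStringSet) of equal-length
#'   aligned protein sequences covering all tips.
#' @return integer vector, one count per column.
#' @export
fitchCounts <- function(tree, aln) {
  if (!is.character(aln)) aln <- as.character(aln)
  miss <- setdiff(tree$tip.label, names(aln))
  if (length(miss)) stop("tips without sequence: ", paste(miss, collapse = ", "))
  ncol <- unique(nchar(aln[tree$tip.label]))
  if (length(ncol) != 1L) stop("alignment rows differ in length")
  ALL <- bitwShiftL(1L, length(.AA)) - 1L
  enc <- function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- match(ch, .AA)
    m <- ifelse(is.na(idx), ALL, bitwShiftL(1L, idx - 1L))
    as.integer(m)
  }
  tipMask <- t(vapply(tree$tip.label, function(id) enc(aln[[id]]),
                      integer(ncol)))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  masks <- matrix(0L, ntip + nnode, ncol)
  masks[seq_len(ntip), ] <- tipMask
  seen <- logical(ntip + nnode)
  seen[seq_len(ntip)] <- TRUE
  counts <- integer(ncol)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    cm <- masks[child, ]
    if (!seen[par]) {
      masks[par, ] <- cm
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(masks[par, ], cm)
      zero <- inter == 0L
      counts[zero] <- counts[zero] + 1L
      inter[zero] <- bitwOr(masks[par, ], cm)[zero]
      masks[par, ] <- inter
    }
  }
  counts
}

## two-cluster Poisson-gamma mixture machinery --------------------------------

## method-of-moments gamma shape from Poisson-gamma counts (mean d, rate ~
## gamma(alpha, alpha)); var = d + d^2/alpha
.momShape <- function(x) {
  d <- mean(x); v <- var(x)
  if (!is.finite(v) || v <= d) return(50)        # near-Poisson
  min(max(d^2 / (v - d), 0.05), 50)
}

## log density of the correlated component: shared gamma rate
.logF1 <- function(xa, xb, da, db, alpha) {
  lgamma(xa + xb + alpha) - lgamma(xa + 1) - lgamma(xb + 1) - lgamma(alpha) +
    xa * log(da) + xb * log(db) + alpha * log(alpha) -
    (xa + xb + alpha) * log(alpha + da + db)
}

## log density of the independent component: separate gamma rates
.logF0 <- function(xa, xb, da, db, alpha) {
  dnbinom(xa, size = alpha, mu = da, log = TRUE) +
    dnbinom(xb, size = alpha, mu = db, log = TRUE)
}

.divLoglik <- function(theta, lf1, lf0) {
  mx <- pmax(lf1, lf0)
  sum(mx + log((1 - theta) * exp(lf1 - mx) + theta * exp(lf0 - mx)))
}

## joint ML fit of (theta, alpha) for given count vectors; the gamma shape
## is also profiled under the theta = 0 null so the LRT has 1 df
.fitTheta <- function(xa, xb) {
  da <- mean(xa); db <- mean(xb)
  if (da <= 0 || db <= 0) stop("zero-variation alignment in one cluster")
  alpha0 <- mean(c(.momShape(xa), .momShape(xb)))
  nll <- function(theta, alpha) {
    lf1 <- .logF1(xa, xb, da, db, alpha)
    lf0 <- .logF0(xa, xb, da, db, alpha)
    -.divLoglik(theta, lf1, lf0)
  }
  alt <- optim(c(.logit(0.3), log(alpha0)),
               function(p) nll(.invlogit(p[1]), exp(p[2])),
               method = "L-BFGS-B", lower = c(-12, log(0.02)),
               upper = c(12, log(100)))
  null <- optimize(function(la) nll(0, exp(la)),
                   interval = c(log(0.02), log(100)), tol = 1e-6)
  theta <- .invlogit(alt$par[1])
  alpha <- exp(alt$par[2])
  lnL1 <- -alt$value
  lnL0 <- -null$objective
  if (lnL1 < lnL0) {
    theta <- 0; alpha <- exp(null$minimum); lnL1 <- lnL0
  }
  lf1 <- .logF1(xa, xb, da, db, alpha)
  lf0 <- .logF0(xa, xb, da, db, alpha)
  list(theta = theta, lnL1 = lnL1, lnL0 = lnL0, alpha = alpha,
       da = da, db = db, lf1 = lf1, lf0 = lf0)
}

#' Estimate type-I functional divergence between two paralog clusters
#'
#' Per-site substitution counts are taken per cluster on the pruned tree by
#' Fitch parsimony; the counts follow a Poisson-gamma rate model in which a
#' fraction theta of sites draws independent rates in the two clusters
#' while the rest share one rate. theta is estimated by maximum likelihood;
#' a likelihood-ratio test of theta = 0 uses a chi-square with 1 df;
#' per-site posterior probabilities of divergence and a bootstrap (column
#' resampling) standard error for theta are reported.
#'
#' @param proteinAln named character vector or AAStringSet of aligned
#'   protein sequences.
#' @param tree an [ape::phylo] (or [GeneTree-class]) containing all cluster
#'   members as tips.
#' @param clusterA,clusterB disjoint character vectors of at least 4
#'   sequence/tip ids each.
#' @param nBootstrap bootstrap replicates for the theta standard error
#'   (default 500).
#' @return a [DivergenceResult-class].
#' @export
estimateType1Divergence <- function(proteinAln, tree, clusterA, clusterB,
                                    nBootstrap = 500) {
  if (is(tree, "GeneTree")) tree <- treePhylo(tree)
  if (!is.character(proteinAln)) proteinAln <- as.character(proteinAln)
  if (length(clusterA) < 4L || length(clusterB) < 4L)
    stop("each cluster needs at least 4 members")
  if (length(intersect(clusterA, clusterB)))
    stop("clusters must be disjoint")
  for (ids in list(clusterA, clusterB)) {
    miss <- setdiff(ids, tree$tip.label)
    if (length(miss)) stop("cluster ids missing from tree: ",
                           paste(miss, collapse = ", "))
    miss <- setdiff(ids, names(proteinAln))
    if (length(miss)) stop("cluster ids missing from alignment: ",
                           paste(miss, collapse = ", "))
  }
  treeA <- ape::keep.tip(tree, clusterA)
  treeB <- ape::keep.tip(tree, clusterB)
  xa <- fitchCounts(treeA, proteinAln)
  xb <- fitchCounts(treeB, proteinAln)
  fit <- .fitTheta(xa, xb)
  stat <- max(2 * (fit$lnL1 - fit$lnL0), 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  post <- {
    num <- fit$theta * exp(fit$lf0)
    den <- (1 - fit$theta) * exp(fit$lf1) + num
    ifelse(den > 0, num / den, 0)
  }
  se <- if (nBootstrap > 0) {
    n <- length(xa)
    reps <- vapply(seq_len(nBootstrap), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      tryCatch(.fitTheta(xa[i], xb[i])$theta, error = function(e) NA_real_)
    }, 0)
    sd(reps, na.rm = TRUE)
  } else NA_real_
  new("DivergenceResult", theta = fit$theta, se = se, lrtStat = stat,
      pValue = p, posteriors = post, cutoff = NA_real_,
      selectedSites = integer(0),
      data = list(countsA = xa, countsB = xb, alpha = fit$alpha,
                  nBootstrap = nBootstrap))
}

#' Select functionally divergent sites by the iterative cutoff procedure
#'
#' Posterior probabilities are sorted in descending order and the highest
#' scoring columns are consecutively removed, refitting theta on the
#' remaining columns, until the p-value of the divergence coefficient
#' becomes insignificant (> alpha). The remaining highest posterior of the
#' original fit is the cutoff; the removed columns are the selected sites.
#'
#' @param result a [DivergenceResult-class] from [estimateType1Divergence()].
#' @param alpha significance level (default 0.05).
#' @return the result with \code{cutoff} and \code{selectedSites} filled in
#'   (empty with an NA cutoff when the initial fit is not significant).
#' @export
selectDivergentSites <- function(result, alpha = 0.05) {
  stopifnot(is(result, "DivergenceResult"))
  xa <- result@data$countsA; xb <- result@data$countsB
  post <- result@posteriors
  n <- length(post)
  if (result@pValue > alpha) {
    result@cutoff <- NA_real_
    result@selectedSites <- integer(0)
    return(result)
  }
  ord <- order(post, decreasing = TRUE)
  removed <- integer(0)
  for (k in seq_len(n - 2L)) {
    removed <- ord[seq_len(k)]
    keep <- setdiff(seq_len(n), removed)
    fit <- .fitTheta(xa[keep], xb[keep])
    stat <- max(2 * (fit$lnL1 - fit$lnL0), 0)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    if (p > alpha) {
      result@cutoff <- max(post[keep])
      result@selectedSites <- sort(removed)
      return(result)
    }
  }
  warning("significance persisted after removing nearly all columns")
  result@cutoff <- min(post[removed])
  result@selectedSites <- sort(removed)
  result
}
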