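## Maximum-likelihood fitting of the codon model zoo (M0, two-ratio branch
## model, M1a, M2a_rel, clade model C, branch-site model A), multi-start
## optimization, likelihood-ratio tests and Benjamini-Hochberg correction.

.logit <- function(p) log(p / (1 - p))
.invlogit <- function(x) 1 / (1 + exp(-x))
.softmax <- function(z) { e <- exp(c(z, 0)); e / sum(e) }

## family definitions: free parameters on an unconstrained scale, and the
## mapping to a codonModelSpec
.familyDef <- function(family, branchClassLevels) {
  C <- length(branchClassLevels)
  switch(family,
    M0 = list(
      np = 2L,
      init = function(kappa, w) c(log(kappa), log(max(w, 1e-4))),
      lower = c(log(0.05), log(1e-4)), upper = c(log(50), log(50)),
      spec = function(par, pi, codeId) codonModelSpec(
        kappa = exp(par[1]),
        omega = matrix(exp(par[2]), 1, 1,
                       dimnames = list(NULL, branchClassLevels[1])),
        props = 1, pi = pi, codeId = codeId, family = "M0"),
      estimates = function(par) list(kappa = exp(par[1]), omega = exp(par[2]))),
    branch2 = list(
      np = 1L + C,
      init = function(kappa, w) c(log(kappa), rep(log(max(w, 1e-4)), C)),
      lower = c(log(0.05), rep(log(1e-4), C)),
      upper = c(log(50), rep(log(50), C)),
      spec = function(par, pi, codeId) codonModelSpec(
        kappa = exp(par[1]),
        omega = matrix(exp(par[1 + seq_len(C)]), 1, C,
                       dimnames = list(NULL, branchClassLevels)),
        props = 1, pi = pi, codeId = codeId, family = "branch2"),
      estimates = function(par) c(list(kappa = exp(par[1])),
        setNames(as.list(exp(par[1 + seq_len(C)])),
                 paste0("omega_", branchClassLevels)))),
    M1a = list(
      np = 3L,
      init = function(kappa, w) c(log(kappa), .logit(0.7),
                                  .logit(min(max(w, 0.01), 0.9))),
      lower = c(log(0.05), -12, -12), upper = c(log(50), 12, 7),
      spec = function(par, pi, codeId) {
        p0 <- .invlogit(par[2])
        codonModelSpec(kappa = exp(par[1]),
          omega = matrix(c(.invlogit(par[3]), 1), 2, 1,
                         dimnames = list(NULL, branchClassLevels[1])),
          props = c(p0, 1 - p0), pi = pi, codeId = codeId, family = "M1a")
      },
      estimates = function(par) list(kappa = exp(par[1]),
        p0 = .invlogit(par[2]), omega0 = .invlogit(par[3]))),
    M2a_rel = list(
      np = 5L,
      init = function(kappa, w) c(log(kappa), 1.2, 0.2, .logit(0.2),
                                  log(max(w, 1e-3))),
      lower = c(log(0.05), -15, -15, -12, log(1e-4)),
      upper = c(log(50), 15, 15, 7, log(50)),
      spec = function(par, pi, codeId) {
        p <- .softmax(par[2:3])
        codonModelSpec(kappa = exp(par[1]),
          omega = matrix(c(.invlogit(par[4]), 1, exp(par[5])), 3, 1,
                         dimnames = list(NULL, branchClassLevels[1])),
          props = p, pi = pi, codeId = codeId, family = "M2a_rel")
      },
      estimates = function(par) {
        p <- .softmax(par[2:3])
        list(kappa = exp(par[1]), p0 = p[1], p1 = p[2], p2 = p[3],
             omega0 = .invlogit(par[4]), omega2 = exp(par[5]))
      }),
    CmC = list(
      np = 4L + C,
      init = function(kappa, w) c(log(kappa), 1.2, 0.2, .logit(0.2),
                                  rep(log(max(w, 1e-3)), C)),
      lower = c(log(0.05), -15, -15, -12, rep(log(1e-4), C)),
      upper = c(log(50), 15, 15, 7, rep(log(50), C)),
      spec = function(par, pi, codeId) {
        p <- .softmax(par[2:3])
        w0 <- .invlogit(par[4])
        w2 <- exp(par[4 + seq_len(C)])
        codonModelSpec(kappa = exp(par[1]),
          omega = matrix(c(rep(w0, C), rep(1, C), w2), 3, C, byrow = TRUE,
                         dimnames = list(NULL, branchClassLevels)),
          props = p, pi = pi, codeId = codeId, family = "CmC")
      },
      estimates = function(par) {
        p <- .softmax(par[2:3])
        c(list(kappa = exp(par[1]), p0 = p[1], p1 = p[2], p2 = p[3],
               omega0 = .invlogit(par[4])),
          setNames(as.list(exp(par[4 + seq_len(C)])),
                   paste0("omega2_", branchClassLevels)))
      }),
    branchsiteA = list(
      np = 5L,
      init = function(kappa, w) c(log(kappa), 1.2, 0.2, .logit(0.2),
                                  log(max(w - 1, 0.25))),
      lower = c(log(0.05), -15, -15, -12, -15),
      upper = c(log(50), 15, 15, 7, log(50)),
      spec = function(par, pi, codeId) {
        p <- .softmax(par[2:3])          # p0, p1, p2
        w0 <- .invlogit(par[4])
        w2 <- 1 + exp(par[5])
        p01 <- p[1] + p[2]
        props <- c(p[1], p[2], p[3] * p[1] / p01, p[3] * p[2] / p01)
        fg <- branchClassLevels[branchClassLevels != "background"][1]
        omega <- matrix(c(w0, w0, 1, 1, w0, w2, 1, w2), 4, 2, byrow = TRUE,
                        dimnames = list(NULL, c("background", fg)))
        codonModelSpec(kappa = exp(par[1]), omega = omega, props = props,
                       pi = pi, codeId = codeId, family = "branchsiteA")
      },
      estimates = function(par) {
        p <- .softmax(par[2:3])
        list(kappa = exp(par[1]), p0 = p[1], p1 = p[2], p2 = p[3],
             omega0 = .invlogit(par[4]), omega2 = 1 + exp(par[5]))
      }),
    stop("unknown model family: ", family)
  )
}

.defaultOmegaStarts <- function(family) {
  switch(family,
    M0 = c(0.2, 1),
    branch2 = c(0.2, 1),
    M1a = c(0.1, 0.5),
    M2a_rel = c(0.001, 0.01, 0.1, 0.25, 0.5, 0.75, 1, 2, 3, 4, 5, 10),
    CmC = c(0.001, 0.01, 0.1, 0.25, 0.5, 0.75, 1, 2, 3, 4, 5, 10),
    branchsiteA = c(1.25, 1.5, 1.75, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 10))
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Maximizes the log-likelihood over the family's free parameters (kappa,
#' omega values, site-class proportions) from every start in
#' \code{omegaStarts}, returning the best fit and the per-start record.
#' Model families: "M0" (one ratio), "branch2" (one omega per branch
#' class), "M1a" (nearly neutral), "M2a_rel" (adds a free omega2 class),
#' "CmC" (clade model C: omega2 differs per branch/clade class),
#' "branchsiteA" (foreground-only positive-selection class; null is M1a).
#' "M2a_ref" is accepted as a spelling of "M2a_rel".
#'
#' Branch lengths are estimated under M0 and held fixed for the other
#' families (pass \code{branchLengths} to supply your own, e.g. from a
#' previous M0 fit).
#'
#' @param codonAln a [CodonAlignment-class].
#' @param geneTree a [GeneTree-class] (branch classes mark foreground
#'   lineages / clade partitions where the family needs them).
#' @param family model family name.
#' @param omegaStarts numeric vector of omega initial values (defaults:
#'   the multi-start grids used for clade model C and branch-site model A;
#'   a short grid for the simpler families).
#' @param frequencies codon-frequency mode passed to [codonFrequencies()].
#' @param branchLengths optional per-edge branch lengths (ordered as
#'   \code{treePhylo(geneTree)$edge}) or a [CodonFitResult-class] M0 fit to
#'   take them from; default: estimate under M0.
#' @param kappaStart initial kappa (default 2).
#' @param control passed to [stats::optim()] (L-BFGS-B).
#' @return a [CodonFitResult-class].
#' @export
fitCodonModel <- function(codonAln, geneTree, family = "M0",
                          omegaStarts = NULL, frequencies = "F3x4",
                          branchLengths = NULL, kappaStart = 2,
                          control = list()) {
  if (family == "M2a_ref") family <- "M2a_rel"
  if (inherits(geneTree, "phylo")) geneTree <- geneTree(geneTree)
  tree <- treePhylo(geneTree)
  edgeClass <- branchClasses(geneTree)
  levelsC <- sort(unique(edgeClass))
  if (family %in% c("branch2", "CmC", "branchsiteA") && length(levelsC) < 2L)
    stop("family '", family, "' needs foreground/clade branch labels, ",
         "but all branches share one class")
  if (family == "branchsiteA" && !"background" %in% levelsC)
    stop("branch-site model A needs 'background' branches")
  if (family %in% c("M0", "M1a", "M2a_rel")) levelsC <- "all"
  pi <- codonFrequencies(codonAln, frequencies)
  pat <- .patternData(codonAln, tree)
  def <- .familyDef(family, levelsC)
  if (is.null(omegaStarts)) omegaStarts <- .defaultOmegaStarts(family)
  ctrl <- modifyList(list(maxit = 300, factr = 1e8), control)

  edgeClassUsed <- if (identical(levelsC, "all"))
    rep("all", length(edgeClass)) else edgeClass

  estimateBL <- family == "M0" && is.null(branchLengths)
  if (!estimateBL) {
    if (is.null(branchLengths)) {
      m0 <- fitCodonModel(codonAln, geneTree, "M0", omegaStarts = 0.4,
                          frequencies = frequencies, kappaStart = kappaStart,
                          control = control)
      branchLengths <- m0@estimates$branch_lengths
      kappaStart <- m0@estimates$kappa
    } else if (is(branchLengths, "CodonFitResult")) {
      kappaStart <- branchLengths@estimates$kappa
      branchLengths <- branchLengths@estimates$branch_lengths
    }
    if (length(branchLengths) != nrow(tree$edge))
      stop("branchLengths must have one value per edge")
  }

  nedge <- nrow(tree$edge)
  blBounds <- c(log(1e-6), log(20))
  objective <- function(par) {
    if (estimateBL) {
      bl <- exp(par[def$np + seq_len(nedge)])
      mp <- par[seq_len(def$np)]
    } else {
      bl <- branchLengths
      mp <- par
    }
    spec <- def$spec(mp, pi, geneticCodeId(codonAln))
    tr2 <- tree
    tr2$edge.length <- bl
    -as.numeric(.treeLoglikFromPatterns(pat, tr2, edgeClassUsed, spec))
  }

  startBL <- if (estimateBL) {
    bl0 <- tree$edge.length
    if (is.null(bl0) || any(!is.finite(bl0)) || any(bl0 <= 0))
      bl0 <- rep(0.2, nedge)
    pmin(pmax(log(bl0), blBounds[1]), blBounds[2])
  } else NULL

  starts <- list(); best <- NULL
  for (w in omegaStarts) {
    par0 <- def$init(kappaStart, w)
    lower <- def$lower; upper <- def$upper
    if (estimateBL) {
      par0 <- c(par0, startBL)
      lower <- c(lower, rep(blBounds[1], nedge))
      upper <- c(upper, rep(blBounds[2], nedge))
    }
    fit <- optim(par0, objective, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = ctrl)
    starts[[length(starts) + 1L]] <- data.frame(
      omega_start = w, lnL = -fit$value, convergence = fit$convergence,
      stringsAsFactors = FALSE)
    if (is.null(best) || fit$value < best$value) { best <- fit; best$w <- w }
  }
  startRec <- do.call(rbind, starts)
  if (all(startRec$convergence != 0))
    warning("no optimization start converged cleanly (codes: ",
            paste(unique(startRec$convergence), collapse = ","), ")")

  mp <- if (estimateBL) best$par[seq_len(def$np)] else best$par
  est <- def$estimates(mp)
  est$n_model_params <- def$np       # free parameters excluding branch lengths
  est$branch_lengths <- if (estimateBL)
    exp(best$par[def$np + seq_len(nedge)]) else branchLengths
  nfree <- def$np + if (estimateBL) nedge else 0L
  spec <- def$spec(mp, pi, geneticCodeId(codonAln))
  new("CodonFitResult", family = family, lnL = -best$value, estimates = est,
      nFreeParams = as.numeric(nfree), starts = startRec,
      spec = list(spec = spec, frequencies = frequencies,
                  winning_start = best$w))
}

#' Likelihood-ratio test between two nested codon model fits
#'
#' @param nullFit,altFit [CodonFitResult-class] objects for the nested null
#'   and the alternative.
#' @param df degrees of freedom; default: difference in free-parameter
#'   counts. An override exists because published tests sometimes state a
#'   different df than the parameter-count difference.
#' @param tol tolerance below which a negative statistic is clamped to 0;
#'   a more negative value flags an optimization failure.
#' @return list (stat, df, p_value, null, alt).
#' @export
likelihoodRatioTest <- function(nullFit, altFit, df = NULL, tol = 1e-4) {
  stat <- 2 * (logLik2(altFit) - logLik2(nullFit))
  if (stat < -tol)
    warning(sprintf(
      "alternative lnL (%.6f) below null lnL (%.6f): optimization failure?",
      logLik2(altFit), logLik2(nullFit)))
  stat <- max(stat, 0)
  if (is.null(df)) {
    ## count model parameters only: branch lengths are shared plumbing (the
    ## nested families reuse the M0 branch lengths)
    npar <- function(f) f@estimates$n_model_params %||% f@nFreeParams
    df <- npar(altFit) - npar(nullFit)
  }
  if (df < 1) stop("df must be >= 1 (models not nested?)")
  list(stat = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       null = nullFit@family, alt = altFit@family)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
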