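## Independent brute-force oracles, written straight from the definitions
## with plain loops; they deliberately share no code with the package.

.oracleCode <- function() {
  code <- Biostrings::GENETIC_CODE
  code[order(names(code))]
}

## all single-nucleotide neighbors of a codon
.oracleNeighbors <- function(codon, pos) {
  out <- character(0)
  for (nt in c("A", "C", "G", "T")) {
    if (nt == substr(codon, pos, pos)) next
    nb <- codon
    substr(nb, pos, pos) <- nt
    out <- c(out, nb)
  }
  out
}

## synonymous/nonsynonymous site counts of one codon: per position, the
## synonymous fraction among non-stop single-nucleotide changes
codonSitesOracle <- function(codon) {
  code <- .oracleCode()
  S <- 0; N <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (nb in .oracleNeighbors(codon, pos)) {
      if (code[nb] == "*") next
      nonstop <- nonstop + 1
      if (code[nb] == code[codon]) syn <- syn + 1
    }
    if (nonstop > 0) {
      S <- S + syn / nonstop
      N <- N + (nonstop - syn) / nonstop
    }
  }
  c(S = S, N = N)
}

## all mutational pathways between two codons (permutations of the differing
## positions), each a vector of intermediate codons
.oraclePaths <- function(a, b) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(diffs)) return(list())
  perms <- if (length(diffs) == 1) list(diffs) else {
    out <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { out[[length(out) + 1]] <<- prefix; return() }
      for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
    }
    rec(integer(0), diffs)
    out
  }
  lapply(perms, function(pm) {
    cur <- a
    steps <- character(0)
    for (pos in pm) {
      substr(cur, pos, pos) <- substr(b, pos, pos)
      steps <- c(steps, cur)
    }
    steps
  })
}

## pathway-averaged synonymous/nonsynonymous difference counts, skipping
## pathways through stop codons (all-blocked pairs fall back to all paths)
codonDiffOracle <- function(a, b) {
  code <- .oracleCode()
  paths <- .oraclePaths(a, b)
  if (!length(paths)) return(c(Sd = 0, Nd = 0))
  count <- function(path, allowStops) {
    cur <- a; sd <- 0; nd <- 0
    for (step in path) {
      if (!allowStops && code[step] == "*") return(NULL)
      if (code[cur] == code[step]) sd <- sd + 1 else nd <- nd + 1
      cur <- step
    }
    c(sd, nd)
  }
  counts <- Filter(Negate(is.null), lapply(paths, count, allowStops = FALSE))
  if (!length(counts)) counts <- lapply(paths, count, allowStops = TRUE)
  m <- do.call(rbind, counts)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

## full pairwise NG86 computation from the definitions
ng86Oracle <- function(a, b) {
  code <- .oracleCode()
  n <- nchar(a) / 3
  Sa <- Sb <- Na <- Nb <- Sd <- Nd <- 0
  used <- 0
  for (i in seq_len(n)) {
    ca <- substr(a, 3 * i - 2, 3 * i)
    cb <- substr(b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (code[ca] == "*" || code[cb] == "*") next
    sa <- codonSitesOracle(ca); sb <- codonSitesOracle(cb)
    Sa <- Sa + sa["S"]; Na <- Na + sa["N"]
    Sb <- Sb + sb["S"]; Nb <- Nb + sb["N"]
    d <- codonDiffOracle(ca, cb)
    Sd <- Sd + d["Sd"]; Nd <- Nd + d["Nd"]
    used <- used + 1
  }
  S_bar <- (Sa + Sb) / 2; N_bar <- (Na + Nb) / 2
  pS <- Sd / S_bar; pN <- Nd / N_bar
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- unname(jc(pS)); dN <- unname(jc(pN))
  list(Sd = unname(Sd), Nd = unname(Nd), S_bar = unname(S_bar),
       N_bar = unname(N_bar), pS = unname(pS), pN = unname(pN),
       dS = unname(dS), dN = unname(dN),
       omega = if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_,
       n_codons_used = used)
}

## random sense-codon sequence
randomCodonSeq <- function(nCodons) {
  code <- .oracleCode()
  sense <- names(code)[code != "*"]
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

## exhaustive syntenic-block oracle: enumerate every contiguous segment of
## the pair list sorted by either region's ranks, keep valid (strictly
## monotone, rank gaps within the window in both regions) segments, and
## report the maximal ones (no segment of the same orientation contains them)
syntenyOracle <- function(pairs, windowSize, minPairs) {
  segsFor <- function(p) {
    n <- nrow(p)
    valid <- function(i, j) {
      ra <- p$rank_a[i:j]; rb <- p$rank_b[i:j]
      if (any(diff(ra) <= 0)) return(NA)
      if (any(diff(ra) > windowSize - 1)) return(NA)
      if (any(abs(diff(rb)) > windowSize - 1)) return(NA)
      if (all(diff(rb) > 0)) return("direct")
      if (all(diff(rb) < 0)) return("inverted")
      NA
    }
    segs <- list()
    for (i in seq_len(n)) for (j in i:n) {
      if (j - i + 1 < minPairs) next
      o <- valid(i, j)
      if (!is.na(o))
        segs[[length(segs) + 1]] <- list(
          o = o, keys = sort(paste(p$gene_a[i:j], p$gene_b[i:j], sep = "|")))
    }
    segs
  }
  pA <- pairs[order(pairs$rank_a, pairs$rank_b), , drop = FALSE]
  pB <- pairs
  names(pB)[match(c("rank_a", "rank_b", "gene_a", "gene_b"), names(pB))] <-
    c("rank_b", "rank_a", "gene_b", "gene_a")
  pB <- pB[order(pB$rank_a, pB$rank_b), , drop = FALSE]
  segsB <- lapply(segsFor(pB), function(s) {
    s$keys <- sort(vapply(strsplit(s$keys, "|", fixed = TRUE),
                          function(x) paste(x[2], x[1], sep = "|"), ""))
    s
  })
  segs <- c(segsFor(pA), segsB)
  keep <- rep(TRUE, length(segs))
  for (x in seq_along(segs)) for (y in seq_along(segs)) {
    if (x == y || !keep[x]) next
    if (segs[[x]]$o != segs[[y]]$o) next
    sx <- segs[[x]]$keys; sy <- segs[[y]]$keys
    if (length(sx) < length(sy) && all(sx %in% sy)) keep[x] <- FALSE
    else if (length(sx) == length(sy) && all(sx %in% sy) && y < x)
      keep[x] <- FALSE
  }
  lapply(segs[keep], function(s) list(orientation = s$o, pairs = s$keys))
}

## GY94 generator built independently (plain loops), for likelihood oracles
gy94Oracle <- function(pi, kappa, omega) {
  code <- .oracleCode()
  sense <- names(code)[code != "*"]
  ns <- length(sense)
  Q <- matrix(0, ns, ns, dimnames = list(sense, sense))
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    ci <- sense[i]; cj <- sense[j]
    dpos <- which(strsplit(ci, "")[[1]] != strsplit(cj, "")[[1]])
    if (length(dpos) != 1) next
    r <- pi[cj]
    if (ts[substr(ci, dpos, dpos)] == substr(cj, dpos, dpos)) r <- r * kappa
    if (code[ci] != code[cj]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}
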