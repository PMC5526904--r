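## Genetic-code bookkeeping shared by the NG86 counter, the GY94 engine and
## the simulators. Codon order is fixed (TCAG-major, Biostrings convention is
## alphabetical; we use alphabetical ACGT for determinism).

.NUC <- c("A", "C", "G", "T")

#' All 64 codons in alphabetical order
#' @keywords internal
allCodons <- function() {
  paste0(rep(.NUC, each = 16L), rep(rep(.NUC, each = 4L), times = 4L),
         rep(.NUC, times = 16L))
}

#' Look up a genetic code table
#'
#' @param id NCBI genetic-code id as a string (default "1", the standard
#'   code), or a full 64-long named character vector mapping codons to
#'   one-letter amino acids ("*" for stop).
#' @return named character vector of length 64 (codon -> amino acid).
#' @export
geneticCode <- function(id = "1") {
  if (is.character(id) && length(id) == 64L && !is.null(names(id))) {
    return(id[allCodons()])
  }
  code <- Biostrings::getGeneticCode(as.character(id))
  code[allCodons()]
}

#' Sense (non-stop) codons of a genetic code
#' @param code a code table from [geneticCode()].
#' @return character vector of sense codons in alphabetical order.
#' @export
senseCodons <- function(code = geneticCode()) {
  names(code)[code != "*"]
}

## integer index of each codon among the sense codons (NA for stops)
.senseIndex <- function(code) {
  sense <- senseCodons(code)
  idx <- setNames(rep(NA_integer_, 64L), allCodons())
  idx[sense] <- seq_along(sense)
  idx
}

#' Translate a vector of codons
#' @param codons character vector of 3-letter codons (may contain "---" or
#'   ambiguity letters).
#' @param code a code table from [geneticCode()].
#' @return one-letter amino acids; "-" for all-gap codons, "X" for ambiguous.
#' @export
translateCodons <- function(codons, code = geneticCode()) {
  out <- rep("X", length(codons))
  out[codons == "---"] <- "-"
  known <- codons %in% names(code)
  out[known] <- unname(code[codons[known]])
  out
}

## split a character string of length 3n into codons
.splitCodons <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character())
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

.isAmbiguousCodon <- function(codons) {
  grepl("[^ACGT]", codons) & codons != "---"
}
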