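---
title: "Models and methods behind OhnologEvo"
author: "OhnologEvo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind OhnologEvo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OhnologEvo)
```

OhnologEvo re-implements, as a tested and reusable toolkit, the
comparative-genomics workflow used to trace gene families retained from
whole-genome duplication (WGD): screening similarity-search output for
domain-defined homologs, validating WGD paralogs through outgroup-anchored
synteny, quantifying selective pressure with pairwise and maximum-likelihood
dN/dS models, and locating sites of type-I functional divergence between
paralog clusters. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical choices; it also states what the
synthetic-data generators do and do not emulate.

## Homolog screening

The screening module consumes externally produced similarity tables; it
never runs hmmsearch or BLAST itself.

**Domain-hit filtering.** HMMER `--domtblout` rows are kept when the
sequence E-value and the per-domain conditional E-value are at or below
their thresholds (defaults 1e-2 each, both inclusive) and the hit covers at
least half of the HMM (`(hmm_to - hmm_from + 1) / hmm_length >= 0.5`).
The per-domain independent E-value can be tested instead via
`domEvalueKind = "independent"`. When one protein carries several partial
hits of the same domain, the default judges each domain row on its own;
`merge = "summed"` instead measures coverage on the union of the HMM spans,
which rescues genuinely split hits.

**Redundancy clustering.** `clusterRedundantSequences()` reproduces the
greedy incremental semantics of CD-HIT with `-c 0.95 -g 1 -G 0 -aS 0.6`:
sequences are processed longest first (ties by id); each sequence joins the
best-matching existing representative whose local-alignment identity
(matches / alignment columns, the `-G 0` local definition) is at least
0.95 and whose alignment covers at least 60% of the shorter sequence, else
it founds a cluster. CD-HIT's word-size heuristics are an accelerator, not a
semantic, and are not reproduced; local alignments come from
`Biostrings::pairwiseAlignment` with BLOSUM62.

**Orthology.** `assignOrthologs()` implements the reverse-best-hit rule:
a forward hit (at E <= 1e-3, any rank) is accepted exactly when its reverse
best hit against the query proteome is the query itself. The forward hit is
deliberately *not* required to rank first — paralogs frequently outrank the
true ortholog in the forward search. Ties are broken uniformly everywhere:
bitscore descending, then E-value ascending, then lexicographic subject id.

## Outgroup anchoring and synteny blocks

Paralog families are first anchored in an unduplicated outgroup: members
without any outgroup hit at E < 1e-10 are discarded, and a family whose
members hit different outgroup proteins is split into subgroups sharing one
anchor; subgroups smaller than two die. Anchoring removes chimeric families
before any positional analysis.

`detectSyntenicBlocks()` works on gene *ranks* (order along the
chromosome), not base pairs, because conserved synteny is about relative
order. Anchored pairs between two regions are scanned for maximal runs that
are strictly increasing in both regions (direct) or strictly increasing in
one and decreasing in the other (inverted), where consecutive pairs of a
run must co-occur within a window of `windowSize = 100` gene ranks in
*both* regions. Runs are extracted scanning in each region's order and
pooled (a run interrupted by an interleaved pair in one order can still be
contiguous in the other), then blocks contained in a larger block of the
same orientation are dropped; this construction makes detection exactly
symmetric in the two regions. Blocks need `minPairs = 3` anchored pairs.
Both defaults are exposed; they follow the sliding-window practice of
synteny-database pipelines, which publish no single canonical value. With
windows this large, uniformly shuffled gene orders still produce short
chance runs at the minimum block size; real conserved segments distinguish
themselves by run length, so downstream interpretation should weight long
blocks, and `sharedPairCounts()` reports both per-block and total distinct
pair counts. For self-comparisons (both regions on one chromosome) trivial
self-pairs are excluded and the two members of a pair must be at least one
window apart. Strand is recorded but does not define orientation; rank
monotonicity does.

## Pairwise dN/dS (NG86)

`ng86Pairwise()` implements Nei–Gojobori (1986) counting. Synonymous site
counts per codon are computed per position as the synonymous fraction of
the single-nucleotide changes, excluding changes to stop codons and
renormalizing over the remaining changes, so S + N = 3 for every sense
codon. Difference counts average equally over all shortest mutational
pathways between two codons that avoid stop codons; if every pathway is
blocked (possible only for some 2–3 step pairs) the count falls back to
equal weighting over all pathways. Proportions pS = Sd/S and pN = Nd/N
receive the Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)p); p ≥ 3/4
yields a flagged undefined distance that is excluded from clade averages
and counted, never silently clamped. Codons with gaps or ambiguity in
either sequence are pairwise-deleted. One subtlety worth knowing: because
pathway averaging assigns fractional nonsynonymous steps to synonymous
codon pairs that are connected only through nonsynonymous intermediates
(the two arginine codon boxes, for instance), a strictly purifying process
can still show a small positive Nd.

`cladeRateSummary()` averages the pairwise dN and dS over all within-clade
pairs, for the full alignment and for domain partitions mapped through
alignment gaps from 1-based inclusive residue ranges on a reference
sequence. The summary ω is mean dN / mean dS by default; a
mean-of-pairwise-ratios mode exists because published tables are not always
consistent about which convention was used, and the two differ when dS
varies across pairs.

## Codon-model likelihoods (GY94)

The ML engine builds Goldman–Yang (1994) generators over the 61 sense
codons: q_ij = 0 for multi-nucleotide changes, otherwise proportional to
the target codon frequency π_j, times κ for transitions and ω for
nonsynonymous changes. Within each branch class the generator set is
scaled so one unit of branch length equals one expected substitution per
codon under the model's site-class mixture. Codon frequencies default to
F3x4 estimated from the data (F1x4, F61 and uniform are available); a small
floor keeps every frequency positive so the reversible generator can be
eigendecomposed via its symmetrized form, from which transition matrices
exp(Qt) are assembled exactly. Likelihoods use Felsenstein pruning over
compressed site patterns (the inner loop is compiled C++), with gap and
ambiguous codons integrating over all sense codons, and site classes mixed
on the log scale.

Model families: `M0` (one ω), `branch2` (one ω per branch class), `M1a`
(ω0 < 1 and ω1 = 1), `M2a_rel` (adds a free ω2 class), `CmC` (clade model
C: the third class takes a separate ω2 in each clade partition) and
`branchsiteA` (the foreground gains a ω2 ≥ 1 class; null M1a). Both the
"M2a_rel" and "M2a_ref" spellings are accepted. κ is always a free ML
parameter. Branch lengths are estimated jointly under M0 and then held
fixed for the richer families — the standard desk-scale compromise; pass
`branchLengths` explicitly to reuse or replace them. Optimization is
bounded quasi-Newton (L-BFGS-B) over log-transformed rates and
logit/softmax-transformed proportions, run from every start in
`omegaStarts` with each start's final log-likelihood recorded. The default
grids follow the multi-start practice for the mixture models
(0.001–10 for clade model C, 1.25–10 for branch-site A); the simple
families default to a two-point grid because their likelihood surfaces are
effectively unimodal in ω.

`likelihoodRatioTest()` compares nested fits with 2ΔlnL against a
chi-square. Degrees of freedom default to the difference in *model*
parameter counts, excluding the shared fixed branch lengths (branch2 vs M0:
1; CmC vs M2a_rel: one per extra clade, i.e. 1 for two clades; branch-site
A vs M1a: 2). Published tables occasionally state a different df than the
parameter count implies, so a per-test override exists. A statistic below
zero beyond tolerance flags an optimization failure instead of being
hidden. `bhAdjust()` applies Benjamini–Hochberg step-up correction when
several clades or genes are tested.

## Type-I functional divergence

`estimateType1Divergence()` follows the classic two-cluster design:
per-column substitution counts are computed within each paralog cluster by
Fitch parsimony on the pruned cluster tree (unknown residues act as
wildcards); an ML option for the counts is a deliberate non-goal since
parsimony counts are the classic input. Counts are modeled as Poisson with
a gamma-distributed rate of unit mean: with probability θ a column draws
independent rates in the two clusters, otherwise one shared rate. Both
mixture components integrate to closed-form negative-binomial expressions,
so θ and the gamma shape are maximized jointly by ML (method-of-moments
shape as the start); the shape is re-profiled under the θ = 0 null so the
LRT keeps one degree of freedom. Per-column posteriors of divergence follow
from Bayes' rule at the ML estimates, and a column-resampling bootstrap
(500 replicates by default) gives the standard error of θ.

`selectDivergentSites()` implements the iterative cutoff procedure:
posteriors are sorted descending and the top column is removed and the
model refit (same tree, re-estimated θ, shape and count means) until the
LRT p-value exceeds α = 0.05; the removed columns are the selected sites
and the highest remaining original posterior is the reported cutoff. The
tree is kept fixed across refits; pruning it per iteration would conflate
rate divergence with taxon sampling.

## Synthetic data and what passing tests mean

All generators are pure functions of (parameters, seed); one user seed
fans out into independent per-generator streams, and every dataset ships
with machine-readable truth (`writeSimulationTruth()`).

* `simulateCodonAlignment()` draws root codons from π and evolves them by
  sampling from exp(Q_c t) per branch and site class, so stop codons never
  occur. It emulates rate structure, not indels or alignment error.
* `simulateWgdGeneOrders()` duplicates an ancestral order, drops each gene
  copy independently (`retention` per copy), and applies random segment
  inversions/translocations (geometric segment lengths, mean ≈ 12 genes)
  to one region, with exact outgroup anchors. It does not emulate tandem
  duplications, anchor noise or missing annotations.
* `simulateDivergentClusters()` evolves residues under a uniform 20-state
  exchangeability model with gamma rates shared or independent per column.
  It is adequate for rate-divergence recovery, not a claim about real
  substitution matrices.
* `simulateHitTable()` plants mutually-best hit structure with optional
  decoys that demote the true ortholog to forward rank 2.

Validation therefore shows that the engines compute their definitions
correctly and recover planted parameters under matched generative
assumptions; it does not certify behavior under alignment error, codon
usage bias beyond π, indels, or annotation noise.

## Problem sizes and study conditions used in the validation suite

The packaged checks run at deliberate desk scale: NG86 oracle equivalence
on 200 random 10-codon pairs; pruning verified against a two-taxon closed
form and an exhaustive 61² state sum on four taxa; M0 recovery of ω = 0.2
on 8 taxa × 300 codons (±0.05) and two-ratio recovery of ω_fg = 0.25 /
ω_bg = 0.05 within 50% relative error; LRT calibration from 200 null
simulations of 6 taxa × 100 codons (type-I error in [0.01, 0.10] at
α = 0.05), run single-start since the M0/branch2 surfaces are unimodal;
synteny recovery on 1,000 ancestral genes at retention 0.3 with two
inversions (precision and recall ≥ 0.9); divergence recovery with
θ = 0.4 over 500 columns (±0.15) on two 16-tip clusters — cluster sizes
chosen to match the scale of real vertebrate paralog subfamilies, since
parsimony counts on very small clusters carry little rate information —
and a 50-replicate null holding its level. `scripts/acceptance.R` recomputes
all of these from scratch under a caller-supplied seed.

## Known limitations

* Exact numerical parity with codeml or DIVERGE is not a goal; those
  programs make internal choices (branch-length co-estimation, rate
  grids) that published papers rarely pin down.
* The NG86 module intentionally omits Li–Wu–Luo-style codon-usage-weighted
  site counting and Kimura-corrected variants.
* Branch-site inference reports class posteriors only; no Bayes empirical
  Bayes site identification.
* The divergence estimator's θ is mildly conservative on short trees,
  where parsimony compresses high counts; larger clusters reduce the bias.
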