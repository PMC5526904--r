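## Config-driven orchestration of the analysis stages (screen -> synteny ->
## rates -> codon-model LRTs -> divergence) with logging, per-stage TSV
## reports and a manifest.

.pipelineDefaults <- function() list(
  seq_e_max = 1e-2, dom_e_max = 1e-2, min_coverage = 0.5,
  identity_min = 0.95, short_coverage_min = 0.6,
  ortholog_e_max = 1e-3, anchor_e_max = 1e-10,
  window_size = 100, min_pairs = 3,
  omega_mode = "ratio_of_means",
  models = c("M0", "branch2"), omega_starts = NULL,
  alpha = 0.05, n_bootstrap = 100)

.knownConfigKeys <- list(
  top = c("seed", "out_dir", "stages", "inputs", "params"),
  stages = c("screen", "synteny", "rates", "codonml", "divergence"),
  inputs = c("domtblout", "sequences", "forward_hits", "reverse_hits",
             "query_ids", "loci_a", "loci_b", "families", "outgroup_hits",
             "codon_alignment", "clades", "partitions", "reference_id",
             "tree", "protein_alignment", "protein_tree", "cluster_a",
             "cluster_b"))

#' Run the analysis pipeline from a configuration
#'
#' Executes the enabled stages in dependency order, writing per-stage TSV
#' tables, a run log and a JSON manifest under the output directory.
#' Thresholds default to the screening/anchoring/model values documented in
#' the stage functions and can all be overridden under \code{params}.
#'
#' @param config path to a YAML/JSON config file, or an equivalent named
#'   list with entries seed, out_dir, stages, inputs, params.
#' @return (invisibly) the manifest as a named list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) jsonlite::read_json(config,
      simplifyVector = TRUE) else yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), .knownConfigKeys$top)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  unknown <- setdiff(names(config$stages), .knownConfigKeys$stages)
  if (length(unknown)) stop("unknown stage keys: ", paste(unknown, collapse = ", "))
  unknown <- setdiff(names(config$inputs), .knownConfigKeys$inputs)
  if (length(unknown)) stop("unknown input keys: ", paste(unknown, collapse = ", "))
  params <- modifyList(.pipelineDefaults(), config$params %||% list())
  unknown <- setdiff(names(params), names(.pipelineDefaults()))
  if (length(unknown)) stop("unknown params: ", paste(unknown, collapse = ", "))
  outDir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  inputs <- config$inputs %||% list()
  logPath <- file.path(outDir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "", file = logPath,
                               append = TRUE)
  cat("", file = logPath)
  logLine("OhnologEvo pipeline, package version %s",
          as.character(utils::packageVersion("OhnologEvo")))
  logLine("seed: %d", as.integer(seed))
  logLine("params: %s", jsonlite::toJSON(params, auto_unbox = TRUE))
  outputs <- character(0)
  needFile <- function(key, stage) {
    p <- inputs[[key]]
    if (is.null(p)) stop(sprintf("stage '%s': missing input '%s'", stage, key))
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop(sprintf("stage '%s': input file not found: %s", stage, p))
    p
  }
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, name)
    logLine("wrote %s (%d rows)", name, nrow(df))
  }
  runStage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) { logLine("stage %s: skipped", name); return() }
    logLine("stage %s: start", name)
    set.seed(.generatorSeed(seed, paste0("stage_", name)))
    tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(outDir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logLine("stage %s: done", name)
  }

  runStage("screen", config$stages$screen, function() {
    if (!is.null(inputs$domtblout)) {
      hits <- readDomtblout(needFile("domtblout", "screen"))
      kept <- filterDomainHits(hits, params$seq_e_max, params$dom_e_max,
                               params$min_coverage)
      emit(kept, "kept_domain_hits.tsv")
    }
    if (!is.null(inputs$sequences)) {
      seqs <- readFasta(needFile("sequences", "screen"), "protein")
      emit(clusterRedundantSequences(seqs, params$identity_min,
                                     params$short_coverage_min),
           "clusters.tsv")
    }
    if (!is.null(inputs$forward_hits)) {
      fw <- read.table(needFile("forward_hits", "screen"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
      rvp <- read.table(needFile("reverse_hits", "screen"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
      qs <- inputs$query_ids %||% unique(fw$query_id)
      orth <- do.call(rbind, lapply(qs, function(q) {
        subj <- assignOrthologs(q, fw, rvp, params$ortholog_e_max)
        if (length(subj)) data.frame(query_id = q, ortholog_id = subj,
                                     stringsAsFactors = FALSE) else NULL
      }))
      if (is.null(orth)) orth <- data.frame(query_id = character(),
                                            ortholog_id = character())
      emit(orth, "orthologs.tsv")
    }
  })

  runStage("synteny", config$stages$synteny, function() {
    readLoci <- function(key) {
      p <- needFile(key, "synteny")
      if (grepl("[.]bed$", p)) readGeneLociBed(p)
      else if (grepl("[.]gff3?$", p)) readGeneLociGff(p)
      else read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    }
    lociA <- readLoci("loci_a")
    lociB <- readLoci("loci_b")
    fam <- read.table(needFile("families", "synteny"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
    if (!is.null(inputs$outgroup_hits)) {
      og <- read.table(needFile("outgroup_hits", "synteny"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
      fam <- anchorParalogFamilies(fam, og, params$anchor_e_max)
      emit(fam, "anchored_families.tsv")
    }
    blocks <- detectSyntenicBlocks(lociA, lociB, fam,
                                   params$window_size, params$min_pairs)
    emit(syntenyBlocks(blocks), "synteny_blocks.tsv")
    emit(syntenyPairs(blocks), "synteny_block_pairs.tsv")
  })

  runStage("rates", config$stages$rates, function() {
    aln <- codonAlignment(readFasta(needFile("codon_alignment", "rates"), "dna"))
    clades <- read.table(needFile("clades", "rates"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
    members <- split(clades$id, clades$clade)
    partitions <- if (!is.null(inputs$partitions))
      read.table(needFile("partitions", "rates"), header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE) else NULL
    emit(cladeRateSummary(aln, members, partitions,
                          inputs$reference_id, params$omega_mode),
         "clade_rates.tsv")
  })

  runStage("codonml", config$stages$codonml, function() {
    aln <- codonAlignment(readFasta(needFile("codon_alignment", "codonml"), "dna"))
    gt <- readGeneTree(needFile("tree", "codonml"))
    fits <- list()
    fits$M0 <- fitCodonModel(aln, gt, "M0",
                             omegaStarts = params$omega_starts %||% c(0.2, 1))
    rows <- list(); tests <- list()
    addFit <- function(f) {
      est <- mlEstimates(f)
      est$branch_lengths <- NULL
      rows[[length(rows) + 1L]] <<- data.frame(
        model = f@family, lnL = logLik2(f), n_free = f@nFreeParams,
        parameters = jsonlite::toJSON(est, auto_unbox = TRUE, digits = 6),
        winning_start = f@spec$winning_start, stringsAsFactors = FALSE)
      logLine("model %s: lnL %.4f (winning omega start %.3g)",
              f@family, logLik2(f), f@spec$winning_start)
    }
    addFit(fits$M0)
    wantsBranch <- any(c("branch2", "CmC", "branchsiteA") %in% params$models)
    if (wantsBranch && length(unique(branchClasses(gt))) < 2L)
      stop("codonml: tree has no foreground/clade branch marks")
    if ("branch2" %in% params$models) {
      fits$branch2 <- fitCodonModel(aln, gt, "branch2",
        omegaStarts = params$omega_starts %||% c(0.2, 1),
        branchLengths = fits$M0)
      addFit(fits$branch2)
      tests$branch2_vs_M0 <- likelihoodRatioTest(fits$M0, fits$branch2)
    }
    if ("CmC" %in% params$models) {
      fits$M2a_rel <- fitCodonModel(aln, gt, "M2a_rel",
        omegaStarts = params$omega_starts, branchLengths = fits$M0)
      addFit(fits$M2a_rel)
      fits$CmC <- fitCodonModel(aln, gt, "CmC",
        omegaStarts = params$omega_starts, branchLengths = fits$M0)
      addFit(fits$CmC)
      tests$CmC_vs_M2a_rel <- likelihoodRatioTest(fits$M2a_rel, fits$CmC)
    }
    if ("branchsiteA" %in% params$models) {
      fits$M1a <- fitCodonModel(aln, gt, "M1a",
        omegaStarts = params$omega_starts, branchLengths = fits$M0)
      addFit(fits$M1a)
      fits$branchsiteA <- fitCodonModel(aln, gt, "branchsiteA",
        omegaStarts = params$omega_starts, branchLengths = fits$M0)
      addFit(fits$branchsiteA)
      tests$branchsiteA_vs_M1a <- likelihoodRatioTest(fits$M1a,
                                                      fits$branchsiteA)
    }
    emit(do.call(rbind, rows), "model_fits.tsv")
    if (length(tests)) {
      tt <- do.call(rbind, lapply(names(tests), function(nm) data.frame(
        test = nm, null = tests[[nm]]$null, alt = tests[[nm]]$alt,
        stat = tests[[nm]]$stat, df = tests[[nm]]$df,
        p = tests[[nm]]$p_value, stringsAsFactors = FALSE)))
      tt$p_adjusted <- bhAdjust(tt$p)
      emit(tt, "model_lrt.tsv")
    }
  })

  runStage("divergence", config$stages$divergence, function() {
    aln <- readFasta(needFile("protein_alignment", "divergence"), "protein")
    tr <- ape::read.tree(needFile("protein_tree", "divergence"))
    res <- estimateType1Divergence(as.character(aln), tr,
                                   unlist(inputs$cluster_a),
                                   unlist(inputs$cluster_b),
                                   nBootstrap = params$n_bootstrap)
    res <- selectDivergentSites(res, params$alpha)
    emit(data.frame(theta = res@theta, se = res@se, lrt = res@lrtStat,
                    p = res@pValue, cutoff = res@cutoff,
                    n_selected = length(res@selectedSites)),
         "divergence_summary.tsv")
    emit(data.frame(column = seq_along(res@posteriors),
                    posterior = res@posteriors,
                    selected = seq_along(res@posteriors) %in% res@selectedSites),
         "divergence_posteriors.tsv")
  })

  manifest <- list(
    package = "OhnologEvo",
    version = as.character(utils::packageVersion("OhnologEvo")),
    seed = as.integer(seed),
    params = params,
    outputs = as.list(setNames(unname(tools::md5sum(file.path(outDir, outputs))),
                               outputs)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logLine("manifest written (%d outputs)", length(outputs))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a self-contained synthetic demo configuration
#'
#' Generates synthetic inputs for every stage (hit tables, gene orders with
#' a planted WGD, a codon alignment evolved under a two-ratio model, and
#' divergent protein clusters), writes them plus their ground truth under
#' \code{dir}, and returns the path of a ready-to-run config file.
#'
#' @param dir directory for inputs, outputs and the config.
#' @param seed integer seed used for every generator.
#' @return path to the written YAML config.
#' @export
demoPipelineConfig <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inDir <- file.path(dir, "inputs")
  dir.create(inDir, showWarnings = FALSE)

  ## screening inputs
  hits <- simulateHitTable(8, 10, noiseHits = 2,
                           rankTwoQueries = "q2", seed = seed)
  write.table(hits$forward, file.path(inDir, "forward_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(hits$reverse, file.path(inDir, "reverse_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeSimulationTruth(hits$truth, file.path(inDir, "hits_truth.json"))

  ## synteny inputs
  wgd <- simulateWgdGeneOrders(200, retention = 0.5, nInversions = 1,
                               nTranslocations = 0, seed = seed)
  write.table(wgd$regionA, file.path(inDir, "loci_a.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(wgd$regionB, file.path(inDir, "loci_b.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(wgd$families, file.path(inDir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeSimulationTruth(wgd$truth, file.path(inDir, "wgd_truth.json"))

  ## codon alignment on a two-clade tree with a foreground mark
  nw <- "(((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1)#1:0.05,((t5:0.1,t6:0.1):0.1,(t7:0.1,t8:0.1):0.1):0.05);"
  gt <- readGeneTree(nw)
  spec <- codonModelSpec(kappa = 2,
    omega = matrix(c(0.05, 0.3), 1, 2,
                   dimnames = list(NULL, c("background", "foreground"))))
  sim <- simulateCodonAlignment(gt, spec, 200, seed = seed)
  writeFasta(alignedSeqs(sim$alignment), file.path(inDir, "codon_aln.fasta"))
  writeLines(nw, file.path(inDir, "tree.nwk"))
  writeSimulationTruth(sim$truth, file.path(inDir, "codon_truth.json"))
  clades <- data.frame(id = paste0("t", 1:8),
                       clade = rep(c("cladeA", "cladeB"), each = 4))
  write.table(clades, file.path(inDir, "clades.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## divergent protein clusters
  ta <- makeBalancedTree("a", 10)
  tb <- makeBalancedTree("b", 10)
  div <- simulateDivergentClusters(ta, tb, 300, theta = 0.4, shape = 0.6,
                                   seed = seed)
  writeFasta(div$alignment, file.path(inDir, "protein_aln.fasta"))
  joint <- sprintf("(%s:0.3,%s:0.3);", sub(";$", "", ta), sub(";$", "", tb))
  writeLines(joint, file.path(inDir, "protein_tree.nwk"))
  writeSimulationTruth(div$truth, file.path(inDir, "divergence_truth.json"))

  cfg <- list(
    seed = as.integer(seed),
    out_dir = file.path(dir, "out"),
    stages = list(screen = TRUE, synteny = TRUE, rates = TRUE,
                  codonml = TRUE, divergence = TRUE),
    inputs = list(
      forward_hits = file.path(inDir, "forward_hits.tsv"),
      reverse_hits = file.path(inDir, "reverse_hits.tsv"),
      loci_a = file.path(inDir, "loci_a.tsv"),
      loci_b = file.path(inDir, "loci_b.tsv"),
      families = file.path(inDir, "families.tsv"),
      codon_alignment = file.path(inDir, "codon_aln.fasta"),
      clades = file.path(inDir, "clades.tsv"),
      tree = file.path(inDir, "tree.nwk"),
      protein_alignment = file.path(inDir, "protein_aln.fasta"),
      protein_tree = file.path(inDir, "protein_tree.nwk"),
      cluster_a = paste0("a", 1:10),
      cluster_b = paste0("b", 1:10)),
    params = list(n_bootstrap = 50))
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  cfgPath
}
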