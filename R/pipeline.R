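## End-to-end orchestration: motif -> shape -> similarity -> covariation
## (affinity optional), with TSV outputs and a JSON manifest.

#' Pipeline run configuration
#'
#' Bundles input locations, thresholds and seeds.  Inputs are either file
#' paths (aligned protein FASTA, a directory of per-protein E-score TSVs,
#' a pentamer shape-table TSV) or \code{simulate = TRUE}, in which case a
#' synthetic cohort is generated from \code{spec}.
#'
#' @param cohortFasta,escoreDir,shapeTableTsv input paths (ignored when
#'   simulating).
#' @param simulate logical; generate inputs with
#'   \code{\link{simulateCohort}}.
#' @param spec \code{\link{CovariationSpec}} used when simulating.
#' @param escoreThreshold 8-mer selection threshold (default 0.45).
#' @param narrowThreshold narrow-MGW call threshold, angstrom (default
#'   5.12); \code{sensitivityThresholds} rerun the maps at other cutoffs.
#' @param nShuffles shuffle-null size (default 1000).
#' @param runAffinity logical; fit the cross-validated affinity models.
#' @param cvFolds,cvRepeats,affinityKmers affinity model layout (defaults
#'   10 folds, 50 repeats, the 1024 best-scoring placed 8-mers).
#' @param seed master seed.
#' @param outputDir directory for outputs.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(cohortFasta = NULL, escoreDir = NULL,
                      shapeTableTsv = NULL, simulate = is.null(cohortFasta),
                      spec = covariationSpec(), escoreThreshold = 0.45,
                      narrowThreshold = 5.12,
                      sensitivityThresholds = c(4.9, 5.0, 5.1, 5.2),
                      nShuffles = 1000L, runAffinity = FALSE,
                      cvFolds = 10L, cvRepeats = 50L, affinityKmers = 1024L,
                      seed = 1L, outputDir = tempfile("shapecovar_run_")) {
  cfg <- list(cohortFasta = cohortFasta, escoreDir = escoreDir,
              shapeTableTsv = shapeTableTsv, simulate = simulate, spec = spec,
              escoreThreshold = escoreThreshold,
              narrowThreshold = narrowThreshold,
              sensitivityThresholds = sensitivityThresholds,
              nShuffles = as.integer(nShuffles), runAffinity = runAffinity,
              cvFolds = as.integer(cvFolds), cvRepeats = as.integer(cvRepeats),
              affinityKmers = as.integer(affinityKmers),
              seed = as.integer(seed), outputDir = outputDir)
  class(cfg) <- "RunConfig"
  cfg
}

.readEscoreDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no E-score tables (*.tsv) found in ", dir)
  out <- lapply(files, readEscoreTable)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' Run the covariation pipeline
#'
#' Executes the stages in dependency order: 8-mer selection and consensus
#' alignment, PFM construction, shape profiling, the three similarity
#' families (protein full/tail/helix, DNA PFM, four shape parameters),
#' matrix-level correlations with shuffle nulls and the binned control, and
#' the position-level hypergeometric/MI maps (optionally the affinity
#' models).  All outputs are written under \code{config$outputDir} together
#' with a manifest recording parameters, seeds and skipped-record counts;
#' reruns with the same config reproduce identical numeric outputs.
#'
#' @param config a \code{\link{runConfig}} list.
#' @return invisibly, a list with every intermediate and result object.
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- inputs ------------------------------------------------------------
  if (config$simulate) {
    sim <- stage("simulate", simulateCohort(config$spec))
    cohort <- sim$cohort
    escoreTables <- lapply(seq_len(ncol(sim$escores)),
                           function(i) sim$escores[, i])
    names(escoreTables) <- colnames(sim$escores)
    shapeTable <- sim$shapeTable
  } else {
    for (p in c(config$cohortFasta, config$escoreDir, config$shapeTableTsv))
      if (is.null(p) || !file.exists(p))
        stop("input path missing or unreadable: ",
             if (is.null(p)) "(not set)" else p)
    cohort <- stage("load_cohort", readProteinCohort(config$cohortFasta))
    escoreTables <- stage("load_escores", .readEscoreDir(config$escoreDir))
    shapeTable <- stage("load_shape_table", readShapeTable(config$shapeTableTsv))
    escoreTables <- escoreTables[names(cohort@msa)]
    if (anyNA(names(escoreTables)))
      stop("E-score tables missing for some cohort proteins")
  }
  ids <- names(cohort@msa)

  ## ---- motif + shape stages ---------------------------------------------
  nDropped <- integer(0)
  sites <- stage("motif", lapply(ids, function(id) {
    sel <- selectKmers(escoreTables[[id]], config$escoreThreshold)
    bs <- suppressMessages(alignToConsensus(sel, proteinId = id))
    nDropped[[id]] <<- attr(bs, "nDropped")
    bs
  }))
  names(sites) <- ids
  pfms <- stage("pfm", lapply(sites, buildPFM))
  profiles <- stage("shape", lapply(sites, function(bs)
    averageShapeProfile(bs, shapeTable)))

  ## ---- similarities ------------------------------------------------------
  subMat <- blosum45()
  protSim <- stage("similarity", proteinSimilarity(cohort, subMat))
  regionSims <- lapply(names(cohort@regions), function(r)
    proteinSimilarity(cohort, subMat, region = r))
  names(regionSims) <- names(cohort@regions)
  pfmSim <- stage("similarity", pfmSimilarity(pfms))
  shapeSims <- lapply(c("MGW", "ProT", "Roll", "HelT"), function(p)
    suppressMessages(shapeSimilarity(profiles, p)))
  names(shapeSims) <- c("MGW", "ProT", "Roll", "HelT")

  ## ---- covariation -------------------------------------------------------
  others <- c(list(dna_pfm = pfmSim), shapeSims)
  correlations <- stage("covary", lapply(others, function(o) matrixPCC(protSim, o)))
  nulls <- stage("covary", lapply(seq_along(others), function(i)
    shuffleNull(protSim, others[[i]], nShuffles = config$nShuffles,
                seed = config$seed + i)))
  names(nulls) <- names(others)
  binned <- stage("covary", binnedPCC(protSim, pfmSim, seed = config$seed))
  calls <- callNarrowGroove(profiles, config$narrowThreshold)
  maps <- stage("covary", covariationMaps(cohort, calls))
  sensitivity <- lapply(config$sensitivityThresholds, function(th)
    covariationMaps(cohort, callNarrowGroove(profiles, th)))
  names(sensitivity) <- sprintf("%.2f", config$sensitivityThresholds)

  ## ---- affinity (optional) ----------------------------------------------
  affinity <- NULL
  if (config$runAffinity) {
    affinity <- stage("affinity", lapply(ids, function(id) {
      esc <- escoreTables[[id]]
      canon <- selectKmers(esc, threshold = min(esc, na.rm = TRUE))  # all, collapsed
      canon <- canon[seq_len(min(nrow(canon), config$affinityKmers)), ]
      bs <- suppressMessages(alignToConsensus(canon, proteinId = id))
      fx <- featurize(bs, shapeTable, seed = config$seed)
      lapply(c("seq", "seq+shape", "seq+shuffled-shape"), function(v)
        fitAffinityCV(fx, variant = v, folds = config$cvFolds,
                      repeats = config$cvRepeats, seed = config$seed))
    }))
    names(affinity) <- ids
  }

  ## ---- outputs -----------------------------------------------------------
  od <- config$outputDir
  writeProteinCohort(cohort, file.path(od, "cohort.fasta"))
  writeShapeTable(shapeTable, file.path(od, "shape_table.tsv"))
  writeMemePFM(pfms, file.path(od, "pfms.meme"))
  writeSimilarityMatrix(protSim, file.path(od, "similarity_protein.tsv"))
  writeSimilarityMatrix(pfmSim, file.path(od, "similarity_dna_pfm.tsv"))
  for (p in names(shapeSims))
    writeSimilarityMatrix(shapeSims[[p]],
                          file.path(od, sprintf("similarity_shape_%s.tsv", tolower(p))))
  writeCovariationMaps(maps, od)
  profTab <- do.call(rbind, lapply(profiles, function(pr) {
    L <- length(pr@mgw)
    data.frame(protein_id = pr@proteinId,
               position = c(seq_len(L), seq_len(L), seq_len(L - 1), seq_len(L - 1)),
               parameter = rep(c("MGW", "ProT", "Roll", "HelT"), c(L, L, L - 1, L - 1)),
               value = c(pr@mgw, pr@prot, pr@roll, pr@helt),
               n_sites = pr@nSites)
  }))
  utils::write.table(profTab, file.path(od, "shape_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  corrTab <- data.frame(
    comparison = names(correlations),
    pcc = vapply(correlations, `[[`, numeric(1), "pcc"),
    p = vapply(correlations, `[[`, numeric(1), "p"),
    null_mean = vapply(nulls, `[[`, numeric(1), "mean"),
    shuffle_p = vapply(nulls, `[[`, numeric(1), "p"))
  utils::write.table(corrTab, file.path(od, "matrix_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "ShapeCovar",
    version = as.character(utils::packageVersion("ShapeCovar")),
    seed = config$seed, simulate = config$simulate,
    escoreThreshold = config$escoreThreshold,
    narrowThreshold = config$narrowThreshold,
    sensitivityThresholds = config$sensitivityThresholds,
    nShuffles = config$nShuffles,
    nProteins = length(ids),
    nSitesPerProtein = vapply(sites, function(s) length(s@sequence), integer(1)),
    nKmersDropped = nDropped,
    runAffinity = config$runAffinity)
  if (config$simulate)
    manifest$spec <- list(seed = config$spec@seed,
                          nProteins = config$spec@nProteins,
                          tailColumn = config$spec@tailColumn,
                          mgwShift = config$spec@mgwShift,
                          shapeEffectWeight = config$spec@shapeEffectWeight)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, sites = sites, pfms = pfms,
                 profiles = profiles, shapeTable = shapeTable,
                 proteinSimilarity = protSim, regionSimilarities = regionSims,
                 pfmSimilarity = pfmSim, shapeSimilarities = shapeSims,
                 correlations = correlations, shuffleNulls = nulls,
                 binned = binned, calls = calls, maps = maps,
                 sensitivity = sensitivity, affinity = affinity,
                 outputDir = od))
}
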