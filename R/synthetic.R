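## Synthetic cohorts with planted sequence/shape covariation, and a synthetic
## pentamer shape table.  The generator emulates the statistical structure the
## analysis assumes: an aligned TF family whose members carrying a basic
## residue at one N-terminal-tail column prefer binding sites with a narrower
## minor groove at chosen positions.

#' Simulate a pentamer shape table
#'
#' Builds a revcomp-consistent table over the 512 canonical pentamers with
#' B-DNA-plausible ranges.  MGW is the 5.8 angstrom B-DNA reference minus
#' \code{atNarrowing} times the pentamer AT fraction (AT-tracts narrow the
#' minor groove; a GC-only pentamer stays at the reference) plus bounded
#' jitter (uniform on +/- 0.12 angstrom, so the AT ordering is strict
#' whenever \code{atNarrowing} exceeds about 0.25).  Propeller twist grows
#' more negative with AT content; Roll and HelT are drawn around canonical
#' B-DNA values.
#'
#' @param seed integer seed.
#' @param atNarrowing angstrom of MGW narrowing per unit AT fraction
#'   (default 0.8).
#' @return a \code{\link{ShapeTable}}.
#' @export
simulateShapeTable <- function(seed = NULL, atNarrowing = 0.8) {
  if (atNarrowing < 0) stop("atNarrowing must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pent <- canonicalPentamers()
  ch <- do.call(rbind, strsplit(pent, "", fixed = TRUE))
  atFrac <- rowMeans(ch == "A" | ch == "T")
  n <- length(pent)
  mgw <- 5.8 - atNarrowing * atFrac + stats::runif(n, -0.12, 0.12)
  prot <- -6 - 8 * atFrac + stats::runif(n, -1.5, 1.5)
  ShapeTable(pent, MGW = mgw, ProT = prot,
             Roll1 = stats::rnorm(n, 2.0, 1.2), Roll2 = stats::rnorm(n, 2.0, 1.2),
             HelT1 = stats::rnorm(n, 34.5, 1.0), HelT2 = stats::rnorm(n, 34.5, 1.0))
}

#' Specification of a planted-covariation cohort
#'
#' Defaults describe the standard validation cohort: 60 proteins, arginine
#' planted at tail column 5 in half of them, and a 0.5 angstrom minor-groove
#' narrowing at binding-site positions 4 and 5 of the carriers' preferred
#' sites.
#'
#' @param nProteins cohort size (>= 4).
#' @param tailColumn protein alignment column carrying the planted residue.
#' @param plantedResidues residues planted in carriers.
#' @param affectedPositions binding-site frame positions that narrow.
#' @param mgwShift angstrom; negative narrows.
#' @param motifCore IUPAC 5-mer core of high-affinity sites.
#' @param escoreNoiseSd sd of per-protein latent-affinity noise (latent
#'   units; one core mismatch costs 1).
#' @param shapeEffectWeight weight of the planted shape term, latent units
#'   per squared angstrom of deviation from the target MGW.
#' @param seed integer seed.
#' @return a \code{\link{CovariationSpec}}.
#' @export
covariationSpec <- function(nProteins = 60L, tailColumn = 5L,
                            plantedResidues = "R",
                            affectedPositions = c(4L, 5L), mgwShift = -0.5,
                            motifCore = "NNAYN", escoreNoiseSd = 0.25,
                            shapeEffectWeight = 8, seed = 1L) {
  methods::new("CovariationSpec", nProteins = as.integer(nProteins),
               tailColumn = as.integer(tailColumn),
               plantedResidues = plantedResidues,
               affectedPositions = as.integer(affectedPositions),
               mgwShift = mgwShift, motifCore = toupper(motifCore),
               escoreNoiseSd = escoreNoiseSd,
               shapeEffectWeight = shapeEffectWeight, seed = as.integer(seed))
}

## 60-residue homeodomain-like consensus used as the MSA backbone
## (three-helix domain: flexible basic tail, helix 3 = recognition helix).
.hdConsensus <- function() {
  paste0("MRKRGRQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALGLTERQIKIWF",
         "QNRRMKWKKE")  # 60 aa
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

## Best-placement core statistics for every canonical 8-mer:
## minimum IUPAC mismatch count to the 5-mer core over 4 offsets x 2 strands,
## and the mean table MGW at the affected frame positions under the best
## placement (the core is anchored at frame positions 3-7).
.kmerCoreStats <- function(kmers, core, affectedPositions, table) {
  k <- nchar(kmers[1])
  chars <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  rck <- revComp(kmers)
  charsRC <- do.call(rbind, strsplit(rck, "", fixed = TRUE))
  pat <- strsplit(core, "", fixed = TRUE)[[1]]
  sets <- .iupacSets[pat]
  if (anyNA(names(sets))) stop("unknown IUPAC code in motifCore: ", core)

  n <- length(kmers)
  bestD <- rep(Inf, n); bestJ <- integer(n); bestStrand <- character(n)
  for (strand in c("+", "-")) {
    cm <- if (strand == "+") chars else charsRC
    for (j in seq_len(k - 4L)) {
      mm <- rep(0L, n)
      for (p in 1:5) mm <- mm + !(cm[, j + p - 1L] %in% sets[[p]])
      better <- mm < bestD  # strict: ties keep plus strand / leftmost j
      bestD[better] <- mm[better]
      bestJ[better] <- j
      bestStrand[better] <- strand
    }
  }
  oriented <- ifelse(bestStrand == "+", kmers, rck)
  ## frame position f maps to k-mer position q = f + j - 3 (core at frame 3-7);
  ## one MGW column per affected position (NA where the pentamer leaves the k-mer)
  mgw <- matrix(NA_real_, n, length(affectedPositions))
  for (ix in seq_along(affectedPositions)) {
    q <- affectedPositions[ix] + bestJ - 3L
    okq <- q >= 3L & q <= k - 2L
    if (any(okq)) {
      pents <- substr(oriented[okq], q[okq] - 2L, q[okq] + 2L)
      mgw[okq, ix] <- .pentamerRows(table, pents)[, "MGW"]
    }
  }
  list(d = bestD, mgwAffected = mgw, strand = bestStrand, j = bestJ)
}

#' Simulate a protein cohort with planted sequence/shape covariation
#'
#' Generates a gapless ~60-column protein MSA and a complete per-protein
#' 8-mer E-score table over the 32,896 strand-collapsed 8-mers.  Proteins
#' split into carriers and non-carriers of the planted residue at the tail
#' column; two protein subfamilies (aligned with carrier status, as in real
#' TF families where tail composition tracks subfamily) differ at a set of
#' non-basic marker columns followed with probability 0.8, over a
#' background of sparse random substitutions.
#'
#' Latent affinity of an 8-mer is minus its best-placement mismatch count to
#' the core motif; carriers additionally gain
#' \code{shapeEffectWeight} times the negative mean squared deviation of the
#' site's table MGW at each affected position from that position's target
#' (its core-match average \code{mu0} plus \code{mgwShift}), pulling their
#' high-affinity sites toward pentamer contexts with the planted narrowing
#' (the shape signal flows only through the pentamer table, so sequence and
#' shape channels stay separable).  Per-protein Gaussian noise
#' is added and E-scores are obtained by rank-transforming the latent
#' affinities onto a symmetric Beta(2,2) distribution on [-0.5, 0.5], which
#' leaves roughly 240 8-mers per protein at or above the 0.45 selection
#' threshold.
#'
#' @param spec a \code{\link{CovariationSpec}}.
#' @param shapeTable optional \code{\link{ShapeTable}}; simulated from the
#'   spec seed when absent.
#' @return list with \code{cohort} (\code{\link{ProteinCohort}}),
#'   \code{escores} (k-mer x protein matrix), \code{shapeTable},
#'   \code{carriers} (logical), \code{mu0} and \code{spec}.
#' @export
simulateCohort <- function(spec = covariationSpec(), shapeTable = NULL) {
  methods::validObject(spec)
  set.seed(spec@seed)
  if (is.null(shapeTable)) shapeTable <- simulateShapeTable(seed = spec@seed + 1000L)
  n <- spec@nProteins
  ids <- sprintf("HD%03d", seq_len(n))
  carriers <- rep(c(TRUE, FALSE), length.out = n)

  ## ---- protein MSA -------------------------------------------------------
  cons <- strsplit(.hdConsensus(), "", fixed = TRUE)[[1]]
  W <- length(cons)
  markerCols <- setdiff(seq(12L, 45L, by = 3L), spec@tailColumn)
  nonBasic <- setdiff(AA20, c("R", "K", "H"))
  ## subfamily markers must stay non-basic so they cannot masquerade as the
  ## planted basic-residue signal in the hypergeometric map
  basicMarker <- cons[markerCols] %in% c("R", "K", "H")
  cons[markerCols[basicMarker]] <- sample(nonBasic, sum(basicMarker), replace = TRUE)
  markerAlt <- vapply(markerCols, function(cc)
    sample(setdiff(nonBasic, cons[cc]), 1L), character(1))
  msa <- matrix(rep(cons, each = n), n, W)
  for (ix in seq_along(markerCols)) {
    cc <- markerCols[ix]
    subRes <- ifelse(carriers, cons[cc], markerAlt[ix])
    follow <- stats::runif(n) < 0.8
    other <- ifelse(carriers, markerAlt[ix], cons[cc])
    msa[, cc] <- ifelse(follow, subRes, other)
  }
  bgCols <- setdiff(seq_len(W), c(spec@tailColumn, markerCols))
  for (cc in bgCols) {
    hit <- stats::runif(n) < 0.08
    if (any(hit)) msa[hit, cc] <- sample(AA20, sum(hit), replace = TRUE)
  }
  tailNonBasic <- c("A", "S", "T", "Q", "N", "G")
  msa[, spec@tailColumn] <- ifelse(
    carriers, sample(spec@plantedResidues, n, replace = TRUE),
    sample(tailNonBasic, n, replace = TRUE))
  seqs <- apply(msa, 1L, paste0, collapse = "")
  names(seqs) <- ids
  cohort <- ProteinCohort(seqs)

  ## ---- E-score tables ----------------------------------------------------
  allK <- .pasteRows(.allKmerChars(8L))
  kmers <- sort(unique(canonicalKmer(allK)))
  st <- .kmerCoreStats(kmers, spec@motifCore, spec@affectedPositions, shapeTable)
  ## per-affected-position core-match baselines and narrowing targets
  mu0 <- colMeans(st$mgwAffected[st$d == 0, , drop = FALSE], na.rm = TRUE)
  target <- mu0 + spec@mgwShift
  ## a shift is infeasible when it asks for far more narrowing (or widening)
  ## than the table offers between the core-match baseline and its extreme
  rngMGW <- range(shapeValues(shapeTable)[, "MGW"])
  headroom <- if (spec@mgwShift <= 0) mu0 - rngMGW[1] else rngMGW[2] - mu0
  if (any(abs(spec@mgwShift) > 1.5 * pmax(headroom, 0)))
    stop("infeasible spec: mgwShift of ", sprintf("%.2f", spec@mgwShift),
         " A exceeds the shape table's available MGW headroom (",
         paste(sprintf("%.2f", headroom), collapse = ", "),
         " A from the core-match baseline to the table extreme)")
  dev2 <- sweep(st$mgwAffected, 2L, target)^2
  shapeTerm <- -rowMeans(dev2, na.rm = TRUE)
  shapeTerm[is.nan(shapeTerm)] <- -mean((.tableMeans(shapeTable)[["MGW"]] - target)^2)
  base <- -st$d
  nk <- length(kmers)
  escoreGrid <- stats::qbeta((seq_len(nk) - 0.5) / nk, 2, 2) - 0.5
  escores <- matrix(NA_real_, nk, n, dimnames = list(kmers, ids))
  for (i in seq_len(n)) {
    latent <- base +
      (if (carriers[i]) spec@shapeEffectWeight * shapeTerm else 0) +
      stats::rnorm(nk, 0, spec@escoreNoiseSd)
    escores[, i] <- escoreGrid[rank(latent, ties.method = "random")]
  }
  list(cohort = cohort, escores = escores, shapeTable = shapeTable,
       carriers = carriers, mu0 = mu0, spec = spec)
}

#' Write a simulated cohort in the pipeline's file dialects
#'
#' Emits the aligned protein FASTA, one E-score TSV per protein, the shape
#' table TSV and a JSON manifest recording the spec and seed.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeSyntheticBundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeProteinCohort(sim$cohort, file.path(dir, "cohort.fasta"))
  writeShapeTable(sim$shapeTable, file.path(dir, "shape_table.tsv"))
  edir <- file.path(dir, "escores")
  dir.create(edir, showWarnings = FALSE)
  for (id in colnames(sim$escores))
    writeEscoreTable(sim$escores[, id], file.path(edir, paste0(id, ".tsv")))
  spec <- sim$spec
  manifest <- list(
    generator = "ShapeCovar::simulateCohort",
    nProteins = spec@nProteins, tailColumn = spec@tailColumn,
    plantedResidues = spec@plantedResidues,
    affectedPositions = spec@affectedPositions, mgwShift = spec@mgwShift,
    motifCore = spec@motifCore, escoreNoiseSd = spec@escoreNoiseSd,
    shapeEffectWeight = spec@shapeEffectWeight, seed = spec@seed,
    synthetic = TRUE)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
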