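## S4 class definitions and validity methods.

#' ShapeTable: pentamer lookup of DNA structural parameters
#'
#' Holds, for each of the 512 canonical pentamers, the minor groove width
#' (MGW, angstrom) and propeller twist (ProT, degrees) assigned to the central
#' base, and the roll and helix twist (degrees) of the two central base-pair
#' steps. Non-canonical pentamers are resolved through reverse complementation
#' at query time (MGW/ProT unchanged; the two step values swap).
#'
#' @slot values numeric matrix, 512 x 6, rownames the canonical pentamers,
#'   columns \code{MGW, ProT, Roll1, Roll2, HelT1, HelT2}.
#' @export
setClass("ShapeTable", representation(values = "matrix"))

setValidity("ShapeTable", function(object) {
  v <- object@values
  msgs <- character(0)
  want <- c("MGW", "ProT", "Roll1", "Roll2", "HelT1", "HelT2")
  if (!identical(colnames(v), want))
    msgs <- c(msgs, paste("columns must be", paste(want, collapse = ", ")))
  canon <- canonicalPentamers()
  if (nrow(v) != 512L || !identical(sort(rownames(v)), canon))
    msgs <- c(msgs, "rownames must be exactly the 512 canonical pentamers")
  if (!all(is.finite(v)))
    msgs <- c(msgs, "all values must be finite")
  if (length(msgs) && any(grepl("finite", msgs)) == FALSE && !all(is.finite(v["MGW" %in% colnames(v)])))
    msgs <- msgs
  if (all(is.finite(v)) && "MGW" %in% colnames(v) && any(v[, "MGW"] <= 0))
    msgs <- c(msgs, "MGW must be positive everywhere")
  if (length(msgs)) msgs else TRUE
})

#' ShapeProfile: per-position average structural features of a binding-site set
#'
#' Base-pair parameters (MGW, ProT) are vectors over the L positions of the
#' binding-site frame; step parameters (Roll, HelT) are vectors over the L-1
#' steps. Positions with no pentamer coverage are \code{NA}, never silently
#' zero; coverage counts are retained.
#'
#' @slot proteinId character scalar.
#' @slot mgw,prot numeric length L (angstrom / degrees), NA where undefined.
#' @slot roll,helt numeric length L-1 (degrees), NA where undefined.
#' @slot nSites integer, number of sites averaged.
#' @slot bpCoverage integer length L, sites contributing per position.
#' @slot stepCoverage integer length L-1, sites contributing per step.
#' @export
setClass("ShapeProfile", representation(
  proteinId = "character", mgw = "numeric", prot = "numeric",
  roll = "numeric", helt = "numeric", nSites = "integer",
  bpCoverage = "integer", stepCoverage = "integer"))

setValidity("ShapeProfile", function(object) {
  L <- length(object@mgw)
  msgs <- character(0)
  if (length(object@prot) != L) msgs <- c(msgs, "prot must have length L")
  if (length(object@roll) != L - 1L || length(object@helt) != L - 1L)
    msgs <- c(msgs, "roll/helt must have length L-1")
  if (length(object@bpCoverage) != L || length(object@stepCoverage) != L - 1L)
    msgs <- c(msgs, "coverage vectors must match L and L-1")
  if (any(!is.na(object@mgw) & object@mgw <= 0))
    msgs <- c(msgs, "defined MGW values must be positive")
  if (length(msgs)) msgs else TRUE
})

#' SimilarityMatrix: symmetric pairwise score matrix over proteins
#'
#' @slot values symmetric numeric matrix with identical row/col labels.
#' @slot metricName one of \code{protein_blosum}, \code{dna_pfm_pcc},
#'   \code{shape_mgw}, \code{shape_prot}, \code{shape_roll}, \code{shape_helt}.
#' @export
setClass("SimilarityMatrix", representation(values = "matrix", metricName = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  ok <- c("protein_blosum", "dna_pfm_pcc", "shape_mgw", "shape_prot",
          "shape_roll", "shape_helt")
  if (length(object@metricName) != 1L || !object@metricName %in% ok)
    msgs <- c(msgs, paste("metricName must be one of", paste(ok, collapse = ", ")))
  if (nrow(v) != ncol(v) || !identical(rownames(v), colnames(v)))
    msgs <- c(msgs, "matrix must be square with identical row/col labels")
  else {
    fin <- v[is.finite(v)]
    if (max(abs(v - t(v)), na.rm = TRUE) > 1e-8)
      msgs <- c(msgs, "matrix must be symmetric")
    if (identical(object@metricName, "dna_pfm_pcc")) {
      if (any(abs(diag(v) - 1) > 1e-8, na.rm = TRUE))
        msgs <- c(msgs, "dna_pfm_pcc requires unit diagonal")
      if (length(fin) && (min(fin) < -1 - 1e-8 || max(fin) > 1 + 1e-8))
        msgs <- c(msgs, "dna_pfm_pcc values must lie in [-1, 1]")
    }
    if (startsWith(object@metricName, "shape_")) {
      if (any(abs(diag(v)) > 1e-8, na.rm = TRUE))
        msgs <- c(msgs, "shape metrics require zero diagonal")
      if (length(fin) && max(fin) > 1e-8)
        msgs <- c(msgs, "shape similarities must be <= 0")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' BindingSiteSet: binding sites of one protein on a common frame
#'
#' Sites are stored oriented to the plus strand of the frame.  \code{offset}
#' is the frame position of the site's first base (1-based; values below 1
#' mean the site starts before the frame and its leading bases fall outside).
#'
#' @slot proteinId character scalar.
#' @slot sequence character vector of oriented site sequences (A/C/G/T).
#' @slot escore numeric vector (NA when absent), PBM scale [-0.5, 0.5].
#' @slot strand character vector, "+"/"-": strand of the original k-mer.
#' @slot offset integer vector, frame position of the first base.
#' @slot frameWidth integer scalar.
#' @export
setClass("BindingSiteSet", representation(
  proteinId = "character", sequence = "character", escore = "numeric",
  strand = "character", offset = "integer", frameWidth = "integer"))

setValidity("BindingSiteSet", function(object) {
  n <- length(object@sequence)
  msgs <- character(0)
  if (length(object@escore) != n || length(object@strand) != n ||
      length(object@offset) != n)
    msgs <- c(msgs, "sequence, escore, strand and offset must be parallel")
  if (!all(object@strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (any(!is.na(object@escore) & abs(object@escore) > 0.5 + 1e-9))
    msgs <- c(msgs, "escore must lie in [-0.5, 0.5]")
  if (n > 0) {
    ends <- object@offset + nchar(object@sequence) - 1L
    if (any(ends < 1L | object@offset > object@frameWidth))
      msgs <- c(msgs, "every site must overlap the frame")
  }
  if (length(msgs)) msgs else TRUE
})

#' PFM: position frequency matrix of one protein's aligned sites
#'
#' @slot proteinId character scalar.
#' @slot freq 4 x W numeric matrix (rows A,C,G,T), columns sum to 1.
#' @slot nSites integer, sites summarised.
#' @slot coverage integer length W, effective site count per column.
#' @export
setClass("PFM", representation(
  proteinId = "character", freq = "matrix", nSites = "integer",
  coverage = "integer"))

setValidity("PFM", function(object) {
  f <- object@freq
  msgs <- character(0)
  if (!identical(rownames(f), DNA_BASES)) msgs <- c(msgs, "rows must be A,C,G,T")
  if (any(f < -1e-12)) msgs <- c(msgs, "frequencies must be nonnegative")
  if (any(abs(colSums(f) - 1) > 1e-9)) msgs <- c(msgs, "columns must sum to 1")
  if (length(object@coverage) != ncol(f))
    msgs <- c(msgs, "coverage must have one entry per column")
  if (length(msgs)) msgs else TRUE
})

#' ProteinCohort: aligned protein sequences with named region windows
#'
#' @slot msa \code{AAStringSet} of equal-width aligned sequences (gap '-').
#' @slot regions named list of integer MSA-column windows, by default the
#'   N-terminal tail (residues 1-9) and the recognition helix (residues 47-55).
#' @slot numberingMap integer vector mapping MSA column to domain residue
#'   number (NA at gap columns of the numbering reference).
#' @export
setClass("ProteinCohort", representation(
  msa = "AAStringSet", regions = "list", numberingMap = "integer"))

setValidity("ProteinCohort", function(object) {
  msgs <- character(0)
  w <- Biostrings::width(object@msa)
  if (length(w) && length(unique(w)) != 1L)
    msgs <- c(msgs, "all aligned sequences must have equal width")
  W <- if (length(w)) w[1] else 0L
  for (nm in names(object@regions)) {
    r <- object@regions[[nm]]
    if (any(r < 1L | r > W))
      msgs <- c(msgs, paste0("region '", nm, "' outside MSA bounds"))
  }
  if (length(object@numberingMap) != W)
    msgs <- c(msgs, "numberingMap must have one entry per MSA column")
  nm <- object@numberingMap[!is.na(object@numberingMap)]
  if (length(nm) > 1L && any(diff(nm) <= 0))
    msgs <- c(msgs, "numberingMap must be strictly increasing over non-gap columns")
  if (is.null(names(object@msa)) && length(object@msa))
    msgs <- c(msgs, "sequences must be named")
  if (length(msgs)) msgs else TRUE
})

#' SubstitutionMatrix: symmetric amino-acid score matrix
#'
#' @slot scores symmetric integer-valued matrix, residue x residue.
#' @slot ambiguity characters present in the file that are ambiguity or stop
#'   codes (B, Z, X, *): retained in \code{scores} but flagged here.
#' @export
setClass("SubstitutionMatrix", representation(
  scores = "matrix", ambiguity = "character"))

setValidity("SubstitutionMatrix", function(object) {
  s <- object@scores
  msgs <- character(0)
  if (nrow(s) != ncol(s) || !identical(rownames(s), colnames(s)))
    msgs <- c(msgs, "scores must be square with identical labels")
  else if (max(abs(s - t(s))) > 0)
    msgs <- c(msgs, "scores must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' NarrowGrooveCall: binary narrow-minor-groove calls per protein and position
#'
#' @slot calls logical matrix, proteins x frame positions; NA where the MGW
#'   profile is undefined.
#' @slot threshold numeric, angstrom; narrow means MGW <= threshold.
#' @export
setClass("NarrowGrooveCall", representation(calls = "matrix", threshold = "numeric"))

#' CovariationMaps: position-by-position covariation statistics
#'
#' @slot hypergeomP numeric matrix (protein MSA column x DNA position) of
#'   upper-tail cumulative hypergeometric p-values.
#' @slot mi numeric matrix, same shape, mutual information in bits.
#' @slot degenerate logical matrix: cells where the hypergeometric test was
#'   vacuous (no basic residues or no narrow calls) and p = 1 was recorded.
#' @slot narrowThreshold numeric, angstrom.
#' @export
setClass("CovariationMaps", representation(
  hypergeomP = "matrix", mi = "matrix", degenerate = "matrix",
  narrowThreshold = "numeric"))

setValidity("CovariationMaps", function(object) {
  msgs <- character(0)
  p <- object@hypergeomP
  if (!identical(dim(p), dim(object@mi)) || !identical(dim(p), dim(object@degenerate)))
    msgs <- c(msgs, "hypergeomP, mi and degenerate must share dimensions")
  pp <- p[is.finite(p)]
  if (length(pp) && (min(pp) <= 0 || max(pp) > 1 + 1e-12))
    msgs <- c(msgs, "p-values must lie in (0, 1]")
  mm <- object@mi[is.finite(object@mi)]
  if (length(mm) && min(mm) < -1e-9)
    msgs <- c(msgs, "MI must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' AffinityCV: cross-validated affinity model result for one protein
#'
#' @slot proteinId character scalar.
#' @slot variant one of \code{seq}, \code{seq+shape}, \code{seq+shuffled-shape}.
#' @slot r2 numeric, squared Pearson correlation between predicted and observed
#'   E-scores, one value per repeat.
#' @slot predictions named numeric, per-8-mer predicted E-score averaged over
#'   repeats.
#' @slot auc numeric, ROC area at the bound/unbound E-score threshold (NA when
#'   a class is empty).
#' @export
setClass("AffinityCV", representation(
  proteinId = "character", variant = "character", r2 = "numeric",
  predictions = "numeric", auc = "numeric"))

#' CovariationSpec: parameters of the synthetic covariation generator
#'
#' @slot nProteins integer, cohort size.
#' @slot tailColumn integer, protein alignment column carrying the planted
#'   residue (N-terminal tail position).
#' @slot plantedResidues character, residues planted in carriers (default "R").
#' @slot affectedPositions integer, binding-site frame positions whose minor
#'   groove narrows in carriers.
#' @slot mgwShift numeric, angstrom; negative = narrowing.
#' @slot motifCore character, IUPAC 5-mer core shared by high-affinity sites.
#' @slot escoreNoiseSd numeric, sd of the latent-affinity noise.
#' @slot shapeEffectWeight numeric, weight of the planted shape term
#'   (affinity units per squared angstrom of deviation from the target MGW).
#' @slot seed integer.
#' @export
setClass("CovariationSpec", representation(
  nProteins = "integer", tailColumn = "integer", plantedResidues = "character",
  affectedPositions = "integer", mgwShift = "numeric", motifCore = "character",
  escoreNoiseSd = "numeric", shapeEffectWeight = "numeric", seed = "integer"))

setValidity("CovariationSpec", function(object) {
  msgs <- character(0)
  if (object@nProteins < 4L) msgs <- c(msgs, "nProteins must be >= 4")
  if (!is.finite(object@mgwShift)) msgs <- c(msgs, "mgwShift must be finite")
  if (nchar(object@motifCore) != 5L) msgs <- c(msgs, "motifCore must be a 5-mer")
  if (any(object@affectedPositions < 1L | object@affectedPositions > 8L))
    msgs <- c(msgs, "affectedPositions must lie within the 8-wide frame")
  if (length(msgs)) msgs else TRUE
})
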