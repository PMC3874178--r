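## Generics and show methods.

#' Average per-position shape profile of a set of aligned binding sites
#'
#' Computes \code{\link{predictShape}} for every site and averages each
#' parameter per frame position, using only the sites with a defined value
#' there (unweighted mean; coverage counts are kept).
#'
#' @param sites a \code{BindingSiteSet}, or a character vector of equal-width
#'   aligned sequences sharing one coordinate frame.
#' @param table a \code{\link{ShapeTable}}.
#' @param proteinId identifier stored in the profile.
#' @return a \code{\link{ShapeProfile}}.
#' @export
setGeneric("averageShapeProfile", function(sites, table, proteinId = "")
  standardGeneric("averageShapeProfile"))

#' Similarity matrix values
#' @param x a \code{SimilarityMatrix}.
#' @return the underlying symmetric numeric matrix.
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' @rdname similarityValues
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

#' Metric name of a similarity matrix
#' @param x a \code{SimilarityMatrix}.
#' @return character scalar.
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname metricName
#' @export
setMethod("metricName", "SimilarityMatrix", function(x) x@metricName)

#' Pentamer shape values
#' @param x a \code{ShapeTable}.
#' @return 512 x 6 numeric matrix keyed by canonical pentamer.
#' @export
setGeneric("shapeValues", function(x) standardGeneric("shapeValues"))

#' @rdname shapeValues
#' @export
setMethod("shapeValues", "ShapeTable", function(x) x@values)

#' Shape profile vector for one parameter
#' @param x a \code{ShapeProfile}.
#' @param parameter one of "MGW", "ProT", "Roll", "HelT".
#' @return numeric vector (length L for MGW/ProT, L-1 for Roll/HelT).
#' @export
setGeneric("profileVector", function(x, parameter = "MGW")
  standardGeneric("profileVector"))

#' @rdname profileVector
#' @export
setMethod("profileVector", "ShapeProfile", function(x, parameter = "MGW") {
  switch(match.arg(parameter, c("MGW", "ProT", "Roll", "HelT")),
         MGW = x@mgw, ProT = x@prot, Roll = x@roll, HelT = x@helt)
})

#' Aligned protein matrix of a cohort
#' @param x a \code{ProteinCohort}.
#' @return character matrix, proteins x MSA columns.
#' @export
setGeneric("msaMatrix", function(x) standardGeneric("msaMatrix"))

#' @rdname msaMatrix
#' @export
setMethod("msaMatrix", "ProteinCohort", function(x) {
  m <- do.call(rbind, strsplit(as.character(x@msa), "", fixed = TRUE))
  rownames(m) <- names(x@msa)
  m
})

setMethod("show", "ShapeTable", function(object) {
  v <- object@values
  cat("ShapeTable: 512 canonical pentamers\n")
  cat(sprintf("  MGW  %.2f..%.2f A   ProT %.1f..%.1f deg\n",
              min(v[, "MGW"]), max(v[, "MGW"]), min(v[, "ProT"]), max(v[, "ProT"])))
  cat(sprintf("  Roll %.1f..%.1f deg  HelT %.1f..%.1f deg\n",
              min(v[, c("Roll1", "Roll2")]), max(v[, c("Roll1", "Roll2")]),
              min(v[, c("HelT1", "HelT2")]), max(v[, c("HelT1", "HelT2")])))
})

setMethod("show", "ShapeProfile", function(object) {
  cat(sprintf("ShapeProfile '%s': %d positions, %d sites\n",
              object@proteinId, length(object@mgw), object@nSites))
  cat("  MGW:", paste(ifelse(is.na(object@mgw), "  NA",
                             sprintf("%.2f", object@mgw)), collapse = " "), "\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d proteins\n",
              object@metricName, nrow(object@values)))
})

setMethod("show", "BindingSiteSet", function(object) {
  cat(sprintf("BindingSiteSet '%s': %d sites on a %d-wide frame\n",
              object@proteinId, length(object@sequence), object@frameWidth))
})

setMethod("show", "PFM", function(object) {
  cat(sprintf("PFM '%s': %d columns from %d sites\n",
              object@proteinId, ncol(object@freq), object@nSites))
  print(round(object@freq, 3))
})

setMethod("show", "ProteinCohort", function(object) {
  cat(sprintf("ProteinCohort: %d proteins, %d aligned columns\n",
              length(object@msa), if (length(object@msa)) Biostrings::width(object@msa)[1] else 0L))
  if (length(object@regions))
    cat("  regions:", paste(sprintf("%s [%d-%d]", names(object@regions),
                                    vapply(object@regions, min, 1L),
                                    vapply(object@regions, max, 1L)),
                            collapse = ", "), "\n")
})

setMethod("show", "CovariationMaps", function(object) {
  cat(sprintf("CovariationMaps: %d protein columns x %d DNA positions (narrow MGW <= %.2f A)\n",
              nrow(object@hypergeomP), ncol(object@hypergeomP), object@narrowThreshold))
  i <- which(object@hypergeomP == min(object@hypergeomP), arr.ind = TRUE)[1, ]
  cat(sprintf("  min hypergeometric p = %.3g at (column %d, position %d)\n",
              min(object@hypergeomP), i[1], i[2]))
})

setMethod("show", "AffinityCV", function(object) {
  cat(sprintf("AffinityCV '%s' [%s]: mean R2 = %.3f, median R2 = %.3f, AUC = %.3f (%d repeats)\n",
              object@proteinId, object@variant, mean(object@r2),
              stats::median(object@r2), object@auc, length(object@r2)))
})

setMethod("show", "CovariationSpec", function(object) {
  cat(sprintf("CovariationSpec: %d proteins, residue {%s} at column %d -> MGW %+.2f A at positions %s\n",
              object@nProteins, paste(object@plantedResidues, collapse = ","),
              object@tailColumn, object@mgwShift,
              paste(object@affectedPositions, collapse = ",")))
})
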