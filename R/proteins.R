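## Protein cohort handling and BLOSUM-based pairwise similarity.

#' Construct a ProteinCohort from aligned sequences
#'
#' @param msa named character vector or \code{AAStringSet} of equal-width
#'   aligned amino-acid sequences (gap character '-').
#' @param regions named list of integer MSA-column windows.  Defaults follow
#'   the homeodomain convention: residues 1-9 form the N-terminal tail and
#'   47-55 the recognition helix (engrailed/Hoxa9 numbering), mapped through
#'   \code{numberingMap}.
#' @param numberingMap integer vector, MSA column to domain residue number
#'   (NA at gap columns of the reference row).  Defaults to 1..width for a
#'   gapless alignment.
#' @return a \code{\link{ProteinCohort}}.
#' @export
ProteinCohort <- function(msa, regions = NULL, numberingMap = NULL) {
  if (!methods::is(msa, "AAStringSet")) msa <- Biostrings::AAStringSet(msa)
  W <- if (length(msa)) Biostrings::width(msa)[1] else 0L
  if (is.null(numberingMap)) numberingMap <- seq_len(W)
  numberingMap <- as.integer(numberingMap)
  if (is.null(regions)) {
    colOf <- function(res) which(numberingMap %in% res)
    regions <- list(nTerminalTail = colOf(1:9), recognitionHelix = colOf(47:55))
    regions <- regions[lengths(regions) > 0L]
  }
  regions <- lapply(regions, as.integer)
  methods::new("ProteinCohort", msa = msa, regions = regions,
               numberingMap = numberingMap)
}

#' Read an aligned-FASTA protein cohort
#'
#' @param path aligned FASTA file (gaps '-').
#' @param ... passed on to \code{\link{ProteinCohort}}.
#' @return a \code{\link{ProteinCohort}}.
#' @export
readProteinCohort <- function(path, ...) {
  ProteinCohort(Biostrings::readAAStringSet(path), ...)
}

#' Write a cohort as aligned FASTA
#' @param cohort a \code{\link{ProteinCohort}}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeProteinCohort <- function(cohort, path) {
  Biostrings::writeXStringSet(cohort@msa, path)
  invisible(path)
}

#' Read a substitution matrix in NCBI flat format
#'
#' Lines starting with '#' are comments; the first data line lists the
#' column residues and each subsequent line a row residue followed by its
#' scores.  Asymmetric entries are an error.  Ambiguity/stop columns
#' (B, Z, X, *) are retained but flagged.
#'
#' @param path file path.
#' @return a \code{\link{SubstitutionMatrix}}.
#' @export
readSubstitutionMatrix <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (length(ln) < 2L) stop("not a substitution matrix file: ", path)
  cols <- strsplit(trimws(ln[1L]), "\\s+")[[1L]]
  rows <- lapply(ln[-1L], function(x) strsplit(trimws(x), "\\s+")[[1L]])
  labs <- vapply(rows, `[`, character(1), 1L)
  s <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(cols))))
  dimnames(s) <- list(labs, cols)
  if (!identical(rownames(s), colnames(s)))
    s <- s[, rownames(s), drop = FALSE]
  asym <- which(abs(s - t(s)) > 0, arr.ind = TRUE)
  if (nrow(asym))
    stop("asymmetric substitution scores, e.g. score(",
         rownames(s)[asym[1L, 1L]], ",", colnames(s)[asym[1L, 2L]],
         ") != score(", colnames(s)[asym[1L, 2L]], ",",
         rownames(s)[asym[1L, 1L]], ")")
  methods::new("SubstitutionMatrix", scores = s,
               ambiguity = intersect(rownames(s), c("B", "Z", "X", "*", "J", "U", "O")))
}

#' The BLOSUM45 substitution matrix
#'
#' Loaded from the matrices shipped with Biostrings.
#'
#' @return a \code{\link{SubstitutionMatrix}}.
#' @export
blosum45 <- function() {
  e <- new.env()
  utils::data("BLOSUM45", package = "Biostrings", envir = e)
  s <- e$BLOSUM45
  methods::new("SubstitutionMatrix", scores = s,
               ambiguity = intersect(rownames(s), c("B", "Z", "X", "*", "J", "U", "O")))
}

#' Pairwise protein similarity over an MSA
#'
#' The similarity of two proteins is the sum of substitution-matrix scores
#' over the selected MSA columns, skipping any column where either row has a
#' gap (raw sums, no length normalisation; skipped-column counts are
#' reported as an attribute).  With \code{region} the sum runs over that
#' named window only, e.g. the N-terminal tail or the recognition helix.
#'
#' @param cohort a \code{\link{ProteinCohort}}.
#' @param matrix a \code{\link{SubstitutionMatrix}} (default BLOSUM45).
#' @param region optional region name from \code{cohort}'s region list.
#' @param maxMissing error if more than this fraction of pairs have no
#'   scorable column (default 0.1).
#' @return a \code{\link{SimilarityMatrix}} with metric \code{protein_blosum};
#'   attribute \code{skippedColumns} holds the mean gap-skipped column count.
#' @export
proteinSimilarity <- function(cohort, matrix = blosum45(), region = NULL,
                              maxMissing = 0.1) {
  stopifnot(methods::is(cohort, "ProteinCohort"),
            methods::is(matrix, "SubstitutionMatrix"))
  aa <- msaMatrix(cohort)
  if (!is.null(region)) {
    if (!region %in% names(cohort@regions))
      stop("unknown region '", region, "'; available: ",
           paste(names(cohort@regions), collapse = ", "))
    aa <- aa[, cohort@regions[[region]], drop = FALSE]
  }
  s <- matrix@scores
  resUsed <- setdiff(unique(as.vector(aa)), "-")
  absent <- setdiff(resUsed, rownames(s))
  if (length(absent))
    stop("residue(s) not covered by the substitution matrix: ",
         paste(absent, collapse = ", "))
  idx <- matrix(match(aa, rownames(s)), nrow(aa), ncol(aa))  # NA at gaps
  n <- nrow(aa)
  v <- matrix(NA_real_, n, n, dimnames = list(rownames(aa), rownames(aa)))
  skipped <- 0
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      skipped <- skipped + sum(!ok)
      v[i, j] <- v[j, i] <- if (any(ok))
        sum(s[cbind(idx[i, ok], idx[j, ok])]) else NA_real_
    }
  }
  ut <- upper.tri(v)
  if (mean(is.na(v[ut])) > maxMissing)
    stop("more than ", round(100 * maxMissing), "% of pairs have no scorable ",
         "column in region '", region, "'")
  out <- methods::new("SimilarityMatrix", values = v, metricName = "protein_blosum")
  attr(out, "skippedColumns") <- skipped / (n * (n + 1) / 2)
  out
}

#' Write a similarity matrix as labeled TSV
#' @param sim a \code{\link{SimilarityMatrix}}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  v <- similarityValues(sim)
  d <- data.frame(protein = rownames(v), v, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
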