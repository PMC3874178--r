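## Small sequence utilities shared across the package.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character DNA strings
#'
#' Thin vectorised wrapper around Biostrings; input must be over {A,C,G,T}.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements (names dropped).
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' Canonical (strand-collapsed) representative of a k-mer
#'
#' The lexicographically smaller of a k-mer and its reverse complement.
#'
#' @param x character vector of DNA strings.
#' @return character vector, same length.
#' @export
canonicalKmer <- function(x) {
  pmin(x, revComp(x))
}

## IUPAC degenerate-base expansion (subset actually used by consensus motifs).
.iupacSets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.checkDnaAlphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T}: ",
         paste(utils::head(unique(x[bad]), 3L), collapse = ", "),
         " (ambiguity codes must be expanded or rejected by the caller)")
  }
  invisible(TRUE)
}

## All 4^k k-mers as a character matrix (rows = k-mers, cols = positions),
## plus the pasted strings. Ordering is deterministic.
.allKmerChars <- function(k) {
  g <- expand.grid(rep(list(DNA_BASES), k), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_len(k)), drop = FALSE]  # leftmost position varies slowest
  m <- as.matrix(g)
  dimnames(m) <- NULL
  m
}

.pasteRows <- function(m) do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))

#' All canonical pentamers
#'
#' The 512 lexicographically-smaller representatives of the 1024 pentamers
#' under reverse complementation (no pentamer is its own reverse complement).
#'
#' @return character vector of length 512, sorted.
#' @export
canonicalPentamers <- function() {
  p <- .pasteRows(.allKmerChars(5L))
  sort(unique(canonicalKmer(p)))
}

## substring columns of an equal-width character vector, vectorised
.substrCols <- function(x, start, stop) substr(x, start, stop)
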