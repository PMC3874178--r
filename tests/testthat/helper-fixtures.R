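## Programmatic fixtures shared across tests.

## ShapeTable with a constant value per parameter.
constantShapeTable <- function(mgw = 5.0, prot = -10, roll = 2, helt = 34) {
  p <- canonicalPentamers()
  ShapeTable(p, MGW = rep(mgw, 512), ProT = rep(prot, 512),
             Roll1 = rep(roll, 512), Roll2 = rep(roll, 512),
             HelT1 = rep(helt, 512), HelT2 = rep(helt, 512))
}

## Write a ShapeTable to a TSV, optionally dropping keys or perturbing one
## cell, to exercise the loader's validation paths.
writeShapeTableFixture <- function(table, path, drop = NULL,
                                   raw1024 = FALSE, breakPair = NULL) {
  v <- shapeValues(table)
  d <- data.frame(pentamer = rownames(v), v, check.names = FALSE)
  if (raw1024) {
    rc <- data.frame(pentamer = revComp(rownames(v)),
                     MGW = v[, "MGW"], ProT = v[, "ProT"],
                     Roll1 = v[, "Roll2"], Roll2 = v[, "Roll1"],
                     HelT1 = v[, "HelT2"], HelT2 = v[, "HelT1"],
                     check.names = FALSE)
    d <- rbind(d, rc)
  }
  if (!is.null(drop)) d <- d[!d$pentamer %in% drop, , drop = FALSE]
  if (!is.null(breakPair)) d$MGW[d$pentamer == breakPair] <- d$MGW[d$pentamer == breakPair] + 1
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## A ShapeProfile built directly from vectors (for similarity-level tests).
madeProfile <- function(id, mgw, roll = NULL, prot = NULL, helt = NULL) {
  L <- length(mgw)
  if (is.null(prot)) prot <- rep(-10, L)
  if (is.null(roll)) roll <- rep(2, L - 1)
  if (is.null(helt)) helt <- rep(34, L - 1)
  methods::new("ShapeProfile", proteinId = id, mgw = mgw, prot = prot,
               roll = roll, helt = helt, nSites = 1L,
               bpCoverage = rep(1L, L), stepCoverage = rep(1L, L - 1))
}

## A tiny NCBI-format substitution matrix file over A,R,N,D.
writeToySubMatrix <- function(path, breakSymmetry = FALSE) {
  lines <- c("# toy matrix",
             "   A  R  N  D",
             "A  4 -1 -2 -2",
             "R -1  6  0 -2",
             "N -2  0  7  1",
             sprintf("D -2 %d  1  8", if (breakSymmetry) 3L else -2L))
  writeLines(lines, path)
  path
}

## Cohort built from explicit aligned sequences.
makeCohort <- function(seqs, ...) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("P%02d", seq_along(seqs))
  ProteinCohort(seqs, ...)
}

## Cohort of N single-column proteins: k basic residues among the first m
## proteins and s-k among the rest, paired with calls TRUE for the first m.
## Used to drive hypergeometricMap to arbitrary (N, s, m, k).
hyperFixture <- function(N, s, m, k) {
  res <- rep("A", N)
  if (k > 0) res[seq_len(k)] <- "R"
  if (s - k > 0) res[m + seq_len(s - k)] <- "R"
  cohort <- makeCohort(res)
  calls <- methods::new("NarrowGrooveCall",
                        calls = matrix(seq_len(N) <= m, N, 1,
                                       dimnames = list(sprintf("P%02d", seq_len(N)), "pos1")),
                        threshold = 5.12)
  list(cohort = cohort, calls = calls)
}

## Similarity matrix wrapper for ad-hoc symmetric matrices.
simMat <- function(v, metric = "protein_blosum") {
  if (is.null(rownames(v))) {
    dimnames(v) <- list(sprintf("P%02d", seq_len(nrow(v))),
                        sprintf("P%02d", seq_len(nrow(v))))
  }
  methods::new("SimilarityMatrix", values = v, metricName = metric)
}
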