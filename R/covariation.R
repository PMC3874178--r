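## Matrix-level and position-level covariation statistics.

.upperTriPairs <- function(a, b) {
  va <- similarityValues(a); vb <- similarityValues(b)
  if (!identical(rownames(va), rownames(vb)))
    stop("similarity matrices must share identical label sets and ordering")
  ut <- upper.tri(va)
  ok <- !is.na(va[ut]) & !is.na(vb[ut])
  list(x = va[ut][ok], y = vb[ut][ok], nDropped = sum(!ok))
}

#' Correlation between two pairwise similarity matrices
#'
#' Pearson correlation over the strict upper triangle (diagonal excluded),
#' with a two-sided p-value from the t approximation.  Pairs where either
#' matrix is NA are dropped.
#'
#' @param a,b \code{\link{SimilarityMatrix}} objects over the same proteins
#'   in the same order.
#' @return list with \code{pcc}, \code{p} and \code{nPairs}.
#' @export
matrixPCC <- function(a, b) {
  pr <- .upperTriPairs(a, b)
  if (length(pr$x) < 3L) stop("need at least 3 comparable pairs")
  if (stats::sd(pr$x) == 0 || stats::sd(pr$y) == 0)
    stop("zero variance in the upper triangle of one matrix")
  ct <- stats::cor.test(pr$x, pr$y, method = "pearson", alternative = "two.sided")
  list(pcc = unname(ct$estimate), p = ct$p.value, nPairs = length(pr$x))
}

#' Shuffle null for the matrix-level correlation
#'
#' Randomly reassigns protein identities (label-to-sequence assignment) and
#' recomputes the protein-similarity/other-similarity correlation each time.
#' Reassigning labels permutes the rows and columns of the protein similarity
#' matrix by the same permutation, so the null is built by permuting the
#' precomputed matrix; the result is identical to recomputing the similarity
#' from the shuffled cohort.  The empirical two-sided p-value is
#' \code{(r + 1) / (n + 1)} where r counts null values at least as extreme
#' as the observed correlation.
#'
#' @param cohort a \code{\link{ProteinCohort}} or a precomputed protein
#'   \code{\link{SimilarityMatrix}}.
#' @param other the binding-site similarity matrix to correlate against.
#' @param matrix substitution matrix used when \code{cohort} is a cohort.
#' @param region optional region name passed to \code{\link{proteinSimilarity}}.
#' @param nShuffles number of shuffles (default 1000).
#' @param seed integer seed for reproducibility.
#' @return list with \code{observed}, \code{null} (length \code{nShuffles}),
#'   \code{mean}, \code{p} and \code{nShuffles}.
#' @export
shuffleNull <- function(cohort, other, matrix = blosum45(), region = NULL,
                        nShuffles = 1000L, seed = NULL) {
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  protSim <- if (methods::is(cohort, "SimilarityMatrix")) cohort
             else proteinSimilarity(cohort, matrix, region = region)
  obs <- matrixPCC(protSim, other)$pcc
  if (!is.null(seed)) set.seed(seed)
  va <- similarityValues(protSim)
  vb <- similarityValues(other)
  ut <- upper.tri(va)
  y <- vb[ut]
  n <- nrow(va)
  null <- vapply(seq_len(nShuffles), function(i) {
    p <- sample.int(n)
    x <- va[p, p][ut]
    ok <- !is.na(x) & !is.na(y)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  r <- sum(abs(null) >= abs(obs))
  list(observed = obs, null = null, mean = mean(null),
       p = (r + 1) / (nShuffles + 1), nShuffles = nShuffles)
}

#' Binned correlation controlling for the similarity-score distribution
#'
#' Upper-triangle pairs are binned by the value of \code{b} (by default the
#' DNA PFM similarity, with the bin edges 0, 0.4, 0.5, ..., 0.9, 1 used for
#' PFM correlation scores); an equal number of pairs is sampled without
#' replacement from each nonempty bin and the Pearson correlation is
#' computed on the sampled union.  Values outside the edge range are clamped
#' into the outer bins; bins shorter than \code{nPerBin} contribute all
#' their pairs.
#'
#' @param a,b \code{\link{SimilarityMatrix}} objects (binning on \code{b}).
#' @param binEdges numeric bin edges (default the seven PFM-score bins).
#' @param nPerBin pairs sampled per bin.
#' @param seed integer seed.
#' @return list with \code{pcc}, \code{p}, \code{nSampled} and
#'   \code{binCounts}.
#' @export
binnedPCC <- function(a, b, binEdges = c(0, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
                      nPerBin = 300L, seed = NULL) {
  pr <- .upperTriPairs(a, b)
  z <- pmin(pmax(pr$y, min(binEdges)), max(binEdges))
  bin <- cut(z, breaks = binEdges, include.lowest = TRUE)
  if (all(is.na(bin))) stop("all bins empty")
  if (!is.null(seed)) set.seed(seed)
  idx <- unlist(lapply(levels(bin), function(lv) {
    i <- which(bin == lv)
    if (length(i) <= nPerBin) i else sample(i, nPerBin)
  }), use.names = FALSE)
  if (length(idx) < 3L) stop("fewer than 3 pairs after binning")
  ct <- stats::cor.test(pr$x[idx], pr$y[idx])
  list(pcc = unname(ct$estimate), p = ct$p.value, nSampled = length(idx),
       binCounts = table(bin))
}

#' Call narrow minor groove per protein and position
#'
#' A position is "narrow" when the protein's average MGW there is at or
#' below the threshold (inclusive).  The default 5.12 angstrom corresponds
#' to the mean MGW over a large homeodomain binding-site compendium; typical
#' sensitivity analyses rerun at 4.9-5.2.
#'
#' @param profiles list of \code{\link{ShapeProfile}}.
#' @param threshold angstrom, inclusive.
#' @return a \code{\link{NarrowGrooveCall}}.
#' @export
callNarrowGroove <- function(profiles, threshold = 5.12) {
  ids <- unname(vapply(profiles, function(p) p@proteinId, character(1)))
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    ids <- make.unique(ifelse(nzchar(ids), ids, "protein"))
  m <- do.call(rbind, lapply(profiles, function(p) p@mgw <= threshold))
  rownames(m) <- ids
  colnames(m) <- paste0("pos", seq_len(ncol(m)))
  methods::new("NarrowGrooveCall", calls = m, threshold = threshold)
}

#' Hypergeometric covariation map
#'
#' For every protein alignment column and binding-site position, tests the
#' co-occurrence of positively charged residues (R, K, H by default: the
#' protonatable basic amino acids) with a narrow minor groove.  With N
#' proteins (those with a defined call at the position), s of which carry a
#' basic residue at the column and m of which have a narrow call, and k the
#' overlap, the p-value is the upper cumulative hypergeometric tail
#' P(K >= k).  Columns/positions where s = 0 or m = 0 are vacuous: p = 1 is
#' recorded and flagged.
#'
#' @param cohort a \code{\link{ProteinCohort}}.
#' @param calls a \code{\link{NarrowGrooveCall}} over the same proteins.
#' @param basicSet residues counted as positively charged.
#' @return numeric matrix of p-values (protein columns x DNA positions) with
#'   attributes \code{negLog10} and \code{degenerate}.
#' @export
hypergeometricMap <- function(cohort, calls, basicSet = c("R", "K", "H")) {
  aa <- msaMatrix(cohort)
  cm <- calls@calls
  if (nrow(aa) != nrow(cm))
    stop("cohort and calls must cover the same proteins")
  basic <- matrix(aa %in% basicSet, nrow(aa), ncol(aa))
  P <- matrix(1, ncol(aa), ncol(cm),
              dimnames = list(paste0("col", seq_len(ncol(aa))), colnames(cm)))
  deg <- matrix(FALSE, ncol(aa), ncol(cm), dimnames = dimnames(P))
  for (d in seq_len(ncol(cm))) {
    ok <- !is.na(cm[, d])
    N <- sum(ok)
    m <- sum(cm[ok, d])
    if (N == 0L || m == 0L) { deg[, d] <- TRUE; next }
    narrow <- cm[ok, d]
    for (cc in seq_len(ncol(aa))) {
      s <- sum(basic[ok, cc])
      if (s == 0L) { deg[cc, d] <- TRUE; next }
      k <- sum(basic[ok, cc] & narrow)
      P[cc, d] <- stats::phyper(k - 1L, m, N - m, s, lower.tail = FALSE)
    }
  }
  attr(P, "negLog10") <- -log10(P)
  attr(P, "degenerate") <- deg
  P
}

.miBits <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  if (n == 0L) return(0)
  pj <- tab / n
  px <- rowSums(pj); py <- colSums(pj)
  e <- outer(px, py)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / e[nz]))
}

#' Mutual information covariation map
#'
#' Plug-in mutual information (bits) between the residue identity at each
#' protein alignment column (full 20-letter + gap alphabet by default, or a
#' binary basic/non-basic recoding) and the binary narrow/not-narrow minor
#' groove call at each binding-site position.  Proteins without a defined
#' call at a position are dropped there.
#'
#' @param cohort a \code{\link{ProteinCohort}}.
#' @param calls a \code{\link{NarrowGrooveCall}}.
#' @param alphabet "residue" (default) or "basic".
#' @param basicSet residues treated as basic in "basic" mode.
#' @return numeric matrix of MI scores (protein columns x DNA positions).
#' @export
miMap <- function(cohort, calls, alphabet = c("residue", "basic"),
                  basicSet = c("R", "K", "H")) {
  alphabet <- match.arg(alphabet)
  aa <- msaMatrix(cohort)
  cm <- calls@calls
  if (nrow(aa) != nrow(cm))
    stop("cohort and calls must cover the same proteins")
  if (alphabet == "basic")
    aa <- matrix(ifelse(aa %in% basicSet, "basic", "other"), nrow(aa), ncol(aa))
  M <- matrix(0, ncol(aa), ncol(cm),
              dimnames = list(paste0("col", seq_len(ncol(aa))), colnames(cm)))
  for (d in seq_len(ncol(cm))) {
    ok <- !is.na(cm[, d])
    if (!any(ok)) next
    for (cc in seq_len(ncol(aa)))
      M[cc, d] <- .miBits(aa[ok, cc], cm[ok, d])
  }
  M
}

#' Combined covariation maps
#'
#' Convenience wrapper computing both the hypergeometric and the MI map on
#' shared narrow-groove calls.
#'
#' @inheritParams hypergeometricMap
#' @inheritParams miMap
#' @return a \code{\link{CovariationMaps}}.
#' @export
covariationMaps <- function(cohort, calls, basicSet = c("R", "K", "H"),
                            alphabet = "residue") {
  P <- hypergeometricMap(cohort, calls, basicSet)
  deg <- attr(P, "degenerate")
  M <- miMap(cohort, calls, alphabet = alphabet, basicSet = basicSet)
  methods::new("CovariationMaps",
               hypergeomP = structure(as.matrix(P), negLog10 = NULL, degenerate = NULL),
               mi = M, degenerate = deg, narrowThreshold = calls@threshold)
}

#' Residue-grouped minor groove width profiles
#'
#' Groups proteins by the residue class (arginine, lysine, histidine, or
#' non-basic "other") found at one protein alignment column, and returns the
#' positionwise mean MGW curve per class together with two-sided Wilcoxon
#' rank-sum p-values comparing each basic class against "other" at every
#' position (exact for small groups, normal approximation with tie
#' correction otherwise, as implemented by \code{wilcox.test}).  Positions
#' with p below \code{alpha} (default 5e-5) are flagged.  Classes with
#' fewer than 2 members are reported but not tested.
#'
#' @param cohort a \code{\link{ProteinCohort}}.
#' @param profiles list of \code{\link{ShapeProfile}}, one per protein, in
#'   cohort order.
#' @param column protein MSA column to group by.
#' @param alpha significance threshold for flagging.
#' @return list with \code{curves} (class x position mean MGW),
#'   \code{pvalues} (basic class x position), \code{flags} (logical, same
#'   shape), \code{classSizes} and \code{classes} (per-protein class).
#' @export
grooveProfilesByResidue <- function(cohort, profiles, column, alpha = 5e-5) {
  aa <- msaMatrix(cohort)
  if (length(profiles) != nrow(aa))
    stop("need one profile per cohort protein")
  res <- aa[, column]
  cls <- ifelse(res == "R", "R", ifelse(res == "K", "K",
                ifelse(res == "H", "H", "other")))
  mgw <- do.call(rbind, lapply(profiles, function(p) p@mgw))
  L <- ncol(mgw)
  classes <- intersect(c("R", "K", "H", "other"), unique(cls))
  curves <- t(vapply(classes, function(g)
    colMeans(mgw[cls == g, , drop = FALSE], na.rm = TRUE), numeric(L)))
  rownames(curves) <- classes
  colnames(curves) <- paste0("pos", seq_len(L))
  basics <- setdiff(classes, "other")
  pvalues <- matrix(NA_real_, length(basics), L,
                    dimnames = list(basics, colnames(curves)))
  tested <- sum(cls == "other") >= 2L
  for (g in basics) {
    if (!tested || sum(cls == g) < 2L) next
    for (j in seq_len(L)) {
      x <- mgw[cls == g, j]; y <- mgw[cls == "other", j]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) >= 2L && length(y) >= 2L)
        pvalues[g, j] <- suppressWarnings(
          stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
    }
  }
  list(curves = curves, pvalues = pvalues,
       flags = !is.na(pvalues) & pvalues < alpha,
       classSizes = table(factor(cls, levels = classes)), classes = cls)
}

#' Write covariation maps as TSV
#'
#' Emits the labeled p-value and MI matrices plus a long-format table
#' \code{(protein_column, dna_position, statistic, value)}.
#'
#' @param maps a \code{\link{CovariationMaps}}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
writeCovariationMaps <- function(maps, dir, prefix = "covariation") {
  wrt <- function(m, path) {
    d <- data.frame(protein_column = rownames(m), m, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  p1 <- wrt(maps@hypergeomP, file.path(dir, paste0(prefix, "_hypergeom_p.tsv")))
  p2 <- wrt(maps@mi, file.path(dir, paste0(prefix, "_mi_bits.tsv")))
  long <- rbind(
    data.frame(protein_column = rep(rownames(maps@hypergeomP), ncol(maps@hypergeomP)),
               dna_position = rep(colnames(maps@hypergeomP), each = nrow(maps@hypergeomP)),
               statistic = "neg_log10_hypergeom_p",
               value = as.vector(-log10(maps@hypergeomP))),
    data.frame(protein_column = rep(rownames(maps@mi), ncol(maps@mi)),
               dna_position = rep(colnames(maps@mi), each = nrow(maps@mi)),
               statistic = "mi_bits", value = as.vector(maps@mi)))
  p3 <- file.path(dir, paste0(prefix, "_long.tsv"))
  utils::write.table(long, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
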