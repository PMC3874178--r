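## 8-mer selection, alignment to the degenerate core consensus, PFMs and
## PFM-level DNA sequence similarity.

#' Select bound 8-mers from an E-score table
#'
#' Keeps all and only k-mers whose relative enrichment score reaches the
#' threshold (default 0.45, the conventional PBM "bound" cutoff), collapsing
#' reverse-complement pairs to one canonical representative (the higher
#' E-score of the pair is retained).
#'
#' @param escores named numeric vector (names = 8-mers) or a data frame with
#'   columns \code{kmer} and \code{escore}.
#' @param threshold numeric, selection threshold on the E-score.
#' @return data frame with columns \code{kmer} (canonical) and \code{escore},
#'   sorted by decreasing E-score.
#' @export
selectKmers <- function(escores, threshold = 0.45) {
  if (is.data.frame(escores)) {
    kmer <- as.character(escores$kmer)
    sc <- as.numeric(escores$escore)
  } else {
    kmer <- names(escores)
    sc <- as.numeric(escores)
  }
  if (is.null(kmer) || anyDuplicated(kmer))
    stop("E-score table must be keyed on distinct k-mers")
  .checkDnaAlphabet(kmer, "k-mer")
  keep <- !is.na(sc) & sc >= threshold
  if (!any(keep))
    stop("no k-mer reaches E-score >= ", threshold,
         "; review the selection threshold")
  d <- data.frame(kmer = canonicalKmer(kmer[keep]), escore = sc[keep],
                  stringsAsFactors = FALSE)
  d <- d[order(-d$escore), , drop = FALSE]
  d <- d[!duplicated(d$kmer), , drop = FALSE]
  rownames(d) <- NULL
  d
}

.uniformPfmFreq <- function(width) {
  matrix(0.25, 4L, width, dimnames = list(DNA_BASES, NULL))
}

## Candidate placement grid for k-mers of width k: one row per
## (strand, pattern offset j) combination, ordered by the deterministic
## tie-break preference (plus strand first, then leftmost frame placement).
.placementGrid <- function(k, patternStart, patternLen = 5L) {
  g <- expand.grid(j = seq_len(k - patternLen + 1L), strand = c("+", "-"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$offset <- patternStart - g$j + 1L
  g[order(g$strand != "+", g$offset), , drop = FALSE]
}

## n x nrow(grid) logical matrix: does the pattern match k-mer i at grid row g?
.matchMatrix <- function(chars, charsRC, grid, pattern) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sets <- .iupacSets[pat]
  if (anyNA(names(sets))) stop("unknown IUPAC code in pattern: ", pattern)
  n <- nrow(chars)
  M <- matrix(FALSE, n, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cm <- if (grid$strand[g] == "+") chars else charsRC
    ok <- rep(TRUE, n)
    for (p in seq_along(sets))
      ok <- ok & cm[, grid$j[g] + p - 1L] %in% sets[[p]]
    M[, g] <- ok
  }
  M
}

## n x nrow(grid) matrix of placement log-likelihoods under a PFM
## (frequencies floored so that zero columns never veto); only frame-covered
## bases contribute.
.loglikMatrix <- function(chars, charsRC, grid, freq, floor = 1e-3) {
  logF <- log(pmax(freq, floor))
  W <- ncol(freq)
  k <- ncol(chars)
  n <- nrow(chars)
  LL <- matrix(0, n, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cm <- if (grid$strand[g] == "+") chars else charsRC
    o <- grid$offset[g]
    for (q in seq_len(k)) {
      f <- o + q - 1L
      if (f >= 1L && f <= W)
        LL[, g] <- LL[, g] + logF[cbind(match(cm[, q], DNA_BASES), f)]
    }
  }
  LL
}

.placeAll <- function(kmers, escores, pattern, patternStart, frameWidth,
                      referenceFreq, proteinId) {
  k <- nchar(kmers[1])
  chars <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  charsRC <- do.call(rbind, strsplit(revComp(kmers), "", fixed = TRUE))
  grid <- .placementGrid(k, patternStart)
  M <- .matchMatrix(chars, charsRC, grid, pattern)
  placeable <- rowSums(M) > 0L

  pick <- function(freq) {
    LL <- .loglikMatrix(chars, charsRC, grid, freq)
    LL[!M] <- -Inf
    ## ties in log-likelihood break to the strand-canonical orientation
    ## (lexicographically smaller oriented sequence) so that aligning the
    ## reverse-complemented k-mer list yields the identical alignment,
    ## then to the leftmost frame placement
    isCanon <- kmers == canonicalKmer(kmers)
    best <- rep(-Inf, nrow(LL))
    bestPref <- rep(-Inf, nrow(LL))
    bestG <- integer(nrow(LL))
    for (g in seq_len(ncol(LL))) {
      canonFlag <- (grid$strand[g] == "+") == isCanon
      pref <- ifelse(canonFlag, 1000, 0) - grid$offset[g]
      upd <- LL[, g] > best + 1e-9 |
        (LL[, g] > best - 1e-9 & pref > bestPref)
      best[upd] <- LL[upd, g]
      bestPref[upd] <- pref[upd]
      bestG[upd] <- g
    }
    i <- which(placeable)
    g <- bestG[i]
    data.frame(
      strand = grid$strand[g],
      offset = grid$offset[g],
      sequence = ifelse(grid$strand[g] == "+", kmers[i], revComp(kmers[i])),
      escore = escores[i], loglik = best[i], stringsAsFactors = FALSE)
  }

  if (!is.null(referenceFreq))
    return(list(placed = pick(referenceFreq), placeable = placeable))
  ## two-pass iterative scheme: provisional PFM from unambiguous placements
  unambiguous <- which(rowSums(M) == 1L)
  prov <- if (length(unambiguous)) {
    g <- apply(M[unambiguous, , drop = FALSE], 1L, which)
    bs <- methods::new("BindingSiteSet", proteinId = proteinId,
                       sequence = ifelse(grid$strand[g] == "+", kmers[unambiguous],
                                         revComp(kmers[unambiguous])),
                       escore = rep(NA_real_, length(g)),
                       strand = grid$strand[g], offset = as.integer(grid$offset[g]),
                       frameWidth = as.integer(frameWidth))
    tryCatch(buildPFM(bs)@freq, error = function(e) .uniformPfmFreq(frameWidth))
  } else .uniformPfmFreq(frameWidth)
  list(placed = pick(prov), placeable = placeable)
}

#' Align selected 8-mers to the degenerate core consensus
#'
#' Places each 8-mer (both strands considered) so that a 5-base window
#' matching the homeodomain core consensus NNAYN or NNAKN sits at frame
#' positions \code{patternStart..patternStart+4} of an 8-wide binding-site
#' frame.  When a k-mer admits several placements they are disambiguated by
#' PFM log-likelihood: against \code{referencePfm} when one is supplied,
#' otherwise by a self-contained two-pass scheme (a provisional PFM is built
#' from the unambiguous placements, then all k-mers are placed against it).
#' With \code{motifVariant = "auto"} both consensus variants are aligned and
#' the one placing more k-mers (total log-likelihood breaking ties) is kept.
#' Remaining ties prefer the strand-canonical orientation (the
#' lexicographically smaller of a k-mer and its reverse complement, so that
#' a reverse-complemented input list aligns identically), then the leftmost
#' frame placement.  K-mers matching neither strand are dropped with a
#' reported count.
#'
#' @param kmers character vector of 8-mers, or the data frame returned by
#'   \code{\link{selectKmers}}.
#' @param motifVariant "NNAYN", "NNAKN" or "auto".
#' @param referencePfm optional \code{\link{PFM}} used for disambiguation.
#' @param proteinId identifier stored on the result.
#' @param frameWidth width of the binding-site frame (default 8).
#' @param patternStart frame position of the first consensus base (default 3,
#'   so the core occupies frame positions 3-7).
#' @return a \code{\link{BindingSiteSet}} with attribute \code{nDropped}.
#' @export
alignToConsensus <- function(kmers, motifVariant = c("auto", "NNAYN", "NNAKN"),
                             referencePfm = NULL, proteinId = "",
                             frameWidth = 8L, patternStart = 3L) {
  motifVariant <- match.arg(motifVariant)
  if (is.data.frame(kmers)) {
    escores <- as.numeric(kmers$escore)
    kmers <- as.character(kmers$kmer)
  } else {
    kmers <- as.character(kmers)
    escores <- rep(NA_real_, length(kmers))
  }
  if (!length(kmers)) stop("no k-mers supplied")
  .checkDnaAlphabet(kmers, "k-mer")
  refFreq <- if (!is.null(referencePfm)) referencePfm@freq else NULL

  variants <- if (motifVariant == "auto") c("NNAYN", "NNAKN") else motifVariant
  res <- lapply(variants, function(v)
    .placeAll(kmers, escores, v, patternStart, frameWidth, refFreq, proteinId))
  nPlaced <- vapply(res, function(r) sum(r$placeable), integer(1))
  totLL <- vapply(res, function(r)
    if (is.null(r$placed)) -Inf else sum(r$placed$loglik), numeric(1))
  best <- order(-nPlaced, -totLL)[1L]
  chosen <- res[[best]]
  if (is.null(chosen$placed) || nrow(chosen$placed) == 0L)
    stop("no k-mer matches the consensus ", paste(variants, collapse = "/"),
         " on either strand")
  nDropped <- sum(!chosen$placeable)
  if (nDropped > 0L)
    message(nDropped, " k-mer(s) without a consensus match dropped")
  p <- chosen$placed
  out <- methods::new("BindingSiteSet", proteinId = proteinId,
                      sequence = p$sequence, escore = p$escore,
                      strand = p$strand, offset = as.integer(p$offset),
                      frameWidth = as.integer(frameWidth))
  attr(out, "nDropped") <- nDropped
  attr(out, "motifVariant") <- variants[best]
  out
}

#' Build a position frequency matrix from aligned binding sites
#'
#' Column-normalised base counts over the placed sites; frame positions not
#' covered by a site contribute nothing there, and per-column effective site
#' counts are tracked.  A column covered by no site at all is an error (the
#' frame is too wide for the data).
#'
#' @param siteset a \code{\link{BindingSiteSet}}.
#' @return a \code{\link{PFM}}.
#' @export
buildPFM <- function(siteset) {
  stopifnot(methods::is(siteset, "BindingSiteSet"))
  n <- length(siteset@sequence)
  if (n == 0L) stop("empty site set")
  W <- siteset@frameWidth
  counts <- matrix(0L, 4L, W, dimnames = list(DNA_BASES, NULL))
  for (o in unique(siteset@offset)) {
    grp <- siteset@sequence[siteset@offset == o]
    cm <- do.call(rbind, strsplit(grp, "", fixed = TRUE))
    for (q in seq_len(ncol(cm))) {
      f <- o + q - 1L
      if (f < 1L || f > W) next
      tab <- table(factor(cm[, q], levels = DNA_BASES))
      counts[, f] <- counts[, f] + as.integer(tab)
    }
  }
  coverage <- colSums(counts)
  if (any(coverage == 0L))
    stop("column(s) with zero coverage: ",
         paste(which(coverage == 0L), collapse = ", "),
         " (frame too wide for these sites)")
  freq <- sweep(counts, 2L, coverage, "/")
  methods::new("PFM", proteinId = siteset@proteinId, freq = freq,
               nSites = n, coverage = as.integer(coverage))
}

#' Pairwise DNA-sequence similarity between PFMs
#'
#' Pearson correlation of the flattened frequency matrices for every pair of
#' proteins; 1 for identical PFMs.
#'
#' @param pfms list of \code{\link{PFM}} with equal frame widths.
#' @return a \code{\link{SimilarityMatrix}} with metric \code{dna_pfm_pcc}.
#' @export
pfmSimilarity <- function(pfms) {
  if (length(pfms) < 2L) stop("need at least 2 PFMs")
  widths <- vapply(pfms, function(p) ncol(p@freq), integer(1))
  if (length(unique(widths)) != 1L) stop("PFMs must have equal frame widths")
  ids <- unname(vapply(pfms, function(p) p@proteinId, character(1)))
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    ids <- make.unique(ifelse(nzchar(ids), ids, "protein"))
  flat <- vapply(pfms, function(p) as.vector(p@freq), numeric(4L * widths[1]))
  sds <- apply(flat, 2L, stats::sd)
  if (any(sds == 0))
    stop("PFM with zero variance (fully uniform) for: ",
         paste(ids[sds == 0], collapse = ", "))
  v <- stats::cor(flat)
  dimnames(v) <- list(ids, ids)
  diag(v) <- 1
  methods::new("SimilarityMatrix", values = v, metricName = "dna_pfm_pcc")
}

#' Read an 8-mer E-score table (TSV, UniPROBE-style)
#'
#' Two columns, k-mer and E-score; a header line is detected and skipped.
#'
#' @param path file path.
#' @return named numeric vector of E-scores.
#' @export
readEscoreTable <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1L,
                             stringsAsFactors = FALSE)
  hasHeader <- is.na(suppressWarnings(as.numeric(first[[2L]])))
  d <- utils::read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  out <- as.numeric(d[[2L]])
  names(out) <- toupper(as.character(d[[1L]]))
  out
}

#' Write an E-score table as TSV
#' @param escores named numeric vector.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEscoreTable <- function(escores, path) {
  utils::write.table(
    data.frame(kmer = names(escores), escore = as.numeric(escores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write PFMs in MEME minimal motif format
#'
#' @param pfms list of \code{\link{PFM}}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeMemePFM <- function(pfms, path) {
  if (methods::is(pfms, "PFM")) pfms <- list(pfms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pfms) {
    writeLines(sprintf("MOTIF %s", p@proteinId), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(p@freq), p@nSites), con)
    for (j in seq_len(ncol(p@freq)))
      writeLines(sprintf(" %8.6f %8.6f %8.6f %8.6f",
                         p@freq["A", j], p@freq["C", j],
                         p@freq["G", j], p@freq["T", j]), con)
    writeLines("", con)
  }
  invisible(path)
}
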