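## Sliding-pentamer DNA shape prediction and shape similarity.

#' Predict per-position structural features of a DNA sequence
#'
#' Slides a pentamer window along the sequence.  The base-pair parameters
#' (MGW, ProT) at position i (1-based) come from the pentamer centered at i,
#' defined for i in 3..L-2; the first and last two positions are NA.  The
#' step parameters (Roll, HelT) at step j (between bases j and j+1) average
#' the contributions of the pentamers whose two central steps cover that
#' step: the pentamer centered at j contributes its second central step and
#' the pentamer centered at j+1 its first, so interior steps have two
#' contributors and the outermost covered steps one.
#'
#' @param seq a single DNA string over {A,C,G,T}, length >= 5.
#' @param table a \code{\link{ShapeTable}}.
#' @return list with numeric vectors \code{mgw}, \code{prot} (length L) and
#'   \code{roll}, \code{helt} (length L-1); NA where undefined.
#' @export
predictShape <- function(seq, table) {
  stopifnot(methods::is(table, "ShapeTable"), length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 5L) stop("sequence must be at least 5 bases long (got ", L, ")")
  .checkDnaAlphabet(seq, "sequence")

  centers <- 3:(L - 2L)
  pents <- substring(seq, centers - 2L, centers + 2L)
  vals <- .pentamerRows(table, pents)

  mgw <- prot <- rep(NA_real_, L)
  mgw[centers] <- vals[, "MGW"]
  prot[centers] <- vals[, "ProT"]

  rollSum <- heltSum <- numeric(L - 1L)
  nContrib <- integer(L - 1L)
  ## pentamer centered at i covers steps i-1 (first central) and i (second)
  s1 <- centers - 1L
  s2 <- centers
  for (k in seq_along(centers)) {
    rollSum[s1[k]] <- rollSum[s1[k]] + vals[k, "Roll1"]
    rollSum[s2[k]] <- rollSum[s2[k]] + vals[k, "Roll2"]
    heltSum[s1[k]] <- heltSum[s1[k]] + vals[k, "HelT1"]
    heltSum[s2[k]] <- heltSum[s2[k]] + vals[k, "HelT2"]
    nContrib[s1[k]] <- nContrib[s1[k]] + 1L
    nContrib[s2[k]] <- nContrib[s2[k]] + 1L
  }
  roll <- helt <- rep(NA_real_, L - 1L)
  cov <- nContrib > 0L
  roll[cov] <- rollSum[cov] / nContrib[cov]
  helt[cov] <- heltSum[cov] / nContrib[cov]

  list(mgw = mgw, prot = prot, roll = roll, helt = helt)
}

## Accumulate shape of many oriented sites into a common frame.
## seqs are plus-strand oriented; offsets give the frame position of each
## site's first base (may be < 1, in which case leading bases fall outside).
## Sites are processed in groups of equal (offset, width) so that the
## pentamer lookups and the per-site step averaging vectorise; the result is
## identical to running predictShape per site and averaging.
.accumulateProfiles <- function(seqs, offsets, frameWidth, table, proteinId,
                                nSites) {
  W <- frameWidth
  bpSum <- matrix(0, 2L, W, dimnames = list(c("MGW", "ProT"), NULL))
  bpN <- matrix(0L, 2L, W)
  stSum <- matrix(0, 2L, W - 1L, dimnames = list(c("Roll", "HelT"), NULL))
  stN <- matrix(0L, 2L, W - 1L)

  grp <- paste(offsets, nchar(seqs))
  for (g in unique(grp)) {
    sel <- grp == g
    gs <- seqs[sel]
    n <- length(gs)
    o <- offsets[sel][1L]
    L <- nchar(gs[1L])
    if (L < 5L) stop("sites must be at least 5 bases long")
    .checkDnaAlphabet(gs, "site")
    centers <- 3:(L - 2L)
    ## pentamer values for all sites x all centers in one lookup
    pents <- unlist(lapply(centers, function(i) substr(gs, i - 2L, i + 2L)))
    vals <- .pentamerRows(table, pents)   # (n * length(centers)) x 6
    cIdx <- rep(seq_along(centers), each = n)

    for (ci in seq_along(centers)) {
      i <- centers[ci]
      f <- o + i - 1L
      rows <- which(cIdx == ci)
      if (f >= 1L && f <= W) {
        bpSum["MGW", f] <- bpSum["MGW", f] + sum(vals[rows, "MGW"])
        bpSum["ProT", f] <- bpSum["ProT", f] + sum(vals[rows, "ProT"])
        bpN[, f] <- bpN[, f] + n
      }
    }
    ## per-site step value = mean of its 1-2 pentamer contributions; the
    ## contributor pattern is identical within the group
    rollC <- heltC <- matrix(0, n, L - 1L)
    nC <- integer(L - 1L)
    for (ci in seq_along(centers)) {
      i <- centers[ci]
      rows <- which(cIdx == ci)
      rollC[, i - 1L] <- rollC[, i - 1L] + vals[rows, "Roll1"]
      rollC[, i] <- rollC[, i] + vals[rows, "Roll2"]
      heltC[, i - 1L] <- heltC[, i - 1L] + vals[rows, "HelT1"]
      heltC[, i] <- heltC[, i] + vals[rows, "HelT2"]
      nC[i - 1L] <- nC[i - 1L] + 1L
      nC[i] <- nC[i] + 1L
    }
    for (s in which(nC > 0L)) {
      f <- o + s - 1L
      if (f >= 1L && f <= W - 1L) {
        stSum["Roll", f] <- stSum["Roll", f] + sum(rollC[, s]) / nC[s]
        stSum["HelT", f] <- stSum["HelT", f] + sum(heltC[, s]) / nC[s]
        stN[, f] <- stN[, f] + n
      }
    }
  }
  avg <- function(s, n) ifelse(n > 0L, s / n, NA_real_)
  methods::new("ShapeProfile", proteinId = proteinId,
               mgw = avg(bpSum["MGW", ], bpN[1L, ]),
               prot = avg(bpSum["ProT", ], bpN[2L, ]),
               roll = avg(stSum["Roll", ], stN[1L, ]),
               helt = avg(stSum["HelT", ], stN[2L, ]),
               nSites = as.integer(nSites),
               bpCoverage = bpN[1L, ], stepCoverage = stN[1L, ])
}

#' @rdname averageShapeProfile
#' @export
setMethod("averageShapeProfile", signature(sites = "character"),
          function(sites, table, proteinId = "") {
  if (length(sites) == 0L) stop("empty site set")
  w <- nchar(sites)
  if (length(unique(w)) != 1L)
    stop("all sites must have equal width (got widths ",
         paste(unique(w), collapse = ", "), ")")
  .accumulateProfiles(toupper(sites), rep(1L, length(sites)), w[1],
                      table, proteinId, length(sites))
})

#' @rdname averageShapeProfile
#' @export
setMethod("averageShapeProfile", signature(sites = "BindingSiteSet"),
          function(sites, table, proteinId = "") {
  if (length(sites@sequence) == 0L) stop("empty site set")
  id <- if (nzchar(proteinId)) proteinId else sites@proteinId
  .accumulateProfiles(sites@sequence, sites@offset, sites@frameWidth,
                      table, id, length(sites@sequence))
})

#' Pairwise shape similarity between average shape profiles
#'
#' Similarity between two proteins is the negative absolute value of the
#' Euclidean distance between their per-position feature vectors for one
#' structural parameter: 0 when the vectors match perfectly, increasingly
#' negative as they diverge.  Positions (or steps) undefined in any profile
#' are dropped from all profiles before the distance is taken; the number of
#' dropped positions is reported via \code{message}.
#'
#' @param profiles list of \code{\link{ShapeProfile}} of equal length.
#' @param parameter one of "MGW", "ProT", "Roll", "HelT".
#' @return a \code{\link{SimilarityMatrix}} with metric \code{shape_<param>}.
#' @export
shapeSimilarity <- function(profiles, parameter = c("MGW", "ProT", "Roll", "HelT")) {
  parameter <- match.arg(parameter)
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  vecs <- lapply(profiles, profileVector, parameter = parameter)
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L) stop("profiles must have equal length")
  m <- do.call(rbind, vecs)
  ids <- unname(vapply(profiles, function(p) p@proteinId, character(1)))
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    ids <- make.unique(ifelse(nzchar(ids), ids, "protein"))
  rownames(m) <- ids
  keep <- colSums(is.na(m)) == 0L
  if (sum(!keep) > 0L)
    message(sum(!keep), " position(s) undefined in at least one profile ",
            "dropped from the ", parameter, " similarity")
  if (sum(keep) == 0L) stop("no positions defined across all profiles")
  d <- as.matrix(stats::dist(m[, keep, drop = FALSE], method = "euclidean"))
  sim <- -abs(d)
  diag(sim) <- 0
  methods::new("SimilarityMatrix", values = sim,
               metricName = paste0("shape_", tolower(parameter)))
}
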