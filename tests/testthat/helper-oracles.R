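## Independent oracles used to validate the package's computations.  These
## deliberately avoid the package's internal shortcuts (canonicalization,
## vectorised lookups, closed-form tails).

## Expand a ShapeTable into an explicit 1024-entry lookup (named list of
## 6-value vectors), spelling out the reverse-complement expansion.
expandShapeLookup <- function(table) {
  v <- shapeValues(table)
  fwd <- lapply(rownames(v), function(p) v[p, ])
  rev <- lapply(rownames(v), function(p)
    c(MGW = v[p, "MGW"], ProT = v[p, "ProT"],
      Roll1 = v[p, "Roll2"], Roll2 = v[p, "Roll1"],
      HelT1 = v[p, "HelT2"], HelT2 = v[p, "HelT1"]))
  out <- c(fwd, rev)
  names(out) <- c(rownames(v), revComp(rownames(v)))
  out
}

## Naive per-window shape scan: plain loops, no canonicalization shortcuts.
## Window starting at w covers bases w..w+4; its centre base is w+2 and its
## two central steps are (w+1,w+2) -> step w+1 and (w+2,w+3) -> step w+2.
## Pass a prebuilt lookup when scanning many sequences against one table.
naiveShapeScan <- function(seq, table, lk = expandShapeLookup(table)) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(s)
  mgw <- prot <- rep(NA_real_, L)
  rollS <- heltS <- numeric(L - 1)
  nC <- integer(L - 1)
  for (w in seq_len(L - 4)) {
    pent <- paste(s[w:(w + 4)], collapse = "")
    vals <- lk[[pent]]
    mgw[w + 2] <- vals[["MGW"]]
    prot[w + 2] <- vals[["ProT"]]
    rollS[w + 1] <- rollS[w + 1] + vals[["Roll1"]]
    heltS[w + 1] <- heltS[w + 1] + vals[["HelT1"]]
    rollS[w + 2] <- rollS[w + 2] + vals[["Roll2"]]
    heltS[w + 2] <- heltS[w + 2] + vals[["HelT2"]]
    nC[w + 1] <- nC[w + 1] + 1L
    nC[w + 2] <- nC[w + 2] + 1L
  }
  roll <- helt <- rep(NA_real_, L - 1)
  roll[nC > 0] <- rollS[nC > 0] / nC[nC > 0]
  helt[nC > 0] <- heltS[nC > 0] / nC[nC > 0]
  list(mgw = mgw, prot = prot, roll = roll, helt = helt)
}

## Upper-tail hypergeometric probability P(K >= k) by exhaustive enumeration
## of all s-subsets of N proteins against a fixed m-set (N <= 12).
enumHyperTail <- function(N, s, m, k) {
  if (s == 0L) return(if (k <= 0L) 1 else 0)
  subsets <- utils::combn(N, s)
  overlaps <- colSums(subsets <= m)   # narrow set taken as proteins 1..m
  mean(overlaps >= k)
}

## Plug-in mutual information in bits by direct double summation.
directMI <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        pi_ <- sum(tab[i, ]) / n
        p_j <- sum(tab[, j]) / n
        total <- total + pij * log2(pij / (pi_ * p_j))
      }
    }
  }
  total
}

## AUC by brute-force concordant-pair counting.
bruteAUC <- function(predicted, labels) {
  pos <- predicted[labels]
  neg <- predicted[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

## Pearson correlation by the direct sum formula.
directPCC <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
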