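test_that("matrix-level PCC behaves on self, negation and direct evaluation", {
  set.seed(7)
  v <- matrix(rnorm(16), 4); v <- v + t(v); diag(v) <- 0
  a <- simMat(v)
  expect_equal(matrixPCC(a, a)$pcc, 1)
  expect_equal(matrixPCC(a, simMat(-v))$pcc, -1)

  w <- matrix(rnorm(16), 4); w <- w + t(w); diag(w) <- 0
  b <- simMat(w)
  r <- matrixPCC(a, b)
  expect_identical(r$nPairs, 6L)
  expect_equal(r$pcc, directPCC(v[upper.tri(v)], w[upper.tri(w)]))
})

test_that("matrix PCC is invariant to a common relabeling of both matrices", {
  set.seed(8)
  v <- matrix(rnorm(25), 5); v <- v + t(v)
  w <- matrix(rnorm(25), 5); w <- w + t(w)
  p <- sample(5)
  r1 <- matrixPCC(simMat(v), simMat(w))
  r2 <- matrixPCC(simMat(v[p, p]), simMat(w[p, p]))
  expect_equal(r1$pcc, r2$pcc)
})

test_that("matrix PCC rejects label mismatches and zero variance", {
  m <- matrix(rnorm(16), 4)
  a <- simMat(m + t(m))
  z <- simMat(matrix(0, 4, 4))
  expect_error(matrixPCC(a, z), "zero variance")
  b <- a; rownames(b@values) <- colnames(b@values) <- letters[1:4]
  expect_error(matrixPCC(a, b), "label")
})

test_that("shuffle null is seed-reproducible and bounds extreme p at 1/(n+1)", {
  set.seed(10)
  base <- matrix(rnorm(36), 6); base <- base + t(base)
  noise <- matrix(rnorm(36, sd = 0.01), 6)
  other <- simMat(base + noise + t(noise))
  a <- simMat(base)
  n1 <- shuffleNull(a, other, nShuffles = 200, seed = 42)
  n2 <- shuffleNull(a, other, nShuffles = 200, seed = 42)
  expect_identical(n1$null, n2$null)
  ## near-identical matrices: observed PCC ~ 1, outside every permuted value
  expect_equal(n1$p, 1 / 201)
})

test_that("permuting the similarity matrix equals recomputing from a shuffled cohort", {
  set.seed(11)
  aas <- Biostrings::AA_STANDARD
  seqs <- vapply(1:6, function(i)
    paste(sample(aas, 10, replace = TRUE), collapse = ""), character(1))
  cohort <- makeCohort(seqs)
  sim <- proteinSimilarity(cohort)
  p <- sample(6)
  shuffled <- makeCohort(stats::setNames(seqs[p], names(seqs)))
  simShuffled <- proteinSimilarity(shuffled)
  expect_equal(unname(similarityValues(simShuffled)),
               unname(similarityValues(sim)[p, p]))
})

test_that("binned PCC with generous bins equals the unbinned correlation", {
  set.seed(12)
  v <- matrix(rnorm(64), 8); v <- v + t(v)
  w <- matrix(runif(64), 8); w <- (w + t(w)) / 2; diag(w) <- 1
  a <- simMat(v)
  b <- simMat(w, metric = "dna_pfm_pcc")
  r <- binnedPCC(a, b, nPerBin = 1000L, seed = 1)
  expect_equal(r$pcc, matrixPCC(a, b)$pcc)
  expect_identical(length(r$binCounts), 7L)  # default seven-bin layout
})

test_that("narrow-groove calls are threshold-inclusive", {
  profs <- list(madeProfile("a", mgw = c(5.12, 5.13)),
                madeProfile("b", mgw = c(4.9, NA)))
  calls <- callNarrowGroove(profs)
  expect_identical(unname(calls@calls["a", ]), c(TRUE, FALSE))
  expect_identical(unname(calls@calls["b", ]), c(TRUE, NA))
  expect_identical(calls@threshold, 5.12)
  for (th in c(4.9, 5.0, 5.1, 5.2)) {
    c2 <- callNarrowGroove(profs, threshold = th)
    expect_identical(unname(c2@calls["a", 1]), 5.12 <= th)
  }
})

test_that("hypergeometric map reproduces the enumerated 1/6 case and k=0", {
  fx <- hyperFixture(N = 4, s = 2, m = 2, k = 2)
  P <- hypergeometricMap(fx$cohort, fx$calls)
  expect_equal(P[1, 1], 1 / 6)
  expect_equal(P[1, 1], enumHyperTail(4, 2, 2, 2))
  fx0 <- hyperFixture(N = 6, s = 3, m = 2, k = 0)
  expect_equal(hypergeometricMap(fx0$cohort, fx0$calls)[1, 1], 1)
})

test_that("hypergeometric p is monotone nonincreasing in the overlap", {
  for (N in c(6, 9)) for (s in c(3, 5)) for (m in c(2, 4)) {
    ks <- max(0, s + m - N):min(s, m)
    ps <- vapply(ks, function(k) {
      fx <- hyperFixture(N, s, m, k)
      hypergeometricMap(fx$cohort, fx$calls)[1, 1]
    }, numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("vacuous cells record p = 1 with a degenerate flag", {
  fx <- hyperFixture(N = 5, s = 0, m = 2, k = 0)
  P <- hypergeometricMap(fx$cohort, fx$calls)
  expect_identical(P[1, 1], 1)
  expect_true(attr(P, "degenerate")[1, 1])
})

test_that("MI map: independence gives 0, perfect binary dependence gives 1 bit", {
  res <- rep(c("R", "R", "A", "A"), 2)
  cal <- rep(c(TRUE, FALSE), 4)  # product structure: independent
  cohort <- makeCohort(res)
  calls <- methods::new("NarrowGrooveCall",
                        calls = matrix(cal, 8, 1,
                                       dimnames = list(names(cohort@msa), "pos1")),
                        threshold = 5.12)
  expect_equal(miMap(cohort, calls)[1, 1], 0)

  cal2 <- res == "R"            # perfectly matched, both at frequency 1/2
  calls2 <- methods::new("NarrowGrooveCall",
                         calls = matrix(cal2, 8, 1,
                                        dimnames = list(names(cohort@msa), "pos1")),
                         threshold = 5.12)
  expect_equal(miMap(cohort, calls2)[1, 1], 1)
})

test_that("MI matches direct summation on a specified 6-protein table", {
  res <- c("R", "R", "K", "A", "A", "A")
  cal <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  cohort <- makeCohort(res)
  calls <- methods::new("NarrowGrooveCall",
                        calls = matrix(cal, 6, 1,
                                       dimnames = list(names(cohort@msa), "pos1")),
                        threshold = 5.12)
  expect_equal(miMap(cohort, calls)[1, 1], directMI(res, cal))
})

test_that("MI is relabeling-invariant and bounded by min(H(residue), 1)", {
  set.seed(14)
  for (i in 1:10) {
    res <- sample(c("R", "K", "Q", "A"), 12, replace = TRUE)
    cal <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    cohort <- makeCohort(res)
    relab <- makeCohort(chartr("RKQA", "WYFD", res))
    calls <- methods::new("NarrowGrooveCall",
                          calls = matrix(cal, 12, 1,
                                         dimnames = list(names(cohort@msa), "pos1")),
                          threshold = 5.12)
    m1 <- miMap(cohort, calls)[1, 1]
    expect_equal(miMap(relab, calls)[1, 1], m1)
    pr <- table(res) / 12
    expect_lte(m1, min(-sum(pr * log2(pr)), 1) + 1e-9)
  }
})

test_that("groove profiles by residue recover a planted narrowing", {
  set.seed(15)
  n <- 30
  profs <- c(
    lapply(seq_len(n), function(i)
      madeProfile(sprintf("R%02d", i), mgw = rnorm(8, 5.4, 0.1) - c(0, 0.5, 0, 0, 0, 0, 0, 0))),
    lapply(seq_len(n), function(i)
      madeProfile(sprintf("O%02d", i), mgw = rnorm(8, 5.4, 0.1))))
  res <- c(rep("R", n), rep("A", n))
  cohort <- makeCohort(stats::setNames(res, vapply(profs, function(p) p@proteinId, "")))
  g <- grooveProfilesByResidue(cohort, profs, column = 1)
  expect_true(g$flags["R", 2])
  expect_lt(g$curves["R", 2], g$curves["other", 2] - 0.3)
})

test_that("identical MGW distributions rarely produce flags at 5e-5", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed + 300)
    profs <- lapply(1:30, function(i)
      madeProfile(sprintf("p%02d", i), mgw = rnorm(6, 5.4, 0.15)))
    res <- rep(c("R", "A"), 15)
    cohort <- makeCohort(stats::setNames(res, vapply(profs, function(p) p@proteinId, "")))
    g <- grooveProfilesByResidue(cohort, profs, column = 1)
    if (any(g$flags, na.rm = TRUE)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("degenerate groupings are reported without tests", {
  profs <- lapply(1:4, function(i) madeProfile(sprintf("p%d", i), mgw = rep(5.4, 6)))
  cohort <- makeCohort(stats::setNames(rep("A", 4),
                                       vapply(profs, function(p) p@proteinId, "")))
  g <- grooveProfilesByResidue(cohort, profs, column = 1)
  expect_identical(rownames(g$curves), "other")
  expect_identical(nrow(g$pvalues), 0L)
})
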