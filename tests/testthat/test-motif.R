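test_that("8-mer selection applies the E-score threshold", {
  sel <- selectKmers(c(AAAATTAA = 0.46, CCCCCCCC = 0.10))
  expect_identical(sel$kmer, "AAAATTAA")
  expect_identical(sel$escore, 0.46)
})

test_that("selection collapses reverse-complement pairs to one representative", {
  s <- "TAATTACG"
  sel <- selectKmers(stats::setNames(c(0.46, 0.47), c(s, revComp(s))))
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$kmer, canonicalKmer(s))
  expect_identical(sel$escore, 0.47)
})

test_that("an empty selection advises reviewing the threshold", {
  expect_error(selectKmers(c(AAAATTAA = 0.2, CCCCCCCC = 0.1)), "threshold")
})

test_that("consensus scan places TTAATTAC at the TAATT window", {
  bs <- alignToConsensus("TTAATTAC", motifVariant = "NNAYN")
  expect_identical(length(bs@sequence), 1L)
  ## both strands match at j = 2 with equal likelihood; the tie resolves to
  ## the canonical orientation GTAATTAA (so a revcomp input aligns identically)
  expect_identical(bs@strand, "-")
  expect_identical(bs@offset, 2L)         # pattern window at k-mer positions 2-6
  expect_identical(bs@sequence, "GTAATTAA")
  ## the matched window is TAATT: A at pattern position 3, T (in Y) at 4
  expect_identical(substr(bs@sequence, 2, 6), "TAATT")
})

test_that("k-mers without a consensus match are dropped with a count", {
  expect_error(alignToConsensus("GGGGGGGG", motifVariant = "NNAYN"), "no k-mer")
  expect_message(bs <- alignToConsensus(c("TTAATTAC", "GGGGGGGG"),
                                        motifVariant = "NNAYN"), "1 k-mer")
  expect_identical(attr(bs, "nDropped"), 1L)
  expect_identical(length(bs@sequence), 1L)
})

test_that("reference-PFM disambiguation matches exhaustive placement scoring", {
  ## CCATTATC has NNAYN windows at j = 1 and j = 4 (plus) and j = 3 (minus)
  kmer <- "CCATTATC"
  freq <- matrix(0.02, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  set.seed(8)
  for (j in 1:8) {
    fav <- sample(4, 1)
    freq[, j] <- 0.04; freq[fav, j] <- 0.88
  }
  ref <- methods::new("PFM", proteinId = "ref", freq = freq, nSites = 10L,
                      coverage = rep(10L, 8))
  bs <- alignToConsensus(kmer, motifVariant = "NNAYN", referencePfm = ref)

  ## independent exhaustive scoring of all placements on both strands
  pat <- list(c("A","C","G","T"), c("A","C","G","T"), "A", c("C","T"),
              c("A","C","G","T"))
  best <- -Inf; bestPl <- NULL
  for (strand in c("+", "-")) {
    s <- strsplit(if (strand == "+") kmer else revComp(kmer), "", fixed = TRUE)[[1]]
    for (j in 1:4) {
      if (!all(mapply(function(b, set) b %in% set, s[j:(j + 4)], pat))) next
      offset <- 3 - j + 1
      ll <- 0
      for (q in seq_along(s)) {
        f <- offset + q - 1
        if (f >= 1 && f <= 8) ll <- ll + log(max(freq[s[q], f], 1e-3))
      }
      if (ll > best + 1e-9) { best <- ll; bestPl <- list(strand, offset) }
    }
  }
  expect_identical(bs@strand, bestPl[[1]])
  expect_identical(bs@offset, as.integer(bestPl[[2]]))
})

test_that("PFM of a single placed site is a 0/1 indicator matrix", {
  bs <- methods::new("BindingSiteSet", proteinId = "x", sequence = "AATTAATT",
                     escore = NA_real_, strand = "+", offset = 1L,
                     frameWidth = 8L)
  pfm <- buildPFM(bs)
  expect_true(all(pfm@freq %in% c(0, 1)))
  expect_identical(unname(pfm@freq["A", 1]), 1)
  expect_identical(unname(pfm@freq["T", 3]), 1)
  expect_identical(pfm@coverage, rep(1L, 8))
})

test_that("aligning the reverse-complemented k-mer list gives the same alignment", {
  kmers <- c("TTAATTAC", "CCATTATC", "ATAATGGC", "TAATTAGC", "ACTTAATT")
  b1 <- suppressMessages(alignToConsensus(kmers, motifVariant = "NNAYN",
                                          proteinId = "x"))
  b2 <- suppressMessages(alignToConsensus(revComp(kmers), motifVariant = "NNAYN",
                                          proteinId = "x"))
  ## identical oriented sequences at identical frame offsets
  expect_identical(b1@sequence, b2@sequence)
  expect_identical(b1@offset, b2@offset)
})

test_that("column frequencies match hand counting on specified placements", {
  seqs <- c("AATTAATT", "TAATTACG", "CTAATTAC", "TAATTGGG")
  offs <- c(1L, 1L, 0L, 2L)
  bs <- methods::new("BindingSiteSet", proteinId = "x", sequence = seqs,
                     escore = rep(NA_real_, 4), strand = rep("+", 4),
                     offset = offs, frameWidth = 8L)
  pfm <- buildPFM(bs)
  ## independent tally
  counts <- matrix(0, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in 1:4) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (q in 1:8) {
      f <- offs[i] + q - 1
      if (f >= 1 && f <= 8) counts[s[q], f] <- counts[s[q], f] + 1
    }
  }
  expect_equal(pfm@freq, sweep(counts, 2, colSums(counts), "/"))
  ## rebuilding from the same sites is idempotent
  expect_equal(buildPFM(bs)@freq, pfm@freq)
  expect_equal(colSums(pfm@freq), rep(1, 8))
})

test_that("a zero-coverage column is an error", {
  bs <- methods::new("BindingSiteSet", proteinId = "x", sequence = "TAATTACG",
                     escore = NA_real_, strand = "+", offset = 2L,
                     frameWidth = 10L)
  expect_error(buildPFM(bs), "zero coverage")
})

test_that("PFM similarity is 1 for identical PFMs and -1/3 for disjoint columns", {
  f1 <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  f2 <- matrix(c(0, 1, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  mk <- function(id, f) methods::new("PFM", proteinId = id, freq = f,
                                     nSites = 1L, coverage = 1L)
  v <- similarityValues(pfmSimilarity(list(mk("a", f1), mk("b", f1), mk("c", f2))))
  expect_identical(unname(v["a", "b"]), 1)
  expect_equal(unname(v["a", "c"]), -1/3)
  expect_equal(unname(v["a", "c"]), directPCC(as.vector(f1), as.vector(f2)))
  expect_true(all(diag(v) == 1))
})

test_that("a fully uniform PFM is rejected by name", {
  fu <- matrix(0.25, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  f1 <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 4, 2,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  mk <- function(id, f) methods::new("PFM", proteinId = id, freq = f,
                                     nSites = 1L, coverage = c(1L, 1L))
  expect_error(pfmSimilarity(list(mk("good", f1), mk("flat", fu))), "flat")
})

test_that("E-score tables round-trip through TSV", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  esc <- c(AAAATTAA = 0.46, CCCCCCCC = 0.10)
  writeEscoreTable(esc, tf)
  expect_equal(readEscoreTable(tf), esc)
})

test_that("MEME minimal output carries the frequency rows", {
  bs <- methods::new("BindingSiteSet", proteinId = "x", sequence = "AATTAATT",
                     escore = NA_real_, strand = "+", offset = 1L,
                     frameWidth = 8L)
  tf <- withr::local_tempfile(fileext = ".meme")
  writeMemePFM(buildPFM(bs), tf)
  ln <- readLines(tf)
  expect_true(any(grepl("^MOTIF x$", ln)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 8", ln)))
})
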