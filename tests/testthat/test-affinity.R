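makeSiteSet <- function(seqs, offs, escores = NULL) {
  if (is.null(escores)) escores <- rep(NA_real_, length(seqs))
  methods::new("BindingSiteSet", proteinId = "x", sequence = seqs,
               escore = escores, strand = rep("+", length(seqs)),
               offset = as.integer(offs), frameWidth = 8L)
}

test_that("featurization flags fills and assigns table averages there", {
  st <- simulateShapeTable(seed = 21)
  mu <- ShapeCovar:::.tableMeans(st)
  ## fully inside the frame: no extension flags
  fx1 <- featurize(makeSiteSet("TAATTACG", 1L), st, seed = 5)
  expect_false(any(fx1$flags))
  ## 2-base 5' fill (offset 3): frame positions 1-2 randomized, shape = average
  fx2 <- featurize(makeSiteSet("TAATTACG", 3L), st, seed = 5)
  expect_identical(unname(fx2$flags[1, 1:2]), c(TRUE, TRUE))
  expect_false(any(fx2$flags[1, 3:8]))
  expect_equal(unname(fx2$shape[1, c("MGW1", "MGW2")]),
               rep(unname(mu["MGW"]), 2))
  ## one-hot columns sum to 1 at every frame position
  for (f in 1:8)
    expect_equal(sum(fx2$seq[1, (f - 1) * 4 + 1:4]), 1)
})

test_that("covered positions carry the site's own pentamer predictions", {
  st <- simulateShapeTable(seed = 22)
  s <- "TAATTACG"
  fx <- featurize(makeSiteSet(s, 1L), st, seed = 5)
  sh <- predictShape(s, st)
  expect_equal(unname(fx$shape[1, paste0("MGW", 3:6)]), sh$mgw[3:6])
  expect_equal(unname(fx$shape[1, paste0("Roll", 2:6)]), sh$roll[2:6])
  mu <- ShapeCovar:::.tableMeans(st)
  expect_equal(unname(fx$shape[1, c("MGW1", "MGW2", "MGW7", "MGW8")]),
               rep(unname(mu["MGW"]), 4))
})

test_that("featurization is deterministic given the seed", {
  st <- simulateShapeTable(seed = 23)
  ss <- makeSiteSet(c("TAATTACG", "CTAATTAC"), c(3L, 0L))
  f1 <- featurize(ss, st, seed = 11)
  f2 <- featurize(ss, st, seed = 11)
  expect_identical(f1, f2)
})

test_that("a noise-free linear target in sequence features is fit exactly", {
  st <- simulateShapeTable(seed = 24)
  set.seed(31)
  kmers <- unique(replicate(400, paste(
    c(sample(c("A","C","G","T"), 2, TRUE), "A",
      sample(c("C","T"), 1), sample(c("A","C","G","T"), 4, TRUE)),
    collapse = "")))
  ss <- makeSiteSet(kmers, rep(3L, length(kmers)))
  fx <- featurize(ss, st, seed = 7)
  beta <- rnorm(ncol(fx$seq), sd = 0.05)
  y <- drop(fx$seq %*% beta)
  for (v in c("seq", "seq+shape", "seq+shuffled-shape")) {
    cv <- fitAffinityCV(fx, escores = y, variant = v, folds = 10,
                        repeats = 3, seed = 2)
    expect_gt(mean(cv@r2), 0.999)
  }
})

test_that("pure-noise E-scores give near-zero cross-validated R2", {
  st <- simulateShapeTable(seed = 25)
  set.seed(32)
  kmers <- unique(replicate(400, paste(
    c(sample(c("A","C","G","T"), 2, TRUE), "A",
      sample(c("C","T"), 1), sample(c("A","C","G","T"), 4, TRUE)),
    collapse = "")))
  ss <- makeSiteSet(kmers, rep(3L, length(kmers)))
  fx <- featurize(ss, st, seed = 7)
  y <- rnorm(length(kmers), 0, 0.1)
  cv <- fitAffinityCV(fx, escores = y, variant = "seq", folds = 10,
                      repeats = 5, seed = 2)
  expect_lt(mean(cv@r2), 0.05)
})

test_that("fold assignment is seed-reproducible and covers every 8-mer", {
  st <- simulateShapeTable(seed = 26)
  ss <- makeSiteSet(rep(c("TAATTACG", "CTAATTAC", "TTAATTAC", "ATAATGGC"), 5),
                    rep(c(1L, 0L, 2L, 1L), 5))
  fx <- featurize(ss, st, seed = 1)
  y <- runif(20, -0.4, 0.4)
  a <- fitAffinityCV(fx, escores = y, variant = "seq", folds = 5, repeats = 4, seed = 9)
  b <- fitAffinityCV(fx, escores = y, variant = "seq", folds = 5, repeats = 4, seed = 9)
  expect_identical(a@r2, b@r2)
  expect_identical(a@predictions, b@predictions)
  expect_identical(length(a@predictions), 20L)
  expect_identical(length(a@r2), 4L)
})

test_that("per-parameter ablation variants use only that shape block", {
  st <- simulateShapeTable(seed = 27)
  ss <- makeSiteSet(rep(c("TAATTACG", "CTAATTAC", "TTAATTAC", "ATAATGGC"), 5),
                    rep(c(1L, 0L, 2L, 1L), 5))
  fx <- featurize(ss, st, seed = 1)
  y <- runif(20, -0.4, 0.4)
  cv <- fitAffinityCV(fx, escores = y, variant = "seq+MGW", folds = 5,
                      repeats = 2, seed = 9)
  expect_identical(cv@variant, "seq+MGW")
  expect_identical(length(cv@r2), 2L)
})

test_that("AUC: perfect separation, discordant-pair formula, U equivalence", {
  obs <- c(0.5, 0.5, 0.5, 0.1, 0.1, 0.1)
  expect_equal(rocAuc(c(6, 5, 4, 3, 2, 1), obs)$auc, 1)
  ## exactly one discordant pair among 3x3: AUC = 1 - 1/9
  pred <- c(3, 2, 0.5, 1, 0, -1)
  expect_equal(rocAuc(pred, obs)$auc, 1 - 1 / 9)
  expect_equal(rocAuc(pred, obs)$auc, bruteAUC(pred, obs >= 0.45))
  set.seed(33)
  for (i in 1:10) {
    p <- sample(seq_len(40))  # tie-free
    lab <- runif(40) < 0.4
    if (!any(lab) || all(lab)) next
    expect_equal(rocAuc(p, ifelse(lab, 0.5, 0))$auc, bruteAUC(p, lab))
  }
})

test_that("label-independent predictions give AUC near 1/2 on average", {
  set.seed(34)
  aucs <- replicate(50, {
    pred <- rnorm(60)
    obs <- ifelse(runif(60) < 0.3, 0.5, 0.1)
    if (length(unique(obs >= 0.45)) < 2) return(NA_real_)
    rocAuc(pred, obs)$auc
  })
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.05)
})

test_that("single-class inputs are rejected", {
  expect_error(rocAuc(1:5, rep(0.5, 5)), "nonempty")
})
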