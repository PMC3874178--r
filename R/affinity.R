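## Shape-augmented multiple linear regression of per-8-mer binding affinity.

#' Sequence and shape features for placed 8-mers
#'
#' For every placed site the binding-site frame is filled out: frame
#' positions not covered by the 8-mer receive a randomly drawn nucleotide
#' (seeded, drawn once per k-mer per run), and the four shape parameters are
#' taken from the site's own pentamer prediction where defined, with the
#' table-average value of the corresponding parameter assigned to every
#' added or edge position.  Sequence features are per-position one-hot
#' indicators; extension flags mark the randomized fill positions.
#'
#' @param siteset a \code{\link{BindingSiteSet}} from
#'   \code{\link{alignToConsensus}}.
#' @param table a \code{\link{ShapeTable}}.
#' @param seed integer governing the flank randomization.
#' @return list with matrices \code{seq} (n x 4W one-hot), \code{shape}
#'   (n x (2W + 2(W-1)): MGW, ProT per position, Roll, HelT per step),
#'   \code{flags} (n x W logical), plus \code{kmers} and \code{escores}.
#' @export
featurize <- function(siteset, table, seed = NULL) {
  stopifnot(methods::is(siteset, "BindingSiteSet"),
            methods::is(table, "ShapeTable"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(siteset@sequence)
  if (n == 0L) stop("empty site set")
  W <- siteset@frameWidth
  mu <- .tableMeans(table)

  seqF <- matrix(0, n, 4L * W)
  colnames(seqF) <- paste0(rep(DNA_BASES, W), rep(seq_len(W), each = 4L))
  shapeF <- matrix(NA_real_, n, 2L * W + 2L * (W - 1L))
  colnames(shapeF) <- c(paste0("MGW", seq_len(W)), paste0("ProT", seq_len(W)),
                        paste0("Roll", seq_len(W - 1L)), paste0("HelT", seq_len(W - 1L)))
  flags <- matrix(FALSE, n, W)

  for (i in seq_len(n)) {
    s <- strsplit(siteset@sequence[i], "", fixed = TRUE)[[1]]
    f <- siteset@offset[i] + seq_along(s) - 1L
    frameBase <- rep(NA_character_, W)
    inside <- f >= 1L & f <= W
    frameBase[f[inside]] <- s[inside]
    fill <- is.na(frameBase)
    if (any(fill)) {
      frameBase[fill] <- sample(DNA_BASES, sum(fill), replace = TRUE)
      flags[i, fill] <- TRUE
    }
    seqF[i, (seq_len(W) - 1L) * 4L + match(frameBase, DNA_BASES)] <- 1

    sh <- predictShape(siteset@sequence[i], table)
    mgw <- rep(mu["MGW"], W); prot <- rep(mu["ProT"], W)
    roll <- rep(mu["Roll"], W - 1L); helt <- rep(mu["HelT"], W - 1L)
    ok <- inside & !is.na(sh$mgw)
    mgw[f[ok]] <- sh$mgw[ok]
    prot[f[ok]] <- sh$prot[ok]
    fs <- siteset@offset[i] + seq_len(length(s) - 1L) - 1L
    okS <- fs >= 1L & fs <= W - 1L & !is.na(sh$roll)
    roll[fs[okS]] <- sh$roll[okS]
    helt[fs[okS]] <- sh$helt[okS]
    shapeF[i, ] <- c(mgw, prot, roll, helt)
  }
  list(seq = seqF, shape = shapeF, flags = flags,
       kmers = siteset@sequence, escores = siteset@escore,
       proteinId = siteset@proteinId)
}

.lsPredict <- function(Xtr, ytr, Xte) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xtr), ytr)
  beta <- fit$coefficients
  if (anyNA(beta)) beta[is.na(beta)] <- 0  # aliased columns dropped by pivoting
  drop(cbind(1, Xte) %*% beta)
}

#' Cross-validated affinity model
#'
#' Fits a multiple linear regression predicting per-8-mer E-scores from
#' sequence features alone (\code{"seq"}), sequence plus the four shape
#' parameters (\code{"seq+shape"}), or sequence plus row-shuffled shape
#' parameters (\code{"seq+shuffled-shape"}; the shuffle is redrawn once per
#' repeat).  Per repeat, the 8-mers are randomly partitioned into
#' \code{folds} groups; each group is predicted by a least-squares model
#' trained on the others, until every 8-mer is predicted exactly once.  The
#' per-repeat R-squared is the squared Pearson correlation between predicted
#' and observed E-scores over all 8-mers (not the in-sample coefficient of
#' determination; the two differ under cross-validation).  Rank-deficient
#' designs are handled by pivoting (aliased columns dropped), which yields
#' valid least-squares predictions.
#'
#' @param features list from \code{\link{featurize}}, or a list with
#'   matrices \code{seq} and \code{shape}.
#' @param escores numeric response per 8-mer (defaults to the E-scores
#'   carried in \code{features}).
#' @param variant model variant; \code{"seq+shape"} may also name a single
#'   parameter block, e.g. \code{"seq+MGW"}, for per-parameter ablations.
#' @param folds,repeats cross-validation layout (defaults 10 and 50).
#' @param seed integer seed; fold assignment is seed-reproducible.
#' @param aucThreshold bound/unbound E-score threshold for the ROC summary.
#' @return an \code{\link{AffinityCV}}.
#' @export
fitAffinityCV <- function(features, escores = NULL,
                          variant = c("seq", "seq+shape", "seq+shuffled-shape",
                                      "seq+MGW", "seq+ProT", "seq+Roll", "seq+HelT"),
                          folds = 10L, repeats = 50L, seed = NULL,
                          aucThreshold = 0.45) {
  variant <- match.arg(variant)
  y <- if (is.null(escores)) features$escores else escores
  if (anyNA(y)) stop("E-scores must be complete")
  n <- length(y)
  if (n < folds) stop("need at least as many observations as folds")
  Xseq <- features$seq
  Xshape <- features$shape
  if (variant %in% c("seq+MGW", "seq+ProT", "seq+Roll", "seq+HelT")) {
    par <- sub("^seq\\+", "", variant)
    Xshape <- Xshape[, grep(paste0("^", par), colnames(Xshape)), drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  r2 <- numeric(repeats)
  predSum <- numeric(n)
  for (rep_i in seq_len(repeats)) {
    X <- switch(variant,
                seq = Xseq,
                `seq+shuffled-shape` = cbind(Xseq, Xshape[sample.int(n), , drop = FALSE]),
                cbind(Xseq, Xshape))
    fold <- sample(rep(seq_len(folds), length.out = n))
    pred <- numeric(n)
    for (fd in seq_len(folds)) {
      te <- fold == fd
      pred[te] <- .lsPredict(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE])
    }
    r2[rep_i] <- stats::cor(pred, y)^2
    predSum <- predSum + pred
  }
  predictions <- predSum / repeats
  names(predictions) <- features$kmers
  lab <- y >= aucThreshold
  auc <- if (length(unique(lab)) == 2L) rocAuc(predictions, y, aucThreshold)$auc
         else NA_real_
  methods::new("AffinityCV",
               proteinId = if (is.null(features$proteinId)) "" else features$proteinId,
               variant = variant, r2 = r2, predictions = predictions, auc = auc)
}

#' ROC curve and AUC for bound/unbound 8-mer classification
#'
#' Observations with E-score at or above the threshold are true positives,
#' the rest true negatives.  The AUC is computed by the rank (Mann-Whitney)
#' method with midranks for ties, equal to the trapezoidal area under the
#' ROC curve.
#'
#' @param predicted numeric predicted scores.
#' @param observed numeric observed E-scores.
#' @param threshold bound/unbound cutoff (default 0.45).
#' @return list with \code{auc} and \code{curve} (data frame of FPR/TPR).
#' @export
rocAuc <- function(predicted, observed, threshold = 0.45) {
  lab <- observed >= threshold
  nPos <- sum(lab); nNeg <- sum(!lab)
  if (nPos == 0L || nNeg == 0L)
    stop("both bound and unbound classes must be nonempty")
  rk <- rank(predicted)  # midranks on ties
  auc <- (sum(rk[lab]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ord <- order(predicted, decreasing = TRUE)
  tpr <- cumsum(lab[ord]) / nPos
  fpr <- cumsum(!lab[ord]) / nNeg
  ## collapse tied thresholds to single curve points
  keep <- !duplicated(predicted[ord], fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
  list(auc = auc, curve = curve)
}
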