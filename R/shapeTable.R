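## Pentamer shape lookup table: construction, IO, canonicalization.

#' Construct a ShapeTable
#'
#' Accepts either the 512 canonical pentamers or all 1024 raw pentamers.  In
#' the raw form, values of reverse-complement pairs must be consistent: equal
#' MGW/ProT and swapped step parameters (\code{Roll1(p) == Roll2(revcomp(p))},
#' likewise HelT); inconsistent pairs are an error naming the pair.
#'
#' @param pentamer character vector of pentamers over {A,C,G,T}.
#' @param MGW,ProT numeric, base-pair parameters of the central base.
#' @param Roll1,Roll2,HelT1,HelT2 numeric, the two central step parameters.
#' @param tol numeric tolerance for reverse-complement consistency.
#' @return a \code{\link{ShapeTable}}.
#' @export
ShapeTable <- function(pentamer, MGW, ProT, Roll1, Roll2, HelT1, HelT2,
                       tol = 1e-6) {
  pentamer <- toupper(as.character(pentamer))
  .checkDnaAlphabet(pentamer, "pentamer")
  if (anyDuplicated(pentamer))
    stop("duplicated pentamer keys: ",
         paste(utils::head(unique(pentamer[duplicated(pentamer)]), 3L), collapse = ", "))
  v <- cbind(MGW = as.numeric(MGW), ProT = as.numeric(ProT),
             Roll1 = as.numeric(Roll1), Roll2 = as.numeric(Roll2),
             HelT1 = as.numeric(HelT1), HelT2 = as.numeric(HelT2))
  if (!all(is.finite(v))) {
    bad <- pentamer[!stats::complete.cases(v) | rowSums(!is.finite(v)) > 0]
    stop("non-finite shape values for: ", paste(utils::head(bad, 3L), collapse = ", "))
  }
  rownames(v) <- pentamer
  canon <- canonicalPentamers()
  if (nrow(v) == 1024L) {
    ## raw dialect: verify revcomp consistency, then keep canonical rows
    if (!setequal(pentamer, .pasteRows(.allKmerChars(5L))))
      stop("raw 1024-pentamer table must contain every pentamer exactly once")
    rc <- revComp(canon)
    a <- v[canon, , drop = FALSE]
    b <- v[rc, , drop = FALSE]
    swapped <- b[, c("MGW", "ProT", "Roll2", "Roll1", "HelT2", "HelT1")]
    colnames(swapped) <- colnames(b)
    dev <- abs(a - swapped)
    bad <- which(apply(dev, 1L, max) > tol)
    if (length(bad))
      stop("reverse-complement inconsistent pentamer pair(s): ",
           paste(utils::head(sprintf("%s/%s", canon[bad], rc[bad]), 3L), collapse = ", "))
    v <- a
  } else {
    keys <- sort(rownames(v))
    if (!identical(keys, canon)) {
      missing <- setdiff(canon, .canonNames(rownames(v)))
      if (length(setdiff(rownames(v), canon)))
        stop("table is neither canonical-512 nor raw-1024; unexpected keys: ",
             paste(utils::head(setdiff(rownames(v), canon), 3L), collapse = ", "))
      stop("missing pentamer(s): ", paste(utils::head(missing, 5L), collapse = ", "))
    }
    v <- v[canon, , drop = FALSE]
  }
  methods::new("ShapeTable", values = v)
}

.canonNames <- function(x) unique(canonicalKmer(x))

#' Read a pentamer shape table from TSV
#'
#' Expects a header line with columns \code{pentamer, MGW, ProT, Roll1, Roll2,
#' HelT1, HelT2}.  The loader resolves whether the file uses the canonical-512
#' or the raw-1024 dialect and validates completeness, finiteness and
#' reverse-complement consistency.
#'
#' @param path file path.
#' @return a \code{\link{ShapeTable}}.
#' @export
readShapeTable <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("pentamer", "MGW", "ProT", "Roll1", "Roll2", "HelT1", "HelT2")
  if (!all(need %in% colnames(d)))
    stop("shape table must have columns: ", paste(need, collapse = ", "))
  ShapeTable(d$pentamer, d$MGW, d$ProT, d$Roll1, d$Roll2, d$HelT1, d$HelT2)
}

#' Write a ShapeTable as TSV (canonical-512 dialect)
#'
#' @param table a \code{\link{ShapeTable}}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeShapeTable <- function(table, path) {
  stopifnot(methods::is(table, "ShapeTable"))
  d <- data.frame(pentamer = rownames(table@values), table@values,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Oriented lookup: rows of the 6-column value matrix for arbitrary pentamers,
## resolving non-canonical queries through reverse complementation (step
## parameters swap; base-pair parameters are strand symmetric).
.pentamerRows <- function(table, pents) {
  v <- table@values
  i <- match(pents, rownames(v))
  out <- matrix(NA_real_, length(pents), 6L,
                dimnames = list(NULL, colnames(v)))
  hit <- !is.na(i)
  out[hit, ] <- v[i[hit], , drop = FALSE]
  if (any(!hit)) {
    rc <- revComp(pents[!hit])
    j <- match(rc, rownames(v))
    if (anyNA(j))
      stop("pentamer(s) not found in table: ",
           paste(utils::head(pents[!hit][is.na(j)], 5L), collapse = ", "))
    w <- v[j, , drop = FALSE]
    out[!hit, ] <- w[, c("MGW", "ProT", "Roll2", "Roll1", "HelT2", "HelT1"),
                     drop = FALSE]
  }
  out
}

## Per-parameter table means, used as the fill value for flank-extended
## positions in the affinity features (base-pair params over 512 rows; step
## params over both step columns).
.tableMeans <- function(table) {
  v <- table@values
  c(MGW = mean(v[, "MGW"]), ProT = mean(v[, "ProT"]),
    Roll = mean(v[, c("Roll1", "Roll2")]), HelT = mean(v[, c("HelT1", "HelT2")]))
}
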