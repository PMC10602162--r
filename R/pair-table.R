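#' Build the 3x3 case/control table for one variant pair
#'
#' Tallies every individual in \code{individuals} with non-missing calls
#' at both variants into the 3 x 3 x 2 (genotype A x genotype B x status)
#' contingency table that MDR and the chi-square filter operate on.
#'
#' @param x a \linkS4class{GenotypeExperiment} with phenotype attached.
#' @param i,j variant (row) indices, \code{i != j}.
#' @param individuals indices of the individuals to tally (default: all).
#' @return a \linkS4class{PairTable}.
#' @examples
#' ge <- GenotypeExperiment(
#'   rbind(c(0L, 0L, 1L, 2L), c(0L, 1L, 1L, 2L)),
#'   data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G"),
#'   status = c(1, 0, 1, 0))
#' pairCounts(buildPairTable(ge, 1, 2))
#' @export
buildPairTable <- function(x, i, j, individuals = seq_len(ncol(x))) {
  stopifnot(is(x, "GenotypeExperiment"))
  if (i == j) stop("'i' and 'j' must name two distinct variants",
                   call. = FALSE)
  if (!length(individuals))
    stop("'individuals' must be a nonempty subset", call. = FALSE)
  st <- .checkStatusFactor(caseStatus(x))[individuals]
  g <- genotypeCalls(x)
  gi <- g[i, individuals]
  gj <- g[j, individuals]
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok))
    stop("degenerate table: no individual has complete genotypes at ",
         "variants ", i, " and ", j, call. = FALSE)
  cell <- factor(3L * gi[ok] + gj[ok], levels = 0:8)
  tab <- table(cell, factor(st[ok], levels = c("case", "control")))
  counts <- array(as.integer(tab), dim = c(3L, 3L, 2L),
                  dimnames = list(gA = .GENO_LABELS, gB = .GENO_LABELS,
                                  status = c("case", "control")))
  # table() fills cell-major: cells 0..8 are (gA, gB) with gB fastest,
  # while array dim 1 is gA -> transpose the 3x3 slices
  counts[, , 1L] <- t(matrix(tab[, "case"], 3L, 3L))
  counts[, , 2L] <- t(matrix(tab[, "control"], 3L, 3L))
  new("PairTable", counts = counts, nComplete = sum(ok))
}

#' PairTable accessors
#'
#' @param x a \linkS4class{PairTable}.
#' @param ... unused.
#' @return \code{pairCounts}: the 3x3x2 integer array;
#'   \code{nComplete}: the number of individuals tallied.
#' @name PairTable-accessors
#' @aliases pairCounts,PairTable-method nComplete,PairTable-method
#' @export
setMethod("pairCounts", "PairTable", function(x, ...) x@counts)

#' @rdname PairTable-accessors
#' @export
setMethod("nComplete", "PairTable", function(x) x@nComplete)

setMethod("show", "PairTable", function(object) {
  cat("PairTable:", object@nComplete, "individuals\n")
  cat("cases:\n"); print(object@counts[, , "case"])
  cat("controls:\n"); print(object@counts[, , "control"])
  invisible(NULL)
})

#' Pearson chi-square test of a genotype-pair table
#'
#' Tests association between the 9 genotype combinations and case/control
#' status. Genotype-combination columns with zero total are dropped and
#' the statistic is Pearson's chi-square on the remaining K x 2 table with
#' K - 1 degrees of freedom; the p-value is the upper-tail chi-square
#' probability. No continuity correction and no minimum expected-count
#' rule are applied (the scan is a raw screen); when any expected count
#' falls below 5 the result carries \code{expectedBelow5 = TRUE}.
#'
#' @param table a \linkS4class{PairTable}.
#' @return an object of class \code{"htest"} with \code{statistic},
#'   \code{parameter} (df), \code{p.value} and \code{expectedBelow5}.
#' @examples
#' ge <- GenotypeExperiment(
#'   rbind(rep(0:2, each = 10), rep(0:2, times = 10)),
#'   data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G"),
#'   status = rep(c(1, 0), 15))
#' chiSquarePair(buildPairTable(ge, 1, 2))
#' @export
chiSquarePair <- function(table) {
  stopifnot(is(table, "PairTable"))
  a <- as.vector(table@counts[, , "case"])
  b <- as.vector(table@counts[, , "control"])
  res <- .chiSquareVec(matrix(a, 1L), matrix(b, 1L))
  if (!is.na(res$skip[1L]))
    stop("undefined test: ", switch(res$skip[1L],
      one_status = "all individuals have the same status",
      single_column = "fewer than two non-empty genotype-combination columns",
      res$skip[1L]), call. = FALSE)
  structure(list(
    statistic = c("X-squared" = res$stat[1L]),
    parameter = c(df = as.integer(res$df[1L])),
    p.value = res$p[1L],
    expectedBelow5 = res$expectLT5[1L],
    method = paste("Pearson chi-square on the non-empty genotype-pair",
                   "columns vs case/control status"),
    data.name = "PairTable"), class = "htest")
}

## Vectorized Pearson chi-square over many K x 2 tables.
## a, b: m x 9 matrices of case / control counts per genotype-combination
## cell. Returns per-row statistic, df (= non-empty columns - 1), upper
## tail p, and a skip reason (NA when testable).
.chiSquareVec <- function(a, b) {
  t_ <- a + b
  Na <- rowSums(a); Nb <- rowSums(b); N <- Na + Nb
  K <- rowSums(t_ > 0)
  skip <- rep(NA_character_, nrow(a))
  skip[Na == 0 | Nb == 0] <- "one_status"
  skip[is.na(skip) & K < 2] <- "single_column"
  ok <- is.na(skip)
  Ea <- t_ * (Na / N)           # expected under independence
  Eb <- t_ * (Nb / N)
  da <- (a - Ea)^2 / Ea
  db <- (b - Eb)^2 / Eb
  da[t_ == 0] <- 0; db[t_ == 0] <- 0
  stat <- rowSums(da) + rowSums(db)
  df <- K - 1L
  p <- rep(NA_real_, nrow(a))
  p[ok] <- stats::pchisq(stat[ok], df[ok], lower.tail = FALSE)
  stat[!ok] <- NA_real_
  expectLT5 <- rowSums(t_ > 0 & (Ea < 5 | Eb < 5)) > 0
  list(stat = stat, df = ifelse(ok, df, NA_integer_), p = p,
       skip = skip, expectLT5 = expectLT5, nComplete = N)
}
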