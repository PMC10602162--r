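#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pchisq runif setNames
NULL

#' GenotypeExperiment: case-control genotype data
#'
#' A \linkS4class{SummarizedExperiment} holding biallelic genotype calls for
#' a case-control cohort. The single assay \code{"genotype"} is an integer
#' matrix (variants x individuals) coded 0 = homozygous reference (AA),
#' 1 = heterozygous (Aa), 2 = homozygous alternate (aa), \code{NA} = missing
#' call. \code{rowData} carries the variant keys (\code{chrom}, \code{pos},
#' \code{ref}, \code{alt}); \code{colData$status} (optional until analysis)
#' is a factor with levels \code{control}, \code{case}.
#'
#' @slot .
#'   inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{GenotypeExperiment}} (constructor),
#'   \code{\link{readGenotypes}}, \code{\link{simulateDataset}}
#' @name GenotypeExperiment-class
#' @exportClass GenotypeExperiment
setClass("GenotypeExperiment",
         contains = "SummarizedExperiment")

.validGenotypeExperiment <- function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    return("assay 'genotype' is required")
  g <- SummarizedExperiment::assay(object, "genotype")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(rd)))
    return(c(msg, paste("rowData must contain:", paste(need, collapse = ", "))))
  if (nrow(rd)) {
    if (any(is.na(rd$pos)) || any(rd$pos < 1))
      msg <- c(msg, "variant positions must be >= 1 (1-based)")
    nts <- c("A", "C", "G", "T")
    if (!all(rd$ref %in% nts) || !all(rd$alt %in% nts))
      msg <- c(msg, "ref/alt alleles must be single nucleotides in {A,C,G,T}")
    if (any(rd$ref == rd$alt))
      msg <- c(msg, "ref and alt alleles must differ")
    key <- paste(rd$chrom, rd$pos, rd$ref, rd$alt)
    if (anyDuplicated(key))
      msg <- c(msg, "(chrom, pos, ref, alt) must be unique across variants")
  }
  cd <- SummarizedExperiment::colData(object)
  if ("status" %in% colnames(cd)) {
    st <- cd$status
    if (!is.factor(st) || !identical(levels(st), c("control", "case")))
      msg <- c(msg, "colData$status must be a factor with levels control, case")
    if (anyNA(st))
      msg <- c(msg, "colData$status must not contain NA")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeExperiment", .validGenotypeExperiment)

#' PairTable: 3x3 case/control contingency table for a variant pair
#'
#' Joint genotype counts for one variant pair, split by phenotype: an
#' integer array of dimension 3 x 3 x 2 indexed by (genotype of variant A,
#' genotype of variant B, status). Only individuals with non-missing calls
#' at both variants contribute; \code{nComplete} records how many did.
#'
#' @slot counts 3x3x2 integer array, dimnames AA/Aa/aa x AA/Aa/aa x
#'   case/control.
#' @slot nComplete number of individuals tallied.
#' @seealso \code{\link{buildPairTable}}, \code{\link{chiSquarePair}},
#'   \code{\link{fitRiskModel}}
#' @name PairTable-class
#' @exportClass PairTable
setClass("PairTable",
         representation(counts = "array", nComplete = "integer"))

setValidity("PairTable", function(object) {
  msg <- character()
  cn <- object@counts
  if (!identical(dim(cn), c(3L, 3L, 2L)))
    return("counts must be a 3x3x2 array")
  if (any(is.na(cn)) || any(cn < 0) || any(cn != round(cn)))
    msg <- c(msg, "counts must be nonnegative integers")
  if (sum(cn) != object@nComplete)
    msg <- c(msg, "sum of the 18 cells must equal nComplete")
  if (length(msg)) msg else TRUE
})

#' RiskModel: high/low-risk labeling of a genotype-pair table
#'
#' The one-dimensional MDR classifier derived from a training
#' \linkS4class{PairTable}: the training case:control ratio is the
#' threshold T, and each of the 9 genotype-combination cells is labeled
#' \code{high} (its own case:control ratio strictly exceeds T; a cell with
#' cases but no controls counts as exceeding), \code{low}, or \code{empty}
#' (no training individuals fell in the cell).
#'
#' @slot thresholdT training cases / training controls.
#' @slot labels 3x3 character matrix of "high"/"low"/"empty".
#' @seealso \code{\link{fitRiskModel}}, \code{\link{classifyPairs}}
#' @name RiskModel-class
#' @exportClass RiskModel
setClass("RiskModel",
         representation(thresholdT = "numeric", labels = "matrix"))

setValidity("RiskModel", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), c(3L, 3L)))
    msg <- c(msg, "labels must be a 3x3 matrix")
  if (!all(object@labels %in% c("high", "low", "empty")))
    msg <- c(msg, "labels must be 'high', 'low' or 'empty'")
  if (length(object@thresholdT) != 1L || object@thresholdT < 0)
    msg <- c(msg, "thresholdT must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' CVPlan: stratified k-fold cross-validation assignment
#'
#' Fold membership for every individual, produced by shuffling cases and
#' controls independently under a seed and dealing each class round-robin
#' to the k folds, so fold sizes within each status class differ by at
#' most one and the assignment is reproducible from the seed.
#'
#' @slot k number of folds.
#' @slot assignment integer fold index in 1..k per individual.
#' @slot seed the seed the assignment was generated from.
#' @seealso \code{\link{makeCvPlan}}, \code{\link{runMdr}}
#' @name CVPlan-class
#' @exportClass CVPlan
setClass("CVPlan",
         representation(k = "integer", assignment = "integer",
                        seed = "integer"))

setValidity("CVPlan", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  a <- object@assignment
  if (anyNA(a) || !all(a %in% seq_len(object@k)))
    msg <- c(msg, "assignments must lie in 1..k")
  else if (length(unique(a)) < object@k)
    msg <- c(msg, "every fold must be nonempty")
  if (length(msg)) msg else TRUE
})

#' PenetranceModel: planted pairwise interaction for the simulator
#'
#' P(case | gA, gB) for each of the 9 genotype combinations of a variant
#' pair, together with the minor-allele frequencies of the two variants.
#' A constant table is a null model (no association by construction).
#'
#' @slot table 3x3 numeric matrix of case probabilities in [0, 1],
#'   rows = genotype of variant A (AA, Aa, aa), columns = variant B.
#' @slot mafA,mafB minor-allele frequencies in (0, 0.5].
#' @seealso \code{\link{PenetranceModel}}, \code{\link{xorPenetrance}},
#'   \code{\link{simulateDataset}}
#' @name PenetranceModel-class
#' @exportClass PenetranceModel
setClass("PenetranceModel",
         representation(table = "matrix", mafA = "numeric", mafB = "numeric"))

setValidity("PenetranceModel", function(object) {
  msg <- character()
  tb <- object@table
  if (!identical(dim(tb), c(3L, 3L)) || !is.numeric(tb))
    msg <- c(msg, "table must be a 3x3 numeric matrix")
  else if (any(is.na(tb)) || any(tb < 0) || any(tb > 1))
    msg <- c(msg, "penetrance entries must lie in [0, 1]")
  for (m in c(object@mafA, object@mafB))
    if (length(m) != 1L || is.na(m) || m <= 0 || m > 0.5)
      msg <- c(msg, "minor-allele frequencies must lie in (0, 0.5]")
  if (length(msg)) unique(msg) else TRUE
})
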