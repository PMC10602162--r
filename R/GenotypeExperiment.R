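#' Construct a GenotypeExperiment
#'
#' Bundles a genotype code matrix, its variant keys and (optionally) the
#' case/control status of every individual into a single validated
#' container. See \linkS4class{GenotypeExperiment} for the encoding.
#'
#' @param genotypes integer matrix, variants x individuals; codes 0 (AA,
#'   homozygous reference), 1 (Aa), 2 (aa), NA (missing call).
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, one row per row of \code{genotypes}.
#' @param status optional phenotype per individual; accepted encodings are
#'   0/1, "control"/"case", or a factor with those levels.
#' @return a \linkS4class{GenotypeExperiment}.
#' @examples
#' ge <- GenotypeExperiment(
#'   genotypes = rbind(c(0L, 1L, 2L), c(0L, 0L, NA)),
#'   variants  = data.frame(chrom = "22", pos = c(16231367L, 17052123L),
#'                          ref = c("A", "G"), alt = c("G", "A")),
#'   status    = c(1, 0, 0))
#' nCases(ge)
#' @export
GenotypeExperiment <- function(genotypes, variants, status = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(is.data.frame(variants) || is(variants, "DataFrame"))
  variants <- as.data.frame(variants)
  if (nrow(variants) != nrow(genotypes))
    stop("'variants' must have one row per genotype row", call. = FALSE)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  cd <- S4Vectors::DataFrame(row.names = seq_len(ncol(genotypes)))
  if (!is.null(status)) {
    status <- .asStatusFactor(status)
    if (length(status) != ncol(genotypes))
      stop("'status' length (", length(status),
           ") does not match the number of individuals (",
           ncol(genotypes), ")", call. = FALSE)
    cd$status <- status
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = unname(genotypes)),
    rowData = S4Vectors::DataFrame(variants),
    colData = cd)
  new("GenotypeExperiment", se)
}

#' Genotype code matrix
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @return integer matrix (variants x individuals) of codes 0/1/2/NA.
#' @name genotypeCalls
#' @aliases genotypeCalls,GenotypeExperiment-method
#' @export
setMethod("genotypeCalls", "GenotypeExperiment", function(x) {
  g <- SummarizedExperiment::assay(x, "genotype")
  dimnames(g) <- NULL
  g
})

#' Variant keys
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @return data.frame with columns chrom, pos, ref, alt.
#' @name variantKeys
#' @aliases variantKeys,GenotypeExperiment-method
#' @export
setMethod("variantKeys", "GenotypeExperiment", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))[, c("chrom", "pos",
                                                      "ref", "alt")]
})

#' Case/control status and counts
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @param value replacement status vector (0/1 or control/case).
#' @return \code{caseStatus}: factor with levels control, case, or NULL if
#'   no phenotype is attached; \code{nCases}/\code{nControls}: integer.
#' @name caseStatus
#' @aliases caseStatus,GenotypeExperiment-method
#'   caseStatus<-,GenotypeExperiment-method nCases,GenotypeExperiment-method
#'   nControls,GenotypeExperiment-method
#' @export
setMethod("caseStatus", "GenotypeExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("status" %in% colnames(cd)) cd$status else NULL
})

#' @rdname caseStatus
#' @export
setReplaceMethod("caseStatus", "GenotypeExperiment", function(x, value) {
  value <- .asStatusFactor(value)
  if (length(value) != ncol(x))
    stop("'status' length does not match the number of individuals",
         call. = FALSE)
  SummarizedExperiment::colData(x)$status <- value
  validObject(x)
  x
})

#' @rdname caseStatus
#' @export
setMethod("nCases", "GenotypeExperiment", function(x) {
  st <- .checkStatusFactor(caseStatus(x))
  sum(st == "case")
})

#' @rdname caseStatus
#' @export
setMethod("nControls", "GenotypeExperiment", function(x) {
  st <- .checkStatusFactor(caseStatus(x))
  sum(st == "control")
})

setMethod("show", "GenotypeExperiment", function(object) {
  cat("GenotypeExperiment:", nrow(object), "variants x", ncol(object),
      "individuals\n")
  st <- caseStatus(object)
  if (is.null(st)) {
    cat("  phenotype: none attached\n")
  } else {
    cat("  phenotype:", sum(st == "case"), "cases /",
        sum(st == "control"), "controls\n")
  }
  g <- genotypeCalls(object)
  nm <- sum(is.na(g))
  if (nm) cat("  missing calls:", nm,
              sprintf("(%.2f%%)\n", 100 * nm / length(g)))
  invisible(NULL)
})
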