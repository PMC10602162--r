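## One-hot genotype CSV layout: 4 metadata columns (chromosome, position,
## ref allele, alt allele) followed by one AA,Aa,aa indicator triple per
## individual. Exactly one indicator of a triple is 1 for a called
## genotype; an all-zero triple is the only other accepted pattern and
## denotes a missing call.

#' Read a one-hot genotype CSV
#'
#' Parses the one-hot case-control genotype layout (see Details) into a
#' \linkS4class{GenotypeExperiment}. Plain and gzip-compressed files are
#' both accepted; an optional header line is detected automatically.
#'
#' @details Each data row is \code{chrom,pos,ref,alt} followed by 3 x
#'   n_individuals 0/1 indicators, one (AA, Aa, aa) triple per individual.
#'   A triple with exactly one 1 maps to genotype code 0/1/2; an all-zero
#'   triple maps to a missing call (NA). Any other pattern (two or more 1s,
#'   or a non-0/1 value) is an encoding error. Row order is preserved.
#'
#' @param path path to a CSV (optionally .gz).
#' @param expectedIndividuals if given, the file must encode exactly this
#'   many individuals.
#' @return a \linkS4class{GenotypeExperiment} without phenotype.
#' @seealso \code{\link{writeGenotypes}}, \code{\link{readPhenotypes}}
#' @export
readGenotypes <- function(path, expectedIndividuals = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)   # connections auto-detect gzip
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("empty genotype file: ", path, call. = FALSE)
  first <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  hasHeader <- length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))
  if (hasHeader) lines <- lines[-1L]
  if (!length(lines)) {  # header-only file: zero variants
    n <- if (is.null(expectedIndividuals)) (length(first) - 4L) %/% 3L
         else expectedIndividuals
    return(GenotypeExperiment(
      genotypes = matrix(integer(), 0L, max(n, 0L)),
      variants = data.frame(chrom = character(), pos = integer(),
                            ref = character(), alt = character())))
  }
  widths <- lengths(strsplit(lines, ",", fixed = TRUE))
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("malformed genotype file: row ", bad + hasHeader,
         " has ", widths[bad], " fields but row ", 1L + hasHeader,
         " has ", widths[1L], call. = FALSE)
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = ",",
                          colClasses = "character", data.table = FALSE)
  ncolTot <- ncol(dt)
  if (ncolTot < 7L || (ncolTot - 4L) %% 3L != 0L)
    stop("malformed genotype file: expected 4 metadata columns plus ",
         "one AA,Aa,aa triple per individual; got ", ncolTot,
         " columns", call. = FALSE)
  n <- (ncolTot - 4L) %/% 3L
  if (!is.null(expectedIndividuals) && n != expectedIndividuals)
    stop("file encodes ", n, " individuals; expected ",
         expectedIndividuals, call. = FALSE)
  variants <- data.frame(chrom = dt[[1L]],
                         pos = as.integer(dt[[2L]]),
                         ref = dt[[3L]], alt = dt[[4L]],
                         stringsAsFactors = FALSE)
  ind <- as.matrix(dt[, -(1:4), drop = FALSE])
  suppressWarnings(storage.mode(ind) <- "integer")
  if (anyNA(ind) || !all(ind %in% c(0L, 1L))) {
    bad <- which(rowSums(is.na(ind) | !(ind == 0L | ind == 1L)) > 0)[1L]
    stop("encoding error: non-{0,1} indicator in data row ", bad,
         call. = FALSE)
  }
  aa <- ind[, seq(1L, ncol(ind), by = 3L), drop = FALSE]
  ab <- ind[, seq(2L, ncol(ind), by = 3L), drop = FALSE]
  bb <- ind[, seq(3L, ncol(ind), by = 3L), drop = FALSE]
  tot <- aa + ab + bb
  if (any(tot > 1L)) {
    bad <- which(rowSums(tot > 1L) > 0)[1L]
    stop("encoding error: indicator triple with more than one 1 in data row ",
         bad, call. = FALSE)
  }
  codes <- ab + 2L * bb          # 0 for AA (aa==1) and for all-zero triples
  codes[tot == 0L] <- NA_integer_
  GenotypeExperiment(genotypes = codes, variants = variants)
}

#' Write a one-hot genotype CSV
#'
#' Emits the one-hot layout read by \code{\link{readGenotypes}}: a header
#' line, then one row per variant with 4 metadata columns followed by an
#' AA,Aa,aa indicator triple per individual (all zeros for a missing
#' call). Reading the file back reproduces the genotype matrix exactly.
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @param path output path; a \code{.gz} suffix gzip-compresses.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(x, path) {
  stopifnot(is(x, "GenotypeExperiment"))
  g <- genotypeCalls(x)
  vk <- variantKeys(x)
  n <- ncol(g)
  header <- paste(c("chromosome", "position", "ref_allele", "alt_allele",
                    rep(c("AA", "Aa", "aa"), n)), collapse = ",")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(g)) {
    ind <- matrix(0L, nrow(g), 3L * n)
    for (code in 0:2) {
      hit <- !is.na(g) & g == code
      cols <- seq(code + 1L, 3L * n, by = 3L)
      ind[, cols] <- ind[, cols] + hit
    }
    rows <- paste(vk$chrom, vk$pos, vk$ref, vk$alt,
                  apply(ind, 1L, paste, collapse = ","), sep = ",")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a phenotype (case/control) CSV
#'
#' Single-column CSV with one label per individual, in the same order as
#' the genotype columns; an optional header line is skipped. Accepted
#' labels: 0/1 or control/case (any capitalisation).
#'
#' @param path path to the phenotype file.
#' @param expectedIndividuals if given, the number of labels must match
#'   (e.g. \code{ncol} of a genotype experiment).
#' @return factor with levels control, case.
#' @examples
#' f <- tempfile(); writeLines(c("status", "1", "0", "0"), f)
#' table(readPhenotypes(f))
#' @export
readPhenotypes <- function(path, expectedIndividuals = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) &&
      !tolower(lines[[1L]]) %in% c("0", "1", "case", "control"))
    lines <- lines[-1L]                       # header
  status <- .asStatusFactor(lines)
  if (!is.null(expectedIndividuals) &&
      length(status) != expectedIndividuals)
    stop("phenotype file has ", length(status), " labels; expected ",
         expectedIndividuals, call. = FALSE)
  status
}

#' Write a phenotype CSV
#'
#' @param status status vector (factor/0-1/labels), see
#'   \code{\link{readPhenotypes}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(status, path) {
  status <- .asStatusFactor(status)
  writeLines(c("status", as.character(status)), path)
  invisible(path)
}
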