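#' Number of unordered variant pairs
#'
#' \code{n(n-1)/2}, exact for any cohort-scale \code{n} (the result is
#' below 2^53 for n up to ~1.3e8, so the double-precision value is exact).
#'
#' @param nVariants nonnegative integer.
#' @return the pair count as a numeric scalar.
#' @examples
#' countPairs(11297253)   # ~6e13 pairwise combinations
#' @export
countPairs <- function(nVariants) {
  if (!is.numeric(nVariants) || length(nVariants) != 1L ||
      is.na(nVariants) || nVariants < 0 || nVariants != floor(nVariants))
    stop("'nVariants' must be a single nonnegative integer", call. = FALSE)
  nVariants * (nVariants - 1) / 2
}

#' Bonferroni-corrected significance threshold
#'
#' @param nTests number of tests in the family (>= 1).
#' @param familyAlpha family-wise error rate, in (0, 1].
#' @return \code{familyAlpha / nTests}.
#' @examples
#' bonferroniThreshold(1883192, 0.05)
#' @export
bonferroniThreshold <- function(nTests, familyAlpha = 0.05) {
  if (!is.numeric(nTests) || length(nTests) != 1L || is.na(nTests) ||
      nTests < 1)
    stop("'nTests' must be a single number >= 1", call. = FALSE)
  if (!is.numeric(familyAlpha) || length(familyAlpha) != 1L ||
      is.na(familyAlpha) || familyAlpha <= 0 || familyAlpha > 1)
    stop("'familyAlpha' must lie in (0, 1]", call. = FALSE)
  familyAlpha / nTests
}

## One-hot genotype-pair cell counts via binarized matrix products.
##
## For each genotype code a, H_a is the (individuals x variants) 0/1
## indicator of "call == a" (missing calls are 0 in all three, so
## individuals incomplete at either variant of a pair drop out of its
## table automatically). The count of cell (a, b) for pair (i, j) within
## a status class is then the inner product H_a[, i] . H_b[, j] over that
## class -- computed for whole blocks of pairs sharing i as one
## vector-matrix product. This is the package's vectorized counting path;
## the per-individual loop equivalent lives in the test suite as oracle.
##
## Returns list(case = m x 9, control = m x 9); cell column order is
## 3*gA + gB + 1.
.pairCellCounts <- function(g, status, individuals, iIdx, jIdx) {
  sub <- g[, individuals, drop = FALSE]
  st <- status[individuals]
  onehot <- function(rows) {
    m <- sub[, rows, drop = FALSE]
    lapply(0:2, function(code) {
      h <- t(m == code)
      h[is.na(h)] <- FALSE
      storage.mode(h) <- "double"
      h
    })
  }
  Hcase <- onehot(which(st == "case"))
  Hctrl <- onehot(which(st == "control"))
  m <- length(iIdx)
  A <- matrix(0, m, 9L)
  B <- matrix(0, m, 9L)
  for (ui in unique(iIdx)) {
    rows <- which(iIdx == ui)
    js <- jIdx[rows]
    for (a in 0:2) {
      vc <- Hcase[[a + 1L]][, ui]
      vk <- Hctrl[[a + 1L]][, ui]
      for (b in 0:2) {
        col <- 3L * a + b + 1L
        A[rows, col] <- as.vector(vc %*% Hcase[[b + 1L]][, js, drop = FALSE])
        B[rows, col] <- as.vector(vk %*% Hctrl[[b + 1L]][, js, drop = FALSE])
      }
    }
  }
  list(case = A, control = B)
}

.allPairsIdx <- function(n) {
  if (n < 2L) return(list(i = integer(), j = integer()))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  list(i = i, j = j)
}

.normalizePairs <- function(pairs, nVariants) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  if (anyNA(pairs) || any(pairs < 1L) || any(pairs > nVariants))
    stop("pair indices must lie in 1..", nVariants, call. = FALSE)
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("a pair must name two distinct variants", call. = FALSE)
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, 2:1]
  list(i = pairs[, 1L], j = pairs[, 2L])
}

#' Exhaustive (or listed) pairwise chi-square association scan
#'
#' Screens variant pairs for association with case/control status by the
#' Pearson chi-square test of \code{\link{chiSquarePair}}, retaining the
#' pairs with \code{p < pThreshold}. Counting is vectorized through
#' binarized matrix products over one-hot genotype indicators; the result
#' is identical for any \code{chunkSize} and any number of workers, and
#' pairs are reported in canonical order (i < j, sorted).
#'
#' Untestable pairs (all contributing individuals in one status class, or
#' fewer than two non-empty genotype-combination columns) are skipped and
#' logged, not fatal; see \code{attr(result, "skips")}.
#'
#' When \code{checkpointDir} is given every completed chunk is written
#' there atomically (\code{chunk-<id>.tsv}); a rerun with
#' \code{resume = TRUE} loads completed chunks instead of recomputing
#' them, so an interrupted scan picks up where it stopped.
#'
#' @param x a \linkS4class{GenotypeExperiment} with phenotype attached.
#' @param pairs optional two-column matrix/data.frame of variant index
#'   pairs; default: all \code{countPairs(nrow(x))} pairs.
#' @param pThreshold retain pairs with p-value strictly below this
#'   (default 1e-6, the screening threshold for the MDR stage).
#' @param chunkSize pairs per work chunk.
#' @param workers parallel workers (forked; results are merged in
#'   deterministic chunk order).
#' @param checkpointDir directory for per-chunk checkpoints (optional).
#' @param resume reuse completed chunk files found in
#'   \code{checkpointDir}.
#' @return data.frame with columns \code{i, j}, the 8 variant-key columns
#'   (\code{chrom_a \dots alt_b}), \code{chi2}, \code{df}, \code{p_value};
#'   attributes \code{nEnumerated} (pairs examined), \code{skips}
#'   (data.frame of untestable pairs with reasons) and
#'   \code{nExpectedBelow5} (retained pairs with some expected count < 5).
#' @seealso \code{\link{runMdr}}, \code{\link{writeScanResults}}
#' @export
scanPairs <- function(x, pairs = NULL, pThreshold = 1e-6,
                      chunkSize = 100000L, workers = 1L,
                      checkpointDir = NULL, resume = FALSE) {
  stopifnot(is(x, "GenotypeExperiment"))
  status <- .checkStatusFactor(caseStatus(x))
  if (!is.numeric(pThreshold) || pThreshold <= 0 || pThreshold > 1)
    stop("'pThreshold' must lie in (0, 1]", call. = FALSE)
  if (chunkSize < 1L) stop("'chunkSize' must be >= 1", call. = FALSE)
  g <- genotypeCalls(x)
  pr <- if (is.null(pairs)) .allPairsIdx(nrow(g))
        else .normalizePairs(pairs, nrow(g))
  npairs <- length(pr$i)
  if (!npairs) {
    out <- .emptyScanResult(x)
    return(out)
  }
  nchunks <- ceiling(npairs / chunkSize)
  useCkpt <- !is.null(checkpointDir)
  if (useCkpt) dir.create(checkpointDir, showWarnings = FALSE,
                          recursive = TRUE)
  chunkFile <- function(c) file.path(checkpointDir,
                                     sprintf("chunk-%06d.tsv", c))
  runChunk <- function(c) {
    if (useCkpt && resume && file.exists(chunkFile(c)))
      return(utils::read.delim(chunkFile(c), colClasses = c(
        i = "integer", j = "integer", chi2 = "numeric", df = "integer",
        p_value = "numeric", expect_lt5 = "logical", skip = "character")))
    idx <- (((c - 1L) * chunkSize + 1L)):min(c * chunkSize, npairs)
    cc <- .pairCellCounts(g, status, seq_len(ncol(g)),
                          pr$i[idx], pr$j[idx])
    cs <- .chiSquareVec(cc$case, cc$control)
    # strict p < threshold; a threshold of 1 means "no filtering", which
    # must also keep pairs whose p is exactly 1 (zero statistic)
    keep <- !is.na(cs$skip) |
      (!is.na(cs$p) & (cs$p < pThreshold | pThreshold >= 1))
    res <- data.frame(i = pr$i[idx][keep], j = pr$j[idx][keep],
                      chi2 = cs$stat[keep], df = as.integer(cs$df[keep]),
                      p_value = cs$p[keep], expect_lt5 = cs$expectLT5[keep],
                      skip = cs$skip[keep], stringsAsFactors = FALSE)
    if (useCkpt) {
      tmp <- paste0(chunkFile(c), ".tmp", Sys.getpid())
      fmt <- res
      # 17 significant digits: doubles survive the text round-trip exactly
      fmt$chi2 <- sprintf("%.17g", fmt$chi2)
      fmt$p_value <- sprintf("%.17g", fmt$p_value)
      utils::write.table(fmt, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      file.rename(tmp, chunkFile(c))   # atomic completion marker
    }
    res
  }
  chunks <- if (workers > 1L)
    parallel::mclapply(seq_len(nchunks), runChunk, mc.cores = workers)
  else lapply(seq_len(nchunks), runChunk)
  all <- do.call(rbind, chunks)
  nLt5 <- sum(all$expect_lt5[is.na(all$skip)])   # among retained pairs
  skips <- all[!is.na(all$skip), c("i", "j", "skip"), drop = FALSE]
  names(skips)[3L] <- "reason"
  rownames(skips) <- NULL
  res <- all[is.na(all$skip), , drop = FALSE]
  res <- res[order(res$i, res$j), , drop = FALSE]
  vk <- variantKeys(x)
  out <- data.frame(
    i = res$i, j = res$j,
    chrom_a = vk$chrom[res$i], pos_a = vk$pos[res$i],
    ref_a = vk$ref[res$i], alt_a = vk$alt[res$i],
    chrom_b = vk$chrom[res$j], pos_b = vk$pos[res$j],
    ref_b = vk$ref[res$j], alt_b = vk$alt[res$j],
    chi2 = res$chi2, df = res$df, p_value = res$p_value,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "nEnumerated") <- npairs
  attr(out, "skips") <- skips
  attr(out, "nExpectedBelow5") <- nLt5
  out
}

.emptyScanResult <- function(x) {
  out <- data.frame(i = integer(), j = integer(),
                    chrom_a = character(), pos_a = integer(),
                    ref_a = character(), alt_a = character(),
                    chrom_b = character(), pos_b = integer(),
                    ref_b = character(), alt_b = character(),
                    chi2 = numeric(), df = integer(), p_value = numeric(),
                    stringsAsFactors = FALSE)
  attr(out, "nEnumerated") <- 0L
  attr(out, "skips") <- data.frame(i = integer(), j = integer(),
                                   reason = character())
  attr(out, "nExpectedBelow5") <- 0
  out
}

#' Write / read retained-pair scan results as TSV
#'
#' Eight variant-key columns followed by \code{chi2}, \code{df},
#' \code{p_value}; floats in scientific notation with 6 significant
#' digits, so files are byte-deterministic.
#'
#' @param results data.frame from \code{\link{scanPairs}}.
#' @param path output path.
#' @return \code{writeScanResults}: \code{path} invisibly;
#'   \code{readScanResults}: the data.frame (without \code{i}/\code{j}
#'   index columns).
#' @export
writeScanResults <- function(results, path) {
  df <- results[, c("chrom_a", "pos_a", "ref_a", "alt_a",
                    "chrom_b", "pos_b", "ref_b", "alt_b",
                    "chi2", "df", "p_value")]
  df$chi2 <- sprintf("%.5e", df$chi2)
  df$p_value <- sprintf("%.5e", df$p_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScanResults
#' @export
readScanResults <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, colClasses = c(
    chrom_a = "character", pos_a = "integer", ref_a = "character",
    alt_a = "character", chrom_b = "character", pos_b = "integer",
    ref_b = "character", alt_b = "character", chi2 = "numeric",
    df = "integer", p_value = "numeric"))
}
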