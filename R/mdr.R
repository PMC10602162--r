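#' Stratified k-fold cross-validation plan
#'
#' Cases and controls are shuffled independently under \code{seed} and
#' each class is dealt round-robin to the \code{k} folds, so per-class
#' fold sizes differ by at most one and no fold can be starved of either
#' class. The same seed always reproduces the same assignment; the
#' caller's RNG state is left untouched.
#'
#' @param status a control/case factor (e.g. \code{caseStatus(x)}) or a
#'   \linkS4class{GenotypeExperiment} with phenotype attached.
#' @param k number of folds (>= 2); both classes must have at least k
#'   members.
#' @param seed integer seed.
#' @return a \linkS4class{CVPlan}.
#' @examples
#' plan <- makeCvPlan(factor(rep(c("case", "control"), each = 10),
#'                           levels = c("control", "case")), k = 5, seed = 1)
#' table(foldAssignments(plan))
#' @export
makeCvPlan <- function(status, k = 5L, seed) {
  if (is(status, "GenotypeExperiment")) status <- caseStatus(status)
  st <- .checkStatusFactor(status)
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
  for (cls in c("case", "control"))
    if (sum(st == cls) < k)
      stop("cannot build ", k, "-fold CV: only ", sum(st == cls), " ",
           cls, " individuals", call. = FALSE)
  fold <- integer(length(st))
  withSeed(seed, {
    for (cls in c("case", "control")) {
      idx <- which(st == cls)
      perm <- if (length(idx) > 1L) sample(idx) else idx
      fold[perm] <- rep_len(seq_len(k), length(idx))
    }
  })
  new("CVPlan", k = k, assignment = fold, seed = as.integer(seed))
}

#' @rdname makeCvPlan
#' @param x a \linkS4class{CVPlan}.
#' @return \code{foldAssignments}: integer fold index (1..k) per
#'   individual.
#' @aliases foldAssignments,CVPlan-method
#' @export
setMethod("foldAssignments", "CVPlan", function(x) x@assignment)

setMethod("show", "CVPlan", function(object) {
  cat("CVPlan:", object@k, "folds over", length(object@assignment),
      "individuals (seed", paste0(object@seed, ")"), "\n")
  print(table(fold = object@assignment))
  invisible(NULL)
})

#' Fit the high/low-risk model of one training table
#'
#' The MDR dimensionality-reduction step: the training case:control ratio
#' is the threshold T, and a genotype-combination cell is labeled
#' \code{high} when its own case:control ratio strictly exceeds T (a cell
#' with cases but no controls exceeds any T; a tie is \code{low}), or
#' \code{empty} when no training individual fell in it. The comparison is
#' done by integer cross-multiplication (cases_cell * controls_total >
#' controls_cell * cases_total), so ties are exact.
#'
#' @param trainTable a \linkS4class{PairTable} built from the training
#'   individuals.
#' @return a \linkS4class{RiskModel}.
#' @export
fitRiskModel <- function(trainTable) {
  stopifnot(is(trainTable, "PairTable"))
  a <- trainTable@counts[, , "case"]
  b <- trainTable@counts[, , "control"]
  num <- sum(a); den <- sum(b)
  if (num == 0 || den == 0)
    stop("undefined threshold: training set must contain at least one ",
         "case and one control", call. = FALSE)
  labels <- matrix("low", 3L, 3L,
                   dimnames = list(gA = .GENO_LABELS, gB = .GENO_LABELS))
  labels[a + b == 0] <- "empty"
  labels[a * den > b * num] <- "high"
  new("RiskModel", thresholdT = num / den, labels = labels)
}

#' RiskModel accessors
#'
#' @param x a \linkS4class{RiskModel}.
#' @return \code{riskLabels}: 3x3 character matrix of
#'   "high"/"low"/"empty"; \code{riskThreshold}: the training
#'   case:control ratio T.
#' @name RiskModel-accessors
#' @aliases riskLabels,RiskModel-method riskThreshold,RiskModel-method
#' @export
setMethod("riskLabels", "RiskModel", function(x) x@labels)

#' @rdname RiskModel-accessors
#' @export
setMethod("riskThreshold", "RiskModel", function(x) x@thresholdT)

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel: threshold T =", format(object@thresholdT, digits = 4),
      "\n")
  print(object@labels)
  invisible(NULL)
})

#' Classify individuals with a risk model
#'
#' Looks up each (gA, gB) genotype combination in the model grid:
#' \code{high} cells predict case; \code{low} and \code{empty} cells
#' predict control (an empty cell carries no evidence of risk).
#' Individuals with a missing call at either variant must be excluded
#' before calling this.
#'
#' @param model a \linkS4class{RiskModel}.
#' @param gA,gB integer genotype codes (0/1/2) at the two variants.
#' @return factor of predictions with levels control, case.
#' @export
classifyPairs <- function(model, gA, gB) {
  stopifnot(is(model, "RiskModel"), length(gA) == length(gB))
  if (anyNA(gA) || anyNA(gB))
    stop("missing genotype codes must be excluded before classification",
         call. = FALSE)
  if (!all(gA %in% 0:2) || !all(gB %in% 0:2))
    stop("genotype codes must be 0, 1 or 2", call. = FALSE)
  lab <- model@labels[cbind(gA + 1L, gB + 1L)]
  factor(ifelse(lab == "high", "case", "control"),
         levels = .STATUS_LEVELS)
}

#' Held-out prediction power of a risk model
#'
#' Classifies the test individuals with complete genotypes at the pair
#' and compares predictions with the true labels. Accuracy is the
#' fraction correct; precision is true cases among predicted cases,
#' defined as 0 when no individual is predicted case. A fold whose usable
#' test set is empty is degenerate (scores NA) and is excluded from mean
#' power.
#'
#' @param model a \linkS4class{RiskModel} fit on the training folds.
#' @param x a \linkS4class{GenotypeExperiment} with phenotype attached.
#' @param i,j the variant pair.
#' @param testIndividuals indices of the held-out individuals.
#' @return list with \code{accuracy}, \code{precision},
#'   \code{nTestUsed}, \code{degenerate}.
#' @export
scoreFold <- function(model, x, i, j, testIndividuals) {
  stopifnot(is(model, "RiskModel"), is(x, "GenotypeExperiment"))
  st <- .checkStatusFactor(caseStatus(x))[testIndividuals]
  g <- genotypeCalls(x)
  gi <- g[i, testIndividuals]
  gj <- g[j, testIndividuals]
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok))
    return(list(accuracy = NA_real_, precision = NA_real_,
                nTestUsed = 0L, degenerate = TRUE))
  pred <- classifyPairs(model, gi[ok], gj[ok])
  truth <- st[ok]
  tp <- sum(pred == "case" & truth == "case")
  predCase <- sum(pred == "case")
  list(accuracy = mean(pred == truth),
       precision = if (predCase == 0) 0 else tp / predCase,
       nTestUsed = sum(ok), degenerate = FALSE)
}

#' Run cross-validated MDR over a list of variant pairs
#'
#' The full five-step procedure. For every fold of a stratified k-fold
#' plan, each pair's risk model is fit on the training folds
#' (\code{\link{fitRiskModel}}), scored on the held-out fold
#' (\code{\link{scoreFold}}), and all pairs are ranked by the fold's
#' power metric; the top \code{ceiling(topFraction * nPairs)} form the
#' fold's top set. A pair's consistency is the number of folds whose top
#' set contains it, and a pair is selected when its consistency equals
#' \code{k}. Rank ties are broken deterministically: higher mean
#' training-table chi-square first, then lexicographic variant keys.
#'
#' All per-fold counting runs through the binarized matrix-product path
#' (see \code{\link{scanPairs}}); results are identical for any chunk
#' size, worker count, or ordering of \code{pairs}, and rows are returned
#' in canonical variant-key order.
#'
#' @param x a \linkS4class{GenotypeExperiment} with phenotype attached.
#' @param pairs two-column matrix/data.frame of variant index pairs.
#' @param k number of CV folds.
#' @param topFraction fraction of pairs forming each fold's top set.
#' @param seed integer seed for the CV plan.
#' @param powerMetric ranking metric: held-out \code{"accuracy"}
#'   (default) or \code{"precision"}; both are always reported.
#' @param chunkSize pairs per work chunk.
#' @param workers parallel workers for the per-chunk counting.
#' @return data.frame, one row per pair in canonical key order: \code{i},
#'   \code{j}, the 8 variant-key columns, \code{power_fold_1..k} (the
#'   ranking metric per fold; NA for a degenerate fold),
#'   \code{mean_accuracy}, \code{mean_precision} (means over
#'   non-degenerate folds), \code{consistency}, \code{selected}.
#'   Attribute \code{manifest} records the configuration and degenerate
#'   fold log.
#' @export
runMdr <- function(x, pairs, k = 5L, topFraction = 0.2, seed,
                   powerMetric = c("accuracy", "precision"),
                   chunkSize = 50000L, workers = 1L) {
  stopifnot(is(x, "GenotypeExperiment"))
  powerMetric <- match.arg(powerMetric)
  if (!is.numeric(topFraction) || topFraction <= 0 || topFraction > 1)
    stop("'topFraction' must lie in (0, 1]", call. = FALSE)
  status <- .checkStatusFactor(caseStatus(x))
  g <- genotypeCalls(x)
  pr <- .normalizePairs(pairs, nrow(g))
  npairs <- length(pr$i)
  if (!npairs) stop("'pairs' must be nonempty", call. = FALSE)
  plan <- makeCvPlan(status, k = k, seed = seed)
  k <- plan@k
  folds <- foldAssignments(plan)

  chunkIdx <- split(seq_len(npairs),
                    ceiling(seq_len(npairs) / chunkSize))
  acc <- prec <- power <- trainChi <- matrix(NA_real_, npairs, k)
  degen <- matrix(FALSE, npairs, k)
  for (f in seq_len(k)) {
    trainIdx <- which(folds != f)
    testIdx <- which(folds == f)
    doChunk <- function(idx) {
      tr <- .pairCellCounts(g, status, trainIdx, pr$i[idx], pr$j[idx])
      te <- .pairCellCounts(g, status, testIdx, pr$i[idx], pr$j[idx])
      num <- rowSums(tr$case); den <- rowSums(tr$control)
      high <- tr$case * den > tr$control * num   # exact tie handling
      tp <- rowSums(te$case * high)
      fp <- rowSums(te$control * high)
      tn <- rowSums(te$control * !high)
      fn <- rowSums(te$case * !high)
      nTest <- tp + fp + tn + fn
      dg <- num == 0 | den == 0 | nTest == 0
      a <- ifelse(dg, NA_real_, (tp + tn) / nTest)
      p <- ifelse(dg, NA_real_, ifelse(tp + fp == 0, 0, tp / (tp + fp)))
      cs <- .chiSquareVec(tr$case, tr$control)
      list(acc = a, prec = p, degen = dg, chi = cs$stat)
    }
    parts <- if (workers > 1L)
      parallel::mclapply(chunkIdx, doChunk, mc.cores = workers)
    else lapply(chunkIdx, doChunk)
    acc[, f] <- unlist(lapply(parts, `[[`, "acc"), use.names = FALSE)
    prec[, f] <- unlist(lapply(parts, `[[`, "prec"), use.names = FALSE)
    degen[, f] <- unlist(lapply(parts, `[[`, "degen"), use.names = FALSE)
    trainChi[, f] <- unlist(lapply(parts, `[[`, "chi"), use.names = FALSE)
  }
  power <- if (powerMetric == "accuracy") acc else prec

  vk <- variantKeys(x)
  key <- .pairKey(vk$chrom[pr$i], vk$pos[pr$i], vk$ref[pr$i],
                  vk$alt[pr$i], vk$chrom[pr$j], vk$pos[pr$j],
                  vk$ref[pr$j], vk$alt[pr$j])
  meanChi <- rowMeans(trainChi, na.rm = TRUE)
  meanChi[is.nan(meanChi) | is.na(meanChi)] <- -Inf
  m <- as.integer(ceiling(topFraction * npairs))
  inTop <- matrix(FALSE, npairs, k)
  for (f in seq_len(k)) {
    pw <- power[, f]
    pw[is.na(pw)] <- -Inf                 # degenerate folds rank last
    ord <- order(-pw, -meanChi, key)
    top <- ord[seq_len(m)]
    top <- top[pw[top] > -Inf]            # never promote a degenerate fold
    inTop[top, f] <- TRUE
  }
  consistency <- rowSums(inTop)
  out <- data.frame(
    i = pr$i, j = pr$j,
    chrom_a = vk$chrom[pr$i], pos_a = vk$pos[pr$i],
    ref_a = vk$ref[pr$i], alt_a = vk$alt[pr$i],
    chrom_b = vk$chrom[pr$j], pos_b = vk$pos[pr$j],
    ref_b = vk$ref[pr$j], alt_b = vk$alt[pr$j],
    stringsAsFactors = FALSE)
  pwCols <- as.data.frame(power)
  names(pwCols) <- paste0("power_fold_", seq_len(k))
  out <- cbind(out, pwCols)
  out$mean_accuracy <- rowMeans(acc, na.rm = TRUE)
  out$mean_precision <- rowMeans(prec, na.rm = TRUE)
  out$mean_accuracy[is.nan(out$mean_accuracy)] <- NA_real_
  out$mean_precision[is.nan(out$mean_precision)] <- NA_real_
  out$consistency <- as.integer(consistency)
  out$selected <- consistency == k
  ordOut <- order(key)
  out <- out[ordOut, , drop = FALSE]
  rownames(out) <- NULL
  dgIdx <- which(degen, arr.ind = TRUE)
  dgLog <- data.frame(i = pr$i[dgIdx[, 1L]], j = pr$j[dgIdx[, 1L]],
                      fold = dgIdx[, 2L])
  dgLog <- dgLog[order(dgLog$i, dgLog$j, dgLog$fold), , drop = FALSE]
  rownames(dgLog) <- NULL
  attr(out, "manifest") <- list(
    seed = as.integer(seed), k = k, topFraction = topFraction,
    powerMetric = powerMetric, nPairs = npairs, topPerFold = m,
    degenerateFolds = dgLog)
  out
}

#' Consistency histogram
#'
#' Counts pairs by consistency value (the number of CV folds in which the
#' pair ranked in the top set), the grouping used to report MDR results.
#'
#' @param results data.frame from \code{\link{runMdr}} (or anything with
#'   a \code{consistency} column).
#' @return named integer vector mapping consistency value to pair count
#'   (ascending; values with zero pairs are omitted).
#' @examples
#' consistencyHistogram(data.frame(consistency = c(5, 5, 2)))
#' @export
consistencyHistogram <- function(results) {
  cons <- results$consistency
  if (!length(cons)) return(setNames(integer(), character()))
  tab <- table(cons)
  setNames(as.integer(tab), names(tab))
}

#' Write / read MDR results as TSV
#'
#' @param results data.frame from \code{\link{runMdr}}.
#' @param path output path.
#' @return \code{writeMdrResults}: \code{path} invisibly;
#'   \code{readMdrResults}: the data.frame.
#' @export
writeMdrResults <- function(results, path) {
  df <- results[, setdiff(names(results), c("i", "j"))]
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.6g", df[[cn]])
  df$selected <- ifelse(results$selected, "true", "false")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeMdrResults
#' @export
readMdrResults <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom_a", "pos_a", "ref_a", "alt_a", "chrom_b", "pos_b",
            "ref_b", "alt_b", "mean_accuracy", "mean_precision",
            "consistency", "selected")
  if (!all(need %in% names(df)))
    stop("malformed MDR results TSV: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df$selected <- df$selected %in% c("true", "TRUE", TRUE)
  df$chrom_a <- as.character(df$chrom_a)
  df$chrom_b <- as.character(df$chrom_b)
  df
}
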