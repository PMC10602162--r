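#' Construct a penetrance model for a planted variant pair
#'
#' @param table 3x3 numeric matrix of P(case | gA, gB); rows = genotype
#'   of variant A (AA, Aa, aa), columns = variant B. A constant table is
#'   a null model.
#' @param mafA,mafB minor-allele frequencies of the two variants, in
#'   (0, 0.5].
#' @return a \linkS4class{PenetranceModel}.
#' @seealso \code{\link{xorPenetrance}}, \code{\link{nullPenetrance}}
#' @export
PenetranceModel <- function(table, mafA = 0.4, mafB = mafA) {
  table <- as.matrix(table)
  dimnames(table) <- list(gA = .GENO_LABELS, gB = .GENO_LABELS)
  new("PenetranceModel", table = table, mafA = mafA, mafB = mafB)
}

#' @rdname PenetranceModel
#' @param x a \linkS4class{PenetranceModel}.
#' @aliases penetranceTable,PenetranceModel-method
#' @export
setMethod("penetranceTable", "PenetranceModel", function(x) x@table)

setMethod("show", "PenetranceModel", function(object) {
  cat("PenetranceModel: maf A =", object@mafA, ", maf B =", object@mafB,
      "\n")
  print(object@table)
  invisible(NULL)
})

#' XOR-style epistatic penetrance model
#'
#' A purely epistatic interaction with no marginal effect at MAF 0.5:
#' P(case) is \code{pHigh} on the cells where exactly one variant is
#' heterozygous ((AA,Aa), (Aa,AA), (Aa,aa), (aa,Aa)) and \code{pLow}
#' elsewhere. The defaults (0.8 / 0.2 at MAF 0.4) give an effect strong
#' enough that a 300/300 cohort recovers the pair essentially always.
#'
#' @param pHigh,pLow case probabilities of the high and low cells.
#' @param maf minor-allele frequency of both variants.
#' @return a \linkS4class{PenetranceModel}.
#' @export
xorPenetrance <- function(pHigh = 0.8, pLow = 0.2, maf = 0.4) {
  tb <- matrix(pLow, 3L, 3L)
  tb[cbind(c(1L, 2L, 2L, 3L), c(2L, 1L, 3L, 2L))] <- pHigh
  PenetranceModel(tb, mafA = maf, mafB = maf)
}

#' @rdname xorPenetrance
#' @param p constant case probability of the null model.
#' @export
nullPenetrance <- function(p = 0.5, maf = 0.4) {
  PenetranceModel(matrix(p, 3L, 3L), mafA = maf, mafB = maf)
}

.hweProbs <- function(maf) {
  q <- maf; p <- 1 - maf
  c(p * p, 2 * p * q, q * q)    # codes 0 (AA), 1 (Aa), 2 (aa)
}

#' Simulate a case-control genotype dataset with known structure
#'
#' Generates the stated world every stage of the pipeline is tested
#' against: null variants drawn under Hardy-Weinberg proportions
#' (p^2, 2pq, q^2) independently of phenotype, plus optional planted
#' variant pairs whose genotypes are sampled retrospectively so that
#' cases and controls follow the conditional genotype-pair distribution
#' implied by each \linkS4class{PenetranceModel} (Bayes inversion of the
#' penetrance table at the model's MAFs: P(g | case) is proportional to
#' P(case | g) P(gA) P(gB), and symmetrically for controls). Planted
#' variants are appended after the null variants and recorded in the
#' truth manifest. No linkage disequilibrium is simulated; the same
#' configuration and seed reproduce the dataset exactly.
#'
#' @param nCases,nControls cohort sizes (the defaults mirror a 527/601
#'   diabetic/non-diabetic cohort).
#' @param nNullVariants number of phenotype-independent variants.
#' @param plantedModels list of \linkS4class{PenetranceModel}s, one per
#'   planted pair.
#' @param baselinePrevalence nominal disease prevalence in (0, 1);
#'   retrospective sampling makes it otherwise inert, so it is validated
#'   and echoed in the manifest only.
#' @param mafRange range the null-variant minor-allele frequencies are
#'   drawn from (uniform).
#' @param seed integer seed.
#' @return list with \code{experiment} (a
#'   \linkS4class{GenotypeExperiment} with phenotype, cases first) and
#'   \code{truth} (the manifest: seed, configuration echo, and for each
#'   planted pair its variant indices, keys, MAFs and penetrance table).
#' @examples
#' sim <- simulateDataset(50, 50, nNullVariants = 20, seed = 1)
#' sim$experiment
#' @export
simulateDataset <- function(nCases = 527L, nControls = 601L,
                            nNullVariants = 100L,
                            plantedModels = list(),
                            baselinePrevalence = 0.1,
                            mafRange = c(0.05, 0.5), seed) {
  stopifnot(nCases >= 1L, nControls >= 1L, nNullVariants >= 0L)
  if (!is.numeric(baselinePrevalence) || length(baselinePrevalence) != 1L ||
      baselinePrevalence <= 0 || baselinePrevalence >= 1)
    stop("'baselinePrevalence' must lie strictly inside (0, 1)",
         call. = FALSE)
  if (length(mafRange) != 2L || any(mafRange <= 0) || any(mafRange > 0.5) ||
      mafRange[1L] > mafRange[2L])
    stop("'mafRange' must be an increasing pair inside (0, 0.5]",
         call. = FALSE)
  for (pm in plantedModels) {
    stopifnot(is(pm, "PenetranceModel"))
    if (all(pm@table == 0))
      stop("unreachable status class: penetrance table is identically 0, ",
           "no case can be generated", call. = FALSE)
    if (all(pm@table == 1))
      stop("unreachable status class: penetrance table is identically 1, ",
           "no control can be generated", call. = FALSE)
  }
  n <- nCases + nControls
  nPlanted <- 2L * length(plantedModels)
  nVar <- nNullVariants + nPlanted
  status <- factor(rep(c("case", "control"), c(nCases, nControls)),
                   levels = .STATUS_LEVELS)
  geno <- matrix(NA_integer_, nVar, n)
  withSeed(seed, {
    if (nNullVariants > 0L) {
      mafs <- runif(nNullVariants, mafRange[1L], mafRange[2L])
      for (v in seq_len(nNullVariants))
        geno[v, ] <- sample(0:2, n, replace = TRUE,
                            prob = .hweProbs(mafs[v]))
    }
    for (mi in seq_along(plantedModels)) {
      pm <- plantedModels[[mi]]
      prior <- outer(.hweProbs(pm@mafA), .hweProbs(pm@mafB))
      pCase <- as.vector(t(pm@table * prior))          # cell = 3*gA+gB
      pCtrl <- as.vector(t((1 - pm@table) * prior))
      if (sum(pCase) == 0 || sum(pCtrl) == 0)
        stop("unreachable status class for planted model ", mi,
             call. = FALSE)
      cells <- integer(n)
      cells[status == "case"] <- sample(0:8, nCases, replace = TRUE,
                                        prob = pCase / sum(pCase))
      cells[status == "control"] <- sample(0:8, nControls, replace = TRUE,
                                           prob = pCtrl / sum(pCtrl))
      rows <- nNullVariants + 2L * mi - c(1L, 0L)
      geno[rows[1L], ] <- cells %/% 3L
      geno[rows[2L], ] <- cells %% 3L
    }
  })
  # synthetic variant keys: chromosome 1, evenly spaced positions,
  # alternating allele pairs (always ref != alt)
  nts <- c("A", "C", "G", "T")
  variants <- data.frame(
    chrom = rep("1", nVar),
    pos = 10000L * seq_len(nVar),
    ref = nts[(seq_len(nVar) - 1L) %% 4L + 1L],
    alt = nts[seq_len(nVar) %% 4L + 1L],
    stringsAsFactors = FALSE)
  ge <- GenotypeExperiment(geno, variants, status = status)
  planted <- lapply(seq_along(plantedModels), function(mi) {
    rows <- nNullVariants + 2L * mi - c(1L, 0L)
    list(i = rows[1L], j = rows[2L],
         keyA = variants[rows[1L], ], keyB = variants[rows[2L], ],
         mafA = plantedModels[[mi]]@mafA, mafB = plantedModels[[mi]]@mafB,
         table = unname(plantedModels[[mi]]@table))
  })
  truth <- list(seed = as.integer(seed),
                nCases = as.integer(nCases),
                nControls = as.integer(nControls),
                nNullVariants = as.integer(nNullVariants),
                baselinePrevalence = baselinePrevalence,
                mafRange = mafRange,
                planted = planted)
  list(experiment = ge, truth = truth)
}

#' Recovery report for planted pairs
#'
#' Joins MDR results to a simulation truth manifest by variant keys and
#' reports, for every planted pair, whether it was scanned, its
#' consistency, mean power, rank by mean power among the scanned pairs,
#' and whether it was selected. A planted pair absent from the results is
#' reported as not scanned, never an error.
#'
#' @param results data.frame from \code{\link{runMdr}}.
#' @param truth manifest from \code{\link{simulateDataset}}.
#' @return data.frame with one row per planted pair: \code{pair},
#'   \code{scanned}, \code{consistency}, \code{mean_power}, \code{rank},
#'   \code{detected}.
#' @export
truthRecoveryReport <- function(results, truth) {
  planted <- truth$planted
  if (!length(planted))
    return(data.frame(pair = character(), scanned = logical(),
                      consistency = integer(), mean_power = numeric(),
                      rank = integer(), detected = logical()))
  resKey <- paste(results$chrom_a, results$pos_a, results$ref_a,
                  results$alt_a, results$chrom_b, results$pos_b,
                  results$ref_b, results$alt_b)
  rankByPower <- rank(-results$mean_accuracy, ties.method = "min")
  rows <- lapply(planted, function(p) {
    kA <- paste(p$keyA$chrom, p$keyA$pos, p$keyA$ref, p$keyA$alt)
    kB <- paste(p$keyB$chrom, p$keyB$pos, p$keyB$ref, p$keyB$alt)
    hit <- match(paste(kA, kB), resKey)
    if (is.na(hit)) hit <- match(paste(kB, kA), resKey)
    if (is.na(hit))
      data.frame(pair = paste(kA, "/", kB), scanned = FALSE,
                 consistency = NA_integer_, mean_power = NA_real_,
                 rank = NA_integer_, detected = FALSE)
    else
      data.frame(pair = paste(kA, "/", kB), scanned = TRUE,
                 consistency = results$consistency[hit],
                 mean_power = results$mean_accuracy[hit],
                 rank = rankByPower[hit],
                 detected = results$selected[hit])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
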