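# Independent brute-force oracles: every counting and scoring quantity the
# package computes through binarized matrix products is recomputed here by
# per-individual loops (and chi-square through stats::chisq.test), so the
# two routes share no code.

# random dataset with genotype probabilities that need not be HWE,
# optional missing calls, random phenotype
randomGe <- function(nVariants, nIndividuals, seed, missingRate = 0.05) {
  set.seed(seed)
  g <- matrix(NA_integer_, nVariants, nIndividuals)
  for (v in seq_len(nVariants)) {
    pr <- as.vector(stats::rmultinom(1, 30, rep(1 / 3, 3))) + 1
    g[v, ] <- sample(0:2, nIndividuals, replace = TRUE, prob = pr)
  }
  if (missingRate > 0)
    g[sample(length(g), round(missingRate * length(g)))] <- NA_integer_
  nts <- c("A", "C", "G", "T")
  vk <- data.frame(chrom = sample(c("1", "2", "X"), nVariants, TRUE),
                   pos = sample(1e6, nVariants),
                   ref = nts[(seq_len(nVariants) - 1L) %% 4L + 1L],
                   alt = nts[seq_len(nVariants) %% 4L + 1L])
  status <- sample(c(rep(1, ceiling(nIndividuals / 2)),
                     rep(0, floor(nIndividuals / 2))))
  GenotypeExperiment(g, vk, status = status)
}

# per-individual tally of the 3x3x2 table
oraclePairTable <- function(ge, i, j, individuals = seq_len(ncol(ge))) {
  g <- genotypeCalls(ge)
  st <- caseStatus(ge)
  counts <- array(0L, c(3, 3, 2),
                  dimnames = list(c("AA", "Aa", "aa"), c("AA", "Aa", "aa"),
                                  c("case", "control")))
  n <- 0L
  for (ind in individuals) {
    a <- g[i, ind]; b <- g[j, ind]
    if (is.na(a) || is.na(b)) next
    s <- if (st[ind] == "case") 1L else 2L
    counts[a + 1L, b + 1L, s] <- counts[a + 1L, b + 1L, s] + 1L
    n <- n + 1L
  }
  list(counts = counts, nComplete = n)
}

# Pearson chi-square via stats::chisq.test on the non-empty columns
oracleChi2 <- function(case9, ctrl9) {
  keep <- (case9 + ctrl9) > 0
  if (sum(case9) == 0 || sum(ctrl9) == 0 || sum(keep) < 2)
    return(list(stat = NA_real_, df = NA_integer_, p = NA_real_))
  m <- rbind(case9[keep], ctrl9[keep])
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(stat = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

# cell-vector (length 9, order 3*gA+gB+1) from an oracle table
.cellVec <- function(counts, slice) {
  as.vector(t(counts[, , slice]))
}

# full naive MDR: per-individual loops for tables and classification,
# chisq.test for the tie-break statistic, same published ranking rule
oracleMdr <- function(ge, pairs, k, topFraction, seed,
                      metric = "accuracy") {
  g <- genotypeCalls(ge)
  st <- caseStatus(ge)
  vk <- variantKeys(ge)
  folds <- foldAssignments(makeCvPlan(st, k = k, seed = seed))
  npairs <- nrow(pairs)
  power <- acc <- prec <- chi <- matrix(NA_real_, npairs, k)
  for (pi in seq_len(npairs)) {
    i <- min(pairs[pi, ]); j <- max(pairs[pi, ])
    for (f in seq_len(k)) {
      tr <- oraclePairTable(ge, i, j, which(folds != f))
      a9 <- .cellVec(tr$counts, "case"); b9 <- .cellVec(tr$counts, "control")
      chi[pi, f] <- oracleChi2(a9, b9)$stat
      num <- sum(a9); den <- sum(b9)
      if (num == 0 || den == 0) next
      Tthr <- num / den
      correct <- 0L; tp <- 0L; predCase <- 0L; used <- 0L
      for (ind in which(folds == f)) {
        ga <- g[i, ind]; gb <- g[j, ind]
        if (is.na(ga) || is.na(gb)) next
        used <- used + 1L
        cellCase <- tr$counts[ga + 1L, gb + 1L, "case"]
        cellCtrl <- tr$counts[ga + 1L, gb + 1L, "control"]
        ratio <- if (cellCtrl == 0 && cellCase > 0) Inf
                 else if (cellCtrl == 0) -1 else cellCase / cellCtrl
        pred <- if (ratio > Tthr) "case" else "control"
        if (pred == st[ind]) correct <- correct + 1L
        if (pred == "case") {
          predCase <- predCase + 1L
          if (st[ind] == "case") tp <- tp + 1L
        }
      }
      if (used == 0L) next
      acc[pi, f] <- correct / used
      prec[pi, f] <- if (predCase == 0L) 0 else tp / predCase
    }
  }
  power <- if (metric == "accuracy") acc else prec
  meanChi <- rowMeans(chi, na.rm = TRUE)
  meanChi[is.nan(meanChi)] <- -Inf
  ii <- pmin(pairs[, 1], pairs[, 2]); jj <- pmax(pairs[, 1], pairs[, 2])
  key <- paste(vk$chrom[ii], formatC(vk$pos[ii], width = 12, flag = "0"),
               vk$ref[ii], vk$alt[ii],
               vk$chrom[jj], formatC(vk$pos[jj], width = 12, flag = "0"),
               vk$ref[jj], vk$alt[jj], sep = ":")
  m <- ceiling(topFraction * npairs)
  inTop <- matrix(FALSE, npairs, k)
  for (f in seq_len(k)) {
    pw <- power[, f]; pw[is.na(pw)] <- -Inf
    ord <- order(-pw, -meanChi, key)
    top <- ord[seq_len(m)]
    inTop[top[pw[top] > -Inf], f] <- TRUE
  }
  list(i = ii, j = jj, key = key, acc = acc, prec = prec, power = power,
       consistency = rowSums(inTop), selected = rowSums(inTop) == k)
}
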