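test_that("countPairs matches the closed form and rejects bad input", {
  expect_identical(countPairs(3), 3)        # {(1,2),(1,3),(2,3)}
  expect_identical(countPairs(0), 0)
  expect_identical(countPairs(1), 0)
  expect_identical(countPairs(11297253), 63813957024378)
  expect_error(countPairs(-1), "nonnegative")
  expect_error(countPairs(2.5), "integer")
})

test_that("bonferroniThreshold is family_alpha / n_tests", {
  expect_equal(bonferroniThreshold(1, 0.05), 0.05)
  expect_equal(bonferroniThreshold(20, 1.0), 0.05)
  expect_equal(bonferroniThreshold(1883192, 0.05), 0.05 / 1883192)
  expect_error(bonferroniThreshold(0), ">= 1")
  expect_error(bonferroniThreshold(10, 0), "\\(0, 1\\]")
  expect_error(bonferroniThreshold(10, 1.5), "\\(0, 1\\]")
})

test_that("truncSignif truncates rather than rounds", {
  expect_equal(truncSignif(2.6551e-8, 3), 2.65e-8)
  expect_equal(truncSignif(0.0599, 2), 0.059)
  expect_equal(truncSignif(0.05, 3), 0.05)
})

test_that("buildPairTable tallies cells and excludes incomplete individuals", {
  vk <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "G")
  g <- rbind(c(0L, 0L, 1L, 2L), c(0L, 1L, 1L, 2L))
  ge <- GenotypeExperiment(g, vk, status = c(1, 0, 1, 0))
  tab <- buildPairTable(ge, 1, 2)
  expect_identical(nComplete(tab), 4L)
  cn <- pairCounts(tab)
  expect_identical(sum(cn), 4L)
  expect_identical(cn["AA", "AA", "case"], 1L)
  expect_identical(cn["AA", "Aa", "control"], 1L)
  expect_identical(cn["Aa", "Aa", "case"], 1L)
  expect_identical(cn["aa", "aa", "control"], 1L)

  # individual 3 missing at variant B: drops out, cell (Aa,Aa,case) empties
  g2 <- g; g2[2, 3] <- NA_integer_
  ge2 <- GenotypeExperiment(g2, vk, status = c(1, 0, 1, 0))
  tab2 <- buildPairTable(ge2, 1, 2)
  expect_identical(nComplete(tab2), 3L)
  expect_identical(pairCounts(tab2)["Aa", "Aa", "case"], 0L)

  expect_error(buildPairTable(ge, 2, 2), "distinct")
  expect_error(buildPairTable(ge, 1, 2, individuals = integer()),
               "nonempty")
  gAllNA <- rbind(rep(NA_integer_, 4), c(0L, 1L, 1L, 2L))
  geNA <- GenotypeExperiment(gAllNA, vk, status = c(1, 0, 1, 0))
  expect_error(buildPairTable(geNA, 1, 2), "degenerate")
})

test_that("buildPairTable equals the per-individual loop oracle", {
  for (seed in c(11, 12, 13)) {
    ge <- randomGe(8, 200, seed = seed, missingRate = 0.1)
    for (pr in list(c(1, 2), c(3, 7), c(5, 8))) {
      tab <- buildPairTable(ge, pr[1], pr[2])
      orc <- oraclePairTable(ge, pr[1], pr[2])
      expect_identical(unname(pairCounts(tab)), unname(orc$counts))
      expect_identical(nComplete(tab), orc$nComplete)
    }
    # and on a subset of individuals
    sub <- sample(ncol(ge), 80)
    tab <- buildPairTable(ge, 2, 6, individuals = sub)
    orc <- oraclePairTable(ge, 2, 6, individuals = sub)
    expect_identical(unname(pairCounts(tab)), unname(orc$counts))
  }
})

test_that("chiSquarePair: zero statistic under exact independence, hand case, symmetry", {
  vk <- data.frame(chrom = "1", pos = c(1L, 2L), ref = "A", alt = "G")
  # every non-empty column has the same 1:1 case:control ratio
  g <- rbind(rep(c(0L, 1L, 2L), each = 4), rep(c(0L, 1L, 2L), each = 4))
  ge <- GenotypeExperiment(g, vk, status = rep(c(1, 0), 6))
  res <- chiSquarePair(buildPairTable(ge, 1, 2))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)

  # two non-empty columns, counts (10,0) and (0,10): all expected 5,
  # statistic 4*5 = 20 on 1 df; upper tail frozen from the closed form
  g <- rbind(rep(c(0L, 1L), each = 10), rep(c(0L, 1L), each = 10))
  ge <- GenotypeExperiment(g, vk, status = rep(c(1, 0), each = 10))
  res <- chiSquarePair(buildPairTable(ge, 1, 2))
  expect_equal(unname(res$statistic), 20)
  expect_identical(unname(res$parameter), 1L)
  expect_equal(res$p.value, 7.744216e-06, tolerance = 1e-6)
  expect_true(res$expectedBelow5 %in% FALSE)

  # swapping the two variants leaves the test invariant
  ge2 <- randomGe(6, 150, seed = 21)
  a <- chiSquarePair(buildPairTable(ge2, 2, 5))
  b <- chiSquarePair(buildPairTable(ge2, 5, 2))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p.value, b$p.value)
})

test_that("chiSquarePair refuses undefined tests", {
  vk <- data.frame(chrom = "1", pos = c(1L, 2L), ref = "A", alt = "G")
  g <- rbind(c(0L, 1L, 2L), c(0L, 1L, 2L))
  geOneStatus <- GenotypeExperiment(g, vk, status = c(1, 1, 1))
  expect_error(chiSquarePair(buildPairTable(geOneStatus, 1, 2)),
               "same status")
  gOneCol <- rbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L))
  geOneCol <- GenotypeExperiment(gOneCol, vk, status = c(1, 0, 1, 0))
  expect_error(chiSquarePair(buildPairTable(geOneCol, 1, 2)),
               "fewer than two")
})

test_that("chiSquarePair agrees with stats::chisq.test across random tables", {
  for (seed in 31:36) {
    ge <- randomGe(5, 120, seed = seed, missingRate = 0.08)
    tab <- buildPairTable(ge, 1, 4)
    res <- chiSquarePair(tab)
    orc <- oracleChi2(.cellVec(pairCounts(tab), "case"),
                      .cellVec(pairCounts(tab), "control"))
    expect_equal(unname(res$statistic), orc$stat, tolerance = 1e-12)
    expect_identical(as.integer(res$parameter), as.integer(orc$df))
    expect_equal(res$p.value, orc$p, tolerance = 1e-12)
  }
})

test_that("scanPairs: threshold 1 keeps every testable pair, in canonical order", {
  ge <- randomGe(10, 60, seed = 41, missingRate = 0)
  res <- scanPairs(ge, pThreshold = 1)
  expect_identical(attr(res, "nEnumerated"), 45L)
  expect_identical(nrow(res) + nrow(attr(res, "skips")), 45L)
  expect_true(all(res$i < res$j))
  expect_false(is.unsorted(order(res$i, res$j)))
  # key columns carry the right variant metadata
  vk <- variantKeys(ge)
  expect_identical(res$pos_a, vk$pos[res$i])
  expect_identical(res$alt_b, vk$alt[res$j])
})

test_that("scanPairs matches per-pair chiSquarePair and is chunk/worker/order invariant", {
  ge <- randomGe(12, 100, seed = 42, missingRate = 0.1)
  res <- scanPairs(ge, pThreshold = 1)
  # vectorized scan equals the one-pair path for every reported pair
  for (r in sample(nrow(res), 10)) {
    one <- chiSquarePair(buildPairTable(ge, res$i[r], res$j[r]))
    expect_equal(res$chi2[r], unname(one$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[r], one$p.value, tolerance = 1e-12)
  }
  for (cs in c(1L, 7L, 66L, 1000L)) {
    alt <- scanPairs(ge, pThreshold = 1, chunkSize = cs)
    expect_identical(alt, res)
  }
  alt <- scanPairs(ge, pThreshold = 1, workers = 2L)
  expect_identical(alt, res)
  # explicit pair list in reversed order and flipped orientation
  pairs <- cbind(res$i, res$j)
  flipped <- pairs[rev(seq_len(nrow(pairs))), 2:1]
  alt <- scanPairs(ge, pairs = flipped, pThreshold = 1, chunkSize = 13L)
  expect_identical(alt, res)
})

test_that("scanPairs skips untestable pairs as logged records, not errors", {
  # variant 2 is monomorphic-with variant 3 giving a single non-empty
  # column; variant 4 is entirely missing so its pairs are one-column too
  g <- rbind(c(0L, 1L, 2L, 0L, 1L, 2L),
             c(0L, 0L, 0L, 0L, 0L, 0L),
             c(1L, 1L, 1L, 1L, 1L, 1L),
             c(0L, 0L, NA, NA, NA, NA))
  vk <- data.frame(chrom = "1", pos = c(1L, 2L, 3L, 4L), ref = "A",
                   alt = "G")
  ge <- GenotypeExperiment(g, vk, status = c(1, 0, 1, 0, 1, 0))
  res <- scanPairs(ge, pThreshold = 1)
  skips <- attr(res, "skips")
  expect_true(nrow(skips) >= 1)
  expect_true(all(c(2, 3) %in% c(skips$i, skips$j) |
                    "single_column" %in% skips$reason))
  # pair (4, x): only individuals 1,2 complete, both with one column or
  # one status; either way logged, not fatal
  expect_identical(nrow(res) + nrow(skips), attr(res, "nEnumerated"))
})

test_that("scanPairs checkpointing resumes an interrupted scan exactly", {
  ge <- randomGe(14, 80, seed = 43)
  dir1 <- tempfile()
  full <- scanPairs(ge, pThreshold = 1, chunkSize = 10L,
                    checkpointDir = dir1)
  done <- list.files(dir1, pattern = "^chunk-.*tsv$")
  expect_identical(length(done), 10L)   # ceiling(91 / 10) chunks
  # simulate a kill after 4 chunks: drop the rest, rerun with resume
  dir2 <- tempfile()
  dir.create(dir2)
  file.copy(file.path(dir1, done[1:4]), dir2)
  resumed <- scanPairs(ge, pThreshold = 1, chunkSize = 10L,
                       checkpointDir = dir2, resume = TRUE)
  expect_identical(resumed, full)
  # a full rerun with resume reuses every chunk (files untouched)
  before <- file.mtime(file.path(dir1, done))
  rerun <- scanPairs(ge, pThreshold = 1, chunkSize = 10L,
                     checkpointDir = dir1, resume = TRUE)
  expect_identical(rerun, full)
  expect_identical(file.mtime(file.path(dir1, done)), before)
})

test_that("retained-pair TSVs round-trip with deterministic formatting", {
  ge <- randomGe(8, 90, seed = 44)
  res <- scanPairs(ge, pThreshold = 1)
  f <- tempfile(fileext = ".tsv")
  writeScanResults(res, f)
  lines <- readLines(f)
  expect_match(lines[1], "^chrom_a\tpos_a")
  expect_match(lines[2], "\t[0-9]\\.[0-9]{5}e[+-][0-9]{2}\t")
  back <- readScanResults(f)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-5)
  expect_identical(back$pos_a, res$pos_a)
  # byte-identical on rewrite
  f2 <- tempfile(fileext = ".tsv")
  writeScanResults(res, f2)
  expect_identical(readLines(f2), lines)
})

test_that("null simulation p-values are approximately uniform", {
  sim <- simulateDataset(120, 120, nNullVariants = 60, seed = 77,
                         mafRange = c(0.2, 0.5))
  res <- scanPairs(sim$experiment, pThreshold = 1)
  p <- res$p_value
  expect_gt(length(p), 1500)
  # coarse uniformity: mean near 1/2, mass in each half near 1/2
  expect_lt(abs(mean(p) - 0.5), 0.05)
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.06)
})
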