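#' Summarise an MDR run
#'
#' Builds the standard reporting of a cross-validated MDR analysis: the
#' consistency histogram, mean held-out power per consistency group, and
#' the Bonferroni-corrected significance threshold for the tested family
#' of pairs (printed truncated to 3 significant digits, the way such
#' thresholds are quoted).
#'
#' @param results data.frame from \code{\link{runMdr}} (or
#'   \code{\link{readMdrResults}}).
#' @param pairsTested size of the tested family for the Bonferroni line;
#'   defaults to \code{nrow(results)}.
#' @param alpha family-wise error rate.
#' @return list with \code{histogram} (named integer vector),
#'   \code{powerByConsistency} (data.frame: consistency, n,
#'   mean_accuracy, mean_precision), \code{nSelected},
#'   \code{bonferroni} (exact threshold) and \code{bonferroniPrinted}
#'   (truncated to 3 significant digits). Class \code{"mdrReport"} with a
#'   print method.
#' @export
mdrReport <- function(results, pairsTested = nrow(results), alpha = 0.05) {
  hist <- consistencyHistogram(results)
  if (!nrow(results)) {
    warning("empty results: nothing to report")
    byCons <- data.frame(consistency = integer(), n = integer(),
                         mean_accuracy = numeric(),
                         mean_precision = numeric())
  } else {
    sp <- split(seq_len(nrow(results)), results$consistency)
    byCons <- data.frame(
      consistency = as.integer(names(sp)),
      n = lengths(sp),
      mean_accuracy = vapply(sp, function(ii)
        mean(results$mean_accuracy[ii], na.rm = TRUE), numeric(1)),
      mean_precision = vapply(sp, function(ii)
        mean(results$mean_precision[ii], na.rm = TRUE), numeric(1)))
    rownames(byCons) <- NULL
  }
  bon <- if (pairsTested >= 1) bonferroniThreshold(pairsTested, alpha)
         else NA_real_
  structure(list(histogram = hist, powerByConsistency = byCons,
                 nSelected = sum(results$selected %in% TRUE),
                 pairsTested = pairsTested, alpha = alpha,
                 bonferroni = bon,
                 bonferroniPrinted = if (is.na(bon)) NA_real_
                                     else truncSignif(bon, 3L)),
            class = "mdrReport")
}

#' @export
print.mdrReport <- function(x, ...) {
  cat("MDR consistency report\n")
  cat("  pairs:", sum(x$histogram), " selected (consistency = max):",
      x$nSelected, "\n")
  if (length(x$histogram)) {
    cat("  consistency histogram:\n")
    for (v in names(x$histogram))
      cat(sprintf("    %s fold(s): %d pair(s)\n", v, x$histogram[[v]]))
    cat("  mean held-out power by consistency group:\n")
    b <- x$powerByConsistency
    for (r in seq_len(nrow(b)))
      cat(sprintf("    consistency %d: accuracy %.4f, precision %.4f (n=%d)\n",
                  b$consistency[r], b$mean_accuracy[r],
                  b$mean_precision[r], b$n[r]))
  }
  if (!is.na(x$bonferroni))
    cat(sprintf("  Bonferroni threshold (alpha=%g, %d tests): %.3g\n",
                x$alpha, as.integer(x$pairsTested), x$bonferroniPrinted))
  invisible(x)
}
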