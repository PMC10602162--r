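## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded package
#' functions never perturb the global random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Truncate a positive number to a number of significant digits
#'
#' Truncation (not rounding): 2.6551e-8 at 3 significant digits is
#' 2.65e-8. Used when reporting Bonferroni thresholds the way journals
#' print them.
#'
#' @param x positive numeric vector.
#' @param digits number of significant digits to keep.
#' @return numeric vector, truncated.
#' @examples
#' truncSignif(0.05 / 1883192, 3)
#' @export
truncSignif <- function(x, digits = 3L) {
  stopifnot(is.numeric(x), all(x > 0 | is.na(x)), digits >= 1L)
  e <- floor(log10(x))
  f <- 10^(digits - 1L - e)
  # nudge by a relative epsilon so values already exact at `digits`
  # (e.g. 0.05) are not knocked down by floating-point representation
  floor(x * f * (1 + 1e-12)) / f
}

## genotype code constants: 0 = hom ref (AA), 1 = het (Aa), 2 = hom alt (aa)
.GENO_LABELS <- c("AA", "Aa", "aa")
.STATUS_LEVELS <- c("control", "case")

.checkStatusFactor <- function(status) {
  if (is.null(status))
    stop("no case/control status attached to this object; ",
         "supply 'status' when constructing the GenotypeExperiment",
         call. = FALSE)
  stopifnot(is.factor(status), identical(levels(status), .STATUS_LEVELS))
  invisible(status)
}

#' Coerce arbitrary phenotype encodings to a control/case factor
#' @noRd
.asStatusFactor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1)))
      stop("numeric phenotype labels must be 0 (control) or 1 (case)",
           call. = FALSE)
    return(factor(ifelse(x == 1, "case", "control"), levels = .STATUS_LEVELS))
  }
  lx <- tolower(trimws(as.character(x)))
  ok <- lx %in% c("0", "1", "case", "control")
  if (!all(ok))
    stop("unknown phenotype label(s): ",
         paste(unique(x[!ok])[seq_len(min(3L, sum(!ok)))], collapse = ", "),
         call. = FALSE)
  factor(ifelse(lx %in% c("1", "case"), "case", "control"),
         levels = .STATUS_LEVELS)
}

#' Deterministic lexicographic key for a variant pair
#' @noRd
.pairKey <- function(chromA, posA, refA, altA, chromB, posB, refB, altB) {
  paste(chromA, formatC(posA, width = 12, flag = "0"), refA, altA,
        chromB, formatC(posB, width = 12, flag = "0"), refB, altB,
        sep = ":")
}
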