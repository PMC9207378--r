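#' Summarize a cohort of index values
#'
#' Computes the sample moments (SD with the n - 1 denominator), the
#' mean-minus-k-SD classification cutoff, and two lower limits of normal:
#' parametric (mean - z(percentile) * SD, z(0.05) = 1.6449) and the
#' linearly interpolated empirical percentile. With the reference-group
#' moments of the angle-at-B index (mean 163.8, SD 14.1 degrees) and k = 1
#' this reproduces the 149.7-degree flattening cutoff.
#'
#' @param values numeric index values (n >= 2, finite).
#' @param k SD multiplier for the cutoff (default 1).
#' @param percentile LLN probability (default 0.05).
#' @return a [CohortSummary-class]; errors with class
#'   \code{fvlInsufficientData} for fewer than 2 values.
#' @examples
#' s <- summarizeCohort(c(163.8 - 14.1 / sqrt(2), 163.8 + 14.1 / sqrt(2)))
#' s@cutoff  # 149.7
#' @export
summarizeCohort <- function(values, k = 1, percentile = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 2L || !all(is.finite(values)))
    .fvlStop("fvlInsufficientData",
             "cohort summary needs at least 2 finite values")
  m <- mean(values)
  s <- stats::sd(values)
  new("CohortSummary",
      n = length(values), mean = m, sd = s, k = as.numeric(k),
      percentile = as.numeric(percentile),
      cutoff = m - k * s,
      llnParametric = m - stats::qnorm(1 - percentile) * s,
      llnEmpirical = unname(stats::quantile(values, probs = percentile,
                                            type = 7)))
}

#' Classify flattening against a cutoff
#'
#' A test is called flattening when its index value is strictly below the
#' cutoff; a value exactly at the cutoff is non-flattening (the cutoff
#' itself belongs to the "at or above" stratum).
#'
#' @param indexValue numeric value(s), e.g. the angle at B in degrees.
#' @param cutoff classification cutoff in the same units.
#' @return logical vector: TRUE = flattening.
#' @examples
#' classifyFlattening(c(144.8, 149.7, 163.8), 149.7)
#' @export
classifyFlattening <- function(indexValue, cutoff) {
  if (!all(is.finite(indexValue)) || !is.finite(cutoff))
    .fvlStop("fvlInvalidInput", "inputs must be finite")
  indexValue < cutoff
}

#' Concordance rate between two sets of binary calls
#'
#' The fraction of paired assessments that agree: matches over total.
#'
#' @param callsA,callsB equal-length vectors of binary calls (logical, or
#'   any type compared elementwise); no missing values.
#' @return a [ConcordanceResult-class]; errors with class
#'   \code{fvlInvalidInput} on a length mismatch or missing calls.
#' @examples
#' concordanceRate(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
concordanceRate <- function(callsA, callsB) {
  if (length(callsA) != length(callsB))
    .fvlStop("fvlInvalidInput", "call vectors must have equal length")
  if (length(callsA) == 0L)
    .fvlStop("fvlInvalidInput", "call vectors must be non-empty")
  if (anyNA(callsA) || anyNA(callsB))
    .fvlStop("fvlInvalidInput", "missing calls are not allowed")
  nc <- sum(callsA == callsB)
  new("ConcordanceResult", nTotal = length(callsA),
      nConcordant = as.integer(nc), rate = nc / length(callsA))
}

#' Validate a subjects-by-raters rating matrix
#'
#' @param ratings matrix or data frame, rows = subjects, columns = raters,
#'   cells categorical (e.g. 0/1 flattening calls); at least 2 subjects and
#'   2 raters, no missing cells.
#' @return the validated matrix.
#' @export
ratingMatrix <- function(ratings) {
  m <- as.matrix(ratings)
  if (nrow(m) < 2L || ncol(m) < 2L)
    .fvlStop("fvlInvalidInput",
             "rating matrix needs at least 2 subjects and 2 raters")
  if (anyNA(m))
    .fvlStop("fvlInvalidInput", "missing ratings are not allowed")
  m
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' The chance-corrected agreement kappa = (Pbar - Pe) / (1 - Pe), where the
#' per-subject agreement is P_i = (sum_j n_ij^2 - m) / (m (m - 1)) for m
#' raters and category counts n_ij, Pbar is its mean, and
#' Pe = sum_j p_j^2 from the pooled category proportions. The confidence
#' interval uses Fleiss' large-sample standard error with a normal
#' approximation; a seeded subject-resampling bootstrap percentile CI is
#' available instead via \code{bootstrap}.
#'
#' When every rating on every subject falls in one category, expected
#' agreement is 1; kappa is returned as 1 with a degenerate CI and the
#' \code{degenerate} flag set (plus a warning).
#'
#' @param ratings subjects x raters matrix of categorical calls (see
#'   [ratingMatrix()]).
#' @param conf confidence level (default 0.95).
#' @param bootstrap number of bootstrap resamples (0 = analytic SE).
#' @param seed RNG seed for the bootstrap.
#' @return a [KappaResult-class].
#' @examples
#' r <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 1, 0))
#' fleissKappa(r)
#' @export
fleissKappa <- function(ratings, conf = 0.95, bootstrap = 0L, seed = NULL) {
  m <- ratingMatrix(ratings)
  stats <- .fleissStats(m)
  if (stats$degenerate) {
    warning("all ratings fall in a single category: expected agreement is 1; ",
            "kappa set to 1 with a degenerate CI")
    return(new("KappaResult", kappa = 1, ciLower = 1, ciUpper = 1,
               nSubjects = nrow(m), nRaters = ncol(m), degenerate = TRUE))
  }
  kap <- stats$kappa
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    reps <- vapply(seq_len(bootstrap), function(i) {
      b <- .fleissStats(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE])
      if (b$degenerate) 1 else b$kappa
    }, numeric(1))
    qs <- stats::quantile(reps, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
    ci <- c(min(qs[1], kap), max(qs[2], kap))
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- kap + c(-1, 1) * z * stats$se
  }
  new("KappaResult", kappa = kap, ciLower = ci[1], ciUpper = ci[2],
      nSubjects = nrow(m), nRaters = ncol(m), degenerate = FALSE)
}

# kappa, Fleiss large-sample SE and degeneracy from a subjects x raters
# matrix, via the category-count representation.
.fleissStats <- function(m) {
  cats <- sort(unique(as.vector(m)))
  n <- nrow(m); r <- ncol(m)
  counts <- vapply(cats, function(cl) rowSums(m == cl),
                   numeric(n))  # n x categories
  counts <- rbind(counts)
  if (length(cats) == 1L)
    return(list(degenerate = TRUE))
  pj <- colSums(counts) / (n * r)
  Pi <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  if (1 - Pe < 1e-12) return(list(degenerate = TRUE))
  kappa <- (Pbar - Pe) / (1 - Pe)
  qj <- 1 - pj
  spq <- sum(pj * qj)
  se <- sqrt(2) / (spq * sqrt(n * r * (r - 1))) *
    sqrt(spq^2 - sum(pj * qj * (qj - pj)))
  list(degenerate = FALSE, kappa = kappa, se = se)
}

#' Unpaired two-sample Student's t-test
#'
#' Classical equal-variance unpaired two-sided t-test, provided for group
#' comparison reports (a thin wrapper over [stats::t.test()]).
#'
#' @param valuesA,valuesB numeric groups, each n >= 2.
#' @return list with \code{statistic}, \code{df}, \code{p.value}, group
#'   means.
#' @export
twoSampleT <- function(valuesA, valuesB) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    .fvlStop("fvlInsufficientData", "each group needs at least 2 values")
  if (stats::var(valuesA) + stats::var(valuesB) == 0)
    .fvlStop("fvlDegenerateVariance",
             "both groups have zero within-group variance")
  tt <- stats::t.test(valuesA, valuesB, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, meanA = mean(valuesA), meanB = mean(valuesB))
}
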