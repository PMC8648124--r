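# Matchability statistics over MatchMatrix objects: amino-acid enrichment,
# per-group success rates, overlap (independence) tests, first-encounter
# curves, power-law fits of match counts vs scaffold-set size, and subset
# resampling.

#' Amino-acid enrichment ratios
#'
#' Frequencies of amino acids in binding sites divided by their frequencies
#' in whole proteins (background).
#'
#' @param site_freqs,background_freqs Named frequency vectors covering the 20
#'   standard amino acids (one-letter codes); the background must be strictly
#'   positive.
#' @return Named numeric vector of ratios.
#' @export
enrichment_ratios <- function(site_freqs, background_freqs) {
  aa <- unname(AA3)
  if (!all(aa %in% names(site_freqs)) || !all(aa %in% names(background_freqs)))
    stop("frequency tables must cover the 20 standard amino acids")
  bg <- background_freqs[aa]
  if (any(bg <= 0))
    stop("zero background frequency for amino acid(s): ",
         paste(aa[bg <= 0], collapse = ", "))
  site_freqs[aa] / bg
}

site_matched <- function(matrix) {
  stopifnot(inherits(matrix, "MatchMatrix"))
  apply(matrix$fast, 1, function(row) isTRUE(any(row, na.rm = TRUE)))
}

#' Match success rates by site grouping
#'
#' @param matrix A `MatchMatrix`.
#' @param grouping Either a vector of keys parallel to the sites, or a
#'   function mapping a site id to its key.
#' @return Data frame with columns `key`, `count`, `matched`, `rate`,
#'   ordered by key ascending; keys with no sites do not appear.
#' @export
success_rate_by <- function(matrix, grouping) {
  stopifnot(inherits(matrix, "MatchMatrix"))
  keys <- if (is.function(grouping)) unlist(lapply(matrix$sites, grouping)) else grouping
  if (length(keys) != length(matrix$sites) || anyNA(keys))
    stop("grouping must yield one non-missing key per site")
  matched <- site_matched(matrix)
  agg <- stats::aggregate(matched, by = list(key = keys),
                          FUN = function(v) c(n = length(v), m = sum(v)))
  out <- data.frame(key = agg$key, count = agg$x[, "n"],
                    matched = agg$x[, "m"],
                    rate = agg$x[, "m"] / agg$x[, "n"])
  out[order(out$key), , drop = FALSE]
}

#' Overlap test between two matched-site indicator vectors
#'
#' Under independence the expected number of sites matched by both scaffold
#' sets is `n_a * n_b / N`. The departure is tested with a 2x2 chi-squared
#' test of independence (1 degree of freedom, no continuity correction); for
#' degenerate margins (a set matching all or no sites) the statistic is 0 and
#' p is 1.
#'
#' @param matched_a,matched_b Logical vectors over the same site universe.
#' @return List with `observed_overlap`, `expected_overlap`, `chi2`, `p`.
#' @export
overlap_test <- function(matched_a, matched_b) {
  if (length(matched_a) != length(matched_b))
    stop("vectors must cover the same site universe")
  n <- length(matched_a)
  if (n == 0L) stop("empty site universe")
  na <- sum(matched_a); nb <- sum(matched_b)
  observed <- sum(matched_a & matched_b)
  expected <- na * nb / n
  tab <- matrix(c(observed, na - observed, nb - observed,
                  n - na - nb + observed), 2, 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    chi2 <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  list(observed_overlap = observed, expected_overlap = expected,
       chi2 = chi2, p = p)
}

#' First-encounter curve
#'
#' Number of binding sites whose first-fast-match-encounter-number is at most
#' `n`, i.e. the number of matched sites a scaffold subset of the first `n`
#' tested scaffolds would have supported. Nondecreasing in `n`.
#'
#' @param matrix A `MatchMatrix`.
#' @param n Scaffold subset size(s), each in `[1, n_scaffolds]`.
#' @return Integer count(s), one per element of `n`.
#' @export
encounter_curve <- function(matrix, n) {
  stopifnot(inherits(matrix, "MatchMatrix"))
  if (any(n < 1L | n > length(matrix$scaffolds)))
    stop("n must be between 1 and the number of scaffolds")
  vapply(as.integer(n), function(k)
    sum(!is.na(matrix$encounter) & matrix$encounter <= k), 0L)
}

#' Fit a power law to a match-count curve
#'
#' Ordinary least squares on (log10 n, log10 count): the exponent is the
#' slope of the log-log plot. Exact inputs `count = c * n^k` are reproduced
#' with r^2 = 1.
#'
#' @param n Positive scaffold-set sizes (>= 2 values).
#' @param count Positive match counts, parallel to `n`.
#' @return An object of class `"power_law_fit"` with elements `exponent`,
#'   `intercept` (log10 scale), `r_squared`; supports `print()` and
#'   `predict(fit, n)` for extrapolation.
#' @export
fit_power_law <- function(n, count) {
  if (is.data.frame(n)) { count <- n[[2]]; n <- n[[1]] }
  if (length(n) < 2L) stop("need at least 2 points")
  if (length(n) != length(count)) stop("n and count must be parallel")
  if (any(n <= 0) || any(count <= 0))
    stop("power-law fitting requires positive n and counts")
  fit <- stats::lm(log10(count) ~ log10(n))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log10(count) - mean(log10(count)))^2)
  r2 <- if (ss_tot < 1e-300) 1 else 1 - ss_res / ss_tot
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = n, count = count),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law fit: count = %.4g * n^%.4f (r^2 = %.4f, %d points)\n",
              10^x$intercept, x$exponent, x$r_squared, length(x$n)))
  invisible(x)
}

#' @export
predict.power_law_fit <- function(object, n, ...) {
  if (any(n <= 0)) stop("n must be positive")
  10^(object$intercept + object$exponent * log10(n))
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(intercept = object$intercept, exponent = object$exponent)
}

#' Resample scaffold subsets and count supported sites
#'
#' Repeatedly draws `subset_size` scaffolds without replacement and counts
#' the binding sites matched to at least one scaffold in the draw. Requires a
#' fully tested matrix (no untested cells): run the matcher with
#' `stop_at_first = FALSE`.
#'
#' @param matrix A fully tested `MatchMatrix`.
#' @param subset_size Scaffolds per draw (<= number of scaffolds).
#' @param reps Number of draws (default 100).
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return List with `mean_matches`, `max_matches` and `counts` (per-rep).
#' @export
resample_subsets <- function(matrix, subset_size, reps = 100L, seed = 1L) {
  stopifnot(inherits(matrix, "MatchMatrix"))
  if (anyNA(matrix$fast))
    stop("matrix has untested cells; rerun matching with stop_at_first = FALSE")
  ns <- length(matrix$scaffolds)
  if (subset_size < 1L || subset_size > ns)
    stop("subset_size must be between 1 and the number of scaffolds")
  counts <- with_seed(seed, vapply(seq_len(reps), function(r) {
    cols <- sample(ns, subset_size)
    sum(apply(matrix$fast[, cols, drop = FALSE], 1, any))
  }, 0L))
  list(mean_matches = mean(counts), max_matches = max(counts),
       counts = counts)
}
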