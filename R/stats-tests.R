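# Statistical procedures: exact Fisher test, BH q-values, the
# character-bootstrap majority test, Mann-Whitney/Wilcoxon wrappers and
# first-order partial correlation.

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the probability-mass convention: the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (up to a 1e-7 relative tolerance, as in `stats::fisher.test`).
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = outcome (`[a, b; c, d]`).
#' @return the two-tailed p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (any(abs(cells - round(cells)) > 1e-8))
    stop("cell counts must be integers")
  cells <- round(cells)
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warning("degenerate table (zero margin); p = 1")
    return(1)
  }
  x <- max(0, k - n):min(k, m)
  px <- dhyper(x, m, n, k)
  p0 <- dhyper(a, m, n, k)
  min(1, sum(px[px <= p0 * (1 + 1e-7)]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values; monotone non-decreasing in p-value
#' rank. `NA` entries propagate.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length (empty in, empty out).
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Character-bootstrap majority test
#'
#' Tests the null hypothesis that per-character convergence is lower for
#' morphological than molecular characters when branch pairs (or
#' quartets) are not independent. Each replicate resamples characters
#' with replacement *within each type* (keeping the original type
#' counts), reruns the unit-level comparison, and checks whether more
#' than half of the units favour the null. The returned `P` is the
#' fraction of replicates doing so — an estimate of the probability that
#' the null is correct.
#'
#' @param m a `char_matrix`.
#' @param analysis function taking a resampled `char_matrix` and
#'   returning one logical per unit, `TRUE` when the unit shows *lower*
#'   morphological than molecular convergence (the null-favouring
#'   direction).
#' @param B number of bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return an object of class `bootstrap_result` with elements `P`,
#'   `n_replicates`, `criterion`.
#' @export
bootstrap_majority_test <- function(m, analysis, B = 10000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  set.seed(seed)
  im <- which(m$type == "morphological")
  io <- which(m$type == "molecular")
  hits <- 0L
  for (b in seq_len(B)) {
    cols <- c(if (length(im)) sample(im, replace = TRUE),
              if (length(io)) sample(io, replace = TRUE))
    units <- analysis(m[cols])
    if (mean(units, na.rm = TRUE) > 0.5) hits <- hits + 1L
  }
  structure(list(P = hits / B, n_replicates = B,
                 criterion = ">50% of units show lower morphological than molecular convergence"),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> P =", x$P, "from", x$n_replicates,
      "replicates\n  criterion:", x$criterion, "\n")
  invisible(x)
}

#' Mann-Whitney / Wilcoxon test
#'
#' Unpaired: two-sided Mann-Whitney U (exact for small tie-free
#' samples, normal approximation with tie correction otherwise).
#' Paired: Wilcoxon signed-rank on within-pair differences — the
#' package's reading of a "paired Mann-Whitney U-test". All-zero
#' differences give p = 1 with a warning.
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @return the two-sided p-value.
#' @export
mann_whitney <- function(x, y, paired = FALSE) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (paired) {
    stopifnot(length(x) == length(y))
    if (all(x == y)) {
      warning("all paired differences are zero; p = 1")
      return(1)
    }
    return(suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value))
  }
  suppressWarnings(wilcox.test(x, y)$p.value)
}

#' First-order Pearson partial correlation
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` — the
#' correlation between `x` and `y` after controlling for `z`.
#' Degenerate inputs (zero variance, or `z` collinear with `x` or `y`)
#' return `NA` with a warning.
#'
#' @param x,y,z numeric vectors of equal length (>= 4).
#' @return the coefficient in `[-1, 1]`, or `NA` when undefined.
#' @export
partial_correlation <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(x) == length(z), length(x) >= 4)
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) {
    warning("zero variance; partial correlation undefined")
    return(NA_real_)
  }
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= .Machine$double.eps) {
    warning("control variable collinear with x or y; undefined")
    return(NA_real_)
  }
  (rxy - rxz * ryz) / sqrt(den)
}
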