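#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired samples. Zero differences are dropped (Wilcoxon's
#' original convention); the exact null distribution is enumerated when the
#' number of non-zero, untied differences is at most `exact_below`, otherwise
#' the normal approximation with tie and continuity correction is used. The
#' reported statistic is the sum of ranks of the positive `a - b` differences.
#'
#' @param paired_a,paired_b Equal-length numeric vectors of paired values.
#' @param exact_below Largest n for which the exact distribution is used
#'   (default 25); ties force the approximation regardless.
#' @return A `stat_test_result` data frame row: `name`, `statistic`,
#'   `p_value`, `p_adjusted` (NA until adjusted), `n` (pairs used), `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_below = 25) {
  stopifnot(length(paired_a) == length(paired_b),
            is.numeric(paired_a), is.numeric(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0L) {
    stop("all paired differences are zero; test is degenerate", call. = FALSE)
  }
  if (length(d) < 5L) {
    stop("need at least 5 non-zero paired differences", call. = FALSE)
  }
  n <- length(d)
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  use_exact <- n <= exact_below
  if (use_exact) {
    p <- signed_rank_exact_p(rk, w)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    p <- ht$p.value
  }
  structure(data.frame(
    name = "wilcoxon_signed_rank",
    statistic = w,
    p_value = p,
    p_adjusted = NA_real_,
    n = n,
    method = if (use_exact) "exact" else "normal approximation",
    stringsAsFactors = FALSE), class = c("stat_test_result", "data.frame"))
}

# exact two-sided p of the positive-rank sum under the sign-flip null,
# by dynamic programming over the distribution of 2*W (integer even with
# average ranks for tied |differences|, so ties are handled exactly,
# which the classical recursion behind psignrank cannot do)
signed_rank_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1)
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  w2 <- round(2 * w)
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at 1. The family of tests being adjusted
#' is exactly the vector passed in one call — the scope of the FDR family is
#' always explicit, never implicit.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(is.numeric(p_values), length(p_values) >= 1)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman correlation (average ranks for ties) with p-values from
#' the t approximation, across the columns of a lesion-by-parameter table.
#' A constant column yields `NA` for its pairs and is flagged.
#'
#' @param table Data frame or matrix, rows = lesions, columns = parameters;
#'   at least 5 rows and 2 columns, no missing values.
#' @return A `spearman_matrix` list: `rho` and `p` matrices (diagonal rho =
#'   1), `n`, and `undefined` (names of constant columns).
#' @export
spearman_matrix <- function(table) {
  m <- as.matrix(table)
  stopifnot(is.numeric(m), nrow(m) >= 5, ncol(m) >= 2, !anyNA(m))
  k <- ncol(m)
  nm <- colnames(m) %||% paste0("V", seq_len(k))
  rho <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  p <- rho
  diag(rho) <- 1
  diag(p) <- 0
  constant <- apply(m, 2, function(col) stats::sd(col) == 0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (constant[i] || constant[j]) next
      ht <- suppressWarnings(
        stats::cor.test(m[, i], m[, j], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ht$estimate)
      p[i, j] <- p[j, i] <- ht$p.value
    }
  }
  structure(list(rho = rho, p = p, n = nrow(m), undefined = nm[constant]),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat(sprintf("<spearman_matrix> %d observations\n", x$n))
  print(round(x$rho, 2))
  if (length(x$undefined)) {
    cat("undefined (constant) columns:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Standard statistical summary of a synthetic cohort
#'
#' Runs the cohort-level analyses on a generated cohort: the paired Wilcoxon
#' test of TBRmax at 20 vs 35 min, and the Spearman correlation matrix over
#' the imaging parameters (K1, k2, DV, VB, SUVmax, TBRmax, Vt).
#'
#' @param cohort A `pet_cohort` from [generate_cohort()].
#' @return List with `tbr_test` (a `stat_test_result`) and `correlations`
#'   (a `spearman_matrix`).
#' @export
cohort_tests <- function(cohort) {
  stopifnot(inherits(cohort, "pet_cohort"))
  les <- cohort$lesions
  tbr <- wilcoxon_signed_rank(les$tbrmax_20, les$tbrmax_35)
  params <- data.frame(K1 = les$K1, k2 = les$k2, DV = les$dv, VB = les$VB,
                       SUVmax = les$suvmax_20, TBRmax = les$tbrmax_20,
                       Vt = les$vt)
  list(tbr_test = tbr, correlations = spearman_matrix(params))
}
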