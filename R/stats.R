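# Prevalence statistics: Mann-Whitney U comparisons between cohorts at code
# and block level, Bonferroni / Benjamini-Hochberg correction, and polygenic
# risk score group comparisons.

#' Two-sided Mann-Whitney U test for binary/count vectors
#'
#' Computes the U statistic via midrank sums. For small samples
#' (`n * m <= exact_limit`) the two-sided p-value comes from the exact
#' permutation distribution of the rank sum (a dynamic program over doubled
#' midranks, valid under arbitrary ties); otherwise from the tie-corrected
#' normal approximation with continuity correction, matching
#' `stats::wilcox.test(exact = FALSE)`. Degenerate all-equal input yields
#' `p = 1`.
#'
#' @param a,b Numeric vectors (typically 0/1 indicators or per-block counts).
#' @param exact_limit Switch to the exact distribution when `length(a) *
#'   length(b)` is at or below this (default 200).
#' @return List with `U` (for sample `a`) and `p`.
#' @examples
#' mann_whitney_binary(c(1, 1, 1, 0), c(0, 0, 0, 0))
#' @export
mann_whitney_binary <- function(a, b, exact_limit = 200L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("empty vector in mann_whitney_binary()", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(a, b))) == 1L) {
    return(list(U = U, p = 1))
  }
  if (n1 * n2 <= exact_limit) {
    p <- .exact_mwu_p(a, b)
  } else {
    p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
  list(U = U, p = min(1, p))
}

# Exact two-sided permutation p-value for the Mann-Whitney U with ties:
# dynamic program over the distribution of the group-a rank sum, using
# doubled midranks (integers). p = P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|).
.exact_mwu_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r2 <- as.integer(round(2 * rank(c(a, b))))  # doubled midranks are integers
  u_obs <- sum(rank(c(a, b))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  # dp[k+1, s+1] = number of k-subsets with doubled-rank sum s
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  dp[1L, 1L] <- 1
  for (x in r2) {
    kmax <- n1
    for (k in kmax:1) {
      shift <- dp[k, seq_len(smax + 1L - x)]
      nz <- which(shift != 0)
      if (length(nz)) {
        dp[k + 1L, nz + x] <- dp[k + 1L, nz + x] + shift[nz]
      }
    }
  }
  counts <- dp[n1 + 1L, ]
  total <- sum(counts)
  sums2 <- which(counts > 0) - 1L              # doubled rank sums
  u_vals <- sums2 / 2 - n1 * (n1 + 1) / 2      # corresponding U values
  dev <- abs(u_vals - n1 * n2 / 2)
  obs_dev <- abs(u_obs - n1 * n2 / 2)
  sum(counts[counts > 0][dev >= obs_dev - 1e-9]) / total
}

# Vectorized binary-column Mann-Whitney: identical U and normal-approximation
# p as the scalar path, computed column-wise from 0/1 counts. Used by
# compare_prevalence for speed on wide indicator matrices.
.mwu_binary_cols <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B); N <- n1 + n2
  k1 <- colSums(A); k2 <- colSums(B)
  N1 <- k1 + k2                      # total ones
  N0 <- N - N1                       # total zeros
  rank0 <- (N0 + 1) / 2
  rank1 <- N0 + (N1 + 1) / 2
  R1 <- (n1 - k1) * rank0 + k1 * rank1
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- (N0^3 - N0) + (N1^3 - N1)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - ties / (N * (N - 1)))
  z <- U - mu
  z <- sign(z) * pmax(abs(z) - 0.5, 0) / sqrt(sigma2)  # continuity correction
  p <- 2 * stats::pnorm(-abs(z))
  p[N1 == 0 | N0 == 0] <- 1          # constant column
  list(U = U, p = pmin(1, p))
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size; must be at least `length(p)`.
#' @return Adjusted p-values `min(1, p * m)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1L) stop("family size m must be >= 1", call. = FALSE)
  if (m < length(p)) stop("m smaller than number of tests", call. = FALSE)
  pmin(1, p * m)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of raw p-values.
#' @return BH-adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Compare condition prevalence between a cohort and its matched controls
#'
#' Runs the two-sided Mann-Whitney U test per condition column, on binary
#' presence indicators at code level or per-block sums of distinct codes at
#' block level, with Bonferroni correction across the family of
#' dementia-vs-control comparisons. Conditions below a pooled prevalence
#' floor are excluded as vacuous; zero-variance columns are kept with
#' `p = 1` and flagged. Results are ordered most- to least-significant.
#'
#' @param cohort_pm,control_pm `presence_matrix` objects sharing a window
#'   (columns are unioned; a condition absent from one side contributes an
#'   all-zero column).
#' @param level `"code"` (binary indicators) or `"block"` (count sums).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @param prevalence_floor Minimum pooled prevalence to test (default 0.005).
#' @param m Bonferroni family size; default the number of conditions tested.
#' @return `data.table`: `condition`, `level`, `prev_cohort`, `prev_control`,
#'   `U`, `p`, `p_adj`, `significant`, `degenerate`.
#' @export
compare_prevalence <- function(cohort_pm, control_pm,
                               level = c("code", "block"), alpha = 0.05,
                               prevalence_floor = 0.005, m = NULL) {
  level <- match.arg(level)
  take <- function(pm) if (level == "block") pm$sums else presence_indicator(pm)
  A <- take(cohort_pm); B <- take(control_pm)
  conds <- sort(union(colnames(A), colnames(B)))
  pad <- function(M, n) {
    out <- matrix(0L, nrow = n, ncol = length(conds),
                  dimnames = list(NULL, conds))
    if (ncol(M)) out[, colnames(M)] <- M
    out
  }
  A <- pad(A, nrow(cohort_pm$status)); B <- pad(B, nrow(control_pm$status))
  pooled_prev <- (colSums(A > 0) + colSums(B > 0)) / (nrow(A) + nrow(B))
  keep <- pooled_prev >= prevalence_floor
  A <- A[, keep, drop = FALSE]; B <- B[, keep, drop = FALSE]
  conds <- conds[keep]
  if (!length(conds)) {
    return(data.table::data.table(condition = character(0), level = character(0),
                                  prev_cohort = numeric(0), prev_control = numeric(0),
                                  U = numeric(0), p = numeric(0), p_adj = numeric(0),
                                  significant = logical(0), degenerate = logical(0)))
  }
  if (level == "code") {
    mw <- .mwu_binary_cols(A, B)
    U <- mw$U; p <- mw$p
  } else {
    res <- lapply(seq_along(conds), function(j) {
      mann_whitney_binary(A[, j], B[, j], exact_limit = 0L)
    })
    U <- vapply(res, `[[`, 0, "U"); p <- vapply(res, `[[`, 0, "p")
  }
  degenerate <- vapply(seq_along(conds), function(j) {
    length(unique(c(A[, j], B[, j]))) == 1L
  }, TRUE)
  p[degenerate] <- 1
  if (is.null(m)) m <- length(conds)
  out <- data.table::data.table(
    condition = conds, level = level,
    prev_cohort = colMeans(A > 0), prev_control = colMeans(B > 0),
    U = U, p = p, p_adj = bonferroni_adjust(p, m),
    degenerate = degenerate)
  out[, significant := p_adj < alpha & !degenerate]
  data.table::setorder(out, p)
  out[]
}

#' Top-k most significant prevalence results
#'
#' @param results Output of [compare_prevalence()].
#' @param k Number of rows (default 20, significant rows only).
#' @export
top_conditions <- function(results, k = 20L) {
  utils::head(results[significant == TRUE], k)
}

#' Compare polygenic risk scores between groups
#'
#' Pairwise two-sided Mann-Whitney U tests (AD vs control, VaD vs control,
#' AD vs VaD) with Benjamini-Hochberg correction across the pairs.
#'
#' @param scores `data.table`/data.frame with columns `group` and `prs`.
#' @return `data.table`: `group1`, `group2`, `n1`, `n2`, `U`, `p`, `p_adj`.
#' @export
compare_prs <- function(scores) {
  sc <- data.table::as.data.table(scores)
  pairs <- list(c("AD", "control"), c("VaD", "control"), c("AD", "VaD"))
  rows <- list()
  for (pr in pairs) {
    x <- sc[group == pr[1], prs]; y <- sc[group == pr[2], prs]
    if (!length(x) || !length(y)) {
      warning(sprintf("compare_prs: missing group in pair %s-%s, skipped",
                      pr[1], pr[2]), call. = FALSE)
      next
    }
    mw <- mann_whitney_binary(x, y, exact_limit = 0L)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      group1 = pr[1], group2 = pr[2], n1 = length(x), n2 = length(y),
      U = mw$U, p = mw$p)
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out)) out[, p_adj := bh_adjust(p)]
  out[]
}
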