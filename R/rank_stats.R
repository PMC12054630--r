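# Shared rank-based statistics: Spearman correlation with a large-sample
# t approximation, the Wilcoxon rank-sum test (exact by enumeration for
# small groups, tie-corrected normal approximation otherwise), and BH FDR.

#' Spearman correlation with a two-tailed large-sample p-value
#'
#' Computes Spearman's rho (Pearson correlation of average-tie ranks) and a
#' two-tailed p-value from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom.
#' For \eqn{|\rho| = 1} the p-value is 0; with fewer than 3 pairs or a
#' zero-variance input both statistics are `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with elements `rho`, `p`, and `n`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  list(rho = rho, p = p, n = n)
}

spearman_p <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- !is.na(rho) & n >= 3L
  unit <- ok & abs(rho) >= 1 - 1e-15
  p[unit] <- 0
  mid <- ok & !unit
  tt <- rho[mid] * sqrt((n - 2) / (1 - rho[mid]^2))
  p[mid] <- 2 * pt(-abs(tt), df = n - 2)
  p
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' When both groups have at most `exact_max` observations the p-value is
#' computed by full enumeration of all group assignments of the pooled
#' (average-tie) ranks: the two-sided p is the null probability of a
#' rank-sum at least as far from its null mean as the observed one. Larger
#' groups use the normal approximation with the tie-corrected variance and
#' no continuity correction.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_max Largest per-group size for which exact enumeration is
#'   used (default 7).
#' @return Two-sided p-value in (0, 1].
#' @export
wilcox_rank_sum_p <- function(x, y, exact_max = 7L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop_fmt("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  center <- nx * (nx + ny + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    sets <- combn(nx + ny, nx)
    ws <- colSums(matrix(r[sets], nrow = nx))
    return(mean(abs(ws - center) >= abs(w - center) - 1e-9))
  }
  n <- nx + ny
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- nx * ny / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(1)
  z <- (w - center) / sqrt(v)
  min(1, 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Thin wrapper around [stats::p.adjust()] with `method = "BH"`, kept as a
#' named operation so that every FDR adjustment in the package goes through
#' one place.
#'
#' @param p Numeric vector of p-values.
#' @return Monotone step-up adjusted q-values, each at most 1.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")
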