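# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: ranks are computed from sort order, Pearson from
# the explicit moment formula, BH by the literal step-up recursion, and the
# exact Wilcoxon null by bitmask enumeration of group assignments.

# average ranks from first principles (sort order + tie averaging)
oracle_rank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# literal BH step-up: q_(i) = min over j >= i of p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    q_sorted[i] <- running
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# exact two-sided Wilcoxon p by bitmask enumeration over all assignments
oracle_wilcox_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  n <- nx + ny
  r <- oracle_rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  center <- nx * (n + 1) / 2
  total <- 0L; extreme <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != nx) next
    total <- total + 1L
    w <- sum(r[bits == 1L])
    if (abs(w - center) >= abs(obs - center) - 1e-9) extreme <- extreme + 1L
  }
  extreme / total
}

# small random count bundle for IO / preprocess tests
make_toy_bundle <- function(n_genes = 8, n_cells = 6, seed = 42) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells,
                   dimnames = list(sprintf("g%02d", 1:n_genes),
                                   sprintf("bc%02d", 1:n_cells)))
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  meta <- data.frame(
    barcode = colnames(counts), species = "mouse",
    cell_type = rep(c("CM", "FB"), length.out = n_cells),
    condition = rep(c("control", "stressed"), each = ceiling(n_cells / 2))[1:n_cells],
    sample_id = "s1", stringsAsFactors = FALSE
  )
  list(counts = counts, meta = meta)
}
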