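# Core of the cross-species screen: anchor correlation ranking, top-K
# selection, homolog transport, intersection, and stress-response
# validation. Tie-breaking is lexicographic on gene label everywhere so
# outputs are byte-deterministic.

#' Per-gene correlation with an anchor gene
#'
#' For every gene, the Spearman (default) or Pearson correlation between
#' its normalized expression and the anchor's across the selected cells.
#' Genes with zero variance are recorded with undefined correlation; genes
#' expressed in fewer than `min_frac_expressing` of the cells, zero-variance
#' genes, and the anchor itself are marked ineligible and excluded from the
#' ranking. Two-tailed p-values use the large-sample t approximation. Rank
#' is 1-based among eligible genes by descending correlation, ties broken
#' by gene label.
#'
#' @param norm Normalized gene x cell matrix (see [lognormalize()]).
#' @param cells Barcodes to use (e.g. from [subset_cells()]).
#' @param anchor Anchor gene label; must be present and expressed in at
#'   least one selected cell.
#' @param min_cells Minimum number of selected cells (default 50).
#' @param min_frac_expressing Eligibility gate on the fraction of cells
#'   with nonzero expression (default 0.01).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with columns gene, rho, p_two_tailed, n_cells,
#'   frac_expressing, eligible, rank; eligible rows first, ordered by rank,
#'   then ineligible rows by gene label.
#' @export
anchor_correlation <- function(norm, cells, anchor, min_cells = 50L,
                               min_frac_expressing = 0.01,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!anchor %in% rownames(norm))
    stop_fmt("anchor gene '%s' not found in the matrix", anchor)
  missing <- setdiff(cells, colnames(norm))
  if (length(missing))
    stop_fmt("%d requested cell(s) not in the matrix (first: %s)",
             length(missing), missing[1L])
  n <- length(cells)
  if (n < min_cells)
    stop_fmt("only %d cells selected; at least %d required", n, min_cells)
  m <- as.matrix(norm[, cells, drop = FALSE])
  av <- m[anchor, ]
  if (all(av == 0))
    stop_fmt("anchor gene '%s' has no nonzero expression in the selection",
             anchor)
  genes <- rownames(m)
  frac <- rowMeans(m > 0)
  gvar <- apply(m, 1L, var)
  has_var <- gvar > 0

  score_m <- if (method == "spearman") t(apply(m, 1L, rank)) else m
  score_a <- if (method == "spearman") rank(av) else av
  rho <- rep(NA_real_, length(genes))
  rho[has_var] <- as.vector(cor(t(score_m[has_var, , drop = FALSE]), score_a))
  p <- spearman_p(rho, n)   # same t approximation for either statistic

  eligible <- has_var & frac >= min_frac_expressing & genes != anchor
  rk <- rep(NA_integer_, length(genes))
  ord <- order(-rho[eligible], genes[eligible])
  rk[which(eligible)[ord]] <- seq_len(sum(eligible))

  out <- data.frame(gene = genes, rho = rho, p_two_tailed = p,
                    n_cells = n, frac_expressing = frac,
                    eligible = eligible, rank = rk,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(!out$eligible, out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-K anchor-correlated genes
#'
#' @param table Output of [anchor_correlation()].
#' @param k Number of genes to keep (default 50); all eligible genes if
#'   fewer. Ties at the boundary are resolved by gene label ascending.
#' @return Character vector of gene labels in rank order.
#' @export
top_k <- function(table, k = 50L) {
  if (k <= 0) stop_fmt("k must be positive")
  el <- table[table$eligible, , drop = FALSE]
  if (!nrow(el)) stop_fmt("no eligible genes to rank")
  el <- el[order(el$rank), , drop = FALSE]
  head(el$gene, k)
}

#' Transport a ranked gene list through a homolog table
#'
#' Many-to-many expansion: every species-B partner of every listed
#' species-A gene is included. `rank_a` is the position in the input list.
#'
#' @param genes Ranked character vector in species-A namespace.
#' @param homologs data.frame with columns `gene_a`, `gene_b`.
#' @param direction `"a_to_b"` (default) or `"b_to_a"`.
#' @return List with `mapped` (data.frame gene_a, rank_a, gene_b),
#'   `n_mappable` (input genes with at least one partner), and `unmapped`
#'   (input genes with none).
#' @export
map_homologs <- function(genes, homologs, direction = c("a_to_b", "b_to_a")) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_a", "gene_b") %in% names(homologs)))
  if (direction == "b_to_a")
    homologs <- data.frame(gene_a = homologs$gene_b, gene_b = homologs$gene_a,
                           stringsAsFactors = FALSE)
  hit <- homologs[homologs$gene_a %in% genes, , drop = FALSE]
  hit$rank_a <- match(hit$gene_a, genes)
  hit <- hit[order(hit$rank_a, hit$gene_b), c("gene_a", "rank_a", "gene_b")]
  rownames(hit) <- NULL
  mappable <- unique(hit$gene_a)
  list(mapped = hit,
       n_mappable = length(mappable),
       unmapped = genes[!genes %in% mappable])
}

#' Cross-species conserved gene set
#'
#' Intersects the homolog-mapped species-A top list with the species-B top
#' list, annotating each conserved gene with its rank on both sides;
#' ordered by species-B rank.
#'
#' @param mapped Result of [map_homologs()] (or its `mapped` data.frame),
#'   in species-B namespace.
#' @param top_b Ranked character vector of species-B genes.
#' @return data.frame with columns gene_b, gene_a, rank_a, rank_b.
#' @export
conserved_intersection <- function(mapped, top_b) {
  if (is.list(mapped) && !is.data.frame(mapped)) mapped <- mapped$mapped
  stopifnot(all(c("gene_a", "rank_a", "gene_b") %in% names(mapped)))
  hit <- mapped[mapped$gene_b %in% top_b, , drop = FALSE]
  hit$rank_b <- match(hit$gene_b, top_b)
  hit <- hit[order(hit$rank_b, hit$gene_a), c("gene_b", "gene_a", "rank_a", "rank_b")]
  rownames(hit) <- NULL
  hit
}

#' Stress-response validation by Wilcoxon rank-sum
#'
#' For each candidate gene, a two-sided Wilcoxon rank-sum test of
#' normalized expression in stressed versus control cells of the chosen
#' cell type (exact by enumeration when both groups have at most 7 cells,
#' tie-corrected normal approximation otherwise), the log2 fold change of
#' group means with a 1e-9 pseudocount, and BH q-values computed across
#' exactly the supplied gene list.
#'
#' @param norm Normalized gene x cell matrix.
#' @param meta Per-cell metadata.
#' @param genes Candidate gene labels (e.g. the conserved set).
#' @param cell_type Cell type to test within (default `"CM"`).
#' @param conditions Length-2 labels, control first (default
#'   `c("control","stressed")`).
#' @param min_cells_per_group Minimum cells per condition (default 3).
#' @return data.frame with columns gene, log2fc, p, q, n_control,
#'   n_stressed, in input gene order.
#' @export
stress_de <- function(norm, meta, genes, cell_type = "CM",
                      conditions = c("control", "stressed"),
                      min_cells_per_group = 3L) {
  missing <- setdiff(genes, rownames(norm))
  if (length(missing))
    stop_fmt("gene(s) not in matrix: %s", paste(missing, collapse = ", "))
  ctrl <- subset_cells(meta, cell_type = cell_type, condition = conditions[1L])
  strs <- subset_cells(meta, cell_type = cell_type, condition = conditions[2L])
  if (length(ctrl) < min_cells_per_group || length(strs) < min_cells_per_group)
    stop_fmt("need >= %d cells per condition in %s cells (found %d control, %d stressed)",
             min_cells_per_group, cell_type, length(ctrl), length(strs))
  mc <- as.matrix(norm[genes, ctrl, drop = FALSE])
  ms <- as.matrix(norm[genes, strs, drop = FALSE])
  eps <- 1e-9
  log2fc <- log2((rowMeans(ms) + eps) / (rowMeans(mc) + eps))
  p <- vapply(seq_along(genes), function(i)
    wilcox_rank_sum_p(ms[i, ], mc[i, ]), numeric(1))
  data.frame(gene = genes, log2fc = log2fc, p = p, q = bh_adjust(p),
             n_control = length(ctrl), n_stressed = length(strs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full cross-species anchor screen on a simulated or loaded pair
#'
#' Convenience wrapper: QC + log-normalization per species, anchor
#' correlation over the chosen cell type, top-K per species, homolog
#' transport A to B, and intersection.
#'
#' @param a,b Lists with `counts` and `meta` (as from [simulate_species()]
#'   or [read_mtx_bundle()]).
#' @param homologs Homolog data.frame (gene_a in A's namespace).
#' @param anchor_a,anchor_b Anchor labels in each namespace.
#' @param cell_type Cell type for the correlation (default `"CM"`).
#' @param condition Optional condition restriction (default `NULL`: all
#'   cells of the cell type).
#' @param k Top-K cutoff, symmetric across species (default 50).
#' @param thr QC thresholds; default [qc_thresholds()] with minimums 0 so
#'   simulated bundles pass through unchanged unless asked otherwise.
#' @param min_frac_expressing Eligibility gate (default 0.01).
#' @return List with per-species correlation tables, top lists, the
#'   homolog mapping and the conserved set data.frame.
#' @export
anchor_screen <- function(a, b, homologs, anchor_a, anchor_b,
                          cell_type = "CM", condition = NULL, k = 50L,
                          thr = qc_thresholds(0, 0, Inf, 0),
                          min_frac_expressing = 0.01) {
  run_side <- function(d, anchor) {
    q <- qc_filter(d$counts, d$meta, thr)
    norm <- lognormalize(q$counts)
    cells <- subset_cells(q$meta, cell_type = cell_type, condition = condition)
    anchor_correlation(norm, cells, anchor,
                       min_frac_expressing = min_frac_expressing)
  }
  corr_a <- run_side(a, anchor_a)
  corr_b <- run_side(b, anchor_b)
  ta <- top_k(corr_a, k)
  tb <- top_k(corr_b, k)
  mp <- map_homologs(ta, homologs)
  cons <- conserved_intersection(mp, tb)
  list(corr_a = corr_a, corr_b = corr_b, top_a = ta, top_b = tb,
       mapping = mp, conserved = cons)
}
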