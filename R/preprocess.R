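# QC filtering and log normalization. Thresholds are configurable because
# the upstream reanalysis this mirrors defers its exact cutoffs to the
# source publication; the defaults here are conventional stand-ins.

#' QC thresholds
#'
#' @param min_counts_per_cell Minimum total count per cell (default 500).
#' @param min_genes_per_cell Minimum detected genes per cell (default 200).
#' @param max_counts_per_cell Optional upper total-count bound (default
#'   `Inf`, i.e. disabled).
#' @param min_cells_per_gene Minimum cells in which a gene is detected
#'   (default 3); applied after the per-cell rules.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_counts_per_cell = 500,
                          min_genes_per_cell = 200,
                          max_counts_per_cell = Inf,
                          min_cells_per_gene = 3) {
  thr <- list(min_counts_per_cell = min_counts_per_cell,
              min_genes_per_cell = min_genes_per_cell,
              max_counts_per_cell = max_counts_per_cell,
              min_cells_per_gene = min_cells_per_gene)
  if (any(unlist(thr) < 0)) stop_fmt("QC thresholds must all be >= 0")
  class(thr) <- "qc_thresholds"
  thr
}

#' Filter cells then genes by QC thresholds
#'
#' Order is deterministic: cells failing any per-cell rule are removed
#' first, then genes detected in fewer than `min_cells_per_gene` of the
#' surviving cells. With all thresholds zero (and no upper bound) the input
#' is returned unchanged.
#'
#' @param counts Sparse gene x cell count matrix.
#' @param meta Matching per-cell metadata (barcode column).
#' @param thr A [qc_thresholds()] object.
#' @return List with filtered `counts`, `meta`, and a `report` listing cells
#'   and genes removed per rule.
#' @export
qc_filter <- function(counts, meta, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"))
  check_bundle(counts, meta)
  totals <- Matrix::colSums(counts)
  ngenes <- Matrix::colSums(counts > 0)
  fail_min <- totals < thr$min_counts_per_cell
  fail_genes <- ngenes < thr$min_genes_per_cell
  fail_max <- totals > thr$max_counts_per_cell
  keep_cells <- !(fail_min | fail_genes | fail_max)
  if (!any(keep_cells)) stop_fmt("empty dataset after QC")
  sub <- counts[, keep_cells, drop = FALSE]
  det <- Matrix::rowSums(sub > 0)
  keep_genes <- det >= thr$min_cells_per_gene
  report <- list(
    cells_in = ncol(counts), genes_in = nrow(counts),
    cells_removed_min_counts = sum(fail_min),
    cells_removed_min_genes = sum(fail_genes),
    cells_removed_max_counts = sum(fail_max),
    cells_removed = sum(!keep_cells),
    genes_removed_min_cells = sum(!keep_genes),
    cells_out = sum(keep_cells), genes_out = sum(keep_genes)
  )
  list(counts = sub[keep_genes, , drop = FALSE],
       meta = meta[keep_cells, , drop = FALSE],
       report = report)
}

#' Library-size log normalization
#'
#' value(g, i) = ln(1 + scale * count(g, i) / total(i)): each cell's counts
#' are scaled to a fixed total (default 10,000) and log1p-transformed.
#' Sparsity is preserved exactly: an entry is zero iff the count is zero.
#' Within a cell the transform is strictly monotone in the count, and
#' multiplying a cell's counts by a constant leaves its normalized values
#' unchanged.
#'
#' @param counts Sparse gene x cell count matrix with no all-zero cells.
#' @param scale Target per-cell total (default 1e4).
#' @return Sparse normalized matrix with the same dimnames.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop_fmt("%d cell(s) have zero total counts; run qc_filter first",
             sum(totals == 0))
  m <- as(counts, "CsparseMatrix")
  cell_of <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(scale * m@x / totals[cell_of])
  m
}

#' Select cell barcodes by metadata
#'
#' @param meta Per-cell metadata (barcode, cell_type, condition, species).
#' @param cell_type,condition,species Labels to match; `NULL` means no
#'   restriction on that field. Unknown labels raise an error listing the
#'   valid ones.
#' @return Character vector of matching barcodes in stored order.
#' @export
subset_cells <- function(meta, cell_type = NULL, condition = NULL,
                         species = NULL) {
  pick <- rep(TRUE, nrow(meta))
  # condition has a closed vocabulary, so asking for a condition absent from
  # this particular dataset is a legal (empty) query, not an error
  vocab_of <- function(field) {
    if (field == "condition") unique(c("control", "stressed", meta$condition))
    else unique(meta[[field]])
  }
  for (field in c("cell_type", "condition", "species")) {
    want <- switch(field, cell_type = cell_type, condition = condition,
                   species = species)
    if (is.null(want)) next
    vocab <- vocab_of(field)
    if (!want %in% vocab)
      stop_fmt("unknown %s '%s'; valid values: %s", field, want,
               paste(sort(vocab), collapse = ", "))
    pick <- pick & meta[[field]] == want
  }
  meta$barcode[pick]
}
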