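# On-disk formats: Matrix-Market bundles (matrix.mtx + features.tsv +
# barcodes.tsv + cell_meta.tsv), the two-column homolog TSV, FASTA, and
# BED3. TSV is the only tabular dialect. All reader errors carry file (and
# where meaningful, line) context; nothing is silently coerced.

BUNDLE_FILES <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "cell_meta.tsv")

#' Write a dataset bundle to a directory
#'
#' Writes the sparse count matrix in Matrix-Market triplet format alongside
#' `features.tsv` (gene labels, one per row), `barcodes.tsv` and
#' `cell_meta.tsv` (header: barcode, species, cell_type, condition,
#' sample_id). The layout round-trips exactly through [read_mtx_bundle()].
#'
#' @param counts Sparse gene x cell integer count matrix with dimnames.
#' @param meta Per-cell metadata data.frame; its `barcode` column must match
#'   `colnames(counts)` exactly.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mtx_bundle <- function(counts, meta, dir) {
  check_bundle(counts, meta)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  write.table(meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a dataset bundle from a directory
#'
#' Inverse of [write_mtx_bundle()]. Validates that all four files are
#' present, that the matrix dimensions match the label files, that all
#' values are non-negative integers, that labels are unique, and that the
#' metadata covers exactly the matrix's barcodes (joined on `barcode`).
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `cell_meta.tsv`.
#' @return List with `counts` (dgCMatrix, genes x cells) and `meta`.
#' @export
read_mtx_bundle <- function(dir) {
  for (f in BUNDLE_FILES) {
    if (!file.exists(file.path(dir, f)))
      stop_fmt("bundle is missing required file '%s' in %s", f, dir)
  }
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(genes))
    stop_fmt("matrix.mtx has %d rows but features.tsv lists %d genes",
             nrow(m), length(genes))
  if (ncol(m) != length(barcodes))
    stop_fmt("matrix.mtx has %d columns but barcodes.tsv lists %d barcodes",
             ncol(m), length(barcodes))
  vals <- if (is(m, "sparseMatrix")) m@x else as.vector(m)
  if (any(vals < 0)) stop_fmt("matrix.mtx contains negative values")
  if (any(vals != round(vals))) stop_fmt("matrix.mtx contains non-integer values")
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    stop_fmt("duplicate gene label(s) in features.tsv: %s",
             paste(dup_g, collapse = ", "))
  dup_b <- unique(barcodes[duplicated(barcodes)])
  if (length(dup_b))
    stop_fmt("duplicate barcode(s) in barcodes.tsv: %s",
             paste(dup_b, collapse = ", "))
  counts <- as(m, "CsparseMatrix")
  dimnames(counts) <- list(genes, barcodes)
  meta <- read.delim(file.path(dir, "cell_meta.tsv"), sep = "\t",
                     stringsAsFactors = FALSE)
  if (!"barcode" %in% names(meta))
    stop_fmt("cell_meta.tsv must have a 'barcode' column")
  if (!setequal(meta$barcode, barcodes) || anyDuplicated(meta$barcode))
    stop_fmt("cell_meta.tsv barcodes do not match barcodes.tsv one-to-one")
  meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
  rownames(meta) <- NULL
  check_bundle(counts, meta)
  list(counts = counts, meta = meta)
}

check_bundle <- function(counts, meta) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("counts must carry gene rownames and barcode colnames")
  if (!identical(colnames(counts), meta$barcode))
    stop_fmt("meta$barcode must equal colnames(counts) in order")
  invisible(TRUE)
}

#' Read a two-column homolog table
#'
#' Tab-separated, two columns (species A symbol, species B symbol), header
#' optional (detected by the literal first line `gene_a<TAB>gene_b`).
#' Many-to-many pairs are preserved; fields are whitespace-trimmed with
#' case kept. An empty file yields an empty table.
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_homolog_table <- function(path) {
  if (!file.exists(path)) stop_fmt("homolog table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(trimws(strsplit(lines[1L], "\t")[[1L]]),
                                 c("gene_a", "gene_b")))
    lines <- lines[-1L]
  if (!length(lines))
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop_fmt("%s line %d: expected 2 tab-separated fields, found %d",
             path, bad[1L], lengths(parts)[bad[1L]])
  tab <- data.frame(gene_a = trimws(vapply(parts, `[[`, "", 1L)),
                    gene_b = trimws(vapply(parts, `[[`, "", 2L)),
                    stringsAsFactors = FALSE)
  tab[!duplicated(tab), , drop = FALSE]
}

#' Write a homolog table
#' @param homologs data.frame with columns `gene_a`, `gene_b`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_homolog_table <- function(homologs, path) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(homologs)))
  write.table(homologs[, c("gene_a", "gene_b")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read DNA sequences from a FASTA file
#'
#' Backed by [Biostrings::readDNAStringSet()]; returns plain uppercase
#' character sequences named by the first whitespace-delimited token of
#' each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Read BED3 intervals
#'
#' Parses minimal three-column BED (chrom, 0-based start, exclusive end).
#' Intervals are kept in the internal 0-based half-open convention; use
#' [bed_to_interval()] for the 1-based inclusive external form. Zero-length
#' and inverted intervals are rejected with the offending line number.
#'
#' @param path BED file path. `track`/`browser`/`#` lines are skipped.
#' @return data.frame with columns `chrom`, `start0`, `end` (0-based
#'   half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_fmt("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(chrom = character(), start0 = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(lines[idx], "[ \t]+")
  out <- lapply(seq_along(idx), function(k) {
    p <- parts[[k]]
    ln <- idx[k]
    if (length(p) < 3L)
      stop_fmt("%s line %d: expected at least 3 fields", path, ln)
    s <- suppressWarnings(as.integer(p[2L]))
    e <- suppressWarnings(as.integer(p[3L]))
    if (is.na(s) || is.na(e))
      stop_fmt("%s line %d: non-numeric coordinates '%s' '%s'",
               path, ln, p[2L], p[3L])
    if (s < 0) stop_fmt("%s line %d: negative start %d", path, ln, s)
    if (e <= s)
      stop_fmt("%s line %d: zero-length or inverted interval (%d >= %d)",
               path, ln, s, e)
    data.frame(chrom = p[1L], start0 = s, end = e, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a run manifest
#'
#' Records inputs, parameters, seed and package version as JSON next to a
#' command's outputs, so every result is traceable.
#'
#' @param path Output JSON path.
#' @param command Command name.
#' @param params Named list of parameters.
#' @param seed Integer seed or `NULL`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, params = list(), seed = NULL) {
  manifest <- list(
    command = command,
    params = params,
    seed = seed,
    package = "anchorseek",
    version = as.character(utils::packageVersion("anchorseek")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
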