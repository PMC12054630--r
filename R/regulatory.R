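# Promoter-interval arithmetic and motif scanning. External interval
# notation is 1-based inclusive ("chr8:46080750-46081200"); BED input is
# 0-based half-open; conversion between the two is centralized here.

#' Genomic interval (1-based inclusive)
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive positions, `start <= end`, both >= 1.
#' @param assembly Optional assembly label (e.g. `"mm39"`).
#' @return Object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, assembly = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop_fmt("positions must be integers")
  if (start < 1L) stop_fmt("positions are 1-based; start %d < 1", start)
  if (start > end) stop_fmt("start (%d) exceeds end (%d)", start, end)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 assembly = as.character(assembly)),
            class = "genomic_interval")
}

#' Interval length in base pairs
#'
#' `end - start + 1` under the 1-based inclusive convention, e.g.
#' chr8:46080750-46081200 spans 451 bp.
#'
#' @param iv A [genomic_interval()].
#' @return Integer number of base pairs.
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1L
}

#' @export
format.genomic_interval <- function(x, ...)
  sprintf("%s:%d-%d", x$chrom, x$start, x$end)

#' @export
print.genomic_interval <- function(x, ...) {
  cat(format(x),
      if (!is.na(x$assembly)) sprintf(" (%s)", x$assembly) else "", "\n",
      sep = "")
  invisible(x)
}

#' Parse "chrom:start-end" into a genomic interval
#'
#' @param s String such as `"chr8:46080750-46081200"` (1-based inclusive).
#' @param assembly Optional assembly label.
#' @return A [genomic_interval()].
#' @export
parse_interval <- function(s, assembly = NA_character_) {
  m <- regmatches(s, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", s))[[1L]]
  if (length(m) != 4L) stop_fmt("cannot parse interval '%s'", s)
  genomic_interval(m[2L], as.integer(gsub(",", "", m[3L])),
                   as.integer(gsub(",", "", m[4L])), assembly)
}

#' Convert between BED (0-based half-open) and 1-based inclusive intervals
#'
#' `bed_to_interval` turns one row of [read_bed()] output into a
#' [genomic_interval()] (start0 + 1, end); `interval_to_bed` is the exact
#' inverse. Both conventions give the same length: end - start0 equals
#' [interval_length()].
#'
#' @param bed_row One-row data.frame with `chrom`, `start0`, `end`.
#' @param assembly Optional assembly label.
#' @return `bed_to_interval`: a [genomic_interval()]; `interval_to_bed`: a
#'   one-row data.frame with `chrom`, `start0`, `end`.
#' @export
bed_to_interval <- function(bed_row, assembly = NA_character_) {
  genomic_interval(bed_row$chrom, bed_row$start0 + 1L, bed_row$end, assembly)
}

#' @rdname bed_to_interval
#' @param iv A [genomic_interval()].
#' @export
interval_to_bed <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  data.frame(chrom = iv$chrom, start0 = iv$start - 1L, end = iv$end,
             stringsAsFactors = FALSE)
}

#' Reverse complement of a DNA string
#'
#' Alphabet A/C/G/T/N, case-insensitive with case preserved;
#' `revcomp(revcomp(s)) == s`. An illegal character is an error reporting
#' its position.
#'
#' @param seq DNA string (may be empty).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return("")
  bad <- regexpr("[^ACGTNacgtn]", seq)
  if (bad > 0L)
    stop_fmt("illegal character '%s' at position %d",
             substr(seq, bad, bad), bad)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

iupac_regex <- function(consensus) {
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  unknown <- setdiff(letters, names(IUPAC_SETS))
  if (length(unknown))
    stop_fmt("consensus contains non-IUPAC code(s): %s",
             paste(unique(unknown), collapse = ", "))
  paste0(vapply(letters, function(l) {
    s <- IUPAC_SETS[[l]]
    if (nchar(s) == 1L) s else paste0("[", s, "]")
  }, ""), collapse = "")
}

consensus_hits_fwd <- function(seq, consensus) {
  # lookahead regex so overlapping occurrences are all found
  rx <- paste0("(?=", iupac_regex(consensus), ")")
  m <- gregexpr(rx, toupper(seq), perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every position where the window matches the degenerate
#' consensus (default `WGATAA`, the GATA-family core), on both strands by
#' default. Overlapping hits are all reported. Minus-strand hits carry the
#' forward-strand coordinate of the site's first base and the site as read
#' on the minus strand. Output is ordered by position, then strand
#' (+ before -).
#'
#' @param seq DNA string.
#' @param consensus IUPAC consensus (default `"WGATAA"`).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return data.frame with columns position (1-based), strand, site, score
#'   (1 for an exact consensus match).
#' @export
scan_consensus <- function(seq, consensus = "WGATAA", both_strands = TRUE) {
  m <- nchar(consensus)
  pos_f <- consensus_hits_fwd(seq, consensus)
  hits <- data.frame(position = pos_f, strand = rep("+", length(pos_f)),
                     stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- revcomp(seq)
    pos_rc <- consensus_hits_fwd(rc, consensus)
    if (length(pos_rc)) {
      fwd_start <- nchar(seq) - (pos_rc + m - 1L) + 1L
      hits <- rbind(hits, data.frame(position = fwd_start, strand = "-",
                                     stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  hits$site <- vapply(seq_len(nrow(hits)), function(i) {
    w <- substr(seq, hits$position[i], hits$position[i] + m - 1L)
    if (hits$strand[i] == "-") revcomp(w) else w
  }, "")
  hits$score <- rep(1, nrow(hits))
  rownames(hits) <- NULL
  hits[, c("position", "strand", "site", "score")]
}

#' Position weight matrix
#'
#' @param matrix 4 x L numeric matrix of per-position base probabilities,
#'   rows named A, C, G, T; each column must sum to 1 (tolerance 1e-9).
#' @param background Background base probabilities (default uniform),
#'   summing to 1.
#' @param pseudocount Regularization weight (default 0.01): scoring uses
#'   p' = (p + pseudocount * background) / (1 + pseudocount).
#' @param motif_id Identifier string.
#' @return Object of class `pwm`.
#' @export
pwm <- function(matrix, background = rep(0.25, 4), pseudocount = 0.01,
                motif_id = "motif") {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop_fmt("PWM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  if (!identical(rownames(matrix), c("A", "C", "G", "T")))
    stop_fmt("PWM rows must be named A, C, G, T in order")
  if (any(abs(colSums(matrix) - 1) > 1e-9))
    stop_fmt("each PWM position must sum to 1")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9)
    stop_fmt("background must be 4 probabilities summing to 1")
  if (pseudocount < 0) stop_fmt("pseudocount must be >= 0")
  structure(list(matrix = matrix, background = as.double(background),
                 pseudocount = pseudocount, motif_id = motif_id),
            class = "pwm")
}

#' Read a JASPAR-style PWM text file
#'
#' Accepts the common four-line layout `A [ 10 2 0 ... ]` (an optional
#' `>id` header line first); counts or probabilities per position, one row
#' per base. Columns are normalized to probabilities.
#'
#' @param path Text file path.
#' @param ... Passed to [pwm()] (background, pseudocount).
#' @return A [pwm()] object.
#' @export
read_jaspar_pwm <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  motif_id <- "motif"
  if (grepl("^>", lines[1L])) {
    motif_id <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (length(lines) != 4L)
    stop_fmt("%s: expected 4 base rows, found %d", path, length(lines))
  rows <- lapply(lines, function(l) {
    base <- toupper(sub("^\\s*([ACGTacgt]).*$", "\\1", l))
    rest <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", l))
    toks <- strsplit(trimws(rest), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (!length(vals) || anyNA(vals))
      stop_fmt("cannot parse PWM row '%s'", l)
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, `[[`, "", "base")
  if (!setequal(bases, c("A", "C", "G", "T")))
    stop_fmt("%s: rows must cover bases A, C, G, T", path)
  mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(mat) <- bases
  mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  mat <- sweep(mat, 2L, colSums(mat), "/")
  pwm(mat, motif_id = motif_id, ...)
}

pwm_score_fwd <- function(seq, x) {
  m <- ncol(x$matrix)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < m) return(list(pos = integer(), score = numeric(), skipped = integer()))
  p_reg <- sweep(x$matrix, 1L, x$pseudocount * x$background, "+") /
    (1 + x$pseudocount)
  lo <- log2(sweep(p_reg, 1L, x$background, "/"))
  idx <- match(chars, c("A", "C", "G", "T"))   # NA for N etc.
  starts <- seq_len(n - m + 1L)
  scores <- numeric(length(starts))
  skipped <- logical(length(starts))
  for (s in starts) {
    win <- idx[s:(s + m - 1L)]
    if (anyNA(win)) { skipped[s] <- TRUE; next }
    scores[s] <- sum(lo[cbind(win, seq_len(m))])
  }
  list(pos = starts[!skipped], score = scores[!skipped],
       skipped = starts[skipped])
}

#' Scan a sequence with a position weight matrix
#'
#' Per window, score = sum over positions of log2(p'(base)/background),
#' with pseudocount-regularized p'. Windows containing a base outside
#' A/C/G/T (e.g. N) are skipped and listed in the `skipped` attribute.
#' Both strands are scanned by default; minus-strand hits carry
#' forward-strand coordinates.
#'
#' @param seq DNA string.
#' @param x A [pwm()] object.
#' @param threshold_bits Minimum log2-odds score for a hit (default 0).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return data.frame with columns position, strand, site, score (bits),
#'   ordered by position then strand; attribute `skipped` lists skipped
#'   window starts per strand.
#' @export
scan_pwm <- function(seq, x, threshold_bits = 0, both_strands = TRUE) {
  stopifnot(inherits(x, "pwm"))
  m <- ncol(x$matrix)
  fwd <- pwm_score_fwd(seq, x)
  hits <- data.frame(position = fwd$pos, strand = rep("+", length(fwd$pos)),
                     score = fwd$score, stringsAsFactors = FALSE)
  skipped <- list(`+` = fwd$skipped)
  if (both_strands) {
    rc <- revcomp(seq)
    rev_ <- pwm_score_fwd(rc, x)
    fwd_start <- nchar(seq) - (rev_$pos + m - 1L) + 1L
    hits <- rbind(hits, data.frame(position = fwd_start, strand = "-",
                                   score = rev_$score,
                                   stringsAsFactors = FALSE))
    skipped$`-` <- nchar(seq) - (rev_$skipped + m - 1L) + 1L
  }
  hits <- hits[hits$score >= threshold_bits, , drop = FALSE]
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  hits$site <- vapply(seq_len(nrow(hits)), function(i) {
    w <- substr(seq, hits$position[i], hits$position[i] + m - 1L)
    if (hits$strand[i] == "-") revcomp(w) else w
  }, "")
  rownames(hits) <- NULL
  out <- hits[, c("position", "strand", "site", "score")]
  attr(out, "skipped") <- skipped
  out
}
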