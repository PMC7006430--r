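#' Hit filter
#'
#' Post-alignment acceptance thresholds for duplicated-sequence hits. Both
#' inequalities are strict: a 40-column or 70%-identity hit is dropped.
#'
#' @param min_length minimum aligned columns, exclusive (default 40: keep
#'   hits with `aln_length > 40`).
#' @param min_identity minimum percent identity, exclusive (default 70).
#' @param max_gap maximum gap in bp between the two arms (start of the
#'   downstream arm minus end of the upstream arm, floored at 0 for
#'   overlapping arms); `Inf` disables the gap filter. The 2000 bp variant
#'   restricts to arms close enough on the molecule to plausibly pair.
#' @return an object of class `hit_filter`.
#' @export
hit_filter <- function(min_length = 40, min_identity = 70, max_gap = Inf) {
  stopifnot(min_length >= 1, min_identity > 0, min_identity <= 100,
            max_gap >= 0)
  structure(list(min_length = min_length, min_identity = min_identity,
                 max_gap = max_gap), class = "hit_filter")
}

hits_columns <- c("seq_id", "q_start", "q_end", "s_start", "s_end", "strand",
                  "identity_pct", "aln_length")

empty_hits <- function() {
  data.frame(seq_id = character(), q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(), strand = character(),
             identity_pct = numeric(), aln_length = integer(),
             stringsAsFactors = FALSE)
}

#' Align a sequence against itself and report duplicated sequences
#'
#' Seed-and-extend local self-alignment on both strand relations. Hits on the
#' opposite strand ("plus/minus") pair a region with the reverse complement
#' of another region of the same molecule — putative intramolecular dsRNA
#' stems (IDS). Same-strand hits ("plus/plus") are tandem duplications (TDS),
#' the structural control.
#'
#' The engine uses exact 11-mer seeds, +1/-2 match/mismatch scores, affine
#' gaps (open 5, extend 2) and x-drop extension; identity is matched columns
#' over aligned columns, gap columns included. The trivial full-length
#' same-strand self-identity is never reported and mirror duplicates are
#' collapsed to canonical ordering (`q_start <= s_start`). The gap filter is
#' not applied here; see [classify_and_gap_filter()].
#'
#' @param sequence nucleotide string; at least `filter$min_length` bases, and
#'   at most 50% non-ACGT characters.
#' @param filter a [hit_filter()].
#' @param seq_id identifier recorded in the hit table.
#' @param seed_len exact-match seed length.
#' @param match,mismatch,gap_open,gap_extend,xdrop alignment scores (positive
#'   penalties).
#' @return hit data frame: `seq_id`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (0-based half-open, query arm leftmost), `strand` ("same"/"opposite"),
#'   `identity_pct`, `aln_length`.
#' @export
self_align <- function(sequence, filter = hit_filter(), seq_id = "seq",
                       seed_len = 11L, match = 1L, mismatch = 2L,
                       gap_open = 5L, gap_extend = 2L, xdrop = 25L) {
  stopifnot(inherits(filter, "hit_filter"), is.character(sequence),
            length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < filter$min_length) {
    stop("sequence shorter than the minimum hit length", call. = FALSE)
  }
  n_bad <- n - sum(strsplit(sequence, "")[[1]] %in% BASES)
  if (n_bad > n / 2) {
    stop(sprintf(
      "sequence '%s' rejected: %d of %d characters (%.0f%%) are not A/C/G/T",
      seq_id, n_bad, n, 100 * n_bad / n), call. = FALSE)
  }
  df <- .cpp_self_align(sequence, as.integer(filter$min_length),
                        filter$min_identity, as.integer(seed_len),
                        as.integer(match), -abs(as.integer(mismatch)),
                        as.integer(gap_open), as.integer(gap_extend),
                        as.integer(xdrop))
  if (nrow(df) == 0L) return(empty_hits())
  out <- data.frame(seq_id = rep(seq_id, nrow(df)),
                    q_start = df$q_start, q_end = df$q_end,
                    s_start = df$s_start, s_end = df$s_end,
                    strand = df$strand, identity_pct = df$identity_pct,
                    aln_length = df$aln_length, stringsAsFactors = FALSE)
  out <- out[order(out$q_start, out$s_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse externally produced self-alignment hits (12-column tabular format)
#'
#' Reads the standard 12-column pairwise tabular alignment format (query,
#' subject, %identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bitscore; 1-based inclusive coordinates; an
#' opposite-strand hit is encoded by `sstart > send`) as produced by, e.g.,
#' `blastn -outfmt 6` of a sequence against itself. Applies the same filter,
#' strand classification, trivial-hit removal and mirror collapse as
#' [self_align()].
#'
#' @param path path to the tabular file.
#' @param filter a [hit_filter()]; length and identity thresholds are applied
#'   (strict `>`), the gap filter is left to [classify_and_gap_filter()].
#' @return hit data frame as in [self_align()].
#' @export
parse_tabular_hits <- function(path, filter = hit_filter()) {
  stopifnot(inherits(filter, "hit_filter"))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad)) {
    stop(sprintf("malformed tabular alignment row (need 12 columns) at line %s",
                 paste(lineno[bad], collapse = ", ")), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  qseq <- m[, 1]; sseq <- m[, 2]
  num <- suppressWarnings(apply(m[, c(3, 4, 7, 8, 9, 10), drop = FALSE], 2,
                                as.numeric))
  num <- matrix(num, ncol = 6)
  if (any(!is.finite(num))) {
    bad <- lineno[which(rowSums(!is.finite(num)) > 0)]
    stop(sprintf("non-numeric coordinate/identity fields at line %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  identity <- num[, 1]; aln_len <- as.integer(num[, 2])
  qstart <- num[, 3]; qend <- num[, 4]; sstart <- num[, 5]; send <- num[, 6]
  if (any(qstart > qend) || any(qstart < 1) || any(pmin(sstart, send) < 1)) {
    bad <- lineno[which(qstart > qend | qstart < 1 | pmin(sstart, send) < 1)]
    stop(sprintf("coordinate order violation (qstart > qend or coordinate < 1) at line %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  opposite <- sstart > send
  df <- data.frame(seq_id = qseq,
                   q_start = as.integer(qstart - 1), q_end = as.integer(qend),
                   s_start = as.integer(ifelse(opposite, send, sstart) - 1),
                   s_end = as.integer(ifelse(opposite, sstart, send)),
                   strand = ifelse(opposite, "opposite", "same"),
                   identity_pct = identity, aln_length = aln_len,
                   stringsAsFactors = FALSE)
  if (any(qseq != sseq)) {
    stop("self-alignment expected: query and subject ids differ on some rows",
         call. = FALSE)
  }
  # trivial same-strand self-identity
  trivial <- df$strand == "same" & df$q_start == df$s_start & df$q_end == df$s_end
  df <- df[!trivial, , drop = FALSE]
  # canonical ordering: leftmost arm is the query arm
  swap <- df$q_start > df$s_start |
    (df$q_start == df$s_start & df$q_end > df$s_end)
  if (any(swap)) {
    tmp_s <- df$q_start[swap]; tmp_e <- df$q_end[swap]
    df$q_start[swap] <- df$s_start[swap]; df$q_end[swap] <- df$s_end[swap]
    df$s_start[swap] <- tmp_s; df$s_end[swap] <- tmp_e
  }
  # mirror collapse: unordered arm pair + strand relation
  key <- paste(df$seq_id, df$q_start, df$q_end, df$s_start, df$s_end, df$strand)
  df <- df[!duplicated(key), , drop = FALSE]
  # filter (strict >)
  df <- df[df$aln_length > filter$min_length &
             df$identity_pct > filter$min_identity, , drop = FALSE]
  rownames(df) <- NULL
  df[hits_columns]
}

#' Classify hits by strand relation and apply the inter-arm gap filter
#'
#' Partitions canonical hits into IDS (opposite strand, putative dsRNA) and
#' TDS (same strand, control). If `filter$max_gap` is finite, hits whose
#' inter-arm gap (`s_start - q_end`, floored at 0 for overlapping arms)
#' exceeds it are dropped.
#'
#' @param hits hit data frame in canonical ordering (see [self_align()]).
#' @param filter a [hit_filter()].
#' @return list with elements `ids` and `tds`, each a hit data frame with an
#'   additional `gap_bp` column.
#' @export
classify_and_gap_filter <- function(hits, filter = hit_filter()) {
  stopifnot(inherits(filter, "hit_filter"))
  if (nrow(hits) == 0L) {
    e <- cbind(empty_hits(), gap_bp = integer())
    return(list(ids = e, tds = e))
  }
  hits$gap_bp <- pmax(0L, hits$s_start - hits$q_end)
  if (is.finite(filter$max_gap)) {
    hits <- hits[hits$gap_bp <= filter$max_gap, , drop = FALSE]
  }
  list(ids = hits[hits$strand == "opposite", , drop = FALSE],
       tds = hits[hits$strand == "same", , drop = FALSE])
}

#' Self-align every transcript of a transcriptome
#'
#' Runs [self_align()] on each pre-mRNA and/or spliced mRNA and stacks the
#' hits, tagging each row with the molecule type. mRNA coordinates are mRNA
#' coordinates (exon concatenation), not genomic.
#'
#' @param transcripts list of `transcript` objects (see
#'   [generate_transcriptome()] or [read_transcripts()]).
#' @param filter a [hit_filter()].
#' @param molecules molecule types to scan, subset of
#'   `c("pre_mrna", "mrna")`.
#' @param ... further arguments to [self_align()].
#' @return hit data frame with a `molecule` column.
#' @export
scan_transcripts <- function(transcripts, filter = hit_filter(),
                             molecules = c("pre_mrna", "mrna"), ...) {
  molecules <- match.arg(molecules, several.ok = TRUE)
  out <- list()
  for (tr in transcripts) {
    if ("pre_mrna" %in% molecules && nchar(tr$seq) >= filter$min_length) {
      h <- self_align(tr$seq, filter, seq_id = tr$gene_id, ...)
      if (nrow(h)) { h$molecule <- "pre_mrna"; out[[length(out) + 1L]] <- h }
    }
    if ("mrna" %in% molecules) {
      sp <- splice_mrna(tr)
      if (nchar(sp$mrna) >= filter$min_length) {
        h <- self_align(sp$mrna, filter, seq_id = tr$gene_id, ...)
        if (nrow(h)) { h$molecule <- "mrna"; out[[length(out) + 1L]] <- h }
      }
    }
  }
  if (!length(out)) return(cbind(empty_hits(), molecule = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
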