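#' Exhaustive local alignment (reference implementation)
#'
#' Full-matrix Smith-Waterman with affine gaps: exact but quadratic. This is
#' the reference against which the seed-and-extend engine is validated; it
#' shares no code with it.
#'
#' @param a,b nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend scoring (positive penalties).
#' @param triangle restrict to aligned pairs with query position strictly
#'   before subject position (self-comparison without the trivial diagonal).
#' @return list with `score`, and when `score > 0`: `q_start`, `q_end`,
#'   `s_start`, `s_end` (0-based half-open), `matches`, `aln_length`.
#' @export
sw_local <- function(a, b, match = 1L, mismatch = 2L, gap_open = 5L,
                     gap_extend = 2L, triangle = FALSE) {
  .cpp_sw_local(toupper(a), toupper(b), as.integer(match),
                -abs(as.integer(mismatch)), as.integer(gap_open),
                as.integer(gap_extend), isTRUE(triangle))
}

#' Enumerate local self-alignment hits by exhaustive dynamic programming
#'
#' Greedy mask-and-repeat enumeration over the full Smith-Waterman matrix:
#' the best local alignment is extracted, its footprint masked, and the
#' search repeated until no alignment passes the filter. Opposite-strand
#' mirror images are masked together and hits are reported in the same
#' canonical form as [self_align()]. Quadratic per pass; intended for
#' sequences up to a few kb as an independent oracle.
#'
#' @param sequence nucleotide string.
#' @param filter a [hit_filter()]; length and identity thresholds (strict
#'   `>`).
#' @param max_hits safety cap on enumerated hits per strand relation.
#' @param max_fail stop after this many consecutive best alignments that
#'   fail the filter; enumeration is score-ordered, so once several noise
#'   alignments in a row fail, no passing alignment remains in practice.
#' @param ... scoring arguments passed to [sw_local()].
#' @return hit data frame as in [self_align()].
#' @export
oracle_local_hits <- function(sequence, filter = hit_filter(), max_hits = 50L,
                              max_fail = 8L, ...) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  out <- list()

  mask <- function(s, from, to) { # 0-based half-open
    if (to > from) {
      substr(s, from + 1L, to) <- strrep("N", to - from)
    }
    s
  }
  passes <- function(r) {
    !is.null(r$aln_length) && r$aln_length > filter$min_length &&
      100 * r$matches / r$aln_length > filter$min_identity
  }

  # any passing hit scores at least floor(0.1 * min_length) under +1/-2
  # scoring (matches > 0.7 c, penalties < 2 * 0.3 c for c columns)
  score_floor <- max(1, floor(0.1 * filter$min_length))

  # same strand: upper triangle of S vs S
  a <- sequence; b <- sequence
  fails <- 0L
  for (i in seq_len(max_hits)) {
    r <- sw_local(a, b, triangle = TRUE, ...)
    if (r$score < score_floor || is.null(r$aln_length)) break
    fails <- if (passes(r)) 0L else fails + 1L
    if (fails >= max_fail) break
    if (passes(r)) {
      out[[length(out) + 1L]] <- data.frame(
        seq_id = "seq", q_start = r$q_start, q_end = r$q_end,
        s_start = r$s_start, s_end = r$s_end, strand = "same",
        identity_pct = 100 * r$matches / r$aln_length,
        aln_length = r$aln_length, stringsAsFactors = FALSE)
    }
    a <- mask(a, r$q_start, r$q_end)
    b <- mask(b, r$s_start, r$s_end)
  }

  # opposite strand: S vs revcomp(S); subject interval maps back through the
  # reverse complement, and each hit has a mirror image that is masked too
  a <- sequence; b <- revcomp(sequence)
  fails <- 0L
  for (i in seq_len(max_hits)) {
    r <- sw_local(a, b, triangle = FALSE, ...)
    if (r$score < score_floor || is.null(r$aln_length)) break
    fails <- if (passes(r)) 0L else fails + 1L
    if (fails >= max_fail) break
    s1 <- n - r$s_end; s2 <- n - r$s_start # subject arm in original coords
    if (passes(r)) {
      q1 <- r$q_start; q2 <- r$q_end
      if (q1 > s1 || (q1 == s1 && q2 > s2)) {
        tmp1 <- q1; tmp2 <- q2; q1 <- s1; q2 <- s2; s1 <- tmp1; s2 <- tmp2
      }
      rec <- data.frame(
        seq_id = "seq", q_start = q1, q_end = q2, s_start = s1, s_end = s2,
        strand = "opposite", identity_pct = 100 * r$matches / r$aln_length,
        aln_length = r$aln_length, stringsAsFactors = FALSE)
      key <- with(rec, paste(q_start, q_end, s_start, s_end))
      seen <- vapply(out, function(d) {
        d$strand == "opposite" && with(d, paste(q_start, q_end, s_start, s_end)) == key
      }, TRUE)
      if (!any(seen)) out[[length(out) + 1L]] <- rec
    }
    # mask the found arms and their mirror images on both strings
    a <- mask(a, r$q_start, r$q_end)
    a <- mask(a, n - r$s_end, n - r$s_start)
    b <- mask(b, r$s_start, r$s_end)
    b <- mask(b, n - r$q_end, n - r$q_start)
  }

  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  res <- res[order(res$q_start, res$s_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
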