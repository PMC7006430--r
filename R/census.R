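#' Splice a transcript into its mature mRNA
#'
#' Concatenates the exons in transcript order and returns the coordinate map
#' between pre-mRNA and mRNA positions (a bijection on exonic positions).
#'
#' @param transcript a `transcript` object (`gene_id`, `seq`, `exons` with
#'   0-based half-open `start`/`end`, sorted and non-overlapping).
#' @return list with `mrna` (sequence string), `pre_to_mrna` (integer vector
#'   indexed by pre-mRNA position + 1, holding the 0-based mRNA position or
#'   `NA` for intronic positions) and `mrna_to_pre` (integer vector indexed by
#'   mRNA position + 1, holding the 0-based pre-mRNA position).
#' @export
splice_mrna <- function(transcript) {
  exons <- transcript$exons
  if (is.null(exons) || nrow(exons) == 0L) {
    stop("transcript has no exons", call. = FALSE)
  }
  L <- nchar(transcript$seq)
  check_interval(exons$start, exons$end, "exon")
  if (any(exons$end > L)) stop("exon beyond sequence end", call. = FALSE)
  o <- order(exons$start)
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("exons overlap", call. = FALSE)
  }
  pieces <- substring(transcript$seq, exons$start + 1L, exons$end)
  mrna <- paste(pieces, collapse = "")
  pre_to_mrna <- rep(NA_integer_, L)
  mpos <- 0L
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i]
    if (w > 0L) {
      pre_to_mrna[(exons$start[i] + 1L):exons$end[i]] <- mpos + 0L:(w - 1L)
      mpos <- mpos + w
    }
  }
  mrna_to_pre <- which(!is.na(pre_to_mrna)) - 1L
  list(mrna = mrna, pre_to_mrna = pre_to_mrna,
       mrna_to_pre = as.integer(mrna_to_pre))
}

#' Merge hit arms into duplex regions with longest-hit attribution
#'
#' Pools both arm intervals of every hit of one class (IDS or TDS), merges
#' overlapping or book-ended intervals into disjoint regions (the semantics
#' of `bedtools sort | merge`), and attributes every covered nucleotide to
#' the longest hit covering it (ties broken by higher identity, then by
#' leftmost hit start).
#'
#' @param hits hit data frame (one class; see [classify_and_gap_filter()]).
#' @param class_label `"IDS"` or `"TDS"`.
#' @return an object of class `duplex_regions`: list with `class_label`,
#'   `hits`, `merged` (data frame seq_id/start/end of disjoint regions) and
#'   `attribution` (data frame seq_id/start/end/aln_length/identity_pct/hit
#'   of maximal runs of nucleotides attributed to one hit).
#' @export
merge_to_regions <- function(hits, class_label = c("IDS", "TDS")) {
  class_label <- match.arg(class_label)
  if (nrow(hits) == 0L) {
    empty <- data.frame(seq_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    return(structure(list(class_label = class_label, hits = hits,
                          merged = empty,
                          attribution = cbind(empty,
                                              data.frame(aln_length = integer(),
                                                         identity_pct = numeric(),
                                                         hit = integer()))),
                     class = "duplex_regions"))
  }
  # per-hit key for molecule-aware grouping (mRNA and pre-mRNA coordinates of
  # one gene must never be pooled together)
  grp <- if ("molecule" %in% names(hits)) {
    paste(hits$seq_id, hits$molecule, sep = "\r")
  } else hits$seq_id
  merged <- list(); attribution <- list()
  for (g in unique(grp)) {
    h <- hits[grp == g, , drop = FALSE]
    sid <- h$seq_id[1L]
    arms <- IRanges::IRanges(
      start = c(h$q_start, h$s_start) + 1L,
      end = c(h$q_end, h$s_end))
    red <- IRanges::reduce(arms)
    mdf <- data.frame(seq_id = sid, start = IRanges::start(red) - 1L,
                      end = IRanges::end(red), stringsAsFactors = FALSE)
    if ("molecule" %in% names(hits)) mdf$molecule <- h$molecule[1L]
    merged[[length(merged) + 1L]] <- mdf
    # attribution: walk hits in priority order, claim unclaimed nucleotides
    pri <- order(-h$aln_length, -h$identity_pct, h$q_start)
    claimed <- IRanges::IRanges()
    for (i in pri) {
      fp <- IRanges::reduce(IRanges::IRanges(
        start = c(h$q_start[i], h$s_start[i]) + 1L,
        end = c(h$q_end[i], h$s_end[i])))
      new <- IRanges::setdiff(fp, claimed)
      if (length(new)) {
        adf <- data.frame(seq_id = sid, start = IRanges::start(new) - 1L,
                          end = IRanges::end(new),
                          aln_length = h$aln_length[i],
                          identity_pct = h$identity_pct[i],
                          hit = i, stringsAsFactors = FALSE)
        if ("molecule" %in% names(hits)) adf$molecule <- h$molecule[1L]
        attribution[[length(attribution) + 1L]] <- adf
        claimed <- IRanges::reduce(IRanges::union(claimed, new))
      }
    }
  }
  structure(list(class_label = class_label, hits = hits,
                 merged = do.call(rbind, merged),
                 attribution = do.call(rbind, attribution)),
            class = "duplex_regions")
}

#' Total merged footprint in bp
#' @param regions a `duplex_regions` object.
#' @return total number of distinct nucleotides covered by the class.
#' @export
region_bp <- function(regions) {
  stopifnot(inherits(regions, "duplex_regions"))
  if (nrow(regions$merged) == 0L) return(0L)
  sum(regions$merged$end - regions$merged$start)
}

default_length_bins <- c(40, 100, 300, Inf)
default_identity_bins <- c(0, 70, 80, 90, 96, 100)

bin_labels <- function(breaks) {
  n <- length(breaks) - 1L
  sprintf("(%s,%s]", breaks[-length(breaks)], breaks[-1L])
}

check_bins <- function(length_bins, identity_bins) {
  if (length(length_bins) < 2L || length_bins[1] > 40 ||
      !is.infinite(length_bins[length(length_bins)]) ||
      is.unsorted(length_bins, strictly = TRUE)) {
    stop("length_bins must be strictly increasing breaks covering [41, Inf)",
         call. = FALSE)
  }
  if (length(identity_bins) < 2L || identity_bins[1] != 0 ||
      identity_bins[length(identity_bins)] != 100 ||
      is.unsorted(identity_bins, strictly = TRUE)) {
    stop("identity_bins must be strictly increasing breaks partitioning (0, 100]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Nucleotide and hit census per (length bin x identity bin)
#'
#' Counts, for IDS and TDS independently, the merged nucleotides and the
#' hits falling into each (length, identity) cell. A nucleotide's cell is
#' that of its attributed hit (the longest hit covering it), so bin totals
#' sum exactly to the merged footprint. Bins are left-open/right-closed.
#'
#' @param ids_regions,tds_regions `duplex_regions` objects (see
#'   [merge_to_regions()]).
#' @param length_bins breaks for aligned length, first break <= 40 and last
#'   `Inf`.
#' @param identity_bins breaks for percent identity, from 0 to 100.
#' @return a `census_table` data frame: `class`, `length_bin`, `identity_bin`,
#'   `bp`, `n_hits`, with attributes `length_bins`/`identity_bins`.
#' @export
census <- function(ids_regions, tds_regions,
                   length_bins = default_length_bins,
                   identity_bins = default_identity_bins) {
  check_bins(length_bins, identity_bins)
  one <- function(regions) {
    stopifnot(inherits(regions, "duplex_regions"))
    lab_l <- bin_labels(length_bins); lab_i <- bin_labels(identity_bins)
    grid <- expand.grid(length_bin = lab_l, identity_bin = lab_i,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$bp <- 0; grid$n_hits <- 0L
    att <- regions$attribution
    if (!is.null(att) && nrow(att)) {
      lb <- cut(att$aln_length, length_bins, labels = lab_l)
      ib <- cut(att$identity_pct, identity_bins, labels = lab_i)
      bp <- tapply(att$end - att$start, list(lb, ib), sum, default = 0)
      key <- paste(grid$length_bin, grid$identity_bin)
      m <- as.data.frame(as.table(bp), stringsAsFactors = FALSE)
      grid$bp <- m$Freq[match(key, paste(m$Var1, m$Var2))]
      grid$bp[is.na(grid$bp)] <- 0
    }
    h <- regions$hits
    if (!is.null(h) && nrow(h)) {
      lb <- cut(h$aln_length, length_bins, labels = lab_l)
      ib <- cut(h$identity_pct, identity_bins, labels = lab_i)
      cnt <- table(lb, ib)
      m <- as.data.frame(cnt, stringsAsFactors = FALSE)
      key <- paste(grid$length_bin, grid$identity_bin)
      grid$n_hits <- m$Freq[match(key, paste(m$lb, m$ib))]
      grid$n_hits[is.na(grid$n_hits)] <- 0L
    }
    grid$class <- regions$class_label
    grid[, c("class", "length_bin", "identity_bin", "bp", "n_hits")]
  }
  out <- rbind(one(ids_regions), one(tds_regions))
  rownames(out) <- NULL
  structure(out, length_bins = length_bins, identity_bins = identity_bins,
            class = c("census_table", "data.frame"))
}

#' Select long, nearly perfect duplex structures
#'
#' Keeps hits with aligned length and identity strictly above the thresholds
#' (defaults: > 300 bp and > 96% identity, the class most strongly purged
#' from transcriptomes). Among structures whose genomic footprints overlap
#' (on the same molecule), only the one with the highest identity is retained
#' (ties: longer, then leftmost). Both arms are required to lie within the
#' same transcript, which holds by construction for self-alignment hits.
#'
#' @param hits hit data frame.
#' @param min_length aligned-length threshold, exclusive.
#' @param min_identity identity threshold (percent), exclusive.
#' @return structure data frame: `seq_id`, `arm1_start`, `arm1_end`,
#'   `arm2_start`, `arm2_end`, `orientation` ("inverted"/"tandem"),
#'   `identity_pct`, `aln_length`, `gap_bp` (plus `molecule` if present).
#' @export
select_structures <- function(hits, min_length = 300, min_identity = 96) {
  keep <- hits[hits$aln_length > min_length &
                 hits$identity_pct > min_identity, , drop = FALSE]
  grp <- if ("molecule" %in% names(keep)) {
    paste(keep$seq_id, keep$molecule, sep = "\r")
  } else keep$seq_id
  sel <- logical(nrow(keep))
  if (nrow(keep)) {
    o <- order(-keep$identity_pct, -keep$aln_length, keep$q_start)
    taken <- list()
    for (i in o) {
      fp <- IRanges::reduce(IRanges::IRanges(
        start = c(keep$q_start[i], keep$s_start[i]) + 1L,
        end = c(keep$q_end[i], keep$s_end[i])))
      g <- grp[i]
      prev <- taken[[g]]
      if (is.null(prev) ||
          sum(IRanges::width(IRanges::intersect(fp, prev))) == 0L) {
        sel[i] <- TRUE
        taken[[g]] <- if (is.null(prev)) fp else
          IRanges::reduce(IRanges::union(prev, fp))
      }
    }
  }
  keep <- keep[sel, , drop = FALSE]
  out <- data.frame(seq_id = keep$seq_id,
                    arm1_start = keep$q_start, arm1_end = keep$q_end,
                    arm2_start = keep$s_start, arm2_end = keep$s_end,
                    orientation = ifelse(keep$strand == "opposite",
                                         "inverted", "tandem"),
                    identity_pct = keep$identity_pct,
                    aln_length = keep$aln_length,
                    gap_bp = pmax(0L, keep$s_start - keep$q_end),
                    stringsAsFactors = FALSE)
  if ("molecule" %in% names(keep)) out$molecule <- keep$molecule
  rownames(out) <- NULL
  out
}

#' Fraction of duplex nucleotides overlapping a repeat annotation
#'
#' Intersects the merged duplex footprint with a (sorted, merged) repeat
#' annotation and reports overlapping and total base counts.
#'
#' @param regions a `duplex_regions` object.
#' @param repeat_annotation data frame with `seq_id`, `start`, `end`
#'   (0-based half-open), or `NULL` when no annotation is available.
#' @return list with `available` (FALSE when `repeat_annotation` is `NULL`),
#'   `no_repeats_annotated` (TRUE for an empty annotation), `overlapping_bp`,
#'   `total_bp` and `fraction`.
#' @export
repeat_overlap_fraction <- function(regions, repeat_annotation) {
  stopifnot(inherits(regions, "duplex_regions"))
  if (is.null(repeat_annotation)) {
    return(list(available = FALSE, no_repeats_annotated = NA,
                overlapping_bp = NA_integer_, total_bp = region_bp(regions),
                fraction = NA_real_))
  }
  total <- region_bp(regions)
  if (nrow(repeat_annotation) == 0L) {
    return(list(available = TRUE, no_repeats_annotated = TRUE,
                overlapping_bp = 0L, total_bp = total,
                fraction = if (total > 0) 0 else NA_real_))
  }
  ov <- 0L
  for (sid in unique(regions$merged$seq_id)) {
    r <- regions$merged[regions$merged$seq_id == sid, , drop = FALSE]
    a <- repeat_annotation[repeat_annotation$seq_id == sid, , drop = FALSE]
    if (nrow(a) == 0L) next
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    ia <- IRanges::reduce(IRanges::IRanges(start = a$start + 1L, end = a$end))
    ov <- ov + sum(IRanges::width(IRanges::intersect(ir, ia)))
  }
  list(available = TRUE, no_repeats_annotated = FALSE,
       overlapping_bp = as.integer(ov), total_bp = total,
       fraction = if (total > 0) ov / total else NA_real_)
}
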