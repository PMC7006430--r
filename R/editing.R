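#' Library statistics for FPKM/coverage conversion
#'
#' @param total_mapped_reads total single-end reads mapped in the pool.
#' @param read_length read length in bp before trimming.
#' @param trim_bp bases removed from each read end before the pileup
#'   (default 5).
#' @return an object of class `library_stats` with the derived
#'   `effective_length = read_length - 2 * trim_bp`.
#' @export
library_stats <- function(total_mapped_reads, read_length, trim_bp = 5) {
  eff <- read_length - 2 * trim_bp
  if (eff < 1) stop("non-positive effective read length", call. = FALSE)
  structure(list(total_mapped_reads = total_mapped_reads,
                 read_length = read_length, trim_bp = trim_bp,
                 effective_length = eff), class = "library_stats")
}

#' Convert FPKM to mean per-base coverage (and back)
#'
#' `coverage = fpkm * total_mapped_reads * effective_length / 1e9`: with
#' 1.343e9 mapped reads of 66 bp effective length, 1 FPKM corresponds to
#' 88.64x coverage.
#'
#' @param fpkm expression in fragments per kilobase per million mapped reads.
#' @param lib a [library_stats()].
#' @return mean per-base coverage.
#' @export
fpkm_to_coverage <- function(fpkm, lib) {
  stopifnot(inherits(lib, "library_stats"))
  fpkm * lib$total_mapped_reads * lib$effective_length / 1e9
}

#' @rdname fpkm_to_coverage
#' @param coverage mean per-base coverage.
#' @export
coverage_to_fpkm <- function(coverage, lib) {
  stopifnot(inherits(lib, "library_stats"))
  coverage * 1e9 / (lib$total_mapped_reads * lib$effective_length)
}

#' Coverage and editing index of one duplex arm
#'
#' Over the adenosines of the arm: the coverage is the mean of
#' `A_count + G_count` (zero-coverage adenosines contribute 0 to the mean),
#' and the editing index is the ratio of all A-to-G mismatches to the summed
#' coverage of all adenosines — the coverage-weighted mean of per-site
#' editing levels.
#'
#' @param profile editing profile data frame (`contig`, `pos`, `ref`,
#'   `A_count`, `G_count`; positions 0-based), e.g. from [simulate_pileup()]
#'   or [read_pileup()].
#' @param arm integer vector `c(start, end)`, 0-based half-open.
#' @param contig restrict to this contig (default: all rows).
#' @return list with `mean_coverage`, `editing_index` (`NA` if no adenosine
#'   has coverage), `n_adenosines`, and `n_covered`.
#' @export
arm_coverage_and_index <- function(profile, arm, contig = NULL) {
  stopifnot(length(arm) == 2L, arm[1] <= arm[2])
  rows <- profile$pos >= arm[1] & profile$pos < arm[2]
  if (!is.null(contig)) rows <- rows & profile$contig == contig
  p <- profile[rows & profile$ref %in% c("A", "a"), , drop = FALSE]
  n_aden <- nrow(p)
  if (n_aden == 0L) {
    return(list(mean_coverage = NA_real_, editing_index = NA_real_,
                n_adenosines = 0L, n_covered = 0L))
  }
  cov <- p$A_count + p$G_count
  idx <- if (sum(cov) > 0) sum(p$G_count) / sum(cov) else NA_real_
  list(mean_coverage = mean(cov), editing_index = idx,
       n_adenosines = n_aden, n_covered = sum(cov > 0))
}

#' Residual identity of a duplex after editing
#'
#' The arm-pair identity of the genomic sequences minus the identity
#' equivalent of the average inosine load:
#' `identity_pct - 100 * avg_inosines / mean(arm lengths)`, floored at 0.
#' Editing converts paired adenosines to inosines (read as G), unwinding the
#' duplex; a structure whose residual identity falls below 96% is no longer
#' "nearly perfect".
#'
#' @param identity_pct genomic arm-pair percent identity.
#' @param avg_inosines average inosines per transcript over the structure
#'   (editing index times number of adenosines, averaged over arms).
#' @param arm_lengths numeric vector of the two arm lengths in bp.
#' @return residual percent identity.
#' @export
residual_identity <- function(identity_pct, avg_inosines, arm_lengths) {
  stopifnot(all(arm_lengths > 0))
  max(0, identity_pct - 100 * avg_inosines / mean(arm_lengths))
}

#' Expression and editing summary of duplex structures
#'
#' For every structure (see [select_structures()]), summarizes both arms from
#' a pileup profile: mean adenosine coverage, region FPKM (the arm's own
#' coverage converted through the library stats — not the host gene's FPKM),
#' editing index, inosines per arm, the per-structure average inosine number,
#' and the residual identity with its below-96% ("unwound") flag.
#'
#' @param structures structure data frame; arm coordinates refer to positions
#'   in `profile`.
#' @param profile editing profile data frame covering the arms.
#' @param lib a [library_stats()].
#' @param inosine_average `"per_arm"` (mean of the two arms'
#'   index x n_adenosines; default) or `"pooled"` (pooled index times pooled
#'   adenosine count, halved between arms).
#' @param unwound_threshold identity threshold for the unwound flag
#'   (default 96).
#' @return the structure data frame with appended columns `coverage1`,
#'   `coverage2`, `fpkm1`, `fpkm2`, `index1`, `index2`, `n_adenosines1`,
#'   `n_adenosines2`, `avg_inosines`, `residual_identity_pct`, `unwound`.
#' @export
structure_editing_summary <- function(structures, profile, lib,
                                      inosine_average = c("per_arm", "pooled"),
                                      unwound_threshold = 96) {
  inosine_average <- match.arg(inosine_average)
  stopifnot(inherits(lib, "library_stats"))
  n <- nrow(structures)
  num <- function() rep(NA_real_, n)
  out <- structures
  out$coverage1 <- num(); out$coverage2 <- num()
  out$fpkm1 <- num(); out$fpkm2 <- num()
  out$index1 <- num(); out$index2 <- num()
  out$n_adenosines1 <- rep(NA_integer_, n)
  out$n_adenosines2 <- rep(NA_integer_, n)
  out$avg_inosines <- num(); out$residual_identity_pct <- num()
  out$unwound <- rep(NA, n)
  for (i in seq_len(n)) {
    ctg <- if ("seq_id" %in% names(structures)) structures$seq_id[i] else NULL
    a1 <- arm_coverage_and_index(profile,
                                 c(structures$arm1_start[i], structures$arm1_end[i]),
                                 contig = ctg)
    a2 <- arm_coverage_and_index(profile,
                                 c(structures$arm2_start[i], structures$arm2_end[i]),
                                 contig = ctg)
    out$coverage1[i] <- a1$mean_coverage; out$coverage2[i] <- a2$mean_coverage
    out$index1[i] <- a1$editing_index; out$index2[i] <- a2$editing_index
    out$n_adenosines1[i] <- a1$n_adenosines; out$n_adenosines2[i] <- a2$n_adenosines
    if (!is.na(a1$mean_coverage)) out$fpkm1[i] <- coverage_to_fpkm(a1$mean_coverage, lib)
    if (!is.na(a2$mean_coverage)) out$fpkm2[i] <- coverage_to_fpkm(a2$mean_coverage, lib)
    ino1 <- if (is.na(a1$editing_index)) NA_real_ else a1$editing_index * a1$n_adenosines
    ino2 <- if (is.na(a2$editing_index)) NA_real_ else a2$editing_index * a2$n_adenosines
    avg <- if (inosine_average == "per_arm") {
      mean(c(ino1, ino2), na.rm = TRUE)
    } else {
      g <- 0; cov <- 0
      for (a in list(a1, a2)) {
        if (!is.na(a$editing_index)) {
          cov_a <- a$mean_coverage * a$n_adenosines
          g <- g + a$editing_index * cov_a
          cov <- cov + cov_a
        }
      }
      if (cov > 0) (g / cov) * (a1$n_adenosines + a2$n_adenosines) / 2 else NA_real_
    }
    if (is.nan(avg)) avg <- NA_real_
    out$avg_inosines[i] <- avg
    if (!is.na(avg)) {
      arm_lens <- c(structures$arm1_end[i] - structures$arm1_start[i],
                    structures$arm2_end[i] - structures$arm2_start[i])
      res <- residual_identity(structures$identity_pct[i], avg, arm_lens)
      out$residual_identity_pct[i] <- res
      out$unwound[i] <- structures$identity_pct[i] > unwound_threshold &
        res < unwound_threshold
    }
  }
  out
}

#' Filter structures by region expression on both arms
#'
#' A structure passes iff **both** arm FPKM values strictly exceed the
#' cutoff.
#'
#' @param summaries output of [structure_editing_summary()].
#' @param fpkm_cutoff expression cutoff (the reference analysis uses 0.01
#'   and 0.1).
#' @return the passing subset of `summaries`.
#' @export
expression_filter <- function(summaries, fpkm_cutoff = 0.01) {
  pass <- !is.na(summaries$fpkm1) & !is.na(summaries$fpkm2) &
    summaries$fpkm1 > fpkm_cutoff & summaries$fpkm2 > fpkm_cutoff
  out <- summaries[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}
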