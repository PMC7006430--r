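#' Exact single-proportion test for IDS depletion, in log space
#'
#' Tests whether inverted duplicated sequences (IDS) are depleted relative to
#' tandem duplicated sequences (TDS) under the null that both are equally
#' probable (IDS fraction 0.5). The default is the one-sided (depletion
#' direction) exact binomial lower tail, `P(X <= n_ids)` for
#' `X ~ Binomial(n_ids + n_tds, 0.5)`, computed by log-space summation so
#' that astronomically small tails (p well below 1e-300) are representable
#' through their log10. Above one million tail terms a normal approximation
#' with continuity correction is used; its log-p relative error there is
#' below 1%.
#'
#' @param n_ids,n_tds non-negative counts; their sum must be >= 1.
#' @param alternative `"less"` (depletion, default) or `"two.sided"`
#'   (twice the smaller tail, capped at 1).
#' @return an object of class `dsrna_proportion_test`: list with `n_ids`,
#'   `n_tds`, `fraction`, `log10_p`, `p_value` (0 when the double underflows),
#'   `p_display` (scientific notation, or `"< 1e-100"` below that bound),
#'   `alternative` and `method` ("exact" or "normal approximation").
#' @export
proportion_test <- function(n_ids, n_tds, alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(n_ids) == 1L, length(n_tds) == 1L,
            n_ids >= 0, n_tds >= 0,
            n_ids == round(n_ids), n_tds == round(n_tds))
  n <- n_ids + n_tds
  if (n < 1) stop("no duplicated sequences: both counts are zero", call. = FALSE)

  log_lower_tail <- function(k, n) {
    if (k >= n) return(0)
    if (k + 1 <= 1e6) {
      method <<- "exact"
      logsumexp(dbinom(0:k, n, 0.5, log = TRUE)) # natural log
    } else {
      method <<- "normal approximation"
      pnorm((k + 0.5 - n / 2) / sqrt(n / 4), log.p = TRUE)
    }
  }
  method <- "exact"
  if (alternative == "less") {
    ln_p <- log_lower_tail(n_ids, n)
  } else {
    k <- min(n_ids, n_tds)
    ln_p <- min(0, log(2) + log_lower_tail(k, n))
    if (n_ids == n_tds) ln_p <- 0 # both tails include the midpoint
  }
  log10_p <- ln_p / log(10)
  p <- 10^log10_p
  p_display <- if (log10_p < -100) "< 1e-100" else
    sprintf("%.3g", p)
  structure(list(n_ids = n_ids, n_tds = n_tds, fraction = n_ids / n,
                 log10_p = log10_p, p_value = p, p_display = p_display,
                 alternative = alternative, method = method),
            class = "dsrna_proportion_test")
}

#' @export
print.dsrna_proportion_test <- function(x, ...) {
  cat(sprintf(
    "Single proportion test (%s, %s)\n  IDS = %d, TDS = %d, fraction = %.4g\n  p = %s (log10 p = %.4g)\n",
    x$alternative, x$method, x$n_ids, x$n_tds, x$fraction, x$p_display,
    x$log10_p))
  invisible(x)
}

#' Depletion report over a census table
#'
#' Runs [proportion_test()] on the IDS/TDS hit counts of every
#' (length bin x identity bin) cell of a census table, plus a pooled row over
#' all cells. Cells with zero hits in both classes are flagged `no_data` and
#' carry no p-value.
#'
#' @param census_table a `census_table` (see [census()]), or a data frame
#'   with columns `class`, `length_bin`, `identity_bin`, `n_hits` (an
#'   optional `molecule` column is honoured).
#' @param alternative passed to [proportion_test()].
#' @return data frame with one row per cell (and per molecule if present)
#'   plus pooled rows: `molecule`, `length_bin`, `identity_bin`, `n_ids`,
#'   `n_tds`, `fraction`, `log10_p`, `p_display`, `no_data`.
#' @export
depletion_report <- function(census_table, alternative = "less") {
  df <- as.data.frame(census_table)
  stopifnot(all(c("class", "length_bin", "identity_bin", "n_hits") %in% names(df)))
  if (!"molecule" %in% names(df)) df$molecule <- "all"
  ids <- df[df$class == "IDS", ]
  tds <- df[df$class == "TDS", ]
  key <- function(d) paste(d$molecule, d$length_bin, d$identity_bin, sep = "\r")
  tds_n <- tds$n_hits[match(key(ids), key(tds))]
  tds_n[is.na(tds_n)] <- 0L
  cells <- data.frame(molecule = ids$molecule, length_bin = ids$length_bin,
                      identity_bin = ids$identity_bin,
                      n_ids = ids$n_hits, n_tds = tds_n,
                      stringsAsFactors = FALSE)
  # pooled row per molecule
  for (mol in unique(cells$molecule)) {
    sub <- cells[cells$molecule == mol, ]
    cells <- rbind(cells, data.frame(molecule = mol, length_bin = "all",
                                     identity_bin = "all",
                                     n_ids = sum(sub$n_ids),
                                     n_tds = sum(sub$n_tds),
                                     stringsAsFactors = FALSE))
  }
  out <- cells
  out$fraction <- NA_real_; out$log10_p <- NA_real_
  out$p_display <- NA_character_
  out$no_data <- out$n_ids + out$n_tds == 0
  for (i in seq_len(nrow(out))) {
    if (out$no_data[i]) next
    t <- proportion_test(out$n_ids[i], out$n_tds[i], alternative = alternative)
    out$fraction[i] <- t$fraction
    out$log10_p[i] <- t$log10_p
    out$p_display[i] <- t$p_display
  }
  rownames(out) <- NULL
  out
}
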