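profile_df <- function(pos, A, G, ref = "A", contig = "seq") {
  data.frame(contig = rep(contig, length(pos)), pos = pos,
             ref = rep(ref, length(pos)), A_count = A, G_count = G,
             stringsAsFactors = FALSE)
}

test_that("arm coverage and editing index follow the counting definitions", {
  p <- profile_df(c(10, 20), c(8, 9), c(2, 1))
  r <- arm_coverage_and_index(p, c(0, 100))
  expect_equal(r$mean_coverage, 10)
  expect_equal(r$editing_index, 3 / 20)
  expect_identical(r$n_adenosines, 2L)

  # all G zero: index 0
  expect_identical(arm_coverage_and_index(profile_df(1:5, 5:9, rep(0, 5)),
                                          c(0, 10))$editing_index, 0)

  # zero-coverage adenosines count in the denominators with weight 0
  pz <- profile_df(c(1, 2), c(10, 0), c(0, 0))
  rz <- arm_coverage_and_index(pz, c(0, 10))
  expect_equal(rz$mean_coverage, 5)
  expect_identical(rz$n_covered, 1L)

  # no adenosines: not applicable
  rn <- arm_coverage_and_index(profile_df(integer(), integer(), integer()),
                               c(0, 10))
  expect_true(is.na(rn$editing_index))
  expect_identical(rn$n_adenosines, 0L)
})

test_that("the editing index is the coverage-weighted mean of site levels", {
  set.seed(401)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    cov <- rpois(n, 20)
    g <- rbinom(n, cov, runif(1, 0, 0.3))
    p <- profile_df(seq_len(n), cov - g, g)
    r <- arm_coverage_and_index(p, c(0, n + 1))
    lv <- ifelse(cov > 0, g / cov, NA)
    w <- cov[cov > 0]
    expect_equal(r$editing_index,
                 sum(w * lv[cov > 0]) / sum(w), tolerance = 1e-12)
  }
})

test_that("FPKM/coverage conversion matches the published library and round-trips", {
  lib <- library_stats(1.343e9, 76, 5)
  expect_identical(lib$effective_length, 66)
  expect_equal(round(fpkm_to_coverage(1, lib), 2), 88.64)
  expect_identical(fpkm_to_coverage(0, lib), 0)
  expect_equal(fpkm_to_coverage(2, library_stats(1e9, 60, 5)), 100)
  # round trip to 10 significant digits
  for (x in c(0.01, 1, 88.64, 1234.5)) {
    expect_equal(coverage_to_fpkm(fpkm_to_coverage(x, lib), lib), x,
                 tolerance = 1e-10)
  }
  expect_error(library_stats(1e9, 10, 5), "effective")
})

test_that("residual identity applies the inosine correction with a floor", {
  expect_equal(residual_identity(98, 6, c(300, 300)), 96)
  expect_equal(residual_identity(97.5, 0, c(300, 300)), 97.5)
  r <- residual_identity(97.5, 9, c(300, 300))
  expect_equal(r, 94.5)
  expect_lt(r, 96) # unwound below the nearly-perfect threshold
  expect_identical(residual_identity(50, 1000, c(100, 100)), 0)
  # monotone non-increasing in the inosine load at fixed geometry
  loads <- seq(0, 20, by = 2)
  res <- vapply(loads, residual_identity, 0, identity_pct = 99,
                arm_lengths = c(200, 200))
  expect_true(all(diff(res) <= 0))
})

test_that("editing index is recovered across the coverage/rate grid", {
  s <- strrep("A", 1000)
  set.seed(402)
  for (cov in c(1, 10, 100)) {
    for (rate in c(0, 0.01, 0.1)) {
      p <- simulate_pileup(c(0, 1000), s, cov, rate)
      r <- arm_coverage_and_index(p, c(0, 1000))
      total <- sum(p$A_count + p$G_count)
      if (total == 0) {
        expect_true(is.na(r$editing_index))
      } else if (rate == 0) {
        expect_identical(r$editing_index, 0)
      } else {
        expect_lt(abs(r$editing_index - rate),
                  3 * sqrt(rate * (1 - rate) / total) + 1e-12)
      }
    }
  }
})

test_that("structure summaries combine arms into inosine and residual calls", {
  set.seed(403)
  s <- strrep("A", 2000)
  st <- data.frame(seq_id = "seq", arm1_start = 0L, arm1_end = 300L,
                   arm2_start = 700L, arm2_end = 1000L,
                   orientation = "inverted", identity_pct = 97.5,
                   aln_length = 300L, gap_bp = 400L, stringsAsFactors = FALSE)
  prof <- rbind(simulate_pileup(c(0, 300), s, 50, 0.03, contig = "seq"),
                simulate_pileup(c(700, 1000), s, 50, 0.03, contig = "seq"))
  lib <- library_stats(1.343e9, 76, 5)
  sm <- structure_editing_summary(st, prof, lib)
  # independent recomputation from the raw counts
  a1 <- prof[prof$pos < 300, ]; a2 <- prof[prof$pos >= 700, ]
  ino <- mean(c(sum(a1$G_count) / sum(a1$A_count + a1$G_count) * nrow(a1),
                sum(a2$G_count) / sum(a2$A_count + a2$G_count) * nrow(a2)))
  expect_equal(sm$avg_inosines, ino, tolerance = 1e-12)
  expect_equal(sm$residual_identity_pct, max(0, 97.5 - 100 * ino / 300),
               tolerance = 1e-12)
  expect_identical(sm$unwound, sm$residual_identity_pct < 96)
  expect_equal(sm$fpkm1, coverage_to_fpkm(mean(a1$A_count + a1$G_count), lib))

  # pooled inosine averaging variant stays close for balanced arms
  sm2 <- structure_editing_summary(st, prof, lib, inosine_average = "pooled")
  expect_equal(sm2$avg_inosines, ino, tolerance = 0.05 * ino)
})

test_that("the both-arms expression rule is strict and matches ground truth", {
  base <- data.frame(seq_id = "s", arm1_start = 0L, arm1_end = 10L,
                     arm2_start = 20L, arm2_end = 30L, identity_pct = 97,
                     stringsAsFactors = FALSE)
  sm <- rbind(base, base, base)
  sm$fpkm1 <- c(0.02, 0.15, 0.011)
  sm$fpkm2 <- c(0.005, 0.12, 0.011)
  expect_identical(nrow(expression_filter(sm, 0.01)), 2L)
  expect_identical(nrow(expression_filter(sm, 0.1)), 1L)
  # strict >: a value exactly at the cutoff fails the passing third row
  sm$fpkm2[3] <- 0.01
  expect_identical(nrow(expression_filter(sm, 0.01)), 1L)
  sm$fpkm1[3] <- 0.01
  expect_identical(nrow(expression_filter(sm, 0.01)), 1L)

  # synthetic cohort: pass set equals the ground-truth predicate
  set.seed(404)
  n <- 40
  cohort <- do.call(rbind, replicate(n, base, simplify = FALSE))
  cohort$fpkm1 <- 10^runif(n, -3, 0)
  cohort$fpkm2 <- 10^runif(n, -3, 0)
  truth <- cohort$fpkm1 > 0.01 & cohort$fpkm2 > 0.01
  expect_identical(nrow(expression_filter(cohort, 0.01)), sum(truth))
})
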