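test_that("repeat copies honour the substitution model", {
  fam0 <- repeat_family("ACGTACGTAC", divergence = 0)
  set.seed(1)
  expect_identical(generate_repeat_copy(fam0), fam0$consensus)

  # divergence 0.5 on a long consensus: observed mismatch fraction within
  # 3 binomial SD of 0.5
  set.seed(2)
  fam <- repeat_family(random_dna(10000), divergence = 0.5)
  copy <- generate_repeat_copy(fam)
  mm <- mean(strsplit(copy, "")[[1]] != strsplit(fam$consensus, "")[[1]])
  expect_lt(abs(mm - 0.5), 3 * sqrt(0.25 / 10000))

  # substitutions never keep the original base
  set.seed(3)
  fam1 <- repeat_family(strrep("A", 5000), divergence = 0.3)
  copy1 <- strsplit(generate_repeat_copy(fam1), "")[[1]]
  expect_false("A" %in% copy1[copy1 != "A"])
  expect_true(all(copy1 %in% c("A", "C", "G", "T")))
})

test_that("pairwise identity of two copies matches theory and an independent aligner", {
  set.seed(4)
  for (d in c(0.02, 0.05, 0.1)) {
    n <- 20000
    fam <- repeat_family(random_dna(n), divergence = d)
    c1 <- generate_repeat_copy(fam)
    c2 <- generate_repeat_copy(fam)
    obs <- 100 * mean(strsplit(c1, "")[[1]] == strsplit(c2, "")[[1]])
    p <- expected_copy_identity(d) / 100
    expect_lt(abs(obs / 100 - p), 3 * sqrt(p * (1 - p) / n))
    # independent oracle: global alignment identity (indel-free pair, so the
    # optimal global alignment is columnwise)
    pa <- Biostrings::pairwiseAlignment(substr(c1, 1, 2000), substr(c2, 1, 2000),
                                        type = "global")
    obs2k <- 100 * mean(strsplit(substr(c1, 1, 2000), "")[[1]] ==
                          strsplit(substr(c2, 1, 2000), "")[[1]])
    expect_equal(Biostrings::pid(pa, type = "PID1"), obs2k, tolerance = 1e-8)
  }
})

test_that("repeat_family validates its invariants", {
  expect_error(repeat_family("", divergence = 0.1), "non-empty|alphabet")
  expect_error(repeat_family("ACGN"), "alphabet")
  expect_error(repeat_family("ACGT", divergence = 0.6), "divergence")
})

test_that("transcriptome generation honours orientation, identity and emptiness", {
  expect_length(generate_transcriptome(sim_config(0))$transcripts, 0)
  expect_identical(nrow(generate_transcriptome(sim_config(0))$truth), 0L)

  # all inverted at zero divergence
  cfg <- sim_config(n_genes = 10, rng_seed = 11, insertion_rate = 2,
                    orientation_prob = 1, divergence = 0)
  tx <- generate_transcriptome(cfg)
  expect_gt(nrow(tx$truth), 0)
  expect_true(all(tx$truth$orientation == "inverted"))
  expect_true(all(tx$truth$true_identity == 100))

  # 50/50 orientation: inverted count within 3 binomial SD of half
  cfg2 <- sim_config(n_genes = 100, rng_seed = 12, insertion_rate = 2)
  tx2 <- generate_transcriptome(cfg2)
  n <- nrow(tx2$truth)
  n_inv <- sum(tx2$truth$orientation == "inverted")
  expect_lt(abs(n_inv - n / 2), 3 * sqrt(n * 0.25))
})

test_that("generation is deterministic and writes byte-identical outputs", {
  cfg <- sim_config(n_genes = 5, rng_seed = 42, insertion_rate = 1.5)
  tx1 <- generate_transcriptome(cfg)
  tx2 <- generate_transcriptome(cfg)
  expect_identical(tx1$truth, tx2$truth)
  expect_identical(lapply(tx1$transcripts, `[[`, "seq"),
                   lapply(tx2$transcripts, `[[`, "seq"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_transcriptome(tx1, d1)
  p2 <- write_transcriptome(tx2, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("compartment bookkeeping matches exon coverage of the arms", {
  cfg <- sim_config(n_genes = 40, rng_seed = 13, insertion_rate = 2)
  tx <- generate_transcriptome(cfg)
  truth <- tx$truth
  expect_gt(nrow(truth), 0)
  for (i in seq_len(nrow(truth))) {
    ex <- tx$transcripts[[truth$gene_id[i]]]$exons
    covered <- rep(FALSE, nchar(tx$transcripts[[truth$gene_id[i]]]$seq))
    for (j in seq_len(nrow(ex))) {
      if (ex$end[j] > ex$start[j]) covered[(ex$start[j] + 1):ex$end[j]] <- TRUE
    }
    in_ex <- function(a, b) all(covered[(a + 1):b])
    both <- in_ex(truth$arm1_start[i], truth$arm1_end[i]) &&
      in_ex(truth$arm2_start[i], truth$arm2_end[i])
    expect_identical(truth$compartment[i],
                     if (both) "both-arms-exonic" else "at-least-one-arm-intronic")
  }
})

test_that("simulated pileups have the configured coverage and editing rate", {
  s <- paste0(strrep("A", 500), strrep("C", 100))
  set.seed(21)
  # editing_rate 0: all G-counts zero, index 0
  p0 <- simulate_pileup(c(0, 600), s, mean_coverage = 30, editing_rate = 0)
  expect_identical(nrow(p0), 500L)
  expect_true(all(p0$G_count == 0))
  expect_identical(arm_coverage_and_index(p0, c(0, 600))$editing_index, 0)

  # zero coverage: region unexpressed
  pz <- simulate_pileup(c(0, 600), s, mean_coverage = 0, editing_rate = 0.5)
  expect_true(all(pz$A_count + pz$G_count == 0))
  expect_true(is.na(arm_coverage_and_index(pz, c(0, 600))$editing_index))
  expect_identical(arm_coverage_and_index(pz, c(0, 600))$mean_coverage, 0)

  # rate 0.1 at coverage 50 over 1000 adenosines: recovered index within 3 SD
  s2 <- strrep("A", 1000)
  set.seed(22)
  p <- simulate_pileup(c(0, 1000), s2, mean_coverage = 50, editing_rate = 0.1)
  res <- arm_coverage_and_index(p, c(0, 1000))
  total_cov <- sum(p$A_count + p$G_count)
  expect_lt(abs(res$editing_index - 0.1), 3 * sqrt(0.1 * 0.9 / total_cov))

  # only adenosines are profiled
  expect_true(all(p0$ref == "A"))
  expect_true(all(p0$pos < 500))
})
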