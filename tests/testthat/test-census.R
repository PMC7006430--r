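test_that("splicing concatenates exons and maps coordinates bijectively", {
  set.seed(201)
  tr <- structure(list(gene_id = "g", seq = random_dna(400),
                       exons = data.frame(start = c(0L, 200L),
                                          end = c(100L, 300L))),
                  class = "transcript")
  sp <- splice_mrna(tr)
  expect_identical(nchar(sp$mrna), 200L)
  expect_identical(sp$pre_to_mrna[200 + 1], 100L) # pre position 200 -> mRNA 100
  expect_identical(sp$mrna_to_pre[100 + 1], 200L)
  expect_identical(sp$mrna,
                   paste0(substr(tr$seq, 1, 100), substr(tr$seq, 201, 300)))
  # bijection on exonic positions
  exonic <- which(!is.na(sp$pre_to_mrna)) - 1L
  expect_identical(sp$mrna_to_pre[sp$pre_to_mrna[exonic + 1L] + 1L], exonic)

  # single exon spanning the whole sequence: identity map
  tr2 <- structure(list(gene_id = "g2", seq = tr$seq,
                        exons = data.frame(start = 0L, end = 400L)),
                   class = "transcript")
  expect_identical(splice_mrna(tr2)$mrna, tr$seq)

  tr3 <- structure(list(gene_id = "g3", seq = tr$seq,
                        exons = data.frame(start = integer(), end = integer())),
                   class = "transcript")
  expect_error(splice_mrna(tr3), "no exons")
})

test_that("a duplex with an intronic arm disappears after splicing", {
  set.seed(202)
  core <- random_dna(120)
  exon1 <- random_dna(300)
  intron <- paste0(random_dna(100), revcomp(core), random_dna(100))
  exon2 <- paste0(random_dna(50), core, random_dna(150))
  pre <- paste0(exon1, intron, exon2)
  tr <- structure(list(gene_id = "g", seq = pre,
                       exons = data.frame(start = c(0L, 300L + nchar(intron)),
                                          end = c(300L, nchar(pre)))),
                  class = "transcript")
  h_pre <- self_align(tr$seq)
  expect_identical(nrow(h_pre[h_pre$strand == "opposite", ]), 1L)
  h_mrna <- self_align(splice_mrna(tr)$mrna)
  expect_identical(nrow(h_mrna), 0L)
})

test_that("interval merging matches a per-base set oracle, book-ends included", {
  h <- rbind(make_hit(100, 200, 150, 250), make_hit(100, 200, 200, 300))
  r <- merge_to_regions(h[1, ], "IDS")
  expect_identical(r$merged$start, 100L)
  expect_identical(r$merged$end, 250L)
  expect_identical(region_bp(r), 150L)

  # book-ended arms merge into one region
  r2 <- merge_to_regions(h[2, ], "TDS")
  expect_identical(nrow(r2$merged), 1L)
  expect_identical(c(r2$merged$start, r2$merged$end), c(100L, 300L))

  # property: merged footprint equals the brute-force base-set union
  set.seed(203)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    starts <- sort(sample(0:500, 2 * n))
    hh <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_hit(starts[2 * i - 1], starts[2 * i - 1] + sample(10:80, 1),
               starts[2 * i], starts[2 * i] + sample(10:80, 1),
               identity = runif(1, 71, 100))
    }))
    hh$aln_length <- as.integer(hh$q_end - hh$q_start)
    rr <- merge_to_regions(hh, "IDS")
    expect_identical(region_bp(rr), length(footprint_bases(hh)))
    # attribution covers exactly the merged footprint, once
    expect_identical(sum(rr$attribution$end - rr$attribution$start),
                     as.integer(region_bp(rr)))
  }
})

test_that("nucleotides are attributed to the longest covering hit", {
  # a 60 bp 98% hit inside a 300 bp 85% hit: all shared bases go to the long hit
  long <- make_hit(0, 300, 1000, 1300, identity = 85)
  short <- make_hit(100, 160, 1100, 1160, identity = 98)
  r <- merge_to_regions(rbind(long, short), "IDS")
  att <- r$attribution
  expect_true(all(att$aln_length == 300))
  expect_identical(sum(att$end - att$start), 600L)
  # tie on length: higher identity wins
  a <- make_hit(0, 100, 500, 600, identity = 90)
  b <- make_hit(50, 150, 700, 800, identity = 95)
  r2 <- merge_to_regions(rbind(a, b), "IDS")
  att2 <- r2$attribution
  claimed_95 <- att2[att2$identity_pct == 95, ]
  expect_true(any(claimed_95$start <= 50 & claimed_95$end >= 100))
})

test_that("census bins partition the footprint and respect monotonicity", {
  ids <- make_hit(0, 350, 500, 850, identity = 97)
  ids$aln_length <- 350L
  cen <- census(merge_to_regions(ids, "IDS"),
                merge_to_regions(ids[0, ], "TDS"))
  top <- cen[cen$class == "IDS" & cen$length_bin == "(300,Inf]" &
               cen$identity_bin == "(96,100]", ]
  expect_identical(top$bp, 700)
  expect_identical(top$n_hits, 1L)
  expect_identical(sum(cen$bp[cen$class == "IDS"]), 700)
  expect_identical(sum(cen$bp[cen$class == "TDS"]), 0)

  expect_error(census(merge_to_regions(ids, "IDS"),
                      merge_to_regions(ids[0, ], "TDS"),
                      length_bins = c(100, Inf)), "length_bins")
  expect_error(census(merge_to_regions(ids, "IDS"),
                      merge_to_regions(ids[0, ], "TDS"),
                      identity_bins = c(50, 100)), "identity_bins")

  # tightening the length threshold never increases any census cell: a
  # nucleotide's attributed (longest) hit is removed only together with
  # every other hit covering it, so no re-attribution occurs
  set.seed(204)
  hh <- do.call(rbind, lapply(1:15, function(i) {
    st <- sample(0:2000, 2)
    make_hit(min(st), min(st) + sample(41:400, 1),
             max(st) + 500, max(st) + 500 + sample(41:400, 1),
             identity = runif(1, 71, 100))
  }))
  hh$aln_length <- as.integer(hh$q_end - hh$q_start)
  loose <- census(merge_to_regions(hh, "IDS"), merge_to_regions(hh[0, ], "TDS"))
  tight <- census(merge_to_regions(hh[hh$aln_length > 100, ], "IDS"),
                  merge_to_regions(hh[0, ], "TDS"))
  expect_true(all(tight$bp <= loose$bp))
  expect_true(all(tight$n_hits <= loose$n_hits))
  # tightening identity can re-attribute bases between cells, but totals and
  # per-cell hit counts stay monotone
  tight_id <- census(merge_to_regions(hh[hh$identity_pct > 90, ], "IDS"),
                     merge_to_regions(hh[0, ], "TDS"))
  expect_lte(sum(tight_id$bp), sum(loose$bp))
  expect_true(all(tight_id$n_hits <= loose$n_hits))
})

test_that("structure selection enforces strict thresholds and overlap dedup", {
  h <- rbind(make_hit(0, 300, 400, 700, identity = 99),     # length 300: out
             make_hit(0, 301, 400, 701, identity = 96),     # identity 96: out
             make_hit(0, 301, 400, 701, identity = 96.1),   # in
             make_hit(1000, 1400, 1600, 2000, identity = 97),
             make_hit(1100, 1500, 1700, 2100, identity = 99))
  h$aln_length <- as.integer(h$q_end - h$q_start)
  s <- select_structures(h)
  expect_identical(nrow(s), 2L)
  # overlapping 97 vs 99: only the 99 retained
  expect_setequal(s$identity_pct, c(96.1, 99))
  expect_identical(s$orientation, c("inverted", "inverted"))
  expect_identical(s$gap_bp, pmax(0L, s$arm2_start - s$arm1_end))
})

test_that("repeat overlap fractions distinguish missing from empty annotation", {
  r <- merge_to_regions(make_hit(0, 50, 50, 100), "IDS")
  ann <- data.frame(seq_id = "seq", start = 50L, end = 150L)
  res <- repeat_overlap_fraction(r, ann)
  expect_identical(res$overlapping_bp, 50L)
  expect_identical(res$total_bp, 100L)
  expect_identical(res$fraction, 0.5)

  empty <- repeat_overlap_fraction(r, ann[0, ])
  expect_true(empty$no_repeats_annotated)
  expect_identical(empty$overlapping_bp, 0L)
  expect_identical(empty$fraction, 0)

  missing <- repeat_overlap_fraction(r, NULL)
  expect_false(missing$available)
  expect_true(is.na(missing$fraction))

  # synthetic truth as annotation: planted footprint fully covered
  set.seed(205)
  cfg <- sim_config(n_genes = 6, rng_seed = 205, insertion_rate = 2,
                    orientation_prob = 1, divergence = 0)
  tx <- generate_transcriptome(cfg)
  hits <- scan_transcripts(tx$transcripts, molecules = "pre_mrna")
  ids <- classify_and_gap_filter(hits)$ids
  # restrict hits to the planted arms so footprint == truth footprint
  truth_bed <- with(tx$truth, data.frame(
    seq_id = rep(gene_id, 2), start = c(arm1_start, arm2_start),
    end = c(arm1_end, arm2_end)))
  clipped <- ids
  for (i in seq_len(nrow(clipped))) {
    tr_g <- tx$truth[tx$truth$gene_id == clipped$seq_id[i], ]
    j <- which.max(interval_overlap(clipped$q_start[i], clipped$q_end[i],
                                    tr_g$arm1_start, tr_g$arm1_end))
    clipped$q_start[i] <- max(clipped$q_start[i], tr_g$arm1_start[j])
    clipped$q_end[i] <- min(clipped$q_end[i], tr_g$arm1_end[j])
    clipped$s_start[i] <- max(clipped$s_start[i], tr_g$arm2_start[j])
    clipped$s_end[i] <- min(clipped$s_end[i], tr_g$arm2_end[j])
  }
  rof <- repeat_overlap_fraction(merge_to_regions(clipped, "IDS"), truth_bed)
  expect_identical(rof$fraction, 1)
})
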