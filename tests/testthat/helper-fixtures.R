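# shared fixtures: planted-duplex constructs and truth matching

# a random sequence with one planted duplicated segment
# returns the sequence and the two arm intervals (0-based half-open)
plant_duplex <- function(core_len = 100, inverted = TRUE, flank = c(800, 500, 600),
                         divergence = 0) {
  core <- random_dna(core_len)
  copy2 <- if (divergence > 0) {
    generate_repeat_copy(repeat_family(core, divergence = divergence))
  } else core
  arm2 <- if (inverted) revcomp(copy2) else copy2
  seqs <- paste0(random_dna(flank[1]), core, random_dna(flank[2]), arm2,
                 random_dna(flank[3]))
  list(seq = seqs,
       arm1 = c(flank[1], flank[1] + core_len),
       arm2 = c(flank[1] + core_len + flank[2],
                flank[1] + core_len + flank[2] + core_len),
       true_identity = 100 * mean(strsplit(core, "")[[1]] ==
                                    strsplit(copy2, "")[[1]]))
}

interval_overlap <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

# match every truth row against a hit table; returns per-duplex logical
# recovery (correct orientation, >= 80% overlap of both arms) and the
# identity deviation of the best-matching hit
match_truth <- function(truth, hits, min_cov = 0.8) {
  recovered <- logical(nrow(truth))
  id_delta <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    want <- if (truth$orientation[i] == "inverted") "opposite" else "same"
    h <- hits[hits$seq_id == truth$gene_id[i] & hits$strand == want, ,
              drop = FALSE]
    if (nrow(h) == 0) next
    w1 <- truth$arm1_end[i] - truth$arm1_start[i]
    w2 <- truth$arm2_end[i] - truth$arm2_start[i]
    ok <- interval_overlap(h$q_start, h$q_end, truth$arm1_start[i],
                           truth$arm1_end[i]) >= min_cov * w1 &
      interval_overlap(h$s_start, h$s_end, truth$arm2_start[i],
                       truth$arm2_end[i]) >= min_cov * w2
    if (any(ok)) {
      recovered[i] <- TRUE
      id_delta[i] <- min(abs(h$identity_pct[ok] - truth$true_identity[i]))
    }
  }
  data.frame(recovered = recovered, id_delta = id_delta)
}

# brute-force per-base footprint of a hit table (union of all arm intervals)
footprint_bases <- function(hits) {
  if (nrow(hits) == 0) return(integer())
  unique(unlist(lapply(seq_len(nrow(hits)), function(i) {
    c(if (hits$q_end[i] > hits$q_start[i]) hits$q_start[i]:(hits$q_end[i] - 1L),
      if (hits$s_end[i] > hits$s_start[i]) hits$s_start[i]:(hits$s_end[i] - 1L))
  })))
}

make_hit <- function(q_start, q_end, s_start, s_end, strand = "opposite",
                     identity = 100, seq_id = "seq") {
  data.frame(seq_id = seq_id, q_start = as.integer(q_start),
             q_end = as.integer(q_end), s_start = as.integer(s_start),
             s_end = as.integer(s_end), strand = strand,
             identity_pct = identity,
             aln_length = as.integer(q_end - q_start),
             stringsAsFactors = FALSE)
}
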