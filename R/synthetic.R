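#' Repeat family
#'
#' A mobile-element-like repeat: a consensus sequence from which mutated
#' copies are drawn. Pairs of copies of one family inserted into a gene in
#' opposite orientation are the canonical source of intramolecular dsRNA
#' stems (inverted duplicated sequences); same-orientation pairs give the
#' tandem control.
#'
#' @param consensus nucleotide string over A/C/G/T (non-empty).
#' @param name label for the family.
#' @param divergence per-base substitution probability applied independently
#'   to every copy, in \[0, 0.5\]. A substitution replaces the base with a
#'   uniformly chosen different base.
#' @return an object of class `repeat_family`.
#' @export
repeat_family <- function(consensus, name = "repeat", divergence = 0.05) {
  stopifnot(is.character(consensus), length(consensus) == 1L)
  if (nchar(consensus) == 0) {
    stop("repeat consensus must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", consensus)) {
    stop("repeat consensus must be over the alphabet {A,C,G,T}", call. = FALSE)
  }
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.5) {
    stop("divergence must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(consensus = consensus, name = name, divergence = divergence),
            class = "repeat_family")
}

#' Draw one mutated copy of a repeat family
#'
#' Each consensus base is substituted independently with probability
#' `family$divergence`; a substitution always changes the base (uniform over
#' the three alternatives). Indels are never introduced, so the per-column
#' identity between any two copies is exact ground truth.
#'
#' Uses the current RNG stream; seed it with [set.seed()] for reproducibility.
#'
#' @param family a [repeat_family()].
#' @return nucleotide string of the same length as the consensus.
#' @export
generate_repeat_copy <- function(family) {
  stopifnot(inherits(family, "repeat_family"))
  chars <- strsplit(family$consensus, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hit <- runif(n) < family$divergence
  if (any(hit)) {
    idx <- match(chars[hit], BASES)
    # offset 1..3 cycles to a different base
    off <- sample.int(3L, sum(hit), replace = TRUE)
    chars[hit] <- BASES[((idx - 1L + off) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

#' Expected pairwise identity of two independent copies
#'
#' Two copies drawn at per-base substitution rate `d` agree at a column with
#' probability `(1 - d)^2 + d^2/3` (both unmutated, or both mutated to the
#' same alternative base).
#'
#' @param divergence per-base substitution probability.
#' @return expected percent identity between two copies.
#' @export
expected_copy_identity <- function(divergence) {
  100 * ((1 - divergence)^2 + divergence^2 / 3)
}

#' Simulation configuration for synthetic transcriptomes
#'
#' Defines gene architecture (alternating exons and introns), the planted
#' duplex regime (insertion rate, orientation mix, arm length and divergence
#' ranges), and the RNG seed. Defaults emulate compact vertebrate-like gene
#' models at desk scale: exons of a few hundred bp, introns around a kilobase,
#' Alu-sized (~300 bp) repeat arms.
#'
#' @param n_genes number of genes to generate.
#' @param rng_seed integer seed; the run stream and per-gene sub-streams
#'   (stable hash of gene id) derive from it.
#' @param n_exons sampler `function(n)` for exon counts per gene (>= 1).
#' @param exon_len,intron_len samplers `function(n)` for segment lengths
#'   (positive integers).
#' @param insertion_rate mean number of planted duplex pairs per gene
#'   (Poisson).
#' @param orientation_prob probability that a planted pair is inverted
#'   (vs tandem).
#' @param divergence per-base substitution rate for repeat copies; a scalar,
#'   or a length-2 range sampled uniformly per insertion.
#' @param arm_length_range integer range for arm lengths when insertions use
#'   private (per-insertion) random consensus sequences.
#' @param families optional list of [repeat_family()] objects; if supplied,
#'   each insertion draws a family uniformly and uses its consensus and
#'   divergence instead of a private random element.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       rng_seed = 1L,
                       n_exons = function(n) 2L + rpois(n, 3),
                       exon_len = function(n) 80L + rpois(n, 120),
                       intron_len = function(n) 300L + rpois(n, 700),
                       insertion_rate = 1,
                       orientation_prob = 0.5,
                       divergence = c(0, 0.079),
                       arm_length_range = c(60L, 500L),
                       families = NULL) {
  stopifnot(n_genes >= 0, insertion_rate >= 0,
            orientation_prob >= 0, orientation_prob <= 1,
            all(divergence >= 0), all(divergence <= 0.5),
            length(divergence) %in% c(1L, 2L),
            length(arm_length_range) == 2L, arm_length_range[1] >= 1,
            arm_length_range[2] >= arm_length_range[1])
  if (!is.null(families)) {
    stopifnot(is.list(families),
              all(vapply(families, inherits, TRUE, "repeat_family")))
  }
  structure(list(n_genes = as.integer(n_genes), rng_seed = as.integer(rng_seed),
                 n_exons = n_exons, exon_len = exon_len,
                 intron_len = intron_len, insertion_rate = insertion_rate,
                 orientation_prob = orientation_prob, divergence = divergence,
                 arm_length_range = as.integer(arm_length_range),
                 families = families),
            class = "sim_config")
}

# insert `arm` at inter-base position p of a gene under construction,
# shifting segments and previously planted arm intervals; the arm joins the
# segment whose bases it lands among (boundary positions join the segment
# starting there; the gene end joins the last segment)
insert_arm <- function(gene, arm, p) {
  len <- nchar(arm)
  seg <- gene$segments
  # segment receiving the insertion
  k <- which(seg$start < p & p < seg$end)
  if (length(k) == 0L) {
    k <- which(seg$start == p)
    if (length(k) == 0L) k <- nrow(seg) # p == gene length
  }
  k <- k[1L]
  gene$seq <- paste0(substr(gene$seq, 1L, p), arm,
                     substr(gene$seq, p + 1L, nchar(gene$seq)))
  seg$end[k] <- seg$end[k] + len
  if (k < nrow(seg)) {
    shift <- seq(k + 1L, nrow(seg))
    seg$start[shift] <- seg$start[shift] + len
    seg$end[shift] <- seg$end[shift] + len
  }
  gene$segments <- seg
  if (length(gene$arms)) {
    gene$arms <- lapply(gene$arms, function(iv) {
      if (iv[1] >= p) iv + len else iv
    })
  }
  gene$arms <- c(gene$arms, list(c(p, p + len)))
  gene
}

# TRUE if inserting at p would split an existing planted arm
splits_arm <- function(gene, p) {
  any(vapply(gene$arms, function(iv) iv[1] < p && p < iv[2], TRUE))
}

#' Generate a synthetic transcriptome with planted duplexes
#'
#' Builds `n_genes` gene models of alternating exons and introns filled with
#' uniform random sequence, then plants pairs of repeat copies in inverted or
#' tandem orientation at uniformly drawn inter-base positions (placements
#' that would split a previously planted arm are redrawn). Every insertion is
#' recorded with its final coordinates, orientation, exact arm-pair identity,
#' and splicing compartment.
#'
#' Deterministic for a fixed `rng_seed`: each gene uses an RNG sub-stream
#' derived by stable hashing of its id, so results do not depend on
#' generation order.
#'
#' @param config a [sim_config()].
#' @return a list with elements `transcripts` (list of `transcript` objects:
#'   `gene_id`, `seq`, `exons` data frame with 0-based half-open `start`/`end`)
#'   and `truth` (data frame: gene_id, arm1_start/end, arm2_start/end,
#'   orientation, true_identity, compartment, arm_length).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  transcripts <- vector("list", config$n_genes)
  truth <- list()
  if (config$n_genes > 0) {
    ids <- sprintf("gene%05d", seq_len(config$n_genes))
    for (g in seq_len(config$n_genes)) {
      set.seed(stable_seed(ids[g], config$rng_seed))
      built <- build_gene(ids[g], config)
      transcripts[[g]] <- built$transcript
      if (nrow(built$truth)) truth[[length(truth) + 1L]] <- built$truth
    }
    names(transcripts) <- ids
  }
  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  rownames(truth) <- NULL
  list(transcripts = transcripts, truth = truth)
}

empty_truth <- function() {
  data.frame(gene_id = character(), arm1_start = integer(), arm1_end = integer(),
             arm2_start = integer(), arm2_end = integer(),
             orientation = character(), true_identity = numeric(),
             compartment = character(), arm_length = integer(),
             stringsAsFactors = FALSE)
}

build_gene <- function(gene_id, config) {
  n_ex <- max(1L, as.integer(config$n_exons(1L)))
  ex_lens <- pmax(1L, as.integer(config$exon_len(n_ex)))
  in_lens <- if (n_ex > 1L) pmax(1L, as.integer(config$intron_len(n_ex - 1L))) else integer()
  types <- character(2L * n_ex - 1L)
  lens <- integer(2L * n_ex - 1L)
  types[seq(1L, length(types), by = 2L)] <- "exon"
  lens[seq(1L, length(types), by = 2L)] <- ex_lens
  if (n_ex > 1L) {
    types[seq(2L, length(types), by = 2L)] <- "intron"
    lens[seq(2L, length(types), by = 2L)] <- in_lens
  }
  ends <- cumsum(lens)
  segments <- data.frame(start = c(0L, ends[-length(ends)]), end = ends,
                         type = types, stringsAsFactors = FALSE)
  gene <- list(seq = random_dna(sum(lens)), segments = segments, arms = list())

  n_ins <- rpois(1L, config$insertion_rate)
  recs <- vector("list", n_ins)
  planted <- list() # per insertion: arm index pair into gene$arms
  for (k in seq_len(n_ins)) {
    if (!is.null(config$families)) {
      fam <- config$families[[sample.int(length(config$families), 1L)]]
    } else {
      div <- if (length(config$divergence) == 2L) {
        runif(1L, config$divergence[1], config$divergence[2])
      } else config$divergence
      arm_len <- sample(seq(config$arm_length_range[1],
                            config$arm_length_range[2]), 1L)
      fam <- repeat_family(random_dna(arm_len), sprintf("%s_ins%d", gene_id, k),
                           divergence = div)
    }
    copy1 <- generate_repeat_copy(fam)
    copy2 <- generate_repeat_copy(fam)
    c1 <- strsplit(copy1, "")[[1]]
    c2 <- strsplit(copy2, "")[[1]]
    true_identity <- 100 * mean(c1 == c2)
    inverted <- runif(1L) < config$orientation_prob
    arm2_seq <- if (inverted) revcomp(copy2) else copy2

    p1 <- draw_position(gene)
    gene <- insert_arm(gene, copy1, p1)
    i1 <- length(gene$arms)
    p2 <- draw_position(gene)
    gene <- insert_arm(gene, arm2_seq, p2)
    i2 <- length(gene$arms)

    planted[[k]] <- c(i1, i2)
    recs[[k]] <- list(orientation = if (inverted) "inverted" else "tandem",
                      true_identity = true_identity,
                      arm_length = nchar(copy1))
  }

  exons <- gene$segments[gene$segments$type == "exon", c("start", "end")]
  rownames(exons) <- NULL
  tr <- structure(list(gene_id = gene_id, seq = gene$seq, exons = exons),
                  class = "transcript")

  truth <- empty_truth()
  for (k in seq_len(n_ins)) {
    a1 <- gene$arms[[planted[[k]][1]]]
    a2 <- gene$arms[[planted[[k]][2]]]
    if (a1[1] > a2[1]) { tmp <- a1; a1 <- a2; a2 <- tmp }
    compartment <- if (arm_in_exons(a1, exons) && arm_in_exons(a2, exons)) {
      "both-arms-exonic"
    } else "at-least-one-arm-intronic"
    truth <- rbind(truth, data.frame(
      gene_id = gene_id, arm1_start = a1[1], arm1_end = a1[2],
      arm2_start = a2[1], arm2_end = a2[2],
      orientation = recs[[k]]$orientation,
      true_identity = recs[[k]]$true_identity,
      compartment = compartment,
      arm_length = recs[[k]]$arm_length, stringsAsFactors = FALSE))
  }
  list(transcript = tr, truth = truth)
}

draw_position <- function(gene, max_tries = 1000L) {
  L <- nchar(gene$seq)
  for (i in seq_len(max_tries)) {
    p <- sample(0:L, 1L)
    if (!splits_arm(gene, p)) return(p)
  }
  stop("could not place insertion without splitting an existing planted arm; ",
       "the configured insertions do not fit in the generated genes",
       call. = FALSE)
}

# is the interval fully covered by the exon set? exons are disjoint and
# separated by introns, so coverage means containment in a single exon
arm_in_exons <- function(iv, exons) {
  any(exons$start <= iv[1] & iv[2] <= exons$end)
}

#' Simulate a per-adenosine read pileup
#'
#' For every adenosine of `sequence` inside `region`, draws a coverage from
#' Poisson(`mean_coverage`) and an A-to-G mismatch count from
#' Binomial(coverage, `editing_rate`). This is the direct synthetic stand-in
#' for an mpileup-derived A/G count table over a dsRNA arm.
#'
#' Uses the current RNG stream; seed it with [set.seed()] for reproducibility.
#'
#' @param region integer vector `c(start, end)`, 0-based half-open, within
#'   the sequence.
#' @param sequence nucleotide string (transcript orientation; adenosines are
#'   `A` characters).
#' @param mean_coverage mean reads per adenosine (>= 0).
#' @param editing_rate per-adenosine probability that a read shows G, in
#'   \[0, 1\].
#' @param contig contig name recorded in the profile.
#' @return an editing profile data frame: `contig`, `pos` (0-based), `ref`,
#'   `A_count`, `G_count`.
#' @export
simulate_pileup <- function(region, sequence, mean_coverage, editing_rate,
                            contig = "seq") {
  stopifnot(length(region) == 2L, region[1] >= 0, region[2] <= nchar(sequence),
            mean_coverage >= 0, editing_rate >= 0, editing_rate <= 1)
  chars <- strsplit(substr(sequence, region[1] + 1L, region[2]), "")[[1]]
  pos <- region[1] + which(chars == "A") - 1L
  n <- length(pos)
  cov <- if (n) rpois(n, mean_coverage) else integer()
  g <- if (n) rbinom(n, cov, editing_rate) else integer()
  data.frame(contig = rep(contig, n), pos = as.integer(pos), ref = rep("A", n),
             A_count = as.integer(cov - g), G_count = as.integer(g),
             stringsAsFactors = FALSE)
}
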