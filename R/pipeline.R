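#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Either a synthetic
#' transcriptome is generated (`simulate` is a [sim_config()]) or an existing
#' one is loaded (`fasta` + `exon_bed`).
#'
#' @param out_dir output directory.
#' @param simulate a [sim_config()], or `NULL` to load inputs from disk.
#' @param fasta,exon_bed pre-mRNA FASTA and exon BED paths (used when
#'   `simulate` is `NULL`).
#' @param hits_tsv optional externally produced 12-column tabular alignment
#'   file; when given it replaces the internal aligner for the pre-mRNA scan.
#' @param repeat_bed optional repeat annotation BED.
#' @param pileup optional pileup TSV for the editing stage; for a simulated
#'   run with `simulate_editing = TRUE` pileups are simulated instead.
#' @param filter a [hit_filter()].
#' @param structure_min_length,structure_min_identity thresholds for
#'   [select_structures()].
#' @param lib a [library_stats()] for FPKM conversion.
#' @param fpkm_cutoff expression cutoff for [expression_filter()].
#' @param simulate_editing simulate pileups over selected structures
#'   (synthetic runs only).
#' @param sim_coverage,sim_editing_rate pileup simulation parameters.
#' @param rng_seed seed for the pileup simulation stage.
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       simulate = NULL,
                       fasta = NULL, exon_bed = NULL,
                       hits_tsv = NULL, repeat_bed = NULL, pileup = NULL,
                       filter = hit_filter(),
                       structure_min_length = 300,
                       structure_min_identity = 96,
                       lib = library_stats(1.343e9, 76, 5),
                       fpkm_cutoff = 0.01,
                       simulate_editing = !is.null(simulate),
                       sim_coverage = 50, sim_editing_rate = 0.05,
                       rng_seed = 1L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(simulate)) {
    if (is.null(fasta) || is.null(exon_bed)) {
      stop("config is missing required input: fasta and exon_bed must be set ",
           "when no simulation is configured", call. = FALSE)
    }
    for (p in c(fasta, exon_bed, hits_tsv, repeat_bed, pileup)) {
      if (!is.null(p) && !file.exists(p)) {
        stop("configured input path does not exist: ", p, call. = FALSE)
      }
    }
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  structure(list(out_dir = out_dir, simulate = simulate, fasta = fasta,
                 exon_bed = exon_bed, hits_tsv = hits_tsv,
                 repeat_bed = repeat_bed, pileup = pileup, filter = filter,
                 structure_min_length = structure_min_length,
                 structure_min_identity = structure_min_identity,
                 lib = lib, fpkm_cutoff = fpkm_cutoff,
                 simulate_editing = simulate_editing,
                 sim_coverage = sim_coverage,
                 sim_editing_rate = sim_editing_rate,
                 rng_seed = as.integer(rng_seed), log_level = log_level),
            class = "run_config")
}

pipe_log <- function(config, stage, msg) {
  if (config$log_level != "quiet") {
    message(sprintf("[dsrna:%s] %s", stage, msg))
  }
}

#' Run the full census pipeline
#'
#' Stages, in order: simulate (or load) the transcriptome; scan pre-mRNA and
#' mRNA by self-alignment (or import external hits); merge and census;
#' depletion statistics; structure selection; editing/expression summaries.
#' Every output file carries a coordinate-convention header comment, and a
#' manifest records inputs, parameters, seed and output checksums.
#' Re-running with an identical configuration reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the in-memory stage results and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  f <- config$filter
  pipe_log(config, "config",
           sprintf("filters: aln_length > %s, identity > %s%%, max_gap = %s",
                   f$min_length, f$min_identity, f$max_gap))
  pipe_log(config, "config",
           sprintf("structure thresholds: > %s bp, > %s%% identity; FPKM cutoff > %s",
                   config$structure_min_length, config$structure_min_identity,
                   config$fpkm_cutoff))

  # stage 1: transcriptome
  if (!is.null(config$simulate)) {
    pipe_log(config, "simulate",
             sprintf("generating %d genes (seed %d)",
                     config$simulate$n_genes, config$simulate$rng_seed))
    txome <- generate_transcriptome(config$simulate)
    paths <- write_transcriptome(txome, config$out_dir)
    outputs <- c(outputs, paths)
    transcripts <- txome$transcripts
  } else {
    pipe_log(config, "load", paste("reading", config$fasta))
    transcripts <- read_transcripts(config$fasta, config$exon_bed)
    txome <- list(transcripts = transcripts, truth = NULL)
  }

  # stage 2: scan
  if (!is.null(config$hits_tsv)) {
    pipe_log(config, "scan", paste("importing external hits from", config$hits_tsv))
    hits <- parse_tabular_hits(config$hits_tsv, f)
    hits$molecule <- "pre_mrna"
  } else {
    pipe_log(config, "scan", sprintf("self-aligning %d transcripts (pre-mRNA and mRNA)",
                                     length(transcripts)))
    hits <- scan_transcripts(transcripts, f)
  }
  parts <- classify_and_gap_filter(hits, f)
  hits_path <- file.path(config$out_dir, "hits.tsv")
  write_tsv(rbind(cbind(parts$ids, class = if (nrow(parts$ids)) "IDS" else character()),
                  cbind(parts$tds, class = if (nrow(parts$tds)) "TDS" else character())),
            hits_path)
  outputs <- c(outputs, hits = hits_path)

  # stage 3: census per molecule
  census_rows <- list(); region_beds <- character()
  for (mol in unique(c(hits$molecule, "pre_mrna"))) {
    ids_m <- parts$ids[parts$ids$molecule == mol, , drop = FALSE]
    tds_m <- parts$tds[parts$tds$molecule == mol, , drop = FALSE]
    ids_r <- merge_to_regions(ids_m, "IDS")
    tds_r <- merge_to_regions(tds_m, "TDS")
    cen <- census(ids_r, tds_r)
    cen$molecule <- mol
    census_rows[[mol]] <- cen
    for (r in list(ids_r, tds_r)) {
      if (nrow(r$merged)) {
        bed <- file.path(config$out_dir,
                         sprintf("regions_%s_%s.bed", mol, r$class_label))
        write_bed(r$merged, bed)
        region_beds <- c(region_beds, bed)
      }
    }
    if (!is.null(config$repeat_bed) && mol == "pre_mrna") {
      ann <- read_bed(config$repeat_bed)
      rof <- repeat_overlap_fraction(ids_r, ann)
      pipe_log(config, "census",
               sprintf("repeat overlap (IDS, pre-mRNA): %s/%s bp",
                       rof$overlapping_bp, rof$total_bp))
    }
  }
  census_table <- do.call(rbind, census_rows)
  rownames(census_table) <- NULL
  census_path <- file.path(config$out_dir, "census.tsv")
  write_tsv(census_table, census_path, coord_header = FALSE)
  outputs <- c(outputs, census = census_path, region_beds)

  # stage 4: depletion statistics
  depletion <- depletion_report(census_table)
  stats_path <- file.path(config$out_dir, "depletion.tsv")
  write_tsv(depletion, stats_path, coord_header = FALSE)
  outputs <- c(outputs, depletion = stats_path)

  # stage 5: structures + editing
  structures <- select_structures(hits, config$structure_min_length,
                                  config$structure_min_identity)
  struct_path <- file.path(config$out_dir, "structures.tsv")
  write_tsv(structures, struct_path)
  outputs <- c(outputs, structures = struct_path)

  summaries <- NULL
  profile <- NULL
  if (!is.null(config$pileup)) {
    profile <- read_pileup(config$pileup)
  } else if (config$simulate_editing && nrow(structures) > 0) {
    set.seed(config$rng_seed)
    profs <- list()
    for (i in seq_len(nrow(structures))) {
      tr <- transcripts[[structures$seq_id[i]]]
      seq_i <- if (!is.null(structures$molecule) &&
                   structures$molecule[i] == "mrna") {
        splice_mrna(tr)$mrna
      } else tr$seq
      for (arm in list(c(structures$arm1_start[i], structures$arm1_end[i]),
                       c(structures$arm2_start[i], structures$arm2_end[i]))) {
        profs[[length(profs) + 1L]] <-
          simulate_pileup(arm, seq_i, config$sim_coverage,
                          config$sim_editing_rate, contig = tr$gene_id)
      }
    }
    profile <- unique(do.call(rbind, profs))
  }
  if (!is.null(profile) && nrow(structures) > 0) {
    summaries <- structure_editing_summary(structures, profile, config$lib)
    edit_path <- file.path(config$out_dir, "editing.tsv")
    write_tsv(summaries, edit_path)
    outputs <- c(outputs, editing = edit_path)
    expressed <- expression_filter(summaries, config$fpkm_cutoff)
    pipe_log(config, "editing",
             sprintf("%d/%d structures expressed above FPKM %s on both arms",
                     nrow(expressed), nrow(summaries), config$fpkm_cutoff))
  }

  # manifest
  manifest <- list(
    package = "dsRNAcensus",
    version = as.character(utils::packageVersion("dsRNAcensus")),
    seed = if (!is.null(config$simulate)) config$simulate$rng_seed else config$rng_seed,
    parameters = list(min_length = f$min_length, min_identity = f$min_identity,
                      max_gap = f$max_gap,
                      structure_min_length = config$structure_min_length,
                      structure_min_identity = config$structure_min_identity,
                      fpkm_cutoff = config$fpkm_cutoff),
    inputs = Filter(Negate(is.null),
                    list(fasta = config$fasta, exon_bed = config$exon_bed,
                         hits_tsv = config$hits_tsv,
                         repeat_bed = config$repeat_bed,
                         pileup = config$pileup)),
    outputs = as.list(tools::md5sum(unname(outputs))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  pipe_log(config, "done", paste("manifest at", manifest_path))
  invisible(list(transcriptome = txome, hits = hits, classified = parts,
                 census = census_table, depletion = depletion,
                 structures = structures, summaries = summaries,
                 manifest_path = manifest_path))
}
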