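COORD_HEADER <- "# coordinates: 0-based, half-open"

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# write a data frame as TSV with the coordinate-convention header comment
write_tsv <- function(df, path, coord_header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (coord_header) writeLines(COORD_HEADER, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open)
#' @param df data frame with `seq_id`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(COORD_HEADER, con)
  cols <- data.frame(chrom = df$seq_id, start = df$start, end = df$end)
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(df)) cols[[extra]] <- df[[extra]] else break
  }
  write.table(cols, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open), skipping comment and track lines
#' @param path BED file.
#' @return data frame with `seq_id`, `start`, `end` (plus `name` if present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("BED rows need at least 3 columns", call. = FALSE)
  out <- data.frame(seq_id = vapply(f, `[`, "", 1L),
                    start = as.integer(vapply(f, `[`, "", 2L)),
                    end = as.integer(vapply(f, `[`, "", 3L)),
                    stringsAsFactors = FALSE)
  if (all(lengths(f) >= 4L)) out$name <- vapply(f, `[`, "", 4L)
  check_interval(out$start, out$end, "BED interval")
  out
}

#' Assemble transcripts from a FASTA and an exon BED
#'
#' The BED's chrom column must name the FASTA records; exon coordinates are
#' 0-based half-open positions on the pre-mRNA sequence.
#'
#' @param fasta_path pre-mRNA FASTA.
#' @param exon_bed_path exon BED.
#' @param max_length transcripts with a pre-mRNA longer than this are
#'   discarded, mirroring the 1 Mbp loader rule.
#' @return named list of `transcript` objects.
#' @export
read_transcripts <- function(fasta_path, exon_bed_path, max_length = 1e6) {
  seqs <- read_fasta(fasta_path)
  bed <- read_bed(exon_bed_path)
  keep <- nchar(seqs) <= max_length
  seqs <- seqs[keep]
  out <- lapply(names(seqs), function(id) {
    ex <- bed[bed$seq_id == id, c("start", "end"), drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    rownames(ex) <- NULL
    if (nrow(ex) == 0L) ex <- data.frame(start = 0L, end = nchar(seqs[[id]]))
    structure(list(gene_id = id, seq = unname(seqs[[id]]), exons = ex),
              class = "transcript")
  })
  setNames(out, names(seqs))
}

#' Write a synthetic transcriptome to disk
#'
#' Writes the pre-mRNA FASTA, the exon BED (0-based half-open) and the
#' planted-duplex truth TSV. Byte-identical across runs for a fixed
#' generator seed.
#'
#' @param transcriptome output of [generate_transcriptome()].
#' @param dir output directory (created if missing).
#' @return named character vector of the three paths.
#' @export
write_transcriptome <- function(transcriptome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "pre_mrna.fasta")
  bed <- file.path(dir, "exons.bed")
  truth <- file.path(dir, "truth.tsv")
  seqs <- vapply(transcriptome$transcripts, `[[`, "", "seq")
  names(seqs) <- vapply(transcriptome$transcripts, `[[`, "", "gene_id")
  write_fasta(seqs, fa)
  exons <- do.call(rbind, lapply(transcriptome$transcripts, function(tr) {
    data.frame(seq_id = tr$gene_id, start = tr$exons$start, end = tr$exons$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(exons)) {
    exons <- data.frame(seq_id = character(), start = integer(),
                        end = integer())
  }
  write_bed(exons, bed)
  write_tsv(transcriptome$truth, truth)
  c(fasta = fa, exon_bed = bed, truth = truth)
}

#' Read a per-adenosine pileup TSV
#'
#' Columns: contig, pos (0-based), ref, A_count, G_count; `#` comment lines
#' are skipped.
#'
#' @param path pileup TSV.
#' @return editing profile data frame.
#' @export
read_pileup <- function(path) {
  df <- read_tsv(path)
  need <- c("contig", "pos", "ref", "A_count", "G_count")
  if (!all(need %in% names(df))) {
    stop("pileup TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' Write a per-adenosine pileup TSV
#' @param profile editing profile data frame.
#' @param path output file.
#' @export
write_pileup <- function(profile, path) {
  write_tsv(profile, path)
}
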