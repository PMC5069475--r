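#' @title Annotation tables, FASTA IO, and sequence primitives
#' @name core_model
#' @description Readers and writers for the package's two external formats
#'   (a tab-separated feature table and multi-record FASTA) plus small
#'   sequence utilities shared by every analysis module.
NULL

FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "control_region")
STRANDS <- c("J", "N")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a mitochondrial genome annotation table
#'
#' Parses a TSV feature table with columns `name`, `kind`, `strand`,
#' coordinates, and optional `anticodon`, `start_codon`, `stop_codon`.
#' Coordinates may be given either as two columns `start`/`end` or as a
#' single `position` column written `start-end` (hyphen or en dash).
#' Truncated stop codons ("T-", "TA") are stored verbatim.
#'
#' @param path path to the TSV file.
#' @param circular is the genome circular? Default `TRUE`.
#' @return A `genome_annotation` object: list with `records` (data.frame in
#'   genome-position order), `circular`, and `genome_length` (max `end`).
#' @export
read_annotation_table <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               fill = TRUE, quote = "", comment.char = "#"),
    error = function(e) stop("failed to parse annotation table: ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("annotation table is empty: ", path)
  names(df) <- tolower(names(df))
  if (!all(c("name", "strand") %in% names(df)))
    stop("annotation table must have 'name' and 'strand' columns")
  if ("position" %in% names(df) && !all(c("start", "end") %in% names(df))) {
    parts <- strsplit(df$position, "–|−|-")
    bad <- which(vapply(parts, length, 1L) != 2L)
    if (length(bad))
      stop("malformed coordinate on line ", bad[1] + 1L, ": ",
           df$position[bad[1]])
    df$start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    df$end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  }
  if (!all(c("start", "end") %in% names(df)))
    stop("annotation table needs 'start'/'end' or a 'position' column")
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad))
    stop("malformed coordinate on line ", bad[1] + 1L,
         " (row '", df$name[bad[1]], "')")
  genome_annotation(df, circular = circular)
}

#' Construct a genome annotation from a records data frame
#'
#' @param records data.frame with at least `name`, `strand`, `start`, `end`;
#'   optional `kind`, `anticodon`, `start_codon`, `stop_codon`.
#' @param circular logical.
#' @return A validated `genome_annotation` (records sorted by `start`).
#' @export
genome_annotation <- function(records, circular = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("kind", "anticodon", "start_codon", "stop_codon"))
    if (!col %in% names(records)) records[[col]] <- NA_character_
  for (col in c("anticodon", "start_codon", "stop_codon")) {
    v <- trimws(as.character(records[[col]]))
    v[!nzchar(v) | is.na(v)] <- NA_character_
    records[[col]] <- v
  }
  if (anyNA(records$kind) || any(!nzchar(records$kind))) {
    guess <- ifelse(grepl("^tRNA", records$name), "tRNA",
             ifelse(grepl("^1[26]S", records$name), "rRNA",
             ifelse(grepl("control", records$name, ignore.case = TRUE),
                    "control_region", "PCG")))
    miss <- is.na(records$kind) | !nzchar(records$kind)
    records$kind[miss] <- guess[miss]
  }
  if (!all(records$kind %in% FEATURE_KINDS))
    stop("unknown feature kind: ",
         paste(setdiff(records$kind, FEATURE_KINDS), collapse = ", "))
  if (!all(records$strand %in% STRANDS))
    stop("strand must be 'J' or 'N', got: ",
         paste(setdiff(records$strand, STRANDS), collapse = ", "))
  if (any(records$start < 1L)) stop("coordinates must be >= 1")
  bad <- which(records$end < records$start)
  if (length(bad))
    stop("end < start for feature '", records$name[bad[1]],
         "' (", records$start[bad[1]], "-", records$end[bad[1]], ")")
  key <- paste(records$name, ifelse(is.na(records$anticodon), "",
                                    records$anticodon))
  if (anyDuplicated(key))
    stop("duplicate feature name (after anticodon qualification): ",
         key[anyDuplicated(key)])
  records <- records[order(records$start, records$end), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 circular = isTRUE(circular),
                 genome_length = max(records$end)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  kinds <- table(factor(x$records$kind, levels = FEATURE_KINDS))
  cat("genome_annotation: ", nrow(x$records), " features, ",
      x$genome_length, " bp",
      if (x$circular) " (circular)", "\n", sep = "")
  cat("  ", paste(names(kinds), as.integer(kinds), sep = ": ",
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a genome annotation back to TSV
#'
#' Inverse of [read_annotation_table()]; writing then re-reading yields
#' identical records.
#'
#' @param annotation a `genome_annotation`.
#' @param path output path.
#' @export
write_annotation_table <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  df <- annotation$records[, c("name", "kind", "strand", "start", "end",
                               "anticodon", "start_codon", "stop_codon")]
  df[is.na(df)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_dna <- function(seq, what = "sequence") {
  bad <- grepl(paste0("[^", paste(DNA_ALPHABET, collapse = ""), "]"), seq)
  if (any(bad))
    stop("non-nucleotide characters in ", what, " (allowed: A,C,G,T,N)")
  invisible(seq)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet.
#'
#' @param path FASTA path.
#' @return named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA file has no records: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  validate_dna(seqs, what = paste0("FASTA record(s) in ", path))
  seqs
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- toupper(seqs)
  validate_dna(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' An involution over the A/C/G/T/N alphabet; N maps to N. The empty string
#' maps to itself.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  validate_dna(seq)
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Extract a feature's sequence from the J-strand genome sequence
#'
#' N-strand features are returned as the reverse complement of the J-strand
#' slice, i.e. in coding orientation.
#'
#' @param genome_seq single J-strand genome string.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"J"` or `"N"`.
#' @return the feature sequence (coding strand).
#' @export
feature_seq <- function(genome_seq, start, end, strand = "J") {
  stopifnot(length(genome_seq) == 1L, strand %in% STRANDS)
  if (start < 1L || end > nchar(genome_seq) || end < start)
    stop("feature coordinates outside sequence: ", start, "-", end)
  s <- substr(genome_seq, start, end)
  if (strand == "N") s <- reverse_complement(s) else s
}
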