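#' @title Nucleotide composition, strand skew, and codon usage
#' @name composition
#' @description Base composition over the A/C/G/T alphabet (N excluded from
#'   the denominator), AT/GC skew in the standard form
#'   `(A - T)/(A + T)` and `(G - C)/(G + C)`, A+T content pooled by codon
#'   position, and codon usage under the invertebrate mitochondrial code.
NULL

# Invertebrate mitochondrial genetic code (NCBI translation table 5).
mito_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("SGC4")
    code
  }
})

mito_stop_codons <- function() names(mito_code())[mito_code() == "*"]

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Base composition of a sequence
#'
#' @param seq a single DNA string (A/C/G/T/N); `N` is excluded from both
#'   numerator and denominator.
#' @return A `base_composition` list: `a`, `c`, `g`, `t` fractions summing
#'   to 1 over counted bases, and `n_counted`.
#' @export
base_composition <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  validate_dna(seq)
  if (!nzchar(seq)) stop("cannot compute composition of an empty sequence")
  counts <- table(factor(seq_chars(seq), levels = c("A", "C", "G", "T")))
  n <- sum(counts)
  if (n == 0L) stop("sequence contains no unambiguous bases")
  structure(as.list(c(counts / n, n_counted = n)) |>
              setNames(c("a", "c", "g", "t", "n_counted")),
            class = "base_composition")
}

#' AT and GC skew of a composition
#'
#' `at_skew = (A - T)/(A + T)`, `gc_skew = (G - C)/(G + C)`. A zero
#' denominator yields `NA` with the corresponding `*_defined` flag set to
#' `FALSE` rather than an error.
#'
#' @param comp a `base_composition` (or any list with `a`, `c`, `g`, `t`).
#' @return list with `at_skew`, `gc_skew`, `at_defined`, `gc_defined`.
#' @export
skew <- function(comp) {
  a <- comp$a; t <- comp$t; g <- comp$g; c <- comp$c
  at <- a + t; gc <- g + c
  list(at_skew = if (at > 0) (a - t) / at else NA_real_,
       gc_skew = if (gc > 0) (g - c) / gc else NA_real_,
       at_defined = at > 0,
       gc_defined = gc > 0)
}

#' A+T content pooled by codon position
#'
#' Codon positions are pooled over all coding sequences, which must be given
#' in coding-strand orientation and in frame. Truncated terminal stop codons
#' must be removed by the caller (or see [strip_stop_codon()]).
#'
#' @param cds_list named character vector/list of in-frame CDS.
#' @return numeric vector of three A+T fractions (positions 1..3).
#' @export
at_content_by_codon_position <- function(cds_list) {
  cds_list <- unlist(cds_list)
  if (length(cds_list) == 0L) stop("no coding sequences supplied")
  bad <- which(nchar(cds_list) %% 3L != 0L)
  if (length(bad)) {
    nm <- names(cds_list)[bad[1]]
    stop("CDS length not divisible by 3: ",
         if (is.null(nm) || !nzchar(nm)) paste0("entry ", bad[1]) else nm)
  }
  tallies <- matrix(0, nrow = 3, ncol = 2,
                    dimnames = list(NULL, c("at", "total")))
  for (s in cds_list) {
    ch <- seq_chars(toupper(s))
    pos <- rep_len(1:3, length(ch))
    keep <- ch %in% c("A", "C", "G", "T")
    for (p in 1:3) {
      sel <- keep & pos == p
      tallies[p, "at"] <- tallies[p, "at"] + sum(ch[sel] %in% c("A", "T"))
      tallies[p, "total"] <- tallies[p, "total"] + sum(sel)
    }
  }
  as.numeric(tallies[, "at"] / tallies[, "total"])
}

#' Remove a terminal (possibly truncated) stop codon from a CDS
#'
#' Drops a trailing complete stop codon (TAA/TAG under the invertebrate
#' mitochondrial code) or a truncated terminator of length 1-2 ("T", "TA"),
#' so the remainder is a whole number of sense codons.
#'
#' @param cds a single CDS string.
#' @return the CDS without its terminator.
#' @export
strip_stop_codon <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  r <- n %% 3L
  if (r > 0L) return(substr(cds, 1L, n - r))  # truncated "T"/"TA"
  if (n >= 3L && substr(cds, n - 2L, n) %in% mito_stop_codons())
    return(substr(cds, 1L, n - 3L))
  cds
}

#' Codon usage table over a set of coding sequences
#'
#' Counts every sense codon across the supplied in-frame coding-strand CDS.
#' Codons containing ambiguous bases are skipped (tallied in
#' `n_skipped_ambiguous`); stop codons are excluded from the table and
#' tallied in `n_stop`. Percentages are over sense codons and sum to 100.
#'
#' @param cds_list named character vector/list of in-frame CDS
#'   (terminators already stripped, or left in and absorbed into `n_stop`).
#' @return A `codon_usage` data.frame with `codon`, `aa`, `count`,
#'   `percent`, sorted by descending count; attributes `n_skipped_ambiguous`
#'   and `n_stop`.
#' @export
codon_usage <- function(cds_list) {
  cds_list <- unlist(cds_list)
  if (length(cds_list) == 0L) stop("no coding sequences supplied")
  bad <- which(nchar(cds_list) %% 3L != 0L)
  if (length(bad))
    stop("CDS length not divisible by 3 at entry ", bad[1])
  codons <- unlist(lapply(cds_list, function(s) {
    ch <- seq_chars(toupper(s))
    if (!length(ch)) return(character())
    apply(matrix(ch, nrow = 3), 2, paste, collapse = "")
  }), use.names = FALSE)
  ambiguous <- grepl("[^ACGT]", codons)
  codons <- codons[!ambiguous]
  is_stop <- codons %in% mito_stop_codons()
  sense <- codons[!is_stop]
  if (!length(sense)) stop("no sense codons to tabulate")
  code <- mito_code()
  sense_codons <- names(code)[code != "*"]
  counts <- table(factor(sense, levels = sense_codons))
  tab <- data.frame(codon = names(counts),
                    aa = unname(code[names(counts)]),
                    count = as.integer(counts),
                    percent = 100 * as.integer(counts) / length(sense),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$codon), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_skipped_ambiguous") <- sum(ambiguous)
  attr(tab, "n_stop") <- sum(is_stop)
  class(tab) <- c("codon_usage", "data.frame")
  tab
}
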