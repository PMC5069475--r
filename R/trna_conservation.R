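#' @title tRNA-family conservation profiling
#' @name trna_conservation
#' @description Per-column conservation classes and the percentage of
#'   identical nucleotide positions (INP%) for aligned gene families, region
#'   (stem/loop) breakdowns given a secondary-structure annotation, a small
#'   deterministic center-star aligner for convenience, and a descriptive
#'   J-strand versus N-strand conservation contrast.
NULL

#' Construct a family alignment
#'
#' @param seqs character vector of aligned sequences (gaps `-`), equal
#'   lengths, at least 2 rows.
#' @param family family name (e.g. "tRNA-Gln").
#' @param taxa optional taxon ids (defaults to names of `seqs`).
#' @return a `family_alignment` list: `family`, `taxa`, `seqs`, `length`.
#' @export
family_alignment <- function(seqs, family = "family", taxa = names(seqs)) {
  seqs <- toupper(unlist(seqs))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 rows")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  if (any(grepl("[^ACGTN-]", seqs)))
    stop("alignment rows may contain only A,C,G,T,N and '-'")
  if (is.null(taxa)) taxa <- paste0("taxon", seq_along(seqs))
  structure(list(family = family, taxa = taxa, seqs = unname(seqs),
                 length = unname(nchar(seqs[1]))),
            class = "family_alignment")
}

# columns of the returned matrix are alignment rows; always a matrix,
# even for single-column alignments
alignment_matrix <- function(aln) {
  matrix(unlist(strsplit(aln$seqs, ""), use.names = FALSE),
         nrow = aln$length)
}

#' Conservation profile and INP% of a family alignment
#'
#' A column is `identical` iff all rows carry the same non-gap residue;
#' `ge80` iff the modal non-gap residue covers at least 80% of rows (gap
#' rows counted in the denominator) without being identical; otherwise
#' `variable`. INP% is `100 * identical columns / alignment length`.
#'
#' @param aln a `family_alignment` (or character vector coerced to one).
#' @return a `conservation_profile` list: `classes` (per column),
#'   `inp_percent`, `n_identical`, `length`, `family`.
#' @export
inp_percent <- function(aln) {
  if (!inherits(aln, "family_alignment")) aln <- family_alignment(aln)
  m <- alignment_matrix(aln)   # columns of m = alignment rows
  nrows <- ncol(m)
  classes <- apply(m, 1, function(col) {
    nongap <- col[col != "-"]
    if (length(nongap) == nrows && length(unique(nongap)) == 1L)
      return("identical")
    if (length(nongap)) {
      tb <- table(nongap)
      if (max(tb) / nrows >= 0.8) return("ge80")
    }
    "variable"
  })
  n_id <- sum(classes == "identical")
  structure(list(classes = classes,
                 inp_percent = 100 * n_id / aln$length,
                 n_identical = n_id, length = aln$length,
                 family = aln$family),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("conservation_profile [%s]: INP%% = %.1f (%d/%d identical)\n",
              x$family, x$inp_percent, x$n_identical, x$length))
  invisible(x)
}

#' Per-region INP% given a secondary-structure annotation
#'
#' @param aln a `family_alignment`.
#' @param structure character vector of per-column region labels (same
#'   length as the alignment), e.g. `acceptor_stem`, `DHU_loop`,
#'   `anticodon_stem`, ... Regions with no columns are omitted.
#' @return data.frame `region`, `n_columns`, `n_identical`, `inp_percent`.
#' @export
region_conservation <- function(aln, structure) {
  if (!inherits(aln, "family_alignment")) aln <- family_alignment(aln)
  if (length(structure) != aln$length)
    stop("structure annotation length (", length(structure),
         ") does not match alignment length (", aln$length, ")")
  prof <- inp_percent(aln)
  regions <- unique(structure)
  out <- do.call(rbind, lapply(regions, function(rg) {
    cols <- which(structure == rg)
    data.frame(region = rg, n_columns = length(cols),
               n_identical = sum(prof$classes[cols] == "identical"),
               inp_percent = 100 * mean(prof$classes[cols] == "identical"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Needleman-Wunsch global alignment, linear gap penalty.
nw_align <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  av <- seq_chars(a); bv <- seq_chars(b)
  n <- length(av); m <- length(bv)
  S <- matrix(0L, n + 1L, m + 1L)
  S[, 1L] <- gap * 0:n
  S[1L, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback (prefer diagonal, then up [gap in b], then left)
  i <- n; j <- m
  ra <- character(); rb <- character()
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
          S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = S[n + 1L, m + 1L])
}

#' Center-star progressive multiple alignment
#'
#' Deterministic center-star alignment under match +1 / mismatch -1 /
#' gap -2: the center is the sequence with the greatest total pairwise
#' alignment score against all others (ties to the first-indexed), every
#' other sequence is aligned to the center pairwise, and the pairwise
#' alignments are merged under "once a gap, always a gap".
#'
#' @param seqs character vector of 2 or more unaligned sequences.
#' @param family passed through to the resulting [family_alignment()].
#' @return a `family_alignment`.
#' @export
center_star_align <- function(seqs, family = "family") {
  seqs <- toupper(unlist(seqs))
  if (!length(seqs)) stop("no sequences supplied")
  if (length(seqs) == 1L) stop("need at least 2 sequences to align")
  validate_dna(seqs)
  n <- length(seqs)
  scores <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    sc <- nw_align(seqs[i], seqs[j])$score
    scores[i, j] <- sc; scores[j, i] <- sc
  }
  center <- which.max(rowSums(scores))  # first index on ties
  pw <- lapply(seq_len(n), function(i) {
    if (i == center) return(NULL)
    nw_align(seqs[center], seqs[i])
  })
  # merged center coordinates: gap counts between consecutive center bases
  clen <- nchar(seqs[center])
  gap_before <- integer(clen + 1L)   # slot k = gaps before center base k
  per_gaps <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == center) next
    ac <- seq_chars(pw[[i]]$a)
    g <- integer(clen + 1L)
    slot <- 1L
    for (ch in ac) {
      if (ch == "-") g[slot] <- g[slot] + 1L else slot <- slot + 1L
    }
    per_gaps[[i]] <- g
    gap_before <- pmax(gap_before, g)
  }
  pad_row <- function(row_center, row_other, g) {
    # re-expand a pairwise alignment onto the merged gap profile
    oc <- seq_chars(row_center); oo <- seq_chars(row_other)
    out <- character()
    slot <- 1L; k <- 1L
    emit_gap <- gap_before[slot] - g[slot]
    out <- c(out, rep("-", emit_gap))
    while (k <= length(oc)) {
      out <- c(out, oo[k])
      if (oc[k] != "-") {
        slot <- slot + 1L
        emit_gap <- gap_before[slot] - g[slot]
        out <- c(out, rep("-", emit_gap))
      }
      k <- k + 1L
    }
    paste(out, collapse = "")
  }
  rows <- character(n)
  center_g <- integer(clen + 1L)
  center_aln <- paste(unlist(lapply(seq_len(clen + 1L), function(s) {
    c(rep("-", gap_before[s]),
      if (s <= clen) substr(seqs[center], s, s) else character())
  })), collapse = "")
  for (i in seq_len(n)) {
    rows[i] <- if (i == center) center_aln else
      pad_row(pw[[i]]$a, pw[[i]]$b, per_gaps[[i]])
  }
  names(rows) <- if (!is.null(names(seqs))) names(seqs) else
    paste0("seq", seq_len(n))
  family_alignment(rows, family = family)
}

#' Mean INP% by coding strand
#'
#' Descriptive contrast of conservation between J-strand and N-strand
#' encoded families; no significance test is attached.
#'
#' @param profiles named list of `conservation_profile` objects (names =
#'   family names).
#' @param strand_map named character vector mapping family name to `"J"` or
#'   `"N"`; every profiled family must be assigned.
#' @return list with `per_family` (data.frame `family`, `strand`,
#'   `inp_percent`) and `mean_by_strand` (named numeric).
#' @export
strand_conservation_contrast <- function(profiles, strand_map) {
  fams <- names(profiles)
  if (is.null(fams) || any(!nzchar(fams)))
    stop("profiles must be a named list (family names)")
  missing <- setdiff(fams, names(strand_map))
  if (length(missing))
    stop("missing strand assignment for: ", paste(missing, collapse = ", "))
  strands <- strand_map[fams]
  if (!all(strands %in% STRANDS)) stop("strands must be 'J' or 'N'")
  inp <- vapply(profiles, `[[`, 0, "inp_percent")
  per_family <- data.frame(family = fams, strand = unname(strands),
                           inp_percent = unname(inp),
                           stringsAsFactors = FALSE)
  means <- vapply(split(per_family$inp_percent, per_family$strand), mean, 0)
  list(per_family = per_family, mean_by_strand = means)
}
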