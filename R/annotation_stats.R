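#' @title Genome-organization statistics
#' @name annotation_stats
#' @description Signed junction gaps between adjacent features, overlap and
#'   spacer summaries, and shared overlap motifs. The sign convention follows
#'   the usual mitogenome table footnote: negative gaps are overlaps, positive
#'   gaps are intergenic spacers, zero means contiguous.
NULL

#' Signed gaps at every junction between adjacent features
#'
#' For adjacent features the gap is `downstream$start - upstream$end - 1`.
#' When the annotation is circular, the junction across the origin (last
#' feature back to the first) is appended and flagged `origin = TRUE`; by
#' convention it is excluded from overlap/spacer summaries.
#'
#' @param annotation a `genome_annotation` (records must be position-sorted,
#'   which [genome_annotation()] guarantees).
#' @return data.frame with columns `upstream`, `downstream`,
#'   `upstream_kind`, `downstream_kind`, `gap`, `origin`.
#' @export
junction_gaps <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  r <- annotation$records
  if (is.unsorted(r$start)) stop("annotation records are not sorted")
  n <- nrow(r)
  if (n < 2L) stop("need at least two features to form a junction")
  up <- seq_len(n - 1L)
  dn <- up + 1L
  gaps <- data.frame(
    upstream = r$name[up], downstream = r$name[dn],
    upstream_kind = r$kind[up], downstream_kind = r$kind[dn],
    upstream_end = r$end[up], downstream_start = r$start[dn],
    gap = r$start[dn] - r$end[up] - 1L,
    origin = FALSE, stringsAsFactors = FALSE)
  if (annotation$circular) {
    gaps <- rbind(gaps, data.frame(
      upstream = r$name[n], downstream = r$name[1L],
      upstream_kind = r$kind[n], downstream_kind = r$kind[1L],
      upstream_end = r$end[n], downstream_start = r$start[1L],
      gap = 0L, origin = TRUE, stringsAsFactors = FALSE))
  }
  gaps
}

#' Summarize overlaps and intergenic spacers
#'
#' Overlap statistics are taken over negative gaps and spacer statistics over
#' positive gaps. The origin junction and, by default, junctions flanking the
#' control region are excluded, so that "spacer" means a genuine short
#' intergenic stretch rather than the control region itself.
#'
#' @param gaps data.frame from [junction_gaps()].
#' @param exclude_kinds feature kinds whose junctions are dropped from the
#'   summary (default `"control_region"`).
#' @return An `organization_summary` list: `n_overlap_junctions`,
#'   `total_overlap_bp`, `max_overlap` (bp), `max_overlap_pairs`,
#'   `n_spacers`, `total_spacer_bp`, `spacer_range`, plus the filtered
#'   `gaps` table.
#' @export
organization_summary <- function(gaps, exclude_kinds = "control_region") {
  stopifnot(is.data.frame(gaps), "gap" %in% names(gaps))
  keep <- !gaps$origin &
    !(gaps$upstream_kind %in% exclude_kinds) &
    !(gaps$downstream_kind %in% exclude_kinds)
  g <- gaps[keep, , drop = FALSE]
  ov <- g[g$gap < 0L, , drop = FALSE]
  sp <- g[g$gap > 0L, , drop = FALSE]
  max_ov <- if (nrow(ov)) max(-ov$gap) else 0L
  tied <- ov[-ov$gap == max_ov, , drop = FALSE]
  structure(list(
    n_overlap_junctions = nrow(ov),
    total_overlap_bp = sum(-ov$gap),
    max_overlap = max_ov,
    max_overlap_pairs = if (nrow(ov))
      Map(c, tied$upstream, tied$downstream) else list(),
    n_spacers = nrow(sp),
    total_spacer_bp = sum(sp$gap),
    spacer_range = if (nrow(sp)) range(sp$gap) else c(NA_integer_, NA_integer_),
    gaps = g), class = "organization_summary")
}

#' @export
print.organization_summary <- function(x, ...) {
  cat("organization_summary\n",
      "  overlaps: ", x$n_overlap_junctions, " junctions, ",
      x$total_overlap_bp, " bp total, max ", x$max_overlap, " bp\n",
      "  spacers : ", x$n_spacers, " spacers, ",
      x$total_spacer_bp, " bp total\n", sep = "")
  invisible(x)
}

#' J-strand sequences of overlap regions shared between adjacent genes
#'
#' Returns, for every overlapping junction, the overlapped slice of the
#' J-strand genome sequence, so that identical overlap motifs (such as the
#' seven-nucleotide ATGATAA shared by the ATP8/ATP6 and ND4L/ND4 junctions
#' in seed-bug mitogenomes) can be compared directly.
#'
#' @param annotation a `genome_annotation`.
#' @param genome_seq J-strand genome sequence (single string).
#' @return data.frame with `upstream`, `downstream`, `start`, `end`,
#'   `overlap_seq`; non-overlapping junctions are excluded.
#' @export
shared_overlap_motifs <- function(annotation, genome_seq) {
  stopifnot(length(genome_seq) == 1L)
  gaps <- junction_gaps(annotation)
  ov <- gaps[!gaps$origin & gaps$gap < 0L, , drop = FALSE]
  res <- lapply(seq_len(nrow(ov)), function(i) {
    up_end <- ov$upstream_end[i]
    start <- ov$downstream_start[i]
    if (start < 1L || up_end > nchar(genome_seq))
      stop("overlap coordinates outside genome sequence for junction ",
           ov$upstream[i], "/", ov$downstream[i])
    data.frame(upstream = ov$upstream[i], downstream = ov$downstream[i],
               start = start, end = up_end,
               overlap_seq = substr(genome_seq, start, up_end),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
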