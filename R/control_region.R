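#' @title Control-region dissection
#' @name control_region
#' @description From-scratch tandem-repeat decomposition, repeat-unit typing
#'   with adjacency analysis, motif scanners (homopolymers, microsatellites,
#'   base-content blocks, stem-loops), and a full partition of a control
#'   region into labeled, non-overlapping segments.
NULL

# --- tandem array detection --------------------------------------------------

new_repeat_array <- function(sc, start, end, period) {
  len <- end - start + 1L
  n_full <- len %/% period
  partial_len <- len %% period
  offsets <- start + (seq_len(n_full) - 1L) * period
  unit_seqs <- vapply(offsets, function(o)
    paste(sc[o:(o + period - 1L)], collapse = ""), "")
  units <- data.frame(offset = offsets, length = period,
                      seq = unit_seqs, stringsAsFactors = FALSE)
  if (partial_len > 0L) {
    po <- start + n_full * period
    units <- rbind(units, data.frame(
      offset = po, length = partial_len,
      seq = paste(sc[po:end], collapse = ""), stringsAsFactors = FALSE))
  }
  mat <- vapply(strsplit(unit_seqs, ""), identity, character(period))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = period)
  consensus <- apply(mat, 1, function(col) {
    tb <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    names(tb)[which.max(tb)]
  })
  identity_mean <- mean(vapply(seq_len(n_full), function(k)
    mean(mat[, k] == consensus), numeric(1)))
  structure(list(start = start, end = end, length = len, period = period,
                 units = units, n_full = n_full,
                 n_partial = as.integer(partial_len > 0L),
                 partial_length = partial_len,
                 consensus = paste(consensus, collapse = ""),
                 identity = identity_mean),
            class = "repeat_array")
}

#' @export
print.repeat_array <- function(x, ...) {
  cat(sprintf(
    "repeat_array: %d-%d (%d bp), period %d, %d full + %d partial, id %.3f\n",
    x$start, x$end, x$length, x$period, x$n_full, x$n_partial, x$identity))
  invisible(x)
}

# Candidate boundaries for one period: qualifying window runs, strict trim
# at the edges, then mismatch-tolerant extension (a mismatch is absorbed
# only when the p positions ahead of it still look periodic, so variable
# sites inside an array are crossed while flanking noise stops extension).
period_candidates <- function(sc, p, min_identity) {
  L <- length(sc)
  if (L < 2L * p + 1L) return(list())
  m <- sc[1:(L - p)] == sc[(p + 1L):L]
  cm <- c(0L, cumsum(m))
  nwin <- L - 2L * p + 1L
  w <- (cm[(1:nwin) + p] - cm[1:nwin]) / p
  q <- which(w >= min_identity)
  if (!length(q)) return(list())
  grp <- cumsum(c(1L, diff(q) > p))
  lapply(split(q, grp), function(run) {
    start <- run[1]
    end <- run[length(run)] + 2L * p - 1L
    # strict trim: boundary positions must themselves be periodic
    while (start < end && !m[start]) start <- start + 1L
    while (end > start && sc[end] != sc[end - p]) end <- end - 1L
    # tolerant extension
    repeat {
      if (start <= 1L) break
      if (sc[start - 1L] == sc[start - 1L + p]) { start <- start - 1L; next }
      lo <- max(1L, start - p)
      if (start - lo >= p &&
          mean(sc[lo:(start - 1L)] == sc[(lo + p):(start - 1L + p)]) >=
            min_identity) { start <- start - 1L; next }
      break
    }
    repeat {
      if (end >= L) break
      if (sc[end + 1L] == sc[end + 1L - p]) { end <- end + 1L; next }
      hi <- min(L, end + p)
      if (hi - end >= p &&
          mean(sc[(end + 1L):hi] == sc[(end + 1L - p):(hi - p)]) >=
            min_identity) { end <- end + 1L; next }
      break
    }
    # score-walk polish: from an interior anchor, a boundary is the
    # argmax of a cumulative walk rewarding periodic matches and
    # penalizing mismatches at the odds implied by min_identity (exact
    # integer scores, so boundary ties resolve deterministically to the
    # outermost position); isolated flank coincidences can never beat
    # the sustained boundary
    m_sc <- as.integer(round(1000 * (1 - min_identity)))
    mm_sc <- -as.integer(round(1000 * min_identity))
    half <- (end - start + 1L) %/% 2L
    anchor <- start + min(2L * p, half)
    lo_lim <- max(1L, start - p)
    if (anchor > start && anchor - 1L >= lo_lim && anchor + p <= L) {
      cum <- 0L; best <- 0L; best_j <- anchor
      for (j in seq.int(anchor - 1L, lo_lim)) {
        cum <- cum + if (sc[j] == sc[j + p]) m_sc else mm_sc
        if (cum >= best) { best <- cum; best_j <- j }  # ties: outermost
      }
      start <- best_j
    }
    anchor <- end - min(2L * p, half)
    hi_lim <- min(L, end + p)
    if (anchor < end && anchor + 1L <= hi_lim && anchor - p >= 1L) {
      cum <- 0L; best <- 0L; best_j <- anchor
      for (j in seq.int(anchor + 1L, hi_lim)) {
        cum <- cum + if (sc[j] == sc[j - p]) m_sc else mm_sc
        if (cum >= best) { best <- cum; best_j <- j }
      }
      end <- best_j
    }
    c(start = start, end = end)
  })
}

interval_overlap <- function(a_start, a_end, b_start, b_end) {
  max(0L, min(a_end, b_end) - max(a_start, b_start) + 1L)
}

#' Detect and decompose tandem-repeat arrays
#'
#' Candidate periods are scored by the shifted self-match rate (the fraction
#' of positions `i` with `seq[i] == seq[i + p]`); for each locally coherent
#' stretch the array boundaries are trimmed and extended as described in the
#' package vignette, units are cut in phase from the array start (so a
#' terminal partial copy is a prefix of the consensus), and overlapping
#' candidates are resolved longest-array-first with a period-minimality
#' rule: a smaller period replaces a larger one over the same span when its
#' consensus identity is within `minimality_tol` of the larger period's.
#'
#' @param seq a single DNA string.
#' @param min_period,max_period candidate period range in bp (defaults 5 and
#'   250, spanning the unit sizes reported for insect control regions).
#' @param min_copies minimum number of full units (default 3).
#' @param min_identity minimum mean unit-to-consensus identity (default 0.8).
#' @param minimality_tol identity tolerance for preferring the smaller of
#'   two near-equivalent periods (default 0.02).
#' @return list of `repeat_array` objects (possibly empty), in genome order.
#' @export
detect_tandem_array <- function(seq, min_period = 5L, max_period = 250L,
                                min_copies = 3L, min_identity = 0.8,
                                minimality_tol = 0.02) {
  stopifnot(length(seq) == 1L, min_period >= 1L, min_copies >= 2L)
  seq <- toupper(seq)
  validate_dna(seq)
  sc <- seq_chars(seq)
  L <- length(sc)
  cands <- list()
  for (p in seq.int(min_period, min(max_period, max(min_period, (L - 1L) %/% 2L)))) {
    if (L < 2L * p + 1L) break
    for (b in period_candidates(sc, p, min_identity)) {
      if (b["end"] - b["start"] + 1L < 2L * p) next
      arr <- new_repeat_array(sc, unname(b["start"]), unname(b["end"]), p)
      if (arr$n_full >= min_copies && arr$identity >= min_identity)
        cands[[length(cands) + 1L]] <- arr
    }
  }
  if (!length(cands)) return(list())
  ord <- order(-vapply(cands, `[[`, 0L, "length"),
               vapply(cands, `[[`, 0L, "period"),
               vapply(cands, `[[`, 0L, "start"))
  cands <- cands[ord]
  accepted <- list()
  taken <- logical(length(cands))
  for (i in seq_along(cands)) {
    if (taken[i]) next
    cand <- cands[[i]]
    clash <- any(vapply(accepted, function(a)
      interval_overlap(a$start, a$end, cand$start, cand$end) > 0L, TRUE))
    if (clash) { taken[i] <- TRUE; next }
    # period minimality over near-identical spans; comparisons are against
    # the current best so a chain of harmonics (4p, 2p, p) collapses to p
    best <- cand
    repeat {
      changed <- FALSE
      for (j in seq_along(cands)) {
        if (j == i || taken[j]) next
        alt <- cands[[j]]
        ov <- interval_overlap(alt$start, alt$end, best$start, best$end)
        un <- max(alt$end, best$end) - min(alt$start, best$start) + 1L
        if (ov / un >= 0.9 && alt$period < best$period &&
            alt$identity >= best$identity - minimality_tol) {
          best <- alt
          taken[j] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    # mark every candidate the accepted span covers
    for (j in seq_along(cands)) {
      if (taken[j]) next
      if (interval_overlap(cands[[j]]$start, cands[[j]]$end,
                           best$start, best$end) > 0L) taken[j] <- TRUE
    }
    taken[i] <- TRUE
    accepted[[length(accepted) + 1L]] <- best
  }
  accepted[order(vapply(accepted, `[[`, 0L, "start"))]
}

# --- unit classification -----------------------------------------------------

#' Classify repeat units by their residues at variable sites
#'
#' Variable sites are unit-alignment columns carrying at least two residues
#' that each occur in `min_minor_count` or more full units. A unit type is a
#' residue combination at those sites; types are numbered by descending copy
#' count (ties broken by first occurrence in the array). A combination seen
#' fewer than `min_minor_count` times is treated as a point mutation and
#' assigned to the nearest type by Hamming distance at the variable sites.
#' The terminal partial copy, if present, is labeled by exact prefix match
#' against the type templates and counted separately from the full units.
#'
#' @param array a `repeat_array` with at least 2 full units.
#' @param min_minor_count minimum copies for a residue/combination to found
#'   a type (default 2).
#' @return A `unit_types` list: `variable_sites` (1-based offsets within the
#'   unit), `type_definitions`, `labels` (per full unit), `counts`,
#'   `adjacency` (transition-count matrix), `partial_label`.
#' @export
classify_units <- function(array, min_minor_count = 2L) {
  stopifnot(inherits(array, "repeat_array"))
  full <- array$units$seq[array$units$length == array$period]
  if (length(full) < 2L) stop("need at least 2 full units to classify")
  if (length(unique(nchar(full))) != 1L)
    stop("full units of unequal length")
  p <- array$period
  mat <- vapply(strsplit(full, ""), identity, character(p))
  var_sites <- which(vapply(seq_len(p), function(r) {
    tb <- table(mat[r, ])
    sum(tb >= min_minor_count) >= 2L
  }, TRUE))
  if (!length(var_sites)) {
    labels <- rep(1L, length(full))
    defs <- data.frame(type = 1L, residues = "", stringsAsFactors = FALSE)
    adjacency <- matrix(length(full) - 1L, 1, 1,
                        dimnames = list("1", "1"))
    return(structure(list(variable_sites = integer(), labels = labels,
                          type_definitions = defs,
                          counts = c(`1` = length(full)),
                          adjacency = adjacency,
                          partial_label = if (array$n_partial) 1L else NA_integer_,
                          consensus = array$consensus),
                     class = "unit_types"))
  }
  combos <- apply(mat[var_sites, , drop = FALSE], 2, paste, collapse = "")
  tb <- table(combos)
  major <- names(tb)[tb >= min_minor_count]
  if (!length(major)) major <- names(tb)[which.max(tb)]
  # order: descending count, ties by first occurrence
  first_at <- vapply(major, function(cb) which(combos == cb)[1], 0L)
  major <- major[order(-as.integer(tb[major]), first_at)]
  type_of_combo <- setNames(seq_along(major), major)
  hamming <- function(a, b) sum(seq_chars(a) != seq_chars(b))
  labels <- vapply(combos, function(cb) {
    if (cb %in% major) return(unname(type_of_combo[cb]))
    d <- vapply(major, hamming, 0L, a = cb)
    cand <- which(d == min(d))
    unname(cand[1])
  }, 0L, USE.NAMES = FALSE)
  counts <- table(factor(labels, levels = seq_along(major)))
  counts <- setNames(as.integer(counts), seq_along(major))
  k <- length(major)
  adjacency <- matrix(0L, k, k, dimnames = list(seq_len(k), seq_len(k)))
  if (length(labels) > 1L)
    for (i in seq_len(length(labels) - 1L))
      adjacency[labels[i], labels[i + 1L]] <-
        adjacency[labels[i], labels[i + 1L]] + 1L
  # type templates: consensus with the type's residues at variable sites
  cons <- seq_chars(array$consensus)
  templates <- vapply(major, function(cb) {
    t <- cons; t[var_sites] <- seq_chars(cb); paste(t, collapse = "")
  }, "")
  partial_label <- NA_integer_
  if (array$n_partial) {
    pseq <- array$units$seq[nrow(array$units)]
    hit <- which(substr(templates, 1L, nchar(pseq)) == pseq)
    partial_label <- if (length(hit)) hit[1] else {
      d <- vapply(templates, function(t)
        hamming(substr(t, 1, nchar(pseq)), pseq), 0L)
      which.min(d)[1]
    }
  }
  structure(list(variable_sites = var_sites, labels = labels,
                 type_definitions = data.frame(
                   type = seq_along(major), residues = major,
                   template = unname(templates), stringsAsFactors = FALSE),
                 counts = counts, adjacency = adjacency,
                 partial_label = as.integer(partial_label),
                 consensus = array$consensus),
            class = "unit_types")
}

#' @export
print.unit_types <- function(x, ...) {
  cat("unit_types: ", length(x$counts), " types at ",
      length(x$variable_sites), " variable site(s) [",
      paste(x$variable_sites, collapse = ", "), "]\n", sep = "")
  cat("  counts: ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Adjacency patterns between consecutive unit types
#'
#' Evaluates, from the transition-count matrix, rules of the form "every
#' occurrence of type X is immediately followed by type Y" (a type in final
#' position with no successor falsifies the rule), and reports the type the
#' terminal partial copy prefix-matches.
#'
#' @param assignment a `unit_types` object from [classify_units()].
#' @param queries list of 2-vectors `c(x, y)` of type ids to test.
#' @return list with `adjacency`, `rules` (data.frame `x`, `y`, `holds`),
#'   and `partial_label`.
#' @export
adjacency_patterns <- function(assignment,
                               queries = list(c(4L, 2L))) {
  stopifnot(inherits(assignment, "unit_types"))
  labels <- assignment$labels
  if (length(labels) < 2L) stop("need at least 2 units for adjacency analysis")
  k <- length(assignment$counts)
  rules <- do.call(rbind, lapply(queries, function(qv) {
    x <- as.integer(qv[1]); y <- as.integer(qv[2])
    holds <- if (x > k || sum(labels == x) == 0L) NA else {
      pos <- which(labels == x)
      all(pos < length(labels)) && all(labels[pos + 1L] == y)
    }
    data.frame(x = x, y = y, holds = holds)
  }))
  list(adjacency = assignment$adjacency, rules = rules,
       partial_label = assignment$partial_label)
}

# --- motif scanners ----------------------------------------------------------

#' Maximal homopolymer runs
#'
#' @param seq a single DNA string.
#' @param min_len minimum run length (>= 3; default 8, the tract length
#'   dissected in the reference control region).
#' @return data.frame `kind`, `start`, `end`, `motif`, `copies`.
#' @export
find_homopolymers <- function(seq, min_len = 8L) {
  stopifnot(min_len >= 3L)
  seq <- toupper(seq)
  validate_dna(seq)
  r <- rle(seq_chars(seq))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
  data.frame(kind = rep("homopolymer", sum(keep)),
             start = starts[keep], end = ends[keep],
             motif = r$values[keep], copies = r$lengths[keep],
             stringsAsFactors = FALSE)
}

is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (strrep(substr(unit, 1L, d), u %/% d) == unit) return(FALSE)
  }
  TRUE
}

#' Maximal perfect microsatellite runs
#'
#' Finds maximal perfect tandem runs of units of length 2..`max_unit` with
#' at least `min_copies` full copies. Runs reducible to a shorter period are
#' reported at the shortest period only, and homopolymer runs are left to
#' [find_homopolymers()] (a unit of one repeated base is not reported).
#'
#' @param seq a single DNA string.
#' @param max_unit maximum unit length (<= 6; default 6).
#' @param min_copies minimum full copies (default 3).
#' @return data.frame `kind`, `start`, `end`, `motif` (the unit), `copies`.
#' @export
find_microsatellites <- function(seq, max_unit = 6L, min_copies = 3L) {
  stopifnot(max_unit <= 6L, max_unit >= 2L)
  seq <- toupper(seq)
  validate_dna(seq)
  sc <- seq_chars(seq)
  L <- length(sc)
  hits <- list()
  for (u in seq.int(2L, max_unit)) {
    if (L < 2L * u) next
    m <- sc[1:(L - u)] == sc[(u + 1L):L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      span_len <- r$lengths[k] + u          # matched stretch + one unit
      copies <- span_len %/% u
      if (copies < min_copies) next
      st <- starts[k]
      unit <- paste(sc[st:(st + u - 1L)], collapse = "")
      if (!is_primitive_unit(unit)) next
      hits[[length(hits) + 1L]] <- data.frame(
        kind = "microsatellite", start = st, end = st + copies * u - 1L,
        motif = unit, copies = copies, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), motif = character(),
                      copies = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, hits)
  # drop hits contained in another hit with a shorter (or equal) period
  period <- nchar(df$motif)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j || !keep[i]) next
      if (df$start[j] <= df$start[i] && df$end[j] >= df$end[i] &&
          (period[j] < period[i] ||
           (period[j] == period[i] &&
            (df$end[j] - df$start[j] > df$end[i] - df$start[i])))) {
        keep[i] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Base-content blocks (A+T-rich or G+C-rich)
#'
#' Slides a window over the sequence, keeps windows whose A+T (or G+C)
#' content meets `threshold`, merges overlapping or nearby qualifying
#' windows (gap < `window`), and recomputes each merged block's content on
#' its final slice.
#'
#' @param seq a single DNA string.
#' @param window window length in bp (must not exceed the sequence length).
#' @param threshold minimum content in the window, in `[0, 1]`.
#' @param mode `"AT"` or `"GC"`.
#' @return data.frame `kind` (`at_rich_block`/`gc_rich_block`), `start`,
#'   `end`, `content`.
#' @export
content_blocks <- function(seq, window, threshold, mode = c("AT", "GC")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  validate_dna(seq)
  sc <- seq_chars(seq)
  L <- length(sc)
  if (window > L) stop("window exceeds sequence length")
  tgt <- if (mode == "AT") c("A", "T") else c("G", "C")
  ind <- as.integer(sc %in% tgt)
  cs <- c(0L, cumsum(ind))
  nwin <- L - window + 1L
  frac <- (cs[(1:nwin) + window] - cs[1:nwin]) / window
  q <- which(frac >= threshold)
  kind <- if (mode == "AT") "at_rich_block" else "gc_rich_block"
  if (!length(q))
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), content = numeric(),
                      stringsAsFactors = FALSE))
  grp <- cumsum(c(1L, diff(q) >= window))
  blocks <- lapply(split(q, grp), function(run) {
    st <- run[1]; en <- run[length(run)] + window - 1L
    data.frame(kind = kind, start = st, end = en,
               content = (cs[en + 1L] - cs[st]) / (en - st + 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  out[order(out$start), , drop = FALSE]
}

#' Stem-loop (hairpin) candidates by inverted-repeat search
#'
#' Scans for two arms of length >= `min_stem` whose reverse complements
#' match with at most `max_mismatch` mispairs, flanking a loop of
#' `min_loop`..`max_loop` bases. Each hit is annotated with whether a
#' "TATA" element occurs within `tata_window` bp upstream of the 5' arm.
#' With `maximal_only = TRUE` (default) hits whose span lies inside a
#' higher-scoring hit are dropped.
#'
#' @param seq a single DNA string.
#' @param min_stem minimum arm length (>= 4; default 6).
#' @param max_loop maximum loop length (default 20).
#' @param max_mismatch maximum mispairs tolerated in the stem (default 1).
#' @param min_loop minimum loop length (default 3).
#' @param tata_window upstream window for the TATA element (default 10).
#' @param maximal_only drop hits contained in better hits (default TRUE).
#' @return data.frame `kind`, `start`, `end`, `stem`, `loop`, `mismatches`,
#'   `score` (stem - mismatches), `tata_upstream`, ordered by descending
#'   score.
#' @export
find_hairpin <- function(seq, min_stem = 6L, max_loop = 20L,
                         max_mismatch = 1L, min_loop = 3L,
                         tata_window = 10L, maximal_only = TRUE) {
  stopifnot(min_stem >= 4L)
  seq <- toupper(seq)
  validate_dna(seq)
  sc <- seq_chars(seq)
  comp <- chartr("ACGTN", "TGCAN", sc)
  L <- length(sc)
  hits <- list()
  max_stem <- (L - min_loop) %/% 2L
  if (max_stem >= min_stem) for (stem in seq.int(min_stem, max_stem)) {
    for (loop in seq.int(min_loop, max_loop)) {
      span <- 2L * stem + loop
      if (span > L) break
      for (i in seq_len(L - span + 1L)) {
        a1 <- sc[i:(i + stem - 1L)]
        a2c <- rev(comp[(i + stem + loop):(i + span - 1L)])
        mm <- sum(a1 != a2c)
        if (mm <= max_mismatch) {
          tata <- FALSE
          if (i > 1L) {
            up <- paste(sc[max(1L, i - tata_window):(i - 1L)], collapse = "")
            tata <- grepl("TATA", up, fixed = TRUE)
          }
          hits[[length(hits) + 1L]] <- data.frame(
            kind = "hairpin", start = i, end = i + span - 1L,
            stem = stem, loop = loop, mismatches = mm,
            score = stem - mm, tata_upstream = tata,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), stem = integer(), loop = integer(),
                      mismatches = integer(), score = integer(),
                      tata_upstream = logical(), stringsAsFactors = FALSE))
  df <- do.call(rbind, hits)
  df <- df[order(-df$score, df$mismatches, df$start, -df$stem), , drop = FALSE]
  if (maximal_only) {
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!keep[i]) next
      inside <- df$start >= df$start[i] & df$end <= df$end[i] &
        seq_len(nrow(df)) > i
      keep[inside & keep] <- FALSE
    }
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# --- partition ---------------------------------------------------------------

default_partition_config <- function() {
  list(min_period = 5L, max_period = 250L, min_copies = 3L,
       min_identity = 0.8,
       microsat_max_unit = 6L, microsat_min_copies = 3L,
       poly_min_len = 8L,
       at_window = 40L, at_threshold = 0.85,
       gc_window = 40L, gc_threshold = 0.25,
       hairpin_min_stem = 6L, hairpin_max_loop = 20L,
       hairpin_max_mismatch = 1L,
       hairpin_downstream_of_array = TRUE)
}

#' Partition a control region into labeled segments
#'
#' Runs all scanners and resolves overlaps by fixed precedence
#' (tandem array > hairpin > microsatellite > poly tract > content blocks,
#' longer block first within the content tier). Detected tandem arrays with
#' a period small enough to be a microsatellite (period <= `microsat_max_unit`)
#' are left to the microsatellite scanner. Content-block fragments shorter
#' than the scan window after carving are dropped, and short unlabeled gaps
#' flanked by a content block are absorbed into it (window-scale boundary
#' uncertainty is inherent to content scanning). Remaining unlabeled runs
#' become `linker` segments, or a single `unassigned` segment when nothing
#' at all was detected. Segments tile the input exactly.
#'
#' @param seq the control-region sequence (single string).
#' @param config named list overriding [default_partition_config()] entries.
#' @return A `control_region_partition`: list with `segments` (data.frame
#'   `kind`, `start`, `end`, `length`), `arrays` (list of `repeat_array`),
#'   `hairpin` (best hit or NULL), `motifs` (all scanner hits).
#' @export
partition_control_region <- function(seq, config = list()) {
  cfg <- default_partition_config()
  stopifnot(all(names(config) %in% names(cfg)))
  cfg[names(config)] <- config
  seq <- toupper(seq)
  validate_dna(seq)
  L <- nchar(seq)
  kind_vec <- rep(NA_character_, L)
  id_vec <- integer(L)
  next_id <- 0L
  claim <- function(start, end, kind) {
    next_id <<- next_id + 1L
    free <- which(is.na(kind_vec[start:end])) + start - 1L
    kind_vec[free] <<- kind
    id_vec[free] <<- next_id
    invisible(NULL)
  }

  arrays <- detect_tandem_array(seq, cfg$min_period, cfg$max_period,
                                cfg$min_copies, cfg$min_identity)
  big_arrays <- Filter(function(a) a$period > cfg$microsat_max_unit, arrays)
  for (a in big_arrays[order(-vapply(big_arrays, `[[`, 0L, "length"))])
    claim(a$start, a$end, "tandem_array")

  hp_region_start <- if (length(big_arrays) && cfg$hairpin_downstream_of_array)
    max(vapply(big_arrays, `[[`, 0L, "end")) + 1L else 1L
  hairpin_best <- NULL
  if (hp_region_start <= L - (2L * cfg$hairpin_min_stem + 3L) + 1L) {
    sub <- substr(seq, hp_region_start, L)
    hp <- find_hairpin(sub, cfg$hairpin_min_stem, cfg$hairpin_max_loop,
                       cfg$hairpin_max_mismatch)
    if (nrow(hp)) {
      hp$start <- hp$start + hp_region_start - 1L
      hp$end <- hp$end + hp_region_start - 1L
      hairpin_best <- hp[1, , drop = FALSE]
      claim(hairpin_best$start, hairpin_best$end, "hairpin")
    }
  }

  ms <- find_microsatellites(seq, cfg$microsat_max_unit,
                             cfg$microsat_min_copies)
  if (nrow(ms)) for (i in order(-(ms$end - ms$start)))
    claim(ms$start[i], ms$end[i], "microsatellite")

  hp_runs <- find_homopolymers(seq, cfg$poly_min_len)
  if (nrow(hp_runs)) for (i in seq_len(nrow(hp_runs)))
    claim(hp_runs$start[i], hp_runs$end[i], "poly_tract")

  # content scanning ignores positions already explained by a
  # higher-precedence segment (masked to N, which counts as neither A+T
  # nor G+C), so e.g. a poly-C tract cannot seed a spurious G+C block
  masked_sc <- seq_chars(seq)
  masked_sc[!is.na(kind_vec)] <- "N"
  masked <- paste(masked_sc, collapse = "")
  at_b <- if (L >= cfg$at_window)
    content_blocks(masked, cfg$at_window, cfg$at_threshold, "AT") else NULL
  gc_b <- if (L >= cfg$gc_window)
    content_blocks(masked, cfg$gc_window, cfg$gc_threshold, "GC") else NULL
  cb <- rbind(
    if (!is.null(at_b) && nrow(at_b))
      data.frame(kind = "at_block", start = at_b$start, end = at_b$end,
                 window = cfg$at_window, stringsAsFactors = FALSE),
    if (!is.null(gc_b) && nrow(gc_b))
      data.frame(kind = "gc_block", start = gc_b$start, end = gc_b$end,
                 window = cfg$gc_window, stringsAsFactors = FALSE))
  if (!is.null(cb) && nrow(cb)) {
    for (i in order(-(cb$end - cb$start)))
      claim(cb$start[i], cb$end[i], cb$kind[i])
    # drop content fragments shorter than the scan window
    frag <- rle(paste(ifelse(is.na(kind_vec), ".", kind_vec), id_vec))
    pos <- 1L
    for (k in seq_along(frag$lengths)) {
      len <- frag$lengths[k]
      kv <- kind_vec[pos]
      if (!is.na(kv) && kv %in% c("at_block", "gc_block")) {
        win <- if (kv == "at_block") cfg$at_window else cfg$gc_window
        if (len < win) {
          kind_vec[pos:(pos + len - 1L)] <- NA_character_
          id_vec[pos:(pos + len - 1L)] <- 0L
        }
      }
      pos <- pos + len
    }
  }

  # absorb short unlabeled gaps flanked by a content block
  gap_runs <- rle(is.na(kind_vec))
  pos <- 1L
  for (k in seq_along(gap_runs$lengths)) {
    len <- gap_runs$lengths[k]
    if (gap_runs$values[k] &&
        len < max(cfg$at_window, cfg$gc_window)) {
      left_i <- pos - 1L
      right_i <- pos + len
      left_kind <- if (left_i >= 1L) kind_vec[left_i] else NA_character_
      right_kind <- if (right_i <= L) kind_vec[right_i] else NA_character_
      pick <- NULL
      content <- c("at_block", "gc_block")
      if (!is.na(left_kind) && left_kind %in% content) pick <- "left"
      if (is.null(pick) && !is.na(right_kind) && right_kind %in% content)
        pick <- "right"
      if (!is.null(pick)) {
        src <- if (pick == "left") left_i else right_i
        kind_vec[pos:(pos + len - 1L)] <- kind_vec[src]
        id_vec[pos:(pos + len - 1L)] <- id_vec[src]
      }
    }
    pos <- pos + len
  }

  any_labeled <- any(!is.na(kind_vec))
  kind_vec[is.na(kind_vec)] <- if (any_labeled) "linker" else "unassigned"

  runs <- rle(paste(kind_vec, id_vec, sep = "\r"))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segments <- data.frame(
    kind = sub("\r.*$", "", runs$values),
    start = starts, end = ends, stringsAsFactors = FALSE)
  # merge directly adjacent same-kind content segments
  i <- 2L
  while (i <= nrow(segments)) {
    if (segments$kind[i] == segments$kind[i - 1L] &&
        segments$kind[i] %in% c("at_block", "gc_block", "linker")) {
      segments$end[i - 1L] <- segments$end[i]
      segments <- segments[-i, , drop = FALSE]
    } else i <- i + 1L
  }
  segments$length <- segments$end - segments$start + 1L
  rownames(segments) <- NULL
  stopifnot(segments$start[1] == 1L,
            segments$end[nrow(segments)] == L,
            all(segments$start[-1] == segments$end[-nrow(segments)] + 1L))
  structure(list(segments = segments, arrays = arrays,
                 hairpin = hairpin_best,
                 motifs = list(microsatellites = ms,
                               homopolymers = hp_runs,
                               at_blocks = at_b, gc_blocks = gc_b),
                 config = cfg),
            class = "control_region_partition")
}

#' @export
print.control_region_partition <- function(x, ...) {
  cat("control_region_partition (", sum(x$segments$length), " bp):\n",
      sep = "")
  print(x$segments)
  invisible(x)
}
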