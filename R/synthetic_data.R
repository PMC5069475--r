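#' @title Seeded synthetic-data generators
#' @name synthetic_data
#' @description Generators emulating the architecture of the reference
#'   seed-bug mitogenome so every analysis stage runs without downloads: a
#'   control region with a GC-richer 5' block, two microsatellite tracts
#'   separated by a poly-C run, an A+T-rich block, a poly-A run, a 53-copy
#'   tandem array of 18-bp units in four types differing at two variable
#'   sites with one 13-bp terminal partial copy, and a downstream stem-loop
#'   with a 5' TATA element; plus whole mitogenomes with strand-biased
#'   composition, tRNA-family alignments with planted conservation, and CDS
#'   pairs with known synonymous/nonsynonymous divergence.
#'
#'   Every generator is a pure function of (config, seed). The control
#'   region generator guarantees identifiable ground truth: guard bases at
#'   element seams stop planted motifs from extending across junctions, and
#'   random elements are resampled until they carry no incidental motif
#'   hits, so the emitted truth table is the unique motif annotation of the
#'   sequence.
NULL

#' Reference-default control-region generator configuration
#'
#' Defaults reproduce the dissected architecture: a 321-bp block of 32.1%
#' G+C, (AATTT)x3 and (TA)x5 microsatellites flanking an 8-bp poly-C, a
#' 103-bp block of 90.3% A+T, an 8-bp poly-A, 34-bp linkers around a tandem
#' array of 52 full 18-bp units (type counts 18/15/15/4 at two variable
#' sites) plus a 13-bp terminal partial copy of Type I, and a 12-bp-stem /
#' 8-bp-loop hairpin with a TATA element immediately 5' of the stem. The
#' Type I template extends the known 13-bp partial-copy prefix
#' ("GAATTAGATTAAA") with five fixed bases; the templates are synthetic,
#' not the deposited sequence.
#'
#' @param type_counts named/positional counts for Types I-IV (default
#'   c(18, 15, 15, 4)).
#' @param with_partial append the terminal partial copy? (default TRUE)
#' @return a `cr_config` list; see source for all fields.
#' @export
cr_config <- function(type_counts = c(18L, 15L, 15L, 4L),
                      with_partial = TRUE) {
  templates <- c(I   = "GAATTAGATTAAATTATA",
                 II  = "GAATAAGATTGAATTATA",
                 III = "GAATTAGATTGAATTATA",
                 IV  = "GAATAAGATTAAATTATA")
  cfg <- list(
    gc_block_len = 321L, gc_block_gc = 0.321,
    microsat_1 = list(unit = "AATTT", copies = 3L),
    polyC_len = 8L,
    microsat_2 = list(unit = "TA", copies = 5L),
    at_block_len = 103L, at_block_at = 0.903,
    polyA_len = 8L,
    linker_len = 34L, linker_at = 0.76,
    unit_templates = templates,
    variable_sites = c(5L, 11L),
    type_counts = as.integer(type_counts),
    partial_prefix_len = if (with_partial) 13L else 0L,
    partial_type = 1L,
    # adjacency rules: successor and predecessor requirements encoding
    # "II after I, III between II and I, IV followed by II"
    follows = list(`4` = 2L, `3` = 1L),     # IV -> II, III -> I
    preceded_by = list(`2` = c(1L, 4L),     # II after I (or a IV chimera)
                       `3` = 2L),           # III only after II
    hairpin_stem = 12L, hairpin_loop = 8L, hairpin_tata = TRUE)
  p <- nchar(templates[1])
  stopifnot(all(nchar(templates) == p), length(type_counts) == 4L)
  tm <- vapply(strsplit(templates, ""), identity, character(p))
  diff_rows <- which(apply(tm, 1, function(r) length(unique(r)) > 1L))
  stopifnot(identical(as.integer(diff_rows), cfg$variable_sites))
  structure(cfg, class = "cr_config")
}

# multinomial base sampler with AT content and skew targets
random_seq <- function(n, at = 0.76, at_skew = 0, gc_skew = 0) {
  if (n == 0L) return("")
  probs <- c(A = at * (1 + at_skew) / 2, C = (1 - at) * (1 - gc_skew) / 2,
             G = (1 - at) * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# --- arrangement sampling ----------------------------------------------------

check_static_feasible <- function(counts, follows) {
  for (x in names(follows)) {
    xi <- as.integer(x); yi <- follows[[x]]
    if (counts[xi] > 0L && counts[yi] == 0L)
      stop("arrangement rule violated: every type ", xi,
           " must be followed by type ", yi,
           ", but type ", yi, " has count 0")
  }
  invisible(TRUE)
}

# Randomized backtracking over unit orders satisfying the adjacency rules.
sample_arrangement <- function(counts, follows, preceded_by,
                               partial_label = NA_integer_,
                               max_nodes = 2e5L, max_restarts = 50L) {
  k <- length(counts)
  n <- sum(counts)
  if (n == 0L) stop("no units to arrange")
  check_static_feasible(counts, follows)
  succ <- rep(NA_integer_, k)
  for (x in names(follows)) succ[as.integer(x)] <- follows[[x]]
  pred <- vector("list", k)
  for (x in names(preceded_by)) pred[[as.integer(x)]] <- preceded_by[[x]]
  for (restart in seq_len(max_restarts)) {
    nodes <- 0L
    rec <- function(seqv, prev, rem) {
      nodes <<- nodes + 1L
      if (nodes > max_nodes) return(NULL)
      i <- length(seqv) + 1L
      if (i > n) return(seqv)
      # pruning: successor rules consume copies of their targets
      for (x in seq_len(k)) {
        if (!is.na(succ[x]) && rem[x] > rem[succ[x]]) return(NULL)
        if (!is.null(pred[[x]]) && rem[x] > 0L) {
          avail <- sum(rem[pred[[x]]]) + as.integer(prev %in% pred[[x]])
          if (rem[x] > avail) return(NULL)
        }
      }
      cand <- which(rem > 0L)
      if (!is.na(prev) && !is.na(succ[prev])) cand <- intersect(cand, succ[prev])
      cand <- Filter(function(t) {
        if (!is.null(pred[[t]]) && !(prev %in% pred[[t]])) return(FALSE)
        if (i == n && !is.na(succ[t])) {
          # terminal unit: its successor requirement must be met by the
          # terminal partial copy, if there is one of the right type
          if (is.na(partial_label) || partial_label != succ[t]) return(FALSE)
        }
        TRUE
      }, cand)
      if (!length(cand)) return(NULL)
      for (t in cand[sample.int(length(cand))]) {
        rem2 <- rem; rem2[t] <- rem2[t] - 1L
        res <- rec(c(seqv, t), t, rem2)
        if (!is.null(res)) return(res)
      }
      NULL
    }
    out <- rec(integer(), NA_integer_, counts)
    if (!is.null(out)) return(out)
  }
  stop("could not satisfy the arrangement rules for counts (",
       paste(counts, collapse = ", "), ") within the search budget")
}

#' Generate a tandem-repeat array from unit templates
#'
#' Unit order is sampled among orders satisfying the configured adjacency
#' rules with the exact type counts (randomized backtracking; an
#' unsatisfiable configuration raises an error naming the violated rule),
#' and the terminal partial copy - a prefix of the Type I template - is
#' appended when configured.
#'
#' @param config a [cr_config()].
#' @param seed integer seed.
#' @return list with `seq` (the array string) and `truth` (labels, period,
#'   unit starts, partial info, expected length).
#' @export
generate_repeat_array <- function(config = cr_config(), seed = 1L) {
  stopifnot(inherits(config, "cr_config"))
  p <- nchar(config$unit_templates[1])
  with_seed_(seed, {
    partial_label <- if (config$partial_prefix_len > 0L)
      config$partial_type else NA_integer_
    labels <- sample_arrangement(config$type_counts, config$follows,
                                 config$preceded_by, partial_label)
    units <- unname(config$unit_templates[labels])
    partial <- if (config$partial_prefix_len > 0L)
      substr(config$unit_templates[config$partial_type], 1L,
             config$partial_prefix_len) else ""
    seqs <- c(units, if (nzchar(partial)) partial)
    list(seq = paste(seqs, collapse = ""),
         truth = list(labels = labels, period = p,
                      unit_starts = cumsum(c(1L, rep(p, length(labels) - 1L))),
                      partial_label = partial_label,
                      partial_length = config$partial_prefix_len,
                      n_full = length(labels),
                      length = length(labels) * p + config$partial_prefix_len))
  })
}

# resample a random element until it carries no incidental motif
clean_element <- function(gen, label, extra_check = NULL, tries = 1000L) {
  for (i in seq_len(tries)) {
    el <- gen()
    if (nchar(el) >= 8L) {
      if (nrow(find_homopolymers(el, 8L))) next
      if (nchar(el) >= 6L && nrow(find_microsatellites(el, 6L, 3L))) next
    }
    if (!is.null(extra_check) && !extra_check(el)) next
    return(el)
  }
  stop("could not draw a motif-free ", label, " element")
}

set_char <- function(s, i, ch) {
  substr(s, i, i) <- ch
  s
}

# Overwrite positions `at` of `s` with bases drawn to differ per-position
# from `avoid`: an anti-match seam guard. A guard block longer than the
# decomposer's per-window mismatch allowance (p * (1 - min_identity))
# makes the planted array boundary the only boundary any qualifying
# window can support.
anti_match <- function(s, at, avoid) {
  sc <- seq_chars(s)
  av <- seq_chars(avoid)
  for (k in seq_along(at))
    sc[at[k]] <- sample(setdiff(BASES, av[k]), 1L)
  paste(sc, collapse = "")
}

#' Generate a control region with recoverable ground truth
#'
#' Concatenates, in order: GC block, (AATTT)n, poly-C, (TA)n, AT block,
#' poly-A, linker, tandem array, linker (with the TATA element at its 3'
#' end), hairpin. Guard bases at the seams and motif-free resampling of the
#' random elements make the emitted ground truth the unique motif
#' annotation of the sequence (see the package vignette).
#'
#' @param config a [cr_config()].
#' @param seed integer seed.
#' @return list with `seq` and `truth` (`segments` data.frame of kind/
#'   start/end in generated order, plus the array's `truth` from
#'   [generate_repeat_array()]).
#' @export
generate_control_region <- function(config = cr_config(), seed = 1L) {
  stopifnot(inherits(config, "cr_config"))
  arr <- generate_repeat_array(config, seed = seed)
  with_seed_(seed + 1L, {
    for (attempt in 1:100) {
      no_at_windows <- function(el)
        nrow(content_blocks(el, 40L, 0.85, "AT")) == 0L
      no_gc_windows <- function(el)
        nrow(content_blocks(el, 40L, 0.25, "GC")) == 0L
      no_arrays <- function(el)
        length(detect_tandem_array(el, 5L, 250L, 3L, 0.8)) == 0L
      gc_block <- clean_element(function()
        random_seq(config$gc_block_len, at = 1 - config$gc_block_gc),
        "GC block", function(el) no_at_windows(el) && no_arrays(el))
      gc_block <- set_char(gc_block, config$gc_block_len, "C")  # seam guard
      ms1 <- strrep(config$microsat_1$unit, config$microsat_1$copies)
      polyC <- strrep("C", config$polyC_len)
      ms2 <- strrep(config$microsat_2$unit, config$microsat_2$copies)
      at_block <- clean_element(function()
        random_seq(config$at_block_len, at = config$at_block_at),
        "AT block", function(el) no_gc_windows(el) && no_arrays(el))
      at_block <- set_char(at_block, 1L, "C")                    # blocks (TA)n/(AT)n carry-over
      at_block <- set_char(at_block, config$at_block_len, "T")   # blocks poly-A extension
      polyA <- strrep("A", config$polyA_len)
      p_unit <- nchar(config$unit_templates[1])
      guard <- ceiling(p_unit * (1 - 0.8)) + 1L  # decomposer default identity
      linker1 <- clean_element(function()
        random_seq(config$linker_len, at = config$linker_at),
        "pre-array linker", no_arrays)
      linker1 <- set_char(linker1, 1L, "T")  # blocks poly-A extension
      # seam guard: last `guard` bases anti-match the first unit's tail,
      # so no periodic window reaches across the array 5' boundary
      first_unit <- config$unit_templates[arr$truth$labels[1]]
      linker1 <- anti_match(linker1,
                            (config$linker_len - guard + 1L):config$linker_len,
                            substr(first_unit, p_unit - guard + 1L, p_unit))
      linker2 <- clean_element(function()
        random_seq(config$linker_len, at = config$linker_at),
        "post-array linker", no_arrays)
      # seam guard, 3' side: anti-match the periodic continuation of the
      # array tail (the bases one period before the array end)
      tail_cont <- substr(arr$seq, nchar(arr$seq) - p_unit + 1L,
                          nchar(arr$seq) - p_unit + guard)
      linker2 <- anti_match(linker2, seq_len(guard), tail_cont)
      stem <- clean_element(function() random_seq(config$hairpin_stem,
                                                  at = 0.5),
                            "hairpin stem")
      loop <- random_seq(config$hairpin_loop, at = config$linker_at)
      tata <- if (config$hairpin_tata) "TATA" else ""
      hairpin <- paste0(stem, loop, reverse_complement(stem))

      parts <- list(gc_block = gc_block, microsatellite = ms1,
                    poly_tract = polyC, microsatellite = ms2,
                    at_block = at_block, poly_tract = polyA,
                    linker = paste0(linker1),
                    tandem_array = arr$seq,
                    linker = paste0(linker2, tata),
                    hairpin = hairpin)
      lens <- vapply(parts, nchar, 0L)
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      segments <- data.frame(kind = names(parts), start = starts,
                             end = ends, stringsAsFactors = FALSE)
      cr <- paste(unlist(parts), collapse = "")
      arr_start <- starts[[8]]; arr_end <- ends[[8]]
      # whole-assembly validation: outside the array, motif scanners must
      # find exactly the planted elements (identifiable ground truth)
      ms_hits <- find_microsatellites(cr, 6L, 3L)
      ms_ok <- all(vapply(seq_len(nrow(ms_hits)), function(i) {
        s <- ms_hits$start[i]; e <- ms_hits$end[i]
        (s >= arr_start && e <= arr_end) ||
          (s >= starts[[2]] && e <= ends[[2]]) ||
          (s >= starts[[4]] && e <= ends[[4]])
      }, TRUE))
      hp_hits <- find_homopolymers(cr, 8L)
      hp_ok <- all(vapply(seq_len(nrow(hp_hits)), function(i) {
        s <- hp_hits$start[i]; e <- hp_hits$end[i]
        (s >= arr_start && e <= arr_end) ||
          (s == starts[[3]] && e == ends[[3]]) ||
          (s == starts[[6]] && e == ends[[6]])
      }, TRUE))
      arr_hits <- detect_tandem_array(cr)
      arr_ok <- all(vapply(arr_hits, function(a)
        a$period <= 6L || (a$start >= arr_start && a$end <= arr_end),
        TRUE))
      if (ms_ok && hp_ok && arr_ok) {
        return(list(seq = cr,
                    truth = list(segments = segments,
                                 array = arr$truth,
                                 array_start = arr_start,
                                 array_end = arr_end,
                                 hairpin = list(start = starts[[10]],
                                                end = ends[[10]],
                                                stem = config$hairpin_stem,
                                                loop = config$hairpin_loop))))
      }
    }
    stop("could not assemble a control region with identifiable ground truth")
  })
}

#' Generate a whole mitogenome around an annotation template
#'
#' Gene bodies are drawn with the configured J-strand composition targets,
#' the shared seven-nucleotide overlap motif ATGATAA is planted at the
#' ATP8/ATP6 and ND4L/ND4 junctions, and the control-region slot receives a
#' generated control region (padded 3' of the hairpin with AT-rich filler
#' to fill the annotated slot).
#'
#' @param annotation a `genome_annotation` template (default: the packaged
#'   reference feature table).
#' @param composition list with `at`, `at_skew`, `gc_skew` J-strand targets
#'   (defaults 0.76, 0.168, -0.208, the reference genome's values).
#' @param cr_cfg control-region config (default [cr_config()]).
#' @param seed integer seed.
#' @return list with `genome` (J-strand string), `annotation`, and `truth`
#'   (control-region truth shifted to genome coordinates, planted motifs).
#' @export
generate_mitogenome <- function(annotation = NULL,
                                composition = list(at = 0.76,
                                                   at_skew = 0.168,
                                                   gc_skew = -0.208),
                                cr_cfg = cr_config(), seed = 1L) {
  if (is.null(annotation))
    annotation <- read_annotation_table(
      system.file("extdata", "panaorus_annotation.tsv", package = "mitocr"))
  glen <- annotation$genome_length
  cr_row <- annotation$records[annotation$records$kind == "control_region", ]
  if (nrow(cr_row) != 1L) stop("annotation template needs one control region")
  cr_gen <- generate_control_region(cr_cfg, seed = seed + 1000L)
  backbone <- with_seed_(seed, random_seq(glen, at = composition$at,
                                          at_skew = composition$at_skew,
                                          gc_skew = composition$gc_skew))
  sc <- seq_chars(backbone)
  cr_slot_len <- cr_row$end - cr_row$start + 1L
  cr_seq <- cr_gen$seq
  if (nchar(cr_seq) > cr_slot_len)
    stop("generated control region exceeds the annotated slot")
  pad_len <- cr_slot_len - nchar(cr_seq)
  pad <- with_seed_(seed + 2000L, random_seq(pad_len, at = 0.85))
  sc[cr_row$start:cr_row$end] <- seq_chars(paste0(cr_seq, pad))
  # shared overlap motif at the two junctions that carry it in the
  # reference genome (coordinates from the annotation template)
  planted <- list()
  find_junction <- function(up, dn) {
    g <- junction_gaps(annotation)
    i <- which(g$upstream == up & g$downstream == dn)
    if (length(i) != 1L || g$gap[i] != -7L) return(NULL)
    c(start = g$downstream_start[i], end = g$upstream_end[i])
  }
  # position-sorted junction pairs (annotation order lists ND4 first)
  for (jn in list(c("ATPase8", "ATPase6"), c("ND4", "ND4L"))) {
    co <- find_junction(jn[1], jn[2])
    if (!is.null(co)) {
      sc[co["start"]:co["end"]] <- seq_chars("ATGATAA")
      planted[[paste(jn, collapse = "/")]] <- unname(co)
    }
  }
  list(genome = paste(sc, collapse = ""),
       annotation = annotation,
       truth = list(cr = cr_gen$truth,
                    cr_offset = cr_row$start - 1L,
                    overlap_motifs = planted,
                    composition = composition))
}

#' Generate a family alignment with planted per-column conservation
#'
#' Each column is identical across rows with the given probability (one
#' residue drawn and copied to every row), otherwise every row draws an
#' independent residue. Region-specific probabilities are supported through
#' a structure annotation.
#'
#' @param n_taxa number of rows (>= 2).
#' @param length alignment length, or implied by `structure`.
#' @param p_identity scalar probability, or named vector by region when
#'   `structure` is given.
#' @param structure optional per-column region labels.
#' @param seed integer seed.
#' @return list with `alignment` (a `family_alignment`), `structure`, and
#'   `truth` (`planted_identical` logical per column).
#' @export
generate_family_alignment <- function(n_taxa = 10L, length = 70L,
                                      p_identity = 0.5, structure = NULL,
                                      seed = 1L) {
  stopifnot(n_taxa >= 2L)
  if (!is.null(structure)) length <- base::length(structure)
  pcol <- if (is.null(structure) || base::length(p_identity) == 1L)
    rep(p_identity[[1]], length) else {
      if (!all(unique(structure) %in% names(p_identity)))
        stop("p_identity must name every region in structure")
      unname(p_identity[structure])
    }
  stopifnot(all(pcol >= 0 & pcol <= 1))
  with_seed_(seed, {
    planted <- runif(length) < pcol
    m <- matrix("", nrow = n_taxa, ncol = length)
    for (j in seq_len(length)) {
      if (planted[j]) m[, j] <- sample(BASES, 1L)
      else m[, j] <- sample(BASES, n_taxa, replace = TRUE)
    }
    rows <- apply(m, 1, paste, collapse = "")
    names(rows) <- paste0("taxon", seq_len(n_taxa))
    list(alignment = family_alignment(rows, family = "synthetic"),
         structure = structure,
         truth = list(planted_identical = planted))
  })
}

# synonymous / nonsynonymous single-base neighbors per sense codon
codon_neighbors <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- mito_code()
    sense <- names(code)[code != "*"]
    res <- lapply(sense, function(cod) {
      ch <- seq_chars(cod)
      syn <- character(); nonsyn <- character()
      for (p in 1:3) for (b in setdiff(BASES, ch[p])) {
        mut <- ch; mut[p] <- b
        mc <- paste(mut, collapse = "")
        if (code[[mc]] == "*") next
        if (code[[mc]] == code[[cod]]) syn <- c(syn, mc)
        else nonsyn <- c(nonsyn, mc)
      }
      list(syn = syn, nonsyn = nonsyn)
    })
    names(res) <- sense
    cache <<- res
    res
  }
})

#' Generate an aligned CDS pair with known divergence
#'
#' The first sequence is random sense codons under the invertebrate
#' mitochondrial code; per codon, at most one event is applied to the
#' second: a random synonymous single-base neighbor with probability
#' `syn_prob`, else a nonsynonymous one with probability `nonsyn_prob`
#' (never creating a stop). The realized event counts are returned, so
#' estimator recovery can be checked against the exact truth.
#'
#' @param n_codons number of codons.
#' @param syn_prob,nonsyn_prob per-codon event probabilities
#'   (`syn_prob + nonsyn_prob <= 1`).
#' @param seed integer seed.
#' @return list with `cds_a`, `cds_b`, `truth` (`n_syn`, `n_nonsyn`).
#' @export
generate_cds_pair <- function(n_codons = 500L, syn_prob = 0.05,
                              nonsyn_prob = 0.02, seed = 1L) {
  stopifnot(syn_prob >= 0, nonsyn_prob >= 0, syn_prob + nonsyn_prob <= 1)
  nb <- codon_neighbors()
  sense <- names(nb)
  with_seed_(seed, {
    a <- sample(sense, n_codons, replace = TRUE)
    b <- a
    u <- runif(n_codons)
    n_syn <- 0L; n_nonsyn <- 0L
    for (i in seq_len(n_codons)) {
      if (u[i] < syn_prob) {
        opts <- nb[[a[i]]]$syn
        if (length(opts)) {
          b[i] <- if (length(opts) == 1L) opts else sample(opts, 1L)
          n_syn <- n_syn + 1L
        }
      } else if (u[i] < syn_prob + nonsyn_prob) {
        opts <- nb[[a[i]]]$nonsyn
        if (length(opts)) {
          b[i] <- if (length(opts) == 1L) opts else sample(opts, 1L)
          n_nonsyn <- n_nonsyn + 1L
        }
      }
    }
    list(cds_a = paste(a, collapse = ""), cds_b = paste(b, collapse = ""),
         truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn))
  })
}
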