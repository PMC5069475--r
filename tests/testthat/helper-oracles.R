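# Shared fixtures and independent oracles. Oracles are written against the
# definitions, not the implementation, so a test comparing the two is a
# genuine dual-route check.

annotation_fixture <- function() {
  system.file("extdata", "panaorus_annotation.tsv", package = "mitocr")
}

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Build a tandem array with anti-matching guard flanks so the planted
# boundaries are the only periodicity boundaries (mirrors what the
# package's own generator does at element seams).
guarded_array_seq <- function(unit, n_copies, partial_len, flank = 30L) {
  p <- nchar(unit)
  arr <- paste0(strrep(unit, n_copies), substr(unit, 1L, partial_len))
  uc <- strsplit(unit, "")[[1]]
  g <- min(5L, p)
  anti <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  left_guard <- paste(vapply(seq.int(p - g + 1L, p),
                             function(k) anti(uc[k]), ""), collapse = "")
  cont <- substr(arr, nchar(arr) - p + 1L, nchar(arr) - p + g)
  right_guard <- paste(vapply(seq_len(g), function(k)
    anti(substr(cont, k, k)), ""), collapse = "")
  flank_l <- paste0(rand_dna(flank), left_guard)
  flank_r <- paste0(right_guard, rand_dna(flank))
  list(seq = paste0(flank_l, arr, flank_r),
       start = nchar(flank_l) + 1L,
       end = nchar(flank_l) + nchar(arr))
}

primitive_unit <- function(p) {
  repeat {
    u <- rand_dna(p)
    d_ok <- TRUE
    for (d in seq_len(p - 1L)) {
      if (p %% d == 0L && strrep(substr(u, 1L, d), p %/% d) == u) {
        d_ok <- FALSE
        break
      }
    }
    if (d_ok) return(u)
  }
}

# --- independent NG86 oracle -------------------------------------------------
# Recomputes Nei-Gojobori quantities for an aligned codon pair list from
# first principles: per-position enumeration for site counts, explicit
# permutation enumeration (via recursion) for pathway averaging, mutations
# to stops nonsynonymous / pathways through stops excluded.

oracle_code <- Biostrings::getGeneticCode("SGC4")
oracle_bases <- c("A", "C", "G", "T")

oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(oracle_bases, ch[pos])) {
      mut <- ch
      mut[pos] <- b
      mc <- paste(mut, collapse = "")
      if (oracle_code[[mc]] != "*" &&
          oracle_code[[mc]] == oracle_code[[codon]])
        s <- s + 1 / 3
    }
  }
  s
}

oracle_pathways <- function(ca, cb) {
  da <- strsplit(ca, "")[[1]]
  db <- strsplit(cb, "")[[1]]
  diffs <- which(da != db)
  if (!length(diffs)) return(c(syn = 0, nonsyn = 0))
  acc <- list()
  walk <- function(cur, remaining, syn, nonsyn) {
    if (!length(remaining)) {
      acc[[length(acc) + 1L]] <<- c(syn = syn, nonsyn = nonsyn)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- db[pos]
      to <- paste(nxt, collapse = "")
      if (oracle_code[[to]] == "*") next
      step_syn <- oracle_code[[paste(cur, collapse = "")]] == oracle_code[[to]]
      walk(nxt, setdiff(remaining, pos),
           syn + as.integer(step_syn), nonsyn + as.integer(!step_syn))
    }
  }
  walk(da, diffs, 0L, 0L)
  if (!length(acc)) return(c(syn = 0, nonsyn = length(diffs)))
  colMeans(do.call(rbind, acc))
}

oracle_ng86 <- function(cds_a, cds_b) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(cds_a)
  cb <- split3(cds_b)
  S <- sum((vapply(ca, oracle_syn_sites, 0) +
              vapply(cb, oracle_syn_sites, 0)) / 2)
  N <- 3 * length(ca) - S
  counts <- rowSums(vapply(seq_along(ca), function(i)
    oracle_pathways(ca[i], cb[i]), numeric(2)))
  ps <- counts["syn"] / S
  pn <- counts["nonsyn"] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = unname(counts["syn"]), Nd = unname(counts["nonsyn"]),
       ps = unname(ps), pn = unname(pn),
       ks = jc(unname(ps)), ka = jc(unname(pn)))
}

random_sense_codons <- function(n) {
  sense <- names(oracle_code)[oracle_code != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# brute-force per-column conservation recount
oracle_inp <- function(rows) {
  L <- nchar(rows[1])
  n_id <- 0L
  for (j in seq_len(L)) {
    col <- substr(rows, j, j)
    if (all(col != "-") && length(unique(col)) == 1L) n_id <- n_id + 1L
  }
  100 * n_id / L
}
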