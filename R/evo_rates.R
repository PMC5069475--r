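#' @title Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#' @name evo_rates
#' @description Synonymous and nonsynonymous substitution rates for a pair
#'   of aligned, gap-free, in-frame coding sequences under the invertebrate
#'   mitochondrial code, with Jukes-Cantor multiple-hit correction, plus the
#'   ordinary least-squares Ka/Ks-vs-GC regression used to relate selective
#'   constraint to base composition across genes.
#'
#'   Conventions: mutations that create a stop codon count as nonsynonymous
#'   in site counting; substitution pathways passing through a stop codon
#'   are excluded from pathway averaging. Sequences must not contain
#'   internal stop codons (strip terminators first).
NULL

BASES <- c("A", "C", "G", "T")

# Fraction of synonymous sites per codon: for each position, the share of
# the three possible point mutations that preserve the amino acid
# (mutations to stop count as nonsynonymous).
codon_syn_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- mito_code()
    sense <- names(code)[code != "*"]
    res <- vapply(sense, function(cod) {
      ch <- seq_chars(cod)
      syn <- 0
      for (p in 1:3) for (b in setdiff(BASES, ch[p])) {
        mut <- ch; mut[p] <- b
        mutc <- paste(mut, collapse = "")
        if (code[[mutc]] != "*" && code[[mutc]] == code[[cod]])
          syn <- syn + 1 / 3
      }
      syn
    }, numeric(1))
    cache <<- res
    res
  }
})

# Average synonymous/nonsynonymous substitution counts between two codons,
# over all orderings of the differing positions that avoid stop codons.
codon_path_counts <- function(cod_a, cod_b) {
  code <- mito_code()
  diff_pos <- which(seq_chars(cod_a) != seq_chars(cod_b))
  k <- length(diff_pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1L) list(diff_pos) else {
    idx <- if (k == 2L) list(1:2, 2:1) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(i) diff_pos[i])
  }
  tot <- c(syn = 0, nonsyn = 0); nvalid <- 0L
  for (ord in perms) {
    cur <- seq_chars(cod_a)
    steps <- c(syn = 0, nonsyn = 0)
    ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- seq_chars(cod_b)[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (code[[to]] == "*") { ok <- FALSE; break }
      if (code[[from]] == code[[to]]) steps["syn"] <- steps["syn"] + 1
      else steps["nonsyn"] <- steps["nonsyn"] + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + steps; nvalid <- nvalid + 1L }
  }
  if (nvalid == 0L) {
    # Every ordering passes through a stop; fall back to counting the
    # direct per-position amino-acid effect so the pair is not dropped.
    cur <- seq_chars(cod_a); tgt <- seq_chars(cod_b)
    return(c(syn = 0, nonsyn = k))
  }
  tot / nvalid
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' Nei-Gojobori (1986) Ka and Ks for an aligned CDS pair
#'
#' Site counts average each codon's synonymous-site fraction over the two
#' sequences; multi-substitution codons average over all stop-free
#' mutational pathways; proportions are Jukes-Cantor corrected. A `pS` or
#' `pN` of 0.75 or more leaves the corresponding rate `NA` with
#' `correction_defined = FALSE`. `ks = 0` leaves `ratio` as `NA` with
#' `ratio_defined = FALSE` (never infinity).
#'
#' @param cds_a,cds_b equal-length, gap-free, in-frame aligned CDS.
#' @return A `kaks_result` list: `ka`, `ks`, `ratio`, `pn`, `ps`,
#'   `n_sites` (c(nonsyn, syn)), `nd`, `sd`, `n_codons`, and the two
#'   definedness flags.
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  validate_dna(c(cds_a, cds_b))
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences must be aligned to equal length")
  if (nchar(cds_a) %% 3L != 0L) stop("alignment length not divisible by 3")
  n_codons <- nchar(cds_a) %/% 3L
  if (n_codons == 0L) stop("empty alignment")
  split_codons <- function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  stops <- mito_stop_codons()
  if (any(ca %in% stops) || any(cb %in% stops))
    stop("internal stop codon in input; strip terminators first")
  syn_tab <- codon_syn_sites()
  amb <- grepl("[^ACGT]", ca) | grepl("[^ACGT]", cb)
  ca <- ca[!amb]; cb <- cb[!amb]
  if (!length(ca)) stop("no unambiguous codons in alignment")
  s_sites <- (syn_tab[ca] + syn_tab[cb]) / 2
  S <- sum(s_sites); N <- 3 * length(ca) - S
  counts <- vapply(seq_along(ca),
                   function(i) codon_path_counts(ca[i], cb[i]), numeric(2))
  Sd <- sum(counts["syn", ]); Nd <- sum(counts["nonsyn", ])
  ps <- Sd / S; pn <- Nd / N
  ks <- jukes_cantor(ps); ka <- jukes_cantor(pn)
  structure(list(
    ka = ka, ks = ks,
    ratio = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
    ratio_defined = !is.na(ka) && !is.na(ks) && ks > 0,
    correction_defined = !is.na(ka) && !is.na(ks),
    pn = pn, ps = ps, nd = Nd, sd = Sd,
    n_sites = c(nonsyn = N, syn = S),
    n_codons = length(ca)), class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4g, Ks = %.4g, Ka/Ks = %s (%d codons)\n",
              x$ka, x$ks,
              if (x$ratio_defined) sprintf("%.4g", x$ratio) else "undefined",
              x$n_codons))
  invisible(x)
}

#' Ordinary least-squares fit of Ka/Ks against G+C content
#'
#' @param points data.frame (or list) with numeric columns/elements
#'   `gc` and `ratio`; at least 3 points.
#' @return A `regression_fit` list: `slope`, `intercept`, `r_squared`.
#' @export
kaks_gc_regression <- function(points) {
  gc <- points$gc; ratio <- points$ratio
  stopifnot(is.numeric(gc), is.numeric(ratio), length(gc) == length(ratio))
  if (length(gc) < 3L) stop("need at least 3 points")
  if (isTRUE(all.equal(var(gc), 0)) || var(gc) == 0)
    stop("zero variance in GC content; regression undefined")
  fit <- lm(ratio ~ gc)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((ratio - mean(ratio))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0),
            class = "regression_fit")
}
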