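test_that("a planted short-period array is recovered exactly", {
  set.seed(31)
  g <- guarded_array_seq("AT", 5L, 0L, flank = 20L)
  det <- detect_tandem_array(g$seq, min_period = 2, max_period = 10,
                             min_copies = 3)
  expect_equal(length(det), 1L)
  expect_equal(det[[1]]$period, 2L)
  expect_equal(det[[1]]$n_full, 5L)
  expect_equal(det[[1]]$start, g$start)
  expect_equal(det[[1]]$end, g$end)
})

test_that("sequences without repeats yield no arrays", {
  expect_equal(detect_tandem_array("ACGT"), list())
  set.seed(32)
  expect_equal(detect_tandem_array(rand_dna(60)), list())
})

test_that("decomposer is exact on random (p, c) arrays with partials", {
  set.seed(33)
  for (trial in 1:25) {
    p <- sample(5:40, 1)
    cc <- sample(3:60, 1)
    unit <- primitive_unit(p)
    partial_len <- sample(0:(p - 1), 1)
    g <- guarded_array_seq(unit, cc, partial_len)
    det <- detect_tandem_array(g$seq)
    expect_gte(length(det), 1L)
    main <- det[[which.max(vapply(det, `[[`, 0L, "length"))]]
    expect_equal(main$period, p)
    expect_equal(main$start, g$start)
    expect_equal(main$end, g$end)
    expect_equal(main$n_full, cc)
    expect_equal(main$partial_length, partial_len)
    # unit-length bookkeeping
    expect_equal(sum(main$units$length), main$length)
  }
})

test_that("the reference-default synthetic array decomposes to 53 x 18 = 949", {
  arr <- generate_repeat_array(cr_config(), seed = 1)
  det <- detect_tandem_array(arr$seq)
  expect_equal(length(det), 1L)
  a <- det[[1]]
  expect_equal(a$period, 18L)
  expect_equal(a$n_full + a$n_partial, 53L)
  expect_equal(a$length, 949L)
  expect_equal(52L * 18L + 13L, 949L)
  expect_equal(sum(a$units$length), 949L)
})

test_that("unit classification recovers planted types and variable sites", {
  # all units identical -> one type, no variable sites
  one <- detect_tandem_array(strrep("GATTACAT", 6), min_period = 5)[[1]]
  ut1 <- classify_units(one)
  expect_equal(length(ut1$variable_sites), 0L)
  expect_equal(unname(ut1$counts), 6L)

  # reference-default: 4 types at 2 sites with counts 18/15/15/4
  arr <- generate_repeat_array(cr_config(), seed = 2)
  a <- detect_tandem_array(arr$seq)[[1]]
  ut <- classify_units(a)
  expect_equal(length(ut$variable_sites), 2L)
  expect_equal(unname(ut$counts), c(18L, 15L, 15L, 4L))
  expect_equal(ut$labels, arr$truth$labels)
  expect_equal(ut$partial_label, 1L)

  # 3 planted variants at one interior site (a variable site in the
  # outermost unit positions would make the true phase ambiguous)
  set.seed(34)
  base <- "GAACCTGGA"
  v2 <- "GAACTTGGA"
  v3 <- "GAACGTGGA"
  seqs <- c(rep(base, 5), rep(v2, 3), rep(v3, 2))[sample(10)]
  a3 <- detect_tandem_array(paste(seqs, collapse = ""), min_period = 5)[[1]]
  expect_equal(a3$n_full, 10L)
  ut3 <- classify_units(a3)
  expect_equal(ut3$variable_sites, 5L)
  expect_equal(sort(unname(ut3$counts), decreasing = TRUE), c(5L, 3L, 2L))
})

test_that("rare residue combinations fold into the nearest major type", {
  units <- c(rep("AAAATT", 4), rep("AACATT", 3), "TAAATT")  # singleton at site 1
  arr <- detect_tandem_array(paste(units, collapse = ""), min_period = 6,
                             min_identity = 0.6)[[1]]
  ut <- classify_units(arr, min_minor_count = 2)
  expect_equal(length(ut$counts), 2L)
  expect_equal(sum(ut$counts), 8L)
})

test_that("adjacency patterns evaluate every-X-followed-by-Y rules", {
  fake <- structure(list(
    variable_sites = 1L, labels = c(1L, 2L, 3L, 1L, 2L, 3L),
    counts = c(`1` = 2L, `2` = 2L, `3` = 2L),
    adjacency = NULL, partial_label = NA_integer_), class = "unit_types")
  adj <- matrix(0L, 3, 3, dimnames = list(1:3, 1:3))
  for (i in 1:5) adj[fake$labels[i], fake$labels[i + 1]] <-
    adj[fake$labels[i], fake$labels[i + 1]] + 1L
  fake$adjacency <- adj
  rep1 <- adjacency_patterns(fake, queries = list(c(1, 2)))
  expect_true(rep1$rules$holds)
  expect_equal(rep1$adjacency["1", "2"], 2L)
  expect_equal(rep1$adjacency["2", "3"], 2L)
  expect_equal(rep1$adjacency["3", "1"], 1L)

  fake$labels <- c(4L, 2L, 4L, 2L)
  fake$counts <- c(`1` = 0L, `2` = 2L, `3` = 0L, `4` = 2L)
  expect_true(adjacency_patterns(fake, list(c(4, 2)))$rules$holds)
  fake$labels <- c(4L, 3L)
  expect_false(adjacency_patterns(fake, list(c(4, 2)))$rules$holds)
  fake$labels <- 2L
  expect_error(adjacency_patterns(fake), "at least 2")
})

test_that("homopolymer scanner reports maximal runs at the threshold", {
  hits <- find_homopolymers("TTACCCCCCCCGA", min_len = 8)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "C")
  expect_equal(hits$end - hits$start + 1L, 8L)
  expect_equal(nrow(find_homopolymers("ACACACAC", min_len = 3)), 0L)
  # lowercase input is normalized before run counting
  expect_equal(nrow(find_homopolymers(tolower("GAAAAAAAAG"), min_len = 8)), 1L)
})

test_that("microsatellite scanner finds the reference tract patterns", {
  m1 <- find_microsatellites(paste0("GGC", strrep("AATTT", 3), "CCG"))
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$motif, "AATTT")
  expect_equal(m1$copies, 3L)
  m2 <- find_microsatellites(paste0("GC", strrep("TA", 5), "GC"))
  expect_equal(m2$motif, "TA")
  expect_equal(m2$copies, 5L)
  # homopolymer runs are not unit-2 microsatellites
  expect_equal(nrow(find_microsatellites("GAAAAG")), 0L)
  # reducible units reported at the shortest period
  m3 <- find_microsatellites(paste0("GC", strrep("AT", 6), "GC"))
  expect_true(all(nchar(m3$motif) == 2L))
})

test_that("content blocks merge qualifying windows and recompute content", {
  all_a <- strrep("A", 60)
  b <- content_blocks(all_a, window = 20, threshold = 0.9, mode = "AT")
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(1L, 60L))
  expect_equal(b$content, 1)
  alt <- strrep("ACGT", 20)
  expect_equal(nrow(content_blocks(alt, 20, 0.9, "AT")), 0L)
  expect_error(content_blocks("ACGT", 10, 0.9, "AT"), "window")
})

test_that("hairpin search finds a perfect inverted repeat with TATA element", {
  s <- paste0("TATA", "GGGGGG", "AAAA", "CCCCCC")
  h <- find_hairpin(s, min_stem = 4, max_loop = 8)
  expect_gte(nrow(h), 1L)
  expect_equal(h$stem[1], 6L)
  expect_equal(h$loop[1], 4L)
  expect_equal(h$mismatches[1], 0L)
  expect_true(h$tata_upstream[1])
  expect_equal(nrow(find_hairpin(strrep("A", 40), min_stem = 6)), 0L)
})

test_that("hairpin search agrees with an exhaustive triple-loop oracle", {
  oracle_hairpins <- function(s, min_stem, max_loop, max_mm) {
    sc <- strsplit(s, "")[[1]]
    comp <- chartr("ACGT", "TGCA", sc)
    out <- list()
    for (i in seq_along(sc)) for (stem in min_stem:((length(sc)) %/% 2))
      for (loop in 3:max_loop) {
        e <- i + 2 * stem + loop - 1
        if (e > length(sc)) next
        mm <- sum(sc[i:(i + stem - 1)] !=
                    rev(comp[(i + stem + loop):e]))
        if (mm <= max_mm)
          out[[length(out) + 1]] <- c(i, e, stem, loop, mm)
      }
    if (!length(out)) return(matrix(numeric(), ncol = 5))
    do.call(rbind, out)
  }
  set.seed(35)
  for (i in 1:5) {
    s <- rand_dna(50)
    got <- find_hairpin(s, min_stem = 6, max_loop = 10, max_mismatch = 0,
                        maximal_only = FALSE)
    want <- oracle_hairpins(s, 6, 10, 0)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      ord_g <- order(got$start, got$end, got$stem)
      ord_w <- order(want[, 1], want[, 2], want[, 3])
      expect_equal(got$start[ord_g], want[ord_w, 1])
      expect_equal(got$end[ord_g], want[ord_w, 2])
    }
  }
})

test_that("partition tiles the reference-default control region in order", {
  g <- generate_control_region(cr_config(), seed = 1)
  p <- partition_control_region(g$seq)
  expect_identical(p$segments$kind,
                   c("gc_block", "microsatellite", "poly_tract",
                     "microsatellite", "at_block", "poly_tract", "linker",
                     "tandem_array", "linker", "hairpin"))
  # tiling invariant
  expect_equal(p$segments$start[1], 1L)
  expect_equal(p$segments$end[nrow(p$segments)], nchar(g$seq))
  expect_true(all(p$segments$start[-1] ==
                    p$segments$end[-nrow(p$segments)] + 1L))
  expect_true(p$hairpin$tata_upstream)
})

test_that("partition of degenerate inputs follows the contract", {
  set.seed(36)
  # a random sequence verified to trigger no scanner: shorter than the
  # content window (window-based content scanning needs window <= length)
  # and rejection-sampled against the remaining scanners
  repeat {
    s <- rand_dna(39)
    if (length(detect_tandem_array(s)) == 0L &&
        nrow(find_microsatellites(s)) == 0L &&
        nrow(find_homopolymers(s, min_len = 8)) == 0L &&
        nrow(find_hairpin(s, min_stem = 6, max_loop = 20,
                          max_mismatch = 1)) == 0L) break
  }
  r <- partition_control_region(s)
  expect_equal(r$segments$kind, "unassigned")
  expect_equal(r$segments$length, 39L)

  arr <- generate_repeat_array(cr_config(), seed = 3)
  pa <- partition_control_region(arr$seq)
  expect_equal(pa$segments$kind, "tandem_array")
})
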