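test_that("INP% matches hand counts and definitions", {
  p1 <- inp_percent(c("ACGTACGT", "ACGTACGT"))
  expect_equal(p1$inp_percent, 100)
  p2 <- inp_percent(c("AC", "AG"))
  expect_equal(p2$inp_percent, 50)
  expect_equal(unname(p2$classes), c("identical", "variable"))
  expect_error(inp_percent("ACGT"), "at least 2")
})

test_that("gap columns cannot be identical; ge80 uses full-row denominator", {
  p <- inp_percent(c("A-C", "A-C", "AAC", "AAC", "AAC"))
  expect_equal(unname(p$classes), c("identical", "variable", "identical"))
  # 8/10 rows share the modal residue, column not identical -> ge80
  rows <- c(rep("A", 8), "C", "G")
  p2 <- inp_percent(rows)
  expect_equal(unname(p2$classes), "ge80")
})

test_that("INP% equals a brute-force per-column recount on random alignments", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    L <- sample(20:80, 1)
    rows <- vapply(seq_len(n), function(j)
      rand_dna(L, bases = c("A", "C", "G", "T", "-")), "")
    expect_equal(inp_percent(rows)$inp_percent, oracle_inp(rows))
  }
})

test_that("INP% is row-permutation invariant and duplicate-row stable", {
  set.seed(62)
  rows <- vapply(1:6, function(i) rand_dna(50), "")
  p0 <- inp_percent(rows)
  expect_equal(inp_percent(rows[sample(6)])$inp_percent, p0$inp_percent)
  expect_equal(inp_percent(c(rows, rows[1]))$classes, p0$classes)
  expect_true(p0$inp_percent >= 0 && p0$inp_percent <= 100)
})

test_that("region conservation splits INP% by structure annotation", {
  rows <- rep("ACGTACGT", 3)
  st <- rep(c("stem", "loop"), each = 4)
  rc <- region_conservation(rows, st)
  expect_equal(rc$inp_percent, c(100, 100))
  # variation planted only in loop columns
  st2 <- rep(c("stem", "loop"), each = 35)
  g <- generate_family_alignment(8, structure = st2,
                                 p_identity = c(stem = 1, loop = 0.2),
                                 seed = 63)
  rc2 <- region_conservation(g$alignment, st2)
  expect_equal(rc2$inp_percent[rc2$region == "stem"], 100)
  expect_lt(rc2$inp_percent[rc2$region == "loop"], 100)
  expect_error(region_conservation(rows, c("stem", "loop")), "length")
})

test_that("center-star alignment handles identity, indels, and bounds", {
  a1 <- center_star_align(c("ACGTT", "ACGTT", "ACGTT"))
  expect_false(any(grepl("-", a1$seqs)))
  a2 <- center_star_align(c("ACGT", "ACT"))
  expect_equal(a2$length, 4L)
  expect_equal(sum(strsplit(a2$seqs[2], "")[[1]] == "-"), 1L)
  expect_identical(gsub("-", "", a2$seqs[2]), "ACT")
  set.seed(64)
  seqs <- vapply(1:5, function(i) rand_dna(sample(50:70, 1)), "")
  a3 <- center_star_align(seqs)
  expect_gte(a3$length, max(nchar(seqs)))
  # rows de-gap back to their inputs
  expect_identical(gsub("-", "", a3$seqs), unname(seqs))
  expect_error(center_star_align(character()), "no sequences")
})

test_that("strand contrast reports per-strand mean INP%", {
  profs <- list(
    `tRNA-Ile` = inp_percent(rep("ACGT", 3)),
    `tRNA-Gln` = inp_percent(c("AAAA", "CCCC", "GGGG")),
    `tRNA-Met` = inp_percent(rep("TTTT", 3)))
  sm <- c(`tRNA-Ile` = "J", `tRNA-Gln` = "N", `tRNA-Met` = "J")
  cc <- strand_conservation_contrast(profs, sm)
  expect_equal(unname(cc$mean_by_strand["J"]), 100)
  expect_equal(unname(cc$mean_by_strand["N"]), 0)
  expect_error(strand_conservation_contrast(profs, sm[1:2]), "missing")
})

test_that("planted J > N conservation is recovered from synthetic families", {
  profs <- list()
  strand_map <- character()
  for (i in 1:3) {
    gj <- generate_family_alignment(8, 70, 0.8, seed = 70 + i)
    gn <- generate_family_alignment(8, 70, 0.3, seed = 80 + i)
    profs[[paste0("J", i)]] <- inp_percent(gj$alignment)
    profs[[paste0("N", i)]] <- inp_percent(gn$alignment)
    strand_map[paste0("J", i)] <- "J"
    strand_map[paste0("N", i)] <- "N"
  }
  cc <- strand_conservation_contrast(profs, strand_map)
  expect_gt(cc$mean_by_strand["J"], cc$mean_by_strand["N"])
})
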