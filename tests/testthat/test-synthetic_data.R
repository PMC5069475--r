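test_that("generators are pure functions of (config, seed)", {
  expect_identical(generate_repeat_array(cr_config(), seed = 5),
                   generate_repeat_array(cr_config(), seed = 5))
  expect_identical(generate_control_region(cr_config(), seed = 5)$seq,
                   generate_control_region(cr_config(), seed = 5)$seq)
  expect_identical(generate_mitogenome(seed = 5)$genome,
                   generate_mitogenome(seed = 5)$genome)
  expect_false(identical(generate_repeat_array(cr_config(), seed = 5)$seq,
                         generate_repeat_array(cr_config(), seed = 6)$seq))
})

test_that("the default repeat array honors counts, rules, and length", {
  arr <- generate_repeat_array(cr_config(), seed = 9)
  expect_equal(nchar(arr$seq), 949L)
  lab <- arr$truth$labels
  expect_equal(as.integer(table(factor(lab, 1:4))), c(18L, 15L, 15L, 4L))
  # every IV followed by II; every III preceded by II and followed by I
  p4 <- which(lab == 4L)
  expect_true(all(p4 < length(lab)) && all(lab[p4 + 1L] == 2L))
  p3 <- which(lab == 3L)
  expect_true(all(lab[p3 - 1L] == 2L))
  expect_true(all(lab[pmin(p3 + 1L, length(lab))] == 1L))
  # terminal partial is the 13-bp Type I prefix
  expect_identical(substr(arr$seq, 949 - 12, 949),
                   substr(cr_config()$unit_templates[["I"]], 1, 13))
})

test_that("degenerate repeat-array configurations behave per contract", {
  cfg <- cr_config(type_counts = c(2L, 0L, 0L, 0L), with_partial = FALSE)
  arr <- generate_repeat_array(cfg, seed = 1)
  expect_equal(arr$truth$labels, c(1L, 1L))
  expect_equal(nchar(arr$seq), 36L)

  bad <- cr_config(type_counts = c(0L, 0L, 0L, 1L), with_partial = FALSE)
  expect_error(generate_repeat_array(bad, seed = 1), "followed by type 2")
})

test_that("the generated control region has the configured layout", {
  g <- generate_control_region(cr_config(), seed = 2)
  # 321 + 15 + 8 + 10 + 103 + 8 + 34 + 949 + (34+4) + 32
  expect_equal(nchar(g$seq), 1518L)
  expect_identical(g$truth$segments$kind,
                   c("gc_block", "microsatellite", "poly_tract",
                     "microsatellite", "at_block", "poly_tract", "linker",
                     "tandem_array", "linker", "hairpin"))
  at <- g$truth$segments[g$truth$segments$kind == "at_block", ]
  at_seq <- substr(g$seq, at$start, at$end)
  expect_equal(at$end - at$start + 1L, 103L)
  comp <- base_composition(at_seq)
  expect_gt(comp$a + comp$t, 0.8)
})

test_that("control-region dissection recovers the generated ground truth", {
  for (sd in c(4, 11)) {
    g <- generate_control_region(cr_config(), seed = sd)
    p <- partition_control_region(g$seq)
    expect_identical(p$segments$kind, g$truth$segments$kind)
    main <- p$arrays[[which.max(vapply(p$arrays, `[[`, 0L, "length"))]]
    expect_equal(main$start, g$truth$array_start)
    expect_equal(main$end, g$truth$array_end)
    expect_equal(main$period, 18L)
  }
})

test_that("generated mitogenomes have the annotated architecture", {
  gm <- generate_mitogenome(seed = 3)
  expect_equal(nchar(gm$genome), 16345L)
  expect_equal(substr(gm$genome, 3984, 3990), "ATGATAA")
  expect_equal(substr(gm$genome, 9311, 9317), "ATGATAA")
  # skew recovery outside the structured control-region slot
  gm0 <- generate_mitogenome(composition = list(at = 0.76, at_skew = 0,
                                                gc_skew = 0), seed = 4)
  body <- substr(gm0$genome, 1, 14492)
  comp <- base_composition(body)
  s <- skew(comp)
  n_at <- (comp$a + comp$t) * comp$n_counted
  n_gc <- (comp$g + comp$c) * comp$n_counted
  expect_lt(abs(s$at_skew), 3 / sqrt(n_at))
  expect_lt(abs(s$gc_skew), 3 / sqrt(n_gc))
})

test_that("family-alignment generator plants the requested conservation", {
  g1 <- generate_family_alignment(10, 400, 1, seed = 5)
  expect_equal(inp_percent(g1$alignment)$inp_percent, 100)
  g2 <- generate_family_alignment(10, 1000, 0.5, seed = 6)
  inp <- inp_percent(g2$alignment)$inp_percent
  se <- 100 * sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(inp - 50), 3 * se + 1)  # +1 for rare accidental identity
  expect_equal(inp_percent(g2$alignment)$inp_percent,
               100 * mean(g2$truth$planted_identical),
               tolerance = 0.02)
})

test_that("CDS-pair generator respects its event probabilities exactly", {
  g0 <- generate_cds_pair(200, syn_prob = 0, nonsyn_prob = 0.05, seed = 7)
  r0 <- ng86_kaks(g0$cds_a, g0$cds_b)
  expect_equal(r0$ks, 0)
  expect_false(r0$ratio_defined)
  g1 <- generate_cds_pair(200, syn_prob = 0.05, nonsyn_prob = 0, seed = 8)
  r1 <- ng86_kaks(g1$cds_a, g1$cds_b)
  expect_equal(r1$ka, 0)
  # single-base events are classified without pathway ambiguity
  expect_equal(r1$sd, g1$truth$n_syn)
  expect_equal(r0$nd, g0$truth$n_nonsyn)
})
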