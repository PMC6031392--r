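# Degenerate matching, binding-site scanning, in-silico PCR and
# discriminative primer design.

test_that("degenerate matching follows IUPAC set semantics", {
  expect_equal(iupac_mismatches("R", "A"), 0L)
  expect_equal(iupac_mismatches("R", "G"), 0L)
  expect_equal(iupac_mismatches("R", "C"), 1L)
  expect_equal(iupac_mismatches("M", "C"), 0L)
  # N in the target never matches, even against primer N
  expect_equal(iupac_mismatches("N", "N"), 1L)
  expect_equal(iupac_mismatches("A", "N"), 1L)
  # identity of a non-degenerate window
  expect_equal(iupac_mismatches("ACGTACGT", "ACGTACGT"), 0L)
  expect_error(iupac_mismatches("ACGT", "ACG"), "length")
  # the engineered primer differs from the matched consensus at exactly
  # the deliberate position
  matched_target <- endoamp:::disambiguate_primer(primer_matched_771r()$sequence)
  expect_equal(iupac_mismatches(primer_en771r()$sequence, matched_target), 1L)
})

test_that("set-semantic matching equals the exhaustive expansion minimum", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      n_deg <- sample(0:4, 1L)
      len <- 12L
      pr <- sample(c("A", "C", "G", "T"), len, TRUE)
      if (n_deg > 0) {
        pos <- sample(len, n_deg)
        pr[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), n_deg, TRUE)
      }
      pr <- paste(pr, collapse = "")
      tg <- rand_dna(len)
      expect_equal(iupac_mismatches(pr, tg), oracle_min_mismatch(pr, tg))
    }
  })
})

test_that("binding-site scan finds planted sites on both strands and matches a brute-force scan", {
  fwd <- primer_27f()
  rev <- primer_en771r()
  withr::with_seed(21, {
    tpl <- rand_dna(1000)
    planted <- endoamp:::disambiguate_primer(fwd$sequence)
    substr(tpl, 101, 120) <- planted
    hits <- scan_binding_sites(fwd, tpl, max_mm = 0L)
    expect_true(any(hits$start == 100L & hits$end == 120L))
    expect_true(all(hits$strand == "+"))
    # reverse primer planted as its reverse complement
    tpl2 <- rand_dna(1000)
    substr(tpl2, 501, 520) <- endoamp:::revcomp(
      endoamp:::disambiguate_primer(rev$sequence))
    rhits <- scan_binding_sites(rev, tpl2, max_mm = 0L)
    expect_true(any(rhits$start == 500L & rhits$mismatches == 0L))
    expect_true(all(rhits$strand == "-"))
    # exhaustive-oracle agreement on random templates
    for (rep in 1:5) {
      tpl3 <- rand_dna(1000)
      for (p in list(fwd, rev)) {
        got <- scan_binding_sites(p, tpl3, max_mm = 3L)
        want <- oracle_scan(p, tpl3, max_mm = 3L)
        expect_equal(got$start, want$start)
        expect_equal(got$mismatches, want$mismatches)
      }
    }
  })
})

test_that("amplicon prediction honors coordinates, the mismatch cap and the 3' rule", {
  fwd <- primer_27f()
  rev <- primer_en771r()
  withr::with_seed(31, {
    tpl <- rand_dna(900)
    substr(tpl, 101, 120) <- endoamp:::disambiguate_primer(fwd$sequence)
    substr(tpl, 831, 850) <- endoamp:::revcomp(
      endoamp:::disambiguate_primer(rev$sequence))
    pred <- predict_amplicon(fwd, rev, tpl)
    expect_equal(pred$fwd_start, 100L)
    expect_equal(pred$rev_end, 850L)
    expect_equal(pred$length, 750L)
    # mismatch within the 3'-terminal protect zone kills amplification
    # even under a generous total budget: the forward primer's 3' end is
    # template positions 117..120
    tpl_bad <- tpl
    substr(tpl_bad, 119, 119) <- chartr("ACGT", "CATG", substr(tpl_bad, 119, 119))
    expect_null(predict_amplicon(fwd, rev, tpl_bad, max_mm = 2L,
                                 three_prime_protect = 4L))
    # the same substitution outside the protect zone is tolerated
    tpl_ok <- tpl
    substr(tpl_ok, 105, 105) <- chartr("ACGT", "CATG", substr(tpl_ok, 105, 105))
    expect_false(is.null(predict_amplicon(fwd, rev, tpl_ok, max_mm = 2L)))
  })
})

test_that("near-neighbor template amplifies with the matched primer but not the engineered one", {
  panel <- make_cag_panel(n_target = 5L, n_outgroup = 5L, seed = 13)
  neighbor <- panel$seq[grepl("Simiduia", panel$id)][1L]
  target <- panel$seq[grepl("Endozoicomonas", panel$id)][1L]
  expect_null(predict_amplicon(primer_27f(), primer_en771r(), neighbor,
                               max_mm = 1L))
  expect_false(is.null(predict_amplicon(primer_27f(), primer_matched_771r(),
                                        neighbor, max_mm = 1L)))
  expect_false(is.null(predict_amplicon(primer_27f(), primer_en771r(),
                                        target, max_mm = 1L)))
})

test_that("predictions are invariant under reverse-complementing the template and swapping orientations", {
  fwd <- primer_27f()
  rev <- primer_en771r()
  # on the reverse-complemented template the specific primer acts as the
  # forward primer and the universal one as the reverse
  fwd_swapped <- degenerate_primer(rev$name, rev$sequence, "forward")
  rev_swapped <- degenerate_primer(fwd$name, fwd$sequence, "reverse")
  panel <- make_cag_panel(n_target = 3L, n_outgroup = 1L, seed = 17)
  for (tpl in panel$seq[grepl("Endozoicomonas", panel$id)]) {
    a <- predict_amplicon(fwd, rev, tpl)
    b <- predict_amplicon(fwd_swapped, rev_swapped, endoamp:::revcomp(tpl))
    expect_false(is.null(a))
    expect_false(is.null(b))
    expect_equal(a$length, b$length)
    expect_equal(a$fwd_mm + a$rev_mm, b$fwd_mm + b$rev_mm)
    # mirrored coordinates
    expect_equal(b$fwd_start, nchar(tpl) - a$rev_end)
  }
})

test_that("primer design separates targets and engineers a deliberate mismatch when needed", {
  # toy alignment: one column separates targets (T) from outgroups (A)
  base <- withr::with_seed(41, rand_dna(30))
  tgt <- base
  substr(tgt, 15, 15) <- "T"
  ogr <- base
  substr(ogr, 15, 15) <- "A"
  des <- design_discriminative_primer(
    c(tgt, tgt), c(ogr, ogr),
    params = list(window = 20L, min_outgroup_mm = 1L, max_engineered = 0L))
  expect_gt(nrow(des), 0L)
  expect_true(all(des$min_outgroup_mm >= 1L))
  expect_true(all(is.na(des$engineered_pos)))

  # indistinguishable outgroups: empty result with a diagnostic
  expect_message(
    res <- design_discriminative_primer(
      c(tgt, tgt), c(tgt, tgt),
      params = list(window = 20L, min_outgroup_mm = 1L)),
    "indistinguishable")
  expect_equal(nrow(res), 0L)
})

test_that("deliberate-mismatch engineering recreates the CAG-repeat discrimination", {
  # target site vs near-neighbor site (1 natural mismatch): the matched
  # consensus hits the outgroup with <= 1 mismatch; a single engineered
  # base must push it to >= 2 while keeping targets within 1 mismatch
  flank <- withr::with_seed(43, rand_dna(10))
  tgt_row <- paste0(flank, CAG_TARGET_SITE, flank)
  ogr_row <- paste0(flank, CAG_NEIGHBOR_SITE, flank)
  des <- design_discriminative_primer(
    c(tgt_row, tgt_row, tgt_row), c(ogr_row, ogr_row),
    params = list(window = 20L, min_outgroup_mm = 2L, max_engineered = 1L,
                  max_target_mm = 1L))
  expect_gt(nrow(des), 0L)
  expect_true(all(des$min_outgroup_mm >= 2L))
  expect_true(all(des$target_mm_sum <= 3L))  # <= 1 per target sequence
  expect_true(any(!is.na(des$engineered_pos)))
  # without engineering no candidate can reach the threshold
  expect_message(
    des0 <- design_discriminative_primer(
      c(tgt_row, tgt_row, tgt_row), c(ogr_row, ogr_row),
      params = list(window = 20L, min_outgroup_mm = 2L, max_engineered = 0L)))
  expect_equal(nrow(des0), 0L)
})

test_that("panel evaluation reports sensitivity and specificity with correct edge cases", {
  # constructed panel: targets amplifiable, outgroups blocked (>= 2
  # mismatches at the specific site under max_mm = 1)
  panel <- make_cag_panel(n_target = 20L, n_outgroup = 20L, seed = 19)
  ev <- evaluate_primer_pair(primer_27f(), primer_en771r(), panel,
                             "Endozoicomonas")
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)
  # removing the engineered mismatch strictly decreases specificity
  ev_matched <- evaluate_primer_pair(primer_27f(), primer_matched_771r(),
                                     panel, "Endozoicomonas")
  expect_equal(ev_matched$sensitivity, 1.0)
  expect_lt(ev_matched$specificity, ev$specificity)
  # empty denominator: nothing amplifies on a site-free panel
  withr::with_seed(23, {
    blank <- data.frame(id = c("x1", "x2"),
                        lineage = rep("Bacteria;P;C;O;F;GenX", 2L),
                        seq = replicate(2L, rand_dna(500)))
  })
  ev0 <- evaluate_primer_pair(primer_27f(), primer_en771r(), blank, "GenX")
  expect_true(is.nan(ev0$specificity))
  expect_equal(ev0$n_amplified, 0L)
  expect_error(evaluate_primer_pair(primer_27f(), primer_en771r(), panel,
                                    "NoSuchGenus"), "matches no panel record")
})
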