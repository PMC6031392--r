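# Template-guided alignment, complete-deletion masking, K2P distances,
# group divergence and neighbor-joining trees.

test_that("template alignment projects queries onto the reference frame", {
  withr::with_seed(51, {
    refseq <- rand_dna(120L)
  })
  # reference row with two gap columns
  ref_row <- paste0(substr(refseq, 1, 60), "--", substr(refseq, 61, 120))
  ref <- c(refA = ref_row)
  # identical query (gaps removed) projects back to the reference row
  expect_equal(template_align(refseq, ref), ref_row)
  # one internal deletion appears as a gap at the deleted column
  del_pos <- 30L
  query <- paste0(substr(refseq, 1, del_pos - 1L),
                  substr(refseq, del_pos + 1L, 120L))
  row <- template_align(query, ref)
  expect_equal(nchar(row), nchar(ref_row))
  ch <- strsplit(row, "")[[1L]]
  expect_equal(ch[del_pos], "-")
  expect_equal(sum(ch == "-"), 3L)  # deletion + the two reference gap columns
  # projection contract: output length always equals the column count
  withr::with_seed(52, {
    for (rep in 1:5) {
      q <- paste0(substr(refseq, 10, 50), rand_dna(5L), substr(refseq, 51, 100))
      expect_equal(nchar(template_align(q, ref)), nchar(ref_row))
    }
  })
  expect_error(template_align(strrep("A", 50L), ref), "no 8-mers")
})

test_that("complete deletion removes gap and missing-data columns and is idempotent", {
  aln <- c(a = "ACGTACGTAC", b = "AC-TACGTAC", c = "ACGTACNTAC")
  m <- mask_gap_columns(aln)
  expect_equal(m$retained, 8L)
  expect_equal(nchar(m$alignment[["a"]]), 8L)
  # gap-free alignment unchanged
  clean <- c(a = "ACGT", b = "TTTT")
  expect_equal(mask_gap_columns(clean)$alignment, clean)
  # idempotent
  expect_equal(mask_gap_columns(m$alignment)$alignment, m$alignment)
  expect_error(mask_gap_columns(c(a = "-N-", b = "AAA")), "no columns")
})

test_that("K2P distances match closed-form values and flag saturation", {
  k0 <- k2p_distance("GATTACA", "GATTACA")
  expect_equal(k0$d, 0)
  expect_equal(k0$P, 0)
  expect_equal(k0$Q, 0)
  k1 <- k2p_distance("GATTACA", "GATTGCA")  # one transition, L = 7
  expect_equal(k1$P, 1 / 7)
  expect_equal(k1$Q, 0)
  expect_equal(k1$d, 0.1682, tolerance = 5e-4)
  k2 <- k2p_distance("AAAA", "ACAA")        # one transversion, L = 4
  expect_equal(k2$P, 0)
  expect_equal(k2$Q, 0.25)
  expect_equal(k2$d, 0.3171, tolerance = 1e-4)
  ks <- k2p_distance("AAAA", "GGGG")        # all transitions: saturated
  expect_true(ks$saturated)
  expect_true(is.na(ks$d))
  expect_error(k2p_distance("AAA", "AAAA"), "length")
})

test_that("the K2P matrix agrees with an independent reference implementation", {
  withr::with_seed(53, {
    base <- rand_dna(400L)
    aln <- setNames(c(base,
                      mutate_at(base, sample(400L, 12L)),
                      mutate_at(base, sample(400L, 30L)),
                      mutate_at(base, sample(400L, 50L))),
                    paste0("t", 1:4))
  })
  got <- k2p_matrix(aln)$d
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln), "")))
  want <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(unname(got), unname(want[rownames(got), colnames(got)]),
               tolerance = 1e-10)
})

test_that("the K2P correction dominates and converges to the p-distance", {
  withr::with_seed(54, {
    for (rep in 1:20) {
      L <- 500L
      a <- rand_dna(L)
      b <- mutate_at(a, sample(L, sample(1:120, 1L)))
      k <- k2p_distance(a, b)
      if (k$saturated) next
      p <- p_distance(a, b)
      expect_gte(k$d, p - 1e-12)
    }
    # convergence: the Taylor remainder is O((P+Q)^2)
    a <- rand_dna(1000L)
    b1 <- mutate_at(a, sample(1000L, 10L))  # P + Q = 0.01
    k1 <- k2p_distance(a, b1)
    expect_lt(abs(k1$d - p_distance(a, b1)), 1.5e-4)
    a2 <- rand_dna(10000L)
    b2 <- mutate_at(a2, sample(10000L, 10L))  # P + Q = 0.001
    k2 <- k2p_distance(a2, b2)
    expect_lt(abs(k2$d - p_distance(a2, b2)), 1.5e-6)
  })
})

test_that("group divergence recovers simulated within- and between-clade distances", {
  # all-identical rows: all means and SEs are zero
  same <- setNames(rep(strrep("ACGT", 50L), 4L), paste0("s", 1:4))
  gd0 <- group_divergence(same, setNames(rep(c("g1", "g2"), each = 2L),
                                         names(same)),
                          n_site_bootstrap = 20L, seed = 1L)
  expect_true(all(gd0$mean_d == 0))
  expect_true(all(gd0$se == 0))
  # two clades with expected pairwise within-distance 2 x 0.025 = 0.05 and
  # clearly larger between-distance
  clades <- list(
    clade_spec("GenA", 6L, 0.025, stem = 0.05, taxonomy_prefix = "B;P;C;O;F"),
    clade_spec("GenB", 6L, 0.025, stem = 0.05, taxonomy_prefix = "B;P;C;O;F")
  )
  panel <- evolve_reference_panel(600L, clades, list(), seed = 42L)
  aln <- setNames(panel$seq, panel$id)
  groups <- setNames(sub("_.*", "", panel$id), panel$id)
  gd <- group_divergence(aln, groups, n_site_bootstrap = 100L, seed = 5L)
  within <- gd[gd$comparison == "within", ]
  between <- gd[gd$comparison == "between", ]
  expect_true(all(within$mean_d < between$mean_d))
  for (i in seq_len(nrow(within))) {
    expect_lt(abs(within$mean_d[i] - 0.05), 3 * within$se[i] + 0.01)
  }
  # SE is reproducible under a fixed seed
  gd2 <- group_divergence(aln, groups, n_site_bootstrap = 100L, seed = 5L)
  expect_identical(gd$se, gd2$se)
})

test_that("neighbor joining recovers additive matrices exactly", {
  # 4 taxa, AB|CD with all leaf and internal branches derivable
  d <- matrix(0.4, 4L, 4L, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.2
  tr <- nj_tree(d)
  expect_equal(sort(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]),
               sort(d), tolerance = 1e-10)
  split_ok <- ape::is.monophyletic(ape::root(tr, "C"), c("A", "B"))
  expect_true(split_ok)
  # 3 taxa: unique topology, three-point branch lengths
  d3 <- matrix(c(0, .3, .5, .3, 0, .4, .5, .4, 0), 3L,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(d3)
  expect_equal(ape::cophenetic.phylo(tr3)[c("x", "y", "z"), c("x", "y", "z")],
               d3, tolerance = 1e-10)
  # randomized additive matrices from random trees
  withr::with_seed(55, {
    for (rep in 1:8) {
      am <- random_additive_matrix(sample(5:9, 1L))
      tr_r <- nj_tree(am$d)
      got <- ape::cophenetic.phylo(tr_r)[rownames(am$d), colnames(am$d)]
      expect_equal(got, am$d, tolerance = 1e-8)
    }
  })
  bad <- d
  bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("site-bootstrap support is high for a clean two-clade split and Newick round-trips", {
  clades <- list(
    clade_spec("GenA", 4L, 0.01, stem = 0.08, taxonomy_prefix = "B;P;C;O;F"),
    clade_spec("GenB", 4L, 0.01, stem = 0.08, taxonomy_prefix = "B;P;C;O;F")
  )
  panel <- evolve_reference_panel(500L, clades, list(), seed = 77L)
  aln <- setNames(panel$seq, panel$id)
  dm <- k2p_matrix(aln)
  tr <- nj_tree(dm, n_bootstrap = 100L, aln = aln, seed = 3L)
  # the bipartition separating the clades must be strongly supported
  focal <- which(vapply(seq_len(tr$Nnode), function(i) {
    tips <- ape::extract.clade(tr, length(tr$tip.label) + i)$tip.label
    setequal(tips, grep("GenA", tr$tip.label, value = TRUE)) ||
      setequal(tips, grep("GenB", tr$tip.label, value = TRUE))
  }, logical(1L)))
  expect_gte(length(focal), 1L)
  expect_true(any(as.numeric(tr$node.label[focal]) >= 95))
  # Newick serialization is a fixed point of serialize -> parse -> serialize
  nwk <- ape::write.tree(tr)
  back <- ape::write.tree(ape::read.tree(text = nwk))
  expect_identical(nwk, back)
})
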