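# Sequence I/O round trips, demultiplexing, the read quality filters and
# bimera screening.

random_records <- function(n, len = 80L, with_qual = TRUE) {
  data.frame(
    id = paste0("r", seq_len(n)),
    seq = replicate(n, rand_dna(len)),
    qual = if (with_qual) {
      replicate(n, rawToChar(as.raw(sample(33:73, len, TRUE))))
    } else NA_character_,
    sample = NA_character_, stringsAsFactors = FALSE
  )
}

test_that("FASTA and FASTQ writing then parsing returns identical records", {
  withr::with_seed(1, {
    recs <- random_records(100L)
  })
  fq <- tempfile(fileext = ".fastq")
  write_fastq(recs, fq)
  back <- parse_fastq(fq)
  expect_equal(back$id, recs$id)
  expect_equal(back$seq, recs$seq)
  expect_equal(back$qual, recs$qual)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  backa <- parse_fasta(fa)
  expect_equal(backa$id, recs$id)
  expect_equal(backa$seq, recs$seq)
})

test_that("line-wrapped FASTA records are concatenated", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">w1 some description", "ACGTACGT", "GGCCTTAA", "AC",
               ">w2", "TTTT"), fa)
  x <- parse_fasta(fa)
  expect_equal(x$seq, c("ACGTACGTGGCCTTAAAC", "TTTT"))
  expect_equal(x$id, c("w1", "w2"))
})

test_that("malformed FASTQ input is reported with record id and line number", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@ok", "ACGT", "+", "IIII",
               "@short_qual", "ACGTACGT", "+", "III"), fq)
  expect_error(parse_fastq(fq), "short_qual")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@truncated", "ACGT"), fq)
  expect_error(parse_fastq(fq), "multiple of 4")
  writeLines(c("@r1", "ACXT", "+", "IIII"), fq)
  expect_error(parse_fastq(fq), "illegal")
  writeLines(c("r1_missing_at", "ACGT", "+", "IIII"), fq)
  expect_error(parse_fastq(fq), "line 1")
})

test_that("demultiplexing assigns by exact tag, tolerates one primer mismatch and keeps the partition", {
  fwd <- primer_27f()
  prim <- endoamp:::disambiguate_primer(fwd$sequence)
  bm <- c(S = "ACGT", U = "GGCC")
  insert <- strrep("GATTACA", 10L)
  mutate1 <- function(s, i) {
    substr(s, i, i) <- chartr("ACGT", "CATG", substr(s, i, i))
    s
  }
  reads <- data.frame(
    id = c("hit", "one_mm", "two_mm", "bad_tag"),
    seq = c(paste0("ACGT", prim, insert),
            paste0("ACGT", mutate1(prim, 7L), insert),
            paste0("ACGT", mutate1(mutate1(prim, 7L), 9L), insert),
            paste0("ACGA", prim, insert)),
    qual = NA_character_, sample = NA_character_, stringsAsFactors = FALSE
  )
  dx <- demultiplex(reads, bm, fwd)
  expect_equal(sort(dx$assigned$id), c("hit", "one_mm"))
  expect_equal(unique(dx$assigned$sample), "S")
  expect_equal(unique(dx$assigned$seq), insert)  # tag and primer stripped
  expect_equal(sort(dx$unassigned$id), c("bad_tag", "two_mm"))
  expect_equal(nrow(dx$assigned) + nrow(dx$unassigned), nrow(reads))
  expect_error(demultiplex(reads, character(0L), fwd), "empty")
})

test_that("quality filters reject on the first violated criterion at the documented boundaries", {
  crit <- quality_criteria(min_len = 280L, max_len = 350L, min_mean_q = 20,
                           max_homopolymer = 7L, allow_ambiguous = FALSE)
  q <- function(len, score = 30L) rawToChar(as.raw(rep(score + 33L, len)))
  mk <- function(id, seq, score = 30L) {
    data.frame(id = id, seq = seq, qual = q(nchar(seq), score),
               sample = NA_character_, stringsAsFactors = FALSE)
  }
  withr::with_seed(2, {
    r279 <- mk("r279", rand_dna(279))
    r280 <- mk("r280", rand_dna(280))
    r350 <- mk("r350", rand_dna(350))
    r351 <- mk("r351", rand_dna(351))
    hp8 <- mk("hp8", paste0(rand_dna(150), "AAAAAAAA", rand_dna(150)))
    hp7 <- mk("hp7", paste0(rand_dna(150), "AAAAAAAT", rand_dna(150)))
    lowq <- mk("lowq", rand_dna(300), score = 20L)  # mean exactly 20 fails
    withn <- mk("withn", paste0(rand_dna(150), "N", rand_dna(150)))
  })
  res <- quality_filter(rbind(r279, r280, r350, r351, hp8, hp7, lowq, withn),
                        crit)
  rep <- res$report
  expect_equal(rep$reason[rep$id == "r279"], "length")
  expect_equal(rep$verdict[rep$id == "r280"], "pass")
  expect_equal(rep$verdict[rep$id == "r350"], "pass")
  expect_equal(rep$reason[rep$id == "r351"], "length")
  expect_equal(rep$reason[rep$id == "hp8"], "homopolymer")
  expect_equal(rep$verdict[rep$id == "hp7"], "pass")
  expect_equal(rep$reason[rep$id == "lowq"], "mean_quality")
  expect_equal(rep$reason[rep$id == "withn"], "ambiguous")
  # specific-primer dataset rule: >= 380 nt, no upper bound, no N
  crit_sp <- quality_criteria(min_len = 380L, max_len = Inf,
                              allow_ambiguous = FALSE)
  withr::with_seed(3, r400 <- mk("r400", rand_dna(400)))
  expect_equal(quality_filter(r400, crit_sp)$report$verdict, "pass")
  expect_error(quality_criteria(min_len = 400L, max_len = 300L), "min_len")
})

test_that("loosening any single criterion never turns a pass into a fail", {
  withr::with_seed(4, {
    reads <- random_records(40L, len = 300L)
    # salt in some edge cases
    reads$seq[1] <- paste0(strrep("A", 9L), rand_dna(291))
    reads$qual[2] <- rawToChar(as.raw(rep(20L + 33L, 300L)))
  })
  base <- quality_criteria(min_len = 280L, max_len = 350L, min_mean_q = 20,
                           max_homopolymer = 7L, allow_ambiguous = FALSE)
  base_pass <- quality_filter(reads, base)$report$verdict == "pass"
  loosened <- list(
    quality_criteria(250L, 350L, 20, 7L, FALSE),
    quality_criteria(280L, 400L, 20, 7L, FALSE),
    quality_criteria(280L, 350L, 10, 7L, FALSE),
    quality_criteria(280L, 350L, 20, 12L, FALSE),
    quality_criteria(280L, 350L, 20, 7L, TRUE)
  )
  for (cr in loosened) {
    loos_pass <- quality_filter(reads, cr)$report$verdict == "pass"
    expect_true(all(loos_pass >= base_pass))
  }
})

test_that("a constructed bimera is detected with its parents and crossover", {
  withr::with_seed(5, {
    parentA <- rand_dna(200L)
    # ~10% divergent second parent, with informative sites flanking the
    # junction so the crossover is localizable
    parentB <- mutate_at(parentA, unique(c(sample(200L, 18L), 98L, 103L)))
  })
  query <- paste0(substr(parentA, 1L, 100L), substr(parentB, 101L, 200L))
  cands <- data.frame(seq = c(parentA, parentB), abundance = c(10L, 10L),
                      stringsAsFactors = FALSE)
  v <- detect_bimera(query, cands, query_abundance = 2L)
  expect_equal(v$verdict, "chimeric")
  expect_setequal(v$parents, c(1L, 2L))
  expect_lt(abs(v$crossover - 100L), 6L)
  # a query identical to a candidate is clean
  clean <- detect_bimera(parentA, cands, query_abundance = 2L)
  expect_equal(clean$verdict, "clean")
  # low-abundance parents are not eligible
  weak <- cands
  weak$abundance <- c(3L, 3L)
  expect_equal(detect_bimera(query, weak, query_abundance = 2L)$verdict,
               "clean")
  expect_warning(v0 <- detect_bimera(query, cands[0, ], 1L), "empty")
  expect_equal(v0$verdict, "clean")
})

test_that("an equidistant query with no crossover advantage stays clean", {
  withr::with_seed(6, q <- rand_dna(120L))
  # parent mismatches interleave so no side can improve by 2
  pA <- mutate_at(q, c(10L, 30L, 50L, 70L, 90L, 110L))
  pB <- mutate_at(q, c(20L, 40L, 60L, 80L, 100L))
  cands <- data.frame(seq = c(pA, pB), abundance = c(8L, 8L),
                      stringsAsFactors = FALSE)
  expect_equal(detect_bimera(q, cands, query_abundance = 1L)$verdict, "clean")
})

test_that("the fast bimera test agrees with the exhaustive all-pairs all-crossovers scan", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      L <- sample(60:200, 1L)
      base <- rand_dna(L)
      n_cand <- sample(2:5, 1L)
      cands <- data.frame(
        seq = vapply(seq_len(n_cand), function(i)
          mutate_at(base, sample(L, sample(3:15, 1L))), character(1L)),
        abundance = sort(sample(4:30, n_cand), decreasing = TRUE),
        stringsAsFactors = FALSE
      )
      query <- if (rep %% 2L == 0L) {
        x <- sample(ceiling(L * 0.3):floor(L * 0.7), 1L)
        paste0(substr(cands$seq[1L], 1L, x),
               substr(cands$seq[2L], x + 1L, L))
      } else {
        mutate_at(base, sample(L, 5L))
      }
      got <- detect_bimera(query, cands, query_abundance = 1L)$verdict
      want <- oracle_bimera(query, cands, query_abundance = 1L)
      expect_equal(got, want)
    }
  })
})
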