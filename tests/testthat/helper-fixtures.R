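# Fixtures and independent brute-force oracles, all built in code.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus")

# --- CAG-repeat near-neighbor fixture -------------------------------------
# The specific reverse-primer site of the target clade matches the
# un-engineered ("matched") consensus perfectly; the near-neighbor site
# differs by one base next to the repeat region, so the matched primer
# still anneals (1 mismatch) while the deliberately mismatched primer
# accumulates 2 mismatches there and fails.
CAG_TARGET_SITE <- "TCAGTGTCAGGCCAGAGTGT"                 # primer orientation
CAG_NEIGHBOR_SITE <- sub("^TCAGT", "TCAGC", CAG_TARGET_SITE)

make_cag_panel <- function(n_target = 50L, n_outgroup = 50L, seed = 7L) {
  clades <- list(
    clade_spec("Endozoicomonas", n_target, depth = 0.01,
               taxonomy_prefix = "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;Hahellaceae"),
    clade_spec("Simiduia", n_outgroup, depth = 0.01,
               taxonomy_prefix = "Bacteria;Proteobacteria;Gammaproteobacteria;Cellvibrionales;Cellvibrionaceae")
  )
  sites <- list(
    list(primer = primer_27f(), start = 100L),
    list(primer = primer_matched_771r(), start = 830L,
         clade_window = c(Endozoicomonas = endoamp:::revcomp(CAG_TARGET_SITE),
                          Simiduia = endoamp:::revcomp(CAG_NEIGHBOR_SITE)))
  )
  evolve_reference_panel(900L, clades, sites, seed)
}

# --- separable classifier corpus ------------------------------------------
# Two genera with disjoint 8-mer vocabularies (AC-alphabet vs GT-alphabet).
separable_corpus <- function(n_per_genus = 3L, len = 60L, seed = 5L) {
  withr::with_seed(seed, {
    mk <- function(alpha) paste(sample(alpha, len, TRUE), collapse = "")
    data.frame(
      id = c(paste0("A", seq_len(n_per_genus)), paste0("B", seq_len(n_per_genus))),
      lineage = rep(c("Bacteria;P1;C1;O1;F1;GenA", "Bacteria;P2;C2;O2;F2;GenB"),
                    each = n_per_genus),
      seq = c(replicate(n_per_genus, mk(c("A", "C"))),
              replicate(n_per_genus, mk(c("G", "T")))),
      stringsAsFactors = FALSE
    )
  })
}

# --- brute-force oracles ---------------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# Minimum Hamming distance over all concrete expansions of a degenerate
# primer (targets restricted to plain ACGT).
oracle_min_mismatch <- function(primer_seq, target_seq) {
  sets <- IUPAC_SETS[strsplit(primer_seq, "")[[1L]]]
  expansions <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  tg <- strsplit(target_seq, "")[[1L]]
  min(apply(expansions, 1L, function(e) sum(e != tg)))
}

# Naive full scan using iupac_mismatches at every offset.
oracle_scan <- function(primer, template, max_mm) {
  query <- if (primer$orientation == "reverse") {
    endoamp:::revcomp(primer$sequence)
  } else primer$sequence
  plen <- nchar(query)
  hits <- list()
  for (s in 0:(nchar(template) - plen)) {
    mm <- iupac_mismatches(query, substr(template, s + 1L, s + plen))
    if (mm <= max_mm) hits[[length(hits) + 1L]] <- c(start = s, mismatches = mm)
  }
  if (!length(hits)) return(data.frame(start = integer(0), mismatches = integer(0)))
  as.data.frame(do.call(rbind, hits))
}

# Exhaustive all-pairs, all-crossovers bimera scan with the same decision
# rule as detect_bimera, written as plain nested loops.
oracle_bimera <- function(query, candidates, query_abundance,
                         min_skew = 2, min_improve = 2L, max_side_mm = 1L) {
  elig <- which(candidates$abundance >= min_skew * query_abundance)
  if (length(elig) < 2L) return("clean")
  mm <- function(x) {
    q <- strsplit(query, "")[[1L]]
    c2 <- strsplit(x, "")[[1L]]
    L <- min(length(q), length(c2))
    as.integer(q[1:L] != c2[1:L])
  }
  vecs <- lapply(candidates$seq[elig], mm)
  L <- min(lengths(vecs))
  totals <- vapply(vecs, function(v) sum(v[1:L]), integer(1L))
  best_single <- min(totals)
  for (a in seq_along(elig)) for (b in seq_along(elig)) {
    if (a == b) next
    for (x in 1:(L - 1L)) {
      la <- sum(vecs[[a]][1:x])
      lb <- sum(vecs[[b]][1:x])
      ra <- totals[a] - la
      rb <- totals[b] - lb
      if (la <= max_side_mm && rb <= max_side_mm &&
          la <= lb - min_improve && rb <= ra - min_improve &&
          la + rb < best_single) {
        return("chimeric")
      }
    }
  }
  "clean"
}

# Greedy clustering re-implemented as plain loops with the same ordering
# and tie-break rule, using seq_identity per pair.
oracle_greedy <- function(seqs, abundances, radius = 0.03) {
  stopifnot(!is.unsorted(rev(abundances)))
  centroids <- integer(0L)
  member <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    best_id <- -Inf
    best_c <- NA_integer_
    for (ci in seq_along(centroids)) {
      idn <- seq_identity(seqs[centroids[ci]], seqs[i])
      if (idn > best_id) {
        best_id <- idn
        best_c <- ci
      }
    }
    if (length(centroids) && best_id >= 1 - radius) {
      member[i] <- best_c
      assigned <- TRUE
    }
    if (!assigned) {
      centroids <- c(centroids, i)
      member[i] <- length(centroids)
    }
  }
  member
}

# Expected OTU count after rarefying to depth d (hypergeometric form).
oracle_expected_otus <- function(counts, d) {
  N <- sum(counts)
  sum(1 - choose(N - counts, d) / choose(N, d))
}

# Random additive distance matrix from a random binary tree.
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 0.5)
  list(d = ape::cophenetic.phylo(tr), tree = tr)
}

# Small synthetic ribotype set with controlled divergences for cluster
# tests: mutate a base sequence at disjoint position blocks.
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1L]]
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  ch[pos] <- swap[ch[pos]]
  paste(ch, collapse = "")
}
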