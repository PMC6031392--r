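# Dereplication, unique-ribotype profiling, greedy centroid OTU clustering
# at 3% divergence (singletons included), seeded rarefying, and the alpha
# diversity statistics of the survey, including its singleton-ratio
# richness S/(N+1) and Shannon-based evenness H/ln(OTUs).

#' Dereplicate reads into unique sequences with per-sample ratio profiles
#'
#' Identical sequences are merged; uniques are sorted by total count
#' (descending, ties broken lexicographically by sequence). The ratio of a
#' unique sequence in a sample is its read count divided by the sample's
#' total reads, as a percentage.
#'
#' @param reads read-set data.frame with `seq` and `sample` columns.
#' @return list with `uniques` (data.frame `seq`, `total`), `counts`
#'   (integer matrix uniques x samples) and `ratio` (percent matrix of the
#'   same shape; columns sum to 100).
#' @export
dereplicate <- function(reads) {
  if (nrow(reads) == 0L) stop("empty read set")
  samp <- reads$sample
  if (is.null(samp)) samp <- rep(NA_character_, nrow(reads))
  samp[is.na(samp)] <- "all"
  counts <- table(reads$seq, samp)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  total <- rowSums(counts)
  ord <- order(-total, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  total <- total[ord]
  ratio <- sweep(counts, 2L, colSums(counts), "/") * 100
  list(uniques = data.frame(seq = rownames(counts), total = as.integer(total),
                            stringsAsFactors = FALSE),
       counts = counts, ratio = ratio)
}

#' Pairwise identity from a terminal-gap-free global alignment
#'
#' Identity = matching columns / alignment columns, with terminal gaps
#' excluded and each internal gap column counting as one difference
#' (match +1, mismatch -1, gap -2, free end gaps).
#'
#' @param a,b DNA strings.
#' @return identity fraction in [0, 1].
#' @export
seq_identity <- function(a, b) {
  seq_identity_many(a, b)[1L]
}

# Identity of one query against many references in a single (vectorized)
# alignment call; same scoring as seq_identity.
seq_identity_many <- function(refs, query) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(refs),
                                       Biostrings::DNAString(query),
                                       type = "overlap",
                                       substitutionMatrix = sm,
                                       gapOpening = 0, gapExtension = 2)
  m <- Biostrings::nmatch(aln)
  x <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  gapcols <- Biostrings::insertion(ind)[, "WidthSum"] +
    Biostrings::deletion(ind)[, "WidthSum"]
  unname(m / (m + x + gapcols))
}

#' Greedy centroid OTU clustering at a fixed divergence radius
#'
#' UPARSE-style: the most abundant unique seeds the first OTU; each
#' subsequent unique joins the existing centroid of highest identity if
#' that identity is at least `1 - radius`, otherwise it seeds a new OTU.
#' Identity ties go to the more abundant (earlier) centroid. A shared
#' 8-mer prescreen (as greedy clustering tools use) skips centroids whose
#' word overlap is far too low to reach the identity threshold, so only
#' plausible centroids are aligned.
#'
#' @param derep result of [dereplicate()] (uniques must be
#'   abundance-sorted; refused otherwise).
#' @param radius divergence radius (default 0.03, the 97% species-like
#'   cut-off).
#' @return an `otu_table`: list with `counts` (integer matrix OTUs x
#'   samples), `centroids` (character), `membership` (unique index -> OTU).
#' @export
greedy_otu_cluster <- function(derep, radius = 0.03) {
  uni <- derep$uniques
  if (is.unsorted(rev(uni$total))) {
    stop("uniques must be sorted by abundance (descending)")
  }
  kmer_ids <- function(s) {
    if (nchar(s) < 8L) return(integer(0L))
    which(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(s), width = 8L)[1L, ] > 0L)
  }
  centroids <- character(0L)
  cent_kmers <- list()
  membership <- integer(nrow(uni))
  for (i in seq_len(nrow(uni))) {
    if (length(centroids) == 0L) {
      centroids <- uni$seq[i]
      cent_kmers[[1L]] <- kmer_ids(uni$seq[i])
      membership[i] <- 1L
      next
    }
    qk <- kmer_ids(uni$seq[i])
    qlen <- nchar(uni$seq[i])
    frac <- vapply(seq_along(centroids), function(j) {
      denom <- min(qlen, nchar(centroids[j])) - 7L
      if (denom <= 0L) return(1)  # too short to prescreen: always align
      length(intersect(cent_kmers[[j]], qk)) / denom
    }, numeric(1L))
    cand <- which(frac >= 1 - 12 * radius)
    ident <- rep(-Inf, length(centroids))
    if (length(cand)) {
      ident[cand] <- seq_identity_many(centroids[cand], uni$seq[i])
    }
    best <- which.max(ident)  # ties -> earliest = most abundant centroid
    if (length(cand) && ident[best] >= 1 - radius) {
      membership[i] <- best
    } else {
      centroids <- c(centroids, uni$seq[i])
      cent_kmers[[length(centroids)]] <- qk
      membership[i] <- length(centroids)
    }
  }
  counts <- rowsum(derep$counts, group = membership, reorder = TRUE)
  storage.mode(counts) <- "integer"
  rownames(counts) <- paste0("OTU_", sprintf("%03d", seq_len(nrow(counts))))
  structure(list(counts = counts, centroids = centroids,
                 membership = membership, radius = radius),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples (radius %.2f), %d reads\n",
              nrow(x$counts), ncol(x$counts), x$radius, sum(x$counts)))
  invisible(x)
}

# Build an otu_table directly from a count matrix (for co-clustered or
# externally derived tables).
as_otu_table <- function(counts, centroids = NULL, radius = 0.03) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, centroids = centroids,
                 membership = seq_len(nrow(counts)), radius = radius),
            class = "otu_table")
}

#' Rarefy an OTU table to an even depth
#'
#' Subsampling is without replacement, exactly `depth` reads per sample;
#' samples below the depth are dropped with a warning. Seeded and
#' reproducible.
#'
#' @param otu an `otu_table`.
#' @param depth target reads per sample (> 0).
#' @param seed integer seed.
#' @return a rarefied `otu_table` (same OTU rows; dropped samples removed).
#' @export
rarefy_table <- function(otu, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  tot <- colSums(otu$counts)
  keep <- tot >= depth
  if (!all(keep)) {
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(colnames(otu$counts)[!keep], collapse = ", "))
  }
  cnt <- otu$counts[, keep, drop = FALSE]
  out <- otu
  if (ncol(cnt) == 0L) {
    out$counts <- cnt
    return(out)
  }
  sub <- withr::with_seed(seed, t(vegan::rrarefy(t(cnt), depth)))
  storage.mode(sub) <- "integer"
  out$counts <- sub
  out
}

#' Alpha diversity indices per sample
#'
#' For each sample: observed OTUs; the survey's richness statistic
#' `R = S / (N + 1)` with `S` the singleton-OTU count and `N` the total
#' OTU count (a singleton ratio, not a richness estimator — implemented
#' verbatim as printed); Shannon `H` (natural log); Gini-Simpson
#' `1 - sum(p^2)`; evenness `E = H / ln(observed OTUs)` (NA for a
#' single-OTU sample).
#'
#' @param otu an `otu_table` or a count matrix (OTUs x samples).
#' @return data.frame with columns `sample`, `reads`, `otus`, `singletons`,
#'   `richness`, `gini_simpson`, `shannon`, `evenness`.
#' @export
alpha_diversity <- function(otu) {
  counts <- if (inherits(otu, "otu_table")) otu$counts else as.matrix(otu)
  if (all(counts == 0)) stop("all counts are zero")
  if (is.null(colnames(counts))) {
    colnames(counts) <- as.character(seq_len(ncol(counts)))
  }
  res <- lapply(colnames(counts), function(sm) {
    x <- counts[, sm]
    x <- x[x > 0]
    S_obs <- length(x)
    H <- unname(vegan::diversity(x, index = "shannon"))
    data.frame(
      sample = sm, reads = sum(x), otus = S_obs,
      singletons = sum(x == 1L),
      richness = sum(x == 1L) / (S_obs + 1L),
      gini_simpson = unname(vegan::diversity(x, index = "simpson")),
      shannon = H,
      evenness = if (S_obs >= 2L) H / log(S_obs) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Evenness from a printed Shannon index and OTU count
#'
#' The tables' evenness convention: Shannon (natural log) divided by the
#' natural log of the observed OTU count.
#'
#' @param shannon Shannon index (natural log).
#' @param n_otus observed OTU count (>= 2).
#' @return evenness value.
#' @export
evenness_from_shannon <- function(shannon, n_otus) {
  if (n_otus < 2L) stop("evenness is undefined for fewer than 2 OTUs")
  shannon / log(n_otus)
}

#' Compare two primer datasets on a common OTU space
#'
#' Both tables (built from co-clustered reads so OTU ids are comparable)
#' are rarefied to an even depth, singleton OTUs (total count exactly 1
#' after rarefying) are removed to prevent sensitivity overestimation, and
#' per-dataset, shared and union OTU counts are reported together with
#' per-sample diversity indices.
#'
#' @param table_a,table_b `otu_table`s sharing OTU row names.
#' @param depth rarefying depth, or `NULL` to skip rarefying.
#' @param seed integer seed for the rarefying draws.
#' @return list with `otus_a`, `otus_b`, `shared`, `union`, `only_a`,
#'   `only_b`, `indices_a`, `indices_b`.
#' @export
compare_primer_sets <- function(table_a, table_b, depth = NULL, seed = 1L) {
  if (!length(intersect(rownames(table_a$counts), rownames(table_b$counts)))) {
    stop("tables share no OTU ids; cluster the datasets jointly first")
  }
  if (!is.null(depth)) {
    table_a <- rarefy_table(table_a, depth, seed = child_seed(seed, "setA"))
    table_b <- rarefy_table(table_b, depth, seed = child_seed(seed, "setB"))
  }
  drop_singletons <- function(tab) {
    keep <- rowSums(tab$counts) != 1L
    tab$counts <- tab$counts[keep, , drop = FALSE]
    tab
  }
  table_a <- drop_singletons(table_a)
  table_b <- drop_singletons(table_b)
  present_a <- rownames(table_a$counts)[rowSums(table_a$counts) > 0L]
  present_b <- rownames(table_b$counts)[rowSums(table_b$counts) > 0L]
  shared <- length(intersect(present_a, present_b))
  list(
    otus_a = length(present_a), otus_b = length(present_b),
    shared = shared,
    union = length(present_a) + length(present_b) - shared,
    only_a = length(present_a) - shared,
    only_b = length(present_b) - shared,
    indices_a = alpha_diversity(table_a),
    indices_b = alpha_diversity(table_b)
  )
}
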