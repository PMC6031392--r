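# Template-guided alignment, complete-deletion gap masking, Kimura
# 2-parameter distances with transition/transversion companions, group
# divergence with site-bootstrap SE, and neighbor-joining trees with
# bootstrap support (ape supplies NJ and Newick I/O).

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

matrix_aln <- function(m) {
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Align a query onto a fixed reference alignment frame
#'
#' The query is globally aligned (match +1, mismatch -1, gap -2, terminal
#' gaps free) to its nearest reference (highest shared 8-mer count); query
#' gaps are projected onto the reference columns and query insertions
#' relative to the template are discarded, so the returned row always has
#' the reference column count (NAST-style projection).
#'
#' @param query DNA string.
#' @param reference_alignment named character vector of aligned reference
#'   rows (equal lengths, `-` for gaps).
#' @param k word size used to pick the nearest reference (default 8).
#' @return single aligned row (character string of reference column count).
#' @export
template_align <- function(query, reference_alignment, k = 8L) {
  if (length(reference_alignment) == 0L) stop("empty reference alignment")
  degap <- gsub("-", "", reference_alignment, fixed = TRUE)
  qp <- word_presence(query, k)[1L, ]
  shared <- vapply(degap, function(r)
    sum(qp & word_presence(r, k)[1L, ]), numeric(1L), USE.NAMES = FALSE)
  if (max(shared) == 0) {
    stop("query shares no ", k, "-mers with any reference")
  }
  best <- which.max(shared)
  ref_row <- reference_alignment[[best]]
  ref_degap <- degap[[best]]
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(query),
                                       Biostrings::DNAString(ref_degap),
                                       type = "overlap",
                                       substitutionMatrix = sm,
                                       gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  # fill over degapped reference coordinates
  res <- rep("-", nchar(ref_degap))
  ref_pos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  for (i in seq_along(sa)) {
    if (sa[i] != "-") {
      ref_pos <- ref_pos + 1L
      res[ref_pos] <- pa[i]
    }
    # sa[i] == "-" is a query insertion relative to the template: discarded
  }
  # project onto reference alignment columns
  ref_chars <- strsplit(ref_row, "", fixed = TRUE)[[1L]]
  out <- rep("-", length(ref_chars))
  out[ref_chars != "-"] <- res
  paste(out, collapse = "")
}

#' Remove every alignment column containing a gap or missing base
#'
#' Complete deletion: a column is retained only if every row holds a
#' definite base (A/C/G/T); gaps, N and ambiguity codes are treated as
#' missing data.
#'
#' @param aln named character vector of aligned rows.
#' @return list with `alignment` (masked rows) and `retained` (site count).
#' @export
mask_gap_columns <- function(aln) {
  m <- aln_matrix(aln)
  keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep)) stop("no columns retained after complete deletion")
  list(alignment = matrix_aln(m[, keep, drop = FALSE]),
       retained = sum(keep))
}

PURINES <- c("A", "G")

#' Kimura 2-parameter distance between two gapless sequences
#'
#' `P` is the transition fraction, `Q` the transversion fraction and
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`. When a log argument is
#' non-positive the pair is saturated: `d` is `NA` and the `saturated`
#' flag is set (callers exclude such pairs from means with a warning).
#'
#' @param s1,s2 equal-length DNA strings (post-masking).
#' @return list `d`, `P`, `Q`, `sites`, `saturated`.
#' @export
k2p_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(s2), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences differ in length")
  if (length(a) < 1L) stop("empty sequences")
  diff <- a != b
  ts <- diff & ((a %in% PURINES) == (b %in% PURINES))
  P <- sum(ts) / length(a)
  Q <- sum(diff & !ts) / length(a)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(d = NA_real_, P = P, Q = Q, sites = length(a),
                saturated = TRUE))
  }
  list(d = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q,
       sites = length(a), saturated = FALSE)
}

#' Uncorrected p-distance between two gapless sequences
#' @param s1,s2 equal-length DNA strings.
#' @return fraction of differing sites.
#' @export
p_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(s2), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences differ in length")
  mean(a != b)
}

#' Pairwise K2P distance matrix of a masked alignment
#'
#' @param aln named character vector of equal-length gapless rows.
#' @return list of symmetric matrices `d`, `P`, `Q`, plus `sites` and
#'   logical `saturated`; class `k2p_matrix`.
#' @export
k2p_matrix <- function(aln) {
  n <- length(aln)
  labs <- names(aln) %||% as.character(seq_len(n))
  d <- P <- Q <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k2p_distance(aln[[i]], aln[[j]])
      d[i, j] <- d[j, i] <- k$d
      P[i, j] <- P[j, i] <- k$P
      Q[i, j] <- Q[j, i] <- k$Q
      sat[i, j] <- sat[j, i] <- k$saturated
    }
  }
  structure(list(d = d, P = P, Q = Q, sites = nchar(aln[[1L]]),
                 saturated = sat), class = "k2p_matrix")
}

# Mean over the pairwise distances selected by `pick` (a 2-column index
# matrix); saturated pairs excluded with a warning.
mean_pairs <- function(dmat, sat, pick, warn = TRUE) {
  v <- dmat[pick]
  s <- sat[pick]
  if (any(s) && warn) {
    warning(sum(s), " saturated pair(s) excluded from the mean")
  }
  mean(v[!s])
}

#' Within- and between-group mean K2P divergence with bootstrap SE
#'
#' Point estimates are means over the relevant pairwise K2P distances of
#' the (already masked) alignment; the standard error is the standard
#' deviation of the mean over `n_site_bootstrap` site-resampled
#' replicates.
#'
#' @param aln named character vector of equal-length gapless rows.
#' @param groups named character vector mapping row labels to group names.
#' @param n_site_bootstrap replicates (default 500).
#' @param seed integer seed.
#' @return data.frame with `comparison`, `group1`, `group2`, `mean_d`,
#'   `se`, `n_pairs`.
#' @export
group_divergence <- function(aln, groups, n_site_bootstrap = 500L, seed = 1L) {
  labs <- names(aln)
  stopifnot(!is.null(labs), all(labs %in% names(groups)))
  g <- groups[labs]
  gn <- unique(g)
  pair_sets <- list()
  for (a in gn) {
    idx <- which(g == a)
    if (length(idx) >= 2L) {
      pr <- t(utils::combn(idx, 2L))
      pair_sets[[length(pair_sets) + 1L]] <-
        list(comparison = "within", group1 = a, group2 = a, pairs = pr)
    }
  }
  if (length(gn) > 1L) {
    for (i in seq_len(length(gn) - 1L)) {
      for (j in (i + 1L):length(gn)) {
        pr <- as.matrix(expand.grid(which(g == gn[i]), which(g == gn[j])))
        pair_sets[[length(pair_sets) + 1L]] <-
          list(comparison = "between", group1 = gn[i], group2 = gn[j],
               pairs = pr)
      }
    }
  }
  m <- aln_matrix(aln)
  point <- k2p_matrix(aln)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_site_bootstrap), function(r) {
      cols <- sample.int(ncol(m), replace = TRUE)
      k2p_matrix(matrix_aln(m[, cols, drop = FALSE]))
    })
  })
  out <- lapply(pair_sets, function(ps) {
    mu <- mean_pairs(point$d, point$saturated, ps$pairs)
    boot <- vapply(reps, function(k)
      mean_pairs(k$d, k$saturated, ps$pairs, warn = FALSE), numeric(1L))
    data.frame(comparison = ps$comparison, group1 = ps$group1,
               group2 = ps$group2, mean_d = mu,
               se = stats::sd(boot, na.rm = TRUE),
               n_pairs = nrow(ps$pairs), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Neighbor-joining tree with site-bootstrap support
#'
#' Canonical Saitou-Nei NJ (via ape) on a K2P distance matrix; negative
#' branch lengths are clamped to zero. When an alignment and bootstrap
#' count are supplied, support per internal edge is the percentage of
#' site-resampled replicate trees containing the bipartition, stored as
#' node labels.
#'
#' @param dm a `k2p_matrix` (or plain symmetric matrix).
#' @param n_bootstrap replicate count (0 = no support values).
#' @param aln the masked alignment the matrix came from (required when
#'   `n_bootstrap > 0`).
#' @param seed integer seed.
#' @return an `ape::phylo` tree (Newick-serializable with
#'   [ape::write.tree()]).
#' @export
nj_tree <- function(dm, n_bootstrap = 0L, aln = NULL, seed = 1L) {
  d <- if (inherits(dm, "k2p_matrix")) dm$d else as.matrix(dm)
  if (any(is.na(d))) stop("distance matrix contains saturated/NA pairs")
  if (any(d < 0) || !isTRUE(all.equal(d, t(d)))) {
    stop("distance matrix must be symmetric with non-negative entries")
  }
  if (nrow(d) < 3L) stop("need at least 3 leaves")
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (n_bootstrap > 0L) {
    stopifnot(!is.null(aln))
    m <- aln_matrix(aln)
    reps <- withr::with_seed(seed, {
      lapply(seq_len(n_bootstrap), function(r) {
        cols <- sample.int(ncol(m), replace = TRUE)
        k <- k2p_matrix(matrix_aln(m[, cols, drop = FALSE]))
        if (any(is.na(k$d))) return(NULL)
        ape::nj(stats::as.dist(k$d))
      })
    })
    reps <- Filter(Negate(is.null), reps)
    cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
    cnt[is.na(cnt)] <- 0L
    tree$node.label <- round(100 * cnt / length(reps))
  }
  tree
}
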