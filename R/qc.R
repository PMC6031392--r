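#' Demultiplex barcoded amplicon reads
#'
#' A read is assigned to a sample iff its first 4 nt exactly match that
#' sample's tag (4-nt tags leave no safe mismatch margin) and the following
#' bases match the expected primer with at most one degenerate-aware
#' mismatch (sequencing error in the primer region should not discard a
#' read, but with >1 mismatch the primer is not recognizable and the read
#' goes to the unassigned bin). Tag and primer prefix are stripped from
#' assigned reads.
#'
#' @param reads read-set data.frame.
#' @param barcode_map named character vector sample -> 4-nt tag.
#' @param primer the [degenerate_primer()] expected right after the tag
#'   (the forward primer as synthesized, 5'->3').
#' @param max_primer_mm mismatch tolerance for the primer prefix.
#' @return list with `assigned` (read set, `sample` filled, prefix
#'   stripped) and `unassigned` (untouched reads).
#' @export
demultiplex <- function(reads, barcode_map, primer, max_primer_mm = 1L) {
  barcode_map <- validate_barcode_map(barcode_map)
  plen <- nchar(primer$sequence)
  tags <- substr(reads$seq, 1L, 4L)
  samp <- names(barcode_map)[match(tags, barcode_map)]
  prim_ok <- rep(FALSE, nrow(reads))
  long_enough <- nchar(reads$seq) >= 4L + plen
  idx <- which(!is.na(samp) & long_enough)
  if (length(idx)) {
    pwin <- substr(reads$seq[idx], 5L, 4L + plen)
    prim_ok[idx] <- vapply(pwin, function(w)
      iupac_mismatches(primer$sequence, w) <= max_primer_mm, logical(1L),
      USE.NAMES = FALSE)
  }
  ok <- !is.na(samp) & prim_ok
  assigned <- reads[ok, , drop = FALSE]
  if (nrow(assigned)) {
    assigned$sample <- samp[ok]
    assigned$seq <- substr(assigned$seq, 5L + plen, nchar(assigned$seq))
    has_q <- !is.na(assigned$qual)
    assigned$qual[has_q] <- substr(assigned$qual[has_q], 5L + plen,
                                   nchar(assigned$qual[has_q]))
  }
  rownames(assigned) <- NULL
  unassigned <- reads[!ok, , drop = FALSE]
  rownames(unassigned) <- NULL
  list(assigned = assigned, unassigned = unassigned)
}

#' Quality criteria for 454-style amplicon reads
#'
#' Defaults follow the universal-primer dataset rules (length window
#' 280-350 nt, mean quality > 20, homopolymer < 8 nt, no ambiguous base);
#' the specific-primer dataset used `min_len = 380` with no upper bound.
#'
#' @param min_len,max_len inclusive read-length window (nt).
#' @param min_mean_q minimum arithmetic mean Phred score (exclusive).
#' @param max_homopolymer maximum allowed single-base run length (nt).
#' @param allow_ambiguous keep reads containing N?
#' @return a `quality_criteria` list.
#' @export
quality_criteria <- function(min_len = 280L, max_len = 350L, min_mean_q = 20,
                             max_homopolymer = 7L, allow_ambiguous = FALSE) {
  if (min_len > max_len) stop("min_len (", min_len, ") > max_len (", max_len, ")")
  if (min_mean_q < 0) stop("min_mean_q must be >= 0")
  structure(list(min_len = min_len, max_len = max_len, min_mean_q = min_mean_q,
                 max_homopolymer = max_homopolymer,
                 allow_ambiguous = allow_ambiguous),
            class = "quality_criteria")
}

longest_homopolymer <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1L]])
  max(r$lengths)
}

#' Apply read quality filters
#'
#' Criteria are checked in the fixed order length window, mean quality,
#' homopolymer run, ambiguous bases; the first violated criterion is the
#' reported failure reason. Mean quality is the arithmetic mean of the raw
#' Phred scores.
#'
#' @param reads read-set data.frame.
#' @param criteria a [quality_criteria()] object.
#' @return list with `pass` (read set), `fail` (read set with a `reason`
#'   column) and `report` (data.frame id/verdict/reason for every input
#'   read).
#' @export
quality_filter <- function(reads, criteria) {
  stopifnot(inherits(criteria, "quality_criteria"))
  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  len <- nchar(reads$seq)
  bad <- len < criteria$min_len | len > criteria$max_len
  reason[bad] <- "length"
  if (!all(is.na(reads$qual))) {
    meanq <- vapply(reads$qual, function(q)
      if (is.na(q)) Inf else mean(phred_scores(q)), numeric(1L),
      USE.NAMES = FALSE)
    bad <- is.na(reason) & meanq <= criteria$min_mean_q
    reason[bad] <- "mean_quality"
  }
  todo <- which(is.na(reason))
  if (length(todo)) {
    hp <- vapply(reads$seq[todo], longest_homopolymer, numeric(1L),
                 USE.NAMES = FALSE)
    reason[todo[hp > criteria$max_homopolymer]] <- "homopolymer"
  }
  if (!criteria$allow_ambiguous) {
    bad <- is.na(reason) & grepl("[^ACGT]", reads$seq)
    reason[bad] <- "ambiguous"
  }
  ok <- is.na(reason)
  fail <- reads[!ok, , drop = FALSE]
  if (nrow(fail)) fail$reason <- reason[!ok]
  rownames(fail) <- NULL
  pass <- reads[ok, , drop = FALSE]
  rownames(pass) <- NULL
  list(pass = pass, fail = fail,
       report = data.frame(id = reads$id,
                           verdict = ifelse(ok, "pass", "fail"),
                           reason = reason, stringsAsFactors = FALSE))
}

# Per-position mismatch indicator of `query` against `ref`, both plain DNA
# strings; compared over the first min(nchar) positions.
mismatch_vector <- function(query, ref) {
  q <- charToRaw(query)
  r <- charToRaw(ref)
  L <- min(length(q), length(r))
  as.integer(q[seq_len(L)] != r[seq_len(L)])
}

#' Detect a two-parent (bimera) chimera
#'
#' A query is tested against every ordered pair of candidate parents whose
#' abundances are both at least `min_skew` times the query abundance (a
#' chimera cannot be more abundant than the templates it formed from). It
#' is called chimeric iff some single-crossover model (left part from
#' parent A, right part from parent B) reconstructs the query nearly
#' exactly — each side matching its parent with at most `max_side_mm`
#' mismatches (tolerating sequencing error) — with strictly fewer total
#' mismatches than the best single parent, and each side of the crossover
#' matching its own parent at least `min_improve` mismatches better than
#' it matches the other parent (the two-parent vote of standard bimera
#' heuristics). The near-exact-halves requirement keeps genuinely distinct
#' ribotypes, which mix against unrelated references by chance, from being
#' miscalled.
#'
#' @param query DNA string.
#' @param candidates data.frame with columns `seq` and `abundance`, sorted
#'   by abundance (descending).
#' @param query_abundance abundance of the query.
#' @param min_skew parent/query abundance ratio required (default 2).
#' @param min_improve per-side mismatch improvement required (default 2).
#' @param max_side_mm residual per-side mismatches allowed in the chimeric
#'   model (default 1).
#' @return list with `verdict` ("chimeric"/"clean"), `parents` (indices
#'   into candidates or NULL), `crossover` (0-based position of the first
#'   right-side base) and `score` (total mismatch improvement).
#' @export
detect_bimera <- function(query, candidates, query_abundance = 1L,
                          min_skew = 2, min_improve = 2L, max_side_mm = 1L) {
  if (nrow(candidates) == 0L) {
    warning("empty candidate list; returning clean")
    return(list(verdict = "clean", parents = NULL, crossover = NA_integer_,
                score = 0L))
  }
  if (is.unsorted(rev(candidates$abundance))) {
    stop("candidates must be sorted by abundance (descending)")
  }
  elig <- which(candidates$abundance >= min_skew * query_abundance)
  clean <- list(verdict = "clean", parents = NULL, crossover = NA_integer_,
                score = 0L)
  if (length(elig) < 2L) return(clean)
  mmv <- lapply(candidates$seq[elig], mismatch_vector, query = query)
  L <- min(lengths(mmv))
  cum <- vapply(mmv, function(v) cumsum(v[seq_len(L)]), numeric(L))
  cum <- matrix(cum, nrow = L)
  totals <- cum[L, ]
  best_single <- which.min(totals)
  best <- clean
  # crossover x: left = positions 1..x, right = x+1..L  (x in 1..L-1)
  for (a in seq_along(elig)) {
    for (b in seq_along(elig)) {
      if (a == b) next
      left_a <- cum[seq_len(L - 1L), a]
      left_b <- cum[seq_len(L - 1L), b]
      right_a <- totals[a] - left_a
      right_b <- totals[b] - left_b
      chim <- left_a + right_b
      ok <- left_a <= max_side_mm & right_b <= max_side_mm &
        left_a <= left_b - min_improve &
        right_b <= right_a - min_improve &
        chim < totals[best_single]
      if (any(ok)) {
        score <- totals[best_single] - chim
        x <- which(ok)[which.max(score[ok])]
        if (score[x] > best$score) {
          best <- list(verdict = "chimeric",
                       parents = c(elig[a], elig[b]),
                       crossover = x, score = as.integer(score[x]))
        }
      }
    }
  }
  best
}

#' Screen a read set for bimeras against its own abundance-ranked uniques
#'
#' Dereplicates the reads, then tests each unique (rarest first) against
#' the more abundant uniques as candidate parents.
#'
#' @param reads read-set data.frame.
#' @param ... passed to [detect_bimera()].
#' @return list with `keep` (non-chimeric reads) and `report` (one row per
#'   unique sequence with verdict).
#' @export
screen_bimeras <- function(reads, ...) {
  tab <- sort(table(reads$seq), decreasing = TRUE)
  uni <- data.frame(seq = names(tab), abundance = as.integer(tab),
                    stringsAsFactors = FALSE)
  verdict <- character(nrow(uni))
  for (i in seq_len(nrow(uni))) {
    cand <- uni[seq_len(i - 1L), , drop = FALSE]
    v <- if (i == 1L) list(verdict = "clean") else
      suppressWarnings(detect_bimera(uni$seq[i], cand, uni$abundance[i], ...))
    verdict[i] <- v$verdict
  }
  chimeric <- uni$seq[verdict == "chimeric"]
  keep <- reads[!(reads$seq %in% chimeric), , drop = FALSE]
  rownames(keep) <- NULL
  list(keep = keep,
       report = data.frame(seq = uni$seq, abundance = uni$abundance,
                           verdict = verdict, stringsAsFactors = FALSE))
}
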