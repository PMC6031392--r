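# Per-window mismatch counts of an encoded primer against an encoded
# template, for every start offset. Returns an integer vector of length
# (length(template) - length(primer) + 1).
window_mismatches <- function(primer_bits, template_bits) {
  plen <- length(primer_bits)
  n <- length(template_bits) - plen + 1L
  if (n < 1L) return(integer(0L))
  mm <- integer(n)
  for (i in seq_len(plen)) {
    mm <- mm + as.integer(bitwAnd(primer_bits[i],
                                  template_bits[i:(i + n - 1L)]) == 0L)
  }
  mm
}

#' Scan a template for degenerate-primer binding sites
#'
#' Forward primers are compared directly against the template; reverse
#' primers are compared as their reverse complement, with the site still
#' reported in template coordinates (0-based, half-open) on the minus
#' strand.
#'
#' @param primer a [degenerate_primer()].
#' @param template DNA string.
#' @param max_mm report sites with at most this many mismatches.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `mismatches`, `strand`, sorted by position.
#' @export
scan_binding_sites <- function(primer, template, max_mm = 1L) {
  stopifnot(inherits(primer, "degenerate_primer"))
  query <- if (primer$orientation == "reverse") revcomp(primer$sequence) else primer$sequence
  pb <- encode_primer(query)
  tb <- encode_target(template)
  if (length(tb) < length(pb)) {
    stop("template (", length(tb), " nt) shorter than primer (", length(pb), " nt)")
  }
  mm <- window_mismatches(pb, tb)
  hit <- which(mm <= max_mm)
  data.frame(
    start = hit - 1L,
    end = hit - 1L + length(pb),
    mismatches = mm[hit],
    strand = rep(if (primer$orientation == "reverse") "-" else "+",
                 length(hit)),
    stringsAsFactors = FALSE
  )
}

# Mismatches within the primer's 3'-terminal `protect` bases for a window
# starting at `start0` (0-based) on the template. For a reverse primer the
# 3' end lies at the left (lowest template coordinates) of the site.
protect_mismatches <- function(primer, template_bits, start0, protect) {
  query <- if (primer$orientation == "reverse") revcomp(primer$sequence) else primer$sequence
  pb <- encode_primer(query)
  plen <- length(pb)
  idx <- if (primer$orientation == "reverse") seq_len(protect) else (plen - protect + 1L):plen
  tpos <- start0 + idx  # 1-based template positions of those primer bases
  sum(bitwAnd(pb[idx], template_bits[tpos]) == 0L)
}

#' Predict the PCR product of a primer pair on a template
#'
#' Amplification is predicted iff both primers have a binding site with at
#' most `max_mm` total mismatches and a perfect 3'-terminal
#' `three_prime_protect`-mer. When several site pairs are possible the
#' shortest product is reported (leftmost forward site on ties).
#'
#' @param fwd forward [degenerate_primer()].
#' @param rev reverse [degenerate_primer()].
#' @param template DNA string.
#' @param max_mm maximum total mismatches per primer site.
#' @param three_prime_protect number of 3'-terminal bases that must match
#'   perfectly.
#' @return a list with fields `fwd_start`, `fwd_end`, `rev_start`,
#'   `rev_end`, `length`, `fwd_mm`, `rev_mm` (coordinates 0-based
#'   half-open), or `NULL` when no product is predicted.
#' @export
predict_amplicon <- function(fwd, rev, template, max_mm = 1L,
                             three_prime_protect = 4L) {
  stopifnot(fwd$orientation == "forward", rev$orientation == "reverse")
  tb <- encode_target(template)
  fs <- scan_binding_sites(fwd, template, max_mm)
  rs <- scan_binding_sites(rev, template, max_mm)
  if (nrow(fs) == 0L || nrow(rs) == 0L) return(NULL)
  keep_f <- vapply(fs$start, function(s)
    protect_mismatches(fwd, tb, s, three_prime_protect) == 0L, logical(1L))
  keep_r <- vapply(rs$start, function(s)
    protect_mismatches(rev, tb, s, three_prime_protect) == 0L, logical(1L))
  fs <- fs[keep_f, , drop = FALSE]
  rs <- rs[keep_r, , drop = FALSE]
  if (nrow(fs) == 0L || nrow(rs) == 0L) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(fs))) {
    ok <- rs$start >= fs$end[i]
    if (!any(ok)) next
    j <- which(ok)[1L]  # sites sorted by position -> shortest product
    len <- rs$end[j] - fs$start[i]
    if (is.null(best) || len < best$length) {
      best <- list(fwd_start = fs$start[i], fwd_end = fs$end[i],
                   rev_start = rs$start[j], rev_end = rs$end[j],
                   length = len, fwd_mm = fs$mismatches[i],
                   rev_mm = rs$mismatches[j])
    }
  }
  best
}

# Degenerate consensus of one alignment column: the smallest IUPAC set
# covering observed target bases, added most-frequent first until the
# covered fraction reaches `conservation`.
column_consensus_bits <- function(bases, conservation) {
  bases <- toupper(bases)
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  if (length(bases) == 0L) return(NA_integer_)
  tab <- sort(table(factor(bases, levels = c("A", "C", "G", "T"))),
              decreasing = TRUE)
  tab <- tab[tab > 0L]
  covered <- 0
  bits <- 0L
  for (b in names(tab)) {
    bits <- bitwOr(bits, IUPAC_BITS[[b]])
    covered <- covered + tab[[b]] / length(bases)
    if (covered >= conservation) break
  }
  bits
}

#' Design a discriminative (optionally deliberately mismatched) primer
#'
#' Slides a window over a target/outgroup alignment, builds the degenerate
#' consensus of the targets, and — when the consensus does not separate the
#' outgroups well enough — introduces up to one deliberate substitution
#' (outside the 3'-protected zone) that maximizes the minimum outgroup
#' mismatch count while keeping every target within the allowed mismatch
#' budget. This is the strategy behind En771R: a single engineered base
#' breaks annealing on the CAG-repeat region of the nearest non-target
#' relative while all targets remain amplifiable.
#'
#' @param target_alignment character vector of aligned target sequences
#'   (shared coordinates; `-` for gaps), length >= 2.
#' @param outgroup_alignment character vector of aligned outgroup sequences
#'   in the same coordinates.
#' @param params list with fields `window` (primer length, default 20),
#'   `min_conservation` (fraction of targets a consensus base set must
#'   cover, default 0.9), `min_outgroup_mm` (required minimum outgroup
#'   mismatches, default 2), `max_engineered` (0 or 1 deliberate
#'   substitutions, default 1), `three_prime_protect` (default 4),
#'   `max_target_mm` (per-target budget after engineering, default 1), and
#'   `orientation` ("forward"/"reverse": reverse emits the reverse
#'   complement of the window consensus).
#' @return data.frame of candidates ranked by (min outgroup mismatches
#'   desc, target mismatch sum asc, window start asc), with columns
#'   `sequence`, `start` (0-based alignment column), `min_outgroup_mm`,
#'   `target_mm_sum`, `engineered_pos` (1-based window position, NA if
#'   none), `engineered_base`. Zero rows (with a message) when no window
#'   can reach `min_outgroup_mm`.
#' @export
design_discriminative_primer <- function(target_alignment, outgroup_alignment,
                                         params = list()) {
  p <- modifyList(list(window = 20L, min_conservation = 0.9,
                       min_outgroup_mm = 2L, max_engineered = 1L,
                       three_prime_protect = 4L, max_target_mm = 1L,
                       orientation = "forward"), params)
  stopifnot(length(target_alignment) >= 2L)
  ncol_aln <- unique(nchar(c(target_alignment, outgroup_alignment)))
  if (length(ncol_aln) != 1L) stop("alignments do not share coordinates")
  tmat <- do.call(rbind, strsplit(toupper(target_alignment), "", fixed = TRUE))
  omat <- do.call(rbind, strsplit(toupper(outgroup_alignment), "", fixed = TRUE))
  w <- p$window
  # window positions protected at the primer 3' end, in window coordinates
  protect_cols <- if (p$orientation == "reverse") seq_len(p$three_prime_protect)
                  else (w - p$three_prime_protect + 1L):w
  out <- list()
  for (s in seq_len(ncol_aln - w + 1L)) {
    cols <- s:(s + w - 1L)
    twin <- tmat[, cols, drop = FALSE]
    if (any(!(twin %in% c("A", "C", "G", "T")))) next  # gapped/ambiguous window
    bits <- vapply(seq_len(w), function(j)
      column_consensus_bits(twin[, j], p$min_conservation), integer(1L))
    if (anyNA(bits)) next
    tgt_enc <- apply(twin, 1L, function(r) unname(IUPAC_BITS[r]))
    tgt_enc <- matrix(tgt_enc, nrow = w)  # w x n_targets
    ogr_enc <- apply(omat[, cols, drop = FALSE], 1L, encode_row_bits)
    ogr_enc <- matrix(ogr_enc, nrow = w)
    cand <- engineer_window(bits, tgt_enc, ogr_enc, p, protect_cols)
    if (is.null(cand)) next
    cand$start <- s - 1L
    out[[length(out) + 1L]] <- cand
  }
  if (length(out) == 0L) {
    message("no window reaches the required minimum outgroup mismatches (",
            p$min_outgroup_mm, "); targets and outgroups may be indistinguishable")
    return(data.frame(sequence = character(0L), start = integer(0L),
                      min_outgroup_mm = integer(0L), target_mm_sum = integer(0L),
                      engineered_pos = integer(0L), engineered_base = character(0L)))
  }
  res <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  res <- res[order(-res$min_outgroup_mm, res$target_mm_sum, res$start), ]
  rownames(res) <- NULL
  if (p$orientation == "reverse") res$sequence <- revcomp(res$sequence)
  res
}

encode_row_bits <- function(ch) {
  b <- unname(IUPAC_BITS[ch])
  b[is.na(b) | ch == "N"] <- 0L
  b
}

# Evaluate one window's consensus; engineer a single substitution if needed
# and allowed. Returns NULL when the window cannot reach min_outgroup_mm.
engineer_window <- function(bits, tgt_enc, ogr_enc, p, protect_cols) {
  mm_profile <- function(b, enc) colSums(matrix(bitwAnd(b, enc), nrow = length(b)) == 0L)
  tgt_mm <- mm_profile(bits, tgt_enc)
  if (any(tgt_mm > p$max_target_mm)) return(NULL)
  ogr_mm <- if (ncol(ogr_enc) > 0L) mm_profile(bits, ogr_enc) else Inf
  best <- list(bits = bits, min_ogr = min(ogr_mm), tsum = sum(tgt_mm),
               pos = NA_integer_, base = NA_character_)
  if (best$min_ogr < p$min_outgroup_mm && p$max_engineered >= 1L) {
    for (j in setdiff(seq_along(bits), protect_cols)) {
      for (b in c("A", "C", "G", "T")) {
        nb <- IUPAC_BITS[[b]]
        if (nb == bits[j]) next
        trial <- bits
        trial[j] <- nb
        t_mm <- mm_profile(trial, tgt_enc)
        if (any(t_mm > p$max_target_mm)) next
        o_mm <- if (ncol(ogr_enc) > 0L) min(mm_profile(trial, ogr_enc)) else Inf
        better <- o_mm > best$min_ogr ||
          (o_mm == best$min_ogr && sum(t_mm) < best$tsum)
        if (better) {
          best <- list(bits = trial, min_ogr = o_mm, tsum = sum(t_mm),
                       pos = j, base = b)
        }
      }
    }
  }
  # require a discrimination margin: every outgroup must mismatch the
  # candidate strictly more than the worst-matching target does
  tmax <- max(mm_profile(best$bits, tgt_enc))
  if (best$min_ogr < p$min_outgroup_mm || best$min_ogr <= tmax) return(NULL)
  list(sequence = paste(IUPAC_FROM_BITS[as.character(best$bits)], collapse = ""),
       min_outgroup_mm = as.integer(min(best$min_ogr, length(bits))),
       target_mm_sum = as.integer(best$tsum),
       engineered_pos = best$pos, engineered_base = best$base)
}

#' Evaluate a primer pair against a reference panel
#'
#' In-silico analogue of a primer specificity/sensitivity test:
#' sensitivity = fraction of target references predicted to amplify;
#' specificity = fraction of amplified references that are target.
#'
#' @param fwd,rev [degenerate_primer()] objects.
#' @param panel data.frame with columns `id`, `lineage`
#'   (semicolon-separated ranks), `seq`.
#' @param target_taxon lineage prefix (or single rank name) defining the
#'   target group; matched against any rank of the lineage.
#' @param max_mm,three_prime_protect amplification rule, see
#'   [predict_amplicon()].
#' @return list with `sensitivity`, `specificity` (NaN when nothing
#'   amplified), `n_amplified`, and a per-record data.frame `table`.
#' @export
evaluate_primer_pair <- function(fwd, rev, panel, target_taxon,
                                 max_mm = 1L, three_prime_protect = 4L) {
  is_target <- vapply(strsplit(panel$lineage, ";", fixed = TRUE),
                      function(r) target_taxon %in% trimws(r), logical(1L))
  if (!any(is_target)) stop("target taxon '", target_taxon,
                            "' matches no panel record")
  preds <- lapply(panel$seq, function(s)
    predict_amplicon(fwd, rev, s, max_mm, three_prime_protect))
  amplified <- !vapply(preds, is.null, logical(1L))
  tab <- data.frame(
    id = panel$id,
    target = is_target,
    amplified = amplified,
    fwd_mm = vapply(preds, function(x) if (is.null(x)) NA_integer_ else x$fwd_mm, integer(1L)),
    rev_mm = vapply(preds, function(x) if (is.null(x)) NA_integer_ else x$rev_mm, integer(1L)),
    product_length = vapply(preds, function(x) if (is.null(x)) NA_integer_ else x$length, integer(1L)),
    stringsAsFactors = FALSE
  )
  list(
    sensitivity = sum(amplified & is_target) / sum(is_target),
    specificity = if (any(amplified)) sum(amplified & is_target) / sum(amplified) else NaN,
    n_amplified = sum(amplified),
    table = tab
  )
}
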