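# IUPAC nucleotide codes as 4-bit sets over (A=1, C=2, G=4, T=8).
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 15L
)

IUPAC_FROM_BITS <- setNames(names(IUPAC_BITS), IUPAC_BITS)

# Encode a primer string (degenerate codes allowed) as bit sets.
encode_primer <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bits <- unname(IUPAC_BITS[ch])
  if (anyNA(bits)) {
    stop("illegal primer character(s): ",
         paste(unique(ch[is.na(bits)]), collapse = ", "))
  }
  bits
}

# Encode a target/template string. An ambiguous target base matches a primer
# code iff their expansion sets intersect, except N (and any non-IUPAC
# character, e.g. a gap) which never matches.
encode_target <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bits <- unname(IUPAC_BITS[ch])
  bits[is.na(bits) | ch == "N"] <- 0L
  bits
}

#' Count mismatches between a degenerate primer window and a target window
#'
#' A position matches iff the target base's expansion set intersects the
#' primer code's expansion set (e.g. primer R = A/G matches target A or G).
#' `N` in the target never matches (conservative against reference
#' ambiguity).
#'
#' @param primer_window IUPAC string (5'->3', already oriented to the strand
#'   being compared).
#' @param target_window plain or ambiguous DNA string of the same length.
#' @return integer mismatch count.
#' @export
iupac_mismatches <- function(primer_window, target_window) {
  p <- encode_primer(primer_window)
  t <- encode_target(target_window)
  if (length(p) != length(t)) {
    stop("primer window (", length(p), " nt) and target window (",
         length(t), " nt) differ in length")
  }
  sum(bitwAnd(p, t) == 0L)
}

# Reverse complement preserving IUPAC degeneracy.
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Pick one concrete base per position of a degenerate primer
# (deterministically: the lexicographically first base in each code's set).
disambiguate_primer <- function(primer_seq) {
  bits <- encode_primer(primer_seq)
  bases <- c("A", "C", "G", "T")
  vapply(bits, function(b) {
    bases[which(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L)[1L]]
  }, character(1L)) |> paste(collapse = "")
}

#' Construct a degenerate primer object
#'
#' @param name primer name.
#' @param sequence 5'->3' IUPAC string, length >= 10.
#' @param orientation `"forward"` or `"reverse"`.
#' @return an object of class `degenerate_primer`.
#' @export
degenerate_primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  encode_primer(sequence)  # validates alphabet
  if (nchar(sequence) < 10L) stop("primer '", name, "' is shorter than 10 nt")
  structure(list(name = name, sequence = sequence, orientation = orientation),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s) 5'-%s-3' [%d nt]\n",
              x$name, x$orientation, x$sequence, nchar(x$sequence)))
  invisible(x)
}

#' The published Endozoicomonas-specific reverse primer En771R
#'
#' Carries a deliberate single-base mismatch (T at position 14) against the
#' consensus of the target genus, engineered to break annealing on the
#' CAG-repeat region of the nearest non-target neighbor.
#' @return a `degenerate_primer`.
#' @export
primer_en771r <- function() {
  degenerate_primer("En771R", "TCAGTGTCARRCCTGAGTGT", "reverse")
}

#' The un-engineered ("matched") 771R reverse primer
#' @return a `degenerate_primer`.
#' @export
primer_matched_771r <- function() {
  degenerate_primer("matched771R", "TCAGTGTCARRCCAGAGTGT", "reverse")
}

#' The bacterial universal forward primer 27F
#' @return a `degenerate_primer`.
#' @export
primer_27f <- function() {
  degenerate_primer("27F", "AGAGTTTGATCMTGGCTCAG", "forward")
}

#' The bacterial universal reverse primer 341R
#' @return a `degenerate_primer`.
#' @export
primer_341r <- function() {
  degenerate_primer("341R", "CTGCTGCCTCCCGTAGG", "reverse")
}
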