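# Read sets are plain data.frames: columns id, seq, qual (Phred+33 string,
# NA for FASTA input) and sample (NA until demultiplexed). This keeps the
# QC stages vectorizable and the fixtures trivially constructible in tests.

read_set <- function(id, seq, qual = NA_character_, sample = NA_character_) {
  data.frame(id = as.character(id), seq = toupper(seq),
             qual = qual, sample = sample, stringsAsFactors = FALSE)
}

#' Parse a (possibly line-wrapped) FASTA file
#'
#' @param path input file.
#' @return data.frame with columns `id`, `seq`, `qual` (NA), `sample` (NA);
#'   the full description line is kept in attribute `desc`.
#' @export
parse_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0L) stop("no FASTA records in ", path)
  desc <- names(x)
  ids <- vapply(strsplit(desc, "[ \t]"), `[[`, character(1L), 1L)
  out <- read_set(ids, as.character(x))
  attr(out, "desc") <- desc
  out
}

#' Write records as FASTA
#'
#' @param records read-set data.frame (or one with `id`/`seq` columns). If a
#'   `desc` column is present it is used as the full header line.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- if (!is.null(records$desc)) records$desc else records$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Parse a 4-line-record FASTQ file (Phred+33)
#'
#' Reports the record id and line number on malformed input (truncated
#' record, sequence/quality length mismatch, illegal characters).
#'
#' @param path input file.
#' @return read-set data.frame (`id`, `seq`, `qual`, `sample`).
#' @export
parse_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) stop("no FASTQ records in ", path)
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hd, 1L, 1L) != "@" | substr(pl, 1L, 1L) != "+")
  if (length(bad)) {
    stop("malformed FASTQ record at line ", (bad[1L] - 1L) * 4L + 1L,
         " of ", path)
  }
  ids <- sub("^@", "", vapply(strsplit(hd, "[ \t]"), `[[`, character(1L), 1L))
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) {
    stop("sequence/quality length mismatch for record '", ids[bad[1L]],
         "' at line ", (bad[1L] - 1L) * 4L + 2L)
  }
  bad <- grep("[^ACGTNRYSWKMBDHV]", sq)
  if (length(bad)) {
    stop("illegal sequence character in record '", ids[bad[1L]],
         "' at line ", (bad[1L] - 1L) * 4L + 2L)
  }
  read_set(ids, sq, ql)
}

#' Write records as FASTQ (Phred+33)
#' @param records read-set data.frame with non-NA `qual`.
#' @param path output file.
#' @export
write_fastq <- function(records, path) {
  if (anyNA(records$qual)) stop("records without qualities cannot be written as FASTQ")
  out <- rbind(paste0("@", records$id), records$seq, "+", records$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

phred_scores <- function(qual) as.integer(charToRaw(qual)) - 33L
phred_string <- function(scores) rawToChar(as.raw(scores + 33L))

#' Read a barcode map TSV (sample <TAB> 4-nt tag)
#' @param path input file.
#' @return named character vector tag names = samples.
#' @export
read_barcode_map <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("sample", "tag"))
  validate_barcode_map(setNames(toupper(x$tag), x$sample))
}

validate_barcode_map <- function(map) {
  if (length(map) == 0L) stop("empty barcode map")
  if (any(nchar(map) != 4L)) stop("barcodes must be exactly 4 nt")
  if (anyDuplicated(map)) stop("barcodes must be unique")
  if (is.null(names(map)) || anyDuplicated(names(map))) {
    stop("barcode map must have unique sample names")
  }
  map
}
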