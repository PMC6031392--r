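# Divergence analysis of the published reference panel: 28 nearly
# full-length 16S rRNA genes (10 Endozoicomonas, 14 Spongiobacter, 4
# outgroup). Requires network access to NCBI and an aligner; the rest of
# the package is fully desk-scale.

#' GenBank accessions of the published 16S reference panel
#'
#' @return named character vector accession -> group
#'   ("Endozoicomonas", "Spongiobacter" or "outgroup").
#' @export
reference_panel_accessions <- function() {
  c(
    HE818335.1 = "Endozoicomonas", HE818343.1 = "Endozoicomonas",
    AB695089.1 = "Endozoicomonas", DQ917901.1 = "Endozoicomonas",
    FJ347758.1 = "Endozoicomonas", JX488685.1 = "Endozoicomonas",
    JX488684.2 = "Endozoicomonas", AB196667.1 = "Endozoicomonas",
    JX152780.1 = "Endozoicomonas", KC878324.1 = "Endozoicomonas",
    DQ889929.1 = "Spongiobacter", DQ917830.1 = "Spongiobacter",
    DQ889931.1 = "Spongiobacter", DQ889906.1 = "Spongiobacter",
    DQ889891.1 = "Spongiobacter", DQ889911.1 = "Spongiobacter",
    DQ917896.1 = "Spongiobacter", DQ917887.1 = "Spongiobacter",
    FJ457274.1 = "Spongiobacter", AB205011.1 = "Spongiobacter",
    DQ917871.1 = "Spongiobacter", DQ917863.1 = "Spongiobacter",
    DQ917879.1 = "Spongiobacter", DQ917877.1 = "Spongiobacter",
    EU599216.4 = "outgroup", AY130994.1 = "outgroup",
    AB467280.1 = "outgroup", AB467279.1 = "outgroup"
  )
}

#' Download FASTA records from GenBank (requires network)
#'
#' @param accessions character vector of accession.version ids.
#' @param dest output FASTA path.
#' @return `dest`, invisibly.
#' @export
fetch_genbank_fasta <- function(accessions, dest) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&rettype=fasta&retmode=text&id=",
    paste(accessions, collapse = ",")
  )
  status <- utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  if (status != 0L) stop("GenBank download failed (status ", status, ")")
  invisible(dest)
}

#' Mean within/between-group K2P divergence of the published panel
#'
#' Downloads the 28 reference accessions, aligns them with MAFFT, applies
#' complete deletion, and reports the group divergence table (the headline
#' value is the mean within-*Endozoicomonas* K2P distance).
#'
#' @param workdir scratch directory for the FASTA and alignment files.
#' @param n_site_bootstrap bootstrap replicates for the SE.
#' @param seed integer seed.
#' @return list with `divergence` (data.frame from [group_divergence()])
#'   and `informative_sites` (columns retained by complete deletion).
#' @export
reference_panel_divergence <- function(workdir = tempfile("genbank"),
                                       n_site_bootstrap = 100L, seed = 1L) {
  acc <- reference_panel_accessions()
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  raw <- file.path(workdir, "panel.fasta")
  fetch_genbank_fasta(names(acc), raw)
  if (Sys.which("mafft") == "") stop("mafft not found on PATH")
  aligned <- file.path(workdir, "panel_aligned.fasta")
  status <- system2("mafft", c("--auto", "--quiet", raw),
                    stdout = aligned)
  if (status != 0L) stop("mafft failed with status ", status)
  x <- parse_fasta(aligned)
  rows <- setNames(toupper(x$seq), x$id)
  # headers are accession.version followed by description
  groups <- acc[match(sub("\\..*$", "", names(rows)),
                      sub("\\..*$", "", names(acc)))]
  names(groups) <- names(rows)
  masked <- mask_gap_columns(rows)
  div <- group_divergence(masked$alignment, groups,
                          n_site_bootstrap = n_site_bootstrap, seed = seed)
  list(divergence = div, informative_sites = masked$retained)
}
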