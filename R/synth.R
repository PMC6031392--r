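# Synthetic reference panels and amplicon read sets with known ground
# truth. The generator emulates the structure of a specific-primer coral
# amplicon survey: a clade-structured target genus plus near-neighbor and
# distant outgroups, a ~750 bp amplicon flanked by a universal forward and
# a taxon-specific reverse primer site, 4-nt sample barcodes, 454-style
# substitution and homopolymer errors, and single-crossover bimeras.

#' Specify a clade for the synthetic reference panel
#'
#' @param name clade (genus) name; becomes the last lineage rank.
#' @param n_taxa number of reference taxa in the clade (>= 1).
#' @param depth expected substitutions/site from the clade ancestor (>= 0).
#' @param kappa transition/transversion rate ratio (> 0); a substitution
#'   is a transition with probability `kappa / (kappa + 2)`.
#' @param stem expected substitutions/site from the shared root to the
#'   clade ancestor (>= 0); controls between-clade divergence.
#' @param taxonomy_prefix semicolon-separated lineage down to family;
#'   `name` is appended as the genus rank.
#' @return a `clade_spec` list.
#' @export
clade_spec <- function(name, n_taxa, depth, kappa = 2, stem = 0,
                       taxonomy_prefix = "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;Hahellaceae") {
  stopifnot(n_taxa >= 1L, depth >= 0, kappa > 0, stem >= 0)
  structure(list(name = name, n_taxa = as.integer(n_taxa), depth = depth,
                 kappa = kappa, stem = stem,
                 taxonomy_prefix = taxonomy_prefix),
            class = "clade_spec")
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

# Substitute bases at `pos` of a character vector under the K2P-style
# scheme: transition with prob kappa/(kappa+2), else one of the two
# transversions uniformly.
substitute_bases <- function(chars, pos, kappa) {
  if (length(pos) == 0L) return(chars)
  ts <- runif(length(pos)) < kappa / (kappa + 2)
  new <- character(length(pos))
  new[ts] <- TRANSITION_OF[chars[pos[ts]]]
  if (any(!ts)) {
    new[!ts] <- vapply(chars[pos[!ts]], function(b)
      sample(TRANSVERSIONS_OF[[b]], 1L), character(1L))
  }
  chars[pos] <- new
  chars
}

# Realize a primer site window on the template strand: the concrete
# consensus for reverse primers is planted as its reverse complement.
realize_site <- function(primer) {
  cons <- disambiguate_primer(primer$sequence)
  if (primer$orientation == "reverse") revcomp(cons) else cons
}

# Introduce exactly `n_mm` mismatches to `primer` inside its planted
# window (given as a character vector in template orientation). Positions
# are drawn at random; replacement bases are chosen outside the primer
# code's expansion set so recomputing mismatches reproduces the count.
plant_mismatches <- function(window_chars, primer, n_mm) {
  plen <- length(window_chars)
  if (n_mm > plen) stop("requested mismatch count (", n_mm,
                        ") exceeds primer length (", plen, ")")
  if (n_mm == 0L) return(window_chars)
  q <- if (primer$orientation == "reverse") revcomp(primer$sequence) else primer$sequence
  bits <- encode_primer(q)
  pos <- sample.int(plen, n_mm)
  for (i in pos) {
    allowed <- c("A", "C", "G", "T")[bitwAnd(c(1L, 2L, 4L, 8L), bits[i]) == 0L]
    window_chars[i] <- if (length(allowed)) sample(allowed, 1L) else window_chars[i]
  }
  window_chars
}

#' Evolve a synthetic reference panel with controlled primer-site mismatches
#'
#' Generates a random root 16S-like sequence, plants primer landing sites
#' at fixed positions, and evolves each clade from the root: the primer
#' windows receive exactly the requested per-clade mismatch count (or an
#' explicit per-clade window sequence), and every other site mutates
#' independently with probability `depth`, transitions favored by `kappa`.
#'
#' @param root_length template length (nt); must span all primer sites.
#' @param clades list of [clade_spec()] objects.
#' @param primer_sites list of sites, each a list with fields `primer` (a
#'   [degenerate_primer()]), `start` (0-based template position) and either
#'   `clade_mm` (named integer vector clade -> mismatch count, default 0)
#'   or `clade_window` (named character vector clade -> explicit window in
#'   template orientation).
#' @param seed integer; fixes all randomness.
#' @return data.frame panel with columns `id`, `lineage`, `seq`.
#' @export
evolve_reference_panel <- function(root_length, clades, primer_sites, seed) {
  spans <- lapply(primer_sites, function(s) {
    plen <- nchar(s$primer$sequence)
    c(s$start + 1L, s$start + plen)
  })
  if (any(vapply(spans, max, numeric(1L)) > root_length)) {
    stop("root_length shorter than the span of the primer sites")
  }
  if (length(spans) > 1L) {
    ord <- order(vapply(spans, `[`, numeric(1L), 1L))
    for (i in seq_along(ord)[-1L]) {
      if (spans[[ord[i]]][1L] <= spans[[ord[i - 1L]]][2L]) {
        stop("overlapping primer sites")
      }
    }
  }
  site_pos <- unlist(lapply(spans, function(s) s[1L]:s[2L]))
  withr::with_seed(seed, {
    root <- sample(c("A", "C", "G", "T"), root_length, replace = TRUE)
    for (s in primer_sites) {
      w <- strsplit(realize_site(s$primer), "", fixed = TRUE)[[1L]]
      root[(s$start + 1L):(s$start + length(w))] <- w
    }
    records <- list()
    for (cl in clades) {
      anc <- root
      if (cl$stem > 0) {
        stem_mut <- setdiff(which(runif(root_length) < cl$stem), site_pos)
        anc <- substitute_bases(anc, stem_mut, cl$kappa)
      }
      for (s in primer_sites) {
        idx <- (s$start + 1L):(s$start + nchar(s$primer$sequence))
        if (!is.null(s$clade_window) && !is.na(s$clade_window[cl$name] %||% NA)) {
          anc[idx] <- strsplit(toupper(s$clade_window[[cl$name]]), "", fixed = TRUE)[[1L]]
        } else {
          n_mm <- 0L
          if (!is.null(s$clade_mm)) n_mm <- as.integer(s$clade_mm[cl$name] %||% 0L)
          if (is.na(n_mm)) n_mm <- 0L
          anc[idx] <- plant_mismatches(root[idx], s$primer, n_mm)
        }
      }
      for (k in seq_len(cl$n_taxa)) {
        taxon <- anc
        mut <- setdiff(which(runif(root_length) < cl$depth), site_pos)
        taxon <- substitute_bases(taxon, mut, cl$kappa)
        records[[length(records) + 1L]] <- data.frame(
          id = sprintf("%s_%02d", cl$name, k),
          lineage = paste(cl$taxonomy_prefix, cl$name, sep = ";"),
          seq = paste(taxon, collapse = ""),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, records)
  })
}

#' Read-simulation parameters
#'
#' @param n_reads_per_sample reads emitted per sample.
#' @param sub_error_rate per-base substitution error probability.
#' @param homopolymer_indel_rate per-run probability that a homopolymer of
#'   length >= 3 is lengthened or shortened by 1 nt (454-characteristic).
#' @param chimera_rate fraction of reads formed by a single crossover
#'   between two templates.
#' @param barcode_map named character vector sample -> unique 4-nt tag.
#' @param length_jitter maximum random 3' truncation (nt).
#' @param seed integer; fixes all randomness.
#' @return a `read_sim_params` list.
#' @export
read_sim_params <- function(n_reads_per_sample, barcode_map,
                            sub_error_rate = 0.005,
                            homopolymer_indel_rate = 0.01,
                            chimera_rate = 0.05, length_jitter = 30L,
                            seed = 1L) {
  rates <- c(sub_error_rate, homopolymer_indel_rate, chimera_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  validate_barcode_map(barcode_map)
  structure(list(n_reads_per_sample = as.integer(n_reads_per_sample),
                 barcode_map = barcode_map, sub_error_rate = sub_error_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 chimera_rate = chimera_rate,
                 length_jitter = as.integer(length_jitter),
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

Q_BASE <- 30L  # baseline quality
Q_ERR <- 10L   # quality emitted at error positions

# Apply substitution + homopolymer-indel errors to one sequence; returns
# list(seq chars, qual ints).
apply_read_errors <- function(chars, sub_rate, hp_rate) {
  qual <- rep(Q_BASE, length(chars))
  err <- which(runif(length(chars)) < sub_rate)
  if (length(err)) {
    chars <- substitute_bases(chars, err, kappa = 1)
    qual[err] <- Q_ERR
  }
  if (hp_rate > 0) {
    r <- rle(chars)
    runs <- which(r$lengths >= 3L)
    hit <- runs[runif(length(runs)) < hp_rate]
    if (length(hit)) {
      ends <- cumsum(r$lengths)
      out_c <- list()
      out_q <- list()
      prev <- 0L
      for (i in seq_along(r$lengths)) {
        idx <- (prev + 1L):ends[i]
        ci <- chars[idx]
        qi <- qual[idx]
        if (i %in% hit) {
          if (runif(1L) < 0.5) {           # lengthen
            ci <- c(ci, ci[1L])
            qi <- c(qi, Q_ERR)
          } else {                          # shorten
            ci <- ci[-1L]
            qi <- qi[-1L]
          }
        }
        out_c[[i]] <- ci
        out_q[[i]] <- qi
        prev <- ends[i]
      }
      chars <- unlist(out_c)
      qual <- unlist(out_q)
    }
  }
  list(seq = chars, qual = qual)
}

#' Simulate barcoded amplicon reads from a reference panel
#'
#' Each read is `barcode + forward primer + amplicon body`, where the
#' amplicon is the predicted product of the primer pair on the source
#' template (the 5' primer region carries the synthesized primer bases, as
#' in a real PCR product). Chimeras are formed by a single crossover,
#' uniform in the middle 50% of the amplicon, between two templates drawn
#' from the same sample profile. Substitution and homopolymer-indel errors
#' are applied downstream of the (error-free) barcode; qualities are a
#' constant Q30 baseline with Q10 at error positions.
#'
#' @param panel data.frame from [evolve_reference_panel()].
#' @param profile numeric matrix of taxon weights (rows = panel ids, cols =
#'   samples); zero-weight taxa are allowed, absent ids are an error.
#' @param fwd,rev the primer pair ([degenerate_primer()]).
#' @param params a [read_sim_params()] object.
#' @param max_mm,three_prime_protect amplification rule used to derive the
#'   per-taxon amplicon (see [predict_amplicon()]).
#' @return list with `reads` (read-set data.frame) and `truth` (data.frame:
#'   read id, sample, source taxon, chimera flag, second parent, crossover).
#' @export
simulate_amplicon_reads <- function(panel, profile, fwd, rev, params,
                                    max_mm = 1L, three_prime_protect = 4L) {
  stopifnot(inherits(params, "read_sim_params"))
  missing <- setdiff(rownames(profile), panel$id)
  if (length(missing)) {
    stop("profile references taxa absent from panel: ",
         paste(missing, collapse = ", "))
  }
  fwd_real <- disambiguate_primer(fwd$sequence)
  amplicons <- list()
  for (tx in rownames(profile)) {
    tpl <- panel$seq[panel$id == tx]
    pred <- predict_amplicon(fwd, rev, tpl, max_mm, three_prime_protect)
    if (is.null(pred) && any(profile[tx, ] > 0)) {
      stop("profiled taxon '", tx, "' yields no predicted amplicon")
    }
    if (!is.null(pred)) {
      body <- substr(tpl, pred$fwd_start + 1L, pred$rev_end)
      # PCR product carries the primer bases at its 5' end
      body <- paste0(fwd_real, substr(body, nchar(fwd_real) + 1L, nchar(body)))
      amplicons[[tx]] <- strsplit(body, "", fixed = TRUE)[[1L]]
    }
  }
  samples <- colnames(profile)
  withr::with_seed(params$seed, {
    reads <- list()
    truth <- list()
    for (sm in samples) {
      w <- profile[, sm]
      w <- w[w > 0]
      taxa <- sample(names(w), params$n_reads_per_sample, replace = TRUE,
                     prob = w)
      is_chim <- runif(params$n_reads_per_sample) < params$chimera_rate
      for (i in seq_len(params$n_reads_per_sample)) {
        id <- sprintf("%s_r%05d", sm, i)
        src <- taxa[i]
        parent2 <- NA_character_
        xover <- NA_integer_
        chars <- amplicons[[src]]
        if (is_chim[i] && length(w) > 1L) {
          parent2 <- sample(setdiff(names(w), src), 1L)
          L <- min(length(chars), length(amplicons[[parent2]]))
          xover <- floor(L * runif(1L, 0.25, 0.75))
          chars <- c(chars[seq_len(xover)],
                     amplicons[[parent2]][(xover + 1L):length(amplicons[[parent2]])])
        } else {
          is_chim[i] <- FALSE
        }
        er <- apply_read_errors(chars, params$sub_error_rate,
                                params$homopolymer_indel_rate)
        if (params$length_jitter > 0L) {
          cut <- sample.int(params$length_jitter + 1L, 1L) - 1L
          if (cut > 0L && cut < length(er$seq)) {
            keep <- seq_len(length(er$seq) - cut)
            er$seq <- er$seq[keep]
            er$qual <- er$qual[keep]
          }
        }
        tag <- params$barcode_map[[sm]]
        reads[[length(reads) + 1L]] <- data.frame(
          id = id,
          seq = paste0(tag, paste(er$seq, collapse = "")),
          qual = paste0(phred_string(rep(Q_BASE, 4L)), phred_string(er$qual)),
          sample = NA_character_, stringsAsFactors = FALSE
        )
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, sample = sm, taxon = src, chimera = is_chim[i],
          parent2 = parent2, crossover = xover, stringsAsFactors = FALSE
        )
      }
    }
    list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
  })
}

#' Default synthetic study panel
#'
#' Five clades emulating the survey's taxonomic structure: the target
#' genus (10 taxa), a sister group within the same family (6 taxa), a
#' near-neighbor whose specific-primer site carries the 2 engineered-site
#' mismatches (3 taxa, the *S. agarivorans* analogue), and two distant
#' outgroup genera (4 mismatches at the specific site). All clades carry
#' perfect universal primer sites (27F at position 100, 341R near 450) and
#' the specific reverse site ends at position 850, giving the ~750 bp
#' product of the published assay.
#'
#' @param seed integer seed.
#' @param depth_target within-clade depth of the target genus.
#' @return data.frame panel (`id`, `lineage`, `seq`).
#' @export
default_panel <- function(seed = 101L, depth_target = 0.05) {
  hahel <- "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;Hahellaceae"
  cellv <- "Bacteria;Proteobacteria;Gammaproteobacteria;Cellvibrionales;Cellvibrionaceae"
  alter <- "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Alteromonadaceae"
  clades <- list(
    clade_spec("Endozoicomonas", 10L, depth_target, stem = 0.02,
               taxonomy_prefix = hahel),
    clade_spec("Spongiobacter", 6L, 0.04, stem = 0.02,
               taxonomy_prefix = hahel),
    clade_spec("Simiduia", 3L, 0.03, stem = 0.06, taxonomy_prefix = cellv),
    clade_spec("Kistimonas", 3L, 0.04, stem = 0.05, taxonomy_prefix = hahel),
    clade_spec("Alteromonas", 3L, 0.05, stem = 0.10, taxonomy_prefix = alter)
  )
  en771r <- primer_en771r()
  sites <- list(
    list(primer = primer_27f(), start = 100L),
    list(primer = primer_341r(), start = 440L),
    list(primer = en771r, start = 850L - nchar(en771r$sequence),
         clade_mm = c(Endozoicomonas = 0L, Spongiobacter = 0L,
                      Simiduia = 2L, Kistimonas = 4L, Alteromonas = 4L))
  )
  evolve_reference_panel(900L, clades, sites, seed)
}

#' Write a panel as FASTA with lineage description lines
#' @param panel data.frame (`id`, `lineage`, `seq`).
#' @param path output file.
#' @export
write_panel_fasta <- function(panel, path) {
  panel$desc <- paste(panel$id, panel$lineage)
  write_fasta(panel, path)
}

#' Read a panel FASTA with semicolon-separated lineages in the description
#' @param path input file.
#' @return data.frame (`id`, `lineage`, `seq`).
#' @export
read_panel_fasta <- function(path) {
  x <- parse_fasta(path)
  desc <- attr(x, "desc")
  lineage <- sub("^\\S+\\s+", "", desc)
  data.frame(id = x$id, lineage = lineage, seq = x$seq,
             stringsAsFactors = FALSE)
}
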