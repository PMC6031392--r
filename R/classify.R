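# RDP-style naive-Bayes k-mer classifier: genus-conditional word
# probabilities with the standard (count + word prior)/(M + 1) smoothing,
# 1/8-subsampling bootstrap confidence, and the multi-database rescue
# procedure used to recover target reads left unclassified by the primary
# reference set.

RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

parse_lineage <- function(lineage) {
  r <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1L]])
  length(r) <- length(RANKS)
  r[is.na(r) | r == ""] <- "unclassified"
  # no gaps: a named rank never follows an unclassified one
  uncl <- r == "unclassified"
  if (any(uncl) && any(!uncl[seq(which(uncl)[1L], length(r))])) {
    stop("lineage has a named rank after an unclassified one: ", lineage)
  }
  setNames(r, RANKS)
}

# Distinct 8-mer presence matrix (sequences x observed words) via
# Biostrings; words containing non-ACGT characters are not counted.
word_presence <- function(seqs, w) {
  freq <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                               width = w)
  freq > 0L
}

#' Train a naive-Bayes k-mer classifier
#'
#' Stores genus-conditional word probabilities
#' `P(word | genus) = (m(word, genus) + P_word) / (M(genus) + 1)`, where
#' `m` counts training sequences of the genus containing the word,
#' `M(genus)` is the genus training-set size, and the word prior is
#' `P_word = (n(word) + 0.5) / (N + 1)` over the whole corpus.
#'
#' @param references data.frame with columns `id`, `lineage`
#'   (semicolon-separated domain..genus), `seq`.
#' @param w word size in nt (default 8).
#' @return a `classifier_model` list (log-probability matrix words x
#'   genera, genus lineages, word size).
#' @export
train_classifier <- function(references, w = 8L) {
  short <- nchar(references$seq) < w
  if (any(short)) {
    stop("training sequence(s) shorter than ", w, " nt: ",
         paste(references$id[short], collapse = ", "))
  }
  lin <- t(vapply(references$lineage, parse_lineage, character(length(RANKS))))
  rownames(lin) <- NULL
  genus <- lin[, "genus"]
  if (length(unique(genus)) < 2L) {
    stop("training corpus has a single genus; classification is degenerate")
  }
  pres <- word_presence(references$seq, w)
  seen <- colSums(pres) > 0L
  pres <- pres[, seen, drop = FALSE]
  N <- nrow(pres)
  prior <- (colSums(pres) + 0.5) / (N + 1)
  genera <- sort(unique(genus))
  m <- rowsum(pres + 0L, group = genus)            # genera x words
  M <- as.vector(table(factor(genus, levels = rownames(m))))
  cond <- (t(m) + matrix(prior, ncol(m), nrow(m))) /
    matrix(M + 1, ncol(m), nrow(m), byrow = TRUE)  # words x genera
  logp <- log(cond)
  lineages <- lin[match(colnames(logp), genus), , drop = FALSE]
  rownames(lineages) <- colnames(logp)
  structure(list(w = w, logp = logp, lineages = lineages),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("<classifier_model> %d-mers, %d words, %d genera\n",
              x$w, nrow(x$logp), ncol(x$logp)))
  invisible(x)
}

unclassified_result <- function(id) {
  list(id = id, lineage = setNames(rep("unclassified", length(RANKS)), RANKS),
       confidence = setNames(rep(0, length(RANKS)), RANKS),
       genus = "unclassified")
}

#' Classify one sequence with bootstrap confidence
#'
#' The full-word genus score is the sum of log conditional probabilities
#' of the read's distinct words; each bootstrap trial rescores
#' `ceiling(k/8)` words drawn with replacement from the read's `k` words.
#' Per-rank confidence is the fraction of trials whose winning genus
#' shares the assigned lineage down to that rank, which makes confidence
#' non-increasing from domain to genus. The assignment is truncated at the
#' deepest rank reaching `cutoff`; deeper ranks become "unclassified".
#'
#' @param model a trained `classifier_model`.
#' @param seq DNA string (>= word size).
#' @param n_bootstrap bootstrap trials (default 100).
#' @param cutoff confidence threshold for assignment (default 0.8).
#' @param seed integer seed for the bootstrap draws.
#' @param id read identifier carried into the result.
#' @return list with `id`, `lineage` (named rank vector, truncated),
#'   `full_lineage`, `confidence` (named numeric), `genus` (pre-truncation
#'   winner).
#' @export
classify_sequence <- function(model, seq, n_bootstrap = 100L, cutoff = 0.8,
                              seed = 1L, id = "query") {
  if (nchar(seq) < model$w) stop("sequence '", id, "' shorter than word size")
  pres <- word_presence(seq, model$w)[1L, ]
  idx <- match(names(pres)[pres], rownames(model$logp))
  idx <- idx[!is.na(idx)]
  k <- length(idx)
  if (k == 0L) {
    res <- unclassified_result(id)
    res$full_lineage <- res$lineage
    return(res)
  }
  L <- model$logp[idx, , drop = FALSE]
  full <- colSums(L)
  winner <- which(full == max(full))
  winner <- winner[order(colnames(L)[winner])][1L]  # deterministic tie-break
  assigned <- model$lineages[winner, ]
  nsub <- ceiling(k / 8)
  wins <- withr::with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(t) {
      sc <- colSums(L[sample.int(k, nsub, replace = TRUE), , drop = FALSE])
      wi <- which(sc == max(sc))
      wi[order(colnames(L)[wi])][1L]
    }, integer(1L))
  })
  win_lin <- model$lineages[wins, , drop = FALSE]
  agree <- t(apply(win_lin, 1L, function(r) r == assigned))  # trials x ranks
  path_ok <- apply(agree, 1L, cumall)                        # ranks x trials
  if (is.null(dim(path_ok))) path_ok <- matrix(path_ok, ncol = 1L)
  conf <- setNames(rowMeans(path_ok), RANKS)
  keep <- conf >= cutoff
  truncated <- assigned
  if (any(!keep)) {
    first_bad <- which(!keep)[1L]
    truncated[first_bad:length(RANKS)] <- "unclassified"
  }
  list(id = id, lineage = setNames(truncated, RANKS),
       full_lineage = setNames(assigned, RANKS),
       confidence = conf, genus = unname(assigned["genus"]))
}

cumall <- function(x) cumprod(as.numeric(x)) > 0

#' Classify a read set
#'
#' @param model a trained `classifier_model`.
#' @param reads read-set data.frame (`id`, `seq`, optionally `sample`).
#' @param n_bootstrap,cutoff see [classify_sequence()].
#' @param seed global seed; each read gets a derived child seed so results
#'   do not depend on processing order.
#' @return data.frame: `id`, `sample`, one column per rank (truncated
#'   assignment), `genus_raw` (pre-truncation winner), `conf_<rank>`
#'   columns.
#' @export
classify_reads <- function(model, reads, n_bootstrap = 100L, cutoff = 0.8,
                           seed = 1L) {
  res <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    r <- classify_sequence(model, reads$seq[i], n_bootstrap, cutoff,
                           seed = child_seed(seed, reads$id[i]),
                           id = reads$id[i])
    res[[i]] <- c(list(id = r$id), as.list(r$lineage),
                  list(genus_raw = r$genus),
                  setNames(as.list(r$confidence), paste0("conf_", RANKS)))
  }
  out <- do.call(rbind, lapply(res, as.data.frame, stringsAsFactors = FALSE))
  out$sample <- if (!is.null(reads$sample)) reads$sample else NA_character_
  out
}

#' Rescue unclassified reads with secondary reference databases
#'
#' Reads left "unclassified" by the primary classifier at (or below) the
#' trigger rank are reclassified against each secondary model; a read
#' counts toward the combined target set if its primary assignment carries
#' a target label or any secondary assignment does. Reads primary-assigned
#' to the target but not target-labelled by any secondary model are set
#' aside as "distantly related" and dropped from target-specific analyses
#' (cross-database agreement stand-in; flagged in the summary).
#'
#' @param primary data.frame from [classify_reads()] on the primary model.
#' @param secondary_models named list of `classifier_model`s (may be
#'   empty: rescue is then a no-op).
#' @param target_labels character vector of taxon names counting as target
#'   at any rank (e.g. the genus in one database, the family in another).
#' @param reads the read set that was classified (for the sequences).
#' @param trigger_rank rank at which "unclassified" triggers rescue
#'   (default "genus").
#' @param n_bootstrap,cutoff,seed passed to the secondary classifications.
#' @return list with per-read `detail` and a `summary` list:
#'   `total`, `primary_target_count`, `unclassified_count`,
#'   `rescued_count_per_database`, `rescued_count` (union),
#'   `combined_target_count`, `discarded_distant_count`,
#'   `non_target_count`.
#' @export
rescue_classify <- function(primary, secondary_models, target_labels, reads,
                            trigger_rank = "genus", n_bootstrap = 100L,
                            cutoff = 0.8, seed = 1L) {
  stopifnot(trigger_rank %in% RANKS)
  n <- nrow(primary)
  has_label <- function(df_rows) {
    apply(df_rows[, RANKS, drop = FALSE], 1L, function(r)
      any(r %in% target_labels))
  }
  primary_target <- has_label(primary)
  unclassified <- primary[[trigger_rank]] == "unclassified"
  rescued_db <- setNames(integer(length(secondary_models)),
                         names(secondary_models))
  rescued_any <- rep(FALSE, n)
  secondary_target_any <- rep(FALSE, n)
  if (length(secondary_models)) {
    need <- which(unclassified | primary_target)
    for (db in names(secondary_models)) {
      cls <- classify_reads(secondary_models[[db]],
                            reads[match(primary$id[need], reads$id), ,
                                  drop = FALSE],
                            n_bootstrap, cutoff,
                            seed = child_seed(seed, db))
      tgt <- has_label(cls)
      secondary_target_any[need] <- secondary_target_any[need] | tgt
      resc <- unclassified[need] & tgt
      rescued_db[db] <- sum(resc)
      rescued_any[need] <- rescued_any[need] | resc
    }
  }
  discarded <- if (length(secondary_models)) {
    primary_target & !secondary_target_any
  } else rep(FALSE, n)
  combined <- (primary_target & !discarded) | rescued_any
  detail <- data.frame(
    id = primary$id, sample = primary$sample,
    primary_target = primary_target, unclassified = unclassified,
    rescued = rescued_any, discarded_distant = discarded,
    combined_target = combined, stringsAsFactors = FALSE
  )
  list(detail = detail, summary = list(
    total = n,
    primary_target_count = sum(primary_target),
    unclassified_count = sum(unclassified),
    rescued_count_per_database = as.list(rescued_db),
    rescued_count = sum(rescued_any),
    combined_target_count = sum(combined),
    discarded_distant_count = sum(discarded),
    non_target_count = n - sum(primary_target & !discarded) -
      sum(rescued_any) - sum(discarded)
  ))
}

#' Primer specificity summary from classification counts
#'
#' Reproduces the survey's headline arithmetic: the primary-database
#' fraction, the combined (primary + rescued) fraction, and the remaining
#' unaccounted fraction, as percentages rounded half-away-from-zero to one
#' decimal.
#'
#' @param primary_target reads assigned to the target by the primary
#'   database.
#' @param rescued unclassified reads recovered as target by a secondary
#'   database.
#' @param total_qualified total qualified reads.
#' @return list `primary_pct`, `combined_pct`, `other_pct`.
#' @export
specificity_summary <- function(primary_target, rescued, total_qualified) {
  if (total_qualified <= 0) stop("total_qualified must be positive")
  if (primary_target + rescued > total_qualified) {
    stop("primary_target + rescued exceeds total_qualified")
  }
  list(
    primary_pct = round_half_away(100 * primary_target / total_qualified, 1L),
    combined_pct = round_half_away(100 * (primary_target + rescued) / total_qualified, 1L),
    other_pct = round_half_away(100 * (total_qualified - primary_target - rescued) / total_qualified, 1L)
  )
}

#' Fraction of unclassified reads rescued by a secondary database
#' @param rescued rescued read count.
#' @param unclassified unclassified read count.
#' @return percentage rounded half-away-from-zero to one decimal.
#' @export
rescue_fraction <- function(rescued, unclassified) {
  if (unclassified <= 0) stop("unclassified must be positive")
  round_half_away(100 * rescued / unclassified, 1L)
}
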