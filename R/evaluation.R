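# Scoring classifier output against simulation truth at every taxonomic
# rank, the predominant-match novelty breakdown, and cross-classifier
# agreement. Reads the classifier cannot place (unscoreable) and
# comparisons touching an UNKNOWN rank label are counted as their own
# "indeterminate" category and excluded from accuracy denominators --
# an unplaceable read is not a wrong read.

#' Read / write a predictions table
#'
#' Predictions TSV columns: `read_id`, `best_taxon`, `best_score`,
#' `runner_up_taxon`, `margin`, `n_scored_kmers` (the [classify_reads()]
#' output). Unclassified reads carry `NA` in `best_taxon`.
#'
#' @param path TSV path.
#' @return Data.frame of predictions.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "",
                    colClasses = c(read_id = "character",
                                   best_taxon = "character"))
}

#' @rdname read_predictions
#' @param predictions Data.frame from [classify_reads()].
#' @export
write_predictions <- function(predictions, path) {
  con <- file(path, open = "wb")
  utils::write.table(predictions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

.check_pred_truth <- function(predictions, truth) {
  stopifnot(is.data.frame(predictions), is.data.frame(truth),
            all(c("read_id", "best_taxon") %in% names(predictions)),
            all(c("read_id", "source_taxon") %in% names(truth)))
  missing <- setdiff(predictions$read_id, truth$read_id)
  if (length(missing) > 0L)
    stop("predicted read(s) absent from truth: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ...", call. = FALSE)
}

#' Per-rank classification accuracy against simulation truth
#'
#' A read is correct at a rank iff [agree_at_rank()] between its predicted
#' and true taxon is `"match"` there; reads whose comparison is
#' indeterminate (either lineage [UNKNOWN] at that rank, or the read
#' unclassified) are excluded from the denominator and reported separately.
#' Two averages are emitted: `accuracy` pools all reads;
#' `accuracy_per_organism` first computes the accuracy within each true
#' source taxon and then averages those, so small and large read sets per
#' organism weigh equally.
#'
#' @param predictions Data.frame with `read_id`, `best_taxon` (`NA` =
#'   unclassified), e.g. from [classify_reads()].
#' @param truth Data.frame with `read_id`, `source_taxon`, e.g. from
#'   [simulate_readset()] or its truth TSV.
#' @param taxonomy A `taxonomy_table` resolving every predicted and true
#'   taxon.
#' @param ranks Ranks to evaluate (default all of [taxonomy_ranks()]).
#' @return A `rank_accuracy_report` data.frame: one row per rank with
#'   `rank`, `n_evaluable`, `n_correct`, `n_indeterminate`, `accuracy`,
#'   `accuracy_per_organism`.
#' @export
rank_accuracy <- function(predictions, truth, taxonomy,
                          ranks = taxonomy_ranks()) {
  .check_pred_truth(predictions, truth)
  .check_rank(ranks)
  m <- merge(predictions[, c("read_id", "best_taxon")],
             truth[, c("read_id", "source_taxon")], by = "read_id")
  classified <- !is.na(m$best_taxon)
  rows <- lapply(ranks, function(r) {
    status <- rep("indeterminate", nrow(m))
    if (any(classified))
      status[classified] <- agree_at_rank(taxonomy, m$best_taxon[classified],
                                          m$source_taxon[classified], r)
    evaluable <- status != "indeterminate"
    # per-organism accuracy over evaluable reads only
    org_acc <- tapply(seq_len(nrow(m)), m$source_taxon, function(idx) {
      ev <- idx[status[idx] != "indeterminate"]
      if (length(ev) == 0L) return(NA_real_)
      mean(status[ev] == "match")
    })
    data.frame(rank = r,
               n_evaluable = sum(evaluable),
               n_correct = sum(status == "match"),
               n_indeterminate = sum(!evaluable),
               accuracy = if (any(evaluable))
                 sum(status == "match") / sum(evaluable) else NA_real_,
               accuracy_per_organism = mean(org_acc, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rank_accuracy_report", "data.frame")
  out
}

#' Predominant-match breakdown per source organism
#'
#' For the reads simulated from each source organism, reports the modal
#' predicted taxon, the fraction of that organism's reads assigned to it,
#' and whether that fraction strictly exceeds `threshold` (the "confident"
#' predominant-match rule: a novel organism whose reads pile up on one
#' database taxon is matching something specific, not scattering by
#' chance). Modal ties break lexicographically; unclassified reads stay in
#' the denominator.
#'
#' @inheritParams rank_accuracy
#' @param threshold Confidence cut on the modal fraction (default 0.40,
#'   strict inequality).
#' @return Data.frame with `source_organism`, `n_reads`,
#'   `predominant_match`, `fraction`, `confident`, sorted by organism.
#' @export
predominant_match_breakdown <- function(predictions, truth,
                                        threshold = 0.40) {
  .check_pred_truth(predictions, truth)
  m <- merge(predictions[, c("read_id", "best_taxon")],
             truth[, c("read_id", "source_taxon")], by = "read_id")
  orgs <- sort(unique(m$source_taxon), method = "radix")
  rows <- lapply(orgs, function(o) {
    preds <- m$best_taxon[m$source_taxon == o]
    n <- length(preds)
    hits <- preds[!is.na(preds)]
    if (length(hits) == 0L) {
      modal <- NA_character_; frac <- 0
    } else {
      tab <- table(hits)
      top <- names(tab)[tab == max(tab)]
      modal <- sort(top, method = "radix")[1L]
      frac <- as.numeric(max(tab)) / n
    }
    data.frame(source_organism = o, n_reads = n,
               predominant_match = modal, fraction = frac,
               confident = frac > threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Agreement between two sets of assignments
#'
#' Compares two prediction tables over their shared reads, per rank, via
#' [agree_at_rank()]: fractions of reads whose two assignments match,
#' mismatch, or are indeterminate (either assignment unclassified or either
#' lineage [UNKNOWN] at that rank). The three fractions sum to 1.
#' Symmetric in its two arguments.
#'
#' @param predictions_a,predictions_b Data.frames with `read_id`,
#'   `best_taxon`.
#' @param taxonomy A `taxonomy_table` resolving every assigned taxon.
#' @param ranks Ranks to compare (default species, genus, phylum).
#' @return An `agreement_report` data.frame: per rank, `n_reads` (shared),
#'   `match`, `mismatch`, `indeterminate` fractions.
#' @export
compare_assignments <- function(predictions_a, predictions_b, taxonomy,
                                ranks = c("species", "genus", "phylum")) {
  stopifnot(all(c("read_id", "best_taxon") %in% names(predictions_a)),
            all(c("read_id", "best_taxon") %in% names(predictions_b)))
  .check_rank(ranks)
  shared <- intersect(predictions_a$read_id, predictions_b$read_id)
  if (length(shared) == 0L)
    stop("compare_assignments(): the two prediction sets share no read ids",
         call. = FALSE)
  a <- predictions_a$best_taxon[match(shared, predictions_a$read_id)]
  b <- predictions_b$best_taxon[match(shared, predictions_b$read_id)]
  ok <- !is.na(a) & !is.na(b)
  rows <- lapply(ranks, function(r) {
    status <- rep("indeterminate", length(shared))
    if (any(ok)) status[ok] <- agree_at_rank(taxonomy, a[ok], b[ok], r)
    data.frame(rank = r,
               n_reads = length(shared),
               match = mean(status == "match"),
               mismatch = mean(status == "mismatch"),
               indeterminate = mean(status == "indeterminate"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("agreement_report", "data.frame")
  out
}
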