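# Ranked-lineage storage and roll-up. Leaf-level predictions (strain or
# species) are lifted to coarser ranks through an eight-level lineage table;
# gaps in deposited lineages (uncultured / unclassified taxa) are carried as
# the reserved token UNKNOWN and surface as their own "indeterminate"
# category downstream, never as silent mismatches.

#' Reserved token for a missing rank label
#' @export
UNKNOWN <- "UNKNOWN"

#' The fixed rank schema, finest to coarsest
#'
#' @return Character vector: strain, species, genus, family, order, class,
#'   phylum, superkingdom.
#' @export
taxonomy_ranks <- function() {
  c("strain", "species", "genus", "family", "order", "class",
    "phylum", "superkingdom")
}

#' Construct a taxonomy table from a data.frame
#'
#' @param df Data.frame with a `taxon_id` column plus one column per rank in
#'   [taxonomy_ranks()]. Empty or `NA` cells become [UNKNOWN].
#' @return A `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  ranks <- taxonomy_ranks()
  missing_cols <- setdiff(c("taxon_id", ranks), names(df))
  if (length(missing_cols) > 0L)
    stop("taxonomy table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon_id in taxonomy table: ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "),
         call. = FALSE)
  df <- df[, c("taxon_id", ranks)]
  for (r in ranks) {
    v <- as.character(df[[r]])
    v[is.na(v) | v == ""] <- UNKNOWN
    df[[r]] <- v
  }
  df$taxon_id <- as.character(df$taxon_id)
  rownames(df) <- NULL
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Load a taxonomy table from TSV
#'
#' Expects a UTF-8 tab-separated file with a header row naming `taxon_id`
#' and every rank of [taxonomy_ranks()], one row per taxon. Empty cells
#' become [UNKNOWN]; a duplicated `taxon_id` is an error.
#'
#' @param path Path to the TSV file.
#' @return A `taxonomy_table`.
#' @export
load_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  tab <- taxonomy_table(df)
  attr(tab, "path") <- path
  tab
}

#' Save a taxonomy table to TSV
#'
#' @param table A `taxonomy_table`.
#' @param path Output path.
#' @export
save_taxonomy <- function(table, path) {
  stopifnot(inherits(table, "taxonomy_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.taxonomy_row <- function(table, taxon_id) {
  i <- match(taxon_id, table$taxon_id)
  if (anyNA(i))
    stop("taxon_id not in taxonomy table: ",
         paste(unique(taxon_id[is.na(i)]), collapse = ", "), call. = FALSE)
  i
}

.check_rank <- function(rank) {
  if (!all(rank %in% taxonomy_ranks()))
    stop("unknown rank(s): ",
         paste(setdiff(rank, taxonomy_ranks()), collapse = ", "),
         call. = FALSE)
  rank
}

#' Look up the label of a taxon at a rank
#'
#' Vectorised over `taxon_id`.
#'
#' @param table A `taxonomy_table`.
#' @param taxon_id Taxon id(s); an absent id is an error.
#' @param rank A single rank from [taxonomy_ranks()].
#' @return Character vector of labels (possibly [UNKNOWN]).
#' @export
lineage_at_rank <- function(table, taxon_id, rank) {
  stopifnot(inherits(table, "taxonomy_table"), length(rank) == 1L)
  .check_rank(rank)
  table[[rank]][.taxonomy_row(table, taxon_id)]
}

#' Compare two taxa at a rank
#'
#' `"match"` iff both labels are defined and equal; `"indeterminate"` iff
#' either label is [UNKNOWN]; `"mismatch"` otherwise. Vectorised over
#' `taxon_a` / `taxon_b`.
#'
#' @param table A `taxonomy_table`.
#' @param taxon_a,taxon_b Taxon ids (recycled to common length).
#' @param rank A single rank from [taxonomy_ranks()].
#' @return Character vector in `{"match", "mismatch", "indeterminate"}`.
#' @export
agree_at_rank <- function(table, taxon_a, taxon_b, rank) {
  la <- lineage_at_rank(table, taxon_a, rank)
  lb <- lineage_at_rank(table, taxon_b, rank)
  out <- ifelse(la == UNKNOWN | lb == UNKNOWN, "indeterminate",
                ifelse(la == lb, "match", "mismatch"))
  out
}
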