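# Building, serialising and loading profile databases. Training FASTA
# records are pooled into one profile per taxon according to a grouping
# policy -- by_strain for viral genomes (one label per strain/segment,
# per the mapping file), by_species for fungal sequences where many partial
# deposits share a species label. Taxonomy is never parsed out of FASTA
# headers; the record -> taxon mapping is an explicit two-column TSV.

DB_FORMAT <- "nbc_profile_db"
DB_VERSION <- 1L

#' Read a (multi-)FASTA file
#'
#' Wrapped or unwrapped records; lowercase is upper-cased. Record ids are
#' the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#'
#' One unwrapped record per sequence; byte-stable across runs.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, open = "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
  invisible(path)
}

#' Read a record-to-taxon mapping TSV
#'
#' Two tab-separated columns with header `record_id`, `taxon_id`.
#'
#' @param path Path to the TSV.
#' @return Named character vector: `mapping[record_id] == taxon_id`.
#' @export
read_mapping <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (!all(c("record_id", "taxon_id") %in% names(df)))
    stop("mapping TSV must have columns 'record_id' and 'taxon_id'",
         call. = FALSE)
  stats::setNames(df$taxon_id, df$record_id)
}

#' Write a record-to-taxon mapping TSV
#'
#' @param mapping Named character vector (record_id -> taxon_id).
#' @param path Output path.
#' @export
write_mapping <- function(mapping, path) {
  utils::write.table(
    data.frame(record_id = names(mapping), taxon_id = unname(mapping)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Group FASTA records by taxon
#'
#' @param records Named character vector of sequences (from [read_fasta()]).
#' @param mapping Named character vector mapping record id -> taxon id.
#' @param policy `"by_strain"` (viral convention: the mapping is expected to
#'   carry one label per strain) or `"by_species"` (fungal convention: many
#'   records may share one species label). The policy is recorded in the
#'   database; grouping itself always follows the mapping.
#' @param strict If `TRUE` (default) a record absent from the mapping is an
#'   error; if `FALSE` such records are skipped and their count reported via
#'   a message.
#' @return Named list: taxon id -> character vector of sequences.
#' @export
group_records <- function(records, mapping,
                          policy = c("by_strain", "by_species"),
                          strict = TRUE) {
  policy <- match.arg(policy)
  ids <- names(records)
  unmapped <- setdiff(ids, names(mapping))
  if (length(unmapped) > 0L) {
    if (strict)
      stop("record(s) absent from mapping: ",
           paste(utils::head(unmapped, 5L), collapse = ", "),
           if (length(unmapped) > 5L) " ...", call. = FALSE)
    message(length(unmapped), " unmapped record(s) skipped")
    records <- records[setdiff(ids, unmapped)]
  }
  if (length(records) == 0L) return(stats::setNames(list(), character(0)))
  split(unname(records), unname(mapping[names(records)]))
}

#' Build a profile database
#'
#' One [build_profile()] per taxon over its grouped sequences, validated
#' against a taxonomy table (every taxon id must resolve). Build metadata
#' holds the default pseudocount and MD5 digests of the source files when
#' given; no timestamp is recorded, so rebuilding from identical inputs
#' serialises byte-identically.
#'
#' @param grouped Named list taxon id -> sequences (from [group_records()]).
#' @param n K-mer length in bases.
#' @param taxonomy A `taxonomy_table` covering every taxon id.
#' @param grouping_policy Recorded policy, `"by_strain"` or `"by_species"`.
#' @param alpha_default Default pseudocount for classification (>= 0).
#' @param strand_policy Passed to [build_profile()].
#' @param source_files Optional character vector of input paths to digest
#'   into the metadata.
#' @return A `profile_db`: list with `n`, `grouping_policy`, `profiles`
#'   (sorted by taxon id), `taxonomy_path` and `meta`.
#' @export
build_database <- function(grouped, n, taxonomy,
                           grouping_policy = c("by_strain", "by_species"),
                           alpha_default = 1, strand_policy = "given",
                           source_files = NULL) {
  n <- .check_n(n)
  grouping_policy <- match.arg(grouping_policy)
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  .check_alpha(alpha_default)
  if (length(grouped) == 0L)
    stop("build_database(): no taxa to build", call. = FALSE)
  if (anyDuplicated(names(grouped)))
    stop("duplicate taxon ids in grouped input", call. = FALSE)
  absent <- setdiff(names(grouped), taxonomy$taxon_id)
  if (length(absent) > 0L)
    stop("taxon id(s) not in taxonomy: ", paste(absent, collapse = ", "),
         call. = FALSE)
  too_short <- names(grouped)[!vapply(grouped, function(s) any(nchar(s) >= n),
                                      logical(1))]
  if (length(too_short) > 0L)
    stop("taxon/taxa with no sequence of length >= n = ", n, ": ",
         paste(too_short, collapse = ", "), call. = FALSE)
  taxa <- sort(names(grouped), method = "radix")  # byte order, locale-free
  profiles <- lapply(taxa, function(t)
    build_profile(t, grouped[[t]], n, strand_policy = strand_policy))
  names(profiles) <- taxa
  digests <- NULL
  if (!is.null(source_files))
    digests <- as.list(tools::md5sum(source_files))
  structure(
    list(n = n,
         grouping_policy = grouping_policy,
         profiles = profiles,
         taxonomy_path = attr(taxonomy, "path") %||% NA_character_,
         meta = list(alpha_default = alpha_default,
                     strand_policy = strand_policy,
                     source_digests = digests)),
    class = "profile_db"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.profile_db <- function(x, ...) {
  cat(sprintf("profile_db: %d taxa, n = %d, policy = %s, alpha_default = %g\n",
              length(x$profiles), x$n, x$grouping_policy,
              x$meta$alpha_default))
  invisible(x)
}

.db_payload_json <- function(db) {
  payload <- list(
    n = db$n,
    grouping_policy = db$grouping_policy,
    taxonomy_path = db$taxonomy_path,
    meta = db$meta,
    profiles = lapply(unname(db$profiles), function(p)
      list(taxon_id = p$taxon_id, n = p$n, total = p$total,
           source_bp = p$source_bp,
           kmers = names(p$counts), counts = unname(p$counts)))
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

.md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, open = "wb")
  writeChar(x, con, eos = NULL)
  close(con)
  unname(tools::md5sum(tf))
}

#' Save a profile database
#'
#' Versioned text container: a one-line JSON header carrying the format tag,
#' version and an MD5 integrity digest of the payload, followed by the JSON
#' payload with sparse per-profile count tables (only observed k-mers are
#' stored; dense 4^n tables would be infeasible at the default n).
#'
#' @param db A `profile_db`.
#' @param path Output path.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "profile_db"))
  payload <- .db_payload_json(db)
  header <- as.character(jsonlite::toJSON(
    list(format = DB_FORMAT, version = DB_VERSION,
         digest = .md5_string(payload)),
    auto_unbox = TRUE))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, payload), con, sep = "\n")
  invisible(path)
}

#' Load a profile database
#'
#' Round-trip with [save_database()] is lossless. A file whose version tag
#' is newer than this package understands raises an incompatibility error; a
#' truncated or altered payload fails the integrity digest.
#'
#' @param path Path written by [save_database()].
#' @return A `profile_db`.
#' @export
load_database <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop("database file is truncated: ", path, call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1L]),
                     error = function(e) stop("not a profile database file: ",
                                              path, call. = FALSE))
  if (!identical(header$format, DB_FORMAT))
    stop("not a profile database file: ", path, call. = FALSE)
  if (header$version > DB_VERSION)
    stop(sprintf("database version %s is newer than supported version %d",
                 header$version, DB_VERSION), call. = FALSE)
  payload <- paste(lines[-1L], collapse = "\n")
  if (!identical(.md5_string(payload), header$digest))
    stop("database file failed its integrity digest (truncated or corrupted): ",
         path, call. = FALSE)
  raw <- jsonlite::fromJSON(payload, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  profiles <- lapply(raw$profiles, function(p) {
    counts <- as.integer(unlist(p$counts))
    names(counts) <- as.character(unlist(p$kmers))
    structure(list(taxon_id = p$taxon_id, n = as.integer(p$n),
                   counts = counts, total = as.integer(p$total),
                   source_bp = as.integer(p$source_bp)),
              class = "kmer_profile")
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "taxon_id")
  meta <- raw$meta
  if (!is.null(meta$source_digests)) meta$source_digests <-
    lapply(meta$source_digests, as.character)
  structure(
    list(n = as.integer(raw$n),
         grouping_policy = raw$grouping_policy,
         profiles = profiles,
         taxonomy_path = if (is.null(raw$taxonomy_path)) NA_character_
                         else raw$taxonomy_path,
         meta = meta),
    class = "profile_db"
  )
}

#' Warn about a heterogeneous (mixed-scale) database
#'
#' Unsmoothed likelihood classification favours taxa trained on more
#' sequence: the more training bases, the more distinct k-mers a profile
#' covers and the better a random query scores against it by chance. Mixing
#' databases of very different genome scales (e.g. viruses with
#' bacteria/archaea) is therefore discouraged. This check emits a warning
#' when the spread of per-taxon training bases exceeds `max_ratio`.
#'
#' @param db A `profile_db`.
#' @param max_ratio Largest tolerated `max(source_bp) / min(source_bp)`
#'   (default 100).
#' @return Invisibly, `NULL` when the database is homogeneous, else a list
#'   with `ratio`, `largest` and `smallest` taxon (also raised as a warning;
#'   never an error).
#' @export
heterogeneity_warning <- function(db, max_ratio = 100) {
  stopifnot(inherits(db, "profile_db"), length(db$profiles) >= 1L)
  bp <- vapply(db$profiles, `[[`, numeric(1), "source_bp")
  if (length(bp) < 2L) return(invisible(NULL))
  ratio <- max(bp) / min(bp)
  if (ratio <= max_ratio) return(invisible(NULL))
  rep <- list(ratio = ratio,
              largest = names(bp)[which.max(bp)],
              smallest = names(bp)[which.min(bp)])
  warning(sprintf(
    paste0("database mixes training scales: taxon '%s' has %.0fx more ",
           "training bases than '%s'; unsmoothed likelihoods favour the ",
           "larger profile -- consider separate databases"),
    rep$largest, ratio, rep$smallest), call. = FALSE)
  invisible(rep)
}
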