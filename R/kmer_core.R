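# Naive Bayes N-mer core: k-mer extraction, composition profiles,
# log-likelihood scoring and maximum-likelihood read classification.
#
# The classifier scores a read R against a taxon profile G as
#   log P(R | G) = sum_i log P(kmer_i | G),
# treating k-mers as independent draws (the naive Bayes assumption), with a
# uniform prior over taxa and the read-probability denominator dropped, so the
# argmax over taxa is the maximum-likelihood assignment. No cross-taxon
# smoothing prior is used; an optional within-profile pseudocount alpha keeps
# log-likelihoods finite for unseen k-mers (alpha = 0 reproduces the strict
# behaviour where unseen k-mers score -Inf).

.base_code <- local({
  # A,C,G,T -> 0..3; every other byte (incl. IUPAC ambiguity codes) -> NA
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt("A")] <- 0L
  m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L
  m[utf8ToInt("T")] <- 3L
  m
})

.bases <- c("A", "C", "G", "T")

# Encode one DNA string as integer codes 0..3 (NA for non-ACGT bytes).
.seq_codes <- function(sequence) {
  .base_code[utf8ToInt(sequence)]
}

# Numeric k-mer keys (base-4 packed, stored as doubles; exact for n <= 26)
# at every window start, NA where the window touches a non-ACGT base.
.kmer_keys <- function(sequence, n) {
  L <- nchar(sequence)
  if (L < n) return(numeric(0))
  codes <- .seq_codes(sequence)
  nw <- L - n + 1L
  keys <- numeric(nw)
  for (j in seq_len(n)) {
    keys <- keys * 4 + codes[j:(nw + j - 1L)]
  }
  keys
}

# Decode numeric keys back to k-mer strings.
.decode_keys <- function(keys, n) {
  if (length(keys) == 0L) return(character(0))
  mat <- matrix("", nrow = n, ncol = length(keys))
  rem <- keys
  for (j in n:1) {
    mat[j, ] <- .bases[rem %% 4 + 1]
    rem <- rem %/% 4
  }
  apply_paste <- function(i) paste(mat[, i], collapse = "")
  if (length(keys) == 1L) return(apply_paste(1L))
  do.call(paste0, lapply(seq_len(n), function(j) mat[j, ]))
}

# Encode k-mer strings (all of length n, ACGT only) to numeric keys.
.encode_kmers <- function(kmers, n) {
  if (length(kmers) == 0L) return(numeric(0))
  codes <- .base_code[utf8ToInt(paste(kmers, collapse = ""))]
  mat <- matrix(codes, nrow = n)
  keys <- numeric(ncol(mat))
  for (j in seq_len(n)) keys <- keys * 4 + mat[j, ]
  keys
}

.check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  as.integer(n)
}

#' Extract the N-mers of a DNA sequence
#'
#' Returns the k-mer at every start position of `sequence` (0-based,
#' half-open windows internally; positions `0 .. L - n`). Windows containing
#' any character outside `{A, C, G, T}` -- `N` and the other IUPAC ambiguity
#' codes -- are skipped, so the result may be shorter than `L - n + 1`.
#' Order of the surviving windows is preserved.
#'
#' @param sequence A single DNA string. Lowercase input is upper-cased.
#' @param n K-mer length in bases (integer >= 1).
#' @return Character vector of k-mers, possibly empty.
#' @examples
#' extract_kmers("ACGNT", 2)  # "AC" "CG" -- windows touching N are skipped
#' extract_kmers("AAAA", 2)   # three identical windows
#' @export
extract_kmers <- function(sequence, n) {
  n <- .check_n(n)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  keys <- .kmer_keys(sequence, n)
  ok <- which(!is.na(keys))
  if (length(ok) == 0L) return(character(0))
  substring(sequence, ok, ok + n - 1L)
}

#' Reverse-complement DNA strings
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorised.
#'
#' @param sequence Character vector over the alphabet `{A, C, G, T, N}`
#'   (lowercase accepted).
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence))
  sequence <- toupper(sequence)
  if (any(grepl("[^ACGTN]", sequence)))
    stop("reverse_complement(): sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  comp <- chartr("ACGTN", "TGCAN", sequence)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Build a k-mer composition profile for one taxon
#'
#' Aggregates k-mer counts over all training sequences of a taxon (strain or
#' species, depending on the database grouping policy). With
#' `strand_policy = "both"` the reverse complement of every sequence is
#' counted as well, in which case `source_bp` counts the bases of both
#' strands.
#'
#' @param taxon_id Opaque taxon label.
#' @param sequences Character vector of DNA strings (>= 1 of length >= `n`).
#' @param n K-mer length in bases.
#' @param strand_policy `"given"` (default; count the deposited strand only)
#'   or `"both"`.
#' @return A `kmer_profile`: list with `taxon_id`, `n`, `counts` (named
#'   integer vector, names sorted), `total` (sum of counts) and `source_bp`
#'   (training bases scanned).
#' @examples
#' p <- build_profile("t1", "ACGTACGT", 2)
#' p$counts  # AC 2, CG 2, GT 2, TA 1
#' @export
build_profile <- function(taxon_id, sequences, n,
                          strand_policy = c("given", "both")) {
  n <- .check_n(n)
  strand_policy <- match.arg(strand_policy)
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  sequences <- toupper(sequences)
  if (!any(nchar(sequences) >= n))
    stop(sprintf("build_profile('%s'): no training sequence of length >= n = %d",
                 taxon_id, n), call. = FALSE)
  if (strand_policy == "both")
    sequences <- c(sequences, reverse_complement(sequences))
  keys <- unlist(lapply(sequences, .kmer_keys, n = n), use.names = FALSE)
  keys <- keys[!is.na(keys)]
  counts <- integer(0)
  if (length(keys) > 0L) {
    r <- rle(sort(keys))
    counts <- r$lengths
    names(counts) <- .decode_keys(r$values, n)
  }
  structure(
    list(taxon_id = as.character(taxon_id),
         n = n,
         counts = counts,
         total = sum(counts),
         source_bp = sum(nchar(sequences))),
    class = "kmer_profile"
  )
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("kmer_profile '%s': n = %d, %d distinct %d-mers, total = %d, source_bp = %d\n",
              x$taxon_id, x$n, length(x$counts), x$n, x$total, x$source_bp))
  invisible(x)
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("'alpha' must be a single number >= 0", call. = FALSE)
  alpha
}

#' Log-probability of a k-mer under a profile
#'
#' `log((count(kmer) + alpha) / (total + alpha * 4^n))` in nats. With
#' `alpha = 0` an unseen k-mer returns `-Inf`, the sentinel for strict
#' no-smoothing scoring. Vectorised over `kmer`.
#'
#' @param profile A `kmer_profile`.
#' @param kmer Character vector of k-mers of length `profile$n`.
#' @param alpha Pseudocount, >= 0. Added within this profile only; no
#'   cross-taxon prior.
#' @return Numeric vector of log-probabilities (nats).
#' @export
kmer_log_probability <- function(profile, kmer, alpha = 1) {
  stopifnot(inherits(profile, "kmer_profile"))
  alpha <- .check_alpha(alpha)
  kmer <- toupper(kmer)
  if (any(nchar(kmer) != profile$n) || any(grepl("[^ACGT]", kmer)))
    stop(sprintf("kmer(s) must be length-%d strings over {A,C,G,T}", profile$n),
         call. = FALSE)
  cnt <- profile$counts[kmer]
  cnt[is.na(cnt)] <- 0L
  unname(log(cnt + alpha) - log(profile$total + alpha * 4^profile$n))
}

# Dense log-probability table for a profile (length 4^n); only used when
# 4^n is small enough to materialise (n <= 12).
.dense_log_probs <- function(profile, alpha) {
  den <- log(profile$total + alpha * 4^profile$n)
  lp <- rep(log(alpha) - den, 4^profile$n)  # log(0) = -Inf when alpha = 0
  if (length(profile$counts) > 0L) {
    keys <- .encode_kmers(names(profile$counts), profile$n)
    lp[keys + 1] <- log(profile$counts + alpha) - den
  }
  lp
}

# Score pre-computed window keys against one profile. keys: numeric keys with
# NAs already removed. lp: dense table, or NULL to use sparse lookup.
.score_keys <- function(keys, profile, alpha, lp = NULL) {
  if (length(keys) == 0L) return(NA_real_)
  if (!is.null(lp)) return(sum(lp[keys + 1]))
  pk <- .encode_kmers(names(profile$counts), profile$n)
  cnt <- profile$counts[match(keys, pk)]
  cnt[is.na(cnt)] <- 0L
  sum(log(cnt + alpha)) - length(keys) * log(profile$total + alpha * 4^profile$n)
}

#' Score a read against one profile
#'
#' Sum of [kmer_log_probability()] over every ambiguity-free window of the
#' read. Under `strand_policy = "max_of_strands"` (default) the larger of the
#' forward-read and reverse-complemented-read scores is returned, so that
#' reads sequenced from either strand are scored against strand-as-given
#' profiles.
#'
#' @param read A DNA string (IUPAC ambiguity codes allowed; windows touching
#'   them are skipped).
#' @param profile A `kmer_profile`.
#' @param alpha Pseudocount (see [kmer_log_probability()]).
#' @param strand_policy `"max_of_strands"` or `"forward"`.
#' @return List with `score` (log-likelihood in nats; `NA` when the read has
#'   no scoreable window -- an unscoreable read is a reportable outcome, not
#'   an error) and `n_scored_kmers`.
#' @export
score_read <- function(read, profile, alpha = 1,
                       strand_policy = c("max_of_strands", "forward")) {
  stopifnot(inherits(profile, "kmer_profile"))
  strand_policy <- match.arg(strand_policy)
  alpha <- .check_alpha(alpha)
  read <- toupper(read)
  keys <- .kmer_keys(read, profile$n)
  keys <- keys[!is.na(keys)]
  if (length(keys) == 0L)
    return(list(score = NA_real_, n_scored_kmers = 0L))
  s <- .score_keys(keys, profile, alpha)
  if (strand_policy == "max_of_strands") {
    rkeys <- .kmer_keys(reverse_complement(gsub("[^ACGTN]", "N", read)),
                        profile$n)
    rkeys <- rkeys[!is.na(rkeys)]
    if (length(rkeys) > 0L) s <- max(s, .score_keys(rkeys, profile, alpha))
  }
  list(score = s, n_scored_kmers = length(keys))
}

#' Classify reads against a profile database
#'
#' Maximum-likelihood assignment: each read goes to the taxon whose profile
#' gives the highest [score_read()] log-likelihood, uniform prior over taxa.
#' Ties are broken by the lexicographically smallest `taxon_id` so results
#' are reproducible across runs and platforms. A read with no scoreable
#' window, or whose best score is `-Inf` (possible only with `alpha = 0`),
#' is returned unclassified (`NA` taxon).
#'
#' @param reads Named character vector of read sequences (names are read
#'   ids; unnamed reads get `read1 ...`).
#' @param db A `profile_db` (see [build_database()]).
#' @param alpha Pseudocount; defaults to the database's `alpha_default`.
#' @param strand_policy Passed to [score_read()].
#' @return A data.frame with one row per read: `read_id`, `best_taxon`,
#'   `best_score`, `runner_up_taxon`, `margin` (best minus runner-up, nats;
#'   `Inf` for a single-taxon database) and `n_scored_kmers`.
#' @export
classify_reads <- function(reads, db, alpha = NULL,
                           strand_policy = c("max_of_strands", "forward")) {
  stopifnot(inherits(db, "profile_db"))
  strand_policy <- match.arg(strand_policy)
  if (length(db$profiles) == 0L)
    stop("classify_reads(): empty profile database", call. = FALSE)
  if (is.null(alpha)) alpha <- db$meta$alpha_default
  alpha <- .check_alpha(alpha)
  if (is.null(names(reads)) || any(names(reads) == ""))
    names(reads) <- paste0("read", seq_along(reads))
  reads <- toupper(reads)
  n <- db$n
  taxa <- names(db$profiles)  # already sorted lexicographically at build
  dense <- 4^n <= 2^24
  lps <- if (dense) lapply(db$profiles, .dense_log_probs, alpha = alpha)

  out <- data.frame(read_id = names(reads),
                    best_taxon = NA_character_,
                    best_score = NA_real_,
                    runner_up_taxon = NA_character_,
                    margin = NA_real_,
                    n_scored_kmers = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    keys <- .kmer_keys(reads[[i]], n)
    keys <- keys[!is.na(keys)]
    if (length(keys) == 0L) next
    if (strand_policy == "max_of_strands") {
      rkeys <- .kmer_keys(reverse_complement(gsub("[^ACGTN]", "N", reads[[i]])), n)
      rkeys <- rkeys[!is.na(rkeys)]
    } else rkeys <- numeric(0)
    scores <- vapply(seq_along(taxa), function(t) {
      s <- .score_keys(keys, db$profiles[[t]], alpha,
                       lp = if (dense) lps[[t]])
      if (length(rkeys) > 0L)
        s <- max(s, .score_keys(rkeys, db$profiles[[t]], alpha,
                                lp = if (dense) lps[[t]]))
      s
    }, numeric(1))
    out$n_scored_kmers[i] <- length(keys)
    best <- which.max(scores)  # first max = lexicographically smallest taxon
    if (!is.finite(scores[best]) || is.na(scores[best])) next  # nothing matched
    out$best_taxon[i] <- taxa[best]
    out$best_score[i] <- scores[best]
    if (length(taxa) >= 2L) {
      rest <- scores[-best]
      ru <- which.max(rest)
      out$runner_up_taxon[i] <- taxa[-best][ru]
      out$margin[i] <- scores[best] - rest[ru]
    } else {
      out$margin[i] <- Inf
    }
  }
  out
}

#' Classify one read
#'
#' Single-read convenience wrapper around [classify_reads()].
#'
#' @inheritParams classify_reads
#' @param read A DNA string.
#' @param read_id Read identifier for the result.
#' @return A `classification_result`: list with `read_id`, `best_taxon`,
#'   `best_score`, `runner_up_taxon`, `margin` and `n_scored_kmers`.
#'   `best_taxon` is `NA` for an unscoreable (unclassified) read.
#' @export
classify_read <- function(read, db, alpha = NULL,
                          strand_policy = c("max_of_strands", "forward"),
                          read_id = "read1") {
  df <- classify_reads(stats::setNames(read, read_id), db,
                       alpha = alpha, strand_policy = strand_policy)
  structure(as.list(df[1L, ]), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  if (is.na(x$best_taxon)) {
    cat(sprintf("read '%s': unclassified (%d scoreable k-mers)\n",
                x$read_id, x$n_scored_kmers))
  } else {
    cat(sprintf("read '%s' -> '%s' (log-lik %.3f, margin %.3f over '%s', %d k-mers)\n",
                x$read_id, x$best_taxon, x$best_score, x$margin,
                ifelse(is.na(x$runner_up_taxon), "-", x$runner_up_taxon),
                x$n_scored_kmers))
  }
  invisible(x)
}
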