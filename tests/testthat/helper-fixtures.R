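# Shared test helpers: tiny taxonomy construction and the independent
# brute-force read scorer used as the oracle for the fast scoring path.

# Build a taxonomy_table from a compact spec: a data.frame with taxon_id
# and any subset of rank columns; unspecified ranks default to the
# taxon_id itself (finest ranks) or a shared label (coarser ranks).
tiny_taxonomy <- function(df) {
  ranks <- taxonomy_ranks()
  for (r in ranks) {
    if (is.null(df[[r]])) {
      df[[r]] <- if (r %in% c("strain", "species")) df$taxon_id else "shared"
    }
  }
  taxonomy_table(df)
}

# Independent oracle scorer: plain character window loop (no packed-integer
# encoding), each k-mer probability formed as the exact integer ratio
# (count + alpha) / (total + alpha * 4^n), accumulated in log space as
# sum(log numerator) - k * log(denominator). Forward strand only.
oracle_score_read <- function(read, profile, alpha) {
  n <- profile$n
  L <- nchar(read)
  den <- profile$total + alpha * 4^n
  acc <- 0
  k <- 0L
  i <- 1L
  while (i + n - 1L <= L) {
    km <- substr(read, i, i + n - 1L)
    bad <- FALSE
    for (j in seq_len(n)) {
      if (!substr(km, j, j) %in% c("A", "C", "G", "T")) { bad <- TRUE; break }
    }
    if (!bad) {
      cnt <- unname(profile$counts[km])
      if (is.na(cnt)) cnt <- 0L
      acc <- acc + log(cnt + alpha)
      k <- k + 1L
    }
    i <- i + 1L
  }
  if (k == 0L) return(NA_real_)
  acc - k * log(den)
}

# A random profile over a random genome fragment.
random_profile <- function(taxon = "t", min_len = 100, max_len = 500,
                          n = sample(2:6, 1)) {
  len <- sample(min_len:max_len, 1)
  build_profile(taxon, random_genome(len, 0.5), n)
}

# All 4^n k-mers, lexicographic.
all_kmers <- function(n) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), n),
                   stringsAsFactors = FALSE)
  sort(do.call(paste0, g))
}

# Noise-free simulator configuration (flowgram identity limit).
noiseless_config <- function(...) {
  simulator_config(negative_flow_mean = 0, negative_flow_sd = 0,
                   positive_flow_sigma_scale = 0, ...)
}
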