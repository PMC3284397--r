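# 454-style read simulator. A clone (sequencing fragment) is drawn from the
# source record with Normal(clone_mean, clone_sd) length, uniform start and
# strand; the read is then produced by a simplified flowgram model of
# pyrosequencing: nucleotides are flowed in a fixed cyclic order, a
# homopolymer run of the flowed base yields one signal whose rounded value
# is the called run length. Negative flows (run length 0) draw a small
# lognormal signal (occasional insertions); positive flows draw
# Normal(h, scale * sqrt(h)) (homopolymer over/under-calls, the dominant
# 454 error mode). This is a simplified stand-in for a full flowgram
# simulator, not a bit-level reproduction of any particular tool.

#' Simulator configuration
#'
#' Defaults are the benchmark conditions: 99 flow cycles of "TACG"
#' (a nominal 252 bp per read), clone length Normal(2000, 200) bp, and a
#' lognormal negative-flow signal with raw-scale mean 0.23 and sd 0.15
#' signal units. `negative_flow_mean`/`negative_flow_sd` parameterise the
#' lognormal on the raw signal scale (they are the distribution's mean and
#' sd, converted internally to meanlog/sdlog); set both to 0 to force
#' negative flows silent. `positive_flow_sigma_scale` is the signal sd per
#' sqrt(homopolymer length); 0 disables over/under-calls.
#'
#' @param clone_mean,clone_sd Clone length distribution, bp.
#' @param cycles Number of flow cycles (>= 1).
#' @param flow_order Nucleotide flow order per cycle.
#' @param negative_flow_mean,negative_flow_sd Raw-scale mean/sd of the
#'   lognormal signal for flows over a zero-length run, signal units.
#' @param positive_flow_sigma_scale Signal sd per sqrt(run length).
#' @param reads_per_genome Reads simulated per input record.
#' @param seed Integer RNG seed.
#' @return A `simulator_config`.
#' @export
simulator_config <- function(clone_mean = 2000, clone_sd = 200,
                             cycles = 99, flow_order = "TACG",
                             negative_flow_mean = 0.23,
                             negative_flow_sd = 0.15,
                             positive_flow_sigma_scale = 0.15,
                             reads_per_genome = 100, seed = 1) {
  stopifnot(clone_mean > 0, clone_sd >= 0, cycles >= 1,
            nchar(flow_order) >= 1, !grepl("[^ACGT]", flow_order),
            negative_flow_mean >= 0, negative_flow_sd >= 0,
            positive_flow_sigma_scale >= 0, reads_per_genome >= 1)
  structure(list(clone_mean = clone_mean, clone_sd = clone_sd,
                 cycles = as.integer(cycles), flow_order = flow_order,
                 negative_flow_mean = negative_flow_mean,
                 negative_flow_sd = negative_flow_sd,
                 positive_flow_sigma_scale = positive_flow_sigma_scale,
                 reads_per_genome = as.integer(reads_per_genome),
                 seed = as.integer(seed)),
            class = "simulator_config")
}

# meanlog/sdlog of a lognormal with raw-scale mean m and sd s
.lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Draw one clone from a record
#'
#' Clone length is `round(Normal(clone_mean, clone_sd))` truncated to
#' `[1, nchar(record)]`; start is uniform over valid positions (0-based);
#' strand is uniform, with the clone reverse-complemented on `-`.
#' Consumes the current RNG stream.
#'
#' @param record A DNA string.
#' @param config A `simulator_config`.
#' @return List with `start` (0-based), `strand` (`"+"`/`"-"`),
#'   `clone_length` and `sequence`.
#' @export
draw_clone <- function(record, config) {
  stopifnot(inherits(config, "simulator_config"))
  L <- nchar(record)
  stopifnot(L >= 1L)
  len <- round(stats::rnorm(1L, config$clone_mean, config$clone_sd))
  len <- min(max(len, 1L), L)
  start <- sample.int(L - len + 1L, 1L) - 1L
  strand <- if (stats::runif(1L) < 0.5) "+" else "-"
  seq <- substr(record, start + 1L, start + len)
  if (strand == "-") seq <- reverse_complement(seq)
  list(start = start, strand = strand, clone_length = len, sequence = seq)
}

#' Simulate the flowgram read of one template
#'
#' Iterates `cycles` passes of `flow_order`; at each flow the true
#' homopolymer run length `h` of the flowed base at the current template
#' position produces one signal (`h = 0`: lognormal; `h >= 1`:
#' `Normal(h, scale * sqrt(h))`); `round(signal)` clipped at 0 bases of the
#' flowed base are appended and the template advances by `h`. Stops when
#' the flows or the template are exhausted. Consumes the current RNG
#' stream.
#'
#' @param template A DNA string over `{A,C,G,T}`.
#' @param config A `simulator_config`.
#' @return List with `sequence` (the read; possibly empty), `n_errors`
#'   (Levenshtein distance between the read and the consumed template
#'   prefix) and `template_consumed` (bases of template advanced over).
#' @export
flow_simulate <- function(template, config) {
  stopifnot(inherits(config, "simulator_config"))
  if (grepl("[^ACGT]", template))
    stop("flow_simulate(): template must be over {A,C,G,T}", call. = FALSE)
  runs <- rle(strsplit(template, "", fixed = TRUE)[[1L]])
  n_runs <- length(runs$lengths)
  flows <- strsplit(config$flow_order, "", fixed = TRUE)[[1L]]
  n_flows <- config$cycles * length(flows)
  neg_noisy <- config$negative_flow_sd > 0 || config$negative_flow_mean > 0
  if (config$negative_flow_sd > 0) {
    lp <- .lnorm_pars(config$negative_flow_mean, config$negative_flow_sd)
  }
  pos_scale <- config$positive_flow_sigma_scale

  called_base <- character(n_flows)
  called_len <- integer(n_flows)
  ri <- 1L          # next unread template run
  consumed <- 0L    # template bases advanced over
  for (fi in seq_len(n_flows)) {
    if (ri > n_runs) break
    base <- flows[(fi - 1L) %% length(flows) + 1L]
    if (runs$values[ri] == base) {
      h <- runs$lengths[ri]
      signal <- if (pos_scale > 0) stats::rnorm(1L, h, pos_scale * sqrt(h))
                else h
      ri <- ri + 1L
      consumed <- consumed + h
    } else {
      signal <- if (!neg_noisy) 0
                else if (config$negative_flow_sd > 0)
                  stats::rlnorm(1L, lp[["meanlog"]], lp[["sdlog"]])
                else config$negative_flow_mean
    }
    k <- max(round(signal), 0)
    if (k > 0) {
      called_base[fi] <- base
      called_len[fi] <- k
    }
  }
  keep <- called_len > 0L
  sequence <- paste(strrep(called_base[keep], called_len[keep]),
                    collapse = "")
  prefix <- substr(template, 1L, consumed)
  n_errors <- as.integer(utils::adist(sequence, prefix))
  list(sequence = sequence, n_errors = n_errors,
       template_consumed = consumed)
}

#' Simulate a full read set with provenance
#'
#' Draws exactly `config$reads_per_genome` reads from every input record
#' (clone draw + flowgram simulation), recording full provenance per read.
#' Deterministic for a fixed `config$seed`: reruns are byte-identical,
#' including the output files. The caller's RNG state is left untouched.
#'
#' @param genomes Named character vector of source records, or the path of
#'   a FASTA file.
#' @param config A `simulator_config`.
#' @param mapping Optional named character vector mapping record id ->
#'   source taxon; defaults to the record id itself.
#' @param out_fasta,out_truth Optional output paths for the reads FASTA and
#'   the truth TSV (columns: read_id, source_taxon, source_record, start,
#'   strand, clone_length, n_errors).
#' @return Invisibly, a data.frame with one row per read: `read_id`,
#'   `sequence`, `source_taxon`, `source_record`, `start` (0-based),
#'   `strand`, `clone_length`, `n_errors`.
#' @export
simulate_readset <- function(genomes, config, mapping = NULL,
                             out_fasta = NULL, out_truth = NULL) {
  stopifnot(inherits(config, "simulator_config"))
  if (is.character(genomes) && length(genomes) == 1L && is.null(names(genomes))) {
    if (!file.exists(genomes))
      stop("cannot read genome file: ", genomes, call. = FALSE)
    genomes <- read_fasta(genomes)
  }
  stopifnot(length(genomes) >= 1L, !is.null(names(genomes)))
  if (is.null(mapping))
    mapping <- stats::setNames(names(genomes), names(genomes))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  rows <- vector("list", length(genomes) * config$reads_per_genome)
  k <- 0L
  for (rec in names(genomes)) {
    for (i in seq_len(config$reads_per_genome)) {
      # redraw on the (rare) empty read so every emitted read has sequence
      for (attempt in 1:100) {
        clone <- draw_clone(genomes[[rec]], config)
        fl <- flow_simulate(clone$sequence, config)
        if (nchar(fl$sequence) > 0L) break
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        read_id = sprintf("%s_r%03d", rec, i),
        sequence = fl$sequence,
        source_taxon = unname(mapping[rec]),
        source_record = rec,
        start = clone$start,
        strand = clone$strand,
        clone_length = clone$clone_length,
        n_errors = fl$n_errors,
        stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, rows)
  if (!is.null(out_fasta))
    write_fasta(stats::setNames(reads$sequence, reads$read_id), out_fasta)
  if (!is.null(out_truth)) {
    con <- file(out_truth, open = "wb")
    utils::write.table(reads[, c("read_id", "source_taxon", "source_record",
                                 "start", "strand", "clone_length",
                                 "n_errors")],
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(reads)
}
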