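# Deterministic synthetic benchmark scenarios: random genomes, point-mutant
# "novel" relatives, and a tree-consistent eight-rank taxonomy, so that
# training, simulation and evaluation are exercisable end-to-end with known
# ground truth and no external downloads. Defaults mirror the viral
# benchmark conditions: 20 taxa, a 55% novel split, and genomes of tens to
# hundreds of kilobases.

.with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`, split evenly within each pair.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc GC content, strictly between 0 and 1.
#' @param seed Optional seed; when given the draw is deterministic and the
#'   caller's RNG state is left untouched.
#' @return A DNA string.
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length >= 1)
  if (!is.numeric(gc) || base::length(gc) != 1L || is.na(gc) ||
      gc <= 0 || gc >= 1)
    stop("'gc' must be strictly between 0 and 1", call. = FALSE)
  .with_local_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Mutate a genome by point substitutions
#'
#' Each site is independently substituted, with probability `divergence`,
#' to a base drawn uniformly from the three alternatives. Length is
#' preserved; no indels.
#'
#' @param genome A DNA string over `{A,C,G,T}`.
#' @param divergence Per-site substitution probability in `[0, 1]`.
#' @param seed Optional seed (see [random_genome()]).
#' @return The mutated DNA string.
#' @export
mutate_genome <- function(genome, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 1)
  if (divergence == 0) return(genome)
  .with_local_seed(seed, {
    codes <- .seq_codes(genome)
    stopifnot(!anyNA(codes))
    L <- length(codes)
    hit <- which(stats::runif(L) < divergence)
    if (length(hit) > 0L) {
      # offset 1..3 from the current base guarantees a different base
      codes[hit] <- (codes[hit] + sample.int(3L, length(hit),
                                             replace = TRUE)) %% 4L
    }
    paste(.bases[codes + 1L], collapse = "")
  })
}

#' Benchmark scenario specification
#'
#' Defaults are the benchmark conditions: 20 taxa with genomes of
#' 50--150 kb, 55% of taxa novel (held out of the database), and novel taxa
#' diverged from an in-database relative by 0.10 substitutions per site.
#' The taxonomy is generated tree-consistent with a nested shape:
#' `species_per_genus` species per genus, `genera_per_order` genera per
#' order, `orders_per_phylum` orders per phylum; family is 1:1 with genus
#' and class 1:1 with order.
#'
#' @param n_taxa Total number of taxa (in-database + novel).
#' @param length_range Genome length range, bp (uniform draw).
#' @param gc GC content of generated genomes.
#' @param fraction_novel Fraction of taxa held out as novel (in `[0, 1]`;
#'   `n_novel = ceiling(fraction_novel * n_taxa)`).
#' @param divergence Substitutions per site between a novel taxon and its
#'   in-database relative (in `[0, 0.5]`).
#' @param species_per_genus,genera_per_order,orders_per_phylum Taxonomy
#'   shape knobs (integers >= 1).
#' @param seed Integer seed; the whole scenario is deterministic in it.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(n_taxa = 20, length_range = c(50000, 150000),
                          gc = 0.5, fraction_novel = 0.55,
                          divergence = 0.10, species_per_genus = 2,
                          genera_per_order = 2, orders_per_phylum = 2,
                          seed = 1) {
  stopifnot(n_taxa >= 1, length(length_range) == 2L,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            fraction_novel >= 0, fraction_novel <= 1,
            divergence >= 0, divergence <= 0.5,
            species_per_genus >= 1, genera_per_order >= 1,
            orders_per_phylum >= 1)
  n_novel <- as.integer(ceiling(fraction_novel * n_taxa))
  if (n_novel >= n_taxa && n_novel > 0L)
    stop("scenario needs at least one in-database taxon to derive novel taxa from",
         call. = FALSE)
  structure(list(n_taxa = as.integer(n_taxa),
                 length_range = as.integer(length_range), gc = gc,
                 fraction_novel = fraction_novel, divergence = divergence,
                 species_per_genus = as.integer(species_per_genus),
                 genera_per_order = as.integer(genera_per_order),
                 orders_per_phylum = as.integer(orders_per_phylum),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# Lineage for the i-th in-database taxon under the nested shape.
.shape_lineage <- function(i, taxon_id, spec) {
  gi <- (i - 1L) %/% spec$species_per_genus + 1L
  oi <- (gi - 1L) %/% spec$genera_per_order + 1L
  pi <- (oi - 1L) %/% spec$orders_per_phylum + 1L
  data.frame(taxon_id = taxon_id,
             strain = taxon_id,
             species = sprintf("sp%03d", i),
             genus = sprintf("gen%03d", gi),
             family = sprintf("fam%03d", gi),   # 1:1 with genus
             order = sprintf("ord%03d", oi),
             class = sprintf("cls%03d", oi),    # 1:1 with order
             phylum = sprintf("phy%03d", pi),
             superkingdom = "SyntheticViruses",
             stringsAsFactors = FALSE)
}

#' Generate a full benchmark scenario
#'
#' In-database taxa get independent random genomes; novel taxa are point
#' mutants of an in-database relative (assigned round-robin) and share
#' every rank from genus upward with that relative while carrying their own
#' strain and species labels, so the finest rank at which a novel read can
#' be classified correctly is genus. All outputs are deterministic per
#' `spec$seed`.
#'
#' @param spec A [scenario_spec()].
#' @param out_dir Optional directory; when given, writes `training.fasta`,
#'   `heldout.fasta`, `mapping.tsv` (training records) and `taxonomy.tsv`
#'   (all taxa) there.
#' @return List with `training` and `novel` (named character vectors of
#'   genomes; record id = taxon id), `mapping` (training record -> taxon),
#'   `novel_relative` (novel taxon -> its in-database relative),
#'   `taxonomy` (a `taxonomy_table` over all taxa), `spec`, and `paths`
#'   when `out_dir` was given.
#' @export
make_scenario <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  n_novel <- as.integer(ceiling(spec$fraction_novel * spec$n_taxa))
  n_train <- spec$n_taxa - n_novel
  .with_local_seed(spec$seed, {
    train_ids <- sprintf("T%03d", seq_len(n_train))
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                   n_train, replace = TRUE)
    training <- stats::setNames(
      vapply(lens, function(L) random_genome(L, spec$gc), character(1)),
      train_ids)
    lineages <- do.call(rbind, lapply(seq_len(n_train), function(i)
      .shape_lineage(i, train_ids[i], spec)))

    novel <- stats::setNames(character(0), character(0))
    novel_relative <- stats::setNames(character(0), character(0))
    if (n_novel > 0L) {
      novel_ids <- sprintf("N%03d", seq_len(n_novel))
      rel_idx <- rep_len(seq_len(n_train), n_novel)
      novel <- stats::setNames(
        vapply(seq_len(n_novel), function(j)
          mutate_genome(training[[rel_idx[j]]], spec$divergence),
          character(1)),
        novel_ids)
      novel_relative <- stats::setNames(train_ids[rel_idx], novel_ids)
      novel_lineages <- do.call(rbind, lapply(seq_len(n_novel), function(j) {
        rel <- lineages[rel_idx[j], ]
        rel$taxon_id <- novel_ids[j]
        rel$strain <- novel_ids[j]
        rel$species <- sprintf("sp_nov%03d", j)
        rel
      }))
      lineages <- rbind(lineages, novel_lineages)
    }
    taxonomy <- taxonomy_table(lineages)
    mapping <- stats::setNames(train_ids, train_ids)

    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(training = file.path(out_dir, "training.fasta"),
                    heldout = file.path(out_dir, "heldout.fasta"),
                    mapping = file.path(out_dir, "mapping.tsv"),
                    taxonomy = file.path(out_dir, "taxonomy.tsv"))
      write_fasta(training, paths$training)
      if (length(novel) > 0L) write_fasta(novel, paths$heldout)
      else { con <- file(paths$heldout, "wb"); close(con) }
      write_mapping(mapping, paths$mapping)
      save_taxonomy(taxonomy, paths$taxonomy)
    }
    list(training = training, novel = novel, mapping = mapping,
         novel_relative = novel_relative, taxonomy = taxonomy,
         spec = spec, paths = paths)
  })
}
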