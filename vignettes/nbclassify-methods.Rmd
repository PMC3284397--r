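---
title: "Naive Bayes N-mer classification: model, simulator and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Naive Bayes N-mer classification: model, simulator and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbclassify)
```

This vignette is the package's own account of its methods: the classifier
and its assumptions, the parameters that matter, what the read simulator
and the synthetic scenarios do and do not emulate, and the numerical and
design choices made where the design was genuinely open.

## The classifier

Each taxon $G$ in a database is represented by a composition profile: the
counts $c_G(w)$ of every length-$N$ subsequence ("N-mer") of its training
sequence, stored sparsely (only observed N-mers; a dense table has $4^N$
cells and is infeasible at the default $N = 15$). A read $R$ with
ambiguity-free windows $w_1 \dots w_K$ is scored

$$\log P(R \mid G) \;=\; \sum_{i=1}^{K} \log
  \frac{c_G(w_i) + \alpha}{T_G + \alpha\,4^N},$$

with $T_G = \sum_w c_G(w)$, and assigned to $\arg\max_G \log P(R \mid G)$.
The assumptions, and what they buy or cost:

- **K-mer independence** (naive Bayes). False for overlapping windows, but
  it is what makes the score a sum and the classifier trainable from
  counts alone; it also means repetitive sequence is *informative* rather
  than a nuisance — a species-specific repeat inflates exactly the counts
  that its reads will query.
- **Uniform prior over taxa; read-probability denominator dropped.** The
  argmax is then pure likelihood. The cost is a genome-length bias for
  queries resembling nothing in the database, discussed below.
- **No cross-taxon smoothing.** Corpus-wide (e.g. genus-specific) priors
  help only when the database densely samples each group; for sparse
  viral/fungal databases of partial sequences they would pull scores
  toward whatever happens to be deposited. The pseudocount $\alpha$ is
  strictly within-profile.

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `n` | 15 (tests use 2–8) | bases | matches the published classifier family this package re-implements; at $N=15$ profiles of real genomes stay sparse. Tests and the desk-scale benchmark use $N \le 8$ so that $4^N$ stays enumerable. |
| `alpha` | 1 | counts | add-one within the profile keeps every log finite; `alpha = 0` reproduces the strict no-smoothing scorer ($-\infty$ for unseen N-mers, reads matching nothing come back unclassified). |
| `strand_policy` (scoring) | `max_of_strands` | — | deposited training sequences have a strand, reads do not; scoring both orientations of the read against strand-as-given profiles handles that without doubling the database. |
| `strand_policy` (training) | `given` | — | the training representation matches the deposited sequences; `both` is available and then `source_bp` counts both strands so `source_bp >= total` always holds. |

Ambiguous bases (`N` and other IUPAC codes) void every window that touches
them — no fractional counting, fully deterministic. Coordinates are 0-based
half-open internally; all logarithms are natural. Ties in the argmax break
toward the lexicographically smallest taxon id, so results are identical
across runs and platforms.

### The length bias, and what smoothing does to it

With no smoothing, a profile is punished per query N-mer it lacks; a genome
ten times longer misses roughly ten times fewer random N-mers, so queries
unlike anything in the database drift to the longest genome. This package
reproduces that mechanism by design (no length normalisation is applied —
query-length normalisation is an open problem for this classifier family),
and `heterogeneity_warning()` flags databases whose per-taxon training
volumes differ by more than a configurable ratio (default 100; advisory
only, never fatal).

A finding worth recording: **add-one smoothing neutralises the bias at
small $N$.** With $\alpha = 1$ the denominator $T_G + 4^N$ grows with the
training volume, and for Poisson-distributed counts the expected per-N-mer
gain of the longer genome ($\approx \Delta T \log 2 / 4^N$) is smaller than
its denominator cost ($\approx \Delta T / 4^N$), so the *shorter* genome is
slightly favoured. In the package's bias test the longer of two genomes
(20 kb vs 200 kb, $N = 8$, 2,000 random 250 bp queries) wins essentially
every assignment at $\alpha = 0.01$ — the no-smoothing limit, which is the
regime of the classifier this package models — and would lose at
$\alpha = 1$. At the default $N = 15$, where $4^N$ dwarfs any $T_G$, the
denominators are nearly equal and the bias reappears even with
$\alpha = 1$.

## The read simulator

The simulator emulates 454 pyrosequencing in two stages.

**Clone draw.** Fragment length $\sim \mathrm{round}(\mathcal N(2000,
200))$ bp, truncated to $[1, L]$; start uniform; strand uniform, with the
clone reverse-complemented on the minus strand.

**Flowgram.** Nucleotides are flowed in 99 cycles of the order `TACG`
(nominally 252 bp of random sequence). At each flow, the homopolymer run
length $h$ of the flowed base at the current template position produces one
signal: $h = 0$ draws a lognormal with raw-scale mean 0.23 and sd 0.15
signal units; $h \ge 1$ draws $\mathcal N(h,\, 0.15\sqrt h)$. The called
run is $\mathrm{round}(\text{signal})$ clipped at zero, and the template
advances by $h$. Errors are therefore homopolymer over/under-calls and
occasional one-base insertions at negative flows — the characteristic 454
error spectrum — and `n_errors` records the Levenshtein distance between
the read and the consumed template prefix.

The lognormal parameters are read as the distribution's **raw-scale mean
and sd** (converted internally to meanlog/sdlog). Read as meanlog/sdlog
they would give every negative flow a median signal of $e^{0.23} \approx
1.26$ — an insertion at nearly every flow and ~396 bp reads of mostly
noise — while the raw-scale reading calls an insertion at only ~5% of
negative flows and yields mean read lengths of ~274 bp under the defaults,
consistent with the nominal 252 bp flow budget plus insertions. Both
interpretations are one config field away (`negative_flow_mean`,
`negative_flow_sd`).

This is a simplified stand-in for a full flowgram simulator: no
carry-forward/incomplete-extension chemistry, no quality values, no
position-dependent noise. "Approximately 100 reads per genome" is resolved
to exactly `reads_per_genome` per record for determinism; a fixed seed
gives byte-identical FASTA/TSV outputs, and the caller's RNG state is left
untouched.

## Synthetic scenarios, and what passing tests show

`make_scenario()` builds: in-database taxa with independent i.i.d.-random
genomes (default 20 taxa, 50–150 kb, GC 0.5); novel taxa as point-mutant
derivatives (default divergence 0.10 substitutions/site — a strain/species
scale divergence; no indels or rearrangements) of an in-database relative
assigned round-robin; and a tree-consistent eight-rank taxonomy in which a
novel taxon carries its own strain and species labels but its relative's
genus and everything coarser. The default 55% novel fraction mirrors the
benchmark split the package's evaluation stage was built for. The taxonomy
shape is controlled by `species_per_genus`, `genera_per_order`,
`orders_per_phylum`; family is 1:1 with genus and class 1:1 with order,
which keeps the schema at eight ranks without extra knobs.

What this emulates well: the *information structure* of the benchmark —
reads whose true taxon is in the database versus reads that can only be
recovered at genus level or above, with exact ground truth. What it does
not emulate: real genome composition (codon structure, skews, shared
repeat families), realistic inter-taxon relatedness (random genomes are
maximally unrelated, making in-database classification easier than for
close real strains), and real lineage gaps (`UNKNOWN` ranks are exercised
by constructed tables, not by the generator). Passing the desk-scale
benchmark therefore demonstrates the pipeline's correctness and the
classifier's behaviour in its intended regimes, not field accuracy on real
viral or fungal data.

## Evaluation semantics

- A read is **correct at rank $r$** iff its predicted and true taxa carry
  the same defined label at $r$. Comparisons touching an `UNKNOWN` label,
  and unclassified reads, are **indeterminate**: excluded from the
  accuracy denominator and reported as their own count, never counted as
  wrong.
- `rank_accuracy()` reports both a pooled per-read accuracy and a
  per-organism mean (organisms weigh equally regardless of read counts),
  since "average accuracy" is ambiguous between the two.
- The **predominant match** of a source organism is its modal predicted
  taxon; it is *confident* when its fraction strictly exceeds 0.40 (reads
  piling up on one database taxon indicate a specific relationship;
  scattering indicates nothing in the database is close). Modal ties break
  lexicographically; unclassified reads stay in the denominator.
- `compare_assignments()` reports match/mismatch/indeterminate fractions
  per rank over the shared read set (defaults species, genus, phylum) and
  is symmetric in its arguments.

On a tree-consistent taxonomy with no `UNKNOWN`s, a match at a finer rank
implies a match at every coarser rank, so accuracy is non-decreasing from
strain to phylum — asserted as a property test and visible in any
novel-taxon scenario (strain accuracy 0, high genus accuracy).

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is in its intended
regime: the in-database benchmark uses 20 genomes of 50–150 kb at $N = 8$
with 100 reads per genome; the oracle-equivalence check runs 200 random
profile/read pairs at $N \in \{2..6\}$ against an independent string-loop
scorer (agreement within $10^{-9}$; probabilities are exact small-integer
ratios in both routes, so the only float entry point is the log); the
normalisation check enumerates all $4^N$ N-mers at $N \le 6$; clone-length
distribution is checked by Kolmogorov–Smirnov at 10,000 draws. The
self-consistency property (an exact-substring read of length $4N$ returns
to its source genome) is exercised at $N = 8$: at $N = 6$ a 5 kb random
genome already contains most of the 4,096 possible 6-mers, a saturated
regime in which profiles of random genomes are barely distinguishable and
which the property is not about.

Databases serialise to a versioned two-part text container — a one-line
JSON header (format tag, version, MD5 digest) plus a JSON payload with the
sparse count tables — so round-trips are lossless, truncation and
corruption are detected, files from a newer format version are refused
explicitly, and rebuilding from identical inputs is byte-identical (no
timestamps in the metadata).

## Known limitations

- No query-length score normalisation (open problem; scores of reads of
  different lengths are not comparable to each other, only across taxa for
  one read).
- The flowgram model is a simplified stand-in (above); its parameters were
  not fit to real flowgram data.
- Multi-segment viruses are grouped however the mapping file says —
  one profile per segment and one per virus are both expressible, and the
  package takes no position.
- At the default $N = 15$ classification falls back from the dense
  $4^N$ scoring table to sparse lookups and is correspondingly slower;
  the intended regime for large databases is modest read batches.
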