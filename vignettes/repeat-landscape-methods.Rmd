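---
title: "Methods: repeat landscape characterization with repeatscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat landscape characterization with repeatscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`repeatscape` characterizes the repetitive landscape of a set of genomic
sequences — the situation faced when a genome is sampled through BAC or
fosmid assemblies rather than a finished reference. Repeats are found by
three complementary routes:

1. **Tandem repeats** — arrays of a repeated unit (period 2–500 bp),
   classified as microsatellites (2–8 bp), minisatellites (9–100 bp) and
   satellites (>100 bp).
2. **Homology** — alignment against a classified repeat library, with a
   gap-adjusted similarity (*sim*) and a modified 80-80-80 full-length
   standard.
3. **De novo discovery** — self-alignment of the sequence set plus a
   structural scan for LTR-like direct repeats, yielding consensus
   *seeds* that are mapped back to the reference, clustered, and merged
   into families.

Because real repeat landscapes have no accessible ground truth, the
package ships a simulator that plants repeat families and tandem arrays
with exact coordinates; the whole analysis is validated by parameter
recovery against those plants.

# Sequence sets and coordinates

All statistics exclude unresolved residues: `total_len`, GC, and length
quantiles are computed on N-excluded lengths, and every "% of set"
denominator is the non-N total. N50 is the length L such that records of
N-excluded length ≥ L cumulatively contain at least half the total; mean
and median lengths are truncated toward zero, matching how such tables
are conventionally printed. Whether N50 should use N-included lengths is
genuinely ambiguous for gappy assemblies; N-excluded was chosen for
consistency with the footnoted length convention and is used throughout.

Internally every interval is 0-based half-open. Conversion to 1-based
inclusive happens only at format boundaries (GFF3, TRF `.dat`, BLAST
tabular); BED stays 0-based. This removes a whole class of off-by-one
errors from interval arithmetic, which is delegated to `IRanges`.

# Alignment machinery

Two alignment engines coexist, with distinct roles:

* `local_align()` / the protein route use `Biostrings::pairwiseAlignment`
  (full-matrix Smith–Waterman / Needleman–Wunsch, affine gaps). Exact
  match and gap counts are recomputed from the returned traceback, so
  every hit carries the quantities the *sim* formula needs.
* Genome-scale searches (`seeded_search()`, self-alignment, seed
  mapping) first find candidate regions by exact k-mer seeding (k = 12,
  occurrence cap 40 to skip low-complexity DNA) and diagonal chaining,
  then align each candidate exactly with a banded affine-gap kernel
  (`src/balign.cpp`). The band is centred on the diagonal range implied
  by the chain with a ±150 bp drift margin — generous relative to the
  indel densities the pipeline operates at (net drift of order tens of
  bp over a few kbp), so the banded optimum equals the unbanded one in
  practice. Global identities for clustering use the same kernel with a
  band of at least max(150, 20% of the longer sequence).

Default nucleotide scoring is match +3, mismatch −4, gap open 5, gap
extend 2 (a gap of length L costs 5 + 2L), the BLASTN-style scheme used
for repeat annotation; the minimum reported local score is 50. The test
suite checks `local_align` against an independent full-matrix DP oracle
on short sequences and the banded global identity against
`Biostrings` full-matrix alignments.

## The sim similarity

Hits carry `sim = match_count / (alignment_length − query_gap_length −
subject_gap_length + gap_count)`, where the gap lengths count gap
residues per side and `gap_count` counts gap *openings* (the BLAST
`gapopen` quantity). With no gaps all three terms vanish and sim is
fraction identity — a property the tests assert for arbitrary gap-free
tracebacks. Counting openings rather than gap columns is a deliberate
reading of an ambiguous convention; it penalizes long gaps less than
scattered ones, which suits diverged elements whose indels cluster.

## The modified 80-80-80 filter

`full_length_filter()` keeps a hit when (1) its span on the library
(reference) element is strictly greater than 80 bp, (2) sim ≥ 0.80, and
(3) the reference span covers ≥ 80% of the reference length. The length
clause is measured on the reference span, consistent with the coverage
clause; alignment columns would differ only through gaps and make the
two clauses measure different things. Each clause is boundary-tested
independently (79/80 bp spans, sim 0.799, coverage 0.794).

# Tandem repeats

The detector is deliberately *not* a reimplementation of Tandem Repeats
Finder's probabilistic model; it keeps TRF's scoring convention (match
+2, mismatch −7, indel −7, minimum score 50, periods 2–500, copy number
≥ 1.8, period-1 runs excluded) and interoperates with real TRF output
through `read_trf_dat()`. Candidate periods come from exact k-mer
recurrence: a k-mer equal to the k-mer d positions downstream votes for
period d (k = 5 for d ≥ 5; k = d for d < 5). Votes are chained with a
gap tolerance of 2d+4 for short periods (which recur by chance every
4^d bp, so chains must be split aggressively) and 2d+20 otherwise, and
chains are kept only if the votes span at least 0.6 periods beyond the
first copy at a density ≥ 0.25 — random recurrence has density ~4^−k.
Each surviving candidate window is verified by local *wraparound*
dynamic programming against its majority phase consensus (Rcpp kernel
`src/wdp.cpp`): the consensus is treated as circular, so the alignment
extends through any number of copies and maximal array extension falls
out of the local DP. Harmonic re-detections of one array at a multiple
of its period are removed, preferring higher score then smaller period.

Overlaps between accepted arrays are resolved greedily by descending
score (ties: longer array, leftmost, smaller period); a candidate
overlapping accepted arrays by more than 10% of its own length is
dropped. The 10% tolerance is a free parameter — score-based
discrimination is the principle, the threshold keeps abutting arrays
with trivial overlap. "Variants" in the summary table counts distinct
*canonical* motifs per bin, where the canonical motif is the
lexicographic minimum over all rotations of the motif and of its reverse
complement (so AT/TA is one class, and the six spellings of the AT-rich
trinucleotide collapse). Copy numbers are reported to one decimal and
summed per bin; summation (rather than averaging) is what makes the
grand-total row conserve its parts, which the tests assert.

# De novo family discovery

## Seeds

Self-alignment seeding collects all chained k-mer matches of the set
against itself (trivial self-diagonal removed, both strands). Chain end
intervals are single-linkage clustered at ≥ 80% reciprocal overlap;
since intervals at different loci do not overlap, clusters correspond to
genomic *occurrence loci*. Each locus must be supported by at least 3
chains verified by exact alignment (HSP score ≥ 100 and span ≥ 80 bp) —
verification is lazy and cached, so an HSP verified once supports both
its loci. This is an efficiency reordering of "verify all HSPs, then
cluster": the surviving loci are identical, but only ~3 alignments per
locus are paid. With the support threshold at 3, a family needs at
least 4 copies for its loci to qualify — a deliberate choice: a repeat
should recur enough to give a stable majority consensus.

Qualifying loci linked by verified HSPs are grouped (connected
components), and each group emits one consensus seed from its widest
locus (star alignment of the locus's distinct member intervals to the
longest, per-column majority). Emitting one seed per group rather than
one per locus removes the per-copy redundancy *before* the expensive
re-mapping stage; the end result — a redundancy-filtered seed library —
is the same.

A structural pass then scans for direct-repeat pairs ≥ 100 bp at ≥ 80%
identity separated by 0.4–20 kbp within one sequence — the signature of
an LTR element — and adds the spanned region as a single-copy seed,
*skipping* candidates whose repeat ends lie inside already-qualified
loci (those are just copies of an already-found family). Two final
filters: a seed whose source neighbourhood is mostly covered by detected
tandem arrays is an SSR fragment and is dropped (the neighbourhood, not
the seed, is tested — one unit of a long-period satellite is not tandem
by itself); and near-duplicate seeds are collapsed at 0.8 global
identity in either orientation, with a shared-k-mer prescreen so that
unrelated pairs never reach the aligner.

## Instances, clusters, families

`map_seeds()` uses the seeds as the library of a non-redundant homology
search (highest-scoring annotation wins per region; a hit overlapping an
accepted one by more than half its span is discarded) and keeps hits
passing the 80-80-80 filter with the seed as reference. This
non-redundancy step is what prevents double-counting: an LTR-only seed's
hits fall inside the full-element hits and are discarded, and a
truncated genomic copy fails the 80% reference-coverage clause.
Instances are extracted in seed orientation (minus-strand hits
reverse-complemented).

Clustering is greedy centroid assignment: instances sorted by length
descending (ties by position) join the first centroid with global
identity ≥ 0.80 — matches over alignment columns of a global alignment
with end gaps penalized, since full-length instances are comparable in
extent. The fixed sort order makes output deterministic;
order-independence is not promised, matching the behaviour of greedy
centroid clusterers generally. Cluster consensi are star alignments
projected onto the centroid: per centroid column, majority over
A/C/G/T/gap, ties to the centroid's residue, gap-majority columns
dropped. Projection discards member insertions relative to the centroid;
for members within 20% divergence of a common ancestor this loses
almost nothing and keeps the consensus length anchored.

Families are connected components of the cluster graph where an edge
means the two consensi align under the 80-80-80 rule with the *shorter*
consensus as the reference (so a terminal-repeat cluster merges into its
parent element's family). Family coverage is the summed length of all
member sequences across the family's clusters; the representative
cluster is the one with the most members (ties: longer consensus).
Families whose representative consensus gets a full-length nucleotide
hit to a classified library entry take that entry's name, mirroring how
known and novel families mix in published family tables.

# Classification

`classify_repeat()` applies a strict three-route precedence:

1. **Nucleotide**: best full-length-filter-passing hit to the library →
   inherit the complete classification including family.
2. **Protein**: best local alignment between the sequence's ORFs
   (six-frame, ≥ 100 aa, standard code) and the library entries' ORFs at
   ≥ 35% identity over ≥ 100 aa → superfamily (and implied order/class)
   only, family `NA`. The 0.35/100 aa thresholds bracket the 38–59%
   translated similarities that superfamily-level calls typically rest
   on, while staying far above the twilight zone.
3. **Structural**: direct terminal-repeat pair → (I, LTR); inverted →
   (II, TIR); poly-A tail with an ORF and no terminal repeats →
   (I, LINE); otherwise unknown.

The precedence is monotone: adding a qualifying nucleotide hit can only
refine a call, never downgrade it (tested). Gypsy vs Copia
discrimination by internal domain *order* is out of scope; superfamily
calls rest on homology evidence only.

Structural detectors follow simplified LTRharvest/LTRdigest-style
rules. `detect_ltr_pair()` locally aligns the first and last
W = min(2500, length/3) bp of an element in both orientations and
accepts repeats ≥ 100 bp at ≥ 80% identity. `detect_ppt()` reports the
longest window of ≥ 10 bp at ≥ 90% purines within 30 bp interior of the
3′ LTR. `detect_pbs()` searches 30 bp interior of each LTR for ≥ 11 bp
of exact-or-one-mismatch complementarity to a tRNA 3′ end; the package
ships one fixed synthetic 18-mer as its tRNA fixture (a stand-in for a
host tRNA database — any real tRNA 3′ end can be passed instead).

# The simulator and what validation does (and does not) show

`simulate_genome()` plants features into i.i.d. background at a target
GC (0.38 by default, a conifer-like value). LTR masters carry identical
direct LTRs, a PBS (reverse complement of the tRNA fixture) directly
interior to the 5′ LTR and a 12 bp polypurine tract interior to the 3′
LTR; TIR masters carry inverted terminal repeats; LINE-like masters a
poly-A tail with optional 5′ truncation of copies. Copies diverge by
independent per-site substitutions and indels (geometric lengths, mean
3), insert on either strand at uniform positions avoiding feature
interiors — except explicit nesting, which inserts a copy inside a
previous copy and extends the host's truth interval across the insertion.
The realized identity of every copy is recorded from the edit script and
agrees with alignment-based measurement within ±0.02 (tested).

The standard validation genome (`benchmark_genome_spec()`) is 3
sequences × ~200 kbp with K ∈ 1..5 planted LTR families and 20 tandem
arrays spanning periods 2–450. Family defaults — 3 kbp elements, 400 bp
LTRs, 10 copies, substitution rate 0.05, indel rate 0.005 — are a
compact but realistic plant LTR element (real families range from ~3 to
~30 kbp; the size here keeps per-element alignments cheap without
changing any algorithmic behaviour). Masters are independent random
draws, so inter-family identity is far below every threshold in the
pipeline. The genome seed is derived from (not equal to) the spec seed
so the background stream never replays the motif draws.

Against these genomes the full pipeline recovers exactly K families
with copy counts within ±1, ≥ 90% of planted tandem arrays with the
correct canonical period (or a harmonic), and a total repetitive content
within ±15% relative of the planted truth; structural detectors find
≥ 90% of planted LTR pairs/PBS/PPT with a false-positive rate ≤ 5% on
random 1 kb sequences. These are the quantities `scripts/acceptance.R`
recomputes.

What passing does **not** show: the background is i.i.d. (no isochores,
no gene content, no segmental duplication), families are equally sized
and cleanly separated in identity, solo LTRs and recombination-derived
fragments are absent, and assembly artifacts (collapsed repeats, Ns,
chimeric joins) are not modelled. Performance on real BAC/fosmid data —
where most repetitive sequence is partial, degraded and nested — will
be dominated by exactly the phenomena the simulator omits; the
validation demonstrates correctness of the machinery, not field
sensitivity.

# Numerical and degenerate-input choices

* Ties are broken deterministically everywhere (score, then span, then
  position/period/name); all greedy stages are therefore reproducible.
* Alignment through N is blocked by a large negative score rather than
  treated as mismatch, which also implements iterated masking.
* Empty inputs return typed empty tables; an all-N record, an empty
  library, and a zero-denominator sim are errors.
* `detect_tandem` on a record shorter than twice the minimum period,
  and `detect_ltr_pair` on sequences under 400 bp, return nothing.
* Percentages are printed to 2 decimals in content and family tables
  and 3 in tandem summaries, following the precision of the tables they
  mirror; underlying values are kept at full precision.

# Problem sizes used by the shipped analyses

The analysis drivers and the acceptance script run the benchmark
genomes described above (600 kbp per genome, K = 1..5), 30 structural
test elements and 100 random negative controls — sizes chosen so the
complete validation, including five full pipeline runs, completes in
minutes on one CPU while every stage still operates well above its
detection thresholds.

# Known limitations

* The de novo route needs ≥ 4 copies of a family (support ≥ 3) unless
  the structural LTR scan fires; low-copy non-LTR families are invisible
  to it by design.
* Banded alignment underestimates scores if the true alignment drifts
  beyond the band; margins are sized for the simulator's indel regime,
  and pathological inputs (huge structural indels inside one element)
  would need the full-matrix route.
* `read_blast_m8()` approximates match counts from the percent-identity
  column; exact counts require the internal aligner. Both paths fill the
  same hit contract.
* The tandem detector's period proposals come from exact k-mer
  recurrence, so arrays diverged far beyond ~10% per site can fail to
  nominate their true period (TRF's probabilistic model is more
  sensitive there; its `.dat` output can be ingested directly).
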