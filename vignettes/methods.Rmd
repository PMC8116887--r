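---
title: "Reference-free somatic break-point detection with kmerscout: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free somatic break-point detection with kmerscout: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerscout)
```

## The detection model

kmerscout compares two read sets — tumor and matched normal from the same
patient — entirely through their k-mer content, without a reference genome
or alignment. The underlying abstraction: the normal genome N is an
(approximately) random character sequence, the tumor genome T is N with
substitutions, insertions and deletions at a small number of well-separated
sites, and each sample is observed only through reads of uniform length $r$
covering each position $\alpha$ times on average, from both strands, with
a per-base substitution error rate $\varepsilon$ and possible contamination
of the tumor sample by normal cells.

A k-mer present in only one sample marks a mutation or its boundary, but on
its own it cannot *align* the two samples at that locus. The key device is
the **almost-matching pair**: two k-mers whose middle $k-2$ bases (the
**stem**) agree but whose first or last base differs. If $k$ is large
enough that a stem occurs in a single genomic location, a tumor-exclusive
k-mer together with a normal-supported k-mer on the same stem pins down the
mutation boundary and lets reads from the two samples be stacked at the
same locus. Because the two DNA strands are sequenced in opposite
directions, a stem and its reverse complement mark the same locus; the
**root** — the alphabetically smaller of the two — is the strand-neutral
key. A non-palindromic root gathers $2 \times 4 \times 4 = 32$ k-mers (16
per stem); a palindromic stem is its own reverse complement and gathers 16.

With bases packed two bits each in A<C<G<T order, string comparisons become
integer comparisons, and every k-mer maps to the **root-major sort key**

$$\mathrm{key} = (\mathrm{root} \ll 5)\,|\,(\mathrm{stem\_flag} \ll 4)
  \,|\,(\mathrm{first} \ll 2)\,|\,\mathrm{last},$$

so that plain integer sorting lands all k-mers of a root in one contiguous
block of at most 32 keys. This key is the index of the on-disk histogram.

### Choice of k

The useful band is roughly $24 < k < 32$: long enough that stems are
effectively unique in a genome, short enough that a read error (which
corrupts up to $k$ windows) does not erase too much signal. The default is
$k = 28$. The package caps the pipeline at $k \le 28$: root codes cross the
R boundary as doubles, which are exact integers up to $2^{53}$, and
$2(k-2) \le 52$ bits holds exactly for $k \le 28$. R-level numeric
encodings (`encode_kmer()`, `sort_key()`) are exact for sequences up to 26
bases; longer k-mers are handled as strings at the surface and as native
64-bit integers inside.

## Count: external-memory histogram construction

`build_histogram()` streams both FASTQ files, emits one update
`(sort key, (1,0))` or `(sort key, (0,1))` per valid k-mer window (windows
containing non-ACGT characters are skipped, preserving the rest of the
read), and feeds them to **Sort-Reduce**: updates are buffered up to the
memory budget, sorted, equal keys merged by saturating 16-bit counter
addition, and spilled as a sorted run; runs are then merged at a fixed
fan-in (default 16), again reducing equal keys on the fly, until a single
fully reduced run remains. The result is identical, bit for bit, to an
in-memory hash-table accumulation — the test suite asserts this against a
naive oracle across budgets and fan-ins — but the peak resident set is the
phase-1 buffer plus one read-ahead record per merged run.

Two format decisions matter downstream:

* **k-mer-indexed entries.** The histogram stores one 12-byte entry (8-byte
  key, two 2-byte counters) per *observed* k-mer, not one 136-byte record
  per root. Most of a root's 32 variants are never observed, so on sparse
  data the k-mer-indexed file is about 91% smaller than the root-indexed
  equivalent ($1 - 12/136$ when each root shows one variant).
* **Singleton removal.** A root whose total count across both samples is
  exactly 1 is sequencing noise with overwhelming probability (expected
  count of an error k-mer is about 1, of a real one about
  $\alpha(r-k+1)/r$). All entries of such roots are dropped during the
  final streaming pass. The definition is *total count 1*, the faithful
  surrogate for "appears in only one read" given that repeated occurrences
  within one read are negligible at $k = 28$.

Counters saturate at 65535 rather than wrap; saturation is flagged in the
file header. Quality lines are read and ignored; paired-end files are
treated as independent single-end reads; reads are counted on the strand
given in the FASTQ, since root canonicalization already pairs the strands.

### Partitioning

The root space $[0, 4^{k-2})$ can be range-partitioned
(`partition_bounds()`) into $P$ equal half-open intervals; Count and Label
run per partition touching only in-range roots, and the per-partition
databases are merged afterwards. Output is invariant to $P$ (asserted by
checksum in the tests). Range (rather than hash) partitioning keeps each
partition's band-pass filter tight.

## Label: serving look-ups from a read-only store

The Label unit must fetch, for every read k-mer, *all* counters of the
k-mer's root. The histogram is written once and then only read, which
permits a store layout no general-purpose database can match:

* **Root records.** Consecutive histogram entries of a root fold into a
  136-byte record: 8-byte root code plus 64 16-bit counters (normal and
  tumoral for each of the 32 variant slots; variant $v$ occupies slots
  $2v$ and $2v+1$; the flag-1 half of a palindromic root stays zero for a
  fixed record size). One record answers the whole root query, so one
  storage read suffices per look-up.
* **Chunks.** Records pack 30 per 4096-byte chunk — one flash page — in
  root order, with no record spanning chunks.
* **Implicit multi-level index.** The first key of each chunk forms a
  sorted array; each level above keeps every 16th key, so level $j+1$ has
  $\lceil |j|/16 \rceil$ keys and the $i$-th key of a level covers children
  $16i..16i+15$ below — array positions are the pointers, and a descent
  reads at most 16 consecutive keys (one cache line burst) per level.
  The descent provably equals flat binary search; the tests compare it
  against `findInterval()` on random probes.
* **Negative-look-up filters.** A band-pass check against the stored
  min/max root rejects out-of-range probes for free (particularly sharp
  when the root space is partitioned), and a Bloom filter (10 bits/key, 7
  hashes, double hashing $h_i = h_1 + i\,h_2$ over two seeded splitmix64
  mixes; seeds persisted in the header) rejects most of the remaining
  absent roots. The filter has no false negatives by construction; its
  theoretical false-positive rate at the defaults is
  $(1 - e^{-hn/m})^h \approx 0.0082$, and the measured rate on random
  absent probes is asserted within a factor two of that.

The invariant the design leans on — **at most one data-chunk read per
look-up** — is instrumented: every look-up result carries its chunk-read
count and the tests assert the bound. A Bloom false positive costs exactly
its one chunk read and resolves to absent.

### The frequency-predicted cache

The histogram itself predicts its future look-up load: during labeling a
root is probed once per occurrence of its k-mers in the reads, which is
exactly what its counters total. `build_cache()` therefore ranks roots by
total count (ties to the lower root code), and admits whole roots greedily
under a byte budget, accounted in the compact 12-bytes-per-present-k-mer
format. Whole-root admission is deliberate: the Label unit always needs
all counters of a root, so a partial hit would still cost the storage
read. A hit reconstructs the full 64-counter record, making the cache
semantically invisible — pipeline output is asserted identical for any
budget including zero. On skewed (Zipf-like) genomes the hit fraction far
exceeds the cached fraction of roots, and per-partition caches under the
same budget serve at least the single-cache fraction, which is why
partitioned runs benefit twice from the same DRAM.

### The interestingness rule

The concrete thresholds of the original somatic-calling heuristic are not
part of this package's sources; the rule is therefore parameterized and
every threshold is exposed in `label_config()`:

variant $v$ of a root is **tumoral-interesting** iff
$t_v \ge T_{\min}$ (default 4: "seen multiple times", several reads beyond
what an error can produce at $\alpha = 30$), and
$n_v \le N_{\max}$ (default 1: tolerance for normal contamination of the
tumor sample), and some *other* variant $w \ne v$ of the same root has
$n_w \ge W_{\min}$ (default 4) — the almost-matching witness that makes
cross-sample alignment possible. A symmetric mode (off by default) swaps
the roles to catch normal-only k-mers.

One design choice deserves emphasis. A read enters the interesting-read
table if it touches any **root** hosting an interesting variant — not only
if it contains the interesting k-mer itself. Under the tumoral-only rule
the normal-sample reads never contain the tumor allele, so admitting reads
by exact interesting k-mer would produce single-sample read groups and no
break-point could ever be reconstructed; admitting by root is what brings
the witness-carrying normal reads into the database. The k-mer table still
lists only the interesting variants themselves.

## Group: anchor alignment and break-point calls

One candidate group forms per root with at least one interesting k-mer;
its members are all database reads hitting that root, from both samples. A
member whose hit k-mer carries the stem on the opposite strand is
reverse-complemented (offset recomputed as $|read| - k - pos$ for the
k-mer start), so the anchor stem matches literally in every oriented
member. Groups with identical member sets collapse to the lowest root.

Alignment is **gapless**: each member shifts so its anchor stem starts at
column 0; per column and per sample the base counts, coverage and majority
consensus (ties give `N`) are computed. The anchor occupies the same
columns in every member by construction. Gapless anchoring is the minimal
faithful reading of the reconstruction sketches this family of methods
publishes; its documented cost is that an indel appears as a *divergence
region* downstream of the mutation (the frame shift makes roughly 3 of 4
columns disagree, with chance re-matches fragmenting the region) rather
than as gapped columns.

That cost dictates the calling rule. Since injected mutations are at least
$3k$ apart, a group spans a single locus, and the break-point — the start
or end of the mutation — is where the two consensi *begin* to diverge
moving away from the matched anchor. `call_breakpoints()` therefore finds
all columns where both samples have coverage $\ge C_{\min}$ (default 3)
and unambiguous differing consensus, and emits one call per side of the
anchor at the divergent column nearest it, with $\pm 2k$ context from both
consensi. Calling every fragment of the divergence region separately would
scatter calls across the frame-shifted tail and destroy precision without
adding information; the onset column is the quantity the alignment
actually determines. A pure point mutation yields the classic single
divergent column adjacent to the anchor.

`evaluate_calls()` maps calls back to reference coordinates through member
provenance (a layout column is a read position, unflipped and unstranded
into the source genome; the per-call position is the median over
normal-origin members) and scores recall and precision against the
simulator's manifest at tolerance $k$.

## The synthetic patient generator

`make_patient()` is the embodiment of the sampling model above, and its
defaults are the study conditions used throughout the acceptance checks:
reference length $L = 2\times10^5$, coverage $\alpha = 30$, read length
$r = 100$, substitution error rate $\varepsilon = 10^{-3}$, 20 SNVs, 3
insertions and 3 deletions of 2-20 bases, minimum mutation separation
$3k = 84$, tumor contamination 5%, seed 1. Mutation sites are drawn by a
spacing transform (sorted draws from a shrunken range, shifted apart by
the separation), so placement is guaranteed rather than retried. Reads
start uniformly on $[0, |genome| - r]$, flip strand with probability 1/2
(emitted as reverse complements), and substitute each base independently
with probability $\varepsilon$. Read ids carry `origin=pos:strand:source`
so ground-truth evaluation needs no alignment. Everything is deterministic
per seed, byte for byte.

The $L = 2\times10^5$ scale is chosen so the full pipeline — about nine
million k-mer updates and four hundred thousand distinct roots — runs in
well under a minute while exhibiting every phenomenon the method depends
on: singleton noise floor from read errors, strand-split coverage,
contaminated tumor reads, and indel frame shifts.

What the simulator deliberately does *not* model: diploidy and germline
heterozygosity, GC or positional coverage bias, sequencer-specific indel
errors and quality profiles, and genomic repeats (the reference is i.i.d.
uniform, so stems are essentially unique by construction — real genomes
violate this locally and the method's own $k$-range argument is the
defense). Passing the recovery tests therefore demonstrates correctness of
the machinery under the stated model, not calling performance on real
tumor genomes. Two further edge effects are documented rather than
modeled away: the first and last read-length of the genome receive fewer
read starts, so edge k-mers can lack normal coverage; and coverage at a
specific k-mer is Poisson-thinned to about $\alpha(r-k+1)/r \approx 21$,
which is why the default thresholds sit far below it.

## Numerical and degenerate-input choices

* Counters: 16-bit saturating; totals and budgets in doubles.
* Ties in consensus go to `N` (never called); ties in cache ranking to the
  lower root code; groups with identical members to the lower root —
  every tie-break is fixed so output is reproducible.
* Empty inputs degrade cleanly: empty update streams produce an empty run
  file; an empty histogram produces a store whose band-pass rejects
  everything; identical samples produce an empty database, no groups and
  no calls.
* Bloom sizing: $10 n$ bits rounded up to whole chunks, minimum 64 bits,
  so tiny stores stay valid.
* Run and histogram files are little-endian with magic headers; merge
  passes validate strict key monotonicity and abort on corruption.
* `lookup_batch()` processes sub-batches of `queue_depth` probes;
  concurrency knobs shape batching only — the tests assert the result
  multiset equals sequential look-ups.

## Problem sizes used by the checks

The test suite and the acceptance script size their problems as: Sort-Reduce
oracle at $10^5$ updates over $10^3$ keys across three budgets and three
fan-ins; store equivalence over every present root plus $10^4$ random
absent probes; cache curves over 40,000 Zipf-distributed probes on ~1,200
roots; parameter recovery on the default patient (twice: with noise and
contamination, and with both zeroed); and partition invariance at
$P \in \{1, 2, 4\}$ on a $3\times10^4$-base patient, compared by checksum.

## Known limitations

* Gapless alignment cannot type mutations (no SNV/INS/DEL label on calls)
  and reports indels as divergence onsets, not as gapped columns with the
  inserted/deleted sequence spelled out.
* Overlapping groups spanning one large structural variant are only
  deduplicated when their member sets are identical; a long SV shows up as
  several nearby calls.
* `symmetric` mode (germline-style normal-only k-mers) is provided but
  untuned.
* The pipeline requires $4 \le k \le 28$; the upper limit is the exact
  integer range of doubles at the language boundary, inside the
  recommended $24 < k < 32$ band but excluding $29..31$.
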