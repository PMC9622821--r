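---
title: "Methods: detecting and analysing smORF translation in long non-canonical RNAs"
author: "lncorf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analysing smORF translation in long non-canonical RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncorf)
```

# The problem

Long non-canonical RNAs (lncRNAs) — transcripts over 200 nt without an
annotated coding sequence — carry tens of thousands of small open reading
frames (smORFs, here called lncORFs when they sit on a lncRNA). Ribosome
profiling can decide which of these are actually translated: a translating
ribosome protects a footprint (RPF) whose 5′ ends recur every three
nucleotides in one reading frame. `lncorf` implements that decision as a
pipeline of small, testable stages: ORF cataloguing, footprint-length-resolved
frame calibration, an exact binomial framing test, a replicated
translation-status classifier, developmental-regulation calls, cis-feature
scoring, reciprocal-best-hit micropeptide homology search, and pairwise
dN/dS. A deterministic synthetic-data generator with planted ground truth
stands in for deposited sequencing data, so every stage can be exercised and
validated end to end on a laptop.

# ORF catalogue

`find_orfs()` scans transcripts (forward strand; 6-frame optionally, for
EST-style peptide databases) for AUG→STOP frames, reading each AUG to the
first in-frame stop. Codon counts are stop-exclusive and bounded to 10–150
codons, the range of smORF peptides worth cataloguing. Among ORFs sharing a
stop codon in the same frame, only the 5′-most AUG is kept (internal ORFs
are nested fragments of the same translation unit). All coordinates are
0-based half-open on the transcript 5′→3′ strand; ORFs overlapping annotated
CDS or uORF intervals by ≥1 bp on the same strand are removed
(`filter_against_annotation()`), mirroring `bedtools intersect -v -s`.
ORFs containing N are dropped with a message. The caller is verified against
an exhaustive substring-enumeration oracle on short random transcripts.

# Frame calibration and the framing test

RPF lengths between 26 and 36 nt show consistent triplet periodicity but in
length-dependent frames (shorter footprints favour frame 0, longer ones
frame 2, with intermediate lengths mixed — the consequence of variable
ribonuclease trimming at the fragment ends). `calibrate_frames()` therefore
learns, per RPF length, the dominant frame over a set of canonical
(known-translated) ORFs of the *same sample*; calibration is never pooled
across samples because framing patterns drift between libraries. Exact ties
resolve to the lowest frame index and flag the length as ambiguous; lengths
without reads get no expected frame and are skipped downstream.

Reads are attributed by their raw 5′ end with no P-site offsetting: a
constant per-length offset only relabels which frame is dominant, and the
calibration absorbs it. Reads whose 5′ end falls in the −18/+15 nt flanks
around an ORF are kept for metagene output but never enter the test counts.

`framing_test(n, k)` is the one-sided upper-tail exact binomial test
`P(X ≥ k | n, p0 = 1/3)`: three frames, no prior, and framing is an *excess*
in the expected frame only. An ORF/length is framed when `p < 0.01`. The
smallest all-in-frame count that can pass is 5 reads
(`(1/3)^5 ≈ 0.0041 < 0.01`, while `(1/3)^4 ≈ 0.012` cannot). No minimum
read-count filter is applied beyond the test itself. Framing detected at
distinct (length, replica, stage) triples counts as independent translation
events (`count_translation_events()`), because different footprint lengths
arise from different ribonuclease-protection events.

# Translation-status classification

Per stage, with two biological replicas T and B
(`classify_status()`):

* **transcribed** — RNA-seq RPKM > 1 in *either* replica;
* **ribo-bound** — additionally footprint RPKM > 1 in *both* replicas;
* framing is consulted only once the ribo-bound condition holds:
  framed in both replicas → `robust`, in exactly one → `limited`,
  in neither → `ribo_bound_only`;
* transcribed but not bound → `transcribed_only`; otherwise
  `not_expressed`.

The ordering matters: an ORF with footprint signal in a single replica is
`transcribed_only` even if that replica shows framing, because framing on
irreproducible binding is not interpretable. RPKM uses the library's total
mapped reads as denominator, supplied explicitly (`library_size`) rather
than inferred, since the mapped total exceeds the reads on the analysed
transcripts.

Stage specificity (`stage_summary()`) is constitutive / stage-specific /
never, for transcription and translation separately. Quantitative
regulation between time-contiguous stages uses translational efficiency
TE = RPKM^FP / RPKM^RNA (replica-averaged per stage, so one TE per ORF per
stage), transformed as `log10(TE)`; log base is a display convention and
cancels in the standardisation. Z-scores are taken within each stage across
ORFs and the Z-ratio is the per-ORF z difference standardised by its SD
across ORFs; `|Z| ≥ 1.5` (an empirical threshold) flags a regulatory event
(`te_z_ratios()`). The function refuses degenerate tables (zero variance,
fewer than 3 ORFs, non-positive TE) loudly rather than returning NA.

# Cis features

**Kozak context.** Eight positions around the start codon are scored: −5…−1
and +4…+6 (the AUG itself is excluded). `build_kozak_model()` estimates
per-position nucleotide frequencies from canonical start contexts with a
pseudocount of 1 per nucleotide, against a background of the pooled
position-independent frequencies of the same contexts with the same
per-position pseudocounts (the pooled pseudocount is necessarily 8× the
per-position one; this is the unique convention under which a position whose
usage equals the pooled usage gets weight exactly 0). Weights are
natural-log odds. Scores are reported centered so that the canonical-set
mean is 0. A consequence of the shared pseudocount convention: a nucleotide
absent at one position but present elsewhere in the pool weighs finitely
negative; one absent from the entire pool weighs exactly 0.

**Cistronic position.** `cistronic_rank()` ranks each ORF 5′→3′ among *all*
predicted ORFs of its transcript, blind to translation status.

**Codon usage.** `milc()` implements MILC, the within-family
synonymous-codon usage distance to a reference set (canonical ORFs):
`M_a = 2 Σ o_c ln(f_c/g_c)` per synonymous family, summed, divided by the
codon count L, minus a correction `C = Σ (r_a − 1)/L` over observed
families. Since `M_a` is a G-statistic with `r_a − 1` degrees of freedom
under the reference usage, this correction makes a sequence sampled from
the reference score ~0 — the property the implementation is validated by
(a constant-based check would tie the test to one correction variant;
variants differing by O(1) offsets exist in the literature, and the
sampled-reference property pins down the one consistent with a
zero-centred statistic). Met/Trp contribute 0; stop codons are excluded;
codons missing from the reference fall back to a 0.5 pseudocount with a
message.

# Homology search

`search_and_validate()` is a reciprocal-best-hit (RBH) search over
per-species smORF peptide databases (10–150 aa, in-silico translations,
deduplicated; `build_smorf_db()`). The alignment engine is Smith–Waterman
local alignment with BLOSUM62 and affine gaps (open 11, extend 1) via
`Biostrings::pairwiseAlignment`; the pipeline's substance — forward ranking
with a score floor of 0.4× the query self-score, reciprocal validation
against the whole query ORFome, conservation annotation and scoring — is
independent of the engine, and an iterative profile search could be swapped
in behind the same interface. A forward hit is validated only if the
original query is its top reciprocal hit (rejecting paralog traps).

The validated pair is annotated per column: `*` identical, `:` strong
similarity (PAM250 > 0.5), `.` weak similarity (Clustal weak groups —
the numeric PAM250 cutoff is specified only for the strong tier, so the
weak tier follows the established Clustal grouping), space otherwise or at
gaps. The conservation-weighted score is
`(100·#* + 70·#: + 30·#.) / query length`, bounded by 100 (full-length
perfect conservation). Percent identity also uses the query length as
denominator, for consistency with the score. `conservation_depth()` counts
species (ordered by divergence) with validated hits passing identity > 50%
and reports the most divergent one.

# Selection (dN/dS)

`li93_dnds()` implements the Li (1993)/Pamilo–Bianchi counting estimator on
pairwise in-frame codon alignments. Sites are classed by degeneracy via
enumeration over the genetic code: 4-fold if all three substitutions are
synonymous, 2-fold if exactly the transition is synonymous (this collapses
the three-fold Ile third positions, and sends e.g. the first position of
CGA to 0-fold because its transition creates a stop), 0-fold otherwise.
Site counts are averaged between the two sequences; a differing position
whose class differs between sequences contributes ½ to each class. With
transition/transversion proportions `P_i, Q_i` per class,
`A_i = −½ln(1−2P_i−Q_i) + ¼ln(1−2Q_i)`, `B_i = −½ln(1−2Q_i)`,
`dS = (L2·A2 + L4·A4)/(L2+L4) + B4` and
`dN = A0 + (L0·B0 + L2·B2)/(L0+L2)`. Saturation (log argument ≤ 0) yields
non-finite distances flagged in the result rather than an error; `dS = 0`
flags the ratio undefined (infinite when `dN > 0`). Gap-containing and
stop-containing codon columns are dropped pairwise; ambiguous bases are
treated like gaps (dropped with the column) since their correct weighting
is not well defined for a counting method.

# Overlap and clustering statistics

`representation_factor()` is observed/expected overlap with
`expected = n1·n2/N`; 1 means the random expectation. Significance uses
hypergeometric tails (enrichment and depletion both reported; the test is
the natural exact null for drawing two fixed-size sets from a universe).
`poisson_clustering()` compares the per-transcript count of ribo-bound ORFs
with a Poisson(λ = mean) expectation via chi-square goodness of fit, pooling
bins from the right until every expected count is ≥ 5 and spending one
degree of freedom on the estimated λ. λ is fitted on all supplied
transcripts (all transcribed lncRNAs), not only multi-ORF ones.

# The synthetic-data generator

`simulate_transcriptome()` / `simulate_reads()` emulate one embryonic-style
study: three stages (Early/Mid/Late) × two replicas (T/B), Poly-Ribo-Seq
RPF populations of lengths 26–36 nt with length-dependent dominant frames
(26–30 → frame 0, 31 → an even mix of frames 0 and 2, 32–36 → frame 2) and
framing fidelity π = 0.75, plus uniform-coverage RNA-seq. Everything is a
pure function of `(config, seed)`.

Design choices worth knowing:

* **Library size 4e7** mapped reads per sample — the recommended minimal
  depth of ~40 million mapped reads per replica for lncRNA-scale work.
* **Planted RPKM levels** sit an order of magnitude above the RPKM > 1
  threshold for expressed classes (RNA 10, footprint 30 for bound lncORFs;
  canonical 30/60) and well below it for silent ones (0.2/0.1). Footprint
  coverage of bound ORFs is set so that even the shortest planted-robust
  ORF carries enough reads (~a minimum of 20 framed reads per sample) for
  its framing to be statistically detectable — planted statuses must be
  recoverable from the emitted reads, otherwise the truth table would
  contradict its own data.
* **Frame sampling**: a footprint lands in its length's dominant frame with
  probability exactly π and in each other frame with probability (1−π)/2,
  so π = 1/3 is exactly uniform and the framing test's type-I behaviour can
  be asserted against it. `limited` ORFs carry fidelity π in one planted
  replica and 1/3 in the other (a coverage-asymmetry reading of the
  classifier's own definition, not a biological model).
* **Status mix** (robust 0.15 / limited 0.15 / ribo-bound 0.20 /
  transcribed-only 0.50 over ORFs of transcribed lncRNAs, 15% of lncRNAs
  untranscribed) is allocated exactly by largest-remainder rounding, so
  planted class counts are exact by construction.
* **Sequence construction** guarantees that `find_orfs()` recovers exactly
  the planted catalogue: ORF interiors use G-free sense codons, stops are
  always TAA, spacers are G-free, and start contexts are
  rejection-sampled so the only ATG occurrences are planted starts.
* **Kozak strength** is planted by setting `round(8s)` of the 8 context
  positions to a fixed consensus (CAATC|GGT) and the rest to random
  non-consensus bases, so strength is a property of the emitted sequence.
  The consensus is base-balanced (each nucleotide twice) which keeps the
  trained model's pooled background near uniform and the per-position
  weights comparable; with an unbalanced consensus the score depends on
  *which* positions are consensus rather than how many, and a scalar
  "strength" would not be identifiable.
* **Homologue evolution** (`evolve_codon_sequence()`) is a Gillespie
  simulation of single-nucleotide substitutions with transition bias κ,
  nonsynonymous scaling ω, and rejection of stop-generating changes; rates
  are normalised so the branch length t is the expected neutral
  substitutions per site. Decoys are residue-shuffled homologue peptides
  (composition-matched, order-destroyed).

What the generator does **not** emulate: rRNA contamination, alignment
error and multi-mapping, UMI structure, positional coverage biases (ramps,
pauses), overlapping ORFs, non-AUG initiation, isoform structure, and
inter-replicate overdispersion beyond Poisson sampling. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under its stated model, not robustness to every artefact of real
libraries.

# Numerical choices and problem sizes

Ties in frame calibration resolve to the lowest frame index and are flagged;
zero-read lengths are skipped, not guessed. Degenerate Z-ratio inputs error
loudly. The binomial test is exact (no normal approximation). The validation
suite uses desk-scale problem sizes chosen for tight Monte-Carlo error at
interactive runtimes: 10,000 null ORFs for the type-I check, 1000
reads/length for calibration recovery, a 60-lncRNA / 30-canonical default
study for end-to-end status recovery, 200 seeded 300-codon pairs per ω for
dN/dS recovery, 30 queries with 10× decoys for homology recovery, and
500+ ORFs for Kozak-strength recovery.

# Worked example

```{r, eval = FALSE}
library(lncorf)
res <- run_pipeline(sim_config(seed = 1))
table(res$status$status)
head(res$te_changes[res$te_changes$significant, ])
```

# Known limitations

* Deduplication is per transcript; projecting ORFs across isoforms to
  genomic coordinates is out of scope (a genome-projection hook can be
  layered on the interval types).
* The homology engine is pairwise local alignment, not an iterative
  profile search; very remote homologues below the score floor are missed
  by construction.
* The Li counting estimator is biased downward at high divergence and
  undefined at saturation; both conditions are flagged, not fixed.
* BAM/SAM input is not parsed; an upstream adapter must produce the
  transcript-aligned read TSV.
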