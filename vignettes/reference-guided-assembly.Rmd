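---
title: "Reference-guided metagenomic assembly with metaguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided metagenomic assembly with metaguide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Short-read metagenome assembly is hard precisely where public genome
databases are rich: when a sampled organism has close relatives among
hundreds of thousands of reference genomes, de novo assemblers ignore that
information, while naive reference mapping drowns in redundancy (dozens of
near-identical strains per species) and picks up false references. metaguide
implements a reference-guided pipeline for this setting: select the
references the sample plausibly contains, collapse them into species-level
units, assemble each unit greedily against its best-matching references, and
polish the result so contigs reflect the *sampled* organism rather than the
reference used as a guide. Reads not explained by any reference are exported
for downstream de novo assembly.

## The method, stage by stage

**Reference selection by marker-gene coverage.** Each reference genome
carries 40 universal single-copy marker genes (consumed here as interval
annotations; detecting them is out of scope). Marker sequences are clustered
per family at 99% identity and each cluster keeps its founder as
representative — greedy incremental clustering, longest sequence first, a
gene joining the first representative it matches at or above the threshold.
All sample reads are aligned to the representatives only; a representative's
coverage is inherited by every member gene of its cluster. A gene counts as
covered when the *breadth* of coverage (fraction of positions with depth at
least 1) strictly exceeds 0.90, and a genome is selected when at least 75%
of the 40 families are covered (inclusive). The asymmetry — strict `>` for
breadth, inclusive `>=` for the fraction — follows the wording of each rule
("exceeds" vs "at least"). Depth itself plays no role in selection; breadth
is the criterion. The denominator is always 40, so genomes with missing
marker annotations are penalized rather than quietly advantaged.

**Reference culling at the species boundary.** Selected genomes are grouped
by average nucleotide identity (ANI) at the conventional 95% prokaryotic
species threshold. ANI is estimated from bottom-s MinHash sketches (k = 21,
s = 1000) via the Mash distance transform
ANI = 100·(1 + ln(2J/(1+J))/k), where J is the Jaccard index on the merged
bottom-s sketch. A Jaccard of zero is reported as "undetected" (`NA`), never
as 0% identity. Clusters are single-linkage connected components: the 95%
cutoff is a species boundary, and chaining through intermediate strains is
the intended behavior. This ANI estimator is a declared stand-in for
chaining-based tools; for thresholding at 95% its accuracy is ample
(at 3% true divergence it lands near 97%, far from the boundary on small
genomes).

**Cluster prioritization.** Clusters are processed in order of the *exact*
intersection (k = 28, never sketched) between the cluster's canonical k-mer
set and the k-mers of the still-unassigned reads, recomputed from scratch
before every selection. Reads consumed by one cluster are excluded from all
later clusters, so priorities can only shrink; a cluster whose intersection
never rises above zero is reported as skipped.

**Greedy within-cluster assembly.** Inside a cluster the reference to
assemble next is the member whose sketch has maximal containment in the
unassigned-read k-mer set — a greedy set-cover approximation of "the genome
that explains the most remaining reads". Reads are aligned to that guide
with the internal aligner, every maximal run of positions with depth >= 1
becomes a contig carrying the guide's sequence, runs shorter than 500 bp are
discarded (and their reads returned to the pool), and AGP v2.1 records tile
the full guide with contig (W) and gap (N) parts. Assembly of the cluster
stops at the first of: (i) all reads assembled, (ii) all references
assembled, (iii) the guide's cumulative contig length below 5% of that
guide's length, (iv) longest contig under 2,000 bp. Criteria (iii)/(iv)
detect diminishing returns; when they fire in a multi-genome cluster the
offending guide's contigs are discarded and its reads are returned, but a
singleton cluster always retains its assembly. Criterion (iii) is evaluated
against the *current* guide's length — the reading consistent with the
per-genome termination narrative the method reports.

**Polishing.** Supporting reads are realigned to each contig. Reads that
fail the ungapped aligner are split-anchored on their first and last
21 bases to detect a single indel of up to 10 bp; they contribute deletion
marks or insertion observations plus flank coverage. At every position with
depth >= 2 a symbol supported by >= 60% of overlapping reads replaces the
contig symbol (base, deletion, or following insertion); literal ties in
support between challenger and reference keep the reference. Everything
else keeps the guide base. The polisher is a defined replacement for an
external polishing tool: the published method specifies the *goal*
(reconstruct the sample, not the reference), not the mechanism, so the
mechanism here is fully specified and exactly testable.

## The aligner

The internal short-read aligner is seed-and-extend and deliberately
ungapped: exact 21-mer seeds anchor candidate placements, the full read is
scored ungapped at each candidate offset (both strands), and the best
placement is reported iff matches/length >= 0.85, with ties resolved to the
leftmost coordinate then the '+' strand. Placements running off a target
end are not considered. The 0.85 default tolerates ~95% ANI strain
divergence plus ~1% sequencing error on 100 bp reads; 21 bp seeds make
spurious anchors in 100–300 kb genomes vanishingly rare while a read with a
few substitutions almost always retains one exact seed. Ungapped scoring
keeps the aligner byte-for-byte comparable to a brute-force all-offsets
oracle (the basis of its tests); small sample-vs-reference indels surface
as unmapped reads and are recovered at polishing by the split-anchor path.
Paired-end mates are mapped independently; pairing matters only for read
accounting (a pair is "used" when either mate is).

## Hashing and numeric choices

Canonical k-mers (lexicographic min of a window and its reverse complement)
are packed 2 bits/base and mixed through a seeded splitmix64 finalizer. The
64-bit result is masked to 53 bits so hash values are exactly representable
as R doubles; at desk scale (< 2^25 distinct k-mers) the extra collision
probability is negligible (< 10^-8 per pair of sets). The hash seed is a
config constant (42), making every run bit-reproducible; matching the hash
values of external sketching tools is a non-goal. Marker identity is
matches / alignment columns on the minimum-edit banded global alignment
(band 5% of the longer length, floor 10, widened by the length
difference) — a fully defined stand-in for the word-filter heuristics of
the usual clustering tool. Sketch k defaults: 28 for exact intersections
(an external k-mer counter's convention), 21 for containment/ANI sketches
(the common MinHash convention); the upstream method does not state the
sketch parameters it screens with, so these are declared defaults.

## The synthetic world

The generator states the world the tests live in, chosen once:

- 4 species as independent random genomes of 100–300 kb (pairwise ANI
  undetectable at k = 21, standing in for < 85% ANI), the first species
  carrying 3 reference strains (substitution mutants at 1% and 2%,
  i.e. ~99% and ~98% Mash-transform ANI), plus 2 absent decoy references.
- 40 marker genes of 1,000 bp per genome, derived from fixed per-family
  ancestors. Inter-species marker divergence is 10% from the ancestor
  (universal single-copy genes sit well below 99% nucleotide identity
  across genera), so different species' markers never share a 99% cluster
  and decoys cannot inherit coverage; within a species, strain markers
  inherit the strain's 1–2% divergence and usually do share clusters.
  1,000 bp is a realistic marker length and keeps the read-edge coverage
  taper (reads must lie fully inside the alignment target) small relative
  to the gene.
- sample organisms are 1% substitution mutants of one reference per
  present species — the "related but not identical to the database"
  regime the method exists for.
- abundances follow a geometric series with ratio 0.7 (log-linear), so at
  20x mean depth the rarest species still sits near 11x.
- reads are 100 bp pairs, insert 300 +/- 30, with 0.5% i.i.d. substitution
  errors; read names carry no truth (origins live in a sidecar table).

What the generator does *not* emulate: quality-correlated or indel error
profiles, GC-coverage bias, repeats and mobile elements, host
contamination, and real phylogenetic structure. A green end-to-end test
therefore establishes the pipeline's bookkeeping and statistical behavior
under its stated assumptions, not performance on real gut metagenomes.

## Degenerate inputs and edge rules

Empty read input or an empty selection ends the run gracefully with an
explicit no-reference-recruited summary and complete (empty) outputs.
Unsketchable sequences (all-N or shorter than k) raise an error at
containment time rather than silently scoring 0. A breadth of exactly 0.90
does not cover a gene; 30/40 families select a genome, 29/40 do not; a
500 bp run is a contig, 499 bp is not; a 2,000 bp longest contig survives
criterion (iv), 1,999 bp does not. Ties everywhere are broken
deterministically (leftmost coordinate, '+' strand, longer genome, smaller
cluster id, alphabetical id), so identical inputs give byte-identical
outputs.

## Known limitations

- Deletions/insertions are *detected* robustly (split-anchor marks) but
  *applied* conservatively: reads spanning an indel near their ends can
  still map ungapped and dilute the indel's majority below 0.6, leaving
  the reference base in place. Substitution polishing does not share this
  limitation.
- The ungapped aligner underestimates identity in the presence of true
  indels; such reads simply stay unassigned until polishing.
- Criterion (i) ("all reads assembled") is evaluated against
  cluster-recruited reads, and reads of discarded assemblies are recycled
  into the pool — both points where the published description is silent
  and this implementation takes the more read-conserving option.
- The config file is JSON rather than YAML (no YAML parser among the
  package's allowed dependencies); the structure is identical.
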