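---
title: "Methods: in-silico screening of insecticide target sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico screening of insecticide target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`tsitescreen`. The package implements a comparative screen of insecticide
target-site genes — ortholog identification, splice-isoform analysis,
RNA-editing detection, resistance-allele genotyping, motif assessment and
distance-based phylogenetics — organised so that every stage can be
validated end-to-end on synthetic genomes with known truth.

## Ortholog assignment

Queries (predicted proteins of the genome under study) are compared to a
reference ortholog panel by optimal local alignment (Smith–Waterman via
`Biostrings::pairwiseAlignment`), scored with BLOSUM62 and affine gap
penalties 11 (open) / 1 (per residue), the scale BLASTp users expect. A hit
is significant when it covers more than 95 % of the query and its E-value
is below 1e-100; both thresholds are exposed in `search_thresholds()`.

E-values follow ungapped Karlin–Altschul statistics,
`E = K * m * n * exp(-lambda * S)`. `lambda` is solved numerically from
`sum_ij p_i p_j exp(lambda * s_ij) = 1` over Robinson–Robinson amino-acid
frequencies (`karlin_lambda()`; 0.3176 for BLOSUM62, matching the published
constant). `K` is shipped as the published ungapped BLOSUM62 value 0.13
rather than computed: the full Karlin–Altschul lattice computation buys no
decision accuracy here, because the acceptance threshold (1e-100) sits many
orders of magnitude away from the E-values of both true orthologs (~1e-150
for a 300-residue match) and chance hits (>1e-3). This is a documented
approximation, not BLAST's gapped statistics.

Whether the published coverage/E-value rule was applied reciprocally is not
something the screen can recover from its description, so
`assign_orthologs()` defaults to reciprocal-best assignment (the stricter,
standard orthology criterion) with `reciprocal = FALSE` available as the
one-way fallback.

Percent identity is computed on global (Needleman–Wunsch) alignments as
100 × identical columns / alignment columns. The companion "divergence"
statistic mimics an alignment-viewer convention whose exact formula is
proprietary; we report 100 × (substitutions + indel events) / ungapped
columns, label it an approximation, and never use it for decisions —
identity is the decision surface. `merge_fragments()` (split gene
predictions) requires exact suffix–prefix identity, as the motivating case
showed a 100 %-identity overlap; a mismatch-tolerant mode is deliberately
not the default. `deletion_span()` counts subject residues opposite gaps in
the query under a global alignment.

## Transcript-to-genome mapping and splice events

The mapper (`map_transcript()`) assumes what the data model guarantees:
transcripts match their locus exactly except for a handful of
substitutions (RNA-editing sites). It therefore uses exact-match
seed-and-extend rather than full spliced-alignment DP:

* the first 20 nt anchor the transcript on either strand (up to the
  mismatch budget);
* extension proceeds until the per-exon mismatch budget (default 2) is
  exhausted;
* at a stall, candidate donors are every `GT` within an 18-nt slide window
  behind the stall point (extension can run a few bases into an intron by
  spending budget, so the window is wider than the budget's expected
  penetration); candidate acceptors are `AG` positions at least
  `min_intron` (default 30 nt) downstream whose following 20 nt continue
  the transcript — the first 3 exactly, the rest within budget;
* the search is depth-first with backtracking, trying leftmost donors and
  shortest introns first, so among equal-scoring chains the
  consensus-satisfying, leftmost-donor chain is returned.

The 30-nt intron minimum treats shorter gaps as deletions, avoiding
spurious GT-AG hits inside tandem repeats. Both strands are tried; a
transcript with no consensus-consistent chain is an error ("unmappable
transcript"), not a silent partial result.

Event classification (`diff_isoforms()`) compares exon chains in
sense-strand coordinates against a designated primary transcript. The
primary defaults to the longest spliced transcript (ties broken
lexicographically) — annotation pipelines imply a "variant X1" ordering
but never define it, so the package uses a reproducible rule and lets the
caller override it (as the demonstration loci do, where the annotated
primary is the shorter form). Alternative-acceptor/donor events carry a
signed shift in nt (positive = exon extension relative to the primary);
`in_frame` is `shift %% 3 == 0`. The peptide added by a single in-frame
event is recovered by translating both isoforms (longest ORF) and taking
the residues inserted in the variant — this is robust to junctions that
fall mid-codon, where translating the inserted nucleotides alone would
give the wrong peptide. Feature tables (`config_table()`) name cassette
exons in genomic order with letter suffixes and emit X/– matrices;
`enumerate_isoforms()` spans the 2^n configuration space in binary-counting
order.

`find_missing_exon()` searches a locus for a (possibly diverged) exon as
nucleotide (match 2 / mismatch −3, gaps 5/2) or as protein against all six
translated frames. The detection floor — alignment covering ≥ 60 % of the
exon and scoring ≥ 25 % of the exon's self-alignment — is deliberately
permissive: the screen's "absent from genome" call should only fire when
even a diverged copy (~80 % identity, which the tests plant) would have
been found.

## RNA-editing calls

Editing evidence is one assembled transcript per isoform, not reads; there
is no coverage or quality model, mirroring a transcriptome-assembly
comparison. `call_editing()` requires length-concordant evidence
(substitutions only), reports every exonic mismatch, classes sense-strand
A>G as `candidate_edit` and everything else as `non-AG-mismatch`
(logged, excluded from the edit list). Sites within 3 nt of a splice
junction are flagged junction-proximal/low-confidence. "A-to-I" is
operationally A>G, per field convention. `classify_known_sites()` labels
cataloged sites `candidate_edit` / `genomically_encoded` (the genome
already carries the edited base — the situation reported for two known
sites of the alpha6 receptor) / `not_detected`; the shipped alpha6 site
file is a template because the external site numbering depends on the
transcript build.

## Resistance-site projection

The catalog keeps each mutation in its source's own reference coordinates
(e.g. positions 1338–4946 in the diamondback-moth ryanodine receptor,
A302S in the fruit-fly RDL) and never renumbers. `project_site()` aligns
reference to query semi-globally (terminal gaps free, Gonnet-250, gap
10/0.2): free terminal gaps are essential so that a query lacking an
alignable N-terminus yields `unalignable` at N-terminal sites (the
phenolamine-receptor T8P/L22S case) instead of a misprojection. States
partition exhaustively: `susceptible` (wild-type residue), `resistant`
(cataloged resistance residue), `divergent` (neither), `unalignable`. A
low-confidence flag fires when identity in the ±20-residue window around
the site drops below 50 %, guarding against paralog misprojection.
Reference/catalog drift (reference residue ≠ cataloged wild type) warns
and proceeds. Mapped positions of catalog sites in the query are reported
via projection only, never asserted from external numbering.

## Motif engine

`parse_pattern()` supports the PROSITE pattern grammar used by pattern
entries: residue letters, `x`, `[sets]`, `{negated sets}`, `(n)`/`(n,m)`
counts, `-` separators, `<`/`>` anchors. Negated sets accept any residue
not listed — so the unknown residue `X` passes `{P}` but fails `[ST]`,
which keeps published motif strings containing `X` matchable. Fixed-width
patterns scan vectorised; variable-width patterns use greedy backtracking.
All overlapping matches are reported (ScanProsite behaviour); a greedy
non-overlap mode sits behind a flag. The shipped PTM catalog carries the
six canonical patterns for the annotated PTM classes (PS00001, PS00004,
PS00005, PS00006, PS00008, PS00009) in a PROSITE-style flat file that
users can replace.

Channel features are evaluated absolutely (DEKA/DEEA, MFL, cys-loop
C-x(13)-C) or relative to user-supplied TM annotations: pore triplets are
searched in the 10 residues immediately N-terminal to TM2 ("immediately
preceding" has no published width; 10 is configurable), reporting
`present`, or `variant` with the observed triplet (e.g. KDR where GEK was
expected), or `not_evaluable` when the annotation is missing. TM segments
are inputs; a Kyte–Doolittle helper (window 19, threshold 1.6) can propose
them but is never auto-trusted.

## Phylogenetics

`progressive_msa()` builds a UPGMA guide tree from pairwise global-
alignment distances and merges profiles with an affine-gap profile–profile
aligner (Rcpp) under the Gonnet-250 matrix, gap 10/0.2. The Gonnet table
ships in its published log-odds units, under which a gap opening of 10
costs roughly four average identities — a scale consistent with those
penalties (a ×10-scaled matrix makes gaps nearly free and riddles
alignments of substitution-only families with spurious gaps). Sequences
are canonically sorted by name first, so the alignment is invariant to
input order. The PAM level (250) is the common default of the alignment
tools this emulates; the matrix file records its source.

Distances: p-distance with pairwise deletion of gap sites (the common
protein default of distance-tree tools), with `-ln(1-p)` Poisson
correction switchable. `neighbor_joining()` is a from-scratch Saitou–Nei
implementation: Q-criterion agglomeration, ties broken by the
lexicographically smallest pair of cluster labels (a cluster is labelled
by its smallest member), negative branch estimates clamped to zero with a
count kept (`attr(tree, "clamped")`), trifurcating root. `ape::nj` serves
as an independent cross-check in the test suite (Robinson–Foulds distance
zero on additive and near-additive matrices), never as the implementation.
Bootstrap supports resample alignment columns with replacement; support is
the percentage of replicate trees containing each internal bipartition of
the full-data tree, reproducible under a fixed seed. The study-scale
default is 1000 replicates; tests and the orchestrated screen use 25–100,
which the package treats as desk-scale analysis sizes.

## The synthetic-data generator

`simulate_screen_data()` emulates the structure the pipeline assumes from
a curated genome + transcriptome pair: multi-exon genes (3–6 exons,
250–450 codons) with GT-AG introns of 40–120 nt on both strands (40 %
minus-strand), cassette exons (probability 0.25, frame-preserving),
alternative donor/acceptor sites (probability 0.25; shifts 12/15 nt, the
frame-preserving magnitudes the motivating gene models show), Poisson(1)
A>G edits per gene planted ≥ 6 nt from junctions and capped at the
mapper's per-exon budget, resistance alleles planted at rate 0.3 at
cataloged codons, reference orthologs diverged 7 % (the ~93 % identity
typical of the beetle-to-beetle ortholog diagonal), channel motifs
embedded with TM annotations, and an 8-taxon protein family diverged along
a known tree at rate 0.05 per edge. Alternative splice sites are planted
with their genomic constraints satisfied exactly: an acceptor extension
ends with the AG that forms the primary acceptor, a donor extension starts
with the GT that forms the primary donor.

One RNG stream per output type (structure, motifs, resistance, sequence
realisation, edits, family) derives from the master seed, so enlarging one
aspect does not perturb the others; output is byte-deterministic under the
seed. What the generator does **not** emulate: realistic codon usage and
base composition (uniform backgrounds), indel divergence between orthologs
(substitutions only), read-level evidence, editing levels, selection.
Passing tests therefore demonstrate algorithmic correctness on the stated
data model — exact exon copies up to isolated substitutions — not
robustness to assembly error, heterozygosity or non-canonical splicing.

Two fixture loci (`alpha3_splice_locus()`, `phcl_splice_locus()`) are
constructed, fully synthetic sequences whose junction geometry reproduces
published splice arithmetic: a 12-nt acceptor extension that adds MSSS
across a phase-2 junction, and a four-feature locus (cassette exons 9a/9b,
a 12-nt donor extension adding VNIN, a 15-nt acceptor extension adding
SCLLQ) with seven observed variants and an isoform space of 16. Only the
geometry and the added peptides match the published gene models; all
flanking sequence is random.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally, 1-based closed only in
  GFF3 and reports; every writer documents the boundary.
* IUPAC ambiguity codes are accepted in DNA input and treated as
  mismatches by all comparators (conservative for edit/mutation calls);
  ambiguous codons translate to `X`.
* NJ Q-criterion ties use a 1e-12 tolerance before the label rule.
* `bootstrap_nj()` saves and restores the caller's RNG state.
* Empty inputs fail loudly (empty FASTA record, empty database, fewer than
  2 sequences to align, fewer than 3 taxa for NJ); an empty transcript set
  in the orchestrated screen leaves splicing/editing tables empty and runs
  the other stages.
* `run_screen()` output is byte-deterministic: no timestamps, fixed column
  orders, checksummed MANIFEST.

## Analysis sizes

The analysis scripts and test suite run at desk scale chosen to exercise
every code path while keeping a full run in minutes on one CPU: 8–40-gene
bundles for stage tests, 300–1000 genes for mapping-recovery rates,
10,000 random sequences for the motif-engine/regex cross-check, 100 seeded
simulations for NJ topology recovery, 25–100 bootstrap replicates in the
orchestrated screen (1000 in the standalone phylogeny script). These are
the package's validation sizes, not limits of the implementation.

## Known limitations

* E-values are ungapped approximations with a constant K; they rank hits
  correctly at the decision scale used but are not BLAST-comparable.
* The mapper targets curated transcript/genome pairs; it is not a spliced
  aligner for noisy reads and will refuse (rather than force) chains that
  violate the splice consensus.
* The divergence statistic is a labelled approximation of a viewer
  convention.
* Real-accession quantities (published identity percentages, protein
  lengths) require the original database records; the package validates
  the machinery on constructions with the same geometry instead, and makes
  no claim about the original sequences.
* Trees are distance-based (NJ); no ML/Bayesian inference, no rate
  heterogeneity.
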