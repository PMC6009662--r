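---
title: "Methods: splice-event classification and NMD target prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-event classification and NMD target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asnmd)
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
parameters matter, and what the synthetic-data tests do and do not show
about real data.

## Coordinates and the transcript model

All internal coordinates are 0-based half-open; GFF3's 1-based inclusive
convention is converted exactly once, in `load_annotation()` /
`write_gff3()`. A `transcript_model` is an exon chain (sorted,
non-overlapping, introns ≥ 1 nt) with an optional CDS whose spliced
length must be a positive multiple of 3; isoforms violating that are kept
with the CDS dropped and a warning, because a mis-annotated CDS should
not cost the gene its event analysis.

## Main-ORF selection

Candidate ORFs are every ATG with an in-frame stop (non-ATG starts are
not considered; candidates containing N are discarded). Selection is
lexicographic — homology score, then protein length, then isoform
expression, then 5′-most start — and the ordering is configurable. The
reference isoform of a gene is the isoform whose selected ORF wins the
same comparison. Homology leads because curated main ORFs are anchored by
protein evidence, not length; when no homology is supplied the criterion
silently yields to length, so the default behaviour on annotation-only
input is "longest ORF".

One subtlety matters for PTC calling: in a frameshifted isoform the
*longest* ORF can start downstream of the splicing change and read
through to the normal stop, masking the PTC entirely. The feature layer
therefore evaluates each alternative isoform's stop position from the ORF
**anchored at the gene's authentic start codon** (the reference ORF's
genomic ATG) whenever that ATG is present in the isoform, falling back to
the lexicographic choice otherwise. This matches how a curator reads such
an isoform: translation starts at the gene's start codon and terminates
where the new frame says it terminates.

## Event decomposition

`diff_isoforms()` compares exon membership base by base over the genomic
intersection of the two isoforms' spans (differences at the transcript
ends are transcription-start/termination variation, not splicing). Each
maximal run of bases exonic in exactly one isoform becomes one event, so
the event intervals tile the symmetric difference of the exonic base sets
exactly and disjointly — the property the test suite checks against an
independent per-base oracle on 1,000 random isoform pairs. A run's type
comes from its flanking junctions: a whole intron of one isoform exonic
in the other is a retained (or spliced) intron; a run sharing one intron
boundary, with the other boundary matched by an intron of the second
isoform, is an alternative donor or acceptor (donor = the intron's
transcript-5′ boundary, assigned strand-aware); a run strictly inside an
intron whose two flanking junctions pair with the intron's boundaries is
an included (or skipped) exon. Runs matching no pattern are typed
retained/spliced by direction, flagged `residual`, and logged rather than
silently classified. Events identical in (gene, type, interval,
junctions) across alternative isoforms are merged into one catalog entry
with a deterministic id.

An **exitron** is a retained intron strictly inside the reference CDS
whose length is a multiple of 3 and which introduces no stop codon when
spliced into the CDS in frame. The frame-preservation requirement is an
interpretation: a frameshifting retention almost surely creates a
downstream PTC, so "does not introduce a PTC" effectively implies 3n. The
implementation verifies the stronger property directly — the modified CDS
translates with its only stop at the reference stop position.

## The 50-nt rule and PTC status

`call_orf_and_ptc()` measures, for every junction, the distance from the
first base after the stop codon; the transcript satisfies the rule when
some junction lies **≥ 50 nt** downstream (boundary tested exactly: 50 nt
→ true, 49 nt → false). `is_ptc` is the union of that rule and "stop
strictly 5′ of the gene's reference stop", because an early stop in the
last exon is still premature to a curator even if it escapes the
junction rule; both components are reported separately so either
definition can be used downstream.

uORFs are ATGs in the 5′ leader with an in-frame stop (minimum two codons
including the stop); the stop may lie past the main start, flagged
`overlaps_main_start`. Codon frequencies are tallied over all uORF codons
— the classifier features expose ATC, AAC and GGT, the codons whose
under-representation distinguishes NMD targets.

## Feature matrix

Features come in blocks: one-hot AS type; structural (PTC call, 3′ UTR
junction count and distance, UTR lengths, exon/intron architecture,
event-to-TSS/CDS distances, uORF profile); composition (k ∈ {1,2,3}
k-mer frequencies over the spliced transcript, the 3′ UTR and the event
interval ± 50 nt — k is not fixed by any external constraint, and
{1,2,3} keeps the block at 252 informative, estimable columns);
motif counts (forward strand only; double-strand counting is a
configuration away but transcripts are single-stranded objects);
methylation (coverage-weighted mean mC in ±25 nt windows at donor,
acceptor and across the event, each with a missingness flag — "at splice
sites" admits many windows, ±25 nt spans the splice-site consensus
region); and, in EXP mode only, expression (log2FC, FDR, CPM per
contrast). NOEXP columns are a strict subset of EXP columns. Absent
values become 0 after the join; distance-type anchors are expressed as
inter-base boundaries so every feature is invariant under a
strand-flipped mirror of the locus (a tested property).

Filtering drops near-zero-variance columns (frequency ratio > 95/5 and
unique fraction < 10%) and then, from each pair with |Pearson r| > 0.75,
the member with the larger mean absolute correlation (ties by column
order), until the maximum pairwise |r| is at or below the cutoff; the
procedure is idempotent. The collinear PTC family
(`is_ptc`, `rule_50nt`, `has_3utr_junction`, `n_3utr_spliced_introns`,
`stop_upstream_of_reference`) typically survives as a single
representative — importance rankings should be read per cluster, not per
original column.

## Differential testing

With two replicates per genotype, a per-event exact conditional test is
more robust than a fitted GLM. Counts are scaled to the geometric-mean
library size; conditioned on the overall total *s*, the group-A total is
compared against its distribution under a negative binomial with common
mean *s*/n and a **pooled method-of-moments dispersion**
φ̂ = Σ(v − m) / Σ(m² − v/n) over all event × group cells (the corrected
denominator unbiases E[m²]; φ̂ is clamped at 0). The two-sided p-value
sums all outcomes at most as likely as the observed one; at φ = 0 the
test reduces exactly to the conditional binomial test, which the suite
verifies by full enumeration. Null calibration is checked by simulation:
10,000 null events at mean 50, dispersion 0.1, 2 vs 2 reject at
α = 0.05 at a rate inside 0.05 ± 0.01. BH is used for FDR ("FDR
corrected" fixes the error criterion but not the procedure; BH is the
field default). An event is NMD-responsive when FDR < 0.01 with the same
sign in both mutant contrasts — the two-mutant concordance is what
separates direct targets from line-specific secondary changes, and the
planted "secondary" class in the generator exists precisely to verify
that it is rejected.

CPM is the only between-library normalization; TMM-style composition
correction is out of scope. Consequently the simulator assigns equal
sequencing depth as the library size (the event table is a small window
on a transcriptome, so its column sums are not depth estimates).

Gene-level consensus follows the 2-of-3 / both-mutants rule at adjusted
*P* < 0.05, with sign conflicts across mutants resolved to `not_de`; the
16-case truth table is enumerated in the tests. Enrichment of a gene set
is an upper-tail hypergeometric probability.

## Read counting

A read supports the alternative side of an event when its gapped
alignment spans an alt-unique diagnostic junction, or — for retained
introns — aligns contiguously across an intron boundary. Reads matching
no event, or more than one, stay unassigned; counts are integers and no
read is counted twice (count conservation is asserted per library).
Counting the alternative side, rather than both sides, reflects what the
differential layer tests: the abundance of the isoform that responds to
NMD inhibition.

## The ensemble

The roster holds twelve deliberately heterogeneous base learners: ridge /
elastic-net / lasso logistic regression, two random-forest
implementations, gradient-boosted trees, CART, linear and RBF SVMs,
Gaussian naive Bayes, 5-NN and a shallow neural network. It emulates a
large automated classifier collection at a size that keeps repeated CV
tractable; the contract is the accuracy-filtered voting ensemble, not
parity with any particular collection. Each learner is evaluated by mean
accuracy over 3 × 5 stratified CV resamples (stratification is necessary
at n ≈ 100 with class imbalance), retained at accuracy ≥ 0.95 (EXP) /
≥ 0.75 (NOEXP), and refit on the full training set. All preprocessing
(per-learner standardization) is computed inside the training fold, so no
fold statistics leak into evaluation. Prediction is a strict majority of
retained-model votes with exact ties resolved to non-NMD — the
false-positive-averse choice consistent with conservative curation.
Importances are normalized to [0, 1] within each model before medians are
taken across retained models; each feature's sign (positive/negative
predictor) comes from its marginal direction among predicted-NMD vs
predicted-non-NMD events.

Seeds flow from one configuration value into fold assignment and every
stochastic learner, so a fixed seed reproduces the retained set, votes
and report bit for bit.

## The synthetic generator

`generate_fixture()` is first-class, tested code, not a test fixture. It
lays each gene out in transcript orientation with every exon–exon
junction codon-aligned, which lets it plant frame-preserving changes from
stop-free codons and premature stops exactly at junctions; minus-strand
genes are produced by reverse-complementing the finished contig. Planted
NMD events create a stop with a junction ≥ 50 nt downstream; planted
non-NMD retained introns are exitrons (a frameshifting PTC+ retention
would have an ambiguous golden label, so the generator does not produce
one). Every planted isoform is verified by a small string-level codon
scanner — independent of the package's Biostrings-based ORF caller — and
the gene is re-drawn on the rare mismatch, so golden labels are honest
without being circular. Default conditions mirror the emulated study: two
replicates for WT and each of two mutant lines, NB counts at dispersion
0.1, log-normal baseline means (meanlog = log 100, sdlog = 0.6 — a
typical moderately-expressed event; the value is the package's choice, as
no external value exists), NMD log2 fold changes uniform on (1, 3) in
both mutants, 30% NMD events, 10% secondary events, and an event-type mix
spread across all six types so each classifier path is exercised.

What the generator does *not* emulate: alignment and mapping artifacts,
positional read biases, overlapping genes, more than one event per gene
(except where tests build them by hand), composition shifts between
libraries, and any correlation structure among features beyond what the
planted biology induces. Passing tests therefore demonstrate correctness
of the algorithms under the stated statistical model, not performance on
real libraries; on real data the ensemble's accuracy depends on the
curation quality of the training labels, exactly as in the emulated
study. Default test problem sizes (a 200-gene fixture for label
recovery, 10,000 events for calibration, 1,000 isoform pairs for the
classification oracle) are the package's choices balancing statistical
resolution against a short default test run.

## Numerical and degenerate-input choices

Zero library sizes, negative counts, p-values outside [0, 1], empty
universes, all-columns-removed filters and schema mismatches raise
immediate errors naming the offence. Sequences shorter than k yield
all-zero composition blocks (logged); empty leaders yield zero uORFs;
ties in ORF selection resolve to the 5′-most start; the discrete
two-sided p-value includes outcomes within a 1 + 1e-10 relative
tolerance of the observed probability to absorb floating-point noise.
log2 fold changes carry a 0.5-count prior so zero counts stay finite.

## Known limitations

Event pairing is all-vs-one-reference; mutually exclusive exons are not a
type; complex nested differences decompose into flagged residual events
rather than compound types. Dispersion is a single common value (a
tagwise shrinkage estimator could be plugged in). The NB test's
conditioning is exact only under the common-dispersion model. Domain
disruption analysis (BLAST/PFAM) and GO-style enrichment beyond the plain
hypergeometric test are outside the package's scope.
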