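---
title: "Methods: the prioritization funnel, spectra, and signature refitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the prioritization funnel, spectra, and signature refitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticfunnel)
```

# Scope and assumptions

`somaticfunnel` starts where variant calling ends: its inputs are per-sample
tables of *annotated* somatic mutations (coordinates, alleles, gene symbol,
HGVS cDNA/protein notation, dbSNP status, optional trinucleotide context),
plus plain-text gene lists and a signature catalog. It performs no
alignment, no variant calling, no transcript-model annotation, and no
database lookups — dbSNP membership, for instance, is simply the presence of
a non-empty rs identifier in the input. Coordinates are 1-based inclusive
(VCF convention) everywhere. Gene symbols are trimmed, upper-cased, and
matched case-insensitively, since the gene lists a study compares typically
come from several databases with inconsistent casing.

The package addresses the two-cohort design: a case group and a control
group with the same tumor type but different clinical background, where the
question is which recurrently mutated driver genes are *specific* to the
case group and *not already reported* for the disease.

# The funnel

`run_funnel()` applies a fixed stage order; configuration can change
thresholds but not reorder stages, because the stage order is part of the
method's definition:

1. **Known polymorphisms** (`filter_known_polymorphisms()`). Default: every
   record with a dbSNP identifier is removed. The alternative policy —
   remove only dbSNP records with population AF at or below
   `af_max_known` — exists because the two natural readings of
   "known variants with low allele frequency were excluded" genuinely
   differ: one removes all catalogued variants, the other keeps the common
   ones. The default is the stricter, more conventional reading (a
   catalogued germline variant is not a somatic candidate). Under the AF
   policy, records with *unknown* AF are kept, since the criterion cannot be
   established for them.
2. **Transcript collapsing** (`collapse_transcripts()`). One genomic change
   annotated against several transcripts is one mutation. The key is
   (`sample_id`, `chrom`, `pos`, `ref`, `alt`) — deliberately stricter than
   "same genomic location", because two different substitutions at one
   position are distinct mutations. The representative is the
   lexicographically lowest transcript, making the operation deterministic
   and idempotent; conflicting gene symbols within a key are all retained
   (`;`-joined) with a warning rather than silently dropped.
3. **Driver retention** (`retain_driver_genes()`): keep records whose gene
   is in the supplied driver catalog.
4. **Reported-gene exclusion** (`exclude_reported_genes()`): remove genes in
   the union of the supplied previously-reported lists. Because stages 3–5
   are all gene-level set operations, excluding before or after the
   case/control overlap yields the same final set; the test suite asserts
   this on random inputs.
5. **Case-unique overlap** (`group_unique_genes()`): case genes minus
   control genes, both taken after stages 1–4.
6. **Recurrence** (`recurrence_filter()`): keep genes mutated in at least
   `recurrence_min` (default 2) distinct units. The unit defaults to
   `SAMPLE`; a `PATIENT` mode counts `patient_id`s instead, which matters
   when one patient contributes several samples — in the motivating study
   two samples are one patient, and one candidate gene (CARD11) is recurrent
   only across that pair, so the study's own list implies sample-level
   counting. Both modes are provided and tested.
7. **Amino-acid change** (`nonsynonymous_gene_filter()`): drop genes with no
   protein-affecting mutation. Splice-site, frameshift, indel (including
   UTR indels), nonsense, nonstop and missense classes all count as
   protein-affecting; only `SYNONYMOUS` and `OTHER` do not. UTR indels are
   deliberately retained as protein-affecting: the motivating study's final
   list keeps a gene whose only printed mutation is a 3'UTR single-base
   deletion, which fixes this design choice.

**Unclassified records.** A record may legitimately carry no classifiable
annotation (no HGVS, length-preserving alleles). Such records keep an `NA`
consequence, and the gene-level filter treats them as *potentially*
protein-affecting: a gene is dropped only when it has classified mutations
and none changes the protein. Absence of annotation is not evidence of a
silent mutation; the alternative (treating unannotated as silent) would make
the funnel's outcome depend on annotation completeness rather than biology.

# Consequence classification

`classify_consequence()` is a total, deterministic priority cascade:

1. HGVS intron offsets −1/−2 → splice acceptor; +1/+2 → splice donor. This
   is the canonical-dinucleotide rule; no splice-strength model is scored.
   `p.?` alone never triggers a splice call — published tables use `p.?`
   for both splice and UTR events, so the cDNA offset decides.
2. Allele (or HGVS edit) length differences: exactly 1 bp in coding
   sequence → frameshift; longer, UTR-located, or intronic → indel.
   Length-preserving multi-base substitutions (delins) are indels.
3. Protein substitution: same residue → synonymous, else missense.
4. Stop gain → nonsense; 5. stop loss → nonstop.
6. An annotated "no protein change" (`-`) on a coding substitution →
   synonymous.
7. Otherwise `OTHER`, with a warning when the record carried no usable
   information at all (never an error — one malformed record must not kill
   a cohort analysis).

A precomputed `consequence` column wins over re-derivation unless
`classify_variants(reclassify = TRUE)`, because upstream annotators may
know transcript context this package does not.

The HGVS parsers accept the notational looseness of published tables
(spaces around `>` and `+`, three-letter residue codes, `p.(...)`).

# Spectra

Six-class spectra (`sample_spectrum()`, `group_spectrum_summary()`) count
single-base substitutions only, collapsed to pyrimidine reference. Indels
are excluded from spectra by definition of the class keys, even though
category accounting (`category_counts()`) tabulates 1-bp length differences
as "frameshift" inside its substitution block, mirroring the two-level
layout used in exome summary tables. The two cohort-summary conventions are
both provided because they answer different questions: `MEAN_OF_SAMPLES`
weighs each sample equally (robust to one hypermutated sample),
`POOLED` weighs each mutation equally; they agree exactly when per-sample
totals are equal, and the tests assert that identity. Frequencies are kept
as fractions; percent formatting is a rendering concern.

Samples with zero substitutions get an all-zero spectrum flagged with an
`empty` attribute rather than `NaN` frequencies, and are skipped when
averaging sample frequency vectors.

# SBS96 and signature refitting

`build_sbs96_matrix()` assigns each substitution-with-context to one of the
96 channels, ordered by class, then 5' flank, then 3' flank, alphabetically
(the COSMIC catalog order). Purine-reference records are reverse-
complemented — context and alleles together — and a record whose context
middle base contradicts its reference allele after strand normalization is
rejected with a warning and counted in an attribute; silent drops would bias
downstream exposures invisibly.

Exposures are estimated by **refitting**, not extraction: weights `w ≥ 0`
minimize `‖v − P w‖₂` for the catalog matrix `P` (Lawson–Hanson active-set
non-negative least squares, implemented in the package and cross-checked in
the tests against an independent solver and an exhaustive lattice search).
De-novo NMF signature extraction is out of scope: with a handful of samples,
attribution against a known catalog is the defensible analysis, and it is
what published percentage breakdowns correspond to. Counts — not
frequencies — are fit, so a sample with more mutations influences a pooled
fit proportionally; percentages are shares of fitted weights, and the
reconstruction cosine similarity is reported as the fit diagnostic.
`prune_below` (default 0, i.e. off) removes trace signatures below a percent
threshold and refits once; no further model selection is emulated.

Numerical notes: the NNLS tolerance scales with `‖PᵀV‖` and machine epsilon;
the active-set iteration is capped at 30·K steps; degenerate inner steps
(zero step length) drop the offending variable rather than loop. An all-zero
count vector is an error, not a zero fit.

# CNV comparison

Events are matched by exact (`chrom`, `start`) key — start-site matching is
the stated method being implemented, and interval-overlap logic would
change the statistic, not refine it. "Found in both groups" is interpreted
as both groups' *recurrent* key sets (matching the order of operations in
the source procedure: select recurrent per group, then remove shared);
`against = "all_control"` compares to every control event instead, for the
stricter reading.

# The synthetic generator

`generate_cohort()` emulates the study conditions the analysis assumes:
7 case and 5 control samples by default, Poisson-distributed per-sample
mutation counts with mean 2000 (the order of magnitude of per-sample somatic
burden in the motivating cohorts), signature mixtures of 0.84/0.10/0.06
(case) and 0.81/0.11/0.08 (control) over the three packaged synthetic
signatures — a dominant aristolochic-acid-like T>A process plus a flat
clock-like and a CpG deamination component — and a dbSNP tagging fraction of
0.2 (catalogued germline variants are roughly a fifth of raw annotated calls
in such data). The packaged signatures are synthetic, separable stand-ins
(pairwise cosine < 0.5), not COSMIC entries; real catalogs are read with
`read_signature_catalog()`.

Planted driver mutations are placed on per-gene disjoint coordinate ranges
so transcript collapsing can never merge two distinct plantings, and planted
records are classified with the package's own classifier while the
manifest's expected final set is derived directly from the configuration —
so the planted-truth recovery tests close the loop between generator and
funnel through two independent routes.

What the generator does *not* emulate: mutational hotspots, gene length and
trinucleotide-abundance biases, subclonal allele fractions, sequencing
artifacts, and annotation errors. Passing the recovery tests therefore shows
the pipeline's logic is correct under its stated assumptions, not that those
assumptions hold in any particular real cohort.

# Problem sizes and determinism

The test suite runs at deliberately small scale: 200 random cohorts of ≤ 30
records for the brute-force funnel equivalence, 100 random generator
configurations for planted-truth recovery, 20 seeds at 2000
mutations/sample for dominant-signature recovery (±5 percentage points),
and 1000 random substitutions for the spectrum invariants. These sizes give
stable verdicts for set-level and percentage-level assertions while keeping
the whole suite under a couple of minutes. All randomness flows through
explicit seeds; `run_funnel()` and `run_all()` are fully deterministic given
their inputs, and reruns produce byte-identical report bundles.

# Known limitations

* Consequence classification trusts the input HGVS; there is no
  reference-genome recomputation, so inconsistent annotation propagates.
* The splice rule is positional (±2); non-canonical splice-affecting
  variants classify as missense/synonymous/other according to their protein
  notation.
* Signature refitting has no exome/genome trinucleotide-abundance
  renormalization and handles SBS signatures only (no doublet or indel
  signatures).
* CNV matching by exact start coordinate will split events whose callers
  disagree by a few bases; that sensitivity is inherent to the method
  implemented.
* Cohort-scale results from the motivating study (total mutation counts,
  funnel stage totals, reported signature percentages) depend on raw data
  that is not publicly deposited; the package validates against the
  printed per-mutation table and against synthetic ground truth instead.
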