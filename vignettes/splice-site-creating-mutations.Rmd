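---
title: "Finding and interpreting splice-site-creating mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and interpreting splice-site-creating mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological problem

Nearly all introns begin with `GT` and end with `AG`. A single-nucleotide
variant that *completes* one of these dinucleotides close to an annotated
exon–intron boundary can out-compete the annotated site: the spliceosome
adopts the novel boundary, and the exon is either **extended** into the
intron (novel site on the intronic side) or **shrunken** (novel site on the
exonic side). The coding interpretation of such variants is misleading —
many are annotated synonymous or intronic — yet the transcript-level effect
can be as severe as any nonsense allele: a premature termination codon
(PTC), a frameshift, degradation by nonsense-mediated decay (NMD), or an
in-frame deletion that guts a protein domain.

`splicegain` implements the complete reasoning chain for these
splice-site-creating mutations (SCMs): discovery from a VCF against a
genome + GTF, novel-junction geometry, transcript rebuilding and
consequence classification, junction-read validation, positional spectrum
summaries, and a family-cohort screen for rare recessive candidates.
Because the real inputs of such studies (population variant databases,
controlled-access RNA-seq and exome cohorts) cannot be shipped, the package
also contains a first-class synthetic-data generator with a full
ground-truth registry, so every stage of the pipeline is testable end to
end.

## The discovery cascade

`run_filter_cascade()` applies six stages in order, recording per-stage
survivor counts in a filter trace (`tidy()` on the result):

| stage | rule | default |
|---|---|---|
| gene body | SNV within the representative isoform of a panel gene | panel = all genes |
| region | exonic, or intronic within `intron_window` nt of a boundary | 50 nt |
| creation | ALT completes GT or AG that REF did not, strand-resolved | — |
| strength | novel-site window score ≥ `min_strength` (log2-odds) | 0 |
| allele frequency | AF ≤ `max_af`; unknown AF passes and is tallied | 0.01 |
| splice gain | delta score ≥ `min_delta` | 0.80 |

Notes on the individual rules:

* **Representative isoform.** One isoform per gene, the one with the
  greatest *summed exon length* (mature-transcript length, not genomic
  span); ties break to the lexicographically smallest transcript id so the
  choice is deterministic. Genes with only non-coding isoforms are
  retained; CDS-dependent classifications report `not_in_CDS`/`ncRNA` for
  them.
* **The 50-bp intronic window** reflects the reach of exome capture around
  exons: beyond it, neither the capture designs that produce cohort VCFs
  nor the splice predictors being consumed are reliable, so deep-intronic
  sites are out of scope by design.
* **Both overlapping dinucleotides** of an SNV are scanned: the selection
  rule is "creates GT or AG", with no restriction on whether the SNV forms
  the first or second base. Candidates coinciding with the transcript's own
  annotated splice dinucleotides are excluded — those disrupt or recreate an
  existing site rather than creating a novel one. A variant inside two
  genes is evaluated independently per gene.
* **Unknown allele frequency passes** the AF stage (with a warning and a
  counter): a variant absent from the population database is rare by
  assumption, and cohort-only variants must not be discarded.
* **Delta-score semantics.** Only the *gain* scores (`DS_AG`, `DS_DG`) of a
  SpliceAI-dialect annotation are thresholded, taking the maximum over gene
  entries. Loss scores describe disruption of annotated sites, which is a
  separate question handled by the benchmark-set construction
  (`build_known_scm_set()`), not by the discovery threshold.

## Splice-site strength

The strength stage scores the **novel boundary's** sequence window: donors a
9-mer (3 exonic + 6 intronic bases, created GT at positions 4–5), acceptors
a 23-mer (20 intronic + 3 exonic bases, created AG at positions 19–20),
with the ALT allele substituted and the sequence strand-resolved. Anchoring
on the novel (not the annotated) geometry is deliberate: it is the novel
site whose strength decides whether it can function.

The default backend (`train_pwm()`) is a position-weight matrix trained on
the annotated splice sites of the supplied annotation itself: per-position
base probabilities with pseudocount 1, scored as
`sum_i log2(p[b_i, i] / q[b_i])` against the training-set base composition
`q`. This is deterministic for fixed input and needs no external data; a
score of 0 means "no better than background", which makes the default
threshold `min_strength = 0` a deliberately permissive pre-filter — false
positives surviving it are removed by the delta-score stage. A
`maxent_tables` backend (`load_maxent_tables()`) accepts externally supplied
maximum-entropy splice models in a documented plain-text layout (submodels
as position subsets with k-mer score tables, combined additively in log
space with signs), degenerating to a plain lookup table for a single
full-window submodel.

## Junction geometry and consequence

`derive_novel_junction()` turns an accepted candidate into geometry: a
created donor ends its exon immediately before the GT, a created acceptor
begins its exon immediately after the AG; `offset_nt` is the distance
between novel and annotated boundary in transcription orientation, and the
event is an extension or shrinkage by side. The genomic intervals of both
the novel and the annotated intron are reported, which is what junction-read
counting needs.

`rebuild_transcript()` resizes the affected exon, applies the SNV to the
genome, splices, and re-threads the CDS from the annotated start codon.
`classify_ptc()` then translates from that start and scans for the first
stop codon; a stop ending earlier than the annotated stop is a PTC.
Categories partition four ways:

* `PTC_in_novel_exon` — the stop codon lies inside the altered exon. This
  is checked positionally, not via frame: an extension under frameshift
  whose first stop physically falls in the extended exon is still
  "in the novel exon" (the frame flag is recorded separately). This is the
  one place where the published category naming is ambiguous for
  frameshifting extensions; the positional rule is a consistent reading and
  is applied uniformly.
* `PTC_frameshift` — any other PTC.
* `no_PTC` — translation reaches the annotated stop; for frame-preserving
  events `aa_deleted`/`aa_inserted` are `offset_nt / 3`.
* `not_in_CDS` — the alteration does not touch the coding sequence.

Alterations that remove the start (or stop) codon are reported as a
`status` of `start_lost`/`stop_lost` with no category: they are real but
rare geometries that the four-way partition was never meant to describe,
and folding them into a PTC class would overstate what is known.

**NMD** is predicted by the classical 50-nt rule: the PTC must start at
least 50 nt upstream of the final exon–exon junction of the *altered*
transcript. The rule is an approximation (NMD efficiency varies by tissue
and transcript), but it is the standard desk criterion and the only one the
available inputs support. `pathogenic_potential()` flags calls that
introduce a PTC or overlap an annotated protein domain
(`domain_overlap()`, hmmscan-style tables pre-filtered at E ≤ 0.001, one
shared residue suffices).

## Junction-read validation

`count_junction_reads()` accepts either a junction count table (exact
intron-interval match; STAR `SJ.out.tab`-like TSV columns) or SAM/BAM
alignments, counting split reads whose N-gap matches the intron exactly
with at least `min_overhang` (default 6) aligned bases on both sides.
Junction equality is exact by design: validation presumes reads were mapped
to a personalised reference (`apply_variants_to_reference()`), after which
novel junctions align precisely.

`compute_jaf()` is the exact ratio `J_n / (J_n + J_a)`; it errors rather
than returning 0 when no reads exist, because "no evidence" and "novel
junction unused" are different findings. The expression rule
(`expression_check()`) reads "at least five junction reads covering either
the novel or the annotated junction" literally as `J_n >= 5 | J_a >= 5`; a
combined-sum variant is available by flag. `compare_expression()` flags a
carrier strictly below the non-carrier median, with no significance test —
one carrier per locus cannot support one.

Percentages (`compute_validation_metrics()`, `compute_added_fraction()`)
are rounded half-away-from-zero to one decimal. Note one display
consequence: 40/53 = 75.47% prints as 75.5 under this rule; a truncating
display would print 75.4. The underlying counts are always reported
alongside.

## The cohort screen

`screen_cohort()` keeps delta-accepted, consequence-annotated calls that
lie in panel genes, have pathogenic potential, have AF ≤ 0.01 or unknown,
and are never homozygous in unaffected samples (hemizygous genotypes code
as homozygous, so X-linked calls in males are screened by the same rule).
Zygosity counts are tabulated separately for affected and unaffected
carriers; no segregation in *all* affected relatives is enforced — counts
are reported and the judgement left to the analyst.
`detect_compound_het()` pairs two or more heterozygous hits in one gene in
an affected sample and infers phase from relatives: a relative carrying
exactly one variant of the pair shows the pair can separate, i.e. in
trans; otherwise phase is unknown.

Two AF conventions coexist deliberately: discovery retains AF ≤ 0.01 while
the screen *excludes* AF > 0.01 — both thresholds are configurable and the
defaults follow the respective conventions of the two analysis contexts.

## The synthetic-data generator

`generate_genome()` emulates the structural facts the pipeline depends on:
20 genes (default), one per contig, random strands, 4–8 exons, introns
200–2000 nt that always begin `GT` (with a consensus-like donor hexamer)
and end `AG` behind an 18-nt polypyrimidine tract, and a complete,
internally stop-free CDS whose start/stop are confined to the terminal
exons. `plant_scms()` writes variant loci into that reference: each true
call gets a consensus-like context (so the self-trained PWM scores it
positive — mimicking the fact that functional created sites resemble
annotated ones), a guaranteed non-dinucleotide pre-mutation pair, and an
exact geometry at the planned offset; exonic rewrites are re-verified to
keep the reference CDS stop-free. Negatives come in four classes — deep
intronic, wrong dinucleotide, common allele (AF 0.05), low delta (0.3) —
each designed to die at exactly one cascade stage, which makes the
trace itself an assertion. The default plan plants 100 true calls
(including the canonical 11-nt acceptor extension, 41-nt donor extension
with an in-frame stop, 35-nt frameshifting shrinkage and 51-nt clean
shrinkage deleting 17 residues) and 400 negatives.

The truth registry records expected geometry and consequence *computed by
string surgery at planting time*, a code path independent of the discovery
machinery, so recovering the registry is a genuine round-trip. What the
generator does **not** emulate: sequencing error, alignment ambiguity,
realistic allele-frequency spectra, alternative isoforms, non-canonical
(GC/U12) introns, and splice-regulatory sequence beyond the core motifs.
Passing tests therefore demonstrate correctness of the pipeline's logic,
not calibration of the thresholds on real genomes.

`simulate_junction_evidence()` draws carrier novel-junction reads
`Binomial(depth, JAF)` per locus; `generate_cohort()` builds families
around planted causal calls: a recessive family (three affected
homozygotes, one unaffected heterozygote), a compound-het family with a
phase-informative sibling, and a decoy homozygous in an unaffected member.

## Numerical and interface choices

* **Coordinates** are 1-based inclusive everywhere, matching VCF/GTF and
  the Bioconductor interval stack; offsets are reported in transcription
  orientation. A 0-based half-open internal layer was considered and
  rejected: in R it would add conversions at every boundary and align with
  nothing.
* **Determinism**: all generators take seeds and use isolated RNG scopes;
  identical seeds give byte-identical FASTA/GTF/VCF.
* **Degenerate inputs** error early and specifically: indels, ref
  mismatches, position collisions, zero-read JAF, empty non-carrier sets,
  genotypes for unscreened variants.
* **Problem sizes in the test-suite**: the full fixture (20 genes, 500
  variants) is built once per run and shared; the brute-force
  splice-translate oracle checks 500 random junction geometries against an
  independent seqinr-based reimplementation; positional-region
  classification is cross-checked against a linear scan over 2000 random
  positions. These sizes give exhaustive coverage of the geometry space at
  a few minutes of runtime.

## Known limitations

Only SNVs are handled (indels change boundary arithmetic and are rejected
at parse time); only canonical GT/AG creation is considered — variants that
strengthen pre-existing cryptic sites or create splicing-regulatory
elements are invisible to this method; deep-intronic discovery (> 50 bp) is
excluded by design; the delta score is consumed, not computed, so the
pipeline's recall is bounded by the upstream annotator's; and NMD
prediction is a positional rule, not a quantitative model.
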