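---
title: "smorfreg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smorfreg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ribosome profiling (Ribo-Seq) sequences ribosome-protected mRNA
fragments; actively translated regions show two signatures: enrichment
of inferred P-sites at one of the three codon frame positions (3-nt
periodicity) and reasonably uniform coverage along the reading frame.
smorfreg is a pipeline for discovering unannotated small open reading
frames (smORFs, here ≤ 150 codons) from such data: it enumerates
candidate ORFs on an assembled transcriptome, scores translation per
sample, filters for novelty against an annotated reference and a known
proteome, rescues cross-sample presence by raw footprint counts,
classifies genomic context, tests for stimulus-regulated expression
with a negative-binomial Wald test, and tiers evolutionary conservation
by translated homology search against a panel of mammalian genomes.
Every stage can be exercised offline against seeded synthetic data with
full ground truth.

## Coordinates and data model

Internally every interval is 0-based half-open; GTF input/output and
printed genomic spans are 1-based inclusive and converted at the
boundary.  A transcript is an ordered chain of disjoint exons with a
strand, an optional CDS (from which 5'/3' UTR intervals are derived),
and a biotype.  Published smORF loci are printed as genomic spans; a
span of 189 nt corresponds to a 63-aa microprotein when the span covers
the coding codons only, or 62 aa if it includes the stop codon.  Because
printed spans rarely state which convention they use, `span_aa_length()`
reports both readings.

P-sites are assigned at 5' end + 12 nt for read lengths 26–32 (the
common convention; other lengths are skipped by default).  A P-site
falling inside several overlapping same-strand transcripts increments
each transcript's track: scoring is per-ORF, so duplication across
transcripts does not distort any single ORF's statistic.

## The calling statistic

For an ORF spanning transcript positions `[s, e)` (stop codon included)
with per-position P-site counts `v`:

* `f` — fraction of counts at positions congruent to `s` mod 3
  (periodicity);
* `pme` — normalized entropy of the in-frame per-codon counts over the
  `L - 1` coding codons (stop excluded):
  `pme = (-Σ pᵢ log pᵢ) / log(L - 1)`, defined as 0 with no in-frame
  counts and as 1 with a single coding codon;
* `score = f · pme`, in `[0, 1]`.

An ORF is called when `score ≥ 0.7` **and** the ORF holds at least 10
P-sites.  Both thresholds are configurable; 0.7 is the default because
the source methodology states it as the filter, while one figure legend
quotes 0.8 — we expose both rather than resolve the discrepancy
silently.  Whether the upstream caller's coverage component counts
off-frame reads per codon is not documented anywhere we could verify;
`pme` here uses in-frame counts only, which makes the two factors of the
product measure orthogonal properties (frame preference vs. positional
uniformity).  The statistic is deliberately transparent — a replacement
for an opaque classifier score, with the same threshold semantics.

Candidate ORFs run from the 5'-most ATG of each stop-delimited region to
its in-frame stop, in all three frames, with 6–151 codons
(150 aa + stop) by default; ATG-only starts (near-cognate starts are out
of scope); peptides containing X (from N-containing codons) are
excluded.

## Novelty

A candidate is rejected when (in order) it overlaps an annotated CDS
exon on the same strand by ≥ 1 nt; or its peptide reaches E ≤ 1e-3
against the known proteome under the same scoring system as the
conservation search; or it violates the codon-length bounds.  The
protein screen aligns against the `*`-joined proteome in one pass — the
stop penalty prevents alignments from crossing protein boundaries, so
the best score equals the best per-protein score.

## Cross-sample rescue

Per-sample periodicity calling has false negatives: coverage can be
excellent in a sample whose periodicity narrowly fails the threshold.
Every smORF called in ≥ 1 sample is therefore re-counted in all samples
(all frames — coverage, not periodicity) and declared present wherever
its raw count reaches a threshold (default 10; an "extremely relaxed"
alternative of 2 is exposed for exploratory reporting).  Calls are never
revoked.  One ambiguity in the source text — "a count threshold of ≤ 10"
versus "a count threshold of ten" — is resolved as `counts ≥ 10`, the
only reading under which the step rescues anything.  Counting windows
are transcript-space; genome-space counting is not implemented (the
upstream tool's choice is undocumented).

## Context classification

Precedence on same-strand overlap: 5'UTR ⇒ uORF, else 3'UTR ⇒ dORF,
else non-coding-biotype exon ⇒ ncRNA; else any gene-span overlap
(either strand) ⇒ intragenic; else intergenic with the signed distance
to the nearest gene (ties toward the lower start coordinate).  The
source reports a single label per smORF with percentages summing to
~100% but never states a precedence; this ordering matches the reported
dominance of 5'UTR smORFs and is applied deterministically.

## Differential expression

A deliberately transparent DESeq2-style two-group analysis:
median-of-ratios size factors; per-feature NB GLM
`count ~ NB(s_j · μ · 2^(x_j β), α)` fitted by IRLS with a log link and
offset `log s_j`; Wald `z = β/SE(β)` from the information matrix;
two-sided normal p; BH across tested features; significance at
`|log2FC| ≥ 1` and `FDR < 0.05` (a strict-inequality flag covers the
"> 1" reading that some legends use).  No LFC shrinkage, no outlier
filtering, no independent filtering, no multi-factor designs.

**Dispersion.**  The base estimator is feature-wise method of moments on
normalized counts, floored at 1e-8.  Used as a plug-in at n = 3 + 3 it
has ~4 degrees of freedom, which makes the Wald null t₄-like rather than
normal (measured type-I error ≈ 0.12 at nominal 0.05).  The default
therefore moderates the feature-wise estimates toward a robust
parametric mean–dispersion trend `α(μ) = a₁ + a₀/μ` via a normal-normal
posterior mean in log space, with sampling variance `trigamma((m-p)/2)`
and prior variance equal to the MAD-based excess spread of the estimates
around the trend.  Unlike DESeq2's prior floor of 0.25, the floor here
is a small regularizer (0.01): when the data themselves indicate
homogeneous dispersion, near-full shrinkage to the trend is exactly what
restores a normal null.  The cost is mild anti-conservativeness if true
dispersions are highly heterogeneous while appearing homogeneous; the
unmoderated estimator remains available (`moderate_dispersion = FALSE`).
Measured null type-I error across seeds: 0.044–0.058 at nominal 0.05
(99% binomial envelope [0.037, 0.063] at 2000 features).

## Conservation

Full six-frame translation of each target genome (stop codons stay in
the translated strings; their substitution penalty confines local
alignments to stop-delimited segments), affine-gap Smith–Waterman with
BLOSUM62, gap open 11, gap extend 1 (a gap of length g costs 11 + g),
and Karlin–Altschul E-values `E = K·m·n·e^(−λS)` with λ = 0.267,
K = 0.041 (the published gapped parameters for this scoring system),
m = query length and n = the total translated target length.  Hits at
E ≤ 1e-3 count as conservation; identity and coverage are reported, not
thresholded; whether a hit begins at a methionine is annotated per hit,
never used as a filter.  There is no word seeding — the full dynamic
program is exact and fast enough for the synthetic genome scale this
package targets (a C++ kernel at ~80 M cells/s).  Tiers are a pure
function of the species hit set: no hits ⇒ human-specific; only primate
hits ⇒ primate-restricted; any rodent hit ⇒ rodent-conserved; otherwise
broad-mammal.

Note a structural detectability floor: with this scoring system a
perfect match of an m-aa peptide scores roughly 5m, so queries shorter
than ~13–15 aa cannot reach E ≤ 1e-3 against a genome-scale search
space regardless of conservation.  Very short smORFs are thus
"human-specific by construction" under any E-value criterion — a
property of the statistic, not of biology.

## The synthetic world

The generators state one world and keep it:

* genome of 2 Mb over 4 chromosomes; 300 transcripts (60%
  protein-coding with CDS and 450–700 nt UTRs, 40% lncRNA), 1–3 exons;
* 150 planted smORFs with context quotas 70% uORF / 22% ncRNA / 7%
  dORF / 1% intergenic (the reported context distribution), lengths
  from `N(l) ∝ e^(−0.02 l)` over 5–150 aa (the reported decay constant),
  amino-acid usage mildly enriched in A/G/P/R; every cassette is
  preceded by an in-frame stop so the planted ATG is the 5'-most of its
  region and enumeration recovers exactly the planted span; intergenic
  smORFs live on "novel" transcripts present in the assembled
  transcriptome but absent from the reference annotation;
* footprints: each smORF is translated in all 4 samples at Poisson
  depth 100, with clean periodicity 0.95 in one designated sample and,
  with probability 0.15, in each further sample; otherwise periodicity
  degrades to 0.5 — enough to defeat the 0.7 score threshold while
  leaving coverage intact.  This is the regime behind the rescue
  reversal: one sample passes the caller, the others fail it, coverage
  rescues them.  Background reads (0.02 per transcript nt, uniform
  frame) supply the untranslated baseline (in-frame fraction ≈ 1/3);
* RNA-seq counts: NB with constant dispersion 0.05, log-normal feature
  means (median 500), 2 conditions × 3 replicates, 10% non-null
  features at |log2FC| = 2;
* orthologs: per-species genomes with back-translated (most-used human
  codons), 5%-diverged copies embedded according to the planted tier
  (primate-restricted ⇒ chimp only; broad-mammal ⇒ all but mouse/rat;
  rodent-conserved ⇒ all; human-specific ⇒ none).

What the generator does **not** emulate: real human sequence
composition, splice-isoform complexity, UMI/duplication artifacts,
nucleotide-level (synonymous-site) conservation — divergence is applied
at the amino-acid level and re-back-translated, which is adequate
because the search is protein-space.  A green test therefore
establishes the pipeline's internal correctness and statistical
calibration, not performance on real libraries.

## Numerical choices and degenerate inputs

* `pme` uses the convention 0·log 0 = 0; a single coding codon gives
  pme = 1; an ORF with zero P-sites scores 0 without error.
* IRLS coefficients are clamped to ±30 (natural log) so an all-zero
  group yields a huge-|β|, huge-SE fit instead of divergence;
  features with all-zero counts are excluded from testing and from the
  BH denominator.
* Size factors error out (with advice to prefilter) when no feature is
  nonzero in every sample.
* Venn partitions enumerate only non-empty subsets; ties in
  nearest-gene distance break toward the lower start coordinate.
* The pipeline's conserve stage searches a deterministic subset of
  smORFs (default 40) to keep a full run in minutes on one CPU; set
  `conservation_subset = Inf` for the complete search.
* The pipeline config file is JSON (no YAML parser is assumed present);
  all thresholds default to the values above.

## Known limitations

Two-group Wald only; ATG starts only; no BAM input (footprints arrive
as BED6+1 or a P-site table); no word-seeded alignment heuristics, so
genome-scale (vertebrate-sized) conservation searches are out of reach;
the dispersion moderation trades a small amount of robustness to
dispersion heterogeneity for calibration at n = 3.
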