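---
title: "Methods: genome-wide NLR annotation with nlrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide NLR annotation with nlrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the decisions we took where the methodology
was genuinely open.

## The annotation problem

Plant NBS-LRR (NLR) resistance genes are numerous, highly clustered,
heavily pseudogenized, and share their nucleotide-binding domain's P-loop
with the (far larger) protein-kinase family. A repertoire survey therefore
chains several analyses, each with its own failure modes: homology search
with a domain model, species-specific refinement of that model, exclusion
of kinases, architecture classification, physical mapping, recovery of
relics that the domain search cannot see, pseudogene diagnosis, and
phylogeny. `run_pipeline()` executes these stages in that order; each stage
is also exported on its own.

## Profile HMM search and E-value calibration

`build_profile()` estimates a Plan7-like profile (match/insert/delete, no
insert↔delete transitions) from a seed alignment. Columns with gap
fraction ≤ 0.5 become match states; emissions and transitions take Laplace
(+1) pseudocounts; the background is the Robinson–Robinson amino-acid
frequency set. `viterbi()` performs local alignment: paths start and end in
a match state, flanking residues are free, entry is uniform over match
states (a `log2(1/M)` charge), and the score is the log2-odds of the best
path. The search screens whole proteins for an internal domain, which is
why the model is local on both axes.

E-values are calibrated empirically rather than taken from an external
search tool: `calibrate_evalue()` fits a Gumbel distribution by maximum
likelihood to the Viterbi scores of `n_null = 1000` i.i.d. background
sequences of length 350 (about the length scale of the searched proteins),
and `E = N · P(S ≥ s)` with `N` the database size. The fit is deterministic
under its seed. This choice makes thresholding reproducible and
monotone-equivalent to tool-reported E-values; the defaults
(`strict_evalue = 1e-60`, `relaxed_evalue = 1e-2`) are the two published
operating points of the two-pass strategy that
`refine_species_model()` implements: strict pass with the seed model,
re-alignment of the strict hits' envelopes, rebuild and recalibration of a
species model, relaxed re-search. When the strict pass yields fewer than
two hits the refinement falls back to the seed model with a warning.

Kinase exclusion (`kinase_filter()`) is a score competition: a candidate is
removed exactly when it scores more bits against the packaged kinase model
than against the NBS model. The packaged kinase seed deliberately shares
the P-loop with the NBS model, reproducing the confounder that motivates
the filter.

## Domain architecture

The four NBS motifs (P-loop, kinase-2, kinase-3a, GLPL) are located with
consensus-derived PSSMs; `find_nbs_subdomains()` selects the
highest-total-score combination of at most one hit per motif that respects
the canonical order without overlap (exhaustive over ≤ 6 candidates per
motif). TIR and LRR domains are PSSM window scans; LRR is called present at
≥ 2 non-overlapping repeat hits. PSSM thresholds default to a fraction
(0.5–0.6) of the maximum attainable score — for motifs of width ≥ 8 this
separates noisy consensus copies from background windows by many standard
deviations of the null score.

Coiled-coils use a Lupas-style 28-residue sliding window over a packaged
heptad propensity table (hydrophobics rewarded at positions a/d, charged
residues at e/g), taking the best of the seven register phases, mapped to a
probability by a logistic centred at 18 (an ideal heptad window scores
about 29.6; random windows score below ~6). The two published decision
thresholds (probability 90 from one predictor, score cut-off 0.025 from a
second validating predictor) map onto one probability scale: segments are
called at `cc_prob_threshold = 0.9` and flagged `validated` when their peak
probability also clears `1 − 0.025`. The full HMM of the first predictor
and the pairwise-correlation model of the second are intentionally not
re-implemented; the decision boundary semantics are preserved at desk
scale.

`assign_architecture()` applies the branch logic: TIR present → TNL/TN; CC
present (no TIR) → CNL/CN; neither → the NBS-signature subscript, where the
signature (`classify_signature()`) is primarily the kinase-2 terminal
residue (W → CC lineage, D → TIR lineage) with the two lineage sub-profile
Viterbi scores as fallback and consistency check. The subscripted codes are
interpreted as that signature, following the classical CNL/TNL signature
literature. Proteins with both CC and TIR resolve to the TIR branch (rarer
and more specific) with a logged conflict flag. NBS model coverage below
`partial_nbs_threshold = 0.5` yields `PARTIAL`; the source methodology
counts genes with "a very small portion" of the domain separately without
quantifying it, so the half-model default is ours and is configurable.

`em_discover_motif()` is a one-occurrence-per-sequence (OOPS) EM with
random restarts, the model class behind the motif-based subdomain
comparisons; its log-likelihood is non-decreasing by construction and the
best of `n_starts = 10` seeded restarts is returned.

## Physical mapping

Coordinates are 1-based inclusive throughout — the native convention of
GFF3, Biostrings and IRanges. We deliberately did not introduce a 0-based
internal layer: in an R package built on 1-based container libraries, a
second convention is where off-by-one errors would come from, not where
they are prevented. All interval arithmetic is tested against worked
examples and brute-force oracles.

`anchor_genes()` places scaffold genes on pseudomolecules; reverse-oriented
scaffolds mirror coordinates (`chr_start = offset + scaffold_length − end +
1`) and flip strands. Clusters are single-linkage chains of genes whose
start-to-start distance is ≤ `cluster_max_gap = 100000` bp. "Cluster" has
no crisp published definition; we adopt 100 kb because that is the
proximity statistic the pseudogene analysis itself reports (>90% of
pseudogenes within 100 kb of another NBS gene), and the threshold is
configurable. Super-clusters chain cluster spans within 500 kb. A gene is
"alone" when its nearest same-chromosome NBS gene is strictly farther than
3 Mb, or when it is the only NBS gene on its chromosome.

Flanking windows follow the published rule: scaffolds with two NBS genes
get a 100 kb flank, three or more get 200 kb, fewer are dropped. The window
is anchored symmetrically on the outermost NBS gene boundaries (the
methodology is silent on the anchor; this is our reading) and clipped to
scaffold bounds. ORFs (ATG-to-stop, ≥ 80 codons, six frames — the
methodology is again silent; these are conventional choices) are screened
against the packaged reference R-protein set by Smith–Waterman with
BLOSUM62, replacing a live database search so calls are reproducible.
Homology requires E ≤ 1e-5 (Karlin–Altschul with published gapped-BLOSUM62
constants), ≥ 30% identity and ≥ 50% reference coverage. An ORF homologous
to an NLR reference with zero NBS-model coverage is "NBS-derived"; with
coverage in (0, 0.5) "partial NBS"; homologous only to non-NLR stress
references, "resistance-like".

## Pseudogene diagnosis

`align_protein_to_dna()` aligns an intact reference protein to candidate
DNA with a dynamic program over (protein position × DNA position): a match
consumes three bases in frame or two/four across a frameshift
(`frameshift_penalty = 12`, about half a doubled gap-opening cost), gaps
are affine and consume whole codons or residues, and in-frame stop codons
score a mismatch floor (−8) and are recorded as events. Alignment is local;
reference coverage is the aligned fraction of the reference.

`call_pseudogene()` shortlists references by shared 4-mers (ties by id,
making calls order-independent), aligns against the top 3, and interprets
the best alignment with the priority **scaffold-end > premature stop >
frameshift > partial deletion > intact**. The priority is ours — the
methodology does not say how genes with multiple lesions were labelled —
and premature stop outranks frameshift because a stop is directly
observable in frame. Scaffold-end requires the gene within 500 bp of a
scaffold terminus with the alignment truncated on that side; partial
deletion requires clean reference coverage below
`coverage_threshold = 0.8`. Transposition and exon-skipping causes are out
of scope (they need transposon libraries and transcript evidence); the
cause vocabulary is extensible.

## Phylogeny

NBS domains are extracted from the P-loop start to the GLPL end plus 30
residues; proteins lacking either motif are excluded, our concrete reading
of "incomplete NBS domains were not included". `progressive_align()` builds
a UPGMA guide tree on shared 3-mer distances (the guide metric is our
choice) and merges profiles by global Needleman–Wunsch (BLOSUM62, gap open
10, extend 0.5; a length-k gap costs `open + (k−1)·extend`). The manual
end-curation step of the original workflow is replaced by an automatic
rule: leading/trailing columns with gap fraction > 0.8 are trimmed
(`trim_alignment_ends()`, configurable).

Distances are pairwise-deletion p-distances (Poisson correction
available). `nj_tree()` is the standard Saitou–Nei agglomeration; the
Q-minimum pair is joined at each step with ties broken by the
lexicographically smallest taxon-label pair, negative branch estimates are
clamped to zero and counted (the convention of the classic desktop
phylogenetics tools). `bootstrap_support()` resamples columns with
replacement (default 500 replicates, the published setting) and scores each
internal bipartition of the full-data tree; taxa are canonically ordered
first so support values do not depend on input order. Clade labels
propagate from reference leaves: each unlabelled leaf takes the label of
its smallest enclosing bipartition side that contains references of exactly
one label, otherwise `unassigned` — a root-free formulation, so no rooting
heuristic can break a clade.

## The synthetic genome: what it emulates, and what it does not

`generate_genome()` emulates the *structure* of a draft plant genome as
seen by an NLR survey: pseudomolecules assembled from anchored scaffolds
(plus deliberately unanchored scaffolds carrying ~16% of the NLRs), genes
of all eight architecture codes at roughly the CNL-dominated proportions of
Solanaceae repertoires (85% CNL-lineage), physical clusters of 2–8 genes
with start-to-start gaps of 8–30 kb, singletons, one chromosome with a lone
NLR, 40% pseudogenes with a premature-stop/frameshift-dominated cause mix
(40/40/15/5%, largest-remainder apportionment), kinase decoys sharing the
P-loop, random background genes, and unannotated near-cluster relics
(NBS-less and partial-NBS NLR copies, plus stress-gene copies). Proteins
are built from packaged consensus blocks: three NBS lineage signatures (two
CC-lineage variants, mirroring the CC(I)/CC(II) split, and one TIR-lineage
variant with the kinase-2 terminal D), an ideal heptad CC block, a TIR
consensus and a plant-type LRR unit. Neutral substitution noise is applied
at the founder (5%) and gene (2%) level *outside* the four NBS motifs and
the CC heptads, reflecting that these are the most conserved residues of
real NLRs and keeping classification signal interpretable.

Two generator policies deserve emphasis. First, lesions are placed
downstream of the NBS block (uniformly over codons from `nbs_end + 15` to
30 codons before the CDS end). Detected pseudogene sets in real surveys are
conditioned on retaining at least a partial NBS domain — a lesion 5' of the
NBS makes the gene invisible to the HMM stage, in simulation as in
reality. `plant_pseudogene()` itself accepts any internal codon; the
restriction is the genome generator's placement policy. Second, the
architecture-accuracy criterion is evaluated on intact genes: a lesion
legitimately changes the observable architecture (a CNL truncated inside
its LRR array *is* observed as CN), so truth-code agreement for lesioned
genes is not a meaningful target; lesioned genes are scored on cause and
breakpoint instead.

What the generator does **not** emulate: realistic intergenic composition,
transposable elements, introns (a fixed-intron option exists but the
packaged conditions use single-exon genes), alternative splicing, GC
heterogeneity, segmental duplications, or assembly error beyond scaffold
truncation. Passing the planted-recovery tests therefore demonstrates that
the pipeline's logic is correct and internally consistent at realistic
signal-to-noise, not that its thresholds are optimal for any particular
real genome.

## Numerical and degenerate-input choices

* Percentages in summary tables round half away from zero
  (`round_half_up()`), matching how published tables print.
* An empty FASTA reads as an empty tibble; an empty record set summarises
  to an all-zero table; a proteome of zero rows searches to zero hits.
* Hit ranking ties break by target id; pseudogene reference ties by
  reference id; NJ ties by taxon-label pair — every ranking in the package
  has a deterministic tie-break, so equal seeds give byte-identical
  outputs.
* e-PCR counts substitutions and indels separately (≤ 3 each per primer, as
  published). Alignments are canonical — an insertion may not directly
  follow a deletion, so an indel pair cannot impersonate a substitution —
  and the primer's first and last bases must pair with template bases (gaps
  strictly internal), the hybridization-sensible convention. Binding
  decisions equal a brute-force edit-distance scan in the tests.
* X residues score as background in all profile scans; ambiguous codons
  translate to X.

## Problem sizes

The packaged study conditions (and the sizes used throughout the tests and
the acceptance script) are: 60 NLR genes across all eight codes, 40 kinase
decoys, 200 background genes, 9 anchored clusters plus unanchored material
on a ~13 Mb genome of 28 scaffolds; E-value calibration at 1000 null
sequences of length 350; 500 bootstrap replicates in the pipeline (100 in
the focused bootstrap tests). A full pipeline run completes in about two
minutes on one CPU.

## Known limitations

* The coiled-coil score is a single-sequence propensity model; it will not
  match specialised coiled-coil predictors on borderline real segments.
* The Gumbel calibration assumes the searched proteins resemble the null's
  composition; strongly biased proteomes would shift E-values (the
  strict/relaxed thresholds would then deserve recalibration).
* The pseudogene caller diagnoses only the four modelled causes; genes
  disabled by transposon insertion or mis-splicing will surface as
  frameshift/deletion calls or as intact.
* The NBS phylogeny uses distance methods; fine-scale topology inside
  clades should not be over-interpreted relative to likelihood methods.
* Published counts from any specific real genome are not reproduced here;
  they depend on that genome's assembly and annotation. The package
  validates the *pathway* on planted truth and reproduces the published
  tables' internal arithmetic.
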