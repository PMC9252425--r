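---
title: "Curation and network analysis of R2R3-MYB families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and network analysis of R2R3-MYB families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mybscope)
```

mybscope implements a complete desk-scale pipeline for the curation and
functional analysis of plant R2R3-MYB transcription-factor families:
repeat detection and domain-integrity rules, representative-isoform
selection and chromosome-ordered naming, motif-based clade
classification, qPCR relative quantification, and tree-ensemble
regulatory-network inference with GO enrichment. Every stage can be
exercised on synthetic inputs with planted ground truth, so the whole
pipeline is testable without any external download. This vignette
explains the models, the tunable parameters, and the design choices.

## The R2R3 domain model

Plant R2R3-MYB proteins carry two tandem MYB repeats (R2 and R3), each
folding into three α-helices. The package represents the domain in a
fixed 105-position coordinate system (`canonical_template()`): R2 spans
positions 1–52, R3 spans 53–105. Five landmark tryptophans anchor the
hydrophobic core at positions 6, 26 and 46 (R2) and 78 and 97 (R3).
Thirteen further residues are modeled as conserved (E10, D11, L14, G22,
C42, R43, R45, E63, G75, A82, R88, K94, N95), together with the leucine
insertion at position 35 and the four-residue LRPD linker between the
repeats. In plants the first R3 tryptophan slot is typically occupied by
phenylalanine or isoleucine instead of tryptophan; the slot position is
not fixed by convention, so the template places it at position 58 (in R3
helix 1, between the linker and the landmark at 78) and makes it
configurable, as is the linker offset (default 50–53, immediately after
the last R2 landmark). The F/I slot never counts toward the five-landmark
tryptophan census.

### Repeat detection

`scan_repeats()` is a windowed, no-indel log-odds scan: every window of
profile length is scored as $\sum_p \log_2 f_p(x)/b(x)$ and
non-overlapping hits above a bit-score threshold are selected greedily
(higher score first, then smaller start). Hits closer together than
`min_gap` or farther apart than `max_gap` (defaults 0 and 20 residues)
split into separate repeat groups; the repeat count of the largest group
determines the MYB class (1 repeat = MYB-related, 2 = R2R3, 3 = 3R,
4+ = 4R).

A gapless fixed-width scan is sufficient here because all downstream
rules operate on fixed landmark coordinates anchored at the detected R2
start; domains with internal insertions or deletions (rare in real
families, and excluded from logo representations for the same reason)
are outside the recall scope of this scanner, and a profile-HMM scanner
should be used upstream when they matter.

The default threshold of 50 bits was calibrated on the synthetic null:
random sequences of matched composition score far below it (window score
means around −60 bits with standard deviation ≈ 10 under a
template-derived profile), while an intact repeat scores well above 100
bits even at a 5% substitution rate, and a repeat missing a 10–20 residue
internal block cannot reach it (an intact run of about 30 aligned
positions would be needed). The test suite verifies a < 5% false-positive
rate over seeded random draws.

### Integrity rules

`integrity_filter()` encodes the curation rule used for family
membership: a sequence fails if fewer than two full-length repeats are
found (`incomplete_repeat`), or if more than two of the five landmark
tryptophans are lost (`tryptophan_deficient`). The boundary is
deliberately asymmetric: three matched landmarks pass, two fail. Whether
a compliant F or I at the R3 first slot should be treated as a "missing
tryptophan" is not decidable from the curation rule as usually stated;
the package excludes that slot from the census (the five landmarks are
exactly 6/26/46/78/97), and the choice is documented here rather than
silently assumed.

### Logo statistics

`compute_logo()` reports per-column information content
$IC = \log_2 20 - H$ (bits) with letter heights $f \cdot IC$, dropping
columns above a gap fraction (default 0.5). The optional small-sample
correction subtracts the expected entropy bias $19/(2 n \ln 2)$; IC is
clamped at zero so disabling the correction never lowers a column.

## Synthetic data: what it emulates, what it does not

The generators produce every input the pipeline consumes, each with a
truth table enumerating exactly the generated entities:

* `simulate_family()` embeds the template domain in random flanks
  (uniform 10–80 residues per side) with seeded point substitutions that
  never touch constrained positions, plus four decoy classes mirroring
  discarded sequence categories: R2-only fragments, internally truncated
  repeats, tryptophan-deficient domains (three landmarks mutated to
  alanine), and triple-repeat architectures. Unconstrained template
  positions are drawn from the 19 non-tryptophan residues so that
  tryptophan remains the distinctive, rare landmark residue — in real MYB
  alignments W outside the landmark columns is exceptional, and this
  choice keeps the landmark columns identifiable in census analyses.
  Truncated-repeat decoys delete a central block so that neither
  remaining intact run can carry a full-window hit.
* `simulate_gene_models()` generates multi-isoform gene models on the
  fourteen wheat-style chromosomes plus the unanchored set "U", flagging
  for a seeded fraction of genes an incomplete-domain longest isoform so
  that the second-longest rule has something to do.
* `simulate_qpcr()` builds three biological × three technical replicates
  per condition; the stressed Ct of a target is shifted by
  $-\log_2(\text{fold})$ and Gaussian measurement noise (default SD 0.1
  cycles) enters through the target measurements. The reference gene is
  generated noise-free: it stands for a stability-selected internal
  anchor, and this idealization is what makes fold recovery within 10%
  at 0.1-cycle noise a guaranteed property rather than a coin flip
  (with noise also on the reference, the ΔΔCt standard error grows from
  0.047 to 0.067 cycles and ~5% of seeds would miss the 10% band).
* `simulate_grn_expression()` draws TF abundances i.i.d. log-normal and
  builds each non-TF gene as a linear (or hinge) function of its
  regulators plus noise scaled to a fraction of the signal spread
  (default 0.3); TPM columns are normalized to $10^6$ and counts are
  Poisson draws around the abundances.
* `simulate_go_annotation()` plants exactly one enriched category;
  all others are annotated at random.

None of these emulate real data complexity — no indels in domains, no
correlated TF programs, no batch structure, no overdispersion beyond
Poisson. Passing tests therefore demonstrate correctness of the
*methods* under their stated assumptions, not performance on real
genomes.

## Curation conventions

Representative isoforms follow the longest/second-longest rule: the
longest CDS is kept if its domain passes the integrity filter, otherwise
the next-longest passing isoform; genes with no passing isoform keep the
longest and inherit its class. Equal lengths break by mRNA identifier.

Naming (`assign_names()`) orders genomes A, then B, then unanchored U;
chromosomes 1–7 within a genome; genes by representative start
coordinate within a chromosome. Whether real curations order
within-chromosome genes by coordinate or by annotation identifier is
usually unstated; coordinate order is used here, and U genes — whose
coordinates are not assumed reliable — order by gene identifier after
all placed genes. The ordinal is global, so a 233-gene family runs from
`TdMYB1A001` to `TdMYBU233`.

Molecular weight uses average (not monoisotopic) residue masses plus one
water, the convention of the standard pI/Mw web tools; the isoelectric
point solves for zero net charge under the Bjellqvist pK set by
bisection on pH ∈ [0, 14] (≤ 60 iterations, |charge| < 1e-4), which a
brute-force 1e-4-step grid scan confirms to 1e-3 in the tests.

Protein→genome mapping multiplies the span by three, walks the exon
chain in transcription order (reverse for minus strand), and splits at
exon boundaries; interval lengths always sum to three times the protein
span, and a reverse-complement translation round trip is tested.

## Motifs and clades

Motif presence uses a PWM log-odds scan with the threshold expressed as
a fraction of the attainable score range (`min + f·(max − min)`,
default f = 0.8). Expressing the threshold on the range rather than as a
bare multiple of the maximum keeps the two degenerate ends meaningful —
f = 0 accepts everything, f = 1 demands the perfect consensus — because
log-odds scores of non-matching windows are negative. The default is
calibrated so random sequences are called present in well under 5% of
draws.

The Poaceae clade rules are a pure function of six presence bits,
applied in priority order: PS1 ∧ motif-12 ∧ ¬PS2 → Poaceae-specific
group A; PS1 ∧ PS2 ∧ ¬motif-12 → group B; PS3 → Poaceae-unique;
PS4 ∧ PS5 → Poaceae-basal; otherwise unclassified. On real data the
rule sets are disjoint and the priority is inert; it only guards
degenerate inputs. Known single-sequence exceptions in published trees
are data annotations, not rule branches — classification stays
motif-driven and identifiers can be pinned via an override table by the
caller.

`compare_motifs()` reports the mean column-wise Pearson correlation of
probability vectors over the best ungapped offset alignment (minimum
overlap: half the shorter motif). Whether published motif–motif
correlations were computed between matrices or between occurrence
patterns is often ambiguous; the occurrence-level phi coefficient is
therefore exposed separately as `presence_correlation()`, so both views
are checkable against a presence/absence supplement. The shipped
`synthetic_ps_motifs()` are random-consensus stand-ins for
demonstration and testing — they are not the published motif models.

Subfamily assignment walks each query leaf rootward to the smallest
clade containing an annotated reference and takes the majority reference
subgroup, with ties reported as `"ambiguous"` rather than guessed.

## Expression

`delta_delta_ct()` averages technical replicates within biological
replicates, forms ΔCt against the reference gene per biological
replicate, and reports $2^{-\Delta\Delta Ct}$ stressed vs control with a
two-sample Student's t test **on the ΔCt values** (standard Livak
practice; testing on the fold scale is not equivalent) at tiers
p < 0.1, 0.05, 0.01. The fold-scale spread is the fold equivalent of the
ΔΔCt standard error, $rel \cdot (2^{se} - 1)$. Conditions with no
detected Ct set the status: activation from a silent control baseline is
`not_quantifiable` (a ratio against nothing is undefined), silence in
both conditions is `not_expressed`.

The matrix filters are strict and boundary-tested: genes are expressed
when TPM > 5 in at least one sample (exactly 5 everywhere drops the
gene); study arms need ≥ 3 biological replicates, judged per
(study, condition) group. Display summaries average replicate TPMs
*before* the log2(x + 1) transform.

`differential_expression()` is a deliberate stand-in, not a
dispersion-shrinkage method: median-of-ratios size factors, Welch t on
log2(normalized + 1), Benjamini–Hochberg adjustment, with the call
requiring |log2FC| strictly above 1 *and* adjusted p < 0.05. Its output
columns match what a DESeq2 results table provides, so a proper
dispersion-modeled table can be substituted wherever the output is
consumed.

## Network inference and enrichment

`infer_network()` implements the GENIE3 scheme with ranger random
forests: per target, expression is standardized to unit variance and
predicted from all regulators (self excluded) by an ensemble of
regression trees (bootstrap resampling, random candidate subsets at
each split, variance-reduction splitting); a regulator's edge weight is
its impurity importance. Defaults are 100 trees and the square-root
candidate rule, the usual GENIE3 configuration; no parameters beyond
these are assumed. TPM input is the default analysis choice, with the
matrix type left to the caller. Samples are put into a canonical order
internally (per-gene rank keys) before fitting, so a seeded run is
exactly invariant to the column order of the input — a property a
bootstrap RNG tied to sample positions would otherwise break.

`prune_top_edges()` keeps the top k edges (default 16,000) with
deterministic lexicographic tie-breaks, making top-k sets nested in k;
`extract_subnetwork()` restricts to query regulators and reports
out-degrees, including zeros for query TFs that retained no edges after
pruning — an expected outcome, not an error.

`go_enrichment()` tests hypergeometric upper tails over categories with
10–1,000 annotated genes. Family-wise error control is by permutation:
random query sets of equal size define the null distribution of the
minimum p-value, and the adjusted p is the permutation fraction with the
(1 + count)/(1 + B) convention — the +1 keeps the permutation p-value
valid (it can never be zero), at the price of a slightly conservative
floor of 1/(B + 1). Bonferroni is available as a fast deterministic
fallback. Hypergeometric p-values are verified against exhaustive
enumeration on universes of ≤ 20 genes.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at desk scale, chosen to
exercise every property comfortably on one CPU: families of 100–200
members for census and classification properties; 1,000 simulated qPCR
tables for the null type-I calibration; planted networks of 200 genes ×
20 TFs × 100 samples across ten seeds for the noisy-recovery bound
(AUPR ≥ 5× the random baseline; a 20-gene zero-noise network checks
perfect recovery); and 100 seeded null runs for the GO FWER calibration.

## Known limitations

* The repeat scanner is gapless; indel-bearing domains are not
  recovered.
* The DE test has no dispersion shrinkage and is anti-conservative for
  low counts relative to negative-binomial methods.
* The permutation FWER floor is 1/(B + 1); very small adjusted p-values
  require large B.
* Motif discovery is consumed, not performed: motifs enter as matrices
  (TSV or MEME minimal text).
* The synthetic generators share none of the linkage disequilibrium,
  paralogy or batch structure of real wheat data; genome-scale counts
  (family sizes, edge counts) are not reproduced at desk scale.
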