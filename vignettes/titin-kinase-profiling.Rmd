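---
title: "Profiling the titin pseudokinase region: similarity maps, signature motifs and structure comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the titin pseudokinase region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titinkinase)
```

## Scientific background

Titin kinase (TK) is the single signalling domain of the giant sarcomeric
protein titin: a vertebrate pseudokinase flanked by an N-terminal linker
(NL, ~33 residues) and a C-terminal regulatory domain (CRD) that packs
against the kinase and plugs its active site. Its pseudokinase character is
written into a small set of sequence motifs: a bulky hydrophobic residue
(θ ∈ {M, L, I, F}) in position 1 of the β3 AxK motif (θxK, typically MAK),
a glutamate in place of the canonical DFG aspartate (ExG), the presence or
absence of a putatively inhibitory P+1-loop tyrosine, and — in the flanking
tails — an [N/L]YD anchor motif in the NL, and in the CRD an
[R/K]H[R/K]RYY motif (helix αR1), an R-7x-R motif (helix αR2) and a small
residue at position −2 of the latter that packs into the ATP pocket against
the θ residue, completing the catalytic spine in lieu of ATP. The θ and −2
residues co-vary by volume compensation: bulky θ with small −2 in
pseudokinase TKs, small θ (A) with large −2 (L/I) in active relatives such
as twitchin kinase.

Teleost fish carry two titin gene copies (*ttna*, *ttnb*) from the teleost
genome duplication. Clustering TK-region sequences by pairwise similarity
separates them into isoform and clade groups and lets unannotated fish
titin genes be classified by nearest labelled anchors (e.g. the annotated
zebrafish *ttna*/*ttnb*). This package implements that pipeline end to end:
curation, pairwise alignment, similarity-map embedding, anchored
classification, reference-anchored motif extraction and quantification,
covariation, crystal-structure comparison, and a seeded simulator that
generates families with known truth so every stage is testable without
external downloads.

## Pairwise alignment and the similarity map

All pairwise scores come from global alignment with affine gaps
(substitution table: BLOSUM62 with the ambiguity code X zeroed; gap open
10, gap extend 0.5 per position; a gap of length L costs
`open + extend * L`). Terminal gaps are free in the standard ends-free
sense — at most one sequence leaves residues unaligned at each end — which
suits domain-region sequences whose database trimming differs. Percent
identity is counted over columns where both sequences place a residue; X
never counts as identical. Because the identity convention behind published
identity matrices is rarely stated, values computed here can differ from
printed ones by a point or two; comparisons in this package use a ±1.5
percentage-point tolerance.

The similarity map normalizes raw scores into correlation-like
coefficients,

$$ r_{ij} = \frac{s_{ij}}{\sqrt{s_{ii}\,s_{jj}}}, \qquad r_{ii} = 1 , $$

and embeds sequences by the spectral decomposition of \(r\):
\(x_i(d) = \sqrt{\lambda_d}\, v_d(i)\) over the top-\(k\) positive
eigenvalues, so that \(x_i \cdot x_j \approx r_{ij}\). Dimensions are
ordered by eigenvalue: dimension 1 carries the signal shared by all
sequences, and each later dimension a successively less prominent axis of
divergence — which is what makes the *order* of splits interpretable (an
isoform split appearing in an earlier dimension than the clade split means
isoform divergence is the larger effect). An optional quasi-Newton
least-squares refinement of \(\sum_{i \le j} (x_i\cdot x_j - r_{ij})^2\)
(unit diagonal included) is available and is only accepted when it does not
increase the error; the default is the pure spectral solution, which is
deterministic and keeps dimensions eigen-aligned.

Numerical conventions: eigenvector signs are fixed by making the
largest-magnitude coordinate of each dimension positive; labelled anchors
re-orient the isoform/clade dimensions afterwards (isoform *a* below zero,
*b* above; neoteleostei below zero). If anchors of one label straddle zero
the dimension does not separate that label and an error is raised rather
than a silent call. Fewer than \(k\) positive eigenvalues yields the
achievable dimensions plus a warning flag. `k = 4` is the default: with the
mammalian outgroup included, the leading non-shared dimensions carry the
mammal–fish, isoform and clade contrasts.

Classification offers two methods. *sign-quadrant* reads isoform from the
sign of dimension 2 and clade from dimension 3 (the fish-only layout);
*nearest-centroid* (default, required once mammals are included and five
clusters exist) assigns each sequence to the nearest anchor-defined
centroid in dimensions 2..k, ignoring the shared-signal dimension 1.

## Curation

`curate_sequences()` applies, in order: keyword exclusion on descriptions
(case-insensitive; defaults `"myosin light chain kinase"`,
`"LOW_QUALITY"`), exact-duplicate removal on residue strings (first
occurrence kept; near-duplicates are retained since no similarity threshold
is defined for "made unique"), and partial-sequence removal. "Full kinase
region" is operationalized as coverage of all kinase-domain anchors of the
reference annotation (glycine-rich loop through the P+1 loop) by the
query-to-reference column map. The report tallies each removal class and
the counts always sum to the input size; curation is idempotent.

## Reference annotations and motif extraction

Two reference annotations ship with the package: the medaka TKb frame
(residue 1 = M27887 of the parent entry; default) and the human TK frame
(offset −15 over the kinase domain, so the catalytic aspartate is D144 and
the P+1 tyrosine Y187). **The shipped reference sequences are synthetic
stand-ins** — random backgrounds with every annotated anchor residue or
motif implanted at its literature position — because the real sequences are
database depositions; only the coordinate frames and anchor layout carry
meaning, which is all that anchored extraction needs.

`map_columns()` aligns a query to the reference once and maps every
reference position to a query position or gap. A query is declared
unmappable when alignment identity falls below 25% *or* fewer than 50
columns align: under ends-free alignment an unrelated sequence can reach
high identity over a handful of spuriously matched columns, so the identity
floor alone is not a sufficient guard.

`extract_signature()` reads anchored fields off mapped columns (glycine
loop window, θ residue, ExG slot, P+1 residue, −2 fallback) and finds
pattern fields by scanning the mapped NL and CRD windows: `[N/L]YD`,
`[R/K]H[R/K]RYY` and `R.{7}R` (first match kept and the number of matches
reported). Position −2 is the residue two before the first R-7x-R arginine,
falling back to the anchored column when the pattern is absent. Residue
classes are fixed sets, configurable per call: bulky {M, L, I, F}, small
{G, A, S, T}, large {L, I, V, M, F} — valine deliberately excluded from
"small" so that the rare V at position −2 is counted separately. The
glycine-loop call is template matching at the anchored window over
GxGxxG / RxGxxG / Ax[C/S]xxG (ties resolved toward the canonical form),
reporting both the best template and the literal 6-mer. Absence of a motif
is a value (`"none"`); an uncovered anchor is `NA` and excluded from
frequency denominators with the exclusion count reported.

The θ/−2 covariation is summarized as a 2×2 contingency (θ bulky vs not ×
−2 small vs not) with a Haldane-corrected odds ratio and the association
coefficient \(\sqrt{\chi^2/n}\) (the φ coefficient, in [0, 1]). An empty
margin — e.g. a pure TK set where every θ is bulky — makes the association
undefined and is flagged rather than reported as 0 or 1.

## Structure comparison

Coordinates are parsed with bio3d (PDB or mmCIF); when alternate locations
are present the highest-occupancy conformer is kept. Superposition is the
least-squares rigid-body solution via the SVD construction with a
reflection guard (det U = +1 always, also on mirrored inputs). When no
correspondence is supplied, chains are paired by sequence-aligning their
Cα sequences and taking all aligned columns with Cα present in both — no
outlier trimming, matching the "all overlapping Cα atoms" convention of
published RMSDs. rmsd² equals the mean squared per-pair deviation by
construction, and per-residue deviations are reported in correspondence
order.

Two conventions are config-exposed because the literature does not define
them: the "lateral group" distance between charged residues defaults to the
*terminal-charged-atoms* rule (e.g. lysine NZ to the nearer glutamate
carboxylate oxygen), with *closest-heavy-sidechain* as the alternative; and
when a residue pair exists in several chain copies of one asymmetric unit
the result is aggregated as mean ± half-range across copies. Spine
contiguity uses the minimum side-chain heavy-atom distance between
consecutive spine residues with a 5.5 Å default cutoff (a common
van-der-Waals contact allowance), and optionally reports the C-spine
completion contact of the CRD −2 residue against the θ column.

## The synthetic-data generator

`simulate_families()` emulates the five-group TK family — mammal, plus fish
isoforms a/b × neoteleostei/non-neoteleostei — with known truth:

* The root is the reference frame with non-anchor positions substituted at
  `root_divergence = 0.35`. Tips then sit at roughly 45–56% identity to the
  reference, inside the range real vertebrate TK sequences span against a
  single annotated frame (57–96% in published matrices); a fully random
  background would place families near the mapping floor and is not what
  the real data look like.
* Branch rates: `class_split = 0.25` (root → mammal/fish),
  `isoform_split = 0.15`, `clade_split = 0.06`, `tip = 0.03` per site.
  The isoform rate deliberately exceeds the clade rate, reproducing the
  observed hierarchy in which gene copies within an organism differ more
  than the same copy across fish groups — so the isoform split must appear
  in an earlier embedding dimension than the clade split.
* The clade substitution set is drawn once per clade and applied to both
  isoform lineages. This mirrors the observed map geometry, where a single
  dimension separates fish groups for *both* isoforms simultaneously; with
  independent per-copy clade mutations the two clade contrasts would need
  two dimensions and the weaker one would fall outside k = 4.
* Anchor columns are overwritten per group from motif tables whose default
  probabilities are the published per-cluster percentages (θ = M at
  98.5/98.9/100/40/77.4% across mammal and fish groups, remainder split
  L:I:F = 8.7:0.6:2.6; DxG at 17.6/6.7% in fish a; P+1 tyrosine at
  96.4/28.6/46.7% and absent in isoform b; −2 position 76.8% A, 15.2% S/T,
  4.8% G, 1.5% V, rare E/Q, renormalized; NYD vs LYD at 73.8/26.2%; loop
  templates GxGxxG for mammals and isoform b, RxGxxG for non-neoteleostei
  a, Ax[C/S]xxG for neoteleostei a). Mutation acts only on non-anchor
  sites, and the NL/CRD windows are kept free of residues that could form
  spurious motif matches, so implanted frequencies are exactly recoverable
  by extraction — the recovery tests then measure only sampling noise,
  checked against exact binomial intervals.
* Substitutions draw replacements from a uniform background over the 20
  residues (configurable in principle but kept uniform so analytic
  expectations stay simple). There is no indel process by default
  (anchored columns stay aligned); an optional `indel_rate` inserts or
  deletes at non-anchor sites to stress the column mapping. A
  `truncation_fraction` cuts sequences mid-kinase to exercise
  partial-sequence curation.

What the generator does **not** emulate: realistic substitution matrices
and rate heterogeneity across sites, phylogenetic structure within groups
(all group members are i.i.d. around one ancestor), composition bias, and
real NL/CRD length variation. Passing the closure tests therefore shows the
pipeline recovers planted structure of the kind the real data exhibit; it
does not certify performance on real families whose divergence patterns are
messier.

`simulate_structure_pair()` builds a random-walk Cα trace (3.8 Å steps),
applies a random rigid transform plus isotropic Gaussian coordinate noise
σ, and reports the expected post-superposition RMSD
\(\sigma\sqrt{3(1 - 2/n)}\) — the 2/n term accounting for the six fitted
rigid-body parameters; a Monte-Carlo check confirms the formula is
unbiased.

## Study sizes and determinism

The package's chosen study sizes are: 10 sequences per group (50 per
replicate) for embedding/classification studies, 20 seeded replicates for
closure properties, and 400 per group for motif-frequency recovery (where
binomial intervals need tight widths). Every stochastic routine takes an
explicit seed and restores the caller's RNG state; the same seed yields
byte-identical FASTA output.

## Known limitations

* The shipped reference sequences are synthetic; mapping real sequences
  should use the real deposited reference regions in the same frames.
* Identity values depend on the alignment convention (±1–2 points against
  published matrices whose aligner and denominator are unstated).
* The embedding is fit to the normalized coefficients with unit diagonal;
  whether published maps used raw or bit-normalized scores before the
  correlation transform is not recoverable, so exact third-party numeric
  output is out of scope — the package reproduces the geometry (cluster
  structure, dimension ordering), not coordinates.
* Sign-quadrant classification is fish-only by construction; use
  nearest-centroid when mammals are included.
* `spine_check` evaluates contiguity in the listed residue order and does
  not search for alternative spine paths.

## A worked pass over simulated data

```{r pipeline, eval = FALSE}
sim <- simulate_families(sim_config(seed = 1))
cur <- curate_sequences(sim$set, reference = ref_medakaTKb())
emb <- embed_similarity(build_similarity(cur$set), k = 4)
first <- sim$truth[!duplicated(sim$truth$group), ]
anchors <- data.frame(id = first$id, isoform = first$isoform,
                      clade = ifelse(first$taxon_class == "mammal",
                                     "mammal", first$fish_clade))
cl <- classify_sequences(emb, anchors)
table(cl$assignments$cluster, sim$truth$group)

sigs <- lapply(cur$set$records, extract_signature, ref = ref_medakaTKb())
head(group_frequencies(sigs, sim$truth$group))
```
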