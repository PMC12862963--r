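# titinkinase

Sequence and structure profiling of the titin kinase (TK) region of
vertebrate titins — the N-terminal linker (NL), the pseudokinase domain and
the C-terminal regulatory domain (CRD).

## What it is for

Titin kinase is a conserved vertebrate pseudokinase: its catalytic motifs
deviate from active kinases (a bulky hydrophobic θ residue in the β3 θxK
motif instead of the canonical small A/V, an ExG slot instead of DFG), and
its flanking tails carry a small set of strongly conserved motifs — the NL
[N/L]YD anchor, the CRD [R/K]H[R/K]RYY and R-7x-R motifs, and a small
residue at position −2 of R-7x-R that packs into the ATP pocket against the
θ residue and completes the catalytic spine. Teleost fish carry two titin
gene copies (*ttna*/*ttnb*), and clustering TK-region sequences separates
isoforms and fish clades, so the TK domain serves as a proxy for classifying
whole titin genes.

The package implements that analysis for people working on sarcomeric
kinases or titin gene annotation:

* **Curation** of TK-region FASTA sets (keyword exclusion, deduplication,
  partial-sequence removal by reference-anchor coverage).
* **Pairwise similarity maps**: global alignment scores s_ij are normalized
  to correlation-like coefficients r_ij = s_ij / √(s_ii·s_jj) and embedded
  by spectral decomposition, x_i(d) = √λ_d · v_d(i), so dot products
  reproduce r and dimension order ranks the prominence of divergences.
* **Anchored classification** of sequences into isoform/clade clusters from
  labelled anchors (sign-quadrant or nearest-centroid).
* **Motif extraction and quantification**: reference-anchored reads of the
  glycine-rich loop, θxK, ExG, P+1, [N/L]YD, [R/K]H[R/K]RYY, R-7x-R and
  position −2; per-group frequency tables; θ/−2 covariation (odds ratio and
  φ association).
* **Structure comparison**: PDB/mmCIF parsing, Kabsch superposition with
  reflection guard, per-residue Cα deviations, functional-group distances
  (e.g. the K68–E83 salt-bridge gap reporting the open αC conformation),
  and catalytic/regulatory spine contiguity.
* **A seeded simulator** of five-group TK families (mammal + fish a/b ×
  neoteleostei/non-neoteleostei) with implanted motif frequencies and known
  truth, plus rigid-body structure pairs with noise — so the whole pipeline
  is testable offline.

## Worked example

```r
library(titinkinase)

sim <- simulate_families(sim_config(seed = 1))   # 5 groups x 10 sequences
emb <- embed_similarity(build_similarity(sim$set), k = 4)
#> Similarity-map embedding: 50 sequences, 4 dimensions
#>   eigenvalues: 30.987, 6.806, 6.174, 2.611

first <- sim$truth[!duplicated(sim$truth$group), ]
anchors <- data.frame(id = first$id, isoform = first$isoform,
                      clade = ifelse(first$taxon_class == "mammal",
                                     "mammal", first$fish_clade))
cl <- classify_sequences(emb, anchors)           # nearest-centroid
mean(cl$assignments$cluster == sim$truth$group)
#> [1] 1
```

Eigenvalue 1 (31.0) is the signal shared by all 50 sequences; the next
dimensions carry the mammal–fish, isoform and clade contrasts in decreasing
order of divergence, and every sequence lands in its true cluster.

```r
extract_signature(ref_medakaTKb()$record, ref_medakaTKb())
#> TK signature (medTKb_synthetic_ref)
#>   gly loop GAGSSG [GxGxxG]  beta3 theta M (bulky)  DFG slot ELG
#>   P+1 A  NL [N/L]YD NYD  alphaR1 RHRRYY  -2 A (small)

sigs <- lapply(sim$set$records, extract_signature, ref = ref_medakaTKb())
tab <- group_frequencies(sigs, sim$truth$group)
subset(tab, feature == "theta_residue" & value == "M")
#>                    group value  n pct
#>                   mammal     M 10 100
#>      fish_a_neoteleostei     M 10 100
#>  fish_a_non-neoteleostei     M  2  20
#>      fish_b_neoteleostei     M 10 100
#>  fish_b_non-neoteleostei     M  7  70
```

The θ-position methionine is near-fixed in mammals, neoteleostei and
isoform b, and depleted in non-neoteleostei isoform a — the per-group
pattern the generator implants (at n = 10 per group the small groups are
noisy; the recovery tests use n = 400).

```r
pair <- simulate_structure_pair(seed = 1, n_points = 500, noise_sigma = 0.5)
superpose(pair$a, pair$b)
#> Superposition: 500 pairs, RMSD 0.904 A
pair$expected_rmsd
#> [1] 0.864...  # sigma * sqrt(3 * (1 - 2/n))
```

## Documentation

The methods vignette (`vignettes/titin-kinase-profiling.Rmd`) describes the
model and conventions: the scoring scheme and ends-free alignment, the
spectral embedding and its sign/orientation rules, motif extraction windows
and residue classes, structure-comparison conventions, the simulator's
design and what it does and does not emulate, and known limitations.
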