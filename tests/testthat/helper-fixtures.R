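# Shared fixtures built in code at test time.

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# Default anchor table for a simulated five-group family: the first
# sequence of every group, labelled with the generator truth.
sim_anchor_table <- function(truth) {
  first <- truth[!duplicated(truth$group) & !truth$truncated, ]
  data.frame(id = first$id,
             isoform = first$isoform,
             clade = ifelse(first$taxon_class == "mammal", "mammal",
                            first$fish_clade),
             stringsAsFactors = FALSE)
}

# Embedding dimension most correlated with a binary labelling.
dominant_dim <- function(X, labels) {
  v <- as.numeric(factor(labels))
  which.max(abs(suppressWarnings(apply(X, 2, stats::cor, y = v))))
}

# Adjusted Rand index between a predicted and a true partition
# (independent implementation used for cluster-recovery checks).
ari <- function(pred, truth) {
  mclust::adjustedRandIndex(pred, truth)
}

# Minimal signature stand-in for covariation tests.
fake_signature <- function(theta_class, minus2_class) {
  structure(list(theta_class = theta_class, minus2_class = minus2_class),
            class = "tk_signature")
}

# A small alanine-like residue with a side chain, for synthetic models.
res_atom_rows <- function(chain, resno, resid, atoms_xyz) {
  do.call(rbind, lapply(names(atoms_xyz), function(el) {
    p <- atoms_xyz[[el]]
    data.frame(chain = chain, resno = resno, insert = "", resid = resid,
               elety = el, x = p[1], y = p[2], z = p[3], o = 1,
               is_polymer = TRUE, stringsAsFactors = FALSE)
  }))
}
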