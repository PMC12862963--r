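# Deposited inputs (not redistributed)

The published-value benchmark tests in
`tests/testthat/test-acceptance.R` compare package output against values
obtained from third-party deposited data. Those files are not
redistributed here; to run the comparisons, place in this directory:

- `XP_023806503_27887-28241.fasta` — medaka ttnb TK region (NL + kinase +
  CRD), residues 27887-28241 of NCBI entry XP_023806503.
- `Q8WZ42_32150-32491.fasta` — human titin TK region, residues
  32150-32491 of UniProtKB Q8WZ42.
- `9qj2.pdb`, `6ygn.pdb` — PDB coordinate entries.
- `tk_sequences_labelled.fasta` — curated TK-region sequence set with
  `class=`/`clade=`/`isoform=` header tags (or a sidecar TSV).

Without these files the corresponding tests report the missing inputs and
fail; all synthetic-data checks are independent of them.
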