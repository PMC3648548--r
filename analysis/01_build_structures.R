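#!/usr/bin/env Rscript
# Step 1 — study structures.
#
# The analysis runs on a synthetic C5-symmetric pore pentamer whose contact
# topology is known exactly; when the deposited coordinates (4F8H wild-type
# GLIC, 4IRE NQN mutant, 2BG9 muscle nAChR) have been supplied by the user
# (see allopath::find_structure), later steps pick them up automatically.
# Writes the synthetic structures and their ground-truth networks under
# results/.

suppressPackageStartupMessages(library(allopath))
dir.create("results/structures", showWarnings = FALSE, recursive = TRUE)

fx <- make_pore_pentamer()
write_structure(fx$model, "results/structures/pore_pentamer.pdb",
                remarks = "synthetic C5 pore pentamer; gate residue 11")
cat("pore pentamer:", nrow(fx$model$residues), "residues,",
    sum(fx$n_true) / 2, "ground-truth contacts\n")

ring <- make_fixture("ring_pentamer", n_residues_per_chain = 20)
write_structure(ring$model, "results/structures/ring_pentamer.pdb",
                remarks = "synthetic C5 ring pentamer")

for (id in c("4f8h", "4ire", "2bg9")) {
  f <- find_structure(id)
  cat(sprintf("deposited %s: %s\n", toupper(id),
              if (is.na(f)) "not supplied" else f))
}
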