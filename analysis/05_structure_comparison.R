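#!/usr/bin/env Rscript
# Step 5 — structure superposition and the nAChR cross-check.
#
# When the deposited files are supplied: Kabsch-superposes the NQN mutant
# (4IRE) onto wild-type GLIC (4F8H) on C-alpha atoms (mutated positions
# paired by number), and repeats the path protocol on the muscle-type nAChR
# (2BG9) from the agonist-binding residues of the alpha1 subunit to the 9'
# gate L251. Without them, demonstrates the superposition utility on a
# rigidly displaced copy of the synthetic pentamer.

suppressPackageStartupMessages(library(allopath))

f_wt <- find_structure("4f8h"); f_mut <- find_structure("4ire")
if (!is.na(f_wt) && !is.na(f_mut)) {
  wt <- read_structure(f_wt, chains = LETTERS[1:5])
  mut <- read_structure(f_mut, chains = LETTERS[1:5])
  rmsd <- superpose_rmsd(wt, mut, atom_names = "CA", allow_mutations = TRUE)
  cat(sprintf("CA RMSD, NQN mutant vs wild type: %.2f A\n", rmsd))
} else {
  fx <- make_pore_pentamer()
  mv <- fx$model
  xy <- cbind(-mv$atoms$y, mv$atoms$x)
  mv$atoms$x <- xy[, 1] + 30; mv$atoms$y <- xy[, 2]; mv$atoms$z <- mv$atoms$z - 5
  cat(sprintf("rigidly moved synthetic copy, recovered RMSD: %.2e A\n",
              superpose_rmsd(fx$model, mv)))
}

f_n <- find_structure("2bg9")
if (!is.na(f_n)) {
  model <- read_structure(f_n)
  tm <- build_transition_model(count_contacts(model))
  p1 <- yen_k_shortest(tm, "A:190", "A:251", k = 1)
  cat("nAChR alpha1 Y190 -> L251 rank-1 path:\n ", p1$nodes, "\n")
  cat("chains on path:",
      unique(tm$residues$chain[p1$node_index[[1]]]), "\n")
} else {
  cat("2BG9 not supplied; nAChR cross-check skipped\n")
}
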