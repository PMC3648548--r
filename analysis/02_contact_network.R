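#!/usr/bin/env Rscript
# Step 2 — residue contact network and Markov transmission model.
#
# Counts heavy-atom contacts at the 4.5 A cutoff, row-normalizes into the
# transition matrix, and reports connectivity plus the equilibrium
# distribution (which depends only on contact degrees). Uses the deposited
# GLIC structure when supplied, the synthetic pentamer otherwise.

suppressPackageStartupMessages(library(allopath))
dir.create("results", showWarnings = FALSE)

f <- find_structure("4f8h")
if (!is.na(f)) {
  model <- read_structure(f, chains = LETTERS[1:5])
} else {
  model <- read_structure("results/structures/pore_pentamer.pdb")
}
cat("structure:", model$source_id, "-", nrow(model$residues), "residues\n")

net <- count_contacts(model, cutoff = 4.5)
tm <- build_transition_model(net, diagonal_mode = "zero")
print(net)

conn <- connectivity_report(tm)
cat("connected components:", conn$n_components, "\n")

pi_eq <- equilibrium_distribution(tm)
top <- order(pi_eq, decreasing = TRUE)[1:5]
cat("highest-degree residues (equilibrium mass):\n")
print(data.frame(key = tm$residues$key[top], pi = round(pi_eq[top], 4)))

export_network(tm, "results/network_counts.tsv", which = "n")
export_network(tm, "results/network_M.tsv", which = "M")
cat("wrote results/network_counts.tsv, results/network_M.tsv\n")
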