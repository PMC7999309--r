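#!/usr/bin/env Rscript
# Step 5 — network-based cytokine inference.
#
# Interactions are kept above a 0.4 combined score (strict), cytokines
# need at least five connections to significantly altered proteins to be
# eligible, and each eligible cytokine is scored by the class-normalized
# double ratio e_d = (k_d / T_d) / (k_total / T_total); the
# fold-connection ratio e_case / e_control summarizes its leaning toward
# case-associated proteins. The decorated network (proteins sized by
# |pi|, colored by pro-/anti-inflammatory cytokine contact) is exported
# for Cytoscape.

library(cytopi)

net <- read_network("results/simulated/network.tsv")
diff_tab <- read.delim("results/differential/differential_table.tsv")

filtered <- filter_edges(net, min_score = 0.4)
sig <- diff_tab[diff_tab$class_label != "not_significant",
                c("protein_id", "class_label")]
enr <- enrichment_scores(filtered, sig)
dec <- decorate_network(filtered, diff_tab, enr)

dir.create("results/cytokines", showWarnings = FALSE, recursive = TRUE)
write.table(enr, "results/cytokines/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_decorated_network(dec,
                        graphml_path = "results/cytokines/network.graphml",
                        sif_path = "results/cytokines/network.sif",
                        node_attr_path = "results/cytokines/node_attributes.tsv")

cat(nrow(filtered), "of", nrow(net), "edges pass the score filter\n")
cat(nrow(enr), "cytokines eligible (>= 5 connections to significant proteins)\n")
cat("top cytokines by fold-connection to case-associated proteins:\n")
print(head(enr, 5))
planted <- c("IL6", "TNF", "IL10")
cat("planted cytokines with fold > 1:",
    sum(enr$fold_connection[enr$cytokine %in% planted] > 1), "of 3\n")
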