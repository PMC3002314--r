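#!/usr/bin/env Rscript
# Filter candidate miRNA-target pairs: a pair is kept when the target mRNA
# shows a significant negative regression on the miRNA (p < 1e-4) across
# the shared samples.  Candidates here are all pairs of differentially
# expressed miRNAs and mRNAs (standing in for a sequence-predicted list).

library(gbmnet)

seed <- 1L
study <- sim_study(default_study_config(seed))
dir.create("results", showWarnings = FALSE)

de_mrna <- de_analysis(study$mrna, study$groups_mrna)
de_mirna <- de_analysis(study$mirna, study$groups_mirna)
cand <- expand.grid(mirna = de_mirna$feature[de_mirna$significant],
                    mrna = de_mrna$feature[de_mrna$significant],
                    stringsAsFactors = FALSE)
targets <- filter_targets(cand, study$mrna, study$mirna, p_threshold = 1e-4)
write.table(targets, "results/mirna_targets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

acc <- targets[targets$accepted, ]
cat(sprintf("%d of %d candidate pairs accepted (negative slope, p < 1e-4)\n",
            nrow(acc), nrow(targets)))
print(acc[order(acc$p), c("mirna", "mrna", "coefficient", "p", "r_squared")],
      row.names = FALSE)
planted <- paste(study$truth$targets$mirna, study$truth$targets$mrna)
cat(sprintf("Planted repressive pairs recovered: %d of %d\n",
            sum(planted %in% paste(acc$mirna, acc$mrna)), length(planted)))

# combined regulation graph: directed arcs + coexpression edges
mrna_net <- build_network(select_lambda(standardize(
  study$mrna[, study$groups_mrna == "tumor"]))$fit)
net <- target_network(targets, mrna_net = mrna_net)
cat(sprintf("Combined target network: %d nodes, %d arcs, %d edges\n",
            igraph::vcount(net), sum(igraph::E(net)$arc),
            sum(!igraph::E(net)$arc)))
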