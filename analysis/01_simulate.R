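#!/usr/bin/env Rscript
# Generate the synthetic multi-omic study all downstream analyses run on:
# mutation events for 179 tumor/normal pairs over a 306-gene panel, mRNA
# and miRNA expression with known coexpression structure, planted
# differential expression, repressive miRNA-target pairs, mutation-dosage
# eQTL effects (one triangle regulation cycle) and survival times.
# The seed fixes every draw; rerunning reproduces the data byte for byte.

library(gbmnet)

seed <- 1L
config <- default_study_config(seed)
study <- sim_study(config)
files <- write_sim_data(study, "results/data")

cat("Synthetic study written to results/data:\n")
cat(sprintf("  %d tumor / %d normal mutation samples, %d genes\n",
            nrow(study$muts$tumor_events), nrow(study$muts$normal_events),
            length(study$muts$gene_ids)))
cat(sprintf("  mRNA: %d features x %d samples; miRNA: %d x %d\n",
            nrow(study$mrna), ncol(study$mrna),
            nrow(study$mirna), ncol(study$mirna)))
cat(sprintf("  planted: %d burden genes, %d mRNA edges, %d miRNA edges,\n",
            length(study$truth$burden$effect_genes),
            nrow(study$truth$mrna_edges), nrow(study$truth$mirna_edges)))
cat(sprintf("  %d repressive target pairs, %d eQTL effects, survival HR %.2f on %s\n",
            nrow(study$truth$targets), nrow(study$truth$eqtl),
            exp(study$truth$survival$log_hazard),
            names(study$truth$survival$log_hazard)))
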