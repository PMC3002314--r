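#!/usr/bin/env Rscript
# Group-regression eQTL mapping: regress each expression feature on the
# mutated-allele burden of each disease-associated gene (trans declared at
# alpha / #genes, cis at unadjusted 0.05), then search for triangle
# regulation cycles: a mutation gene that regulates both an mRNA and a
# miRNA, where that miRNA also represses that mRNA.

library(gbmnet)

seed <- 1L
study <- sim_study(default_study_config(seed))
dir.create("results", showWarnings = FALSE)

assoc <- test_all_genes(study$muts, mode = "T_a")
hits <- assoc$gene[assoc$fdr < 0.05]
cat("Burden-associated genes scanned as eQTL:",
    paste(hits, collapse = ", "), "\n")

sub <- mutation_dataset(study$muts$tumor_events[, hits, drop = FALSE],
                        study$muts$normal_events[, hits, drop = FALSE],
                        study$muts$tumor_hom[, hits, drop = FALSE],
                        study$muts$normal_hom[, hits, drop = FALSE])
sc_m <- scan_eqtl(sub, study$mrna, "mRNA")
sc_mi <- scan_eqtl(sub, study$mirna, "miRNA")
eqtl <- rbind(sc_m, sc_mi)
write.table(eqtl, "results/eqtl.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- eqtl[eqtl$significant, ]
cat(sprintf("Significant eQTL: %d (trans threshold %.3g over %d genes)\n",
            nrow(sig), attr(sc_m, "trans_threshold"), length(hits)))
print(sig[, c("mutation_gene", "target", "coefficient", "p", "r_squared",
              "fold_change", "locality")], row.names = FALSE)

de_mrna <- de_analysis(study$mrna, study$groups_mrna)
de_mirna <- de_analysis(study$mirna, study$groups_mirna)
cand <- expand.grid(mirna = de_mirna$feature[de_mirna$significant],
                    mrna = de_mrna$feature[de_mrna$significant],
                    stringsAsFactors = FALSE)
targets <- filter_targets(cand, study$mrna, study$mirna, 1e-4)

tri <- find_triangles(sc_m, sc_mi, targets)
write.table(tri, "results/triangles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\n%d triangle regulation cycle(s) found:\n", nrow(tri)))
print(tri[, c("mutation_gene", "mrna", "mirna")], row.names = FALSE)
cat("Planted cycle: ", study$truth$eqtl$gene[1], "->",
    study$truth$eqtl$target[1], "and", study$truth$eqtl$target[2], "\n")
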