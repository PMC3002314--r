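#!/usr/bin/env Rscript
# Rank coexpression-network nodes by damage value: the size of a node's
# connected component minus the largest component left after removing the
# node.  High-damage nodes hold the network together; their perturbation
# fragments it.

library(gbmnet)

seed <- 1L
study <- sim_study(default_study_config(seed))
dir.create("results", showWarnings = FALSE)

rank_net <- function(expr, groups, label) {
  tum <- expr[, groups == "tumor", drop = FALSE]
  net <- build_network(select_lambda(standardize(tum))$fit)
  dmg <- rank_by_damage(net)
  cat(sprintf("%s network: top damage values\n", label))
  print(head(dmg, 5), row.names = FALSE)
  cbind(kind = label, dmg)
}
dmg <- rbind(rank_net(study$mrna, study$groups_mrna, "mrna"),
             rank_net(study$mirna, study$groups_mirna, "mirna"))
write.table(dmg, "results/damage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top <- dmg[dmg$damage > 1, ]
cat(sprintf("%d of %d nodes are cut vertices (damage > 1)\n",
            nrow(top), nrow(dmg)))
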