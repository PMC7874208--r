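#!/usr/bin/env Rscript
# Group-level statistics on the standard recordings: per-cycle genotype
# contrasts with Benjamini-Hochberg correction (wild type vs each mutant),
# the omnibus two-way ANOVA, and the normality screen of the per-larva
# values. Writes results/group_stats.csv and results/normality.csv.

library(vsrquant)

m <- read.csv("results/cycles_standard.csv")
m$genotype <- sub("_[0-9]+$", "", m$larva_id)
tabs <- split(m, m$larva_id)
genos <- vapply(tabs, function(tb) tb$genotype[1], character(1))

stats_rows <- list()
for (mut in setdiff(unique(genos), "wildtype")) {
  keep <- genos %in% c("wildtype", mut)
  gt <- group_table(tabs[keep], genos[keep])
  for (metric in unique(gt$metric)) {
    s <- compare_groups(gt, metric)
    n_sig <- sum(s$per_cycle$q_bh < 0.05)
    message(sprintf("wildtype vs %-8s %-22s F_genotype=%8.2f  sig cycles %2d/%d",
                    mut, metric, s$omnibus$F[1], n_sig, nrow(s$per_cycle)))
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      comparison = paste0("wildtype_vs_", mut), metric = metric,
      s$per_cycle[, c("cycle_index", "p_raw", "q_bh", "stars")],
      F_genotype = s$omnibus$F[1], p_genotype = s$omnibus$p[1])
  }
}
write.csv(do.call(rbind, stats_rows), "results/group_stats.csv", row.names = FALSE)

# normality screen of per-larva mean normalized integrals per genotype
ret <- m[!m$excluded, ]
per_larva <- aggregate(normalized_integral_deg ~ larva_id + genotype,
                       data = ret, FUN = mean)
screen <- normality_screen(split(per_larva$normalized_integral_deg,
                                 per_larva$genotype))
print(screen, row.names = FALSE)
write.csv(screen, "results/normality.csv", row.names = FALSE)
message("wrote results/group_stats.csv and results/normality.csv")
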