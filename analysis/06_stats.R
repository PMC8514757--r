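#!/usr/bin/env Rscript
# Cross-model statistics: collapse the experiment manifest into per-VT
# match states and 2x2 tables per contrast, with Fisher's exact p-values.

library(vtgrad)

man <- read.csv("results/experiment/manifest.csv", stringsAsFactors = FALSE)
man$pathway_match <- as.logical(man$pathway_match)
man$exit_site_match <- as.logical(man$exit_site_match)

summ <- build_match_matrix(man, contrasts = list(c("baseline", "ab_tm")))
print(summ)
write_comparison_csv(summ, "results/match_states.csv")

rows <- do.call(rbind, lapply(names(summ), function(nm) {
  do.call(rbind, lapply(names(summ[[nm]]$tables), function(what) {
    tb <- summ[[nm]]$tables[[what]]
    data.frame(contrast = nm, quantity = what,
               a = tb[1, 1], b = tb[1, 2], c = tb[2, 1], d = tb[2, 2],
               fisher_p = summ[[nm]]$p_values[[what]])
  }))
}))
write.csv(rows, "results/match_tables.csv", row.names = FALSE)
print(rows)
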