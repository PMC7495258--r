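#!/usr/bin/env Rscript
# Validity screening of the simulated pump records: how many carry a
# patient ID that maps to the registry and a drug-library medication name
# (the quadrant table), and what the invalid IDs look like.

library(pumpconcord)

cohort <- read_cohort("results/synthetic")
screen <- screen_sprs(cohort$sprs, cohort$registry, cohort$drug_library)
tab1 <- quadrant_table(screen)

write.csv(tab1, "results/validity_quadrants.csv", row.names = FALSE)
cat_tab <- sort(table(screen$invalid_category), decreasing = TRUE)
write.csv(data.frame(category = names(cat_tab), n = as.integer(cat_tab)),
          "results/invalid_id_categories.csv", row.names = FALSE)

message("screened ", nrow(screen), " pump records")
print(as.data.frame(tab1))
message("usable for linkage (ID+ and name+): ", tab1$n[1], " (",
        tab1$pct[1], "%)")
message("invalid-ID categories:")
print(cat_tab)
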