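#!/usr/bin/env Rscript
# Stage 4: weighted promiscuity index over the bundled synthetic coupling
# tables (three dataset dialects; values invented, see
# inst/extdata/README_extdata.txt).

suppressMessages(library(stcontacts))
dir.create("results", showWarnings = FALSE)

path <- function(f) system.file("extdata", f, package = "stcontacts")
avet <- read_coupling_table(path("synthetic_coupling_avet.csv"), "AVET")
gtp <- read_coupling_table(path("synthetic_coupling_gtp.csv"), "GTP")
inoue <- read_coupling_table(path("synthetic_coupling_inoue.csv"), "INOUE")

idx <- promiscuity_index(list(avet, gtp, inoue))
write.table(idx, "results/promiscuity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Weighted promiscuity index (AVET x4, GTP x2, INOUE x1; composite in\n")
cat("[0, 4], higher = broader coupling across Gs/Gi/Gq/G12-13):\n\n")
print(idx, row.names = FALSE, digits = 3)
cat("\nWrote results/promiscuity.tsv\n")
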