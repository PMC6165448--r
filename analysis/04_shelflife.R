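#!/usr/bin/env Rscript
# Step 4 -- shelf-life monitoring over three weeks of refrigerated
# storage.
#
# For every class and band: a quadratic storage-time trend with its
# Spearman goodness of fit (|r| > 0.2 acceptance), and a one-way scan
# across sampling days reporting significance and direction of change.
# The drifted bands (triglyceride ester 1744 and C-O 1170-1154 down,
# amides 1627/1541 down, olefinic 3100-3020 down, methyl/methylene
# 2950-2920/2852 up, fatty-acid C-H 1117 up, trans marker 966 up after
# day 10) should dominate the accepted list.
#
# Reads results/bands.csv; writes results/trends.csv and
# results/day_scan.csv.

suppressPackageStartupMessages(library(hamqa))
bands <- utils::read.csv("results/bands.csv", check.names = FALSE)

out <- shelflife(bands, variables = ftir_bands()$band)

out$trends$c0 <- signif(out$trends$c0, 5)
out$trends$c1 <- signif(out$trends$c1, 5)
out$trends$c2 <- signif(out$trends$c2, 5)
out$trends$spearman_r <- round(out$trends$spearman_r, 3)
utils::write.csv(out$trends, "results/trends.csv", row.names = FALSE)
utils::write.csv(out$scan, "results/day_scan.csv", row.names = FALSE)

message("accepted trends per class (|spearman r| > 0.2):")
print(table(out$trends$class, out$trends$accepted))

message("significant day effects and their directions:")
sig <- out$scan[out$scan$significant, c("class", "variable", "direction")]
print(table(sig$variable, sig$direction))
message("wrote results/trends.csv and results/day_scan.csv")
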