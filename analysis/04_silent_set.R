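#!/usr/bin/env Rscript
# Analytical prediction of homeostatically trapped silent states: points in
# the conductance plane where the voltage and calcium equations are both
# quenched at the calcium target, with branch stability checked by direct
# simulation.
#
# Writes results/silent_set.csv

suppressPackageStartupMessages(library(calreg))
dir.create("results", showWarnings = FALSE)

ref <- reference_model()
tg <- reference_targets(ref)

# wide calcium-axis extent: trapped silence needs a large window current
pw <- plane_def(ref)
pw$ylim <- c(0.1, 20) * pw$y_ref

ss <- silent_set(pw, tg$Ca_target, resolution = 40)
cat(sprintf("silent set: %d points; calcium-axis range %.1fx - %.1fx\n",
            nrow(ss), min(ss$y) / pw$y_ref, max(ss$y) / pw$y_ref))

ss <- label_silent_branches(ss, pw, tg$Ca_target)
print(table(ss$branch))

# the depolarised branch, ordered along the calcium axis, shows a single
# stable -> unstable transition (destabilisation of the quiescent state)
branch <- ss[ss$V_V > -30, ]
branch <- branch[order(branch$y), ]
cat("depolarised-branch labels along y:",
    paste(rle(branch$branch)$values, collapse = " -> "), "\n")

write.csv(data.frame(
  x = ss$x, y = ss$y, x_rel = ss$x / pw$x_ref, y_rel = ss$y / pw$y_ref,
  V_V = ss$V_V, V_Ca = ss$V_Ca, mismatch = ss$mismatch,
  dIdV = ss$dIdV, branch = ss$branch
), "results/silent_set.csv", row.names = FALSE)
cat("wrote results/silent_set.csv\n")
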