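#!/usr/bin/env Rscript
# Plane maps on the calcium/non-calcium projection: the calcium level set,
# the acute four-state map, the basins of attraction under regulation, and
# the four-way robustness segmentation.
#
# Writes results/plane_{level_set,acute,basin,segmentation}.csv

suppressPackageStartupMessages(library(calreg))
dir.create("results", showWarnings = FALSE)

ref <- reference_model()
tg <- reference_targets(ref)
reg <- regulation_state(ref, Ca_target = tg$Ca_target)
pl <- plane_def(ref) # x: non-calcium channels, y: CaS + CaT

cat("adaptive calcium level set...\n")
ca_field <- plane_calcium_field(pl)
lev <- adaptive_level_set(ca_field, pl, target = tg$Ca_target,
                          budget = 150, seed = 3)
write.csv(lev$level_set, "results/plane_level_set.csv", row.names = FALSE)
cat(sprintf("  %d samples, %d segments, %d diagonal crossing(s)\n",
            lev$n_evals, nrow(lev$level_set),
            diagonal_crossings(lev, field = ca_field)))

cat("acute (no-regulation) state map...\n")
acute <- basin_map(plane_acute_field(pl, tg$cfg), pl, budget = 120, seed = 4)
write.csv(acute$points, "results/plane_acute.csv", row.names = FALSE)
print(table(acute$points$label))

cat("basins of attraction under regulation (slow)...\n")
bas <- basin_map(plane_basin_field(pl, reg, tg$cfg), pl, budget = 70,
                 seed = 5)
write.csv(bas$points, "results/plane_basin.csv", row.names = FALSE)
print(table(bas$points$label))

# segmentation on the basin-map sample points, pairing each with the acute
# label at the same location
acute_at <- vapply(seq_len(nrow(bas$points)), function(k) {
  basin_label_at(acute, bas$points$x[k], bas$points$y[k])
}, character(1))
seg <- data.frame(bas$points,
                  acute = acute_at,
                  segment = segment_robustness(acute_at, bas$points$label))
write.csv(seg, "results/plane_segmentation.csv", row.names = FALSE)
print(table(seg$segment))

# diagonal containment: size perturbations return to the canonical state
diag_scales <- c(0.2, 0.6, 1, 1.4, 2)
diag_lab <- vapply(diag_scales, function(s) {
  recovery_experiment(with_gbar(ref, ref$gbar * s), reg, tg$cfg)$state_label
}, character(1))
cat("diagonal points:", paste(diag_scales, diag_lab, sep = ":", collapse = " "), "\n")
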