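#!/usr/bin/env Rscript
# Step 2: stability diagrams in the (N_Cdc42, N_GAPs) plane for the wild type
# and the Bem1 deletion, the critical GAP/Cdc42 threshold of the latent
# (Bem1-independent) mechanism, and its shift under a global GEF-activity
# boost. Requires results/reference_params.json from 01_screen.R.

library(cdc42rd)

cfg <- load_config("results/reference_params.json")
ref <- cfg$parameters
geom <- cfg$geometry
anchors <- cfg$copy_numbers
an <- unclass(anchors)

n_grid <- 20L
ax_c <- log_axis(an[["N_Cdc42"]] / 10, an[["N_Cdc42"]] * 10, n_grid)
ax_g <- log_axis(an[["N_GAPs"]] / 10, an[["N_GAPs"]] * 10, n_grid)

message("scanning ", n_grid, "x", n_grid, " copy-number grids")
dWT <- stability_diagram(ref, ax_c, ax_g, anchors, geom, "WT", l_max = 16)
dB1 <- stability_diagram(ref, ax_c, ax_g, anchors, geom, "bem1_delta",
                         l_max = 16)
nWT <- sum(dWT$cells$class == "laterally_unstable")
nB1 <- sum(dB1$cells$class == "laterally_unstable")
message("unstable (spontaneously polarizing) cells: WT ", nWT,
        ", bem1-delta ", nB1,
        " - the Bem1-less regime is ", round(nWT / max(nB1, 1), 1),
        "x smaller")

th <- critical_gap_threshold(ref, an[["N_Cdc42"]], anchors, geom,
                             scenario = "bem1_delta",
                             bracket = c(0.6 * an[["N_GAPs"]],
                                         20 * an[["N_GAPs"]]), l_max = 16)
message(sprintf(
  "critical GAP copy number at N_Cdc42 = %d: %.0f (GAP/Cdc42 ratio %.3f)",
  an[["N_Cdc42"]], th$N_GAPs_crit, th$N_GAPs_crit / an[["N_Cdc42"]]))
message(sprintf("the 25%% Bem3 share (%.0f -> %.0f) %s the threshold",
                an[["N_GAPs"]], 0.75 * an[["N_GAPs"]],
                if (th$N_GAPs_crit > 0.75 * an[["N_GAPs"]] &&
                    th$N_GAPs_crit < an[["N_GAPs"]]) "crosses"
                else "does not cross"))

boosts <- c(1, 2, 5)
th_boost <- vapply(boosts, function(b) {
  critical_gap_threshold(ref, an[["N_Cdc42"]], anchors, geom,
                         scenario = c("bem1_delta", "gef_boost"),
                         knobs = list(gef_boost_factor = b),
                         bracket = c(0.5 * an[["N_GAPs"]],
                                     30 * an[["N_GAPs"]]),
                         l_max = 16)$N_GAPs_crit
}, numeric(1))
message("GEF-boost ladder (x1, x2, x5) raises the threshold to: ",
        paste(round(th_boost), collapse = ", "))

write_outputs(list(
  diagram_wt = dWT,
  diagram_bem1_delta = dB1,
  thresholds = data.frame(gef_boost = boosts, N_GAPs_crit = th_boost,
                          ratio = th_boost / an[["N_Cdc42"]])),
  "results", config = cfg)
message("wrote results/diagram_wt.csv, results/diagram_bem1_delta.csv, ",
        "results/thresholds.csv")
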