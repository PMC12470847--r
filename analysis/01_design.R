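#!/usr/bin/env Rscript
# Stimulus design: build the aperture sequence for one pRF mapping run and
# tabulate its timing arithmetic. Writes results/design_summary.csv and
# results/aperture_annotation.csv.

suppressPackageStartupMessages(library(prfadapt))
dir.create("results", showWarnings = FALSE)

grid <- field_grid(7.5, 0.25)
ap <- build_run_apertures(grid = grid)
d <- ap$design

summary <- data.frame(
  quantity = c("reference_sf_cpd", "run_volumes", "run_duration_s",
               "mapping_volumes", "bar_frames", "blank_volumes",
               "bar_width_deg", "bar_centre_travel_deg",
               "aperture_radius_deg", "wedge_full_width_deg"),
  value = c(geometric_mean_sf(0.5, 3.5), d$n_total, d$n_total * d$tr,
            d$n_mapping, sum(colSums(ap$frames) > 0),
            length(d$blank_after) * d$blank_len,
            d$bar_width, (d$n_bar_steps - 1) * d$bar_width / 2,
            ap$geom$aperture_radius, ap$geom$wedge_full_width))
write.csv(summary, "results/design_summary.csv", row.names = FALSE)
write.csv(data.frame(volume = seq_along(ap$annotation),
                     annotation = ap$annotation),
          "results/aperture_annotation.csv", row.names = FALSE)

cat("One mapping run:", d$n_total, "volumes at TR", d$tr, "s =",
    d$n_total * d$tr, "s (5 min 30 s);", d$n_mapping,
    "mapping volumes of which", sum(colSums(ap$frames) > 0),
    "carry a bar.\n")
cat("Mid-SF mapping/reference stimulus:",
    round(geometric_mean_sf(0.5, 3.5), 2),
    "cpd, the geometric mean of the 0.5 and 3.5 cpd adapters.\n")
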