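#!/usr/bin/env Rscript
# Step 1: build the synthetic inventory panel.
#
# Emulates a provincial permanent-plot inventory: 1712 plots, seven surveys
# at 5-year intervals (1989-2019), each survey's composition the noisy NDES
# image of the previous one under the 2014-2019 reference parameters, and a
# third of the plots relocated between surveys (so they cannot be paired
# across that period). Writes the panel, the species map, and Table-1-style
# dominance tallies.

suppressPackageStartupMessages(library(ndes))
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(n_plots = 1712, n_surveys = 7, start_year = 1989,
                        drop_fraction = 1 / 3, seed = 20240801)
panel <- generate_panel(cfg)
write_plot_table(panel, "results/synthetic_panel.csv")
write_species_map(species_group_map(), "results/species_groups.yaml")

years <- sort(unique(panel$year))
tallies <- do.call(rbind, lapply(seq_len(length(years) - 1), function(i) {
  p <- pair_surveys(panel, c(years[i], years[i + 1]))
  tal <- tally_dominant_groups(p, "former")
  data.frame(period = paste(years[i], years[i + 1], sep = "-"),
             pine = tal$counts["pine"], fir = tal$counts["fir"],
             broadleaf = tal$counts["broadleaf"], total = tal$total,
             ties = tal$ties, excluded = sum(attr(p, "exclusions")))
}))
rownames(tallies) <- NULL
write.csv(tallies, "results/dominance_tallies.csv", row.names = FALSE)

cat("Synthetic panel:", length(unique(panel$plot_id)), "distinct plots over",
    length(years), "surveys,", nrow(panel), "survey records.\n")
cat("Paired plots and former-survey dominance per period:\n")
print(tallies, row.names = FALSE)
cat("\nWith a one-third relocation rate roughly two-thirds of the panel is\n",
    "pairable in each period, matching the structure of a real inventory\n",
    "in which relocated plots drop out of the paired analysis.\n", sep = "")
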