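#!/usr/bin/env Rscript
# Generate the synthetic study system: a shelf-sea climate scenario pair
# (baseline 1985 vs two 2050 warming scenarios of +0.77 C and +1.27 C mean
# SST), four virtual species (two "threatened", two "commercial") with known
# environmental envelopes, presence-only occurrence records sampled from
# those envelopes, six synthetic protected-area polygons, and a pipeline
# config. Everything downstream reads these files.
#
# Usage: Rscript analysis/01_fixtures.R [seed] [outdir]

suppressMessages(library(seashift))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
outdir <- if (length(args) >= 2) args[2] else "results/demo_data"

cfg_path <- make_demo(outdir, seed = seed)
cfg <- yaml::read_yaml(cfg_path)

occ <- read_occurrences(cfg$occurrences)
cat("Wrote", outdir, "\n")
cat("  config:          ", cfg_path, "\n")
cat("  occurrence rows: ", nrow(occ), "across",
    length(unique(occ$species)), "species\n")
cat("  protected areas: ", length(read_polygons(cfg$protected_areas)), "\n")
cat("  climate scenarios:", paste(cfg$future_periods, collapse = ", "), "\n")
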